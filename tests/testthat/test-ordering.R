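test_that("Strahler base cases follow the order-increment rule", {
  # single edge
  g <- random_tree_graph(1, seed = 1)$graph
  expect_equal(assign_strahler(g)$edges$strahler_order, 1L)
  # two order-1 daughters -> parent order 2
  g <- vesselmorph:::new_skeleton_graph(
    data.frame(id = 1:4, row = c(0, 10, 20, 20), col = c(0, 0, -5, 5),
               degree = 0L, landmark = c("root", rep("junction", 3)),
               flagged = FALSE),
    data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4), length = 10,
               mean_diameter = 5, strahler_order = NA_integer_,
               diam_flag = FALSE),
    setNames(list(rbind(c(0, 0), c(10, 0)), rbind(c(10, 0), c(20, -5)),
                  rbind(c(10, 0), c(20, 5))), c("1", "2", "3")),
    list(), dims = c(30L, 30L), rooted = TRUE, roots = 1L)
  g <- vesselmorph:::refresh_degrees(g)
  ord <- assign_strahler(g)$edges$strahler_order
  expect_equal(ord, c(2L, 1L, 1L))
  # daughters (2, 1) -> parent stays 2: extend daughter 3 into two leaves
  g2 <- g
  g2$nodes <- rbind(g2$nodes,
                    data.frame(id = 5:6, row = 30, col = c(-10, 0),
                               degree = 0L, landmark = "junction",
                               flagged = FALSE))
  g2$edges <- rbind(g2$edges,
                    data.frame(id = 4:5, from = 3, to = 5:6, length = 10,
                               mean_diameter = 4,
                               strahler_order = NA_integer_,
                               diam_flag = FALSE))
  g2$paths[["4"]] <- rbind(c(20, -5), c(30, -10))
  g2$paths[["5"]] <- rbind(c(20, -5), c(30, 0))
  g2 <- vesselmorph:::refresh_degrees(g2)
  ord <- assign_strahler(g2)$edges
  expect_equal(ord$strahler_order[ord$id == 1], 2L)  # (2,1) daughters
  expect_equal(ord$strahler_order[ord$id == 2], 2L)
})

test_that("edge orders equal a brute-force post-order recursion on 200 random trees", {
  for (k in 1:200) {
    n <- sample(1:63, 1)
    rt <- random_tree_graph(n, seed = 5000 + k)
    g <- assign_strahler(rt$graph)
    oracle <- brute_strahler(rt$parent)
    got <- g$edges$strahler_order[order(g$edges$to)]
    expect_identical(got, unname(oracle$edge_order[-1]))
  }
})

test_that("Strahler bound and monotonicity hold on random trees", {
  for (k in 1:50) {
    n <- sample(3:63, 1)
    rt <- random_tree_graph(n, seed = 9000 + k)
    g <- assign_strahler(rt$graph)
    n_term <- sum(!(g$edges$to %in% g$edges$from))
    expect_lte(max(g$edges$strahler_order), floor(log2(n_term)) + 1)
    # order never increases from parent edge to daughter edge
    for (i in seq_len(nrow(g$edges))) {
      outs <- g$edges$strahler_order[g$edges$from == g$edges$to[i]]
      if (length(outs))
        expect_true(all(outs <= g$edges$strahler_order[i]))
    }
  }
})

test_that("junction classification is a pure function of daughter orders", {
  expect_equal(as.character(classify_junction(c(1, 1))), "bifurcation")
  expect_equal(as.character(classify_junction(c(2, 1))), "branching")
  expect_equal(as.character(classify_junction(c(3, 3))), "bifurcation")
  expect_error(classify_junction(1L), ">= 2 daughters")
  # > 2 daughters: classified on the two largest-diameter daughters
  cls <- classify_junction(c(1, 2, 2), daughter_diameters = c(1, 5, 4))
  expect_equal(as.character(cls), "bifurcation")
  expect_true(attr(cls, "flagged"))
  for (k in 1:100) {
    o <- sample(1:5, 2, replace = TRUE)
    expect_equal(as.character(classify_junction(o)),
                 if (o[1] == o[2]) "bifurcation" else "branching")
  }
})

test_that("an X of two strokes resolves into two independent paths", {
  mk <- function(a, r0, c0) stroke_spec(a, length = 200, diameter = 7,
                                        start = c(r0, c0),
                                        disc = disc_geometry(c(150, 20), 40))
  disc <- disc_geometry(c(120, 16), 40)
  for (half in c(20.5, 44)) {      # 41 and 88 degree crossings
    s1 <- mk(half, 120.3, 15.2); s2 <- mk(-half + 1, 190.7, 15.8)
    mask <- render_tree(list(s1, s2), 380, 380)
    g <- build_graph(skeletonize(mask))
    g <- prune_spurs(estimate_diameters(mask, g))
    g <- root_components(g, disc, max_dist_dd = 10)
    len0 <- sum(g$edges$length)
    g2 <- resolve_crossings(g)
    # two pass-through vessels, no junction left
    expect_equal(nrow(g2$edges), 2)
    expect_equal(sum(g2$nodes$degree >= 3), 0)
    # total skeleton length conserved (paths re-paired, not deleted)
    expect_equal(sum(g2$edges$length), len0, tolerance = 0.05)
    # continuity pairing: each resolved path stays nearly straight
    for (eid in g2$edges$id) {
      p <- g2$paths[[as.character(eid)]]
      chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
      expect_gt(chord / vesselmorph:::polyline_length(p), 0.97)
    }
  }
})

test_that("graphs without degree-4 nodes pass crossing resolution unchanged", {
  specs <- arcade_pair(21)
  mask <- render_tree(specs, 560, 560)
  g <- root_components(prune_spurs(estimate_diameters(
    mask, build_graph(skeletonize(mask)))), std_disc())
  g2 <- resolve_crossings(g)
  expect_equal(nrow(g2$edges), nrow(g$edges))
  expect_equal(sort(g2$edges$length), sort(g$edges$length))
})
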