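test_that("a straight line becomes two endpoints and one edge", {
  m <- matrix(FALSE, 10, 40); m[5, 3:37] <- TRUE
  g <- build_graph(m)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_setequal(g$nodes$landmark, "endpoint")
  expect_equal(g$edges$length, 34, tolerance = 0.01)
})

test_that("a Y shape gives three endpoints, one junction, three edges", {
  y <- matrix(FALSE, 40, 40)
  y[30:39, 20] <- TRUE
  for (i in 0:10) { y[30 - i, 20 - i] <- TRUE; y[30 - i, 20 + i] <- TRUE }
  g <- build_graph(y)
  expect_equal(nrow(g$edges), 3)
  expect_equal(sum(g$nodes$landmark == "junction"), 1)
  expect_equal(sum(g$nodes$landmark == "endpoint"), 3)
  expect_equal(g$nodes$degree[g$nodes$landmark == "junction"], 3)
})

test_that("every skeleton pixel is covered once by node clusters or edge interiors", {
  specs <- arcade_pair(3)
  s <- skeletonize(render_tree(specs, 560, 560))
  g <- build_graph(s)
  n_interior <- sum(vapply(g$paths, function(p) nrow(p) - 2L, integer(1)))
  n_cluster <- sum(vapply(g$node_pixels, nrow, integer(1)))
  expect_equal(n_interior + n_cluster, sum(s))
})

test_that("edge geometry invariants hold on a synthetic forest", {
  specs <- arcade_pair(7)
  mask <- render_tree(specs, 560, 560)
  g <- build_graph(skeletonize(mask))
  g <- estimate_diameters(mask, g)
  for (i in seq_len(nrow(g$edges))) {
    p <- g$paths[[as.character(g$edges$id[i])]]
    nf <- match(g$edges$from[i], g$nodes$id)
    nt <- match(g$edges$to[i], g$nodes$id)
    # path endpoints coincide with node positions
    expect_equal(unname(p[1, ]), c(g$nodes$row[nf], g$nodes$col[nf]))
    expect_equal(unname(p[nrow(p), ]), c(g$nodes$row[nt], g$nodes$col[nt]))
    # arc length >= euclidean distance between the nodes
    eu <- sqrt((g$nodes$row[nf] - g$nodes$row[nt])^2 +
               (g$nodes$col[nf] - g$nodes$col[nt])^2)
    expect_gte(g$edges$length[i] + 1e-9, eu)
    expect_gt(g$edges$mean_diameter[i], 0)
  }
})

test_that("spur pruning removes short terminal edges and merges through-nodes", {
  # Y with one very short arm
  y <- matrix(FALSE, 40, 40)
  y[30:39, 20] <- TRUE
  for (i in 0:12) y[30 - i, 20 - i] <- TRUE
  for (i in 0:3) y[30 - i, 20 + i] <- TRUE    # 4-px spur
  g <- build_graph(y)
  expect_equal(nrow(g$edges), 3)
  gp <- prune_spurs(g, min_length = 10)
  expect_equal(nrow(gp$edges), 1)             # spur gone, arms merged
  expect_equal(sum(gp$nodes$landmark == "junction"), 0)
  # min_length = 0 is the identity
  expect_equal(nrow(prune_spurs(g, 0)$edges), nrow(g$edges))
})

test_that("pruning is monotone in min_length and reaches a spur-free fixpoint", {
  specs <- arcade_pair(11)
  g0 <- build_graph(skeletonize(render_tree(specs, 560, 560)))
  last <- Inf
  for (ml in c(0, 3, 6, 12, 25)) {
    gp <- prune_spurs(g0, ml)
    expect_lte(nrow(gp$edges), last)
    last <- nrow(gp$edges)
    # fixpoint: no attached terminal edge shorter than min_length
    deg <- gp$nodes$degree; names(deg) <- gp$nodes$id
    e <- gp$edges
    attached_term <- xor(deg[as.character(e$from)] == 1,
                         deg[as.character(e$to)] == 1)
    expect_false(any(attached_term & e$length < ml))
  }
})

test_that("diameters recover drawn stroke widths", {
  for (w in c(1, 9)) {
    sp <- stroke_spec(0, length = 60, diameter = max(w, 1),
                      start = c(150.3, 150.7),
                      disc = disc_geometry(c(150, 150), 40))
    m <- if (w == 1) {
      g1 <- matrix(FALSE, 300, 300); g1[150, 140:200] <- TRUE
      raster_mask(g1, "artery")
    } else render_tree(sp, 300, 300)
    g <- estimate_diameters(m, build_graph(skeletonize(m)))
    est <- max(g$edges$mean_diameter)
    if (w == 1) expect_true(est >= 1 && est <= 2)
    else expect_true(est >= 8 && est <= 10)
  }
})

test_that("rendered tree diameters are recovered within ten percent", {
  specs <- arcade_pair(13)
  mask <- render_tree(specs, 560, 560)
  g <- vessel_graph_from_mask(mask, std_disc())
  # root edges carry the planned trunk diameters
  for (k in 1:2) {
    planned <- specs[[k]]$segments$diameter[1]
    root <- g$roots[which.min(abs(
      g$nodes$row[match(g$roots, g$nodes$id)] - specs[[k]]$root_point[1]))]
    d <- g$edges$mean_diameter[g$edges$from == root]
    expect_equal(max(d), planned, tolerance = 0.1)
  }
})

test_that("rooting picks the disc-nearest node and orients edges outward", {
  specs <- arcade_pair(17)
  disc <- std_disc()
  mask <- render_tree(specs, 560, 560)
  g <- build_graph(skeletonize(mask))
  g <- prune_spurs(estimate_diameters(mask, g))
  g <- root_components(g, disc)
  expect_length(g$roots, 2)
  for (k in 1:2) {
    rt <- g$nodes[match(g$roots, g$nodes$id), ]
    d <- sqrt((rt$row - specs[[k]]$root_point[1])^2 +
              (rt$col - specs[[k]]$root_point[2])^2)
    expect_lt(min(d), 2.5)
  }
  # BFS distance from roots must strictly grow along every edge
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from),
               to = as.character(g$edges$to)), directed = TRUE,
    vertices = data.frame(name = as.character(g$nodes$id)))
  expect_true(igraph::is_dag(ig))
  # every non-root node has exactly one parent edge
  non_roots <- setdiff(g$nodes$id, g$roots)
  expect_true(all(table(factor(g$edges$to, levels = non_roots)) == 1))
  # far-away debris is dropped
  lone <- matrix(FALSE, 560, 560); lone[20, 10:40] <- TRUE
  m2 <- raster_mask(mask$grid | lone, "artery")
  g2 <- root_components(prune_spurs(estimate_diameters(
    m2, build_graph(skeletonize(m2)))), disc)
  expect_length(g2$roots, 2)
  expect_error(
    root_components(build_graph(skeletonize(raster_mask(lone, "artery"))),
                    disc),
    "no rooted vasculature")
})
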