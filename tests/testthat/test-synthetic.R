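test_that("tree generation is deterministic and respects its invariants", {
  disc <- std_disc()
  a <- generate_tree_spec(4, disc = disc, seed = 7)
  b <- generate_tree_spec(4, disc = disc, seed = 7)
  expect_identical(a, b)
  c <- generate_tree_spec(4, disc = disc, seed = 8)
  expect_false(identical(a, c))
  # diameters positive and non-increasing along parentage
  s <- a$segments
  expect_true(all(s$diameter > 0))
  for (i in which(!is.na(s$parent)))
    expect_lte(s$diameter[i], s$diameter[s$id == s$parent[i]] + 1e-12)
  # junction angles in (0, 180); daughters emanate from the node point
  expect_true(all(a$junctions$planned_angle > 0 &
                  a$junctions$planned_angle < 180))
  for (k in seq_len(nrow(a$junctions))) {
    j <- a$junctions[k, ]
    for (d in c(j$daughter1, j$daughter2)) {
      sd <- s[s$id == d, ]
      expect_equal(c(sd$start_r, sd$start_c), c(j$node_r, j$node_c))
    }
  }
  # root on the disc edge
  expect_equal(sqrt(sum((a$root_point - disc$center)^2)),
               disc$diameter / 2, tolerance = 1e-9)
  # acyclic and rooted: every non-root has exactly one parent
  expect_equal(sum(is.na(s$parent)), 1)
  expect_true(all(s$parent[!is.na(s$parent)] < s$id[!is.na(s$parent)]))
})

test_that("depth 1 yields a single unbranched segment", {
  sp <- generate_tree_spec(1, disc = std_disc(), seed = 3)
  expect_equal(nrow(sp$segments), 1)
  expect_equal(nrow(sp$junctions), 0)
  gt <- ground_truth_morphometry(sp)
  expect_equal(nrow(gt$junctions), 0)
  expect_true(is.na(gt$MA))
  expect_false(is.null(attr(gt$MA, "flag")))
})

test_that("constant laws propagate exactly through the ground truth", {
  # without the raster guard, a constant 60-degree law and constant
  # (0.8, 0.6) ratios give angle 60 and coefficient 1 at every junction
  sp <- generate_tree_spec(3, angle_law = law_constant(60),
                           diameter_ratio_law = law_constant(c(0.8, 0.6)),
                           disc = std_disc(), seed = 5, cone_guard = FALSE)
  gt <- ground_truth_morphometry(sp)
  expect_equal(nrow(gt$junctions), 3)
  expect_equal(gt$junctions$angle_deg, rep(60, 3))
  expect_equal(gt$junctions$coefficient, rep(0.8^2 + 0.6^2, 3))  # = 1
  # symmetric bifurcation: equal daughter subtrees -> equal orders
  expect_true(all(gt$junctions$class[1] == "bifurcation" |
                  gt$junctions$class[1] == "branching"))
})

test_that("ground-truth junction classes match a brute-force Strahler recursion", {
  for (sd in 1:25) {
    sp <- generate_tree_spec(4, disc = std_disc(), seed = sd)
    gt <- ground_truth_morphometry(sp)
    s <- sp$segments
    parent <- ifelse(is.na(s$parent), NA_integer_, s$parent)
    oracle <- brute_strahler(parent)$edge_order
    for (k in seq_len(nrow(sp$junctions))) {
      j <- sp$junctions[k, ]
      o1 <- oracle[j$daughter1]; o2 <- oracle[j$daughter2]
      expect_equal(gt$junctions$class[gt$junctions$junction == j$id],
                   if (o1 == o2) "bifurcation" else "branching")
    }
  }
})

test_that("rendering draws binary stadium strokes of the stated area", {
  sp <- stroke_spec(0, length = 40, diameter = 6, start = c(50.4, 20.6),
                    disc = disc_geometry(c(50, 20), 30))
  m <- render_tree(sp, 100, 100)
  expect_true(is.logical(m$grid))
  area <- 40 * 6 + pi * 3^2              # rectangle plus end caps
  expect_equal(sum(m$grid), area, tolerance = 0.1)
  # empty spec renders an all-background mask
  empty <- sp; empty$segments <- sp$segments[0, ]
  expect_equal(sum(render_tree(empty, 100, 100)$grid), 0)
  # out-of-canvas segment errors and names the culprit
  expect_error(render_tree(sp, 30, 30), "segment 1")
})

test_that("rendered and re-measured stroke width matches the drawn width", {
  sp <- stroke_spec(27.3, length = 80, diameter = 9,
                    start = c(200.3, 40.7),
                    disc = disc_geometry(c(200, 40), 40))
  m <- render_tree(sp, 300, 300)
  g <- estimate_diameters(m, build_graph(skeletonize(m)))
  est <- max(g$edges$mean_diameter)
  expect_true(est >= 8 && est <= 10)
})

test_that("cohort simulation is deterministic with exact degenerate limits", {
  par <- data.frame(group = "normal", vessel_class = "artery",
                    metric = "MA", mean = 80, sd = 0, n = 5)
  co <- simulate_cohort(cohort_spec(par, seed = 1))
  expect_equal(nrow(co), 5)
  expect_equal(co$MA, rep(80, 5))
  # law of large numbers at n = 10000
  par2 <- transform(par, sd = 5, n = 10000L)
  co2 <- simulate_cohort(cohort_spec(par2, seed = 42))
  expect_equal(mean(co2$MA), 80, tolerance = 0.2 / 80)
  # byte-identical reruns
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(simulate_cohort(cohort_spec(par2, seed = 9)), f1,
            row.names = FALSE)
  write.csv(simulate_cohort(cohort_spec(par2, seed = 9)), f2,
            row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("cohort spec validation rejects malformed inputs", {
  par <- data.frame(group = "extreme", vessel_class = "vein",
                    metric = "MA", mean = 1, sd = 1, n = 5)
  expect_error(cohort_spec(par), "unknown group")
  par2 <- transform(par, group = "low", sd = -1)
  expect_error(cohort_spec(par2), "SD")
})

test_that("CI inversion recovers the SD that generated the interval", {
  set.seed(11)
  x <- rnorm(400, 50, 7)
  d <- describe_group(x)
  expect_equal(ci_to_sd(d$ci_lo, d$ci_hi, d$n), sd(x), tolerance = 0.01)
})

test_that("tree spec JSON round-trips", {
  sp <- generate_tree_spec(3, disc = std_disc(), seed = 2)
  f <- tempfile(fileext = ".json")
  write_tree_spec(sp, f)
  sp2 <- read_tree_spec(f)
  expect_equal(sp2$segments$diameter, sp$segments$diameter)
  expect_equal(sp2$junctions$planned_angle, sp$junctions$planned_angle)
  expect_equal(sp2$disc$diameter, sp$disc$diameter)
})
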