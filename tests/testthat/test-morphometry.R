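test_that("the measurement annulus has inclusive boundaries", {
  disc <- disc_geometry(c(0, 0), 100)
  expect_true(in_annulus(c(0, 120), disc))    # 1.2 D from center
  expect_false(in_annulus(c(0, 90), disc))    # inside inner boundary
  expect_true(in_annulus(c(0, 100), disc))    # inner boundary inclusive
  expect_true(in_annulus(c(0, 250), disc))    # outer boundary inclusive
  expect_false(in_annulus(c(0, 250.1), disc))
})

test_that("branch angle handles exact and degenerate geometries", {
  j <- c(50, 50)
  p_right <- cbind(50, 50:90)                 # along +col
  p_down <- cbind(50:90, 50)                  # along +row
  p_left <- cbind(50, 50:10)
  expect_equal(branch_angle(j, p_down, p_right), 90)
  expect_equal(branch_angle(j, p_right, p_left), 180)
  short <- cbind(50, 50:51)
  expect_warning(a <- branch_angle(j, short, p_right), "shorter")
  expect_true(is.na(a))
})

test_that("branch coefficient is the exponent-2 area ratio", {
  expect_equal(branch_coefficient(10, 8, 6), 1.00)
  expect_equal(branch_coefficient(10, 10, 10), 2.00)
  expect_equal(branch_coefficient(10, 9, 7), 1.30)
  expect_error(branch_coefficient(0, 1, 1), "positive")
  expect_error(branch_coefficient(5, -1, 1), "positive")
})

test_that("BC and BEC share arithmetic and differ only by junction class", {
  # swapping the daughter orders flips the class but not the coefficient
  specs <- arcade_pair(19)
  g <- vessel_graph_from_mask(render_tree(specs, 560, 560), std_disc())
  jt <- junction_table(g, std_disc())
  for (k in seq_len(nrow(jt))) {
    expect_equal(jt$coefficient[k],
                 branch_coefficient(jt$d_parent[k], jt$d1[k], jt$d2[k]))
    expect_equal(jt$class[k],
                 if (jt$order1[k] == jt$order2[k]) "bifurcation"
                 else "branching")
  }
})

test_that("main angle is the ray angle at the disc center", {
  # two straight arcades whose anchors sit 45 degrees above and below
  # the horizontal through the disc center
  disc <- disc_geometry(c(200, 100), 50)
  mk <- function(theta) generate_tree_spec(
    1, disc = disc, seed = 1, root_theta = theta,
    root_diameter = 8, root_length = 120)
  sup <- mk(-44); inf <- mk(44)
  mask <- render_tree(list(sup, inf), 400, 400)
  g <- vessel_graph_from_mask(mask, disc)
  ma <- main_angle(g, disc)
  expect_equal(as.numeric(ma), 88, tolerance = 2 / 88)
  # analytic ground truth agrees
  gt <- ground_truth_main_angle(list(sup, inf), disc)
  expect_equal(as.numeric(ma), as.numeric(gt), tolerance = 2 / 88)
  # diametrically opposite anchors -> 180 degrees
  op <- render_tree(list(mk(-90 + 8), mk(90 + 8)), 400, 400)
  g2 <- vessel_graph_from_mask(op, disc)
  expect_equal(as.numeric(main_angle(g2, disc)), 180, tolerance = 0.03)
})

test_that("main angle needs trees, flags a lone arcade", {
  disc <- disc_geometry(c(200, 100), 50)
  sp <- generate_tree_spec(2, disc = disc, seed = 1, root_theta = -44,
                           root_diameter = 8, root_length = 90)
  g <- vessel_graph_from_mask(render_tree(sp, 400, 400), disc)
  ma <- main_angle(g, disc)
  expect_true(is.na(ma))
  expect_match(attr(ma, "flag"), "superior or inferior")
})

test_that("measure_image aggregates junction metrics per class within the annulus", {
  specs <- arcade_pair(23)
  disc <- std_disc()
  mask <- render_tree(specs, 560, 560)
  g <- vessel_graph_from_mask(mask, disc)
  gt <- ground_truth_morphometry(specs)
  rec <- measure_image(g, NULL, disc, "img1")
  expect_equal(nrow(rec), 2)
  a <- rec[rec$vessel_class == "artery", ]
  v <- rec[rec$vessel_class == "vein", ]
  # counts equal the ground-truth annulus-restricted counts
  gin <- gt$junctions[gt$junctions$in_annulus, ]
  expect_equal(a$n_branching, sum(gin$class == "branching"))
  expect_equal(a$n_bifurcation, sum(gin$class == "bifurcation"))
  # per-class means match the ground-truth means within tolerance
  if (a$n_branching > 0)
    expect_equal(a$BA, mean(gin$angle_deg[gin$class == "branching"]),
                 tolerance = 3 / 40)
  if (a$n_bifurcation > 0)
    expect_equal(a$BEA, mean(gin$angle_deg[gin$class == "bifurcation"]),
                 tolerance = 3 / 40)
  expect_equal(a$MA, as.numeric(gt$MA), tolerance = 2 / 90)
  # empty vein mask is flagged, not an error
  expect_match(v$flags, "no vasculature")
  expect_true(is.na(v$MA) && is.na(v$BA))
})

test_that("junctions outside the annulus leave branch metrics undefined but MA defined", {
  # a tiny disc far from every junction pushes all junctions outside
  specs <- arcade_pair(29)
  mask <- render_tree(specs, 560, 560)
  small_disc <- disc_geometry(c(280, 280), 18)
  g <- vessel_graph_from_mask(mask, small_disc)
  rec <- measure_image(g, NULL, small_disc, "img")[1, ]
  expect_true(is.na(rec$BA) && is.na(rec$BC) &&
              is.na(rec$BEA) && is.na(rec$BEC))
  expect_false(is.na(rec$MA))
  expect_match(rec$flags, "no junctions in annulus")
})

test_that("metrics are invariant to rotation and uniform scaling", {
  disc <- std_disc()
  specs <- arcade_pair(5)
  m0 <- render_tree(specs, 560, 560)
  r0 <- measure_image(vessel_graph_from_mask(m0, disc), NULL, disc, "a")[1, ]
  # 90 degree rotation of the raster and annotation
  mr <- raster_mask(t(m0$grid[nrow(m0$grid):1, ]), "artery")
  rr <- measure_image(vessel_graph_from_mask(mr, disc), NULL, disc, "a")[1, ]
  expect_equal(rr$MA, r0$MA, tolerance = 2 / r0$MA)
  expect_equal(rr$BA, r0$BA, tolerance = 2 / r0$BA)
  expect_equal(rr$BEA, r0$BEA, tolerance = 2 / r0$BEA)
  expect_equal(rr$BC, r0$BC, tolerance = 0.05)
  expect_equal(rr$BEC, r0$BEC, tolerance = 0.05)
  # uniform 2x scale of geometry, disc and canvas
  sc <- function(sp, s) {
    sp$segments$start_r <- (sp$segments$start_r - 0.5) * s + 0.5
    sp$segments$start_c <- (sp$segments$start_c - 0.5) * s + 0.5
    sp$segments$length <- sp$segments$length * s
    sp$segments$diameter <- sp$segments$diameter * s
    sp$disc <- disc_geometry((sp$disc$center - 0.5) * s + 0.5,
                             sp$disc$diameter * s)
    sp
  }
  d2 <- disc_geometry((disc$center - 0.5) * 2 + 0.5, disc$diameter * 2)
  m2 <- render_tree(lapply(specs, sc, s = 2), 1120, 1120)
  r2 <- measure_image(vessel_graph_from_mask(m2, d2), NULL, d2, "a")[1, ]
  expect_equal(r2$MA, r0$MA, tolerance = 2 / r0$MA)
  expect_equal(r2$BA, r0$BA, tolerance = 2 / r0$BA)
  expect_equal(r2$BEA, r0$BEA, tolerance = 2 / r0$BEA)
  expect_equal(r2$BC, r0$BC, tolerance = 0.05)
  expect_equal(r2$BEC, r0$BEC, tolerance = 0.05)
})
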