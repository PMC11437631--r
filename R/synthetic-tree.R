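# direction angles are degrees; 0 = +col (temporal east), 90 = +row
# (inferior, image rows grow downward); unit vector in (row, col)
ang2vec <- function(deg) {
  r <- deg * pi / 180
  c(sin(r), cos(r))
}

# run expr with a private RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a parametric vascular tree with exact ground truth
#'
#' Builds a rooted binary-ish tree that emulates one temporal arcade:
#' the root sits on the optic-disc edge and the tree grows radially
#' outward. Every junction's branch angle is drawn from
#' \code{angle_law} (truncated to (10, 170) degrees) and its daughter
#' diameter ratios from \code{diameter_ratio_law} (in (0, 1], returned
#' with d1 >= d2). With \code{cone_guard = TRUE} all growth directions
#' are confined to the arcade's angular wedge (root direction +/-
#' \code{sector_half}), realized branch angles are floored at 26 degrees
#' (narrower junctions are not recoverable from a raster at these
#' calibers), and the finished tree is checked analytically for
#' stroke-stroke collisions between non-adjacent segments and for
#' segments within 3 degrees of a grid-aligned direction (whose
#' rasterized caliber quantizes to a constant and cannot carry the
#' planned diameter); an invalid draw is deterministically resampled. When a clamp moves a direction
#' the junction's recorded angle is recomputed from the actual
#' directions, so the ground truth stays exact. With
#' \code{cone_guard = FALSE} drawn angles propagate unmodified and no
#' collision check runs.
#'
#' The minor daughter loses one extra generation of depth with
#' probability \code{asym_prob}; the resulting subtree-depth asymmetry
#' produces a mixture of branching junctions (unequal daughter Strahler
#' orders) and bifurcation junctions (equal orders).
#'
#' @param depth number of segment generations (>= 1); depth 1 is a
#'   single unbranched segment.
#' @param angle_law,diameter_ratio_law \code{\link{vessel_laws}}.
#' @param disc a \code{disc_geometry}.
#' @param vessel_class \code{"artery"} or \code{"vein"}.
#' @param seed integer; the same seed reproduces the spec exactly.
#' @param root_theta root position/direction on the disc edge, degrees
#'   (0 = temporal, negative = superior).
#' @param root_diameter trunk diameter in px (default D/7; at typical
#'   desk-scale canvases this keeps distal branches measurable).
#' @param root_length first-segment length in px (default 1.15 D).
#' @param length_decay per-generation length factor.
#' @param asym_prob probability that the minor daughter loses an extra
#'   generation.
#' @param sector_half half-width of the root's angular growth cone,
#'   degrees.
#' @param cone_guard enforce disjoint sibling growth cones (default
#'   \code{TRUE}).
#' @return A \code{tree_spec}: list with \code{segments} (id, parent,
#'   start, direction angle, length, diameter, generation),
#'   \code{junctions} (node point, daughter ids, planned angle, planned
#'   ratios), \code{root_point}, \code{root_direction}, \code{disc},
#'   \code{vessel_class}, \code{seed}.
#' @export
generate_tree_spec <- function(depth, angle_law = law_uniform(55, 95),
                               diameter_ratio_law = law_uniform(0.65, 0.9),
                               disc, vessel_class = c("artery", "vein"),
                               seed = 1L, root_theta = -52,
                               root_diameter = disc$diameter / 7,
                               root_length = 1.15 * disc$diameter,
                               length_decay = 0.85, asym_prob = 0.5,
                               sector_half = 50, cone_guard = TRUE) {
  vessel_class <- match.arg(vessel_class)
  stopifnot(inherits(disc, "disc_geometry"))
  if (depth < 1) stop("depth must be >= 1")
  if (inherits(angle_law, "vessel_law") && angle_law$dist == "uniform" &&
      (angle_law$min < 10 || angle_law$max > 170))
    stop("angle law bounds must lie in (10, 170) degrees")
  for (attempt in 0:199) {
    spec <- generate_tree_once(depth, angle_law, diameter_ratio_law, disc,
                               vessel_class, seed + attempt * 7919L,
                               root_theta, root_diameter, root_length,
                               length_decay, asym_prob, sector_half,
                               cone_guard)
    spec$seed <- as.integer(seed)
    if (!cone_guard || tree_spec_valid(spec)) return(spec)
  }
  stop("could not draw a collision-free tree; relax the parameters")
}

generate_tree_once <- function(depth, angle_law, diameter_ratio_law, disc,
                               vessel_class, seed, root_theta,
                               root_diameter, root_length, length_decay,
                               asym_prob, sector_half, cone_guard) {
  with_seed(seed, {
    R <- disc$diameter / 2
    segs <- list(); juncs <- list()
    root_start <- disc$center + R * ang2vec(root_theta)
    # stack entries: parent id, start, angle, length, diameter, depth
    # left, generation, sector
    stack <- list(list(id = 1L, parent = NA_integer_, start = root_start,
                       angle = root_theta, len = root_length,
                       diam = root_diameter, left = depth - 1L, gen = 1L))
    next_id <- 2L
    margin <- 6   # angular clearance (deg) so strokes of finite width clear
    while (length(stack)) {
      s <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      id <- s$id
      segs[[id]] <- data.frame(
        id = id, parent = s$parent, start_r = s$start[1],
        start_c = s$start[2], angle_deg = s$angle, length = s$len,
        diameter = s$diam, gen = s$gen)
      if (s$left <= 0L) next
      endp <- s$start + s$len * ang2vec(s$angle)
      theta <- draw_law(angle_law, 1, 10, 170)
      rr <- draw_ratio_pair(diameter_ratio_law)
      side <- sample(c(-1, 1), 1)
      # larger daughter deviates less, weighted by the ratios
      if (cone_guard) theta <- max(theta, 26)
      dev1 <- theta * rr[2] / sum(rr)
      dev2 <- theta - dev1
      a1 <- s$angle + side * dev1
      a2 <- s$angle - side * dev2
      if (cone_guard) {
        # keep all growth inside the arcade wedge
        lo <- root_theta - (sector_half - margin)
        hi <- root_theta + (sector_half - margin)
        a1 <- min(max(a1, lo), hi)
        a2 <- min(max(a2, lo), hi)
      }
      theta_act <- abs(a1 - a2)
      jitter <- stats::runif(2, 0.9, 1.1)
      extra <- stats::rbinom(1, 1, asym_prob)
      left1 <- s$left - 1L
      left2 <- max(s$left - 1L - extra, 0L)
      id1 <- next_id; id2 <- next_id + 1L
      next_id <- next_id + 2L
      # push daughter 2 first so daughter 1 is processed next (DFS)
      stack[[length(stack) + 1L]] <-
        list(id = id2, parent = id, start = endp, angle = a2,
             len = s$len * length_decay * jitter[2],
             diam = s$diam * rr[2], left = left2, gen = s$gen + 1L)
      stack[[length(stack) + 1L]] <-
        list(id = id1, parent = id, start = endp, angle = a1,
             len = s$len * length_decay * jitter[1],
             diam = s$diam * rr[1], left = left1, gen = s$gen + 1L)
      juncs[[length(juncs) + 1L]] <- data.frame(
        id = id, node_r = endp[1], node_c = endp[2],
        daughter1 = id1, daughter2 = id2,
        planned_angle = theta_act, r1 = rr[1], r2 = rr[2])
    }
    segments <- do.call(rbind, segs)
    junctions <- if (length(juncs)) do.call(rbind, juncs) else
      data.frame(id = integer(0), node_r = numeric(0), node_c = numeric(0),
                 daughter1 = integer(0), daughter2 = integer(0),
                 planned_angle = numeric(0), r1 = numeric(0),
                 r2 = numeric(0))
    structure(list(vessel_class = vessel_class, root_point = root_start,
                   root_direction = ang2vec(root_theta),
                   segments = segments, junctions = junctions,
                   disc = disc, seed = seed),
              class = "tree_spec")
  })
}

# minimum distance between two 2-D segments (p0-p1, q0-q1)
seg_seg_dist <- function(p0, p1, q0, q1) {
  pt_seg <- function(pt, a, b) {
    v <- b - a
    L2 <- sum(v^2)
    t <- if (L2 < .Machine$double.eps) 0 else
      min(max(sum((pt - a) * v) / L2, 0), 1)
    sqrt(sum((pt - (a + t * v))^2))
  }
  # dense sampling is robust enough at these scales
  ts <- seq(0, 1, length.out = 17)
  min(vapply(ts, function(t) pt_seg(p0 + t * (p1 - p0), q0, q1),
             numeric(1)),
      vapply(ts, function(t) pt_seg(q0 + t * (q1 - q0), p0, p1),
             numeric(1)))
}

# validity: every junction angle recoverable, no segment within ~2
# degrees (3) of a grid-aligned direction (a near-axis or near-diagonal
# stroke rasterizes with its width quantized to a constant, so the
# drawn caliber cannot equal the planned one), and no stroke collision
# between non-adjacent segments
tree_spec_valid <- function(spec, min_angle = 24, clearance = 2) {
  if (nrow(spec$junctions) &&
      any(spec$junctions$planned_angle < min_angle)) return(FALSE)
  # the root direction is chosen by the caller and identical across
  # resampling attempts, so only the randomly drawn daughters are
  # subject to the grid-alignment rejection
  drawn <- !is.na(spec$segments$parent)
  a45 <- spec$segments$angle_deg[drawn] %% 45
  if (any(pmin(a45, 45 - a45) < 3)) return(FALSE)
  segs <- spec$segments
  n <- nrow(segs)
  if (n < 2) return(TRUE)
  ends <- t(vapply(segs$id, function(id) seg_end(spec, id), numeric(2)))
  starts <- cbind(segs$start_r, segs$start_c)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    adjacent <- identical(segs$parent[j], segs$id[i]) ||
      identical(segs$parent[i], segs$id[j]) ||
      (!is.na(segs$parent[i]) && !is.na(segs$parent[j]) &&
         segs$parent[i] == segs$parent[j])
    if (adjacent) next
    dmin <- seg_seg_dist(starts[i, ], ends[i, ], starts[j, ], ends[j, ])
    if (dmin < (segs$diameter[i] + segs$diameter[j]) / 2 + clearance)
      return(FALSE)
  }
  TRUE
}

#' @export
print.tree_spec <- function(x, ...) {
  cat(sprintf("<tree_spec> %s, %d segments, %d junctions, seed %d\n",
              x$vessel_class, nrow(x$segments), nrow(x$junctions), x$seed))
  invisible(x)
}

seg_end <- function(spec, id) {
  s <- spec$segments[spec$segments$id == id, ]
  c(s$start_r, s$start_c) + s$length * ang2vec(s$angle_deg)
}

# analytic Strahler orders of the spec tree (named by segment id)
spec_strahler <- function(spec) {
  segs <- spec$segments
  kids <- split(segs$id, factor(segs$parent, levels = segs$id))
  ord <- rep(NA_integer_, nrow(segs)); names(ord) <- segs$id
  # process in reverse id order: daughters always have larger ids
  for (id in rev(segs$id)) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch) || length(ch) == 0) ord[as.character(id)] <- 1L
    else {
      o <- ord[as.character(ch)]
      m <- max(o)
      ord[as.character(id)] <- if (sum(o == m) >= 2L) m + 1L else m
    }
  }
  ord
}

#' Analytic ground-truth morphometry of tree specs
#'
#' Computes, without any rasterization, the per-junction angle (from the
#' planned direction vectors), coefficient (from the planned diameters),
#' junction class (from analytically assigned Strahler orders of the
#' spec tree) and annulus membership, plus the main angle when specs for
#' both hemifields are supplied.
#'
#' @param specs a \code{tree_spec} or a list of them (one forest /
#'   vessel class); all must share a disc.
#' @return A list with \code{junctions} (data.frame: tree, junction id,
#'   class, angle_deg, coefficient, in_annulus, node position) and
#'   \code{MA} (degrees; \code{NA} with attribute \code{flag} when a
#'   hemifield has no tree).
#' @export
ground_truth_morphometry <- function(specs) {
  if (inherits(specs, "tree_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "tree_spec")))
  disc <- specs[[1]]$disc
  jl <- list()
  for (t in seq_along(specs)) {
    sp <- specs[[t]]
    if (nrow(sp$junctions) == 0) next
    ord <- spec_strahler(sp)
    j <- sp$junctions
    o1 <- ord[as.character(j$daughter1)]
    o2 <- ord[as.character(j$daughter2)]
    jl[[length(jl) + 1L]] <- data.frame(
      tree = t, junction = j$id,
      class = ifelse(o1 == o2, "bifurcation", "branching"),
      angle_deg = j$planned_angle,
      coefficient = j$r1^2 + j$r2^2,
      in_annulus = vapply(seq_len(nrow(j)), function(k)
        in_annulus(c(j$node_r[k], j$node_c[k]), disc), logical(1)),
      node_r = j$node_r, node_c = j$node_c)
  }
  junctions <- if (length(jl)) do.call(rbind, jl) else
    data.frame(tree = integer(0), junction = integer(0),
               class = character(0), angle_deg = numeric(0),
               coefficient = numeric(0), in_annulus = logical(0),
               node_r = numeric(0), node_c = numeric(0))
  ma <- ground_truth_main_angle(specs, disc)
  list(junctions = junctions, MA = ma)
}

#' Analytic main angle of a set of tree specs
#'
#' Per hemifield, selects the largest-trunk spec; the anchor is the
#' distal endpoint of its maximal-Strahler-order chain; the main angle
#' is measured at the disc center between the two anchor rays.
#'
#' @param specs list of \code{tree_spec}s.
#' @param disc a \code{disc_geometry}.
#' @return Angle in degrees (attribute \code{anchors}), or \code{NA}
#'   with attribute \code{flag} when a hemifield holds no tree.
#' @export
ground_truth_main_angle <- function(specs, disc) {
  rows <- vapply(specs, function(sp) sp$root_point[1], numeric(1))
  diam <- vapply(specs, function(sp) sp$segments$diameter[1], numeric(1))
  sup <- which(rows < disc$center[1]); inf <- which(rows >= disc$center[1])
  if (length(sup) == 0 || length(inf) == 0)
    return(flagged_na("missing superior or inferior tree"))
  anchor <- function(sp) {
    ord <- spec_strahler(sp)
    maxord <- max(ord)
    segs <- sp$segments
    kids <- split(segs$id, factor(segs$parent, levels = segs$id))
    cur <- segs$id[is.na(segs$parent)]
    repeat {
      if (ord[as.character(cur)] < maxord) break
      anc <- seg_end(sp, cur)
      ch <- kids[[as.character(cur)]]
      if (is.null(ch) || length(ch) == 0) break
      o <- ord[as.character(ch)]
      nxt <- ch[which.max(o)]
      if (max(o) < maxord) break
      cur <- nxt
    }
    anc
  }
  a_sup <- anchor(specs[[sup[which.max(diam[sup])]]])
  a_inf <- anchor(specs[[inf[which.max(diam[inf])]]])
  ma <- angle_between(a_sup - disc$center, a_inf - disc$center)
  attr(ma, "anchors") <- rbind(superior = a_sup, inferior = a_inf)
  ma
}

#' Rasterize tree specs into a binary vessel mask
#'
#' Each segment is drawn as a stroke of its specified diameter: every
#' pixel whose center lies within half a diameter of the centerline
#' segment is set (disk-stamping, giving stadium-shaped strokes with
#' round end caps). The output is strictly binary.
#'
#' @param specs a \code{tree_spec} or list of them (drawn into one
#'   mask).
#' @param height,width canvas size in px.
#' @param clear_disc if \code{TRUE}, pixels inside the optic disc are
#'   cleared.
#' @return A \code{raster_mask}.
#' @export
render_tree <- function(specs, height, width, clear_disc = FALSE) {
  if (inherits(specs, "tree_spec")) specs <- list(specs)
  g <- matrix(FALSE, height, width)
  for (t in seq_along(specs)) {
    sp <- specs[[t]]
    for (i in seq_len(nrow(sp$segments))) {
      s <- sp$segments[i, ]
      p0 <- c(s$start_r, s$start_c)
      p1 <- p0 + s$length * ang2vec(s$angle_deg)
      hw <- s$diameter / 2
      lo <- floor(pmin(p0, p1) - hw) ; hi <- ceiling(pmax(p0, p1) + hw)
      if (lo[1] < 1 || lo[2] < 1 || hi[1] > height || hi[2] > width)
        stop(sprintf("segment %d of tree %d leaves the canvas", s$id, t))
      rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      v <- p1 - p0
      L2 <- sum(v^2)
      tt <- if (L2 < .Machine$double.eps) 0 else
        pmin(pmax(((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / L2, 0), 1)
      dr <- rr - (p0[1] + tt * v[1]); dc <- cc - (p0[2] + tt * v[2])
      hit <- (dr * dr + dc * dc) <= hw * hw
      g[rows, cols] <- g[rows, cols] | hit
    }
  }
  if (clear_disc) {
    disc <- specs[[1]]$disc
    rr <- matrix(seq_len(height), height, width)
    cc <- matrix(seq_len(width), height, width, byrow = TRUE)
    g[(rr - disc$center[1])^2 + (cc - disc$center[2])^2 <
        (disc$diameter / 2)^2] <- FALSE
  }
  raster_mask(g, vessel_class = specs[[1]]$vessel_class)
}

#' Serialize / deserialize a tree spec as JSON
#' @param spec a \code{tree_spec}.
#' @param path file path.
#' @return \code{path} invisibly / the restored \code{tree_spec}.
#' @export
write_tree_spec <- function(spec, path) {
  stopifnot(inherits(spec, "tree_spec"))
  out <- unclass(spec)
  out$disc <- list(center = spec$disc$center, diameter = spec$disc$diameter)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_tree_spec
#' @export
read_tree_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$disc <- disc_geometry(j$disc$center, j$disc$diameter)
  j$segments <- as.data.frame(j$segments)
  j$junctions <- as.data.frame(j$junctions)
  j$root_point <- as.numeric(j$root_point)
  j$root_direction <- as.numeric(j$root_direction)
  structure(j, class = "tree_spec")
}
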