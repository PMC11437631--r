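#' Is a point inside the measurement annulus?
#'
#' The branch-metric measurement zone spans 0.5 to 2.0 disc diameters
#' outward from the optic-disc edge, i.e. radial distances r from the
#' disc center with (r - D/2) between 0.5 D and 2.0 D, boundaries
#' inclusive.
#'
#' @param point numeric (row, col).
#' @param disc a \code{disc_geometry}.
#' @param inner,outer annulus bounds in disc diameters from the disc
#'   edge.
#' @return Logical.
#' @export
in_annulus <- function(point, disc, inner = 0.5, outer = 2.0) {
  stopifnot(inherits(disc, "disc_geometry"))
  r <- sqrt(sum((as.numeric(point) - disc$center)^2))
  edge_dist <- r - disc$diameter / 2
  edge_dist >= inner * disc$diameter & edge_dist <= outer * disc$diameter
}

# least-squares direction of a daughter path leaving a junction.
# path: n x 2 polyline starting at the junction position.
# fit_len: arc length of path to use; trim_radius: skip pixels closer
# than this to the junction (junction bulge).
daughter_direction <- function(path, fit_len, trim_radius = 0) {
  if (nrow(path) < 2) return(NULL)
  origin <- path[1, ]
  cum <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  pts <- path[cum <= max(fit_len, cum[2]), , drop = FALSE]
  if (trim_radius > 0) {
    d <- sqrt((pts[, 1] - origin[1])^2 + (pts[, 2] - origin[2])^2)
    keep <- d > trim_radius
    keep[nrow(pts)] <- TRUE   # always keep the farthest point
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 2) {
    v <- path[nrow(path), ] - origin
  } else {
    ctr <- colMeans(pts)
    cv <- crossprod(sweep(pts, 2, ctr))
    v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    if (sum(v * (ctr - origin)) < 0) v <- -v   # point away from junction
  }
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) NULL else v / nv
}

#' Angle between two daughter vessels at a junction
#'
#' Each daughter's initial direction is a least-squares line fit over the
#' first \code{min(path length, fit_len)} px of its centerline path
#' (default fit length: three parent diameters), optionally excluding
#' pixels inside the junction bulge. The angle between the two directions
#' is returned in degrees, in (0, 180].
#'
#' @param junction_point numeric (row, col) of the junction.
#' @param path1,path2 daughter centerline polylines, each starting at the
#'   junction.
#' @param fit_len fit length in px.
#' @param trim_radius exclusion radius around the junction in px; a
#'   length-2 vector applies a separate radius per daughter.
#' @return Angle in degrees, or \code{NA} (with a warning) when a
#'   daughter path is shorter than 3 px.
#' @export
branch_angle <- function(junction_point, path1, path2, fit_len = 15,
                         trim_radius = 0) {
  l1 <- polyline_length(path1); l2 <- polyline_length(path2)
  if (l1 < 3 || l2 < 3) {
    warning("daughter path shorter than 3 px: junction skipped")
    return(NA_real_)
  }
  trim_radius <- rep_len(trim_radius, 2)
  d1 <- daughter_direction(path1, fit_len + trim_radius[1], trim_radius[1])
  d2 <- daughter_direction(path2, fit_len + trim_radius[2], trim_radius[2])
  if (is.null(d1) || is.null(d2)) return(NA_real_)
  a <- angle_between(d1, d2)
  if (!is.na(a) && a == 0) a <- NA_real_
  a
}

#' Branching / bifurcation coefficient
#'
#' The dimensionless daughter-to-parent caliber relation
#' \eqn{(d_1^2 + d_2^2) / d_0^2}: the junction-exponent-2 area ratio used
#' throughout the retinal branching-geometry literature. Evaluated at
#' branching junctions it is the branching coefficient (BC), at
#' bifurcation junctions the bifurcation edge coefficient (BEC); both use
#' this identical arithmetic.
#'
#' @param d_parent parent segment diameter (px), > 0.
#' @param d1,d2 daughter segment diameters (px), > 0.
#' @return The coefficient (dimensionless).
#' @export
branch_coefficient <- function(d_parent, d1, d2) {
  if (any(c(d_parent, d1, d2) <= 0) || any(!is.finite(c(d_parent, d1, d2))))
    stop("all diameters must be positive")
  (d1^2 + d2^2) / d_parent^2
}

#' Main angle of one vessel class
#'
#' The main angle (MA) is measured at the optic-disc center between the
#' superior and inferior temporal arcades: in each hemifield (above /
#' below the disc-center row) the tree with the largest root diameter is
#' selected; on it, the maximal-Strahler-order edge chain is followed
#' from the root, and the distal endpoint of the last edge holding the
#' maximal order is the anchor point. MA is the angle at the disc center
#' (or \code{vertex} override) between the rays to the two anchors.
#'
#' @param graph a rooted, ordered \code{skeleton_graph} holding all
#'   components of one vessel class.
#' @param disc a \code{disc_geometry}.
#' @param vertex optional (row, col) vertex override; default the disc
#'   center.
#' @return Angle in degrees in (0, 180], or \code{NA} with attribute
#'   \code{flag} when a hemifield holds no tree. Attribute
#'   \code{anchors}: 2 x 2 matrix of the anchor points.
#' @export
main_angle <- function(graph, disc, vertex = NULL) {
  stopifnot(inherits(disc, "disc_geometry"))
  g <- graph
  if (!g$rooted) stop("graph must be rooted and ordered")
  if (is.null(vertex)) vertex <- disc$center
  comp <- graph_components(g)
  roots <- g$roots
  if (length(roots) == 0) return(flagged_na("no rooted tree"))
  root_rows <- match(roots, g$nodes$id)
  root_diam <- vapply(roots, function(r) {
    d <- g$edges$mean_diameter[g$edges$from == r]
    if (length(d) == 0 || all(is.na(d))) 0 else max(d, na.rm = TRUE)
  }, numeric(1))
  above <- g$nodes$row[root_rows] < disc$center[1]
  pick <- function(side) {
    cand <- which(side & root_diam > 0)
    if (length(cand) == 0) cand <- which(side)
    if (length(cand) == 0) return(NA_integer_)
    cand[which.max(root_diam[cand])]
  }
  i_sup <- pick(above); i_inf <- pick(!above)
  fallback <- FALSE
  if (is.na(i_sup) || is.na(i_inf)) {
    # hemifield split empty (e.g. a rotated image): fall back to the
    # two largest-trunk trees, which in a standard fundus orientation
    # are exactly the superior and inferior temporal arcades
    if (length(roots) < 2)
      return(flagged_na("missing superior or inferior tree"))
    ord2 <- order(root_diam, decreasing = TRUE)[1:2]
    i_sup <- ord2[1]; i_inf <- ord2[2]
    fallback <- TRUE
  }
  anchor <- function(root) {
    cc <- comp[match(root, g$nodes$id)]
    in_comp <- g$edges$from %in% g$nodes$id[comp == cc]
    maxord <- suppressWarnings(max(g$edges$strahler_order[in_comp],
                                   na.rm = TRUE))
    cur <- root; anc <- root
    repeat {
      outs <- which(g$edges$from == cur)
      if (length(outs) == 0) break
      o <- g$edges$strahler_order[outs]
      best <- outs[order(-o, -g$edges$mean_diameter[outs])][1]
      if (is.na(g$edges$strahler_order[best]) ||
          g$edges$strahler_order[best] < maxord) break
      cur <- g$edges$to[best]
      anc <- cur
    }
    nd <- g$nodes[match(anc, g$nodes$id), ]
    if (nd$degree >= 3) refine_junction_position(g, anc)
    else c(nd$row, nd$col)
  }
  a_sup <- anchor(roots[i_sup]); a_inf <- anchor(roots[i_inf])
  ma <- angle_between(a_sup - vertex, a_inf - vertex)
  if (!is.na(ma) && ma == 0) ma <- NA_real_
  attr(ma, "anchors") <- rbind(superior = a_sup, inferior = a_inf)
  if (fallback) attr(ma, "flag") <- "hemifield split empty: used two largest trees"
  ma
}

flagged_na <- function(msg) {
  x <- NA_real_
  attr(x, "flag") <- msg
  x
}

# arc length along p1 until its points clear `clearance` px from p2
# (thinning keeps two daughters fused until their strokes separate; the
# fused stretch must not enter the direction fit)
fusion_trim <- function(p1, p2, clearance) {
  n2 <- min(nrow(p2), 120L)
  q <- p2[seq_len(n2), , drop = FALSE]
  n1 <- min(nrow(p1), 120L)
  cum <- 0
  for (i in seq_len(n1)) {
    if (i > 1) cum <- cum + sqrt(sum((p1[i, ] - p1[i - 1, ])^2))
    dmin <- sqrt(min((q[, 1] - p1[i, 1])^2 + (q[, 2] - p1[i, 2])^2))
    if (i > 1 && dmin > clearance) return(cum)
  }
  cum
}

# subpixel junction relocation: least-squares intersection of the
# incident edges' fitted direction lines (thinning displaces the node
# centroid outward along the daughters' fused stub)
refine_junction_position <- function(g, v) {
  nd <- g$nodes[match(v, g$nodes$id), ]
  pos <- c(nd$row, nd$col)
  eids <- g$edges$id[g$edges$from == v | g$edges$to == v]
  if (length(eids) < 3) return(pos)
  A <- matrix(0, 2, 2); b <- c(0, 0)
  used <- 0L
  for (eid in eids) {
    e <- g$edges[g$edges$id == eid, ]
    p <- oriented_path(g, eid, v)
    d <- if (is.na(e$mean_diameter)) 4 else e$mean_diameter
    trim <- max(d, 4)
    pts <- path_window(p, trim, trim + 3 * max(d, 4))
    if (is.null(pts) || nrow(pts) < 3) next
    ctr <- colMeans(pts)
    cv <- crossprod(sweep(pts, 2, ctr))
    u <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    P <- diag(2) - tcrossprod(u)
    A <- A + P; b <- b + P %*% ctr
    used <- used + 1L
  }
  if (used < 2) return(pos)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(pos)
  sol <- as.numeric(sol)
  # reject implausible relocations
  if (sqrt(sum((sol - pos)^2)) > 25) pos else sol
}

# rows of path with arc length in [lo, hi]
path_window <- function(p, lo, hi) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  keep <- cum >= lo & cum <= hi
  if (!any(keep)) return(NULL)
  p[keep, , drop = FALSE]
}

#' Per-junction measurements for one vessel-class graph
#'
#' Measures every junction (one parent edge, two or more daughter
#' edges) of a rooted, ordered graph: refined subpixel position,
#' junction class from the daughter Strahler orders, the angle between
#' the two (largest) daughters, and the daughter-to-parent coefficient.
#'
#' @param graph a rooted, ordered, crossing-resolved
#'   \code{skeleton_graph}.
#' @param disc a \code{disc_geometry} (for the annulus flag).
#' @param config a \code{\link{run_config}}.
#' @return A data.frame with one row per junction: \code{junction_id,
#'   row, col, class, order1, order2, d_parent, d1, d2, angle_deg,
#'   coefficient, in_annulus, flagged}.
#' @export
junction_table <- function(graph, disc, config = run_config()) {
  g <- graph
  out <- list()
  jn <- g$nodes[g$nodes$landmark == "junction" & !g$nodes$flagged, ]
  for (k in seq_len(nrow(jn))) {
    v <- jn$id[k]
    pos <- refine_junction_position(g, v)
    ins <- which(g$edges$to == v)
    outs <- which(g$edges$from == v)
    if (length(ins) != 1 || length(outs) < 2) next
    d0 <- g$edges$mean_diameter[ins]
    od <- g$edges$mean_diameter[outs]
    oo <- g$edges$strahler_order[outs]
    if (any(is.na(oo))) next
    cls <- classify_junction(oo, od)
    sel <- if (length(outs) > 2)
      outs[order(od, decreasing = TRUE)[1:2]] else outs
    p1 <- oriented_path(g, g$edges$id[sel[1]], v)
    p2 <- oriented_path(g, g$edges$id[sel[2]], v)
    d1 <- g$edges$mean_diameter[sel[1]]; d2 <- g$edges$mean_diameter[sel[2]]
    clr <- if (all(is.finite(c(d1, d2)))) (d1 + d2) / 2 else 4
    # the medial axis bends smoothly across the junction bulge (about
    # one parent diameter) and two daughters stay fused until their
    # strokes clear each other; both stretches are excluded from the
    # direction fit
    trim <- if (config$trim_junction && is.finite(d0)) {
      c(max(d0, fusion_trim(p1, p2, clr)),
        max(d0, fusion_trim(p2, p1, clr)))
    } else 0
    fit_len <- config$fit_factor * if (is.finite(d0)) d0 else 5
    ang <- suppressWarnings(branch_angle(pos, p1, p2, fit_len, trim))
    coef <- if (is.finite(d0) && all(is.finite(c(d1, d2))))
      branch_coefficient(d0, d1, d2) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      junction_id = v, row = pos[1], col = pos[2],
      class = as.character(cls),
      order1 = oo[match(sel[1], outs)], order2 = oo[match(sel[2], outs)],
      d_parent = d0, d1 = d1, d2 = d2,
      angle_deg = ang, coefficient = coef,
      in_annulus = in_annulus(pos, disc, config$annulus_inner,
                              config$annulus_outer),
      flagged = isTRUE(attr(cls, "flagged")))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(junction_id = integer(0), row = numeric(0), col = numeric(0),
               class = character(0), order1 = integer(0),
               order2 = integer(0), d_parent = numeric(0), d1 = numeric(0),
               d2 = numeric(0), angle_deg = numeric(0),
               coefficient = numeric(0), in_annulus = logical(0),
               flagged = logical(0))
}

# measure all junction metrics for one vessel-class graph
measure_class <- function(graph, disc, vessel_class, image_id,
                          config = run_config()) {
  g <- graph
  flags <- character(0)
  rec <- data.frame(image_id = image_id, vessel_class = vessel_class,
                    MA = NA_real_, BA = NA_real_, BC = NA_real_,
                    BEA = NA_real_, BEC = NA_real_,
                    n_branching = 0L, n_bifurcation = 0L,
                    flags = "", stringsAsFactors = FALSE)
  if (is.null(g) || nrow(g$edges) == 0) {
    rec$flags <- "no vasculature"
    return(rec)
  }
  ma <- main_angle(g, disc, vertex = config$ma_vertex)
  rec$MA <- as.numeric(ma)
  if (!is.null(attr(ma, "flag"))) flags <- c(flags, attr(ma, "flag"))

  jt <- junction_table(g, disc, config)
  if (any(jt$flagged))
    flags <- c(flags, sprintf("junction %d has >2 daughters",
                              jt$junction_id[jt$flagged]))
  if (config$annulus_all_metrics) jt <- jt[jt$in_annulus, , drop = FALSE]
  br <- jt[jt$class == "branching", ]
  bi <- jt[jt$class == "bifurcation", ]
  rec$n_branching <- nrow(br)
  rec$n_bifurcation <- nrow(bi)
  if (any(is.finite(br$angle_deg))) rec$BA <- mean(br$angle_deg, na.rm = TRUE)
  if (any(is.finite(br$coefficient)))
    rec$BC <- mean(br$coefficient, na.rm = TRUE)
  if (any(is.finite(bi$angle_deg))) rec$BEA <- mean(bi$angle_deg, na.rm = TRUE)
  if (any(is.finite(bi$coefficient)))
    rec$BEC <- mean(bi$coefficient, na.rm = TRUE)
  if (nrow(jt) == 0L) flags <- c(flags, "no junctions in annulus")
  rec$flags <- paste(unique(flags), collapse = "; ")
  rec
}

# full path of an edge oriented to start at node_id
oriented_path <- function(g, eid, node_id) {
  p <- g$paths[[as.character(eid)]]
  e <- g$edges[g$edges$id == eid, ]
  if (e$to == node_id) p <- p[nrow(p):1, , drop = FALSE]
  p
}

#' Measure all vascular metrics for one image
#'
#' Iterates the annulus-restricted junctions of each vessel-class graph,
#' classifies them (branching vs bifurcation), averages the branch angle
#' and coefficient per class of junction, and measures the main angle
#' (not annulus-restricted). Metrics with zero qualifying junctions are
#' reported as \code{NA}, never 0.
#'
#' @param artery_graph,vein_graph rooted, ordered, crossing-resolved
#'   \code{skeleton_graph}s (either may be \code{NULL}).
#' @param disc a \code{disc_geometry}.
#' @param image_id identifier copied into the output rows.
#' @param config a \code{\link{run_config}}.
#' @return A data.frame with one row per vessel class: columns
#'   \code{image_id, vessel_class, MA, BA, BC, BEA, BEC, n_branching,
#'   n_bifurcation, flags}.
#' @export
measure_image <- function(artery_graph, vein_graph, disc, image_id = "image",
                          config = run_config()) {
  rbind(measure_class(artery_graph, disc, "artery", image_id, config),
        measure_class(vein_graph, disc, "vein", image_id, config))
}

#' Run the full mask-to-graph pipeline for one vessel class
#'
#' Convenience wrapper: skeletonize, build the graph, estimate diameters,
#' prune spurs, root at the disc, resolve crossings and assign Strahler
#' orders.
#'
#' @param mask a \code{raster_mask}.
#' @param disc a \code{disc_geometry}.
#' @param config a \code{\link{run_config}}.
#' @return A measured-ready \code{skeleton_graph}, or \code{NULL} when
#'   the mask holds no rootable vasculature.
#' @export
vessel_graph_from_mask <- function(mask, disc, config = run_config()) {
  if (!any(mask$grid)) return(NULL)
  skel <- suppressWarnings(skeletonize(mask))
  g <- build_graph(skel)
  if (nrow(g$edges) == 0) return(NULL)
  g <- estimate_diameters(mask, g)
  g <- prune_spurs(g, config$spur_min_length)
  if (nrow(g$edges) == 0) return(NULL)
  g <- tryCatch(root_components(g, disc, config$root_drop_dd),
                error = function(e) NULL)
  if (is.null(g)) return(NULL)
  g <- resolve_crossings(g)
  assign_strahler(g)
}
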