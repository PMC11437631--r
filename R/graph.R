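#' @importFrom stats aggregate
NULL

# Internal constructor for the centerline graph.
#
# nodes:  data.frame(id, row, col, degree, landmark, flagged)
# edges:  data.frame(id, from, to, length, mean_diameter, strahler_order,
#                    diam_flag)
# paths:  named list (edge id as character) of n x 2 matrices (row, col);
#         first and last rows are the incident node centroids, interior
#         rows are skeleton pixels
# node_pixels: named list (node id) of k x 2 integer matrices
new_skeleton_graph <- function(nodes, edges, paths, node_pixels, dims,
                               rooted = FALSE, roots = integer(0)) {
  structure(list(nodes = nodes, edges = edges, paths = paths,
                 node_pixels = node_pixels, dims = dims,
                 rooted = rooted, roots = roots),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$rooted) sprintf(", rooted (%d roots)", length(x$roots))
              else ""))
  invisible(x)
}

empty_graph <- function(dims) {
  new_skeleton_graph(
    nodes = data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                       degree = integer(0), landmark = character(0),
                       flagged = logical(0)),
    edges = data.frame(id = integer(0), from = integer(0), to = integer(0),
                       length = numeric(0), mean_diameter = numeric(0),
                       strahler_order = integer(0), diam_flag = logical(0)),
    paths = list(), node_pixels = list(), dims = dims)
}

# Euclidean polyline length; equals the 1/sqrt(2) chain metric on
# 8-connected pixel paths.
polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Build a centerline graph from a skeleton raster
#'
#' Nodes are placed at skeleton pixels with a neighbor count different
#' from two (endpoints and junction pixels); adjacent such pixels are
#' merged into a single node at their centroid, since thinning emits
#' small junction-pixel clusters at anatomical branch points. Edges trace
#' the maximal degree-2 pixel paths between node clusters. Every skeleton
#' pixel belongs to exactly one node cluster or one edge interior.
#'
#' @param skel logical matrix, a 1-px-wide skeleton (see
#'   \code{\link{skeletonize}}).
#' @return A \code{skeleton_graph}.
#' @export
build_graph <- function(skel) {
  stopifnot(is.matrix(skel))
  skel <- skel != 0
  dims <- dim(skel)
  if (!any(skel)) return(empty_graph(dims))
  nr <- nrow(skel); nc <- ncol(skel)
  nbc <- neighbor_count(skel)
  nodepix <- skel & nbc != 2L

  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]

  # label 8-connected clusters of node pixels
  nodelab <- matrix(0L, nr, nc)
  n_clusters <- 0L
  label_cluster_pixels <- function(pixmat) {
    # pixmat: k x 2 (row, col); returns membership vector 1..m
    k <- nrow(pixmat)
    if (k == 1) return(1L)
    idx <- (pixmat[, 2] - 1L) * nr + pixmat[, 1]
    el <- NULL
    for (o in seq_len(nrow(offs))) {
      rr <- pixmat[, 1] + offs$dr[o]; cc <- pixmat[, 2] + offs$dc[o]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nidx <- (cc - 1L) * nr + rr
      m <- match(nidx, idx)
      hit <- ok & !is.na(m)
      if (any(hit)) el <- rbind(el, cbind(which(hit), m[hit]))
    }
    gr <- igraph::graph_from_edgelist(
      if (is.null(el)) matrix(integer(0), 0, 2) else el, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, k - igraph::vcount(gr)))
    igraph::components(gr)$membership[seq_len(k)]
  }

  npix <- which(nodepix, arr.ind = TRUE)
  if (nrow(npix) > 0) {
    memb <- label_cluster_pixels(npix)
    n_clusters <- max(memb)
    nodelab[(npix[, 2] - 1L) * nr + npix[, 1]] <- as.integer(memb)
  }

  visited <- matrix(FALSE, nr, nc)
  edge_from <- integer(0); edge_to <- integer(0)
  interiors <- list()

  skel_neighbors <- function(r, c) {
    rr <- r + offs$dr; cc <- c + offs$dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ok[ok] <- skel[cbind(rr[ok], cc[ok])]
    cbind(rr[ok], cc[ok])
  }

  # walk a degree-2 path starting next to a node cluster
  walk <- function(sr, sc, from_label, np_r, np_c) {
    path <- matrix(NA_real_, 4096, 2)
    n <- 0L
    prev <- c(np_r, np_c); cur <- c(sr, sc); first <- TRUE
    repeat {
      visited[cur[1], cur[2]] <<- TRUE
      n <- n + 1L
      if (n > nrow(path)) path <- rbind(path, matrix(NA_real_, nrow(path), 2))
      path[n, ] <- cur
      nb <- skel_neighbors(cur[1], cur[2])
      keep <- !(nb[, 1] == prev[1] & nb[, 2] == prev[2])
      cand <- nb[keep, , drop = FALSE]
      labs <- nodelab[cbind(cand[, 1], cand[, 2])]
      is_node <- labs > 0L
      if (first && any(!is_node) && any(is_node & labs == from_label)) {
        # don't immediately fall back into the cluster we started from
        cand <- cand[!(is_node & labs == from_label), , drop = FALSE]
        labs <- labs[!(is_node & labs == from_label)]
        is_node <- labs > 0L
      }
      first <- FALSE
      if (any(is_node)) {
        to_label <- labs[is_node][1]
        return(list(to = to_label, interior = path[seq_len(n), , drop = FALSE]))
      }
      if (nrow(cand) == 0L)
        return(list(to = from_label, interior = path[seq_len(n), , drop = FALSE]))
      nxt <- cand[1, ]
      if (visited[nxt[1], nxt[2]])
        return(list(to = from_label, interior = path[seq_len(n), , drop = FALSE]))
      prev <- cur; cur <- nxt
    }
  }

  trace_from_cluster <- function(label, pix) {
    for (i in seq_len(nrow(pix))) {
      nb <- skel_neighbors(pix[i, 1], pix[i, 2])
      if (nrow(nb) == 0) next
      labs <- nodelab[cbind(nb[, 1], nb[, 2])]
      starts <- nb[labs == 0L, , drop = FALSE]
      for (j in seq_len(nrow(starts))) {
        if (visited[starts[j, 1], starts[j, 2]]) next
        w <- walk(starts[j, 1], starts[j, 2], label, pix[i, 1], pix[i, 2])
        edge_from <<- c(edge_from, label)
        edge_to <<- c(edge_to, w$to)
        interiors[[length(interiors) + 1L]] <<- w$interior
      }
    }
  }

  cluster_pix <- split.data.frame(as.data.frame(npix),
                                  nodelab[(npix[, 2] - 1L) * nr + npix[, 1]])
  cluster_pix <- lapply(cluster_pix, as.matrix)
  for (lab in names(cluster_pix))
    trace_from_cluster(as.integer(lab), cluster_pix[[lab]])

  # pure cycles: degree-2 components with no node pixel; promote one pixel
  leftover <- skel & !nodepix & !visited
  while (any(leftover)) {
    ij <- which(leftover, arr.ind = TRUE)[1, , drop = FALSE]
    n_clusters <- n_clusters + 1L
    nodelab[ij] <- n_clusters
    nodepix[ij] <- TRUE
    cluster_pix[[as.character(n_clusters)]] <- ij
    trace_from_cluster(n_clusters, ij)
    leftover <- skel & !nodepix & !visited
  }

  # assemble nodes
  ids <- sort(as.integer(names(cluster_pix)))
  cent <- t(vapply(as.character(ids), function(k) colMeans(cluster_pix[[k]]),
                   numeric(2)))
  deg <- integer(length(ids))
  if (length(edge_from)) {
    tab <- table(factor(c(edge_from, edge_to), levels = ids))
    deg <- as.integer(tab)
  }
  nodes <- data.frame(id = ids, row = cent[, 1], col = cent[, 2],
                      degree = deg,
                      landmark = ifelse(deg >= 3, "junction", "endpoint"),
                      flagged = FALSE, stringsAsFactors = FALSE)

  ne <- length(edge_from)
  edges <- data.frame(id = seq_len(ne), from = edge_from,
                      to = edge_to, length = rep(NA_real_, ne),
                      mean_diameter = rep(NA_real_, ne),
                      strahler_order = rep(NA_integer_, ne),
                      diam_flag = rep(FALSE, ne))
  paths <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    cf <- cent[match(edge_from[i], ids), ]
    ct <- cent[match(edge_to[i], ids), ]
    paths[[i]] <- rbind(cf, interiors[[i]], ct)
    rownames(paths[[i]]) <- NULL
    edges$length[i] <- polyline_length(paths[[i]])
  }
  names(paths) <- as.character(edges$id)
  node_pixels <- cluster_pix
  names(node_pixels) <- as.character(as.integer(names(cluster_pix)))

  new_skeleton_graph(nodes, edges, paths, node_pixels, dims)
}

# recompute degrees from the edge table (self-loops count twice)
refresh_degrees <- function(g) {
  tab <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes$id))
  g$nodes$degree <- as.integer(tab)
  lm <- g$nodes$landmark
  is_root <- lm == "root"
  g$nodes$landmark <- ifelse(is_root, "root",
                             ifelse(g$nodes$degree >= 3, "junction", "endpoint"))
  g
}

# merge chains through a degree-2 node v; returns modified graph
merge_through_node <- function(g, v) {
  eids <- g$edges$id[g$edges$from == v | g$edges$to == v]
  if (length(eids) != 2) return(g)
  e1 <- g$edges[g$edges$id == eids[1], ]
  e2 <- g$edges[g$edges$id == eids[2], ]
  a <- if (e1$from == v) e1$to else e1$from
  b <- if (e2$from == v) e2$to else e2$from
  p1 <- g$paths[[as.character(e1$id)]]
  p2 <- g$paths[[as.character(e2$id)]]
  if (e1$to != v) p1 <- p1[nrow(p1):1, , drop = FALSE]    # a -> v
  if (e2$from != v) p2 <- p2[nrow(p2):1, , drop = FALSE]  # v -> b
  newp <- rbind(p1, p2[-1, , drop = FALSE])
  len <- e1$length + e2$length
  md <- if (is.na(e1$mean_diameter) || is.na(e2$mean_diameter)) NA_real_
        else (e1$mean_diameter * e1$length + e2$mean_diameter * e2$length) /
             max(len, .Machine$double.eps)
  nid <- max(g$edges$id) + 1L
  g$edges <- g$edges[!(g$edges$id %in% eids), ]
  g$edges <- rbind(g$edges,
                   data.frame(id = nid, from = a, to = b, length = len,
                              mean_diameter = md, strahler_order = NA_integer_,
                              diam_flag = e1$diam_flag || e2$diam_flag))
  g$paths[[as.character(e1$id)]] <- NULL
  g$paths[[as.character(e2$id)]] <- NULL
  g$paths[[as.character(nid)]] <- newp
  # fold the node's pixels into nothing (centroid stays inside the path)
  g$nodes <- g$nodes[g$nodes$id != v, ]
  g$node_pixels[[as.character(v)]] <- NULL
  refresh_degrees(g)
}

#' Remove short terminal spurs and simplify the graph
#'
#' Iteratively deletes terminal edges (one endpoint of degree one,
#' attached to a junction) shorter than \code{min_length}, then merges
#' the two surviving edges of any resulting degree-2 node into one
#' (paths concatenated, diameters length-weighted averaged), repeating
#' to a fixpoint. Isolated segments (both endpoints terminal) are whole
#' vessels, not thinning artifacts, and are kept.
#'
#' With \code{min_length = NULL} an adaptive threshold
#' \code{max(5, 1.5 * d)} px is used per spur, where \code{d} is the
#' largest mean diameter among the other edges at its junction (spur
#' artifacts scale with vessel width); edges without diameters fall back
#' to 5 px.
#'
#' @param graph a \code{skeleton_graph}.
#' @param min_length numeric threshold in px, 0 for no pruning, or
#'   \code{NULL} for the adaptive default.
#' @return The pruned \code{skeleton_graph}.
#' @export
prune_spurs <- function(graph, min_length = NULL) {
  g <- graph
  if (!is.null(min_length) && min_length <= 0) return(g)
  repeat {
    g <- refresh_degrees(g)
    g <- drop_artifact_loops(g)
    g <- bust_small_cycles(g)
    g <- contract_junction_complexes(g)
    deg <- g$nodes$degree; names(deg) <- g$nodes$id
    e <- g$edges
    d_from <- deg[as.character(e$from)]; d_to <- deg[as.character(e$to)]
    term <- xor(d_from == 1, d_to == 1)   # spur: exactly one loose end
    if (any(term)) {
      thr <- if (!is.null(min_length)) rep(min_length, nrow(e)) else {
        vapply(seq_len(nrow(e)), function(i) {
          jn <- if (d_from[i] == 1) e$to[i] else e$from[i]
          others <- e$mean_diameter[(e$from == jn | e$to == jn) &
                                      e$id != e$id[i]]
          others <- others[!is.na(others)]
          if (length(others)) max(5, 1.5 * max(others)) else 5
        }, numeric(1))
      }
      kill <- term & e$length < thr
    } else kill <- logical(nrow(e))
    removed <- FALSE
    if (any(kill)) {
      drop_ids <- e$id[kill]
      loose <- ifelse(d_from[kill] == 1, e$from[kill], e$to[kill])
      g$edges <- g$edges[!(g$edges$id %in% drop_ids), ]
      for (id in drop_ids) g$paths[[as.character(id)]] <- NULL
      keep_nodes <- !(g$nodes$id %in% loose)
      for (v in g$nodes$id[!keep_nodes])
        g$node_pixels[[as.character(v)]] <- NULL
      g$nodes <- g$nodes[keep_nodes, ]
      g <- refresh_degrees(g)
      removed <- TRUE
    }
    # merge pass-through nodes created by pruning
    merged <- TRUE
    while (merged) {
      merged <- FALSE
      cand <- g$nodes$id[g$nodes$degree == 2 & g$nodes$landmark != "root"]
      for (v in cand) {
        eids <- g$edges$id[g$edges$from == v | g$edges$to == v]
        if (length(eids) == 2) {   # excludes self-loops
          g <- merge_through_node(g, v)
          merged <- TRUE
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }
  g
}

# Junction bulges of three thick overlapping strokes can thin into a
# small ring (a cycle of short edges between degree->=3 nodes). Break
# every such short cycle by dropping its thinnest edge. Long cycles
# (two distinct vessels crossing twice, resolved later as crossings)
# are left alone.
bust_small_cycles <- function(g, max_total = NULL) {
  repeat {
    if (nrow(g$edges) < 2) return(g)
    ig <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(g$edges$from),
                     to = as.character(g$edges$to),
                     eid = g$edges$id),
      directed = FALSE,
      vertices = data.frame(name = as.character(g$nodes$id)))
    gi <- igraph::girth(ig)
    if (!is.finite(gi$girth) || gi$girth == 0) return(g)
    vcyc <- as.integer(names(gi$circle))
    # edges along the cycle (for a 2-cycle: the parallel pair)
    eids <- integer(0)
    nv <- length(vcyc)
    for (i in seq_len(nv)) {
      a <- vcyc[i]; b <- vcyc[if (i == nv) 1 else i + 1]
      cand <- g$edges$id[(g$edges$from == a & g$edges$to == b) |
                           (g$edges$from == b & g$edges$to == a)]
      if (length(cand)) eids <- c(eids, cand)
    }
    eids <- unique(eids)
    if (length(eids) < 2) return(g)
    rows <- match(eids, g$edges$id)
    total <- sum(g$edges$length[rows])
    dmax <- suppressWarnings(max(g$edges$mean_diameter[rows], na.rm = TRUE))
    if (!is.finite(dmax)) dmax <- 5
    thr <- if (is.null(max_total)) max(30, 5 * dmax) else max_total
    if (total >= thr) return(g)
    drop_row <- rows[order(ifelse(is.na(g$edges$mean_diameter[rows]), 0,
                                  g$edges$mean_diameter[rows]))][1]
    drop_id <- g$edges$id[drop_row]
    g$edges <- g$edges[g$edges$id != drop_id, ]
    g$paths[[as.character(drop_id)]] <- NULL
    g <- refresh_degrees(g)
  }
}

# Thinning of strokes that overlap at shallow angles can trap single
# background pixels, leaving tiny skeleton loops: short self-loop edges
# and short parallel edge pairs. Drop them (the thinner of a parallel
# pair), keeping the graph a tree locally.
drop_artifact_loops <- function(g, max_len = NULL) {
  e <- g$edges
  if (nrow(e) < 1) return(g)
  thr <- function(i) {
    d <- e$mean_diameter[i]
    if (is.null(max_len)) max(15, 3 * ifelse(is.na(d), 5, d)) else max_len
  }
  drop <- integer(0)
  self <- which(e$from == e$to)
  for (i in self) if (e$length[i] < thr(i)) drop <- c(drop, e$id[i])
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  dup <- setdiff(dup, self)
  for (k in unique(key[dup])) {
    idx <- which(key == k & e$from != e$to)
    if (length(idx) < 2) next
    if (all(e$length[idx] < vapply(idx, thr, numeric(1)))) {
      keep <- idx[order(-ifelse(is.na(e$mean_diameter[idx]), 0,
                                e$mean_diameter[idx]), e$length[idx])][1]
      drop <- c(drop, setdiff(e$id[idx], e$id[keep]))
    }
  }
  if (length(drop)) {
    g$edges <- g$edges[!(g$edges$id %in% drop), ]
    for (id in drop) g$paths[[as.character(id)]] <- NULL
    g <- refresh_degrees(g)
  }
  g
}

# Thinning can split one anatomical branch point into two nodes a
# couple of pixels apart. Contract internal edges (both endpoints of
# degree >= 3) shorter than about one vessel diameter into a single
# node.
contract_junction_complexes <- function(g) {
  repeat {
    g <- refresh_degrees(g)
    deg <- g$nodes$degree; names(deg) <- g$nodes$id
    e <- g$edges
    thr <- pmax(6, 1.2 * ifelse(is.na(e$mean_diameter), 4, e$mean_diameter))
    cand <- which(e$from != e$to &
                    deg[as.character(e$from)] >= 3 &
                    deg[as.character(e$to)] >= 3 &
                    e$length < thr)
    if (length(cand) == 0) break
    i <- cand[1]
    u <- e$from[i]; v <- e$to[i]
    iu <- match(u, g$nodes$id); iv <- match(v, g$nodes$id)
    w <- max(g$nodes$id) + 1L
    pos <- c(mean(g$nodes$row[c(iu, iv)]), mean(g$nodes$col[c(iu, iv)]))
    g$nodes <- rbind(g$nodes,
                     data.frame(id = w, row = pos[1], col = pos[2],
                                degree = 0L, landmark = "junction",
                                flagged = g$nodes$flagged[iu] ||
                                  g$nodes$flagged[iv]))
    px <- rbind(g$node_pixels[[as.character(u)]],
                g$node_pixels[[as.character(v)]])
    g$node_pixels[[as.character(w)]] <- px
    drop_id <- e$id[i]
    g$edges <- g$edges[g$edges$id != drop_id, ]
    g$paths[[as.character(drop_id)]] <- NULL
    for (j in seq_len(nrow(g$edges))) {
      key <- as.character(g$edges$id[j])
      if (g$edges$from[j] %in% c(u, v)) {
        g$edges$from[j] <- w
        g$paths[[key]][1, ] <- pos
      }
      if (g$edges$to[j] %in% c(u, v)) {
        g$edges$to[j] <- w
        g$paths[[key]][nrow(g$paths[[key]]), ] <- pos
      }
      g$edges$length[j] <- polyline_length(g$paths[[key]])
    }
    g$nodes <- g$nodes[!(g$nodes$id %in% c(u, v)), ]
    g$node_pixels[[as.character(u)]] <- NULL
    g$node_pixels[[as.character(v)]] <- NULL
  }
  refresh_degrees(g)
}

#' Estimate per-edge vessel diameters from the mask
#'
#' For every edge, the diameter is the mean over its centerline pixels
#' of the local stroke width, measured with subpixel precision: from
#' each retained centerline pixel the mask is sampled by bilinear
#' interpolation along both normals of the local path tangent, and the
#' 0.5-level crossing marks the vessel boundary on each side. Pixels
#' within one local radius (Euclidean distance transform at the node) of
#' either end node are excluded, since junction bulges inflate the width
#' there; edges too short to retain any pixel fall back to the all-pixel
#' mean and are flagged.
#'
#' @param mask the \code{raster_mask} the graph was derived from.
#' @param graph a \code{skeleton_graph}.
#' @return The graph with \code{mean_diameter} set on every edge.
#' @export
estimate_diameters <- function(mask, graph) {
  stopifnot(inherits(mask, "raster_mask"))
  g <- graph
  gm <- mask$grid * 1
  dt <- as.matrix(EBImage::distmap(gm))
  nr <- nrow(gm); nc <- ncol(gm)
  dt_at <- function(r, c) {
    r <- pmin(pmax(round(r), 1), nr); c <- pmin(pmax(round(c), 1), nc)
    dt[cbind(r, c)]
  }
  bilinear <- function(r, c) {
    r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
    r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
    fr <- r - r0; fc <- c - c0
    gm[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      gm[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      gm[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      gm[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  # subpixel distance to the 0.5 boundary along direction (ur, uc)
  half_width <- function(pr, pc, ur, uc, rmax) {
    ts <- seq(0, rmax, by = 0.25)
    v <- bilinear(pr + ts * ur, pc + ts * uc)
    k <- which(v < 0.5)[1]
    if (is.na(k)) return(NA_real_)          # never exits: overlap region
    if (k == 1) return(0)
    ts[k - 1] + 0.25 * (v[k - 1] - 0.5) / (v[k - 1] - v[k])
  }
  for (i in seq_len(nrow(g$edges))) {
    p <- g$paths[[as.character(g$edges$id[i])]]
    n <- nrow(p)
    interior <- if (n > 2) p[2:(n - 1), , drop = FALSE] else p
    from_pos <- p[1, ]; to_pos <- p[n, ]
    r_from <- dt_at(from_pos[1], from_pos[2])
    r_to <- dt_at(to_pos[1], to_pos[2])
    dist_from <- sqrt((interior[, 1] - from_pos[1])^2 +
                      (interior[, 2] - from_pos[2])^2)
    dist_to <- sqrt((interior[, 1] - to_pos[1])^2 +
                    (interior[, 2] - to_pos[2])^2)
    keep <- dist_from > r_from & dist_to > r_to
    flag <- !any(keep)
    idx <- if (flag) seq_len(nrow(interior)) else which(keep)
    # smooth the pixel chain before taking tangents: staircase zigzag
    # tilts the normals and inflates the measured width by 1/cos(phi)
    sm <- interior
    if (nrow(interior) >= 5) {
      kk <- seq_len(nrow(interior))
      sm[, 1] <- stats::filter(interior[, 1], rep(1 / 5, 5), sides = 2)
      sm[, 2] <- stats::filter(interior[, 2], rep(1 / 5, 5), sides = 2)
      sm[is.na(sm[, 1]), ] <- interior[is.na(sm[, 1]), ]
    }
    widths <- numeric(0)   # one entry per retained pixel, in path order
    centered <- interior
    for (k in seq_len(nrow(interior))) {
      k0 <- max(k - 3L, 1L); k1 <- min(k + 3L, nrow(interior))
      tg <- sm[k1, ] - sm[k0, ]
      nt <- sqrt(sum(tg^2))
      if (nt < .Machine$double.eps) next
      tu <- tg / nt
      nrm <- c(-tu[2], tu[1])
      rmax <- dt_at(interior[k, 1], interior[k, 2]) + 3
      # sample at three tangent phases to break grid aliasing of
      # axis- and diagonal-aligned strokes
      ws <- numeric(0); offs <- numeric(0)
      for (ph in c(0, 1 / 3, 2 / 3)) {
        pr <- interior[k, 1] + ph * tu[1]; pc <- interior[k, 2] + ph * tu[2]
        hp <- half_width(pr, pc, nrm[1], nrm[2], rmax)
        hm <- half_width(pr, pc, -nrm[1], -nrm[2], rmax)
        if (!is.na(hp) && !is.na(hm)) {
          ws <- c(ws, hp + hm)
          offs <- c(offs, (hp - hm) / 2)
        }
      }
      if (length(ws)) {
        if (k %in% idx) widths <- c(widths, mean(ws))
        # re-center the stored path point on the subpixel midpoint of
        # the stroke profile; downstream direction fits gain subpixel
        # precision
        off <- mean(offs)
        if (abs(off) <= 1.5)
          centered[k, ] <- interior[k, ] + off * nrm
      }
    }
    if (n > 2) {
      p[2:(n - 1), ] <- centered
      g$paths[[as.character(g$edges$id[i])]] <- p
      g$edges$length[i] <- polyline_length(p)
    }
    if (length(widths)) {
      g$edges$mean_diameter[i] <- max(robust_edge_width(widths), 0.5)
      g$edges$diam_flag[i] <- flag
    } else {
      # single-pixel-scale edge: fall back to the distance transform
      g$edges$mean_diameter[i] <-
        max(mean(2 * dt_at(interior[, 1], interior[, 2]) - 1), 1)
      g$edges$diam_flag[i] <- TRUE
    }
  }
  g
}

#' Root each connected component at the disc and orient edges outward
#'
#' For every connected component the node nearest the optic-disc center
#' becomes the root; edges are re-oriented to point away from it
#' (\code{from} = parent side). Components whose nearest node lies
#' farther than \code{max_dist_dd} disc diameters from the disc center
#' are dropped as unrooted debris.
#'
#' @param graph a \code{skeleton_graph}.
#' @param disc a \code{disc_geometry}.
#' @param max_dist_dd drop radius in disc diameters (default 3).
#' @return A rooted, directed \code{skeleton_graph}.
#' @export
root_components <- function(graph, disc, max_dist_dd = 3) {
  stopifnot(inherits(disc, "disc_geometry"))
  g <- graph
  if (nrow(g$nodes) == 0) stop("no rooted vasculature")
  comp <- graph_components(g)
  keep_nodes <- integer(0); roots <- integer(0)
  dcen <- disc$center
  for (cc in unique(comp)) {
    nid <- g$nodes$id[comp == cc]
    nd <- g$nodes[comp == cc, ]
    d <- sqrt((nd$row - dcen[1])^2 + (nd$col - dcen[2])^2)
    if (min(d) > max_dist_dd * disc$diameter) next
    keep_nodes <- c(keep_nodes, nid)
    roots <- c(roots, nid[which.min(d)])
  }
  if (length(keep_nodes) == 0) stop("no rooted vasculature")
  drop <- setdiff(g$nodes$id, keep_nodes)
  if (length(drop)) {
    g$edges <- g$edges[!(g$edges$from %in% drop | g$edges$to %in% drop), ]
    g$paths <- g$paths[as.character(g$edges$id)]
    g$nodes <- g$nodes[g$nodes$id %in% keep_nodes, ]
    for (v in drop) g$node_pixels[[as.character(v)]] <- NULL
  }
  g$nodes$landmark[g$nodes$id %in% roots] <- "root"
  g <- orient_from_roots(g, roots)
  g$rooted <- TRUE
  g$roots <- roots
  refresh_degrees(g)
}

# Average the per-pixel stroke widths of one edge, discarding the
# stretches near either end that are still contaminated by junction
# bulges or sibling-stroke fusion: anchor on the median of the middle
# third, then trim inward from both ends while samples deviate from it.
robust_edge_width <- function(w) {
  n <- length(w)
  if (n < 6) return(stats::median(w))
  mid <- w[ceiling(n / 3):floor(2 * n / 3)]
  med <- stats::median(mid)
  tol <- max(0.15 * med, 0.6)
  lo <- 1L
  while (lo < n && abs(w[lo] - med) > tol) lo <- lo + 1L
  hi <- n
  while (hi > 1 && abs(w[hi] - med) > tol) hi <- hi - 1L
  core <- w[lo:hi]
  core <- core[abs(core - med) <= 2 * tol]
  if (length(core) < 3) med else mean(core)
}

# undirected connected-component labels aligned with g$nodes rows
graph_components <- function(g) {
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$edges$from),
                   to = as.character(g$edges$to)),
    directed = FALSE, vertices = data.frame(name = as.character(g$nodes$id)))
  igraph::components(ig)$membership[as.character(g$nodes$id)]
}

# BFS orientation: every edge points away from its component root
orient_from_roots <- function(g, roots) {
  inc <- split(c(g$edges$id, g$edges$id),
               c(g$edges$from, g$edges$to))
  order_seen <- rep(NA_integer_, nrow(g$nodes))
  names(order_seen) <- g$nodes$id
  cnt <- 0L
  for (r in roots) {
    if (!is.na(order_seen[as.character(r)])) next
    q <- r
    cnt <- cnt + 1L
    order_seen[as.character(r)] <- cnt
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (eid in inc[[as.character(v)]]) {
        row <- which(g$edges$id == eid)
        u <- if (g$edges$from[row] == v) g$edges$to[row] else g$edges$from[row]
        if (is.na(order_seen[as.character(u)])) {
          cnt <- cnt + 1L
          order_seen[as.character(u)] <- cnt
          if (g$edges$from[row] != v) g <- reverse_edge(g, row)
          q <- c(q, u)
        } else if (order_seen[as.character(u)] <
                     order_seen[as.character(v)] &&
                   g$edges$from[row] == v) {
          # non-tree edge: orient from the earlier-discovered node
          g <- reverse_edge(g, row)
        }
      }
    }
  }
  g
}

reverse_edge <- function(g, row) {
  tmp <- g$edges$from[row]
  g$edges$from[row] <- g$edges$to[row]
  g$edges$to[row] <- tmp
  key <- as.character(g$edges$id[row])
  p <- g$paths[[key]]
  g$paths[[key]] <- p[nrow(p):1, , drop = FALSE]
  g
}

# unit tangent of an edge at one of its nodes, pointing away from it,
# estimated from the point at arc length `reach` along the path
edge_tangent <- function(g, eid, node_id, reach = 6) {
  e <- g$edges[g$edges$id == eid, ]
  p <- g$paths[[as.character(eid)]]
  if (e$to == node_id) p <- p[nrow(p):1, , drop = FALSE]
  pos <- p[1, ]
  cum <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  k <- which(cum >= min(reach, max(cum)))[1]
  if (is.na(k) || k < 2) k <- nrow(p)
  v <- p[k, ] - pos
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps) c(0, 0) else v / nv
}

#' Export a skeleton graph as JSON
#'
#' Writes nodes (id, position, degree, landmark), edges (id, endpoints,
#' length, mean diameter, Strahler order) and pixel paths for external
#' inspection.
#'
#' @param graph a \code{skeleton_graph}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  out <- list(
    nodes = graph$nodes,
    edges = graph$edges,
    paths = lapply(graph$paths, function(p) unname(as.matrix(p))),
    rooted = graph$rooted, roots = graph$roots, dims = graph$dims)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
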