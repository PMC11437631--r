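#' Resolve vessel crossings at degree-4 nodes
#'
#' A degree-4 skeleton node is an image location where two distinct
#' vessels overlap, not an anatomical junction. Each such node is split
#' into two pass-through vessel paths by pairing its four incident edges
#' so that total tangent-direction continuity is maximal (each incoming
#' edge is paired with the outgoing edge closest to a 180-degree
#' continuation); ties are broken by diameter similarity. The node is
#' removed and paired edges merged, so total skeleton length is
#' conserved. Nodes of degree 5 or more are pathological: they are
#' flagged and excluded from measurement, not split.
#'
#' @param graph a rooted \code{skeleton_graph}
#'   (see \code{\link{root_components}}).
#' @return A \code{skeleton_graph} in which every former degree-4 node
#'   has been replaced by two continuous paths; with single-vessel-class
#'   masks the result is a forest.
#' @export
resolve_crossings <- function(graph) {
  g <- refresh_degrees(graph)
  g <- contract_x_connectors(g)
  repeat {
    cand <- g$nodes$id[g$nodes$degree == 4 & g$nodes$landmark != "root"]
    # only nodes with 4 distinct incident edges (self-loops disqualify)
    cand <- Filter(function(v) {
      sum(g$edges$from == v) + sum(g$edges$to == v) == 4 &&
        !any(g$edges$from == v & g$edges$to == v)
    }, cand)
    if (length(cand) == 0) break
    v <- cand[[1]]
    eids <- g$edges$id[g$edges$from == v | g$edges$to == v]
    dirs <- lapply(eids, function(e) edge_tangent(g, e, v))
    diams <- g$edges$mean_diameter[match(eids, g$edges$id)]
    pairings <- list(rbind(c(1, 2), c(3, 4)),
                     rbind(c(1, 3), c(2, 4)),
                     rbind(c(1, 4), c(2, 3)))
    score <- vapply(pairings, function(pr) {
      sum(vapply(seq_len(2), function(k) {
        a <- dirs[[pr[k, 1]]]; b <- dirs[[pr[k, 2]]]
        angle_between(a, b)   # straight continuation ~ 180
      }, numeric(1)))
    }, numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1 && !all(is.na(diams))) {
      dsim <- vapply(pairings[best], function(pr) {
        sum(abs(diams[pr[, 1]] - diams[pr[, 2]]), na.rm = TRUE)
      }, numeric(1))
      best <- best[which.min(dsim)]
    }
    pr <- pairings[[best[1]]]
    for (k in 1:2) g <- merge_pair_at(g, v, eids[pr[k, 1]], eids[pr[k, 2]])
    g$nodes <- g$nodes[g$nodes$id != v, ]
    g$node_pixels[[as.character(v)]] <- NULL
    g <- refresh_degrees(g)
  }
  high <- g$nodes$degree >= 5
  if (any(high)) g$nodes$flagged[high] <- TRUE
  if (g$rooted) g <- orient_from_roots(g, g$roots)
  refresh_degrees(g)
}

# Thinning renders a crossing of two thick vessels at a shallow angle
# as two degree-3 nodes joined by a short connector (an X split into
# two Ys). Detect the X signature - the four outer edges pair into two
# near-straight continuations across the connector - and contract the
# connector so the node becomes degree 4 and is resolved as a crossing.
contract_x_connectors <- function(g) {
  repeat {
    g <- refresh_degrees(g)
    deg <- g$nodes$degree; names(deg) <- g$nodes$id
    e <- g$edges
    dmax <- ifelse(is.na(e$mean_diameter), 5, e$mean_diameter)
    cand <- which(e$from != e$to &
                    deg[as.character(e$from)] == 3 &
                    deg[as.character(e$to)] == 3 &
                    e$length < 2.5 * pmax(dmax, 4))
    hit <- FALSE
    for (i in cand) {
      u <- e$from[i]; v <- e$to[i]
      eu <- setdiff(g$edges$id[g$edges$from == u | g$edges$to == u],
                    e$id[i])
      ev <- setdiff(g$edges$id[g$edges$from == v | g$edges$to == v],
                    e$id[i])
      if (length(eu) != 2 || length(ev) != 2) next
      du <- lapply(eu, function(id) edge_tangent(g, id, u, reach = 10))
      dv <- lapply(ev, function(id) edge_tangent(g, id, v, reach = 10))
      sc <- sapply(1:2, function(k) {
        min(angle_between(du[[1]], dv[[k]]),
            angle_between(du[[2]], dv[[3 - k]]))
      })
      if (max(sc, na.rm = TRUE) < 140) next   # not a straight-through X
      # contract u and v into one degree-4 node
      iu <- match(u, g$nodes$id); iv <- match(v, g$nodes$id)
      w <- max(g$nodes$id) + 1L
      pos <- c(mean(g$nodes$row[c(iu, iv)]), mean(g$nodes$col[c(iu, iv)]))
      g$nodes <- rbind(g$nodes,
                       data.frame(id = w, row = pos[1], col = pos[2],
                                  degree = 0L, landmark = "junction",
                                  flagged = FALSE))
      g$node_pixels[[as.character(w)]] <-
        rbind(g$node_pixels[[as.character(u)]],
              g$node_pixels[[as.character(v)]])
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
      hit <- TRUE
      break
    }
    if (!hit) break
  }
  refresh_degrees(g)
}

# merge two edges meeting at v into one pass-through edge
merge_pair_at <- function(g, v, e1_id, e2_id) {
  e1 <- g$edges[g$edges$id == e1_id, ]
  e2 <- g$edges[g$edges$id == e2_id, ]
  a <- if (e1$from == v) e1$to else e1$from
  b <- if (e2$from == v) e2$to else e2$from
  p1 <- g$paths[[as.character(e1_id)]]
  p2 <- g$paths[[as.character(e2_id)]]
  if (e1$to != v) p1 <- p1[nrow(p1):1, , drop = FALSE]   # a -> v
  if (e2$from != v) p2 <- p2[nrow(p2):1, , drop = FALSE] # v -> b
  newp <- rbind(p1, p2[-1, , drop = FALSE])
  len <- e1$length + e2$length
  md <- if (is.na(e1$mean_diameter) || is.na(e2$mean_diameter)) NA_real_
        else (e1$mean_diameter * e1$length + e2$mean_diameter * e2$length) /
             max(len, .Machine$double.eps)
  nid <- max(g$edges$id) + 1L
  g$edges <- g$edges[!(g$edges$id %in% c(e1_id, e2_id)), ]
  g$edges <- rbind(g$edges,
                   data.frame(id = nid, from = a, to = b, length = len,
                              mean_diameter = md,
                              strahler_order = NA_integer_,
                              diam_flag = e1$diam_flag || e2$diam_flag))
  g$paths[[as.character(e1_id)]] <- NULL
  g$paths[[as.character(e2_id)]] <- NULL
  g$paths[[as.character(nid)]] <- newp
  g
}

# interior angle between two direction vectors, degrees in [0, 180]
angle_between <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < .Machine$double.eps || nb < .Machine$double.eps) return(NA_real_)
  d <- sum(a * b) / (na * nb)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Assign Strahler orders to a rooted vessel forest
#'
#' Terminal edges receive order 1. A parent edge's order is \code{m + 1}
#' when at least two of its daughter edges attain the maximal daughter
#' order \code{m}, and \code{m} otherwise. The root edge of each
#' component therefore carries the component's maximal order.
#'
#' @param graph a rooted, crossing-resolved \code{skeleton_graph}; must
#'   contain no directed cycle.
#' @return The graph with \code{strahler_order} set on every edge.
#' @export
assign_strahler <- function(graph) {
  g <- graph
  if (!g$rooted) stop("graph must be rooted (see root_components)")
  if (nrow(g$edges) == 0) return(g)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(g$edges$from),
                   to = as.character(g$edges$to)),
    directed = TRUE, vertices = data.frame(name = as.character(g$nodes$id)))
  if (!igraph::is_dag(ig))
    stop("cycle detected: resolve crossings before ordering")
  topo <- as.integer(names(igraph::topo_sort(ig, mode = "out")))
  ord <- rep(NA_integer_, nrow(g$edges))
  out_of <- split(seq_len(nrow(g$edges)), g$edges$from)
  # process child-most nodes first
  for (v in rev(topo)) {
    rows_in <- which(g$edges$to == v)
    outs <- out_of[[as.character(v)]]
    o <- if (is.null(outs) || length(outs) == 0) NULL else ord[outs]
    for (r in rows_in) {
      if (is.null(o)) ord[r] <- 1L
      else {
        m <- max(o)
        ord[r] <- if (sum(o == m) >= 2L) m + 1L else m
      }
    }
  }
  g$edges$strahler_order <- ord
  g
}

#' Classify a junction from its daughter Strahler orders
#'
#' A junction whose two daughter vessels carry the same Strahler order is
#' a bifurcation point (a vessel dividing into two similar vessels); a
#' junction whose daughters carry differing orders is a branching point
#' (a smaller vessel leaving the main vessel). Junctions with more than
#' two daughters are classified on the two largest-diameter daughters and
#' flagged.
#'
#' @param daughter_orders integer vector of daughter Strahler orders
#'   (length >= 2).
#' @param daughter_diameters optional diameters, required to pick the two
#'   dominant daughters when more than two are present.
#' @return \code{"bifurcation"} or \code{"branching"}; attribute
#'   \code{flagged} is \code{TRUE} for over-split junctions.
#' @export
classify_junction <- function(daughter_orders, daughter_diameters = NULL) {
  if (length(daughter_orders) < 2) stop("a junction needs >= 2 daughters")
  flagged <- FALSE
  o <- daughter_orders
  if (length(o) > 2) {
    flagged <- TRUE
    if (is.null(daughter_diameters) ||
        length(daughter_diameters) != length(o))
      stop("daughter_diameters required to classify > 2 daughters")
    keep <- order(daughter_diameters, decreasing = TRUE)[1:2]
    o <- o[keep]
  }
  cls <- if (o[1] == o[2]) "bifurcation" else "branching"
  attr(cls, "flagged") <- flagged
  cls
}
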