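#' Skeletonize a binary vessel mask
#'
#' Topology-preserving thinning of the vessel mask down to an
#' 8-connected, one-pixel-wide centerline. The skeleton is a subset of
#' the foreground, preserves the 8-connectivity of each component, and
#' the operation is idempotent: thinning a skeleton returns it
#' unchanged.
#'
#' The implementation is directional sequential border peeling: in each
#' iteration four sub-passes (north, south, east, west) freeze the
#' pixels whose respective side touches background and delete them one
#' at a time when they are 8-simple (the foreground 8-neighbors form a
#' single connected set and a 4-neighbor is background, checked via a
#' precomputed lookup table against the live image) and not endpoints.
#' Sequential deletion with a true simple-point test can never
#' disconnect a component or delete a stroke outright - failure modes
#' of the classical parallel Zhang-Suen and Guo-Hall schemes on
#' two-pixel-wide diagonals - and the alternating directions peel
#' symmetrically, keeping the skeleton on the medial axis. A final pass
#' removes redundant staircase pixels so junctions appear as compact
#' clusters.
#'
#' @param mask a \code{raster_mask}, or a binary matrix.
#' @return A logical matrix of the same dimensions (the skeleton raster).
#' @export
skeletonize <- function(mask) {
  g <- if (inherits(mask, "raster_mask")) mask$grid else mask != 0
  if (!is.matrix(g)) stop("mask must be a matrix or raster_mask")
  if (!any(g)) {
    warning("empty mask: skeleton is empty")
    return(g & FALSE)
  }
  nr <- nrow(g); nc <- ncol(g)
  lut <- simple_point_lut()$simple
  # pad with background so border pixels have full 8-neighborhoods
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- g
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, -1L))
  repeat {
    repeat {
      deleted <- FALSE
      for (d in dirs) {
        # freeze this sub-pass's border layer: pixels whose `d` side
        # is background now (prevents eating through a stroke)
        core <- p[ri, ci]
        side_bg <- !p[ri + d[1], ci + d[2]]
        cand <- which(core & side_bg, arr.ind = TRUE)
        for (i in seq_len(nrow(cand))) {
          r <- cand[i, 1] + 1L; c <- cand[i, 2] + 1L
          if (!p[r, c]) next
          code <- p[r - 1L, c] + 2L * p[r - 1L, c + 1L] +
            4L * p[r, c + 1L] + 8L * p[r + 1L, c + 1L] +
            16L * p[r + 1L, c] + 32L * p[r + 1L, c - 1L] +
            64L * p[r, c - 1L] + 128L * p[r - 1L, c - 1L]
          if (lut[code + 1L] && nbit_count[code + 1L] >= 2L) {
            p[r, c] <- FALSE
            deleted <- TRUE
          }
        }
      }
      if (!deleted) break
    }
    s <- remove_staircase_pixels(p[ri, ci])
    if (identical(s, p[ri, ci])) break
    p[ri, ci] <- s
  }
  s
}

# number of set bits for each 8-neighborhood code
nbit_count <- vapply(0:255, function(code)
  sum(bitwAnd(code, 2L^(0:7)) > 0L), integer(1))

# lookup table over the 256 neighborhood configurations: TRUE when the
# center is an 8-simple point (one 8-connected foreground component in
# the ring, and at least one 4-neighbor is background)
simple_point_lut <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    simple <- logical(256)
    for (code in 0:255) {
      fg <- which(bitwAnd(code, 2L^(0:7)) > 0L)
      if (length(fg) == 0) { simple[code + 1] <- FALSE; next }
      # background 4-neighbor required (positions 1, 3, 5, 7)
      if (all(c(1, 3, 5, 7) %in% fg)) { simple[code + 1] <- FALSE; next }
      # count 8-connected components among the foreground ring pixels
      k <- length(fg)
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
        if (max(abs(offs[fg[i], ] - offs[fg[j], ])) <= 1) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
      ncomp <- length(unique(vapply(seq_len(k), find, integer(1))))
      simple[code + 1] <- ncomp == 1
    }
    cache <<- list(simple = simple)
    cache
  }
})

# Thinning can leave two-pixel-wide staircases whose pixels all have
# >= 3 neighbors; they would masquerade as junction clusters.
# Sequentially delete any pixel with >= 3 neighbors whose removal keeps
# its neighborhood singly connected (a simple point), until stable.
remove_staircase_pixels <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  repeat {
    nbc <- neighbor_count(s)
    cand <- which(s & nbc >= 3L, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    deleted <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (!s[r, c]) next
      rs <- max(r - 1, 1):min(r + 1, nr); cs <- max(c - 1, 1):min(c + 1, nc)
      if (sum(s[rs, cs]) - 1L < 3L) next   # live neighbor count
      if (is_simple_point(s, r, c)) {
        s[r, c] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  s
}

# TRUE when the foreground 8-neighbors of (r, c) form one 8-connected
# component among themselves (so deleting the pixel preserves topology);
# pixels with <= 1 neighbor (endpoints) are never simple here
is_simple_point <- function(s, r, c) {
  nbr <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(s) && cc >= 1 && cc <= ncol(s) && s[rr, cc])
      nbr <- rbind(nbr, c(dr, dc))
  }
  if (is.null(nbr) || nrow(nbr) < 2) return(FALSE)
  k <- nrow(nbr)
  # union-find over the <= 8 ring pixels
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (max(abs(nbr[i, ] - nbr[j, ])) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1)))) == 1
}

# One Zhang-Suen sub-iteration: logical matrix of core pixels to delete.
# Neighbor labels: p2 = N, p3 = NE, p4 = E, p5 = SE, p6 = S, p7 = SW,
# p8 = W, p9 = NW (image rows increase downward).
zs_deletable <- function(p, step) {
  nr <- nrow(p) - 2L; nc <- ncol(p) - 2L
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  core <- p[ri, ci]
  p2 <- p[ri - 1L, ci];      p3 <- p[ri - 1L, ci + 1L]
  p4 <- p[ri, ci + 1L];      p5 <- p[ri + 1L, ci + 1L]
  p6 <- p[ri + 1L, ci];      p7 <- p[ri + 1L, ci - 1L]
  p8 <- p[ri, ci - 1L];      p9 <- p[ri - 1L, ci - 1L]
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  cond <- core & b >= 2L & b <= 6L & a == 1L
  if (step == 1L) {
    cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
}

# 8-neighbor count of skeleton pixels, same dims as input.
neighbor_count <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- s
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  p[ri - 1L, ci] + p[ri - 1L, ci + 1L] + p[ri, ci + 1L] +
    p[ri + 1L, ci + 1L] + p[ri + 1L, ci] + p[ri + 1L, ci - 1L] +
    p[ri, ci - 1L] + p[ri - 1L, ci - 1L]
}
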