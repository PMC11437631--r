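# Shared fixtures: all built in code, no data files.

# a single-segment tree spec with explicit geometry (bypasses the
# generator so angles/widths are exactly as stated)
stroke_spec <- function(angle_deg, length = 120, diameter = 6,
                        start = c(220.3, 30.7),
                        disc = disc_geometry(c(220, 30), 40),
                        vessel_class = "artery") {
  structure(list(
    vessel_class = vessel_class, root_point = start,
    root_direction = c(sin(angle_deg * pi / 180),
                       cos(angle_deg * pi / 180)),
    segments = data.frame(id = 1L, parent = NA_integer_,
                          start_r = start[1], start_c = start[2],
                          angle_deg = angle_deg, length = length,
                          diameter = diameter, gen = 1L),
    junctions = data.frame(),
    disc = disc, seed = 1L), class = "tree_spec")
}

# standard two-arcade fixture for one vessel class
arcade_pair <- function(seed, disc = disc_geometry(c(280, 280), 64),
                        depth = 3, vessel_class = "artery") {
  list(
    generate_tree_spec(depth, disc = disc, vessel_class = vessel_class,
                       seed = seed, root_theta = -58, sector_half = 46),
    generate_tree_spec(depth, disc = disc, vessel_class = vessel_class,
                       seed = seed + 1000L, root_theta = 48,
                       root_diameter = 9, sector_half = 46))
}

std_disc <- function() disc_geometry(c(280, 280), 64)

# independent brute-force Strahler oracle on a parent-vector tree:
# ord[i] for the edge ENDING at node i (root excluded)
brute_strahler <- function(parent) {
  n <- length(parent)
  kids <- lapply(seq_len(n), function(i) which(parent == i))
  ord <- rep(NA_integer_, n)
  rec <- function(i) {
    ch <- kids[[i]]
    if (length(ch) == 0) return(1L)
    o <- vapply(ch, function(j) {
      oj <- rec(j)
      ord[j] <<- oj
      oj
    }, integer(1))
    m <- max(o)
    if (sum(o == m) >= 2L) m + 1L else m
  }
  for (r in which(is.na(parent) | parent == 0)) ord[r] <- rec(r)
  list(edge_order = ord, kids = kids)
}

# random rooted tree as a skeleton_graph-like structure directly (no
# raster), for ordering tests: returns graph with straight-line paths
random_tree_graph <- function(n_edges, seed) {
  set.seed(seed)
  parent <- c(NA_integer_, vapply(2:(n_edges + 1L), function(i)
    sample.int(i - 1L, 1), integer(1)))
  # node positions: lay out by BFS depth (geometry irrelevant here)
  pos <- matrix(runif(2 * (n_edges + 1L), 10, 400), ncol = 2)
  nodes <- data.frame(id = seq_len(n_edges + 1L), row = pos[, 1],
                      col = pos[, 2], degree = 0L,
                      landmark = "junction", flagged = FALSE)
  edges <- data.frame(id = seq_len(n_edges),
                      from = parent[-1], to = 2:(n_edges + 1L),
                      length = 10, mean_diameter = 5,
                      strahler_order = NA_integer_, diam_flag = FALSE)
  paths <- lapply(seq_len(n_edges), function(i)
    rbind(pos[parent[i + 1L], ], pos[i + 1L, ]))
  names(paths) <- as.character(edges$id)
  g <- vesselmorph:::new_skeleton_graph(
    nodes, edges, paths, list(), dims = c(450L, 450L),
    rooted = TRUE, roots = 1L)
  g <- vesselmorph:::refresh_degrees(g)
  g$nodes$landmark[1] <- "root"
  list(graph = g, parent = parent)
}
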