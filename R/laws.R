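#' Distribution laws for the tree generator
#'
#' Small specification objects for the random draws of
#' \code{\link{generate_tree_spec}}: branch angles (degrees) and daughter
#' diameter ratios. \code{law_constant} always returns its value(s);
#' \code{law_uniform} and \code{law_normal} draw from the corresponding
#' distribution, truncated to the admissible range of the quantity
#' (angles to (10, 170) degrees, ratios to (0, 1]).
#'
#' @param value constant value; for a ratio law, a length-2 vector
#'   (d1/d0, d2/d0).
#' @param min,max uniform bounds.
#' @param mean,sd normal parameters.
#' @return A \code{vessel_law} object.
#' @name vessel_laws
NULL

#' @rdname vessel_laws
#' @export
law_constant <- function(value) {
  structure(list(dist = "constant", value = value), class = "vessel_law")
}

#' @rdname vessel_laws
#' @export
law_uniform <- function(min, max) {
  if (!(min < max)) stop("invalid distribution bounds: min must be < max")
  structure(list(dist = "uniform", min = min, max = max),
            class = "vessel_law")
}

#' @rdname vessel_laws
#' @export
law_normal <- function(mean, sd) {
  if (sd < 0) stop("invalid distribution bounds: sd must be >= 0")
  structure(list(dist = "normal", mean = mean, sd = sd),
            class = "vessel_law")
}

# draw n values from a law, truncated to [lo, hi]
draw_law <- function(law, n = 1, lo = -Inf, hi = Inf) {
  stopifnot(inherits(law, "vessel_law"))
  x <- switch(law$dist,
    constant = rep_len(law$value, n),
    uniform  = stats::runif(n, law$min, law$max),
    normal   = stats::rnorm(n, law$mean, law$sd)
  )
  pmin(pmax(x, lo), hi)
}

# draw a (r1 >= r2) diameter-ratio pair in (0, 1]
draw_ratio_pair <- function(law) {
  if (law$dist == "constant" && length(law$value) == 2) {
    r <- law$value
  } else {
    r <- draw_law(law, 2)
  }
  r <- pmin(pmax(r, 0.05), 1)
  sort(r, decreasing = TRUE)
}
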