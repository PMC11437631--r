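#' Pipeline configuration
#'
#' Collects every tunable default of the measurement pipeline. All
#' lengths are in pixels, angles in degrees.
#'
#' @param annulus_inner,annulus_outer measurement annulus bounds, in disc
#'   diameters outward from the disc edge (defaults 0.5 and 2.0).
#' @param spur_min_length spur-pruning threshold in px; \code{NULL} for
#'   the adaptive \code{max(5, 1.5 * local parent diameter)}.
#' @param fit_factor daughter-direction fit length, as a multiple of the
#'   parent diameter (default 3).
#' @param trim_junction exclude path pixels within one junction radius
#'   from direction fits (default \code{TRUE}).
#' @param root_drop_dd drop components whose nearest node is farther than
#'   this many disc diameters from the disc center (default 3).
#' @param ma_vertex optional (row, col) override of the main-angle
#'   vertex; default \code{NULL} uses the disc center.
#' @param annulus_all_metrics apply the annulus restriction to all four
#'   branch metrics (default \code{TRUE}); if \code{FALSE}, only BA/BC.
#' @param posthoc pairwise comparison method, \code{"lsd"} (pooled-MSE
#'   Fisher LSD, default), \code{"bonferroni"} or \code{"welch"}.
#' @param ci_level confidence level for all intervals (default 0.95).
#' @param seed integer seed for simulation commands.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(annulus_inner = 0.5, annulus_outer = 2.0,
                       spur_min_length = NULL, fit_factor = 3,
                       trim_junction = TRUE, root_drop_dd = 3,
                       ma_vertex = NULL, annulus_all_metrics = TRUE,
                       posthoc = c("lsd", "bonferroni", "welch"),
                       ci_level = 0.95, seed = 1L) {
  posthoc <- match.arg(posthoc)
  if (!(annulus_inner < annulus_outer))
    stop("annulus_inner must be smaller than annulus_outer")
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must lie in (0, 1)")
  structure(list(annulus_inner = annulus_inner,
                 annulus_outer = annulus_outer,
                 spur_min_length = spur_min_length,
                 fit_factor = fit_factor,
                 trim_junction = trim_junction,
                 root_drop_dd = root_drop_dd,
                 ma_vertex = ma_vertex,
                 annulus_all_metrics = annulus_all_metrics,
                 posthoc = posthoc, ci_level = ci_level,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a configuration from a YAML file
#'
#' Keys missing from the file keep their \code{\link{run_config}}
#' defaults.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A \code{run_config}.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}
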