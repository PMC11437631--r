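#' Reference group-level vascular summaries
#'
#' Per-group summary statistics (mean and 95\% CI of the group mean) of
#' the five vascular metrics for arteries and veins across four
#' refractive-status groups (normal, low, moderate and high myopia) of a
#' large pediatric fundus-image cohort, together with the per-group image
#' counts. These serve as inputs for cohort simulation: SDs are not
#' published, so they are recovered from the CIs with
#' \code{\link{ci_to_sd}}.
#'
#' @return A data.frame with columns \code{group, vessel_class, metric,
#'   mean, ci_lo, ci_hi, n}.
#' @export
reference_group_summaries <- function() {
  groups <- c("normal", "low", "moderate", "high")
  n <- c(279L, 1193L, 510L, 384L)
  metrics <- c("MA", "BA", "BC", "BEA", "BEC")
  artery <- list(
    MA  = rbind(c(87.55, 84.02, 91.08), c(82.12, 80.46, 83.78),
                c(82.44, 79.01, 83.86), c(82.43, 79.83, 85.03)),
    BA  = rbind(c(36.28, 34.12, 38.44), c(34.86, 33.90, 35.83),
                c(35.88, 34.35, 37.40), c(33.34, 31.59, 35.09)),
    BC  = rbind(c(1.67, 1.37, 1.96), c(1.31, 1.28, 1.34),
                c(1.55, 1.16, 1.94), c(1.41, 1.33, 1.50)),
    BEA = rbind(c(34.97, 33.34, 36.60), c(34.91, 34.21, 35.61),
                c(34.68, 33.66, 35.71), c(33.73, 32.43, 35.02)),
    BEC = rbind(c(0.92, 0.79, 1.04), c(0.72, 0.70, 0.74),
                c(0.70, 0.68, 0.73), c(0.78, 0.72, 0.84)))
  vein <- list(
    MA  = rbind(c(84.94, 81.50, 88.37), c(79.05, 77.45, 80.65),
                c(78.07, 75.70, 80.43), c(74.31, 71.75, 76.87)),
    BA  = rbind(c(36.19, 34.18, 38.20), c(36.44, 35.50, 37.38),
                c(35.24, 33.84, 36.65), c(37.71, 36.04, 39.39)),
    BC  = rbind(c(1.36, 1.20, 1.52), c(2.35, 0.50, 4.20),
                c(1.34, 1.04, 1.65), c(1.31, 1.23, 1.39)),
    BEA = rbind(c(34.08, 32.74, 35.42), c(35.22, 34.64, 35.81),
                c(34.65, 33.82, 35.48), c(34.05, 32.90, 35.20)),
    BEC = rbind(c(0.94, 0.67, 1.21), c(0.60, 0.58, 0.62),
                c(0.58, 0.55, 0.61), c(0.65, 0.57, 0.73)))
  out <- list()
  for (vc in c("artery", "vein")) {
    tabs <- if (vc == "artery") artery else vein
    for (m in metrics) {
      out[[length(out) + 1L]] <- data.frame(
        group = groups, vessel_class = vc, metric = m,
        mean = tabs[[m]][, 1], ci_lo = tabs[[m]][, 2],
        ci_hi = tabs[[m]][, 3], n = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recover a sample SD from a 95\% CI of the mean
#'
#' Inverts \eqn{CI = mean \pm 1.96\, SD/\sqrt{n}}:
#' \eqn{SD = (halfwidth/1.96)\sqrt{n}}.
#'
#' @param ci_lo,ci_hi interval bounds.
#' @param n sample size the interval was computed from.
#' @return The implied sample SD.
#' @export
ci_to_sd <- function(ci_lo, ci_hi, n) {
  ((ci_hi - ci_lo) / 2) / 1.96 * sqrt(n)
}

#' Cohort simulation specification
#'
#' @param params data.frame with columns \code{group, vessel_class,
#'   metric, mean, sd, n}; one row per group x class x metric.
#' @param seed integer seed.
#' @return A \code{cohort_spec}.
#' @export
cohort_spec <- function(params, seed = 1L) {
  need <- c("group", "vessel_class", "metric", "mean", "sd", "n")
  if (!all(need %in% names(params)))
    stop("params must have columns ", paste(need, collapse = ", "))
  if (any(params$n < 1)) stop("every group needs n >= 1")
  if (any(params$sd < 0)) stop("SDs must be >= 0")
  bad <- !params$group %in% c("normal", "low", "moderate", "high")
  if (any(bad)) stop("unknown group label: ",
                     paste(unique(params$group[bad]), collapse = ", "))
  structure(list(params = params, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a per-image cohort of metric values
#'
#' Draws each metric of each simulated image independently from
#' \code{Normal(mean, sd)} of its group; with \code{sd = 0} every value
#' equals the group mean exactly. The same seed reproduces the table
#' exactly.
#'
#' @param spec a \code{\link{cohort_spec}}, or its \code{params}
#'   data.frame.
#' @param seed seed override (defaults to the spec's).
#' @return A data.frame with columns \code{image_id, group,
#'   vessel_class, MA, BA, BC, BEA, BEC} (only metrics present in the
#'   spec are filled; absent ones are \code{NA}).
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  if (is.data.frame(spec)) spec <- cohort_spec(spec, seed %||% 1L)
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  p <- spec$params
  metrics <- c("MA", "BA", "BC", "BEA", "BEC")
  group_levels <- c("normal", "low", "moderate", "high")
  with_seed(seed, {
    rows <- list()
    for (grp in intersect(group_levels, unique(p$group))) {
      pg <- p[p$group == grp, ]
      ng <- unique(pg$n)
      if (length(ng) != 1)
        stop("inconsistent n within group ", grp)
      for (vc in intersect(c("artery", "vein"), unique(pg$vessel_class))) {
        dat <- data.frame(
          image_id = sprintf("%s_%04d", grp, seq_len(ng)),
          group = grp, vessel_class = vc,
          MA = NA_real_, BA = NA_real_, BC = NA_real_,
          BEA = NA_real_, BEC = NA_real_)
        for (m in metrics) {
          r <- pg[pg$vessel_class == vc & pg$metric == m, ]
          if (nrow(r) == 1)
            dat[[m]] <- stats::rnorm(ng, r$mean, r$sd)
        }
        rows[[length(rows) + 1L]] <- dat
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort parameters implied by the reference summaries
#'
#' Builds a \code{\link{simulate_cohort}} parameter table from
#' \code{\link{reference_group_summaries}}: means as printed; SDs either
#' recovered from the CIs via \code{\link{ci_to_sd}} or fixed (e.g. a
#' small constant for degenerate, means-only cohorts).
#'
#' @param sd \code{"from_ci"} (default) or a fixed numeric SD for every
#'   cell.
#' @param vessel_class optional filter, \code{"artery"} or \code{"vein"}.
#' @param metric optional filter, e.g. \code{"MA"}.
#' @return A params data.frame for \code{\link{cohort_spec}}.
#' @export
reference_cohort_params <- function(sd = "from_ci", vessel_class = NULL,
                                    metric = NULL) {
  p <- reference_group_summaries()
  if (!is.null(vessel_class)) p <- p[p$vessel_class %in% vessel_class, ]
  if (!is.null(metric)) p <- p[p$metric %in% metric, ]
  p$sd <- if (identical(sd, "from_ci"))
    ci_to_sd(p$ci_lo, p$ci_hi, p$n) else as.numeric(sd)
  p[, c("group", "vessel_class", "metric", "mean", "sd", "n")]
}
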