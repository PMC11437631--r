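#' Per-group descriptive statistics
#'
#' Mean, sample SD (n - 1 denominator) and the t-based 95\% CI of the
#' mean: \code{mean +/- t(0.975, n-1) * SD / sqrt(n)}.
#'
#' @param values numeric vector, n >= 2.
#' @param ci_level confidence level (default 0.95).
#' @return A list with \code{n, mean, sd, ci_lo, ci_hi}.
#' @export
describe_group <- function(values, ci_level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("describe_group needs n >= 2")
  m <- mean(values); s <- stats::sd(values)
  half <- stats::qt(1 - (1 - ci_level) / 2, n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_lo = m - half, ci_hi = m + half)
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA across k groups:
#' \code{F = MS_between / MS_within}, with the p-value from the F
#' distribution on (k - 1, N - k) degrees of freedom. Fitted through
#' \code{stats::lm}/\code{stats::anova}.
#'
#' @param groups named list of numeric vectors, each n >= 2.
#' @return An object of class \code{anova_result}: list with \code{F,
#'   df_between, df_within, p, ss_between, ss_within, ms_within} and the
#'   group means/sizes.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  y <- unlist(groups, use.names = FALSE)
  fit <- stats::lm(y ~ g)
  a <- stats::anova(fit)
  structure(list(
    F = a$`F value`[1], df_between = a$Df[1], df_within = a$Df[2],
    p = a$`Pr(>F)`[1], ss_between = a$`Sum Sq`[1],
    ss_within = a$`Sum Sq`[2], ms_within = a$`Mean Sq`[2],
    means = vapply(groups, mean, numeric(1)),
    ns = vapply(groups, length, integer(1))),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Pairwise mean difference between two groups
#'
#' Mean difference (first minus second) with CI and p-value. The default
#' \code{"lsd"} method is Fisher's LSD using the pooled within-group MSE
#' of the full ANOVA across all supplied groups:
#' \code{CI = MD +/- t(1 - alpha/2, df_within) *
#' sqrt(MSE (1/n_i + 1/n_j))}, p from the t statistic on
#' \code{df_within} degrees of freedom. \code{"bonferroni"} multiplies
#' the LSD p by the number of pairs; \code{"welch"} uses an unpooled
#' two-sample t test.
#'
#' @param groups named list of numeric vectors (the full design, used
#'   for the pooled MSE).
#' @param i,j group names (or indices) to compare.
#' @param method \code{"lsd"}, \code{"bonferroni"} or \code{"welch"}.
#' @param ci_level confidence level.
#' @return A one-row data.frame: \code{group_i, group_j, md, ci_lo,
#'   ci_hi, p}.
#' @export
pairwise_comparison <- function(groups, i, j,
                                method = c("lsd", "bonferroni", "welch"),
                                ci_level = 0.95) {
  method <- match.arg(method)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  if (is.numeric(i)) i <- names(groups)[i]
  if (is.numeric(j)) j <- names(groups)[j]
  if (!i %in% names(groups) || !j %in% names(groups))
    stop("unknown group label: ", paste(setdiff(c(i, j), names(groups)),
                                        collapse = ", "))
  xi <- groups[[i]][is.finite(groups[[i]])]
  xj <- groups[[j]][is.finite(groups[[j]])]
  md <- mean(xi) - mean(xj)
  if (identical(i, j))
    return(data.frame(group_i = i, group_j = j, md = 0,
                      ci_lo = 0, ci_hi = 0, p = 1))
  alpha <- 1 - ci_level
  if (method == "welch") {
    tt <- stats::t.test(xi, xj, conf.level = ci_level)
    return(data.frame(group_i = i, group_j = j, md = md,
                      ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                      p = tt$p.value))
  }
  a <- one_way_anova(groups)
  se <- sqrt(a$ms_within * (1 / length(xi) + 1 / length(xj)))
  tcrit <- stats::qt(1 - alpha / 2, a$df_within)
  tstat <- if (se > 0) md / se else sign(md) * Inf
  p <- 2 * stats::pt(-abs(tstat), a$df_within)
  if (method == "bonferroni") {
    k <- length(groups)
    p <- min(1, p * k * (k - 1) / 2)
  }
  data.frame(group_i = i, group_j = j, md = md,
             ci_lo = md - tcrit * se, ci_hi = md + tcrit * se, p = p)
}

#' Full statistical report for a cohort table
#'
#' For every metric x vessel class: per-group descriptives (mean, SD,
#' 95\% CI), the one-way ANOVA across the four refractive groups, and
#' all pairwise mean differences (normal vs each myopia group, and the
#' myopia groups pairwise).
#'
#' @param cohort data.frame with columns \code{image_id, group,
#'   vessel_class} and metric columns \code{MA, BA, BC, BEA, BEC} (any
#'   subset).
#' @param config a \code{\link{run_config}} (post hoc method, CI level).
#' @return A list of data.frames: \code{descriptives}, \code{anova},
#'   \code{pairwise}.
#' @export
build_report <- function(cohort, config = run_config()) {
  group_levels <- c("normal", "low", "moderate", "high")
  bad <- !cohort$group %in% group_levels
  if (any(bad))
    stop("malformed group label in rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  metrics <- intersect(c("MA", "BA", "BC", "BEA", "BEC"), names(cohort))
  classes <- intersect(c("artery", "vein"), unique(cohort$vessel_class))
  groups_present <- intersect(group_levels, unique(cohort$group))
  desc <- list(); anv <- list(); pw <- list()
  for (vc in classes) {
    for (m in metrics) {
      sub <- cohort[cohort$vessel_class == vc, c("group", m)]
      vals <- split(sub[[m]], factor(sub$group, levels = groups_present))
      vals <- lapply(vals, function(v) v[is.finite(v)])
      for (grp in groups_present) {
        if (length(vals[[grp]]) >= 2) {
          d <- describe_group(vals[[grp]], config$ci_level)
          desc[[length(desc) + 1L]] <- data.frame(
            vessel_class = vc, metric = m, group = grp, n = d$n,
            mean = d$mean, sd = d$sd, ci_lo = d$ci_lo, ci_hi = d$ci_hi)
        }
      }
      ok <- vapply(vals, function(v) length(v) >= 2, logical(1))
      if (sum(ok) < 2) {
        warning("fewer than two usable groups for ", vc, " ", m,
                ": comparisons skipped")
        next
      }
      vv <- vals[ok]
      a <- one_way_anova(vv)
      anv[[length(anv) + 1L]] <- data.frame(
        vessel_class = vc, metric = m, F = a$F,
        df_between = a$df_between, df_within = a$df_within, p = a$p)
      nm <- names(vv)
      prs <- t(utils::combn(seq_along(nm), 2))
      for (r in seq_len(nrow(prs))) {
        cmp <- pairwise_comparison(vv, nm[prs[r, 1]], nm[prs[r, 2]],
                                   method = config$posthoc,
                                   ci_level = config$ci_level)
        pw[[length(pw) + 1L]] <- cbind(
          data.frame(vessel_class = vc, metric = m), cmp)
      }
    }
  }
  list(descriptives = if (length(desc)) do.call(rbind, desc) else NULL,
       anova = if (length(anv)) do.call(rbind, anv) else NULL,
       pairwise = if (length(pw)) do.call(rbind, pw) else NULL)
}
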