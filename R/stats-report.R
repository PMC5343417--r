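#' Grouped descriptive statistics of morphometric parameters
#'
#' Mean, SD, min, max and n for every requested grouping cell, for each of
#' the four morphometric parameters at each plane.  A single-record cell
#' reports SD 0 (flagged by n = 1); an empty requested cell is reported as
#' missing rather than fabricated.
#'
#' @param morphometrics long data.frame as produced by
#'   [specimen_morphometrics()] (columns id, gender, side, plane, width,
#'   depth, perimeter, area).
#' @param by character vector of grouping factors among `"gender"`,
#'   `"side"`, `"plane"`.
#' @return data.frame with one row per group x parameter.
#' @export
group_descriptives <- function(morphometrics,
                               by = c("gender", "plane")) {
  stopifnot(all(by %in% c("gender", "side", "plane")))
  params <- c("width", "depth", "perimeter", "area")
  g <- interaction(morphometrics[by], drop = FALSE, sep = "/")
  out <- list()
  for (lev in levels(g)) {
    rows <- morphometrics[g == lev, , drop = FALSE]
    for (p in params) {
      vals <- rows[[p]]
      out[[length(out) + 1L]] <- data.frame(
        group = lev, parameter = p, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals)
             else if (length(vals) == 1) 0 else NA_real_,
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Normality check (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample.  Because the parameters are estimated, the
#' plain KS null distribution is anti-conservative; the Lilliefors
#' correction is used instead.
#'
#' @param values numeric vector (n >= 4).
#' @return list with `statistic` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 observations")
  if (stats::sd(values) == 0) stop("constant input has no defined normality test")
  t <- nortest::lillie.test(values)
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Two-group comparison of one morphometric parameter
#'
#' Independent two-sample t-test (pooled-variance Student form by default;
#' `welch = TRUE` switches to the unequal-variance form).  Significance is
#' decided against the Bonferroni-corrected threshold for the four
#' morphometric parameters, alpha = 0.05/4 = 0.0125 (conventionally printed
#' as 0.013).
#'
#' @param values numeric vector of the parameter.
#' @param group two-level factor (e.g. gender or side).
#' @param alpha decision threshold.
#' @param welch use the Welch unequal-variance form.
#' @return list with `t`, `df`, `p`, `significant`, `direction` (sign of
#'   mean(level1) - mean(level2)), `alpha`.
#' @export
compare_groups <- function(values, group, alpha = 0.05 / 4, welch = FALSE) {
  group <- droplevels(factor(group))
  if (nlevels(group) != 2L) stop("need exactly two non-empty groups")
  if (min(table(group)) < 2L) stop("each group needs n >= 2")
  a <- values[group == levels(group)[1]]
  b <- values[group == levels(group)[2]]
  if (stats::sd(c(a, b)) == 0) {
    res <- list(statistic = 0, parameter = length(values) - 2, p.value = 1)
  } else {
    res <- stats::t.test(a, b, var.equal = !welch)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value),
       significant = unname(res$p.value) < alpha,
       direction = sign(mean(a) - mean(b)),
       alpha = alpha)
}

#' Gender and side comparisons of all parameters at all planes
#'
#' @param morphometrics long data.frame as in [group_descriptives()].
#' @param factor_name `"gender"` or `"side"`.
#' @param alpha decision threshold (Bonferroni-corrected default).
#' @param welch use Welch's t-test.
#' @return data.frame with one row per plane x parameter.
#' @export
compare_gender_side <- function(morphometrics, factor_name = "gender",
                                alpha = 0.05 / 4, welch = FALSE) {
  params <- c("width", "depth", "perimeter", "area")
  out <- list()
  for (pl in unique(morphometrics$plane)) {
    rows <- morphometrics[morphometrics$plane == pl, ]
    for (p in params) {
      r <- compare_groups(rows[[p]], rows[[factor_name]], alpha = alpha,
                          welch = welch)
      out[[length(out) + 1L]] <- data.frame(
        plane = pl, parameter = p, factor = factor_name,
        t = r$t, df = r$df, p = r$p, significant = r$significant,
        direction = r$direction)
    }
  }
  do.call(rbind, out)
}

#' One-way ANOVA across the three planes with Bonferroni post hoc
#'
#' Tests whether a morphometric parameter differs between the distal,
#' middle and proximal planes (optionally within one gender), followed by
#' all three pairwise pooled-variance t-tests with Bonferroni adjustment
#' (adjusted p = min(1, 3 * raw p)).
#'
#' @param morphometrics long data.frame as in [group_descriptives()].
#' @param parameter one of `"width"`, `"depth"`, `"perimeter"`, `"area"`.
#' @param gender restrict to one gender (`NULL` = all).
#' @return list with `f`, `df`, `p` (overall ANOVA) and `posthoc`
#'   (data.frame of pairwise comparisons with `p_raw` and `p_adjusted`).
#' @export
compare_planes_anova <- function(morphometrics, parameter = "width",
                                 gender = NULL) {
  rows <- morphometrics
  if (!is.null(gender)) rows <- rows[rows$gender == gender, ]
  rows$plane <- factor(rows$plane, levels = c("distal", "middle", "proximal"))
  if (any(table(rows$plane) == 0)) stop("all three planes must be present")
  vals <- rows[[parameter]]
  fit <- stats::aov(vals ~ plane, data = rows)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(levels(rows$plane), 2)
  posthoc <- do.call(rbind, apply(pairs, 2, function(pr) {
    a <- vals[rows$plane == pr[1]]
    b <- vals[rows$plane == pr[2]]
    p_raw <- if (stats::sd(c(a, b)) == 0) 1
             else stats::t.test(a, b, var.equal = TRUE)$p.value
    data.frame(group1 = pr[1], group2 = pr[2], p_raw = p_raw,
               p_adjusted = min(1, 3 * p_raw))
  }))
  list(f = an[["F value"]][1], df = an[["Df"]],
       p = an[["Pr(>F)"]][1], posthoc = posthoc)
}

#' Full statistical report over a morphometrics table
#'
#' Bundles the descriptives (by gender, gender x side, and plane), the
#' normality checks, gender and side comparisons, and the per-gender
#' across-plane ANOVAs, mirroring the conventional reporting layout of
#' morphometric bone studies.
#'
#' @param morphometrics long data.frame as in [group_descriptives()].
#' @param alpha Bonferroni-corrected decision threshold.
#' @return an object of class `stats_report` (a named list of tables).
#' @export
stats_report <- function(morphometrics, alpha = 0.05 / 4) {
  params <- c("width", "depth", "perimeter", "area")
  normality <- do.call(rbind, lapply(params, function(p) {
    r <- tryCatch(normality_check(morphometrics[[p]]),
                  error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(parameter = p, statistic = r$statistic, p = r$p)
  }))
  anovas <- list()
  for (g in unique(morphometrics$gender)) {
    for (p in params) {
      a <- compare_planes_anova(morphometrics, p, gender = g)
      anovas[[paste(g, p, sep = ".")]] <- a
    }
  }
  out <- list(
    descriptives = group_descriptives(morphometrics,
                                      by = c("gender", "side", "plane")),
    normality = normality,
    gender = compare_gender_side(morphometrics, "gender", alpha = alpha),
    side = compare_gender_side(morphometrics, "side", alpha = alpha),
    planes = anovas,
    alpha = alpha)
  class(out) <- "stats_report"
  out
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("stats_report (alpha = %.4f, printed %.3f)\n", x$alpha,
              round(x$alpha, 3)))
  cat(sprintf("  gender comparisons: %d/%d significant\n",
              sum(x$gender$significant), nrow(x$gender)))
  cat(sprintf("  side comparisons:   %d/%d significant\n",
              sum(x$side$significant), nrow(x$side)))
  invisible(x)
}
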