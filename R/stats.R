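#' Nonparametric method-comparison statistics
#'
#' Pose-error distributions are heavily right-skewed, so the comparison
#' battery is nonparametric throughout: a Shapiro-Wilk normality gate,
#' Wilcoxon signed-rank for paired camera-view comparisons, Mann-Whitney U
#' for unpaired trial-type comparisons, Cliff's delta effect sizes, and
#' Bland-Altman agreement summarised by the median bias with nonparametric
#' 95% limits of agreement (2.5th/97.5th percentiles). Raw p-values are
#' reported without multiple-testing correction.
#'
#' @name stats-battery
#' @keywords internal
NULL

#' Normality gate
#'
#' Shapiro-Wilk test; the nonparametric flag is raised when p < alpha.
#' Downstream comparisons in this package are nonparametric regardless —
#' the gate documents why. Samples larger than 5000 are tested on the
#' first 5000 values (the routine's supported range); constant samples get
#' the flag with a warning.
#'
#' @param x numeric sample, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with \code{p_value} and \code{use_nonparametric}.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 3L)
  if (stats::sd(x) == 0) {
    warning("constant sample: normality undefined, nonparametric flag set",
            call. = FALSE)
    return(list(p_value = NA_real_, use_nonparametric = TRUE))
  }
  if (length(x) > 5000L) x <- x[seq_len(5000L)]
  p <- stats::shapiro.test(x)$p.value
  list(p_value = p, use_nonparametric = p < alpha)
}

.test_result <- function(method, statistic, p_value, n, effect_size = NA,
                         effect_label = NA_character_, degenerate = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n,
                 effect_size = unname(effect_size),
                 effect_label = effect_label, degenerate = degenerate),
            class = "headkin_test")
}

#' @export
print.headkin_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 6), ", p = ",
      format.pval(x$p_value, digits = 4), ", n = ", x$n, sep = "")
  if (!is.na(x$effect_size)) {
    cat(", ", x$effect_label, " = ", signif(x$effect_size, 4), sep = "")
  }
  if (x$degenerate) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

#' Wilcoxon signed-rank test (paired, two-sided)
#'
#' Zero differences are dropped; ties are mid-ranked. The null
#' distribution is exact for n <= 25 untied differences, otherwise a
#' normal approximation with tie correction is used. The effect size is
#' the median paired difference (a - b).
#'
#' @param a,b paired numeric samples of equal length.
#' @return a \code{headkin_test} (statistic = V, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    return(.test_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                        n = length(d), effect_size = 0,
                        effect_label = "median difference",
                        degenerate = TRUE))
  }
  if (length(nz) < 5L) {
    warning("fewer than 5 nonzero differences: test has little power",
            call. = FALSE)
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                            correct = !exact))
  .test_result("Wilcoxon signed-rank", wt$statistic, wt$p.value,
               n = length(nz), effect_size = stats::median(d),
               effect_label = "median difference")
}

#' Mann-Whitney U test (unpaired, two-sided)
#'
#' Ties are mid-ranked. Exact null distribution when
#' \code{n_a * n_b <= 400} and there are no cross-sample ties, otherwise
#' normal approximation with tie correction. The reported statistic is
#' U_a, the number of (a, b) pairs with a > b plus half the ties —
#' identical to the rank-sum W reported by \code{wilcox.test}.
#'
#' @param a,b numeric samples, each n >= 3.
#' @return a \code{headkin_test} with Cliff's delta as effect size.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  exact <- length(a) * length(b) <= 400L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  .test_result("Mann-Whitney U", wt$statistic, wt$p.value,
               n = length(a) + length(b),
               effect_size = cliffs_delta(a, b),
               effect_label = "Cliff's delta")
}

#' Cliff's delta effect size
#'
#' \code{(#\{a_i > b_j\} - #\{a_i < b_j\}) / (n_a * n_b)}, computed
#' exactly over all pairs; value in [-1, 1].
#'
#' @param a,b non-empty numeric samples.
#' @return delta.
#' @export
cliffs_delta <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  cmp <- sign(outer(a, b, "-"))
  sum(cmp) / (length(a) * length(b))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return r.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Nonparametric Bland-Altman summary
#'
#' Differences d = predicted - reference, summarised by the median bias
#' and nonparametric 95% limits of agreement: the 2.5th and 97.5th
#' percentiles of d under the linear-interpolation percentile rule
#' (\code{quantile} type 7: the p-th percentile interpolates between
#' order statistics at position 1 + p(n-1)).
#'
#' @param predicted,reference numeric vectors of equal length; fewer than
#'   40 pairs triggers a warning (percentile limits unstable).
#' @return list with \code{median_bias}, \code{loa_low}, \code{loa_high},
#'   \code{n}.
#' @export
bland_altman_np <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  d <- predicted - reference
  d <- d[!is.na(d)]
  if (length(d) < 40L) {
    warning("fewer than 40 pairs: 2.5/97.5 percentile limits are unstable",
            call. = FALSE)
  }
  q <- stats::quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
  list(median_bias = stats::median(d), loa_low = q[1], loa_high = q[2],
       n = length(d))
}

#' Bin errors by visibility ratio
#'
#' Half-open bins [e_k, e_{k+1}) with the last bin closed at its upper
#' edge. Per bin: n, mean and standard error (sd/sqrt(n)). Empty bins are
#' reported with n = 0 and NA mean.
#'
#' @param values numeric errors (frames with NA visibility are dropped).
#' @param visibility matching visibility ratios in [0, 1].
#' @param edges ascending bin edges covering [0, 1]
#'   (default \code{seq(0, 1, 0.2)}).
#' @return data.frame: bin_low, bin_high, n, mean, se.
#' @export
bin_by_visibility <- function(values, visibility, edges = seq(0, 1, 0.2)) {
  stopifnot(length(values) == length(visibility),
            !is.unsorted(edges, strictly = TRUE))
  keep <- !is.na(visibility) & !is.na(values)
  values <- values[keep]; visibility <- visibility[keep]
  nb <- length(edges) - 1L
  idx <- findInterval(visibility, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > nb] <- NA
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                    n = 0L, mean = NA_real_, se = NA_real_)
  for (k in seq_len(nb)) {
    v <- values[!is.na(idx) & idx == k]
    out$n[k] <- length(v)
    if (length(v)) {
      out$mean[k] <- mean(v)
      out$se[k] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    }
  }
  out
}

#' Aggregate errors by time step and temporal phase
#'
#' Means and standard errors at each 20 ms video time step, labelled by
#' phase: pre-impact (t = 0 ms), impact (t = 20 ms, the frame closest to
#' ball contact), post-impact (t = 40..100 ms).
#'
#' @param values numeric per-frame values (NA dropped).
#' @param t_ms frame times; must lie on the \code{step_ms} grid.
#' @param step_ms grid spacing (default 20).
#' @param impact_ms time of the impact frame (default 20).
#' @return data.frame: t_ms, phase, n, mean, se.
#' @export
phase_aggregate <- function(values, t_ms, step_ms = 20, impact_ms = 20) {
  stopifnot(length(values) == length(t_ms))
  off <- abs(t_ms / step_ms - round(t_ms / step_ms))
  if (any(off > 1e-6, na.rm = TRUE)) {
    stop("frame times are not on the ", step_ms, " ms grid", call. = FALSE)
  }
  keep <- !is.na(values)
  values <- values[keep]; t_ms <- round(t_ms[keep] / step_ms) * step_ms
  steps <- sort(unique(t_ms))
  out <- data.frame(t_ms = steps,
                    phase = ifelse(steps < impact_ms, "pre-impact",
                                   ifelse(steps == impact_ms, "impact",
                                          "post-impact")),
                    n = 0L, mean = NA_real_, se = NA_real_)
  for (k in seq_along(steps)) {
    v <- values[t_ms == steps[k]]
    out$n[k] <- length(v)
    out$mean[k] <- mean(v)
    out$se[k] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  }
  out
}
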