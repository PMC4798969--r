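#' Per-embryo mean and sample standard deviation
#'
#' @param values Numeric vector of per-embryo counts (n >= 1).
#' @return List: mean, sd (n-1 denominator; `NA` with `sd_defined = FALSE`
#'   when n = 1), n.
#' @export
mean_sd <- function(values) {
  if (length(values) < 1L)
    nmp_error("invalid_params", "at least one value is required")
  n <- length(values)
  list(mean = mean(values),
       sd = if (n > 1L) sd(values) else NA_real_,
       sd_defined = n > 1L,
       n = n)
}

test_result <- function(t, df, p, welch, infinite = FALSE) {
  structure(list(t = t, df = df, p = p,
                 welch_corrected = welch,
                 significant = is.finite(p) && p < 0.05,
                 infinite_t = infinite),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t-test: t = %.4f, df = %.3f, p = %.4g%s\n",
              if (x$welch_corrected) "Welch" else "Student",
              x$t, x$df, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

two_sample_t <- function(a, b, welch) {
  if (length(a) < 2L || length(b) < 2L)
    nmp_error("invalid_params", "each sample needs n >= 2")
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    df <- if (welch) NA_real_ else length(a) + length(b) - 2
    if (mean(a) == mean(b))
      return(test_result(0, df, 1, welch))
    return(test_result(sign(mean(a) - mean(b)) * Inf, df, 0, welch,
                       infinite = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  test_result(unname(ht$statistic), unname(ht$parameter),
              ht$p.value, welch)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Standard unpaired two-sample t-test with pooled variance,
#' df = n_a + n_b - 2, two-sided p. Significance is flagged at p < 0.05
#' (strict). Degenerate zero-variance inputs are handled explicitly:
#' identical means give t = 0, p = 1; distinct means give an infinite-t
#' flag with p = 0.
#'
#' @param a,b Numeric samples of per-embryo counts, each n >= 2.
#' @return A `test_result`: t, df, p, welch_corrected, significant,
#'   infinite_t.
#' @export
students_t <- function(a, b) two_sample_t(a, b, welch = FALSE)

#' Unpaired t-test with Welch correction
#'
#' Welch's statistic with Welch-Satterthwaite degrees of freedom (kept
#' fractional), two-sided p. Used to guard comparisons against unequal
#' variances, e.g. from depth-dependent differences in image acquisition.
#'
#' @inheritParams students_t
#' @return A `test_result` with `welch_corrected = TRUE`.
#' @export
welch_t <- function(a, b) two_sample_t(a, b, welch = TRUE)

#' Fold change between two counts
#'
#' @param count_late,count_early Non-negative counts (later over earlier);
#'   `count_early` must be positive.
#' @return List: `raw` ratio and `rounded` to 2 significant figures (the
#'   reporting convention for fold changes).
#' @export
fold_change <- function(count_late, count_early) {
  if (count_early <= 0)
    nmp_error("undefined_error",
              "fold change is undefined for a zero early count")
  raw <- count_late / count_early
  list(raw = raw, rounded = signif(raw, 2))
}

#' Per-stage count container
#'
#' @param stage_label Stage name (e.g. "E8.5").
#' @param counts Data frame of per-embryo [population_counts()] rows
#'   (one row per embryo, n >= 1).
#' @return Object of class `stage_counts`.
#' @export
stage_counts <- function(stage_label, counts) {
  if (!is.data.frame(counts) || nrow(counts) < 1L)
    nmp_error("invalid_params", "counts needs at least one embryo row")
  structure(list(stage_label = stage_label, counts = counts,
                 n = nrow(counts)), class = "stage_counts")
}

#' Significance stars
#'
#' Convention: `**` for p < 0.0001, `*` for p < 0.05, otherwise `ns`.
#'
#' @param p P-value.
#' @return Character star code.
#' @export
signif_stars <- function(p) {
  ifelse(p < 1e-4, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Compare consecutive developmental stages
#'
#' Runs the selected two-sample test on per-embryo counts of the selected
#' population for every consecutive stage pair. Stages with fewer than two
#' embryos are skipped with a warning.
#'
#' @param series List of [stage_counts()] in stage order (>= 2 stages).
#' @param population Column of the counts table to compare
#'   (e.g. "n_double", "n_total", "n_L3").
#' @param correction "none" for the pooled Student test, "welch" for the
#'   Welch-corrected test.
#' @return Data frame: pair, population, test, t, df, p, significant,
#'   stars.
#' @export
compare_stages <- function(series, population = "n_double",
                           correction = c("none", "welch")) {
  correction <- match.arg(correction)
  if (length(series) < 2L)
    nmp_error("invalid_params", "need at least two stages")
  rows <- list()
  for (k in seq_len(length(series) - 1L)) {
    s1 <- series[[k]]; s2 <- series[[k + 1L]]
    if (s1$n < 2L || s2$n < 2L) {
      warning(sprintf("skipping pair %s vs %s: fewer than 2 embryos",
                      s1$stage_label, s2$stage_label))
      next
    }
    a <- s1$counts[[population]]
    b <- s2$counts[[population]]
    res <- if (correction == "welch") welch_t(a, b) else students_t(a, b)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(s1$stage_label, "vs", s2$stage_label),
      population = population,
      test = if (correction == "welch") "welch" else "student",
      t = res$t, df = res$df, p = res$p,
      significant = res$significant,
      stars = signif_stars(res$p),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pair = character(), population = character(),
                      test = character(), t = numeric(), df = numeric(),
                      p = numeric(), significant = logical(),
                      stars = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
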