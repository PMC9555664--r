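#' Lag-0 correlation between two aligned series
#'
#' @param a,b Numeric vectors of equal length >= 3 with nonzero variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop_eggsync("series lengths differ", "eggsync_misaligned")
  if (length(a) < 3)
    stop_eggsync("need at least 3 paired values", "eggsync_series_too_short")
  if (anyNA(a) || anyNA(b))
    stop_eggsync("series contain missing values", "eggsync_missing_values")
  if (sd(a) == 0 || sd(b) == 0)
    stop_eggsync("correlation undefined for a constant series",
                 "eggsync_undefined_correlation")
  cor(a, b, method = method)
}

#' Breakpoint cross-correlation of two annual series
#'
#' Splits the common year range at `breakpoint_year` and reports the
#' correlation of paired annual means before (years strictly earlier than
#' the breakpoint) and after (breakpoint year onward: the regime-change year
#' belongs to the "after" segment).
#'
#' @param series_a,series_b Annual series as accepted by [run_synchrony()].
#' @param breakpoint_year The split year (e.g. the landfill-closure year).
#' @param method Correlation method, see [pearson_cc()].
#' @return A `split_correlation` list: `breakpoint_year`, `cc_before`,
#'   `n_before`, `cc_after`, `n_after`.
#' @export
split_cc <- function(series_a, series_b, breakpoint_year,
                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- series_values(series_a)
  b <- series_values(series_b)
  if (length(a$years) != length(b$years) || any(a$years != b$years))
    stop_eggsync("the two series must cover identical year ranges",
                 "eggsync_misaligned")
  pre <- a$years < breakpoint_year
  if (sum(pre) < 3)
    stop_eggsync(sprintf("before-breakpoint segment has %d year(s); need >= 3",
                         sum(pre)), "eggsync_insufficient_data")
  if (sum(!pre) < 3)
    stop_eggsync(sprintf("after-breakpoint segment has %d year(s); need >= 3",
                         sum(!pre)), "eggsync_insufficient_data")
  out <- list(breakpoint_year = as.integer(breakpoint_year),
              cc_before = pearson_cc(a$values[pre], b$values[pre], method),
              n_before = sum(pre),
              cc_after = pearson_cc(a$values[!pre], b$values[!pre], method),
              n_after = sum(!pre))
  class(out) <- "split_correlation"
  out
}

#' @export
print.split_correlation <- function(x, ...) {
  cat(sprintf("Cross-correlation around %d: before = %.3f (n = %d), after = %.3f (n = %d)\n",
              x$breakpoint_year, x$cc_before, x$n_before, x$cc_after, x$n_after))
  invisible(x)
}
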