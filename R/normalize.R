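#' Median-normalize a ratio table
#'
#' Divides every condition column by its own median so that each column's
#' median ratio becomes exactly 1.0, the convention under which a ratio of 1
#' means "no change against control". Relative order within a column is
#' preserved, and the operation is idempotent.
#'
#' @param table Either a numeric matrix (features x conditions, all ratios
#'   > 0) or a long-format tibble with columns `condition` and `ratio` (as
#'   produced by [generate_study()] or [read_ratio_table()]).
#' @return The same shape of object with normalized ratios.
#' @export
#' @examples
#' median_normalize(matrix(c(1, 2, 4), ncol = 1))
median_normalize <- function(table) {
  if (is.matrix(table)) {
    if (any(!is.finite(table)) || any(table <= 0)) {
      stop("ratio table contains zero, negative or non-finite ratios; ",
           "cannot median-normalize", call. = FALSE)
    }
    meds <- apply(table, 2, median)
    return(sweep(table, 2, meds, `/`))
  }
  if (!is.data.frame(table) || !all(c("condition", "ratio") %in% names(table))) {
    stop("`table` must be a matrix or a data frame with columns ",
         "`condition` and `ratio`", call. = FALSE)
  }
  bad <- !is.na(table$ratio) & (table$ratio <= 0 | !is.finite(table$ratio))
  if (any(bad)) {
    stop("column(s) ", paste(unique(table$condition[bad]), collapse = ", "),
         " contain zero or negative ratios; cannot median-normalize",
         call. = FALSE)
  }
  dplyr::mutate(dplyr::group_by(table, .data$condition),
                ratio = .data$ratio / median(.data$ratio, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Fit the per-experiment empirical-null significance interval
#'
#' The significance interval is the central range containing `coverage`
#' (default 95%) of the internal technical replicate's control-vs-control
#' ratios. It is computed as the equal-tail empirical quantiles (linear
#' interpolation, type 7) of the log ratios, exponentiated back to the ratio
#' scale. Ratios strictly outside this interval are candidate changes; the
#' interval is fitted separately for each experimental run, so it absorbs
#' that run's technical variation.
#'
#' @param internal_ratios Positive control-vs-control ratios (at least 20).
#' @param coverage Central coverage proportion in (0, 1]; `1` gives the
#'   sample range.
#' @param experiment Optional experiment label stored with the interval.
#' @return A `significance_interval` with fields `experiment`, `lower`,
#'   `upper`, `coverage` and `n_null`.
#' @export
#' @examples
#' set.seed(1)
#' fit_significance_interval(exp(rnorm(1000, 0, 0.1)))
fit_significance_interval <- function(internal_ratios, coverage = 0.95,
                                      experiment = NA_character_) {
  internal_ratios <- internal_ratios[!is.na(internal_ratios)]
  if (length(internal_ratios) < 20L) {
    stop("need at least 20 internal-replicate ratios to fit a significance ",
         "interval (got ", length(internal_ratios), ")", call. = FALSE)
  }
  if (any(internal_ratios <= 0)) {
    stop("internal-replicate ratios must be > 0", call. = FALSE)
  }
  check_scalar_number(coverage, "coverage", lower = 0, upper = 1,
                      strict_lower = TRUE)
  alpha <- (1 - coverage) / 2
  q <- quantile(log(internal_ratios), c(alpha, 1 - alpha), names = FALSE,
                type = 7)
  structure(
    list(experiment = experiment, lower = exp(q[1]), upper = exp(q[2]),
         coverage = coverage, n_null = length(internal_ratios)),
    class = "significance_interval"
  )
}

#' @export
print.significance_interval <- function(x, ...) {
  cat(sprintf(
    "Significance interval%s: [%.4f, %.4f] at %.0f%% coverage (n_null = %d)\n",
    if (is.na(x$experiment)) "" else paste0(" (", x$experiment, ")"),
    x$lower, x$upper, 100 * x$coverage, x$n_null))
  invisible(x)
}

#' Is a ratio strictly outside a significance interval?
#'
#' Boundary ties are not outside: calling is conservative at the interval
#' edges.
#'
#' @param ratio Numeric vector of fold-changes.
#' @param interval A [fit_significance_interval()] result.
#' @return Logical vector (`NA` where the ratio is missing).
#' @export
outside_interval <- function(ratio, interval) {
  stopifnot(inherits(interval, "significance_interval"))
  ratio < interval$lower | ratio > interval$upper
}

# Continuous empirical CDF of the internal log-ratios: the inverse of the
# type-7 quantile function (linear between order statistics), so that
# "strictly outside the coverage-c interval" and "|confidence| > c" are the
# same event.
null_cdf <- function(x, internal_log) {
  s <- sort(internal_log)
  n <- length(s)
  if (n == 1L) {
    return(ifelse(x > s, 1, ifelse(x < s, 0, 0.5)))
  }
  p <- (seq_len(n) - 1) / (n - 1)
  stats::approx(s, p, xout = x, rule = 2, ties = list("ordered", mean))$y
}

#' Signed empirical-null confidence score
#'
#' The confidence of a ratio is the proportion of internal-replicate ratios
#' that the ratio in question is outside of: the coverage of the widest
#' central interval of the null that still excludes it. The score is signed
#' (+ for ratios above the null median, - below) and capped at +/-0.99, so
#' an "Up" call at 95% coverage always carries a confidence between 0.95 and
#' 0.99 inclusive. Values are returned at full precision; use
#' [format_confidence()] for the 2-decimal display convention.
#'
#' @param ratio Positive fold-change(s) to score.
#' @param internal_ratios Positive internal-replicate ratios (the null
#'   sample).
#' @param cap Magnitude cap (default 0.99).
#' @return Numeric vector in `[-cap, cap]`.
#' @export
#' @examples
#' confidence_score(2, exp(seq(-0.3, 0.3, length.out = 41)))
confidence_score <- function(ratio, internal_ratios, cap = 0.99) {
  if (length(internal_ratios) == 0L) {
    stop("empty internal-replicate sample", call. = FALSE)
  }
  if (any(internal_ratios <= 0, na.rm = TRUE)) {
    stop("internal-replicate ratios must be > 0", call. = FALSE)
  }
  if (any(ratio <= 0, na.rm = TRUE)) {
    stop("ratios must be > 0", call. = FALSE)
  }
  internal_ratios <- internal_ratios[!is.na(internal_ratios)]
  g <- null_cdf(log(ratio), log(internal_ratios))
  signed <- 2 * g - 1
  out <- pmin(pmax(signed, -cap), cap)
  out[is.na(ratio)] <- NA_real_
  out
}

#' Format a confidence score for display
#'
#' Reports round signed confidences to two decimals; uncalled entries are
#' conventionally printed in brackets, e.g. `"(0.83)"`.
#'
#' @param confidence Numeric vector of signed confidences.
#' @param called Logical vector; `FALSE` entries are bracketed.
#' @return Character vector.
#' @export
format_confidence <- function(confidence, called = TRUE) {
  called <- rep_len(called, length(confidence))
  txt <- sprintf("%.2f", confidence)
  ifelse(called, txt, paste0("(", txt, ")"))
}
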