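#' Call changes for all ratios of one experiment
#'
#' Applies the per-experiment change rule to every row of a long-format
#' ratio table. In `protein` mode a change requires the ratio to lie
#' strictly outside the experiment's significance interval *and* a present
#' p-value at or below `pvalue_threshold`; in `phospho` mode the interval
#' condition alone decides (the p-value, rarely estimable from few spectra,
#' is reported but not used). A signed confidence score is attached to every
#' row, called or not.
#'
#' @param table Long tibble with columns `feature`, `condition`, `ratio` and
#'   optionally `pvalue`, `experiment`.
#' @param interval The experiment's [fit_significance_interval()] result.
#' @param internal_ratios The same experiment's internal-replicate ratios
#'   (the sample the interval was fitted from).
#' @param mode `"protein"` or `"phospho"`.
#' @param pvalue_threshold p-value cut-off used in protein mode.
#' @return The input tibble with columns `direction` (`"up"`, `"down"`,
#'   `"none"`) and `confidence` added.
#' @export
call_experiment <- function(table, interval, internal_ratios,
                            mode = c("protein", "phospho"),
                            pvalue_threshold = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(interval, "significance_interval"))
  if (!all(c("feature", "condition", "ratio") %in% names(table))) {
    stop("`table` needs columns feature, condition, ratio", call. = FALSE)
  }
  if ("experiment" %in% names(table) && !is.na(interval$experiment)) {
    exps <- unique(table$experiment)
    if (!all(exps == interval$experiment)) {
      stop("interval was fitted for experiment ", interval$experiment,
           " but the table contains ", paste(exps, collapse = ", "),
           call. = FALSE)
    }
  }
  pvalue <- if ("pvalue" %in% names(table)) table$pvalue else
    rep(NA_real_, nrow(table))
  out <- outside_interval(table$ratio, interval)
  called <- if (mode == "protein") {
    !is.na(out) & out & !is.na(pvalue) & pvalue <= pvalue_threshold
  } else {
    !is.na(out) & out
  }
  direction <- rep("none", nrow(table))
  direction[called & table$ratio > interval$upper] <- "up"
  direction[called & table$ratio < interval$lower] <- "down"
  table$direction <- direction
  table$confidence <- confidence_score(table$ratio, internal_ratios)
  table
}

#' Call a single quantification ratio
#'
#' Single-record form of [call_experiment()], returning one change call.
#'
#' @param q A list or one-row data frame with at least `ratio`, and
#'   optionally `feature`, `condition`, `experiment`, `pvalue`.
#' @inheritParams call_experiment
#' @return One-row tibble with `feature`, `condition`, `experiment`,
#'   `direction`, `confidence`, `ratio`, `pvalue`.
#' @export
#' @examples
#' null <- exp(seq(-0.25, 0.25, length.out = 101))
#' iv <- fit_significance_interval(null)
#' call_single_experiment(list(ratio = 1.8, pvalue = 0.01), iv, null)
call_single_experiment <- function(q, interval, internal_ratios,
                                   mode = c("protein", "phospho"),
                                   pvalue_threshold = 0.05) {
  mode <- match.arg(mode)
  q <- as.list(q)
  if (is.null(q$ratio) || is.na(q$ratio) || q$ratio <= 0) {
    stop("`q$ratio` must be a positive fold-change", call. = FALSE)
  }
  if (!is.null(q$experiment) && !is.na(interval$experiment) &&
      q$experiment != interval$experiment) {
    stop("interval was fitted for experiment ", interval$experiment,
         " but the ratio belongs to ", q$experiment, call. = FALSE)
  }
  row <- tibble::tibble(
    feature = q$feature %||% NA_character_,
    condition = q$condition %||% NA_character_,
    experiment = q$experiment %||% interval$experiment,
    ratio = q$ratio,
    pvalue = q$pvalue %||% NA_real_
  )
  call_experiment(row, interval, internal_ratios, mode = mode,
                  pvalue_threshold = pvalue_threshold)[
    , c("feature", "condition", "experiment", "direction", "confidence",
        "ratio", "pvalue")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric-mean average of fold-change ratios
#'
#' Fold-changes are averaged on the log scale so that a doubling and a
#' halving cancel exactly.
#'
#' @param ratios Positive fold-changes; `NA`s are dropped.
#' @return The geometric mean.
#' @export
#' @examples
#' average_ratio(c(0.5, 2))  # 1
average_ratio <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0L) stop("no ratios to average", call. = FALSE)
  if (any(ratios <= 0)) stop("ratios must be > 0", call. = FALSE)
  exp(mean(log(ratios)))
}

#' Arithmetic average of signed confidence scores
#'
#' Because the scores are signed, the averaged confidence is large in
#' magnitude only when the experiments agree in direction; disagreement
#' cancels towards zero.
#'
#' @param confs Signed confidences; `NA`s are dropped.
#' @return The mean signed confidence.
#' @export
average_confidence <- function(confs) {
  confs <- confs[!is.na(confs)]
  if (length(confs) == 0L) stop("no confidences to average", call. = FALSE)
  mean(confs)
}

consensus_direction <- function(up_n, down_n, n_quantified, rule) {
  if (rule == "majority") {
    if (up_n > n_quantified / 2) "up"
    else if (down_n > n_quantified / 2) "down"
    else "none"
  } else {
    if (up_n == 0 && down_n == 0) "none"
    else if (up_n > down_n) "up"
    else if (down_n > up_n) "down"
    else "none"
  }
}

#' Consensus call for one feature and oncogene across experiments
#'
#' Combines per-experiment change calls into one record. Under the default
#' `majority` rule the feature is called only if one direction is reached in
#' strictly more than half of the experiments in which a ratio is recorded;
#' under `any` a single calling experiment suffices. A call in the feature's
#' internal replicate in *any* experiment vetoes the record
#' (`internal_flagged`). The averaged ratio is the geometric mean and the
#' averaged confidence the arithmetic mean over all quantified experiments
#' (not only the calling ones). Records with calls in both directions are
#' flagged `direction_conflict`.
#'
#' @param calls Tibble of per-experiment calls for one feature x oncogene:
#'   columns `experiment`, `ratio`, `confidence`, `direction`.
#' @param internal_calls Tibble of the same feature's internal-replicate
#'   calls (columns including `direction`); may have zero rows.
#' @param rule `"majority"` or `"any"`.
#' @return One-row tibble: `feature`, `condition`, `avg_ratio`,
#'   `avg_confidence`, `call`, `n_quantified`, `n_called`,
#'   `internal_flagged`, `direction_conflict`.
#' @export
consensus_call <- function(calls, internal_calls = NULL,
                           rule = c("majority", "any")) {
  rule <- match.arg(rule)
  if (nrow(calls) == 0L) {
    stop("empty per-experiment call list", call. = FALSE)
  }
  quant <- calls[!is.na(calls$ratio), ]
  if (nrow(quant) == 0L) {
    stop("no experiment recorded a ratio for this feature", call. = FALSE)
  }
  up_n <- sum(quant$direction == "up")
  down_n <- sum(quant$direction == "down")
  call <- consensus_direction(up_n, down_n, nrow(quant), rule)
  internal_flagged <- !is.null(internal_calls) && nrow(internal_calls) > 0 &&
    any(internal_calls$direction != "none")
  if (internal_flagged) call <- "none"
  tibble::tibble(
    feature = if ("feature" %in% names(calls)) calls$feature[1] else NA_character_,
    condition = if ("condition" %in% names(calls)) calls$condition[1] else NA_character_,
    avg_ratio = average_ratio(quant$ratio),
    avg_confidence = average_confidence(quant$confidence),
    call = call,
    n_quantified = nrow(quant),
    n_called = up_n + down_n,
    internal_flagged = internal_flagged,
    direction_conflict = up_n > 0 && down_n > 0
  )
}

#' Consensus records for every feature and oncogene
#'
#' Vectorized form of [consensus_call()] over a full table of per-experiment
#' calls (oncogene and internal-replicate conditions together, as produced
#' by [call_experiment()] across experiments).
#'
#' @param calls Long tibble of per-experiment calls: columns `feature`,
#'   `condition`, `experiment`, `ratio`, `confidence`, `direction`.
#' @param rule `"majority"` or `"any"`.
#' @return Tibble of consensus records, one row per feature x oncogene.
#' @export
consensus_table <- function(calls, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  internal <- is_internal_condition(calls$condition)
  flags <- calls[internal, ] |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(internal_flagged = any(.data$direction != "none"),
                     .groups = "drop")
  onc <- calls[!internal & !is.na(calls$ratio), ] |>
    dplyr::group_by(.data$feature, .data$condition) |>
    dplyr::summarise(
      avg_ratio = exp(mean(log(.data$ratio))),
      avg_confidence = mean(.data$confidence),
      up_n = sum(.data$direction == "up"),
      down_n = sum(.data$direction == "down"),
      n_quantified = dplyr::n(),
      .groups = "drop"
    )
  onc$call <- mapply(consensus_direction, onc$up_n, onc$down_n,
                     onc$n_quantified, MoreArgs = list(rule = rule))
  onc <- dplyr::left_join(onc, flags, by = "feature")
  onc$internal_flagged <- !is.na(onc$internal_flagged) & onc$internal_flagged
  onc$call[onc$internal_flagged] <- "none"
  onc$n_called <- onc$up_n + onc$down_n
  onc$direction_conflict <- onc$up_n > 0 & onc$down_n > 0
  onc[, c("feature", "condition", "avg_ratio", "avg_confidence", "call",
          "n_quantified", "n_called", "internal_flagged",
          "direction_conflict")]
}

#' Run the full calling pipeline on a multi-experiment study
#'
#' Median-normalizes each experiment's ratio table, fits that experiment's
#' empirical-null significance interval from its internal-replicate ratios
#' (pooled if there are several internal columns), applies the
#' per-experiment change rule to every ratio, and combines experiments into
#' consensus records.
#'
#' @param tables A `synthetic_study`, or a named list of long-format
#'   per-experiment tibbles (columns `feature`, `condition`, `ratio`,
#'   optional `pvalue`), each containing at least one internal-replicate
#'   condition (label starting `"internal"`).
#' @param config A [run_config()].
#' @param normalize Median-normalize each table first (default `TRUE`).
#' @return An `itraq_calls` list: `intervals` (tibble `experiment`, `lower`,
#'   `upper`, `coverage`, `n_null`), `experiment_calls` (long tibble of
#'   per-experiment calls), `consensus` (tibble of consensus records) and
#'   `config`.
#' @export
#' @examples
#' study <- generate_study(study_config(n_features = 60, seed = 4))
#' res <- call_study(study)
#' head(res$consensus)
call_study <- function(tables, config = run_config(), normalize = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(tables, "synthetic_study")) tables <- tables$tables
  if (!is.list(tables) || !length(tables)) {
    stop("`tables` must be a nonempty list of per-experiment ratio tables",
         call. = FALSE)
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("exp", seq_along(tables))
  }
  fitted <- lapply(names(tables), function(exp_name) {
    tab <- tables[[exp_name]]
    if (!"experiment" %in% names(tab)) tab$experiment <- exp_name
    if (normalize) tab <- median_normalize(tab)
    internal <- tab$ratio[is_internal_condition(tab$condition)]
    if (!length(internal)) {
      stop("experiment ", exp_name, " has no internal-replicate condition ",
           "(a column whose label starts with \"internal\") to fit the ",
           "empirical null from", call. = FALSE)
    }
    iv <- fit_significance_interval(internal, coverage = config$coverage,
                                    experiment = exp_name)
    calls <- call_experiment(tab, iv, internal, mode = config$mode,
                             pvalue_threshold = config$pvalue_threshold)
    list(interval = iv, calls = calls)
  })
  intervals <- dplyr::bind_rows(lapply(fitted, function(f) {
    tibble::tibble(experiment = f$interval$experiment,
                   lower = f$interval$lower, upper = f$interval$upper,
                   coverage = f$interval$coverage, n_null = f$interval$n_null)
  }))
  experiment_calls <- dplyr::bind_rows(lapply(fitted, `[[`, "calls"))
  consensus <- consensus_table(experiment_calls, rule = config$consensus_rule)
  structure(
    list(intervals = intervals, experiment_calls = experiment_calls,
         consensus = consensus, config = config),
    class = "itraq_calls"
  )
}

#' @export
print.itraq_calls <- function(x, ...) {
  cat(sprintf(
    "iTRAQ change calls: %d experiments, %d consensus records (%d called)\n",
    nrow(x$intervals), nrow(x$consensus), sum(x$consensus$call != "none")))
  invisible(x)
}
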