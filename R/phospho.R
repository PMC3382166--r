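#' Filter phosphopeptide spectra by identification confidence
#'
#' Retains spectra identified with a confidence strictly greater than the
#' threshold (default 20, the inclusion rule for the phosphopeptide
#' analysis). Row order is preserved.
#'
#' @param spectra Tibble with an `id_confidence` column.
#' @param threshold Identification-confidence score cut-off.
#' @return The retained rows.
#' @export
#' @examples
#' filter_by_id_confidence(tibble::tibble(id_confidence = c(10, 20, 21, 95)))
filter_by_id_confidence <- function(spectra, threshold = 20) {
  if (!"id_confidence" %in% names(spectra)) {
    stop("`spectra` needs an `id_confidence` column", call. = FALSE)
  }
  spectra[spectra$id_confidence > threshold, , drop = FALSE]
}

#' Mark which spectra are used in quantification
#'
#' Adds a logical `used` column: `TRUE` for spectra passing the
#' identification-confidence filter.
#'
#' @inheritParams filter_by_id_confidence
#' @return `spectra` with a `used` column.
#' @export
mark_used_spectra <- function(spectra, threshold = 20) {
  if (!"id_confidence" %in% names(spectra)) {
    stop("`spectra` needs an `id_confidence` column", call. = FALSE)
  }
  spectra$used <- spectra$id_confidence > threshold
  spectra
}

# Error-factor-weighted mean of log ratios. Weights are 1/(log10 EF)^2 (the
# EF being the multiplicative 95% CI half-width, log10 EF is proportional to
# the ratio's standard error); equal weights when any EF in the group is
# absent. An EF of exactly 1 (zero estimated error) gets all the weight,
# shared equally among such spectra.
weighted_log_mean <- function(log_ratio, error_factor) {
  keep <- !is.na(log_ratio)
  log_ratio <- log_ratio[keep]
  error_factor <- error_factor[keep]
  if (!length(log_ratio)) return(NA_real_)
  if (anyNA(error_factor)) {
    w <- rep(1, length(log_ratio))
  } else {
    w <- 1 / log10(error_factor)^2
    if (any(is.infinite(w))) w <- ifelse(is.infinite(w), 1, 0)
  }
  sum(w * log_ratio) / sum(w)
}

#' Collapse phosphopeptide spectra to distinct phosphoentities
#'
#' A phosphoentity is a distinct peptide sequence together with its set of
#' modified residues; multiple identified spectra of the same entity are
#' collapsed to one record per condition. The entity ratio is the
#' exponential of the error-factor-weighted mean of the spectrum log ratios
#' (weights `1/(log10 EF)^2`; equal weights when any EF in the group is
#' absent). A per-condition p-value (two-sided one-sample t-test of the
#' spectrum log ratios against 0) is computed where at least two spectra
#' exist; it is reported but never used for change calling.
#'
#' @param spectra Long tibble of (already filtered) spectra with columns
#'   `sequence`, `modifications`, `condition`, `ratio`, and optionally
#'   `protein`, `error_factor`, `experiment`.
#' @return Tibble of entities: `protein`, `sequence`, `modifications`,
#'   `condition`, `ratio`, `pvalue`, `n_spectra_used` (per condition, and
#'   per experiment if an `experiment` column is present).
#' @export
collapse_entities <- function(spectra) {
  needed <- c("sequence", "modifications", "condition", "ratio")
  if (!all(needed %in% names(spectra))) {
    stop("`spectra` needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(spectra$ratio <= 0, na.rm = TRUE)) {
    stop("spectrum ratios must be > 0", call. = FALSE)
  }
  if (!"error_factor" %in% names(spectra)) spectra$error_factor <- NA_real_
  if (!"protein" %in% names(spectra)) spectra$protein <- NA_character_
  group_cols <- c("protein", "sequence", "modifications", "condition")
  if ("experiment" %in% names(spectra)) {
    group_cols <- c("experiment", group_cols)
  }
  spectra |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      pvalue = location_test_p(log(.data$ratio)),
      n_spectra_used = sum(!is.na(.data$ratio)),
      ratio = exp(weighted_log_mean(log(.data$ratio), .data$error_factor)),
      .groups = "drop"
    ) |>
    dplyr::relocate("ratio", .before = "pvalue")
}

# Two-sided one-sample t-test p-value of log ratios against 0; NA when not
# estimable (fewer than 2 values, or zero spread).
location_test_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L || sd(x) == 0) return(NA_real_)
  tstat <- mean(x) / (sd(x) / sqrt(length(x)))
  2 * pt(-abs(tstat), df = length(x) - 1)
}

#' Phosphorylation stoichiometry ratio
#'
#' The phosphopeptide fold-change divided by the parent protein's
#' fold-change: a value near 1 means the site's phosphorylation occupancy is
#' unchanged (the phosphopeptide merely tracked protein abundance), while a
#' value away from 1 indicates a change in the stoichiometry of
#' phosphorylation itself.
#'
#' @param phospho_fold Phosphopeptide fold-change (> 0).
#' @param protein_fold Parent protein fold-change (> 0).
#' @param log2_threshold Absolute log2 stoichiometry below which the site is
#'   classified `"unchanged"`.
#' @return Tibble with `stoichiometry` and `classification`
#'   (`"unchanged"`/`"changed"`).
#' @export
#' @examples
#' stoichiometry_ratio(1.98, 2.07)  # NF-IL3: unchanged occupancy
stoichiometry_ratio <- function(phospho_fold, protein_fold,
                                log2_threshold = 0.5) {
  if (any(phospho_fold <= 0, na.rm = TRUE) ||
      any(protein_fold <= 0, na.rm = TRUE)) {
    stop("fold-changes must be > 0", call. = FALSE)
  }
  ratio <- phospho_fold / protein_fold
  tibble::tibble(
    stoichiometry = ratio,
    classification = ifelse(abs(log2(ratio)) < log2_threshold,
                            "unchanged", "changed")
  )
}

#' Run the phosphopeptide pipeline on a spectrum table
#'
#' Marks and filters spectra by identification confidence, collapses them to
#' distinct phosphoentities, median-normalizes the entity ratio table per
#' experiment, and calls changes in phospho mode (interval condition only;
#' entity p-values are reported but not used).
#'
#' @param spectra Long spectrum tibble as produced by
#'   [generate_phospho_study()] or [read_phospho_spectra()]; must contain an
#'   `experiment` column and internal-replicate conditions.
#' @param config A [run_config()]; its `mode` is forced to `"phospho"`.
#' @return A list: `spectra` (input with `used` flags), `entities`
#'   (collapsed entity table) and the `itraq_calls` result `calls`.
#' @export
phospho_pipeline <- function(spectra, config = run_config(mode = "phospho")) {
  stopifnot(inherits(config, "run_config"))
  config$mode <- "phospho"
  marked <- mark_used_spectra(spectra,
                              threshold = config$id_confidence_threshold)
  entities <- collapse_entities(marked[marked$used, , drop = FALSE])
  if (!"experiment" %in% names(entities)) {
    stop("`spectra` needs an `experiment` column", call. = FALSE)
  }
  entities$feature <- paste(entities$sequence, entities$modifications,
                            sep = "|")
  tables <- split(entities, entities$experiment)
  calls <- call_study(tables, config = config)
  list(spectra = marked, entities = entities, calls = calls)
}
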