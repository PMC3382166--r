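#' Classify protein-vs-mRNA concordance
#'
#' For a feature with a nuclear protein consensus call, asks whether the
#' mRNA layer moved with it. `mrna-concordant`: the mRNA fold crosses the
#' threshold (>= `fold_threshold` or <= its reciprocal) in the same
#' direction as the protein change; `discordant`: it crosses in the opposite
#' direction; `post-translational`: the mRNA does not cross at all — the
#' protein change has no transcript-level explanation.
#'
#' @param nuclear_fold Nuclear protein fold-change(s) (> 0); the protein
#'   call's direction is taken from which side of 1 this lies.
#' @param mrna_fold mRNA fold-change(s) (> 0, `NA` allowed).
#' @param fold_threshold Fold the mRNA must cross (default 2).
#' @return Character vector: `"mrna-concordant"`, `"post-translational"`,
#'   `"discordant"` or `"not-assessed"` (mRNA absent).
#' @export
#' @examples
#' classify_mrna_concordance(0.57, 0.95)  # post-translational
classify_mrna_concordance <- function(nuclear_fold, mrna_fold,
                                      fold_threshold = 2.0) {
  check_scalar_number(fold_threshold, "fold_threshold", lower = 1)
  if (any(nuclear_fold <= 0, na.rm = TRUE)) {
    stop("nuclear fold-changes must be > 0", call. = FALSE)
  }
  if (any(mrna_fold <= 0, na.rm = TRUE)) {
    stop("mRNA fold-changes must be > 0", call. = FALSE)
  }
  n <- max(length(nuclear_fold), length(mrna_fold))
  nuclear_fold <- rep_len(nuclear_fold, n)
  mrna_fold <- rep_len(mrna_fold, n)
  protein_up <- nuclear_fold > 1
  mrna_up <- mrna_fold >= fold_threshold
  mrna_down <- mrna_fold <= 1 / fold_threshold
  out <- ifelse(!mrna_up & !mrna_down, "post-translational",
         ifelse(mrna_up == protein_up, "mrna-concordant", "discordant"))
  out[is.na(mrna_fold)] <- "not-assessed"
  out
}

#' Classify nuclear-vs-cytosolic localization behaviour
#'
#' Distinguishes translocation from compartment-specific regulation:
#' `translocation-consistent` when nuclear and cytosolic folds cross the
#' threshold in opposite directions (protein moved between compartments),
#' `parallel` when both cross in the same direction (whole-cell change),
#' `compartment-specific` when only the nuclear fold crosses, and
#' `parallel-null` when neither crosses.
#'
#' @param nuclear_fold Nuclear fold-change(s) (> 0).
#' @param cytosol_fold Cytosolic fold-change(s) (> 0, `NA` allowed).
#' @param fold_threshold Fold either compartment must cross (default 1.5).
#' @return Character vector: `"translocation-consistent"`, `"parallel"`,
#'   `"compartment-specific"`, `"parallel-null"` or `"not-assessed"`.
#' @export
#' @examples
#' classify_localization(0.56, 1.0)  # compartment-specific
classify_localization <- function(nuclear_fold, cytosol_fold,
                                  fold_threshold = 1.5) {
  check_scalar_number(fold_threshold, "fold_threshold", lower = 1)
  if (any(nuclear_fold <= 0, na.rm = TRUE)) {
    stop("nuclear fold-changes must be > 0", call. = FALSE)
  }
  if (any(cytosol_fold <= 0, na.rm = TRUE)) {
    stop("cytosolic fold-changes must be > 0", call. = FALSE)
  }
  n <- max(length(nuclear_fold), length(cytosol_fold))
  nuclear_fold <- rep_len(nuclear_fold, n)
  cytosol_fold <- rep_len(cytosol_fold, n)
  crosses <- function(x) x >= fold_threshold | x <= 1 / fold_threshold
  nuc_cross <- crosses(nuclear_fold)
  cyt_cross <- crosses(cytosol_fold)
  same_dir <- (nuclear_fold > 1) == (cytosol_fold > 1)
  out <- ifelse(nuc_cross & cyt_cross & !same_dir, "translocation-consistent",
         ifelse(nuc_cross & cyt_cross & same_dir, "parallel",
         ifelse(nuc_cross & !cyt_cross, "compartment-specific",
                "parallel-null")))
  out[is.na(cytosol_fold)] <- "not-assessed"
  out
}

#' Build concordance records for called features
#'
#' Joins consensus-called features with the mRNA and cytosolic layers and
#' classifies each record. Features missing from a layer are kept with
#' category `"not-assessed"`, never silently dropped.
#'
#' @param consensus Consensus records (from [call_study()]), typically
#'   filtered to `call != "none"`.
#' @param mrna_table Tibble `feature`, `condition`, `fold` or `NULL`.
#' @param cytosol_table Tibble `feature`, `condition`, `fold` or `NULL`.
#' @param mrna_fold_threshold Passed to [classify_mrna_concordance()].
#' @param cytosol_fold_threshold Passed to [classify_localization()].
#' @return Tibble of concordance records: `feature`, `condition`,
#'   `nuclear_fold`, `call`, `mrna_fold`, `cytosol_fold`, `mrna_category`,
#'   `localization_category`.
#' @export
concordance_records <- function(consensus, mrna_table = NULL,
                                cytosol_table = NULL,
                                mrna_fold_threshold = 2.0,
                                cytosol_fold_threshold = 1.5) {
  rec <- tibble::tibble(
    feature = consensus$feature,
    condition = consensus$condition,
    nuclear_fold = consensus$avg_ratio,
    call = consensus$call
  )
  join_layer <- function(rec, layer, col) {
    if (is.null(layer)) {
      rec[[col]] <- NA_real_
      return(rec)
    }
    layer <- dplyr::rename(layer[, c("feature", "condition", "fold")],
                           !!col := "fold")
    dplyr::left_join(rec, layer, by = c("feature", "condition"))
  }
  rec <- join_layer(rec, mrna_table, "mrna_fold")
  rec <- join_layer(rec, cytosol_table, "cytosol_fold")
  rec$mrna_category <- classify_mrna_concordance(
    rec$nuclear_fold, rec$mrna_fold, mrna_fold_threshold)
  rec$localization_category <- classify_localization(
    rec$nuclear_fold, rec$cytosol_fold, cytosol_fold_threshold)
  rec
}

#' Transcription-factor-stratified mRNA concordance
#'
#' For each transcription factor in the annotation, among annotated features
#' whose protein call is down, the fraction whose mRNA also crossed the
#' concordance threshold downwards — and symmetrically for up calls. Exact
#' counts are reported alongside the fractions.
#'
#' @param records Concordance records carrying `mrna_category` and `call`
#'   (from [concordance_records()]).
#' @param annotation Tibble `feature`, `tf` mapping features to the
#'   transcription factors with binding sites in their promoters.
#' @return Tibble: `tf`, `direction`, `n_changed`, `n_mrna_concordant`,
#'   `fraction_concordant`.
#' @export
tf_stratified_concordance <- function(records, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    return(tibble::tibble(tf = character(), direction = character(),
                          n_changed = integer(), n_mrna_concordant = integer(),
                          fraction_concordant = numeric()))
  }
  if (!all(c("feature", "tf") %in% names(annotation))) {
    stop("`annotation` needs columns `feature` and `tf`", call. = FALSE)
  }
  changed <- records[records$call %in% c("up", "down"), ]
  dplyr::inner_join(annotation, changed, by = "feature",
                    relationship = "many-to-many") |>
    dplyr::group_by(.data$tf, direction = .data$call) |>
    dplyr::summarise(
      n_changed = dplyr::n(),
      n_mrna_concordant = sum(.data$mrna_category == "mrna-concordant"),
      fraction_concordant = .data$n_mrna_concordant / .data$n_changed,
      .groups = "drop"
    )
}
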