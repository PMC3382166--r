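#' @importFrom rlang .data :=
#' @importFrom utils combn
NULL

ratio_suffixes <- c(ratio = "_ratio", pvalue = "_pvalue", error_factor = "_ef",
                    n_spectra = "_nspec")

#' Read a feature x condition ratio table
#'
#' The on-disk dialect is plain TSV (UTF-8, `.` decimal separator): a
#' `feature` column, then per condition a `<condition>_ratio` column and
#' optional `<condition>_pvalue`, `<condition>_ef` (error factor) and
#' `<condition>_nspec` (spectra count) columns. Internal technical
#' replicates are conditions whose label starts with `"internal"`.
#'
#' @param path TSV file.
#' @param experiment Optional experiment label attached to every row.
#' @return Long tibble: `experiment` (if given), `feature`, `condition`,
#'   `ratio`, `pvalue`, `error_factor`, `n_spectra`; row order of the file
#'   preserved within each condition.
#' @export
read_ratio_table <- function(path, experiment = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"feature" %in% names(wide)) {
    stop("missing required column `feature` in ", path, call. = FALSE)
  }
  ratio_cols <- grep("_ratio$", names(wide), value = TRUE)
  if (!length(ratio_cols)) {
    stop("no `<condition>_ratio` columns found in ", path, call. = FALSE)
  }
  dup <- wide$feature[duplicated(wide$feature)]
  if (length(dup)) {
    stop("duplicate feature identifiers in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  conditions <- sub("_ratio$", "", ratio_cols)
  long <- dplyr::bind_rows(lapply(conditions, function(cond) {
    get_col <- function(suffix) {
      nm <- paste0(cond, suffix)
      if (nm %in% names(wide)) wide[[nm]] else rep(NA_real_, nrow(wide))
    }
    tibble::tibble(
      feature = wide$feature,
      condition = cond,
      ratio = get_col("_ratio"),
      pvalue = get_col("_pvalue"),
      error_factor = get_col("_ef"),
      n_spectra = get_col("_nspec")
    )
  }))
  bad <- !is.na(long$ratio) & long$ratio <= 0
  if (any(bad)) {
    offending <- long[bad, c("feature", "condition", "ratio")]
    stop("nonpositive ratio(s) in ", path, ", e.g. feature ",
         offending$feature[1], ", condition ", offending$condition[1],
         " (ratio ", offending$ratio[1], ")", call. = FALSE)
  }
  if (!is.null(experiment)) {
    long <- dplyr::mutate(long, experiment = experiment, .before = 1)
  }
  long
}

#' Write a ratio table to the package's TSV dialect
#'
#' @param table Long tibble with `feature`, `condition`, `ratio` and
#'   optional `pvalue`, `error_factor`, `n_spectra`.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path) {
  for (col in names(ratio_suffixes)) {
    if (!col %in% names(table)) table[[col]] <- NA_real_
  }
  conditions <- unique(table$condition)
  wide <- tibble::tibble(feature = unique(table$feature))
  for (cond in conditions) {
    sub <- table[table$condition == cond, ]
    sub <- sub[match(wide$feature, sub$feature), ]
    for (col in names(ratio_suffixes)) {
      if (all(is.na(sub[[col]])) && col != "ratio") next
      wide[[paste0(cond, ratio_suffixes[[col]])]] <- sub[[col]]
    }
  }
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read / write phosphopeptide spectrum tables
#'
#' Spectrum TSVs carry one row per identified spectrum with columns
#' `experiment`, `spectrum_id`, `protein`, `sequence`, `modifications`,
#' `id_confidence`, `error_factor` and per-condition `<condition>_ratio`
#' columns.
#'
#' @param path TSV file.
#' @return `read_phospho_spectra()`: long tibble with one row per spectrum
#'   and condition; `write_phospho_spectra()`: `path`, invisibly.
#' @export
read_phospho_spectra <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  id_cols <- c("experiment", "spectrum_id", "protein", "sequence",
               "modifications", "id_confidence", "error_factor")
  missing <- setdiff(setdiff(id_cols, "error_factor"), names(wide))
  if (length(missing)) {
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (!"error_factor" %in% names(wide)) wide$error_factor <- NA_real_
  ratio_cols <- grep("_ratio$", names(wide), value = TRUE)
  if (!length(ratio_cols)) {
    stop("no `<condition>_ratio` columns found in ", path, call. = FALSE)
  }
  tidyr::pivot_longer(wide, dplyr::all_of(ratio_cols),
                      names_to = "condition", values_to = "ratio") |>
    dplyr::mutate(condition = sub("_ratio$", "", .data$condition))
}

#' @rdname read_phospho_spectra
#' @param spectra Long spectrum tibble.
#' @export
write_phospho_spectra <- function(spectra, path) {
  wide <- tidyr::pivot_wider(
    spectra,
    names_from = "condition", values_from = "ratio",
    names_glue = "{condition}_ratio")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write / read per-experiment significance intervals
#'
#' A small TSV (`experiment`, `lower`, `upper`, `coverage`, `n_null`)
#' recording the empirical-null interval of each experimental run.
#'
#' @param intervals Tibble as in the `intervals` element of [call_study()].
#' @param path TSV file.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_significance_intervals <- function(intervals, path) {
  readr::write_tsv(intervals, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_significance_intervals
#' @export
read_significance_intervals <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    experiment = readr::col_character(),
                    lower = readr::col_double(),
                    upper = readr::col_double(),
                    coverage = readr::col_double(),
                    n_null = readr::col_integer()))
}

#' Write / read consensus records
#'
#' @param consensus Consensus tibble from [call_study()].
#' @param path TSV file.
#' @return The tibble (read) or `path` invisibly (write).
#' @export
write_consensus <- function(consensus, path) {
  readr::write_tsv(consensus, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    feature = readr::col_character(),
                    condition = readr::col_character(),
                    call = readr::col_character(),
                    internal_flagged = readr::col_logical(),
                    direction_conflict = readr::col_logical(),
                    .default = readr::col_double()))
}

#' Packaged transcriptions of the published result tables
#'
#' `"table1"` is the proteins-changed-by-four-or-more-oncogenes table
#' (66 rows: accession, gene symbol, protein name, number of oncogenes the
#' protein changes in, and per oncogene the averaged fold-change, averaged
#' signed confidence and a `called` flag — the machine encoding of the
#' printed bold/bracket convention). `"table2"` is the corresponding
#' phosphopeptide selection (8 rows, keyed additionally by the
#' phosphopeptide sequence).
#'
#' @param name `"table1"` or `"table2"`.
#' @return Wide tibble.
#' @export
#' @examples
#' t1 <- load_fixture("table1")
#' t1[t1$gene_symbol == "Pms2", "FIP1L/PDGFRA_ratio"]
load_fixture <- function(name) {
  if (!name %in% c("table1", "table2")) {
    stop("unknown fixture: ", name, " (use \"table1\" or \"table2\")",
         call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "itraqnull",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert a packaged fixture to consensus-record layout
#'
#' Reshapes a [load_fixture()] table to the long consensus layout so that
#' summary operations ([common_targets()], [venn_counts()] inputs) apply to
#' the published rows directly. The call direction of a called cell is taken
#' from which side of 1 its averaged ratio lies.
#'
#' @param fixture A [load_fixture()] result.
#' @return Long tibble: `feature`, `condition`, `avg_ratio`,
#'   `avg_confidence`, `called`, `call`.
#' @export
fixture_to_consensus <- function(fixture) {
  key <- if ("phospho_peptide" %in% names(fixture)) "phospho_peptide" else
    "accession"
  ratio_cols <- grep("_ratio$", names(fixture), value = TRUE)
  conditions <- sub("_ratio$", "", ratio_cols)
  dplyr::bind_rows(lapply(conditions, function(cond) {
    tibble::tibble(
      feature = fixture[[key]],
      condition = cond,
      avg_ratio = fixture[[paste0(cond, "_ratio")]],
      avg_confidence = fixture[[paste0(cond, "_conf")]],
      called = fixture[[paste0(cond, "_called")]]
    )
  })) |>
    dplyr::mutate(call = ifelse(!.data$called, "none",
                                ifelse(.data$avg_ratio > 1, "up", "down")))
}
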