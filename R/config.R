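#' Default oncogene condition labels
#'
#' The six constitutively active protein tyrosine kinases profiled against a
#' common vector control: BCR/ABL, TEL/PDGFRB, NPM/ALK, KIT D816V, FLT3-ITD
#' and FIP1L/PDGFRA.
#'
#' @return Character vector of six condition labels.
#' @export
default_oncogenes <- function() {
  c("BCR/ABL", "TEL/PDGFRB", "NPM/ALK", "KITD816V", "FLT3ITD", "FIP1L/PDGFRA")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single non-missing number")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %s", lower))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

#' Study configuration for the synthetic-data generator
#'
#' Describes the design emulated by [generate_study()]: several biological
#' replicate experiments, each quantifying the same features across the six
#' oncogene channels plus a duplicated-control internal technical replicate,
#' with a fraction of features spiked with true fold-changes.
#'
#' The noise model is Gaussian on the log2 scale: a feature's reported ratio
#' is the mean of `k` spectrum-level log2 ratios (with `k` drawn from a
#' shifted geometric distribution with mean `spectra_per_feature`), scaled so
#' that the reported mean itself has standard deviation `log2_null_sd`.
#'
#' @param n_features Number of quantified features (>= 10).
#' @param n_experiments Number of biological replicate experiments.
#' @param oncogene_names Labels of the non-control conditions.
#' @param n_internal_replicates Internal (control-vs-control) ratio columns
#'   per experiment.
#' @param log2_null_sd Standard deviation of a null feature's reported log2
#'   ratio.
#' @param spectra_per_feature Mean of the shifted-geometric spectrum count
#'   per feature and experiment.
#' @param spike_fraction Proportion of features given a true fold-change.
#' @param spike_fold_range Pair of positive fold-changes; spike magnitudes
#'   are drawn log-uniformly between them and applied up or down with equal
#'   probability.
#' @param mrna_coupling Probability that a spiked feature's mRNA layer
#'   mirrors its protein fold-change (else the mRNA stays null).
#' @param mrna_log2_sd Null log2 noise sd of the mRNA layer.
#' @param cytosol_log2_sd Null log2 noise sd of the cytosolic layer.
#' @param seed Integer master seed; per-experiment substreams are derived by
#'   fixed offsets so adding an experiment leaves earlier ones unchanged.
#'
#' @return A `study_config` list.
#' @export
#' @examples
#' cfg <- study_config(n_features = 100, seed = 1)
study_config <- function(n_features = 3600,
                         n_experiments = 3,
                         oncogene_names = default_oncogenes(),
                         n_internal_replicates = 1,
                         log2_null_sd = 0.15,
                         spectra_per_feature = 10,
                         spike_fraction = 0.05,
                         spike_fold_range = c(1.5, 3),
                         mrna_coupling = 0.3,
                         mrna_log2_sd = 0.25,
                         cytosol_log2_sd = 0.2,
                         seed = 1L) {
  check_scalar_number(n_features, "n_features", lower = 10)
  check_scalar_number(n_experiments, "n_experiments", lower = 1)
  if (!is.character(oncogene_names) || length(oncogene_names) < 1L ||
      anyDuplicated(oncogene_names) || any(!nzchar(oncogene_names))) {
    stop_field("oncogene_names", "must be distinct nonempty labels")
  }
  check_scalar_number(n_internal_replicates, "n_internal_replicates", lower = 1)
  check_scalar_number(log2_null_sd, "log2_null_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(spectra_per_feature, "spectra_per_feature",
                      lower = 1)
  check_scalar_number(spike_fraction, "spike_fraction", lower = 0, upper = 1)
  if (!is.numeric(spike_fold_range) || length(spike_fold_range) != 2L ||
      any(spike_fold_range <= 0) || any(spike_fold_range == 1)) {
    stop_field("spike_fold_range", "must be two positive fold-changes != 1")
  }
  check_scalar_number(mrna_coupling, "mrna_coupling", lower = 0, upper = 1)
  check_scalar_number(mrna_log2_sd, "mrna_log2_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(cytosol_log2_sd, "cytosol_log2_sd",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(seed, "seed")
  structure(
    list(
      n_features = as.integer(n_features),
      n_experiments = as.integer(n_experiments),
      oncogene_names = oncogene_names,
      n_internal_replicates = as.integer(n_internal_replicates),
      log2_null_sd = log2_null_sd,
      spectra_per_feature = spectra_per_feature,
      spike_fraction = spike_fraction,
      spike_fold_range = as.numeric(spike_fold_range),
      mrna_coupling = mrna_coupling,
      mrna_log2_sd = mrna_log2_sd,
      cytosol_log2_sd = cytosol_log2_sd,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  features: %d, experiments: %d, internal replicates/exp: %d\n",
              x$n_features, x$n_experiments, x$n_internal_replicates))
  cat(sprintf("  conditions: %s\n", paste(x$oncogene_names, collapse = ", ")))
  cat(sprintf("  log2 null sd: %g, spectra/feature: %g\n",
              x$log2_null_sd, x$spectra_per_feature))
  cat(sprintf("  spike fraction: %g in [%g, %g]-fold, mRNA coupling: %g\n",
              x$spike_fraction, x$spike_fold_range[1], x$spike_fold_range[2],
              x$mrna_coupling))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Analysis run configuration
#'
#' Gathers every threshold of the calling pipeline in one validated object.
#' Defaults are the study's stated constants: a 95% empirical-null
#' significance interval, a p-value cut-off of 0.05 (protein mode only), an
#' identification-confidence filter of greater than 20 for phosphopeptide
#' spectra, a 2-fold mRNA concordance threshold and majority consensus.
#'
#' @param coverage Coverage of the empirical-null significance interval.
#' @param pvalue_threshold Per-experiment p-value cut-off (protein mode).
#' @param consensus_rule `"majority"` (default) or `"any"`.
#' @param mode `"protein"` (ratio outside interval and p-value <= threshold)
#'   or `"phospho"` (interval condition only).
#' @param mrna_fold_threshold Fold-change an mRNA must cross to count as
#'   concordant/discordant.
#' @param cytosol_fold_threshold Fold-change a cytosolic ratio must cross in
#'   localization classification.
#' @param id_confidence_threshold Spectra with identification confidence
#'   strictly above this value are retained.
#' @param stoichiometry_log2_threshold Absolute log2 phospho/protein ratio
#'   below which site stoichiometry is classified unchanged.
#' @param seed Integer seed recorded with the run.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(coverage = 0.95,
                       pvalue_threshold = 0.05,
                       consensus_rule = c("majority", "any"),
                       mode = c("protein", "phospho"),
                       mrna_fold_threshold = 2.0,
                       cytosol_fold_threshold = 1.5,
                       id_confidence_threshold = 20,
                       stoichiometry_log2_threshold = 0.5,
                       seed = 1L) {
  check_scalar_number(coverage, "coverage", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(pvalue_threshold, "pvalue_threshold", lower = 0, upper = 1)
  consensus_rule <- match.arg(consensus_rule)
  mode <- match.arg(mode)
  check_scalar_number(mrna_fold_threshold, "mrna_fold_threshold",
                      lower = 1)
  check_scalar_number(cytosol_fold_threshold, "cytosol_fold_threshold",
                      lower = 1)
  check_scalar_number(id_confidence_threshold, "id_confidence_threshold",
                      lower = 0, upper = 100)
  check_scalar_number(stoichiometry_log2_threshold,
                      "stoichiometry_log2_threshold", lower = 0)
  check_scalar_number(seed, "seed")
  structure(
    list(
      coverage = coverage,
      pvalue_threshold = pvalue_threshold,
      consensus_rule = consensus_rule,
      mode = mode,
      mrna_fold_threshold = mrna_fold_threshold,
      cytosol_fold_threshold = cytosol_fold_threshold,
      id_confidence_threshold = id_confidence_threshold,
      stoichiometry_log2_threshold = stoichiometry_log2_threshold,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write or read a resolved run configuration
#'
#' Every pipeline run echoes its fully resolved configuration next to its
#' outputs as plain `key<TAB>value` text, so any result file can be traced
#' back to the thresholds that produced it.
#'
#' @param config A [run_config()] object.
#' @param path File to write to / read from.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lines <- vapply(names(config), function(nm) {
    paste(nm, format(config[[nm]], digits = 15), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, col.names = c("key", "value"),
                          colClasses = "character")
  known <- names(formals(run_config))
  bad <- setdiff(kv$key, known)
  if (length(bad)) {
    stop("unknown run_config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(kv$value), kv$key)
  numeric_keys <- setdiff(known, c("consensus_rule", "mode"))
  args[names(args) %in% numeric_keys] <-
    lapply(args[names(args) %in% numeric_keys], as.numeric)
  do.call(run_config, args)
}
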