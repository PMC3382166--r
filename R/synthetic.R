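#' @importFrom rlang .data
#' @importFrom stats median quantile rnorm rgeom runif rbinom pt qt sd setNames
NULL

#' Is a condition label an internal technical replicate?
#'
#' Internal replicates are the control sample labelled in a second channel of
#' the same run; their control-vs-control ratios form the empirical null.
#'
#' @param condition Character vector of condition labels.
#' @return Logical vector.
#' @export
is_internal_condition <- function(condition) {
  startsWith(condition, "internal")
}

internal_condition_names <- function(n) {
  if (n == 1L) "internal" else paste0("internal_", seq_len(n))
}

# Substream seed for experiment e under a master seed; fixed offsets keep
# earlier experiments bit-identical when n_experiments grows.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 7919 * stream) %% 2147483647)
}

# Simulate one condition column: each feature's reported log2 ratio is the
# mean of k spectrum-level log2 ratios, scaled so the mean itself has sd
# `sd_mean`; p-value and error factor come from the k spectra (absent at
# k = 1, where neither is estimable).
simulate_cells <- function(tau, k, sd_mean) {
  n <- length(tau)
  idx <- rep.int(seq_len(n), k)
  spectrum_sd <- sd_mean * sqrt(k)
  draws <- rnorm(length(idx), mean = tau[idx], sd = spectrum_sd[idx])
  m <- unname(rowsum(draws, idx)[, 1]) / k
  ss <- unname(rowsum((draws - m[idx])^2, idx)[, 1])
  pvalue <- rep(NA_real_, n)
  error_factor <- rep(NA_real_, n)
  rep_ok <- k > 1
  se <- sqrt(ss[rep_ok] / (k[rep_ok] - 1) / k[rep_ok])
  tstat <- m[rep_ok] / se
  pvalue[rep_ok] <- 2 * pt(-abs(tstat), df = k[rep_ok] - 1)
  # EF = 10^(t_{0.975, k-1} * SE of mean log10 ratio); multiplicative
  # half-width of the ratio's 95% CI
  error_factor[rep_ok] <-
    pmax(10^(qt(0.975, df = k[rep_ok] - 1) * se * log10(2)), 1)
  list(ratio = 2^m, pvalue = pvalue, error_factor = error_factor)
}

# Spike assignment shared by the protein and phospho generators: which
# features change, in which conditions, and by what fold.
draw_truth <- function(cfg) {
  n <- cfg$n_features
  n_spiked <- round(cfg$spike_fraction * n)
  if (n_spiked == 0L) {
    return(tibble::tibble(feature_idx = integer(), condition = character(),
                          fold = numeric()))
  }
  spiked <- sort(sample.int(n, n_spiked))
  rows <- lapply(spiked, function(i) {
    in_cond <- rbinom(length(cfg$oncogene_names), 1L, 0.5) == 1L
    if (!any(in_cond)) in_cond[sample.int(length(in_cond), 1L)] <- TRUE
    conds <- cfg$oncogene_names[in_cond]
    lr <- sort(log(cfg$spike_fold_range))
    magnitude <- exp(runif(length(conds), lr[1], lr[2]))
    flip <- rbinom(length(conds), 1L, 0.5) == 1L
    fold <- ifelse(flip, 1 / magnitude, magnitude)
    tibble::tibble(feature_idx = i, condition = conds, fold = fold)
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic multi-experiment iTRAQ ratio study
#'
#' Emulates the statistical structure the calling pipeline assumes: several
#' biological replicate experiments, each reporting per-feature fold-change
#' ratios against a common control for the six oncogene channels plus an
#' always-null internal technical replicate; approximately log-normal null
#' ratios centred on 1; per-ratio p-values and error factors derived from
#' spectrum-level replication; and spike-in true changes recorded as ground
#' truth. Matched mRNA and cytosolic fold-change layers are generated so the
#' downstream concordance classifiers have structure to find: a spiked
#' feature's mRNA mirrors its protein fold with probability
#' `mrna_coupling`, while the cytosolic layer stays null (nuclear changes in
#' this design are post-translational, not translocation).
#'
#' @param config A [study_config()].
#' @return A `synthetic_study` list with elements `tables` (named list of
#'   per-experiment tibbles with columns `experiment`, `feature`,
#'   `condition`, `ratio`, `pvalue`, `error_factor`, `n_spectra`),
#'   `mrna_table` and `cytosol_table` (tibbles `feature`, `condition`,
#'   `fold`), `truth` (tibble `feature`, `condition`, `fold`; unchanged
#'   features absent) and `config`.
#' @export
#' @examples
#' study <- generate_study(study_config(n_features = 50, seed = 1))
#' head(study$tables$exp1)
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  features <- sprintf("P%05d", seq_len(cfg$n_features))
  conditions <- c(cfg$oncogene_names,
                  internal_condition_names(cfg$n_internal_replicates))

  set.seed(cfg$seed)
  truth_idx <- draw_truth(cfg)
  truth <- tibble::tibble(feature = features[truth_idx$feature_idx],
                          condition = truth_idx$condition,
                          fold = truth_idx$fold)

  # true log2 fold per feature x condition (0 for null and internals)
  tau <- matrix(0, nrow = cfg$n_features, ncol = length(conditions),
                dimnames = list(NULL, conditions))
  if (nrow(truth_idx)) {
    tau[cbind(truth_idx$feature_idx,
              match(truth_idx$condition, conditions))] <- log2(truth_idx$fold)
  }

  tables <- lapply(seq_len(cfg$n_experiments), function(e) {
    set.seed(substream_seed(cfg$seed, e))
    k <- 1L + rgeom(cfg$n_features, 1 / cfg$spectra_per_feature)
    cols <- lapply(conditions, function(cond) {
      cells <- simulate_cells(tau[, cond], k, cfg$log2_null_sd)
      tibble::tibble(
        experiment = paste0("exp", e),
        feature = features,
        condition = cond,
        ratio = cells$ratio,
        pvalue = cells$pvalue,
        error_factor = cells$error_factor,
        n_spectra = k
      )
    })
    dplyr::bind_rows(cols)
  })
  names(tables) <- paste0("exp", seq_len(cfg$n_experiments))

  # mRNA layer: null noise everywhere, except spiked features whose
  # coupling coin (drawn per feature) says the transcript mirrors the
  # protein change
  set.seed(substream_seed(cfg$seed, 524287))
  coupled_features <- unique(truth$feature)
  coupled_features <- coupled_features[
    rbinom(length(coupled_features), 1L, cfg$mrna_coupling) == 1L]
  mrna <- tidyr::expand_grid(feature = features,
                             condition = cfg$oncogene_names)
  mrna_tau <- rep(0, nrow(mrna))
  if (nrow(truth)) {
    hit <- match(paste(mrna$feature, mrna$condition),
                 paste(truth$feature, truth$condition))
    mirrored <- !is.na(hit) & mrna$feature %in% coupled_features
    mrna_tau[mirrored] <- log2(truth$fold[hit[mirrored]])
  }
  mrna$fold <- 2^(mrna_tau + rnorm(nrow(mrna), 0, cfg$mrna_log2_sd))

  set.seed(substream_seed(cfg$seed, 786433))
  cytosol <- tidyr::expand_grid(feature = features,
                                condition = cfg$oncogene_names)
  cytosol$fold <- 2^rnorm(nrow(cytosol), 0, cfg$cytosol_log2_sd)

  structure(
    list(tables = tables, mrna_table = mrna, cytosol_table = cytosol,
         truth = truth, config = cfg),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic iTRAQ study: %d features x %d conditions, %d experiments, %d spiked feature-condition pairs\n",
    x$config$n_features,
    length(unique(x$tables[[1]]$condition)),
    length(x$tables),
    nrow(x$truth)))
  invisible(x)
}

random_peptide <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  repeat {
    seq <- paste(sample(aa, len, replace = TRUE), collapse = "")
    if (grepl("[STY]", seq)) return(seq)
  }
}

#' Generate a synthetic spectrum-level phosphopeptide study
#'
#' Emits identified-spectrum rows (peptide sequence, phosphosite modification
#' set, identification confidence, error factor and per-condition ratios)
#' such that multiple spectra map to each distinct phosphoentity (a distinct
#' sequence plus set of modified residues). `n_features` is the number of
#' entities; `spectra_per_feature` the mean spectra per entity and
#' experiment. Identification confidences include values at or below 20 so
#' the downstream confidence filter has work to do. Entity-level spike truth
#' is recorded as in [generate_study()].
#'
#' @param config A [study_config()].
#' @return A `phospho_study` list with elements `spectra` (tibble
#'   `experiment`, `spectrum_id`, `protein`, `sequence`, `modifications`,
#'   `id_confidence`, `error_factor`, `condition`, `ratio`), `entities`
#'   (tibble `protein`, `sequence`, `modifications`), `truth` and `config`.
#' @export
generate_phospho_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  n <- cfg$n_features
  conditions <- c(cfg$oncogene_names,
                  internal_condition_names(cfg$n_internal_replicates))

  set.seed(cfg$seed)
  proteins <- sprintf("PP%04d", sample.int(max(ceiling(n / 1.5), 1L), n,
                                           replace = TRUE))
  sequences <- vapply(sample(10:18, n, replace = TRUE), random_peptide,
                      character(1))
  modifications <- vapply(sequences, function(s) {
    sites <- gregexpr("[STY]", s)[[1]]
    n_mod <- min(length(sites), sample(1:2, 1))
    pos <- sort(sample(as.integer(sites), n_mod))
    res <- substring(s, pos, pos)
    paste(sprintf("Pho(%s%d)", res, pos), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  # entity keys must be distinct; re-draw sequences on the (rare) collision
  key <- paste(sequences, modifications)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    sequences[dup] <- vapply(sample(10:18, length(dup), replace = TRUE),
                             random_peptide, character(1))
    key <- paste(sequences, modifications)
  }

  truth_idx <- draw_truth(cfg)
  truth <- tibble::tibble(protein = proteins[truth_idx$feature_idx],
                          sequence = sequences[truth_idx$feature_idx],
                          modifications = modifications[truth_idx$feature_idx],
                          condition = truth_idx$condition,
                          fold = truth_idx$fold)
  tau <- matrix(0, nrow = n, ncol = length(conditions),
                dimnames = list(NULL, conditions))
  if (nrow(truth_idx)) {
    tau[cbind(truth_idx$feature_idx,
              match(truth_idx$condition, conditions))] <- log2(truth_idx$fold)
  }

  spectra <- lapply(seq_len(cfg$n_experiments), function(e) {
    set.seed(substream_seed(cfg$seed, 1000L + e))
    k <- 1L + rgeom(n, 1 / cfg$spectra_per_feature)
    ent <- rep.int(seq_len(n), k)
    n_spec <- length(ent)
    conf <- ifelse(rbinom(n_spec, 1L, 0.15) == 1L,
                   runif(n_spec, 1, 20), runif(n_spec, 21, 99.9))
    ef <- 10^abs(rnorm(n_spec, 0, 0.15))
    base <- tibble::tibble(
      experiment = paste0("exp", e),
      spectrum_id = sprintf("e%d_s%05d", e, seq_len(n_spec)),
      protein = proteins[ent],
      sequence = sequences[ent],
      modifications = modifications[ent],
      id_confidence = conf,
      error_factor = ef
    )
    dplyr::bind_rows(lapply(conditions, function(cond) {
      lr <- rnorm(n_spec, mean = tau[ent, cond],
                  sd = cfg$log2_null_sd * sqrt(k[ent]))
      dplyr::mutate(base, condition = cond, ratio = 2^lr)
    }))
  })
  spectra <- dplyr::bind_rows(spectra)

  structure(
    list(spectra = spectra,
         entities = tibble::tibble(protein = proteins, sequence = sequences,
                                   modifications = modifications),
         truth = truth, config = cfg),
    class = "phospho_study"
  )
}

#' @export
print.phospho_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic phosphopeptide study: %d entities, %d spectrum rows, %d experiments\n",
    nrow(x$entities), nrow(x$spectra), x$config$n_experiments))
  invisible(x)
}
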