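#' Configuration for the synthetic count-matrix generator
#'
#' The generator emulates the statistical structure the trendline screen
#' assumes in a healthy control group: most genes draw from a normal
#' "control envelope" around a gene-specific mean spanning several orders
#' of magnitude; a small coordinated module is elevated 5- to 50-fold in a
#' few affected individuals (an interferon-program analogue); a handful of
#' sex-linked genes are bimodal, high only in a fixed subgroup.
#'
#' @param n_samples Number of samples (default 35).
#' @param n_genes Number of genes (default 8746).
#' @param seed Integer seed; generation is bit-for-bit reproducible.
#' @param mean_log10_range Per-gene means are `10^U(a, b)` (default
#'   `c(0, 5)`).
#' @param baseline_cv Coefficient of variation of the baseline normal
#'   noise (default 0.2).
#' @param tailed_module List: `n_genes` (default 14), `affected_samples`
#'   (a count, drawn at random, or an explicit vector of sample ids;
#'   default 4), `fold_range` (log-uniform fold multipliers per
#'   gene/sample; default `c(5, 50)`).
#' @param bimodal_genes List: `count` (default 10), `high_group_size`
#'   (default 11; the high group is the *last* samples, mirroring a male
#'   subgroup), `low_fraction` (expression level of the low group relative
#'   to the gene mean; default 0.05).
#' @param zero_inflation Probability that a baseline cell is zeroed
#'   (default 0; the screen's input filter makes residual zeros rare).
#' @return Object of class `tlv_sim_config` (a validated list).
#' @export
synthetic_config <- function(n_samples = 35L, n_genes = 8746L, seed = 1L,
                             mean_log10_range = c(0, 5), baseline_cv = 0.2,
                             tailed_module = list(n_genes = 14L,
                                                  affected_samples = 4L,
                                                  fold_range = c(5, 50)),
                             bimodal_genes = list(count = 10L,
                                                  high_group_size = 11L,
                                                  low_fraction = 0.05),
                             zero_inflation = 0) {
  defaults_tail <- list(n_genes = 14L, affected_samples = 4L, fold_range = c(5, 50))
  defaults_bi <- list(count = 10L, high_group_size = 11L, low_fraction = 0.05)
  tailed_module <- utils::modifyList(defaults_tail, as.list(tailed_module))
  bimodal_genes <- utils::modifyList(defaults_bi, as.list(bimodal_genes))
  stopifnot(n_samples >= 2L, n_genes >= 1L,
            length(mean_log10_range) == 2L,
            mean_log10_range[2L] >= mean_log10_range[1L],
            baseline_cv >= 0, zero_inflation >= 0, zero_inflation < 1,
            tailed_module$n_genes >= 0L,
            all(tailed_module$fold_range > 1),
            bimodal_genes$count >= 0L,
            bimodal_genes$high_group_size >= 1L,
            bimodal_genes$high_group_size < n_samples,
            bimodal_genes$low_fraction > 0, bimodal_genes$low_fraction < 1)
  if (is.numeric(tailed_module$affected_samples) &&
      length(tailed_module$affected_samples) == 1L) {
    stopifnot(tailed_module$affected_samples >= 0L,
              tailed_module$affected_samples <= n_samples)
  }
  if (tailed_module$n_genes + bimodal_genes$count > n_genes) {
    stop("tailed plus bimodal genes exceed n_genes")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed),
                 mean_log10_range = as.numeric(mean_log10_range),
                 baseline_cv = baseline_cv,
                 tailed_module = tailed_module,
                 bimodal_genes = bimodal_genes,
                 zero_inflation = zero_inflation),
            class = "tlv_sim_config")
}

#' Generate a synthetic count matrix with ground truth
#'
#' Baseline gene `g` draws `Normal(mu_g, cv * mu_g)` truncated at 0, with
#' `mu_g` log-uniform over `mean_log10_range`. Tailed-module genes are
#' additionally multiplied, in the affected samples only, by per-
#' (gene, sample) folds drawn log-uniformly from `fold_range`. Bimodal
#' genes keep the baseline level in the high group (the last
#' `high_group_size` samples) and are scaled down to `low_fraction` of it
#' elsewhere. Generation is deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with `counts` (gene x sample matrix) and `truth` (list
#'   with `linear_gene_ids`, `tailed_gene_ids`, `bimodal_gene_ids`,
#'   `affected_sample_ids`).
#' @export
generate_counts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "tlv_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  genes <- sprintf("G%05d", seq_len(g))
  samples <- sprintf("S%02d", seq_len(n))

  mu <- 10^stats::runif(g, config$mean_log10_range[1L], config$mean_log10_range[2L])
  counts <- matrix(stats::rnorm(g * n, mean = mu, sd = config$baseline_cv * mu),
                   nrow = g, ncol = n, dimnames = list(genes, samples))
  counts[counts < 0] <- 0

  tailed <- character()
  affected <- character()
  tm <- config$tailed_module
  if (tm$n_genes > 0L) {
    tailed <- sort(sample(genes, tm$n_genes))
    aff <- tm$affected_samples
    if (is.character(aff)) {
      stopifnot(all(aff %in% samples))
      affected <- sort(aff)
    } else if (aff > 0L) {
      affected <- sort(sample(samples, aff))
    }
    if (length(affected)) {
      folds <- matrix(exp(stats::runif(length(tailed) * length(affected),
                                       log(tm$fold_range[1L]),
                                       log(tm$fold_range[2L]))),
                      nrow = length(tailed))
      counts[tailed, affected] <- counts[tailed, affected] * folds
    }
  }

  bimodal <- character()
  bm <- config$bimodal_genes
  if (bm$count > 0L) {
    bimodal <- sort(sample(setdiff(genes, tailed), bm$count))
    low_samples <- samples[seq_len(n - bm$high_group_size)]
    counts[bimodal, low_samples] <- counts[bimodal, low_samples] * bm$low_fraction
  }

  if (config$zero_inflation > 0) {
    drop <- stats::runif(g * n) < config$zero_inflation
    counts[drop] <- 0
  }

  truth <- list(linear_gene_ids = setdiff(genes, c(tailed, bimodal)),
                tailed_gene_ids = tailed,
                bimodal_gene_ids = bimodal,
                affected_sample_ids = affected)
  list(counts = counts, truth = truth)
}

#' Spike-in style control rows
#'
#' Constant-concentration external control rows with small multiplicative
#' technical noise, optionally with one aberrant sample in which every
#' control is elevated — emulating a spike-in addition problem confined to
#' a single library. Uses the current RNG stream (call `set.seed()`
#' beforehand for reproducibility).
#'
#' @param n_samples Number of samples (default 35).
#' @param n_controls Number of control rows (default 4).
#' @param concentrations Per-control nominal levels (default log-spaced
#'   over 10 to 10^4).
#' @param technical_cv Multiplicative noise CV (default 0.05); 0 yields
#'   constant rows, flagged in attribute `constant`.
#' @param aberrant_sample Optional sample index or id whose controls are
#'   multiplied by `aberrant_fold`.
#' @param aberrant_fold Elevation factor for the aberrant sample (default
#'   5).
#' @param sample_ids Sample identifiers (default `S01..`).
#' @return Control x sample matrix (rows `ERCC_01..`), attribute
#'   `constant` = `TRUE` when `technical_cv == 0`.
#' @export
spike_in_reference <- function(n_samples = 35L, n_controls = 4L,
                               concentrations = 10^seq(1, 4, length.out = n_controls),
                               technical_cv = 0.05,
                               aberrant_sample = NULL, aberrant_fold = 5,
                               sample_ids = sprintf("S%02d", seq_len(n_samples))) {
  stopifnot(length(concentrations) == n_controls, all(concentrations > 0),
            technical_cv >= 0, aberrant_fold > 1)
  m <- matrix(rep(concentrations, n_samples), nrow = n_controls,
              dimnames = list(sprintf("ERCC_%02d", seq_len(n_controls)), sample_ids))
  if (technical_cv > 0) {
    m <- m * matrix(exp(stats::rnorm(n_controls * n_samples, 0, technical_cv)),
                    nrow = n_controls)
  }
  if (!is.null(aberrant_sample)) {
    m[, aberrant_sample] <- m[, aberrant_sample] * aberrant_fold
  }
  attr(m, "constant") <- technical_cv == 0
  m
}

#' Gene sets matched to a synthetic ground truth
#'
#' Builds a small collection for testing the enrichment stage against
#' generated data: one set holding the coordinated tailed module (the
#' analogue of an interferon-response pathway) plus random sets drawn
#' from the gene space. Background is the full gene space. Uses the
#' current RNG stream.
#'
#' @param truth Ground-truth list from [generate_counts()].
#' @param gene_ids All gene identifiers of the matrix.
#' @param n_random_sets Number of random decoy sets (default 20).
#' @param set_size Size of each random set (default 50).
#' @return A `tlv_gene_sets` collection.
#' @export
synthetic_gene_sets <- function(truth, gene_ids, n_random_sets = 20L, set_size = 50L) {
  sets <- list(tailed_module = truth$tailed_gene_ids)
  for (i in seq_len(n_random_sets)) {
    sets[[sprintf("random_set_%02d", i)]] <- sample(gene_ids, set_size)
  }
  gene_set_collection(sets, background = gene_ids)
}

#' Write / read ground truth as JSON
#'
#' @param truth Ground-truth list from [generate_counts()].
#' @param path Output path.
#' @return `path` invisibly; [read_ground_truth()] returns the list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(out, as.character)
}
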