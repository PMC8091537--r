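#' Pipeline configuration
#'
#' Collects paths, thresholds and toggles for [run_pipeline()]. Values
#' can come from a YAML/JSON file (`pipeline_config_from_file()`), with
#' function arguments taking precedence over file values, which take
#' precedence over defaults.
#'
#' @param counts Path to the input count matrix, or an in-memory matrix.
#' @param out_dir Output directory (created if missing).
#' @param coding Optional path to a protein-coding gene list (or character
#'   vector).
#' @param aliases Optional path to a two-column alias map (or named
#'   vector).
#' @param gmt Optional path to a GMT file (or `tlv_gene_sets`); enables
#'   the enrichment stage.
#' @param floor,mean_min Low-count filter parameters (default 0.5 / 0.5).
#' @param top_n Top-list size (default 300).
#' @param min_genes Scoring-function minimum (default 1000).
#' @param fdr_flag Flagging benchmark (default 1e-15).
#' @param size_factors Apply median-of-ratios size factors before MVA
#'   (default `TRUE`; disable for already-normalized TPM input).
#' @param statistics Tailedness statistics used by the screen.
#' @param seed Optional integer seed recorded in the report (the pipeline
#'   itself is deterministic).
#' @return Object of class `tlv_pipeline_config`.
#' @export
pipeline_config <- function(counts, out_dir, coding = NULL, aliases = NULL,
                            gmt = NULL, floor = 0.5, mean_min = 0.5,
                            top_n = 300L, min_genes = 1000L, fdr_flag = 1e-15,
                            size_factors = TRUE,
                            statistics = c("range_over_median", "range_over_q3",
                                           "excess_kurtosis", "ratio_q4"),
                            seed = NULL) {
  stopifnot(floor >= 0, mean_min >= 0, top_n >= 1, min_genes >= 1, fdr_flag > 0)
  structure(list(counts = counts, out_dir = out_dir, coding = coding,
                 aliases = aliases, gmt = gmt, floor = floor,
                 mean_min = mean_min, top_n = as.integer(top_n),
                 min_genes = as.integer(min_genes), fdr_flag = fdr_flag,
                 size_factors = isTRUE(size_factors), statistics = statistics,
                 seed = seed),
            class = "tlv_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML or JSON file with keys matching the arguments above.
#' @param ... Overrides applied on top of the file values.
#' @export
pipeline_config_from_file <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full trendline-variability pipeline
#'
#' filter -> scale -> statistics -> top lists -> per-individual screen
#' (-> enrichment when gene sets are configured). All intermediate
#' artifacts are written under `out_dir` with stable names, and a
#' machine-readable JSON report records every effective threshold, the
#' per-statistic top lists and the flagged individuals. Given the same
#' configuration, the run is deterministic.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return The report, invisibly (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "tlv_pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  m <- .stage("read", {
    if (is.character(config$counts)) read_count_matrix(config$counts)
    else as_count_matrix(config$counts)
  })
  say(sprintf("input: %d genes x %d samples", nrow(m), ncol(m)))

  discarded <- NULL
  if (!is.null(config$coding)) {
    coding <- if (is.character(config$coding) && length(config$coding) == 1L &&
                  file.exists(config$coding)) read_gene_list(config$coding)
              else config$coding
    split <- .stage("protein_coding_filter", filter_protein_coding(m, coding))
    m <- split$kept
    discarded <- split$discarded
    write_count_matrix(discarded, out("discard.tsv"))
    say(sprintf("protein-coding filter: %d kept, %d discarded",
                nrow(m), nrow(discarded)))
  }
  if (!is.null(config$aliases)) {
    aliases <- if (is.character(config$aliases) && !is.null(names(config$aliases)))
      config$aliases else read_alias_map(config$aliases)
    m <- .stage("cnv_merge", merge_cnv(m, aliases))
  }
  m <- .stage("low_count_filter",
              filter_low_counts(m, floor = config$floor, mean_min = config$mean_min))
  removed <- attr(m, "removed_genes")
  say(sprintf("low-count filter (floor %g, mean >= %g): %d genes kept, %d removed",
              config$floor, config$mean_min, nrow(m), length(removed)))
  write_count_matrix(m, out("kept.tsv"))

  sf <- NULL
  if (config$size_factors) {
    sf <- .stage("size_factors", size_factors_median_of_ratios(m))
    utils::write.table(data.frame(sample = names(sf), size_factor = sf),
                       out("size_factors.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  mva <- .stage("mva", mva_scale(m, size_factors = sf))
  write_count_matrix(mva$values, out("mva.tsv"))
  utils::write.table(data.frame(gene = names(mva$divisors),
                                divisor = mva$divisors,
                                zero_containing = mva$flags),
                     out("divisors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  stats <- .stage("stats", stats_table(mva))
  utils::write.table(stats, out("stats_mva.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  stats_raw <- .stage("stats_raw", stats_table(m))
  utils::write.table(stats_raw, out("stats_raw.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gene_sets <- NULL
  if (!is.null(config$gmt)) {
    gene_sets <- .stage("gene_sets", {
      gsc <- if (inherits(config$gmt, "tlv_gene_sets")) config$gmt
             else read_gmt(config$gmt)
      # background: analyzed genes inside the collection's annotation space
      gene_set_collection(gsc$sets,
                          background = intersect(gsc$background, rownames(m)))
    })
  }

  screen <- .stage("screen",
                   screen_all_individuals(mva, stats = stats,
                                          gene_sets = gene_sets,
                                          statistics = config$statistics,
                                          min_genes = config$min_genes,
                                          top_n = config$top_n,
                                          fdr_flag = config$fdr_flag))
  dir.create(out("individuals"), showWarnings = FALSE)
  for (smp in names(screen$individuals)) {
    igl <- screen$individuals[[smp]]
    dir.create(out("individuals", smp), showWarnings = FALSE)
    for (statn in names(igl$filtered_genes)) {
      writeLines(igl$filtered_genes[[statn]],
                 out("individuals", smp, paste0(statn, ".txt")))
    }
  }
  for (statn in names(screen$top_lists)) {
    writeLines(screen$top_lists[[statn]]$gene_ids,
               out(paste0("top_", statn, ".txt")))
  }
  say(sprintf("screen: %d/%d individuals flagged (FDR <= %g)",
              length(screen$flagged), ncol(m), config$fdr_flag))

  report <- list(
    parameters = list(floor = config$floor, mean_min = config$mean_min,
                      top_n = config$top_n, min_genes = config$min_genes,
                      fdr_flag = config$fdr_flag,
                      size_factors = config$size_factors,
                      statistics = config$statistics,
                      seed = config$seed),
    input = list(genes = nrow(m), samples = ncol(m),
                 discarded_noncoding = if (is.null(discarded)) 0L else nrow(discarded),
                 removed_low_count = length(removed)),
    size_factors = as.list(sf),
    top_lists = lapply(screen$top_lists, function(tl) {
      list(statistic = tl$statistic, threshold = tl$threshold_value,
           genes = tl$gene_ids)
    }),
    flagged_individuals = screen$flagged,
    best_fdr = if (!is.null(gene_sets)) {
      lapply(screen$individuals, function(i) i$best_fdr)
    } else NULL
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(report)
}
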