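#' Read a gene x sample count matrix from TSV/CSV
#'
#' The expected layout is genes as rows: first column gene identifiers,
#' header row sample identifiers. Files with samples as rows can be read
#' with `transpose = TRUE`.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator. Default `NULL` picks `","` for `.csv` files
#'   and tab otherwise.
#' @param transpose If `TRUE` the file is samples x genes and is transposed
#'   after reading.
#' @return Numeric matrix with gene row names and sample column names.
#'   Non-numeric cells, negative values and duplicated sample identifiers
#'   are errors; duplicated gene identifiers produce a warning (they are
#'   legitimate before multi-location merging, see [merge_cnv()]).
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) {
    stop("count matrix file not found: ", path)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  # data-frame column subsetting silently uniquifies duplicated names, so
  # duplicate sample ids must be caught on the raw header line
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  if (!transpose && anyDuplicated(header[-1L])) {
    stop("duplicated sample identifiers in header: ",
         paste(unique(header[-1L][duplicated(header[-1L])]), collapse = ", "))
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) {
    stop("count matrix must have an identifier column plus at least one data column: ", path)
  }
  ids <- as.character(df[[1L]])
  values <- df[, -1L, drop = FALSE]
  for (j in seq_along(values)) {
    col <- values[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & trimws(col) != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     col[bad[1L]], ids[bad[1L]], colnames(values)[j]))
      }
      values[[j]] <- num
    }
  }
  m <- as.matrix(values)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  validate_count_matrix(m)
  m
}

#' Write a count matrix to TSV/CSV
#'
#' @param m Gene x sample numeric matrix.
#' @param path Output path; `.csv` selects comma separation.
#' @param id_column Header for the gene identifier column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, id_column = "gene") {
  m <- as_count_matrix(m)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(m) {
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value %g at gene '%s', sample '%s'",
                 m[idx[1L], idx[2L]], rownames(m)[idx[1L]], colnames(m)[idx[2L]]))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyDuplicated(rownames(m))) {
    warning("duplicated gene identifiers present (merge with merge_cnv()): ",
            paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  invisible(m)
}

#' Coerce to a gene x sample numeric matrix
#'
#' Accepts a numeric matrix, a data frame (first character column taken as
#' gene identifiers), or an MVA-scaled object (see [mva_scale()]), whose
#' scaled values are used.
#'
#' @param x Object to coerce.
#' @return Numeric matrix with dimnames.
#' @export
as_count_matrix <- function(x) {
  if (inherits(x, "tlv_mva")) return(x$values)
  if (is.data.frame(x)) {
    if (!is.numeric(x[[1L]])) {
      ids <- as.character(x[[1L]])
      x <- as.matrix(x[, -1L, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("cannot interpret input as a gene x sample numeric matrix")
  }
  if (is.null(rownames(x))) rownames(x) <- sprintf("gene_%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("sample_%d", seq_len(ncol(x)))
  x
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of unique symbols, input order preserved.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  unique(lines[nzchar(lines)])
}

#' Read a two-column alias map (location-suffixed symbol, canonical symbol)
#'
#' Used to merge genes reported at multiple genomic locations (copy-number
#' variants) under one canonical symbol.
#'
#' @param path Path to a headerless two-column TSV.
#' @return Named character vector: `names` are location symbols, values the
#'   canonical symbols.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) stop("alias map file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("alias map must have two tab-separated columns: ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Split a count matrix into protein-coding and discarded genes
#'
#' Non-coding transcripts dilute downstream pathway enrichment, so the
#' screen restricts the matrix to a user-supplied protein-coding list and
#' keeps the remainder in a separate "discard" matrix for inspection.
#'
#' @param m Gene x sample matrix.
#' @param protein_coding Character vector of protein-coding symbols.
#' @return List with elements `kept` and `discarded`, both matrices.
#' @export
filter_protein_coding <- function(m, protein_coding) {
  m <- as_count_matrix(m)
  if (length(protein_coding) == 0L) {
    stop("protein-coding gene list is empty")
  }
  keep <- rownames(m) %in% protein_coding
  if (!any(keep)) {
    warning("no genes in the matrix are on the protein-coding list")
  }
  list(kept = m[keep, , drop = FALSE], discarded = m[!keep, , drop = FALSE])
}

#' Merge multi-location gene rows under canonical symbols
#'
#' Rows whose identifier maps to the same canonical symbol via `aliases`
#' (and literal duplicate rows) are summed element-wise into one row, so
#' total counts are conserved. An alias target that collides with an
#' unrelated gene already present in the matrix is an error.
#'
#' @param m Gene x sample matrix.
#' @param aliases Named character vector (see [read_alias_map()]); may be
#'   empty, in which case only literal duplicates are collapsed.
#' @return Matrix with unique gene identifiers, original order of first
#'   appearance preserved.
#' @export
merge_cnv <- function(m, aliases = character()) {
  m <- as_count_matrix(m)
  ids <- rownames(m)
  canonical <- ids
  hit <- ids %in% names(aliases)
  canonical[hit] <- unname(aliases[ids[hit]])
  # an alias target must not capture an unrelated pre-existing row
  targets <- unique(unname(aliases[names(aliases) %in% ids]))
  clash <- targets[targets %in% ids & !(targets %in% names(aliases))]
  # a row literally named like the target participates in the merge only if
  # the user aliased it too; treat silent capture as an error
  if (length(clash)) {
    stop("alias target collides with an existing gene: ",
         paste(clash, collapse = ", "))
  }
  if (!anyDuplicated(canonical) && identical(canonical, ids)) return(m)
  merged <- rowsum(m, group = canonical, reorder = FALSE)
  merged[unique(canonical), , drop = FALSE]
}

#' Floor small counts and drop low-mean genes
#'
#' Values below `floor` are replaced by 0 first; genes whose
#' post-replacement mean falls below `mean_min` are then removed. The order
#' matters and is fixed: flooring happens before the mean test.
#'
#' @param m Gene x sample matrix.
#' @param floor Values strictly below this are set to 0 (default 0.5).
#' @param mean_min Genes with post-replacement mean strictly below this are
#'   removed (default 0.5).
#' @return Filtered matrix with attribute `removed_genes` (character vector
#'   of dropped identifiers).
#' @export
filter_low_counts <- function(m, floor = 0.5, mean_min = 0.5) {
  m <- as_count_matrix(m)
  stopifnot(floor >= 0, mean_min >= 0)
  m[m < floor] <- 0
  keep <- rowMeans(m) >= mean_min
  removed <- rownames(m)[!keep]
  out <- m[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("all genes removed by the low-count filter")
  attr(out, "removed_genes") <- removed
  out
}
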