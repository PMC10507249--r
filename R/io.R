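#' Construct a count matrix
#'
#' The pipeline's entry container: a non-negative integer feature-by-cell
#' matrix whose features are partitioned into genes and spike-ins by an
#' id-prefix rule (ERCC naming by default). The partition is fixed at
#' construction.
#'
#' @param counts numeric matrix, features in rows, cells in columns, with
#'   unique row and column names; entries must be non-negative integers.
#' @param spike_prefix feature-id prefix identifying spike-ins.
#' @return list of class `"count_matrix"` with elements `counts`
#'   (integer matrix) and `is_spike` (named logical).
#' @export
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(c("a", "b", "ERCC-1"), c("c1", "c2")))
#' cm <- count_matrix(m)
#' sum(cm$is_spike)
count_matrix <- function(counts, spike_prefix = "ERCC-") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs feature and cell names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         is_spike = stats::setNames(startsWith(rownames(counts), spike_prefix),
                                    rownames(counts)),
         spike_prefix = spike_prefix),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "features (",
      sum(x$is_spike), "spike-ins ) x", ncol(x$counts), "cells\n")
  invisible(x)
}

#' Gene / spike-in submatrices
#' @param x a `count_matrix`.
#' @return integer matrix restricted to gene or spike-in features.
#' @export
gene_counts <- function(x) x$counts[!x$is_spike, , drop = FALSE]

#' @rdname gene_counts
#' @export
spike_counts <- function(x) x$counts[x$is_spike, , drop = FALSE]

#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported: a TSV with a header row of cell ids
#' and feature ids in the first column, or a MatrixMarket triplet file
#' with sidecar feature/cell id lists (one id per line, files
#' `<stem>_features.tsv` and `<stem>_cells.tsv` next to the `.mtx`).
#'
#' @param path file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param spike_prefix forwarded to [count_matrix()].
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              spike_prefix = "ERCC-") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[-1])
    if (!is.numeric(m)) stop("non-numeric entries in count TSV")
    rownames(m) <- ids
  } else {
    stem <- sub("\\.mtx$", "", path)
    ffeat <- paste0(stem, "_features.tsv")
    fcell <- paste0(stem, "_cells.tsv")
    if (!file.exists(ffeat) || !file.exists(fcell))
      stop("missing sidecar id files for ", path)
    m <- as.matrix(Matrix::readMM(path))
    feats <- readLines(ffeat)
    cells <- readLines(fcell)
    if (nrow(m) != length(feats) || ncol(m) != length(cells))
      stop("dimension mismatch between triplet and sidecar id files")
    dimnames(m) <- list(feats, cells)
  }
  count_matrix(m, spike_prefix = spike_prefix)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_count_matrix()]; the TSV layout is features x cells
#' with a leading `feature_id` column.
#'
#' @param x a `count_matrix`.
#' @param path output path (for `"mtx"`, sidecar id files are written
#'   next to it).
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(feature_id = rownames(x$counts), x$counts,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(rownames(x$counts), paste0(stem, "_features.tsv"))
    writeLines(colnames(x$counts), paste0(stem, "_cells.tsv"))
  }
  invisible(path)
}

.cell_types <- c("oocyte", "granulosa")
.cohorts <- c("fresh", "section_alcohol", "section_formalin")
.positions <- c("neighboring", "non_neighboring")

#' Read / write a cell metadata table
#'
#' Tab-separated, one row per cell; columns `id`, `cell_type`, `cohort`,
#' `diameter_um`, `follicle_diameter_um`, `position`, `ct`,
#' `mapping_rate`. Missing values are encoded as `"."`. Vocabulary is
#' checked: cell types `oocyte`/`granulosa`, cohorts `fresh`/
#' `section_alcohol`/`section_formalin`, positions `neighboring`/
#' `non_neighboring`.
#'
#' @param path file path.
#' @return a data.frame with parsed numeric columns (diameters in um).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = ".")
  need <- c("id", "cell_type", "cohort", "diameter_um",
            "follicle_diameter_um", "position", "ct", "mapping_rate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate cell ids in metadata")
  bad <- setdiff(stats::na.omit(unique(df$cell_type)), .cell_types)
  if (length(bad)) stop("unknown cell_type token: ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$cohort)), .cohorts)
  if (length(bad)) stop("unknown cohort token: ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(df$position)), .positions)
  if (length(bad)) stop("unknown position token: ", paste(bad, collapse = ", "))
  for (col in c("diameter_um", "follicle_diameter_um", "ct", "mapping_rate"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname read_metadata
#' @param records metadata data.frame.
#' @export
write_metadata <- function(records, path) {
  out <- records
  for (col in names(out)) {
    v <- out[[col]]
    v <- ifelse(is.na(v), ".",
                if (is.numeric(v)) format(v, digits = 17, trim = TRUE) else as.character(v))
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# numeric TSV writer used by pipeline stages: fixed full precision so that
# identical inputs give byte-identical files
write_tsv_stable <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- format(out[[col]], digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
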