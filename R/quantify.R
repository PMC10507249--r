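#' Depth-normalize counts to RPM and log2(RPM+1)
#'
#' `RPM = count / denominator * 1e6` per cell. By default the
#' denominator is every mapped feature (genes plus spike-ins, "per
#' million mapped reads"); a genes-only denominator is available since
#' either convention appears in practice. Only gene features are
#' reported; spike reads affect the denominator only.
#'
#' @param x a [count_matrix()].
#' @param denominator_mode `"all_mapped"` or `"genes_only"`.
#' @return list of class `"expression_matrix"`: `rpm` and `log2`
#'   (genes x cells), `denominator_mode`.
#' @export
#' @examples
#' m <- matrix(c(2L, 8L), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
#' to_rpm(count_matrix(m))$rpm
to_rpm <- function(x, denominator_mode = c("all_mapped", "genes_only")) {
  denominator_mode <- match.arg(denominator_mode)
  g <- gene_counts(x)
  denom <- if (denominator_mode == "all_mapped") colSums(x$counts) else colSums(g)
  zero <- denom == 0
  if (any(zero))
    stop("zero-total cell(s): ", paste(colnames(g)[zero], collapse = ", "))
  rpm <- sweep(g, 2, denom, "/") * 1e6
  structure(list(rpm = rpm, log2 = log2(rpm + 1),
                 denominator_mode = denominator_mode),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$rpm), "genes x", ncol(x$rpm),
      "cells, denominator:", x$denominator_mode, "\n")
  invisible(x)
}

#' Calibrate absolute copy numbers against ERCC spike-ins
#'
#' Ordinary least squares of log2(reads) on log2(known copies) over
#' spikes with more than zero reads (at least 3 required). The model
#' exposes the inverse map from reads to estimated copies and the read
#' level corresponding to one copy.
#'
#' @param spike_counts named numeric vector of spike reads (names =
#'   spike ids).
#' @param reference data.frame with `spike_id` and `copies` (> 0).
#' @return list of class `"copy_number_model"`: `slope`, `intercept`
#'   (log2 scale), `n_used`, `residual_sd`, `one_copy_reads`.
#' @export
fit_copy_model <- function(spike_counts, reference) {
  if (any(reference$copies <= 0)) stop("reference copies must be > 0")
  if (anyDuplicated(reference$spike_id)) stop("duplicate spike ids")
  common <- intersect(names(spike_counts), reference$spike_id)
  reads <- spike_counts[common]
  copies <- reference$copies[match(common, reference$spike_id)]
  use <- reads > 0
  if (sum(use) < 3) stop("need >= 3 spikes with positive reads")
  if (stats::var(log2(copies[use])) == 0) stop("zero variance in copies")
  fit <- stats::lm(log2(reads[use]) ~ log2(copies[use]))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  structure(list(slope = b, intercept = a, n_used = sum(use),
                 residual_sd = stats::sd(stats::residuals(fit)),
                 one_copy_reads = 2^a),
            class = "copy_number_model")
}

#' @export
print.copy_number_model <- function(x, ...) {
  cat(sprintf("<copy_number_model> log2(reads) = %.3f + %.3f log2(copies), n = %d\n",
              x$intercept, x$slope, x$n_used))
  invisible(x)
}

#' Predict copies from read counts
#'
#' Inverts the spike-in regression: `copies = 2^((log2(reads) -
#' intercept)/slope)`; zero reads map to zero copies.
#'
#' @param model a [fit_copy_model()] result.
#' @param reads numeric vector of read counts.
#' @return estimated copies.
#' @export
predict_copies <- function(model, reads) {
  out <- numeric(length(reads))
  pos <- reads > 0
  out[pos] <- 2^((log2(reads[pos]) - model$intercept) / model$slope)
  out
}

#' Count detectable genes per cell
#'
#' `raw_positive`: genes with at least one mapped read. `copy_ge_1`:
#' genes whose spike-calibrated copy estimate is >= 1 (requires a
#' [fit_copy_model()] model per cell or one shared model).
#'
#' @param x a [count_matrix()] or a gene count matrix.
#' @param mode `"raw_positive"` or `"copy_ge_1"`.
#' @param model a `copy_number_model`, or a list of one per cell.
#' @return named integer vector, one entry per cell.
#' @export
count_detectable_genes <- function(x, mode = c("raw_positive", "copy_ge_1"),
                                   model = NULL) {
  mode <- match.arg(mode)
  g <- if (inherits(x, "count_matrix")) gene_counts(x) else as.matrix(x)
  if (mode == "raw_positive") return(colSums(g > 0))
  if (is.null(model)) stop("copy mode requires a copy-number model")
  models <- if (inherits(model, "copy_number_model"))
    rep(list(model), ncol(g)) else model
  if (length(models) != ncol(g)) stop("one model per cell required")
  out <- vapply(seq_len(ncol(g)), function(j)
    sum(predict_copies(models[[j]], g[, j]) >= 1), integer(1))
  stats::setNames(out, colnames(g))
}
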