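#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample normalization for exon/junction count matrices. The
#' reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean of that statistic. For every sample, gene-wise
#' log2 count-fraction ratios to the reference (M) and mean log2
#' abundances (A) are computed over features positive in both; the M
#' values are doubly trimmed (by M and by A quantile ranks) and averaged
#' with precision weights from the binomial delta method; the factor is
#' 2 to that mean. Factors are rescaled to geometric mean 1.
#'
#' @param counts features x samples matrix (>= 2 samples, positive
#'   library sizes).
#' @param logratio_trim two-sided M trim fraction (default 0.30).
#' @param abs_trim two-sided A trim fraction (default 0.05).
#' @return list of class `"tmm_result"`: `factors` (named), `lib_size`,
#'   `ref_sample`, `trim` parameters.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop(">= 2 samples required")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("library total must be > 0")
  f75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abs_trim), numeric(1))
  factors <- factors / exp(mean(log(factors)))
  structure(list(factors = stats::setNames(factors, colnames(counts)),
                 lib_size = stats::setNames(lib, colnames(counts)),
                 ref_sample = colnames(counts)[ref],
                 trim = list(logratio = logratio_trim, abs = abs_trim)),
            class = "tmm_result")
}

# single-sample trimmed, precision-weighted mean of M values vs reference
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("sample shares no positive features with the reference")
  po <- obs[pos] / n_obs
  pr <- ref[pos] / n_ref
  M <- log2(po / pr)
  A <- (log2(po) + log2(pr)) / 2
  v <- (n_obs - obs[pos]) / (n_obs * obs[pos]) +
    (n_ref - ref[pos]) / (n_ref * ref[pos])
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f <- 2^(sum(M[keep] / v[keep], na.rm = TRUE) /
            sum(1 / v[keep], na.rm = TRUE))
  if (!is.finite(f)) f <- 1
  f
}

#' @export
print.tmm_result <- function(x, ...) {
  cat("<tmm_result> ref =", x$ref_sample, "; factors:",
      paste(sprintf("%.3f", x$factors), collapse = " "), "\n")
  invisible(x)
}

#' TMM-normalized expression values
#'
#' `value = count / (library size x factor) x 1e6`. Features with a
#' value strictly greater than the detectability cut (published default
#' 2) are considered detectable; `log2(value + 1)` is returned alongside
#' for expression-level analyses.
#'
#' @param counts features x samples matrix.
#' @param tmm a [tmm_factors()] result covering all samples.
#' @return list: `values`, `log2` (matrices), `factors`.
#' @export
tmm_values <- function(counts, tmm) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% names(tmm$factors)))
    stop("missing factor for some sample")
  f <- tmm$factors[colnames(counts)]
  eff <- tmm$lib_size[colnames(counts)] * f
  val <- sweep(counts, 2, eff, "/") * 1e6
  list(values = val, log2 = log2(val + 1), factors = f)
}

#' Detectability mask at a TMM cut
#'
#' @param values TMM value matrix.
#' @param cut detectability threshold; strict inequality (a value equal
#'   to the cut is NOT detectable).
#' @return logical matrix.
#' @export
tmm_detectable <- function(values, cut = 2) values > cut

#' Per-gene exon detection rates with transcript selection
#'
#' For every transcript the detection rate is the fraction of its exons
#' detected, computed per sample and averaged over samples; each gene
#' reports the transcript maximizing that rate (ties broken toward
#' fewer exons, then lexicographic transcript id).
#'
#' @param detected_mask exons x samples logical matrix covering every
#'   exon in the model.
#' @param model exon model data.frame (`gene`, `transcript`,
#'   `exon_index`, `exon_id`).
#' @return data.frame per gene: `gene`, `transcript` (chosen),
#'   `n_exons`, `rate`.
#' @export
exon_detection_rates <- function(detected_mask, model) {
  miss <- setdiff(model$exon_id, rownames(detected_mask))
  if (length(miss)) stop("mask missing exons: ", paste(utils::head(miss), collapse = ", "))
  per_tx <- lapply(split(model, model$transcript), function(tx) {
    m <- detected_mask[tx$exon_id, , drop = FALSE]
    data.frame(gene = tx$gene[1], transcript = tx$transcript[1],
               n_exons = nrow(tx), rate = mean(colMeans(m)))
  })
  tx <- do.call(rbind, per_tx)
  picked <- lapply(split(tx, tx$gene), function(g) {
    g <- g[order(-g$rate, g$n_exons, g$transcript), ]
    g[1, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Detection-rate summaries stratified by exon count
#'
#' For each threshold `t`, the mean detection rate over genes whose
#' chosen transcript has at most `t` exons, together with the fraction
#' of genes at or below `t` exons (a non-decreasing curve).
#'
#' @param rates a [exon_detection_rates()] result.
#' @param max_exons_list positive integer thresholds.
#' @return data.frame: `max_exons`, `mean_rate`, `gene_fraction`,
#'   `n_genes`.
#' @export
rate_by_exon_count <- function(rates, max_exons_list = c(5, 10, 20, 40)) {
  if (any(max_exons_list <= 0)) stop("thresholds must be positive")
  out <- lapply(sort(max_exons_list), function(t) {
    sel <- rates$n_exons <= t
    data.frame(max_exons = t,
               mean_rate = if (any(sel)) mean(rates$rate[sel]) else NA_real_,
               gene_fraction = mean(sel),
               n_genes = sum(sel))
  })
  do.call(rbind, out)
}
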