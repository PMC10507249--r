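#' Two-proportion z-test for detection rates
#'
#' Pooled-proportion two-sided z-test of `k1/n1` vs `k2/n2`. If the
#' pooled proportion is 0 or 1 the test is degenerate and `z = 0,
#' p = 1` is returned. Vectorized over genes.
#'
#' @param k1,k2 detection counts (0 <= k <= n).
#' @param n1,n2 cohort sizes (>= 1).
#' @return data.frame with `z` and `p`.
#' @export
#' @examples
#' detection_rate_test(30, 48, 15, 48)
detection_rate_test <- function(k1, n1, k2, n2) {
  if (any(k1 > n1) || any(k2 > n2) || any(k1 < 0) || any(k2 < 0))
    stop("k must lie in [0, n]")
  if (any(n1 < 1) || any(n2 < 1)) stop("n >= 1 required")
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(pp == 0 | pp == 1, 0, (k1 / n1 - k2 / n2) / se)
  p <- ifelse(pp == 0 | pp == 1, 1, 2 * stats::pnorm(-abs(z)))
  data.frame(z = z, p = p)
}

#' Per-gene expression-bias test between cohorts
#'
#' Two-sided t-test per gene on log2(RPM+1) (Welch by default), flagging
#' a gene as biased iff the absolute mean difference exceeds
#' `min_log2_diff` and p < `alpha`. Genes with zero variance in both
#' cohorts at the same value get `p = 1` and are never flagged.
#'
#' @param expr_a,expr_b genes x cells log2 matrices (same genes, >= 2
#'   cells each).
#' @param min_log2_diff effect-size condition (published default 1).
#' @param alpha p-value condition (published default 0.01).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame per gene: `mean_a`, `mean_b`, `diff` (a - b),
#'   `t`, `p`, `flag` (`"up"`, `"down"` or `""`).
#' @export
expression_bias_test <- function(expr_a, expr_b, min_log2_diff = 1,
                                 alpha = 0.01, var_equal = FALSE) {
  if (ncol(expr_a) < 2 || ncol(expr_b) < 2) stop("cohort with < 2 cells")
  if (!identical(rownames(expr_a), rownames(expr_b)))
    stop("gene panels differ")
  tt <- row_t_test(expr_a, expr_b, var_equal = var_equal)
  flag <- ifelse(abs(tt$diff) > min_log2_diff & tt$p < alpha,
                 ifelse(tt$diff > 0, "up", "down"), "")
  data.frame(gene_id = rownames(expr_a), mean_a = tt$m1, mean_b = tt$m2,
             diff = tt$diff, t = tt$t, p = tt$p, flag = flag,
             row.names = NULL)
}

# vectorized per-row two-sample t test; zero-variance-both rows get
# p = 1 when the means agree, p = 0 otherwise
row_t_test <- function(a, b, var_equal = FALSE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  d <- m1 - m2
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  t[degen] <- 0
  p[degen] <- ifelse(d[degen] == 0, 1, 0)
  list(m1 = m1, m2 = m2, diff = d, t = t, p = p)
}

#' Gene-by-gene fresh-vs-section artifact report
#'
#' Combines the detection-rate z-test (on raw positive counts) and the
#' expression-bias t-test (on log2 RPM+1) for a paired cohort design.
#' Flags require both the effect-size and p-value conditions.
#'
#' @param fresh,section [count_matrix()] objects sharing the gene panel.
#' @param detect_alpha z-test level (published default 0.01).
#' @param bias_min_diff,bias_alpha bias-test conditions.
#' @return data.frame of class `"bias_report"`, one row per gene:
#'   detection counts/rates per cohort, `rate_gap` (fresh - section),
#'   `z`, `z_p`, `detect_error` flag; cohort mean log2 levels, `diff`,
#'   `t`, `t_p`, `bias` direction flag; `fresh_mean_rank`.
#' @export
section_bias_report <- function(fresh, section, detect_alpha = 0.01,
                                bias_min_diff = 1, bias_alpha = 0.01) {
  gf <- gene_counts(fresh); gs <- gene_counts(section)
  if (!identical(rownames(gf), rownames(gs))) stop("gene panels differ")
  n1 <- ncol(gf); n2 <- ncol(gs)
  k1 <- rowSums(gf > 0); k2 <- rowSums(gs > 0)
  zt <- detection_rate_test(k1, n1, k2, n2)
  ef <- to_rpm(fresh)$log2; es <- to_rpm(section)$log2
  # section relative to fresh: negative diff = depressed in sections
  bt <- expression_bias_test(es, ef, min_log2_diff = bias_min_diff,
                             alpha = bias_alpha)
  out <- data.frame(
    gene_id = rownames(gf),
    k_fresh = k1, k_section = k2,
    rate_fresh = k1 / n1, rate_section = k2 / n2,
    rate_gap = k1 / n1 - k2 / n2,
    z = zt$z, z_p = zt$p,
    detect_error = zt$p < detect_alpha,
    mean_fresh = bt$mean_b, mean_section = bt$mean_a,
    diff = bt$diff, t = bt$t, t_p = bt$p, bias = bt$flag,
    row.names = NULL)
  out$fresh_mean_rank <- rank(out$mean_fresh, ties.method = "average")
  class(out) <- c("bias_report", "data.frame")
  out
}

#' Stratify artifact flags by expression rank
#'
#' Genes are binned by the rank of their fresh-cohort mean log2 level
#' (ascending: bin 1 = lowest-expressed) and flag counts plus
#' effect-size summaries are reported per bin. Artifacts of sectioning
#' concentrate in the low-expression bins.
#'
#' @param report a [section_bias_report()] result.
#' @param n_bins number of rank bins (>= 1, <= gene count).
#' @return data.frame per bin: gene count, detection-error and bias flag
#'   counts, mean rate gap, mean log2 difference, mean fresh level.
#' @export
stratify_by_rank <- function(report, n_bins = 10L) {
  ng <- nrow(report)
  if (n_bins < 1 || n_bins > ng) stop("n_bins must lie in [1, gene count]")
  bin <- ceiling(report$fresh_mean_rank / ng * n_bins)
  bin <- pmin(pmax(bin, 1L), n_bins)
  agg <- lapply(split(seq_len(ng), bin), function(i) data.frame(
    n_genes = length(i),
    n_detect_error = sum(report$detect_error[i]),
    n_bias = sum(report$bias[i] != ""),
    mean_rate_gap = mean(report$rate_gap[i]),
    mean_diff = mean(report$diff[i]),
    mean_fresh_level = mean(report$mean_fresh[i])))
  out <- cbind(bin = as.integer(names(agg)), do.call(rbind, agg))
  rownames(out) <- NULL
  out
}
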