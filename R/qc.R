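#' Smirnov-Grubbs outlier test
#'
#' Tests the most extreme observation of a sample against a Gaussian
#' null. `G` is the maximum deviation from the mean on the chosen side
#' divided by the sample standard deviation; the p-value comes from the
#' t-distribution inversion of the Grubbs critical-value identity
#' (`p = n * P(T_{n-2} > t)` one-sided, doubled for two-sided, clamped
#' to \[0, 1\]).
#'
#' @param x numeric vector, length >= 3, finite.
#' @param side `"high"`, `"low"` or `"two-sided"`.
#' @return list of class `"grubbs_result"`: `statistic` (G), `p_value`,
#'   `index` (candidate outlier, `NA` if none), `side`, `n`.
#' @export
#' @examples
#' grubbs_test(c(10, 10, 10, 10, 20), side = "high")
grubbs_test <- function(x, side = c("high", "low", "two-sided")) {
  side <- match.arg(side)
  if (length(x) < 3) stop("n >= 3 required")
  if (any(!is.finite(x))) stop("non-finite input")
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0)
    return(structure(list(statistic = 0, p_value = 1, index = NA_integer_,
                          side = side, n = n), class = "grubbs_result"))
  dev <- switch(side,
                high = x - m,
                low = m - x,
                `two-sided` = abs(x - m))
  idx <- which.max(dev)
  G <- dev[idx] / s
  p <- grubbs_p(G, n, two_sided = side == "two-sided")
  structure(list(statistic = G, p_value = p, index = idx, side = side, n = n),
            class = "grubbs_result")
}

# p-value for the Grubbs statistic via the t identity
grubbs_p <- function(G, n, two_sided = FALSE) {
  if (G <= 0) return(1)
  denom <- (n - 1)^2 - n * G^2
  if (denom <= 0) return(0)
  t <- sqrt(n * (n - 2) * G^2 / denom)
  p <- n * stats::pt(t, df = n - 2, lower.tail = FALSE)
  if (two_sided) p <- 2 * p
  min(1, max(0, p))
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("<grubbs_result> G = %.3f, p = %.4g, side = %s, n = %d\n",
              x$statistic, x$p_value, x$side, x$n))
  invisible(x)
}

#' Gate amplification success by iterative high-Ct outlier exclusion
#'
#' Amplification failures appear as high-Ct outliers. Wells are removed
#' one extreme at a time in the generalized extreme-studentized-deviate
#' manner: at each step the Grubbs statistic and p-value of the current
#' maximum are recorded and the maximum is removed; after `max_iter`
#' steps, every well up to the LAST step whose p-value fell below
#' `alpha` is declared failed. Testing each step before deciding resists
#' masking, which a remove-only-on-rejection loop does not (several
#' simultaneous failures inflate the sd enough to hide each other).
#'
#' @param ct numeric Ct vector (finite).
#' @param alpha gate level (published default 0.01).
#' @param max_iter maximum exclusions; default `floor(n/4)`.
#' @param side side passed to [grubbs_test()] (default `"high"`).
#' @return list: `pass` (logical mask), `trace` (data.frame: iteration,
#'   well, G, p), `alpha`.
#' @export
gate_amplification <- function(ct, alpha = 0.01, max_iter = NULL,
                               side = "high") {
  if (any(!is.finite(ct))) stop("non-finite Ct")
  if (alpha <= 0 || alpha >= 1) stop("alpha in (0, 1)")
  n <- length(ct)
  if (is.null(max_iter)) max_iter <- max(1L, floor(n / 4))
  remaining <- seq_len(n)
  trace <- data.frame(iteration = integer(), well = integer(),
                      G = numeric(), p = numeric())
  removed <- integer()
  for (i in seq_len(max_iter)) {
    if (length(remaining) < 3) {
      warning("fewer than 3 wells remaining; stopping")
      break
    }
    g <- grubbs_test(ct[remaining], side = side)
    if (is.na(g$index)) break  # zero variance: nothing to exclude
    well <- remaining[g$index]
    trace <- rbind(trace, data.frame(iteration = i, well = well,
                                     G = g$statistic, p = g$p_value))
    removed <- c(removed, well)
    remaining <- setdiff(remaining, well)
  }
  n_fail <- if (nrow(trace) && any(trace$p < alpha))
    max(which(trace$p < alpha)) else 0L
  pass <- rep(TRUE, n)
  if (n_fail > 0) pass[trace$well[seq_len(n_fail)]] <- FALSE
  list(pass = pass, trace = trace, alpha = alpha)
}

#' Cell-level quality filters
#'
#' Fails cells below a per-cell-type mapping-rate floor or
#' detectable-gene floor, and cells whose maximum Pearson correlation of
#' log2 expression with any other cell falls below `min_correlation`.
#' Every failed cell carries at least one reason code
#' (`low_mapping_rate`, `low_gene_count`, `low_correlation`).
#'
#' @param records metadata data.frame (see [read_metadata()]).
#' @param x a [count_matrix()] whose cells match `records$id`.
#' @param thresholds named list; per-cell-type floors
#'   `mapping_rate_floor_<type>`, shared `gene_count_floor` and
#'   `min_correlation`. Defaults from [pipeline_config()].
#' @return list of class `"qc_report"`: `cells` (data.frame id, pass,
#'   reasons), `thresholds`.
#' @export
filter_cells <- function(records, x, thresholds = pipeline_config()$thresholds) {
  g <- gene_counts(x)
  if (!all(records$id %in% colnames(g))) stop("metadata/count cell mismatch")
  g <- g[, records$id, drop = FALSE]
  for (ty in unique(records$cell_type)) {
    key <- paste0("mapping_rate_floor_", ty)
    if (is.null(thresholds[[key]]))
      stop("missing mapping-rate threshold for cell type ", ty)
  }
  lg <- log2(sweep(g, 2, pmax(colSums(g), 1), "/") * 1e6 + 1)
  n <- nrow(records)
  maxcor <- rep(NA_real_, n)
  if (n >= 2) {
    cc <- suppressWarnings(stats::cor(lg))
    diag(cc) <- NA
    maxcor <- apply(cc, 2, max, na.rm = TRUE)
  }
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    floor_mr <- thresholds[[paste0("mapping_rate_floor_", records$cell_type[i])]]
    if (!is.na(records$mapping_rate[i]) && records$mapping_rate[i] < floor_mr)
      r <- c(r, "low_mapping_rate")
    if (sum(g[, i] > 0) < thresholds$gene_count_floor)
      r <- c(r, "low_gene_count")
    if (!is.na(maxcor[i]) && maxcor[i] < thresholds$min_correlation)
      r <- c(r, "low_correlation")
    reasons[[i]] <- r
  }
  cells <- data.frame(
    id = records$id,
    pass = lengths(reasons) == 0,
    reasons = vapply(reasons, function(r)
      if (length(r)) paste(r, collapse = ",") else "", character(1)),
    max_correlation = maxcor,
    n_detected = colSums(g > 0))
  structure(list(cells = cells, thresholds = thresholds), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", sum(x$cells$pass), "/", nrow(x$cells), "cells pass\n")
  invisible(x)
}

#' Detect mixed oocyte/granulosa expression profiles
#'
#' Operationalizes visual bimodality screening of cell-vs-oocyte-mean
#' contour plots. Restricted to oocyte-signature genes (oocyte mean
#' log2 >= `sig_high`, granulosa cohort mean log2 <= `sig_low`), each
#' cell's log2 values are fit with 1- and 2-component Gaussian mixtures;
#' a cell is flagged mixed iff BIC favors two components, both weights
#' are >= `weight_floor` and the component means are separated by at
#' least `separation` log2 units. A pure granulosa cell is unimodal
#' near zero and a pure oocyte is unimodal high; only a partial
#' admixture populates both modes.
#'
#' @param gran_log2 genes x cells matrix of granulosa log2(RPM+1).
#' @param oocyte_mean_log2 named per-gene oocyte mean log2 vector (>= 2
#'   oocytes averaged).
#' @param sig_high,sig_low signature floors (log2 units).
#' @param weight_floor,separation mixed-flag conditions.
#' @param min_genes minimum signature size.
#' @param signature optional explicit signature gene set; when supplied
#'   the floors are skipped (used e.g. to run an oocyte control cell
#'   against a granulosa-derived signature).
#' @param oocyte_log2 optional genes x oocytes log2 matrix; when given,
#'   signature genes must additionally be stably expressed across
#'   oocytes (10th percentile >= `sig_high - 2`), which excludes
#'   growth-program genes that are high on average but silent in small
#'   oocytes — a small oocyte would otherwise look bimodal against the
#'   cohort mean.
#' @return data.frame, one row per cell: `delta_bic` (BIC1 - BIC2,
#'   positive favors bimodality), `w_low`, `w_high`, `mu_low`,
#'   `mu_high`, `mixed`.
#' @export
detect_mixed_profiles <- function(gran_log2, oocyte_mean_log2,
                                  sig_high = 6, sig_low = 2,
                                  weight_floor = 0.2, separation = 2,
                                  min_genes = 50L, signature = NULL,
                                  oocyte_log2 = NULL) {
  common <- intersect(rownames(gran_log2), names(oocyte_mean_log2))
  if (!length(common)) stop("no shared genes")
  gran_log2 <- gran_log2[common, , drop = FALSE]
  ooc <- oocyte_mean_log2[common]
  sig <- if (is.null(signature)) {
    keep <- ooc >= sig_high & rowMeans(gran_log2) <= sig_low &
      rowMeans(gran_log2 > 0) <= 0.15
    # the detection-rate ceiling drops oocyte genes sporadically expressed
    # across granulosa cells (a positional phenomenon, not admixture)
    if (!is.null(oocyte_log2)) {
      q10 <- apply(oocyte_log2[common, , drop = FALSE], 1,
                   stats::quantile, probs = 0.1)
      keep <- keep & q10 >= sig_high - 2
    }
    names(ooc)[keep]
  } else intersect(signature, common)
  if (length(sig) < min_genes)
    stop("signature set too small (", length(sig), " < ", min_genes, ")")
  res <- lapply(colnames(gran_log2), function(cell) {
    v <- gran_log2[sig, cell]
    f1 <- gauss1_fit(v); f2 <- gmm2_fit(v)
    dbic <- f1$bic - f2$bic
    lo <- which.min(f2$mu); hi <- 3 - lo
    mixed <- dbic > 0 &&
      min(f2$w) >= weight_floor &&
      abs(diff(f2$mu)) >= separation
    data.frame(cell = cell, delta_bic = dbic,
               w_low = f2$w[lo], w_high = f2$w[hi],
               mu_low = f2$mu[lo], mu_high = f2$mu[hi], mixed = mixed)
  })
  out <- do.call(rbind, res)
  attr(out, "signature") <- sig
  out
}

gauss1_fit <- function(v, sd_floor = 0.2) {
  m <- mean(v); s <- max(stats::sd(v), sd_floor)
  ll <- sum(stats::dnorm(v, m, s, log = TRUE))
  list(mu = m, sd = s, loglik = ll, bic = -2 * ll + 2 * log(length(v)))
}

# 1-D two-component Gaussian mixture by EM; deterministic initialization
# from a median split
gmm2_fit <- function(v, sd_floor = 0.2, max_iter = 200L, tol = 1e-8) {
  n <- length(v)
  lo <- v <= stats::median(v); hi <- !lo
  if (!any(hi)) hi[which.max(v)] <- TRUE
  mu <- c(mean(v[lo]), mean(v[hi]))
  if (diff(range(v)) < 1e-8) mu <- mu + c(-0.1, 0.1)
  sg <- rep(max(stats::sd(v), sd_floor), 2)
  w <- c(mean(lo), mean(hi))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(v, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(v, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d2 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- c(mean(1 - r), mean(r))
    w <- pmax(w, 1e-6); w <- w / sum(w)
    mu <- c(sum((1 - r) * v) / sum(1 - r), sum(r * v) / sum(r))
    sg <- sqrt(c(sum((1 - r) * (v - mu[1])^2) / sum(1 - r),
                 sum(r * (v - mu[2])^2) / sum(r)))
    sg <- pmax(sg, sd_floor)
  }
  d1 <- w[1] * stats::dnorm(v, mu[1], sg[1])
  d2 <- w[2] * stats::dnorm(v, mu[2], sg[2])
  ll <- sum(log(pmax(d1 + d2, .Machine$double.xmin)))
  list(mu = mu, sd = sg, w = w, loglik = ll, bic = -2 * ll + 5 * log(n))
}
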