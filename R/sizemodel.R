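#' PCA of single-cell transcriptomes with expression gene filter
#'
#' Centered, unscaled PCA over cells of the genes whose log2(RPM+1)
#' exceeds `min_log2` in at least one cell. Loadings follow a
#' deterministic sign convention: each column is oriented so that its
#' largest-magnitude entry is positive, making downstream models
#' reproducible bit-for-bit.
#'
#' @param expr genes x cells log2(RPM+1) matrix (>= 3 cells).
#' @param min_log2 expression filter (published default 4).
#' @return list of class `"pca_model"`: `genes` (filtered ids), `mu`
#'   (per-gene means), `loadings` (genes x PCs), `scores` (cells x PCs),
#'   `var_share`.
#' @export
fit_pca <- function(expr, min_log2 = 4) {
  if (ncol(expr) < 3) stop(">= 3 cells required")
  keep <- apply(expr, 1, max) > min_log2
  if (sum(keep) < 2) stop("expression filter leaves < 2 genes")
  x <- t(expr[keep, , drop = FALSE])   # cells x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  sco <- sweep(pc$x, 2, flip, "*")
  structure(list(genes = colnames(x), mu = pc$center,
                 loadings = rot, scores = sco,
                 sdev = pc$sdev,
                 var_share = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", length(x$genes), "genes,", nrow(x$scores), "cells;",
      "PC1/PC2 variance:", paste(round(100 * x$var_share[1:2], 1), collapse = "/"),
      "%\n")
  invisible(x)
}

#' Spearman association of PC scores with diameter
#'
#' Rank correlation (average ranks for ties) of each principal
#' component's per-cell score against the cell diameters.
#'
#' @param scores cells x PCs matrix (or a `pca_model`).
#' @param diameters per-cell diameters, um (no missing values).
#' @return named numeric vector of Spearman rs per PC.
#' @export
pc_diameter_association <- function(scores, diameters) {
  if (inherits(scores, "pca_model")) scores <- scores$scores
  if (nrow(scores) < 3) stop(">= 3 cells required")
  if (any(is.na(diameters))) stop("diameters must be present for all cells")
  apply(scores, 2, function(s) stats::cor(s, diameters, method = "spearman"))
}

#' Per-gene Pearson correlation with diameter
#'
#' Pearson r of each gene's log2 level against diameter; genes with zero
#' expression variance are excluded (undefined r). The positive set is
#' `r > pos_cut` and the negative set `r < neg_cut` (strict
#' inequalities).
#'
#' @param expr genes x cells log2 matrix.
#' @param diameters per-cell diameters.
#' @param pos_cut,neg_cut published defaults 0.85 and -0.80.
#' @return list of class `"gene_diameter_corr"`: `r` (named vector over
#'   testable genes), `positive`, `negative` (gene id sets).
#' @export
gene_diameter_correlations <- function(expr, diameters, pos_cut = 0.85,
                                       neg_cut = -0.80) {
  if (ncol(expr) < 3) stop(">= 3 cells required")
  v <- apply(expr, 1, stats::var)
  if (all(v == 0)) stop("all-constant expression matrix")
  testable <- v > 0
  r <- as.vector(stats::cor(t(expr[testable, , drop = FALSE]), diameters))
  names(r) <- rownames(expr)[testable]
  structure(list(r = r,
                 positive = names(r)[r > pos_cut],
                 negative = names(r)[r < neg_cut],
                 pos_cut = pos_cut, neg_cut = neg_cut),
            class = "gene_diameter_corr")
}

#' Average Z-score profile of a gene set
#'
#' Standardizes each gene across cells and averages the Z scores over
#' the set per cell; zero-variance genes are dropped first.
#'
#' @param expr genes x cells log2 matrix.
#' @param gene_set character vector of gene ids.
#' @return named per-cell mean Z vector.
#' @export
average_zscore_profile <- function(expr, gene_set) {
  sub <- expr[intersect(gene_set, rownames(expr)), , drop = FALSE]
  v <- apply(sub, 1, stats::var)
  sub <- sub[v > 0, , drop = FALSE]
  if (!nrow(sub)) stop("empty gene set after zero-variance removal")
  z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  colMeans(z)
}

#' Fit a 4-parameter logistic (sigmoid) trajectory
#'
#' Least squares of `y = A + (B - A)/(1 + exp(-k (d - d0)))` with
#' multi-start Nelder-Mead/L-BFGS-B; the inflection `d0` is constrained
#' to `[min(d) - 10, max(d) + 10]` um and `k >= 0` (direction is carried
#' by A vs B). A constant response returns the flat fit `k = 0`.
#'
#' @param d diameters, um (>= 5 points spanning more than one grid step).
#' @param y response (e.g. a mean-Z profile or per-gene log2 levels).
#' @return list of class `"sigmoid_fit"`: `A`, `B`, `k`, `d0`, `rss`,
#'   `converged`, `fitted`.
#' @export
fit_sigmoid <- function(d, y) {
  if (length(d) < 5) stop(">= 5 points required")
  if (diff(range(d)) <= 10) stop("d must span more than one grid step")
  if (stats::var(y) == 0) {
    return(structure(list(A = y[1], B = y[1], k = 0, d0 = mean(d),
                          rss = 0, converged = TRUE,
                          fitted = rep(y[1], length(d))),
                     class = "sigmoid_fit"))
  }
  lower <- c(-Inf, -Inf, 0, min(d) - 10)
  upper <- c(Inf, Inf, 5, max(d) + 10)
  f <- function(p) {
    mu <- p[1] + (p[2] - p[1]) / (1 + exp(-p[3] * (d - p[4])))
    sum((y - mu)^2)
  }
  qs <- stats::quantile(d, c(0.25, 0.5, 0.75))
  starts <- expand.grid(k = c(0.05, 0.2, 0.6), d0 = qs)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(min(y), max(y), starts$k[i], starts$d0[i])
    fit <- tryCatch(
      stats::optim(p0, f, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best)) {
    # polish the winning start at tight tolerance; keep the coarse run's
    # convergence status (the polish may stop on a tolerance code)
    polish <- tryCatch(
      stats::optim(best$par, f, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value)
      best[c("par", "value")] <- polish[c("par", "value")]
  }
  if (is.null(best))
    return(structure(list(A = NA, B = NA, k = NA, d0 = NA, rss = Inf,
                          converged = FALSE, fitted = rep(NA_real_, length(d))),
                     class = "sigmoid_fit"))
  p <- best$par
  fitted <- p[1] + (p[2] - p[1]) / (1 + exp(-p[3] * (d - p[4])))
  structure(list(A = p[1], B = p[2], k = p[3], d0 = p[4],
                 rss = best$value, converged = best$convergence == 0,
                 fitted = fitted),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> A = %.3f, B = %.3f, k = %.3f, d0 = %.1f um, RSS = %.3g\n",
              x$A, x$B, x$k, x$d0, x$rss))
  invisible(x)
}

#' Fit the diameter-resolved transcriptome reconstruction model
#'
#' Regresses PC1 and PC2 scores on oocyte diameter by ordinary least
#' squares and reconstructs the expected transcriptome at every grid
#' diameter: `R[g, bin] = mu_g + sum_k (a_k + b_k d_bin) L[g, k]`,
#' K = 2. With `refine = TRUE` (default) the model performs one robust
#' refinement pass: oocytes whose best-match deviates from their
#' observed diameter by more than `deviation_cut` are excluded and the
#' PC regressions refit, so that the growth-deviant cells the model is
#' built to detect do not flatten its own calibration.
#'
#' @param pca a [fit_pca()] model of the oocyte cohort.
#' @param diameters observed per-cell diameters, um.
#' @param grid reconstruction diameters (published default 10-100 um in
#'   10-um steps), strictly increasing.
#' @param refine logical; robust refinement pass.
#' @param deviation_cut um, used by the refinement pass (and recorded
#'   for matching).
#' @return list of class `"size_model"`: `genes`, `mu`, `loadings`
#'   (K = 2), `coef` (2 x 2, intercept/slope per PC), `grid`,
#'   `reconstructed` (genes x bins), `refined`, `excluded` (cells
#'   dropped by the refinement pass).
#' @export
fit_size_model <- function(pca, diameters, grid = seq(10, 100, by = 10),
                           refine = TRUE, deviation_cut = 20) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(diameters) != nrow(pca$scores)) stop("diameter/cell mismatch")
  if (stats::var(diameters) == 0) stop("zero diameter variance")
  if (ncol(pca$loadings) < 2) stop("K = 2 components required")
  L <- pca$loadings[, 1:2, drop = FALSE]
  build <- function(use) {
    co <- vapply(1:2, function(k)
      stats::coef(stats::lm(pca$scores[use, k] ~ diameters[use])),
      numeric(2))  # 2 x 2: rows intercept, slope; cols PC1, PC2
    pcs <- vapply(grid, function(d) co[1, ] + co[2, ] * d, numeric(2))
    R <- pca$mu + L %*% pcs
    colnames(R) <- as.character(grid)
    list(coef = co, R = R)
  }
  use <- seq_along(diameters)
  m <- build(use)
  excluded <- character(0)
  if (refine) {
    expr <- pca$mu + t(pca$scores %*% t(pca$loadings))  # filtered log2 matrix
    rs <- stats::cor(expr, m$R, method = "spearman")
    best <- grid[apply(rs, 1, which.max)]
    dev <- abs(diameters - best) > deviation_cut
    if (any(dev) && sum(!dev) >= 5) {
      excluded <- rownames(pca$scores)[dev]
      m <- build(which(!dev))
    }
  }
  structure(list(genes = pca$genes, mu = pca$mu, loadings = L,
                 coef = m$coef, grid = grid, reconstructed = m$R,
                 refined = refine, excluded = excluded,
                 deviation_cut = deviation_cut),
            class = "size_model")
}

#' @export
print.size_model <- function(x, ...) {
  cat("<size_model>", length(x$genes), "genes; grid",
      min(x$grid), "-", max(x$grid), "um x", length(x$grid), "bins;",
      if (length(x$excluded)) paste(length(x$excluded), "cells excluded by refinement") else "no refinement exclusions",
      "\n")
  invisible(x)
}

#' Match oocytes to the reconstructed diameter grid
#'
#' Spearman rank correlation of each oocyte's log2 profile (restricted
#' to the model's gene list) against every reconstructed grid column;
#' the highest-rs bin is the best match (ties broken toward the smaller
#' diameter and recorded). `delta = observed - best`; a cell is deviant
#' iff `|delta| > deviation_cut` and retarded iff `delta >
#' deviation_cut` (transcriptome younger than the morphology).
#'
#' @param expr genes x cells log2 matrix covering the model's genes.
#' @param diameters observed diameters, um.
#' @param model a [fit_size_model()] result.
#' @param deviation_cut um (published default 20).
#' @return data.frame of class `"match_result"`, one row per cell:
#'   `best_match_um`, `best_rs`, `observed_um`, `delta_um`, `deviant`,
#'   `retarded`, `tie`.
#' @export
match_oocytes <- function(expr, diameters, model,
                          deviation_cut = model$deviation_cut) {
  if (!all(model$genes %in% rownames(expr)))
    stop("expression matrix does not cover the model gene list")
  x <- expr[model$genes, , drop = FALSE]
  rs <- stats::cor(x, model$reconstructed, method = "spearman")
  best_idx <- apply(rs, 1, which.max)
  tie <- vapply(seq_len(nrow(rs)), function(i)
    sum(abs(rs[i, ] - rs[i, best_idx[i]]) < 1e-12) > 1, logical(1))
  # which.max already returns the first (smallest-diameter) maximum
  best <- model$grid[best_idx]
  delta <- diameters - best
  out <- data.frame(
    cell = colnames(x),
    best_match_um = best,
    best_rs = rs[cbind(seq_len(nrow(rs)), best_idx)],
    observed_um = diameters,
    delta_um = delta,
    deviant = abs(delta) > deviation_cut,
    retarded = delta > deviation_cut,
    tie = tie, row.names = NULL)
  class(out) <- c("match_result", "data.frame")
  out
}

#' Top PC2-loading gene lists
#'
#' Genes ranked by signed loading on a chosen component; the `n`
#' largest positive and `n` largest negative contributors are returned
#' (disjoint by construction).
#'
#' @param pca a `pca_model`.
#' @param n list size (published default 500).
#' @param component which PC (default 2).
#' @return list with `positive` and `negative` gene id vectors.
#' @export
top_loading_genes <- function(pca, n = 500L, component = 2L) {
  l <- pca$loadings[, component]
  pos <- names(sort(l[l > 0], decreasing = TRUE))
  neg <- names(sort(l[l < 0]))
  if (length(pos) < n || length(neg) < n)
    stop("fewer than n genes of a sign")
  list(positive = pos[seq_len(n)], negative = neg[seq_len(n)])
}
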