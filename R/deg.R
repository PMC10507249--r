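#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement: `q_(i) =
#' min_{j >= i} p_(j) n / j`, capped at 1. Order-preserving with
#' respect to p ranks.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p outside [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

#' Two-group differential expression with published thresholds
#'
#' Genes below the expression floor (`log2(RPM+1) > floor_log2` in at
#' least one cell) are excluded before testing. Remaining genes get a
#' two-sided t-test (Welch by default) and BH adjustment over the
#' tested genes; a gene passes iff `|mean difference| > diff_cut`,
#' `p < alpha` and `q < q_cut` simultaneously.
#'
#' @param expr genes x cells log2(RPM+1) matrix.
#' @param groups two-level factor/character vector over cells (>= 2
#'   cells per group).
#' @param diff_cut log2 difference cut (published default 1.8, i.e.
#'   >3.5-fold).
#' @param floor_log2 expression floor (published default 4).
#' @param alpha,q_cut t-test and FDR cuts (published defaults 0.05).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return data.frame of class `"deg_result"`, one row per tested gene:
#'   group means, `diff` (first level - second level), `t`, `p`, `q`,
#'   `pass`, `direction`; attribute `criteria` records the snapshot.
#' @export
two_group_deg <- function(expr, groups, diff_cut = 1.8, floor_log2 = 4,
                          alpha = 0.05, q_cut = 0.05, var_equal = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("a group has < 2 cells")
  keep <- apply(expr, 1, max) > floor_log2
  x <- expr[keep, , drop = FALSE]
  a <- x[, groups == levels(groups)[1], drop = FALSE]
  b <- x[, groups == levels(groups)[2], drop = FALSE]
  tt <- row_t_test(a, b, var_equal = var_equal)
  q <- bh_adjust(tt$p)
  pass <- abs(tt$diff) > diff_cut & tt$p < alpha & q < q_cut
  out <- data.frame(
    gene_id = rownames(x),
    mean_1 = tt$m1, mean_2 = tt$m2, diff = tt$diff,
    t = tt$t, p = tt$p, q = q, pass = pass,
    direction = ifelse(pass, ifelse(tt$diff > 0, "up", "down"), ""),
    row.names = NULL)
  attr(out, "criteria") <- list(diff_cut = diff_cut, floor_log2 = floor_log2,
                                alpha = alpha, q_cut = q_cut,
                                welch = !var_equal,
                                groups = levels(groups))
  class(out) <- c("deg_result", "data.frame")
  out
}

#' Multi-group (stage) DEG filter by one-way ANOVA
#'
#' Keeps genes with ANOVA p < `alpha`, maximum level above the
#' expression floor in at least one sample, and a maximum pairwise
#' group-mean difference above `min_pair_diff`. All-identical groups
#' yield `F = 0, p = 1`.
#'
#' @param expr genes x samples log2 matrix.
#' @param stage_labels factor/character over samples (>= 2 groups).
#' @param alpha,floor_log2,min_pair_diff published defaults 0.05, 4, 1.
#' @return character vector of retained gene ids; attribute `table`
#'   holds the per-gene statistics.
#' @export
multi_group_deg <- function(expr, stage_labels, alpha = 0.05,
                            floor_log2 = 4, min_pair_diff = 1) {
  g <- as.factor(stage_labels)
  if (nlevels(g) < 2) stop(">= 2 groups required")
  counts <- table(g)
  n <- ncol(expr); kg <- nlevels(g)
  gm <- vapply(levels(g), function(l)
    rowMeans(expr[, g == l, drop = FALSE]), numeric(nrow(expr)))
  grand <- rowMeans(expr)
  ssb <- rowSums(sweep((gm - grand)^2, 2, as.numeric(counts), "*"))
  sst <- rowSums((expr - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- kg - 1; df2 <- n - kg
  if (df2 < 1) stop("a group with < 2 samples leaves no within-group df")
  Fst <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  p[ssb == 0] <- 1
  Fst[ssb == 0] <- 0
  p[ssw == 0 & ssb > 0] <- 0
  max_lvl <- apply(expr, 1, max)
  max_pair <- apply(gm, 1, function(v) diff(range(v)))
  keep <- p < alpha & max_lvl > floor_log2 & max_pair > min_pair_diff
  out <- rownames(expr)[keep]
  attr(out, "table") <- data.frame(gene_id = rownames(expr), F = Fst, p = p,
                                   max_level = max_lvl,
                                   max_pair_diff = max_pair, keep = keep,
                                   row.names = NULL)
  out
}
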