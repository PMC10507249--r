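test_that("PCA matches an eigendecomposition oracle and honors the filter", {
  set.seed(21)
  expr <- matrix(rnorm(9, 6, 2), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  p <- fit_pca(expr, min_log2 = 0)
  o <- pca_oracle(t(expr))
  for (k in 1:2) {
    expect_equal(abs(p$loadings[, k]), abs(o$loadings[, k]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(abs(p$scores[, k]), abs(o$scores[, k]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # full-rank reconstruction identity
  rec <- p$mu + t(p$scores %*% t(p$loadings))
  expect_equal(unname(rec), unname(expr), tolerance = 1e-8)

  # adding a never-passing gene leaves the model unchanged
  expr2 <- rbind(expr, low = rep(0.5, 3))
  p2 <- fit_pca(expr2, min_log2 = 4)
  p1 <- fit_pca(expr, min_log2 = 4)
  expect_identical(p1$genes, p2$genes)
  expect_equal(p1$loadings, p2$loadings)

  # rank-1 data: PC1 explains everything
  v <- seq(5, 8, length.out = 5)
  r1 <- outer(c(2, 1, 3), v)
  dimnames(r1) <- list(paste0("g", 1:3), paste0("c", 1:5))
  pr <- fit_pca(r1, min_log2 = 0)
  expect_equal(pr$var_share[1], 1, tolerance = 1e-12)

  expect_error(fit_pca(expr[, 1:2, drop = FALSE]), ">= 3 cells")
  expect_error(fit_pca(expr, min_log2 = 99), "< 2 genes")
})

test_that("sign convention makes the PCA deterministic", {
  cfg <- small_sim(seed = 10)
  lg <- to_rpm(gen_oocyte_cohort(cfg)$counts)$log2
  a <- fit_pca(lg); b <- fit_pca(lg)
  expect_identical(a$loadings, b$loadings)
  expect_identical(a$scores, b$scores)
  expect_true(all(vapply(seq_len(ncol(a$loadings)), function(k) {
    l <- a$loadings[, k]; l[which.max(abs(l))] > 0
  }, logical(1))))
})

test_that("Spearman association handles perfect order, ties and nulls", {
  sc <- matrix(seq(10, 1), 10, 1)
  expect_equal(unname(pc_diameter_association(sc, 1:10)), -1)

  # ties handled by average ranks: agree with a brute-force oracle
  set.seed(4)
  d <- c(30, 30, 40, 40, 50, 50)
  s <- rnorm(6)
  expect_equal(unname(pc_diameter_association(matrix(s), d)),
               spearman_oracle(s, d), tolerance = 1e-12)

  # permutation null centers at zero
  set.seed(5)
  rs <- replicate(200, pc_diameter_association(matrix(rnorm(20)), sample(20))[1])
  expect_lt(abs(mean(rs)), 0.06)
})

test_that("gene-diameter correlation sets obey the cuts", {
  d <- seq(20, 80, length.out = 10)
  expr <- rbind(lin = d / 10, anti = -d / 10 + 9, const = rep(5, 10),
                noise = c(5, 3, 6, 2, 7, 4, 6, 3, 5, 4))
  colnames(expr) <- paste0("c", 1:10)
  gc <- gene_diameter_correlations(expr, d)
  expect_equal(gc$positive, "lin")
  expect_equal(gc$negative, "anti")
  expect_false("const" %in% names(gc$r))  # zero variance excluded
  expect_true(length(intersect(gc$positive, gc$negative)) == 0)
  expect_error(gene_diameter_correlations(expr[3, , drop = FALSE] * 0 + 5, d),
               "all-constant")

  # at full cohort scale the emergent r > 0.85 / r < -0.80 sets are pure
  # growth-program genes, and the planted genes whose true trajectory is
  # near-linear in diameter (model r > 0.96), high-amplitude and silent
  # at the low end are recovered into the positive set
  cfg <- sim_config(seed = 13)
  oo <- gen_oocyte_cohort(cfg)
  lg <- to_rpm(oo$counts)$log2
  tj <- oo$truth$trajectory
  de <- oo$truth$effective_diameter
  gc2 <- gene_diameter_correlations(lg, de)
  expect_gte(length(gc2$positive), 100)
  expect_gte(length(gc2$negative), 100)
  expect_gte(mean(gc2$positive %in% tj$gene_id[tj$class == "rising-sigmoid"]),
             0.98)
  expect_gte(mean(gc2$negative %in% tj$gene_id[tj$class == "falling-sigmoid"]),
             0.98)
  ri <- which(tj$class == "rising-sigmoid")
  dg <- seq(20, 80, length.out = 50)
  rmod <- vapply(ri, function(i) {
    v <- tj$A[i] + (tj$B[i] - tj$A[i]) / (1 + exp(-tj$k[i] * (dg - tj$d0[i])))
    stats::cor(v, dg)
  }, numeric(1))
  strong <- rmod > 0.96 & tj$B[ri] > 6 & tj$A[ri] < 1
  expect_gte(mean(tj$gene_id[ri][strong] %in% gc2$positive), 0.85)
})

test_that("average Z profile identities", {
  set.seed(6)
  expr <- matrix(rnorm(50, 5), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  z <- average_zscore_profile(expr, rownames(expr))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  z1 <- average_zscore_profile(expr, "g1")
  expect_equal(unname(z1), as.vector(scale(expr[1, ])), tolerance = 1e-12)
  expect_error(average_zscore_profile(expr * 0 + 2, "g1"), "empty gene set")
})

test_that("sigmoid fit recovers exact and degenerate inputs", {
  d <- seq(20, 80, length.out = 44)
  y <- -1 + 2 / (1 + exp(-0.3 * (d - 45)))
  f <- fit_sigmoid(d, y)
  expect_lt(abs(f$d0 - 45), 1e-5)
  expect_lt(abs(f$k - 0.3), 1e-4)
  expect_true(f$converged)

  fc <- fit_sigmoid(d, rep(2, 44))
  expect_equal(fc$k, 0)
  expect_equal(fc$rss, 0)
  expect_error(fit_sigmoid(d[1:3], y[1:3]), ">= 5 points")
})

test_that("size model algebra on a noise-free rank-2 fixture", {
  # scores exactly linear in diameter: the reconstruction at a training
  # diameter equals the cell's rank-2 projected profile
  d <- c(20, 35, 50, 65, 80)
  L <- cbind(c(0.6, 0.8, 0, 0), c(0, 0, 0.6, -0.8))
  mu <- c(5, 6, 7, 8)
  sc <- cbind(2 * d - 90, -d + 48)
  expr <- mu + L %*% t(sc)
  dimnames(expr) <- list(paste0("g", 1:4), paste0("c", 1:5))
  p <- fit_pca(expr, min_log2 = 0)
  sm <- fit_size_model(p, d, grid = d, refine = FALSE)
  expect_equal(unname(sm$reconstructed), unname(expr), tolerance = 1e-8)

  # default grid has 10 columns at 10..100 um
  sm10 <- fit_size_model(p, d, refine = FALSE)
  expect_equal(as.numeric(colnames(sm10$reconstructed)), seq(10, 100, 10))

  # zero loadings: every column equals mu
  p0 <- p; p0$loadings <- p$loadings * 0
  sm0 <- fit_size_model(p0, d, refine = FALSE)
  expect_true(all(abs(sm0$reconstructed - p$mu) < 1e-12))

  expect_error(fit_size_model(p, rep(50, 5)), "zero diameter variance")
  expect_error(fit_size_model(p, d, grid = c(10, 10, 20)), "strictly increasing")
})

test_that("matching self-matches, breaks ties low and flags deviants", {
  d <- c(20, 35, 50, 65, 80)
  L <- cbind(c(0.6, 0.8, 0, 0), c(0, 0, 0.6, -0.8))
  mu <- c(5, 6, 7, 8)
  sc <- cbind(2 * d - 90, -d + 48)
  expr <- mu + L %*% t(sc)
  dimnames(expr) <- list(paste0("g", 1:4), paste0("c", 1:5))
  p <- fit_pca(expr, min_log2 = 0)
  sm <- fit_size_model(p, d, refine = FALSE)

  # an oocyte equal to the 50-um column best-matches 50 with rs = 1
  probe <- matrix(sm$reconstructed[, "50"], ncol = 1,
                  dimnames = list(rownames(expr), "probe"))
  mr <- match_oocytes(probe, 72, sm)
  expect_equal(mr$best_match_um, 50)
  expect_equal(mr$best_rs, 1, tolerance = 1e-12)
  expect_equal(mr$delta_um, 22)
  expect_true(mr$deviant); expect_true(mr$retarded)

  # tie between identical columns resolves to the smaller diameter
  smt <- sm
  smt$reconstructed[, "100"] <- smt$reconstructed[, "50"]
  mrt <- match_oocytes(probe, 50, smt)
  expect_equal(mrt$best_match_um, 50)
  expect_true(mrt$tie)

  expect_error(match_oocytes(probe[1:2, , drop = FALSE], 50, sm), "gene list")
})

test_that("top loading gene lists are disjoint and sign-partitioned", {
  cfg <- small_sim(seed = 12)
  oo <- gen_oocyte_cohort(cfg)
  p <- fit_pca(to_rpm(oo$counts)$log2)
  tl <- top_loading_genes(p, n = 50)
  expect_length(intersect(tl$positive, tl$negative), 0)
  expect_length(tl$positive, 50)
  tl1 <- top_loading_genes(p, n = 1)
  l <- p$loadings[, 2]
  expect_equal(tl1$positive, names(which.max(l)))
  expect_equal(tl1$negative, names(which.min(l)))
  expect_error(top_loading_genes(p, n = 1e6), "fewer than n")

  # rising and falling trajectory genes separate by loading sign (>= 80%)
  tj <- oo$truth$trajectory
  big <- top_loading_genes(p, n = 400, component = 1)
  ri <- tj$gene_id[tj$class == "rising-sigmoid" & (tj$B - tj$A) > 4]
  fa <- tj$gene_id[tj$class == "falling-sigmoid" & (tj$A - tj$B) > 4]
  in_pos <- mean(ri %in% big$positive)
  in_neg <- mean(ri %in% big$negative)
  side_ri <- if (in_pos >= in_neg) "positive" else "negative"
  side_fa <- setdiff(c("positive", "negative"), side_ri)
  expect_gte(mean(ri %in% big[[side_ri]]), 0.8)
  expect_gte(mean(fa %in% big[[side_fa]]), 0.8)
})

test_that("noise-free monotone synthetic data gives |rs| >= 0.95 on the PC axis", {
  cfg <- small_sim(seed = 13, noise_sd = 0.01, n_retarded = 0L,
                   dropout_midpoint = -20)  # dropout effectively off
  oo <- gen_oocyte_cohort(cfg)
  p <- fit_pca(to_rpm(oo$counts)$log2)
  rs <- pc_diameter_association(p, oo$records$diameter_um)
  expect_gte(max(abs(rs[1:2])), 0.95)
})
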