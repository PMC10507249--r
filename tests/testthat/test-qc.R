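test_that("grubbs statistic matches the closed form", {
  g <- grubbs_test(c(10, 10, 10, 10, 20), side = "high")
  # mean 12, sd sqrt(20): G = 8/sqrt(20)
  expect_equal(g$statistic, 8 / sqrt(20), tolerance = 1e-12)
  expect_equal(g$index, 5L)
  expect_equal(g$statistic, 1.789, tolerance = 1e-3)

  const <- grubbs_test(rep(3, 6))
  expect_equal(const$p_value, 1)
  expect_true(is.na(const$index))

  expect_error(grubbs_test(c(1, 2)), "n >= 3")
  expect_error(grubbs_test(c(1, 2, NA)), "finite")
})

test_that("grubbs p-values agree with a Monte-Carlo null", {
  # scaled to 2e5 draws per n (spec scale 1e6) to stay in the time budget;
  # tolerance 3 Monte-Carlo SEs plus the same allowance for the union bound
  set.seed(71)
  n_draw <- 2e5
  for (n in c(5, 10, 48)) {
    x <- matrix(stats::rnorm(n_draw * n), n_draw, n)
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (n - 1))
    G <- (apply(x, 1, max) - m) / s
    for (alpha in c(0.01, 0.05)) {
      gcrit <- stats::uniroot(function(g) lcmtx:::grubbs_p(g, n) - alpha,
                              c(0.1, (n - 1) / sqrt(n) - 1e-9))$root
      emp <- mean(G > gcrit)
      se <- sqrt(alpha * (1 - alpha) / n_draw)
      expect_lt(abs(emp - alpha), 3 * se + 0.1 * alpha)
    }
  }
})

test_that("amplification gate excludes planted failures and spares null plates", {
  pl <- gen_ct_plate(48, n_failures = 8, failure_shift = 8, seed = 4)
  gate <- gate_amplification(pl$ct, alpha = 0.01)
  expect_true(all(!gate$pass[pl$failed]))
  expect_lte(sum(!gate$pass & !pl$failed), 1)

  # all-equal plate: zero variance, everything passes
  g0 <- gate_amplification(rep(20, 10))
  expect_true(all(g0$pass))

  # null false-exclusion rate bounded by 2 * alpha (here: 200 plates)
  fails <- 0L
  for (s in 1:200) {
    pl0 <- gen_ct_plate(48, n_failures = 0, seed = s)
    fails <- fails + sum(!gate_amplification(pl0$ct)$pass)
  }
  expect_lte(fails / (200 * 48), 0.02)
})

test_that("cell filters fire the right reason codes", {
  cfg <- small_sim(seed = 7)
  oo <- gen_oocyte_cohort(cfg)
  rec <- oo$records
  rec$mapping_rate[1] <- 0.02   # below the 3% oocyte floor
  th <- pipeline_config()$thresholds
  th$gene_count_floor <- 100
  rep <- filter_cells(rec, oo$counts, th)
  expect_false(rep$cells$pass[1])
  expect_match(rep$cells$reasons[1], "low_mapping_rate")
  expect_true(all(rep$cells$pass[-1]))

  # a pure-noise cell among structured cells fails the correlation screen
  cm <- oo$counts
  set.seed(1)
  noise <- as.integer(rpois(nrow(cm$counts), 5))
  cm$counts[, 10] <- noise
  rep2 <- filter_cells(rec, cm, th)
  expect_match(rep2$cells$reasons[10], "low_correlation")

  # missing threshold for a present cell type errors
  expect_error(filter_cells(transform(rec, cell_type = "granulosa"), oo$counts,
                            th[setdiff(names(th), "mapping_rate_floor_granulosa")]),
               "missing mapping-rate threshold")
})

test_that("mixed-profile detector flags mixtures, spares pure cells and oocytes", {
  cfg <- small_sim(seed = 8)
  oo <- gen_oocyte_cohort(cfg)
  gr <- gen_granulosa_cohort(cfg)
  eo <- to_rpm(oo$counts)$log2
  eg <- to_rpm(gr$counts)$log2
  ooc_mean <- rowMeans(eo)

  mp <- detect_mixed_profiles(eg, ooc_mean, min_genes = 30, oocyte_log2 = eo)
  truth <- gr$truth$mixed[mp$cell]
  expect_true(all(mp$mixed[truth]))          # 50/50 mixtures flagged
  expect_lte(sum(mp$mixed[!truth]), 1)       # pure cells essentially never

  # an oocyte against the oocyte mean is unimodal high: never flagged
  mo <- detect_mixed_profiles(eo, ooc_mean, min_genes = 30,
                              signature = attr(mp, "signature"))
  expect_false(any(mo$mixed))

  # weights sum to one and flag implies the separation/weight conditions
  expect_equal(mp$w_low + mp$w_high, rep(1, nrow(mp)), tolerance = 1e-6)
  flg <- mp[mp$mixed, ]
  expect_true(all(pmin(flg$w_low, flg$w_high) >= 0.2))
  expect_true(all(flg$mu_high - flg$mu_low >= 2))

  expect_error(detect_mixed_profiles(eg, ooc_mean, min_genes = 1e5),
               "signature set too small")
})
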