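test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim(seed = 3)
  a <- gen_oocyte_cohort(cfg)
  b <- gen_oocyte_cohort(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$effective_diameter, b$truth$effective_diameter)
  c <- gen_oocyte_cohort(small_sim(seed = 4))
  expect_false(identical(a$counts$counts, c$counts$counts))

  p1 <- gen_ct_plate(48, n_failures = 3, seed = 9)
  p2 <- gen_ct_plate(48, n_failures = 3, seed = 9)
  expect_identical(p1, p2)
  expect_identical(gen_ercc_counts(seed = 5), gen_ercc_counts(seed = 5))
})

test_that("oocyte cohort matches its ground truth", {
  cfg <- small_sim(seed = 2)
  oo <- gen_oocyte_cohort(cfg)
  expect_equal(ncol(gene_counts(oo$counts)), 44)
  expect_equal(nrow(gene_counts(oo$counts)), cfg$n_genes)
  expect_equal(sum(oo$counts$is_spike), cfg$n_spikes)
  tr <- oo$truth
  expect_equal(sum(tr$retarded), cfg$n_retarded)
  # effective <= observed, equality exactly for non-retarded cells
  expect_true(all(tr$effective_diameter <= tr$observed_diameter))
  expect_equal(tr$observed_diameter[tr$retarded] - tr$effective_diameter[tr$retarded],
               rep(cfg$retard_delta, cfg$n_retarded), ignore_attr = TRUE)
  # flat genes have k = 0
  flat <- tr$trajectory$class %in% c("flat", "oocyte-specific", "housekeeping")
  expect_true(all(tr$trajectory$k[flat] == 0))
  # rising genes track diameter; flat genes do not
  lg <- to_rpm(oo$counts)$log2
  tj <- tr$trajectory
  ri <- tj$class == "rising-sigmoid" & (tj$B - tj$A) > 4
  fl <- tj$class == "flat" & tj$A > 2
  r_ri <- as.vector(stats::cor(t(lg[tj$gene_id[ri], ]), tr$effective_diameter))
  r_fl <- as.vector(stats::cor(t(lg[tj$gene_id[fl], ]), tr$effective_diameter))
  expect_gt(stats::median(r_ri), 0.6)
  expect_lt(stats::median(abs(r_fl)), 0.2)
})

test_that("granulosa truth-consistency: planted offset and mixtures recoverable", {
  cfg <- small_sim(seed = 5, neighboring_deg_style = "offset")
  gr <- gen_granulosa_cohort(cfg)
  lg <- to_rpm(gr$counts)$log2
  pos <- gr$truth$position
  nn <- gr$truth$deg_nonneighboring
  diff <- rowMeans(lg[nn, pos == "non_neighboring"]) -
    rowMeans(lg[nn, pos == "neighboring"])
  # planted 3.0 log2 offset recovered within sampling error
  expect_equal(mean(diff), cfg$deg_offset, tolerance = 0.1)

  # mixed cells correlate with the oocyte mean more than any pure cell
  oo <- gen_oocyte_cohort(cfg)
  ooc_mean <- rowMeans(to_rpm(oo$counts)$log2)
  cors <- apply(lg, 2, stats::cor, y = ooc_mean)
  expect_gt(min(cors[gr$truth$mixed]), max(cors[!gr$truth$mixed]))

  # zero mixing fraction => no mixed cells in truth
  gr0 <- gen_granulosa_cohort(small_sim(seed = 5, n_mixed = 0L))
  expect_false(any(gr0$truth$mixed))
})

test_that("fresh/section truth-consistency: planted gap and bias recoverable", {
  cfg <- sim_config(n_genes = 6000, seed = 6)
  fs <- gen_fresh_vs_section(cfg)
  gf <- gene_counts(fs$fresh); gs <- gene_counts(fs$section)
  da <- fs$truth$detect_artifacts
  gap <- rowMeans(gf[da, ] > 0) - rowMeans(gs[da, ] > 0)
  expect_lt(abs(mean(gap) - cfg$detect_drop), 0.05)
  # thinning bias: pseudo-bulk log2 fold of library fractions
  ba <- fs$truth$bias_artifacts
  fold <- log2((rowSums(gs[ba, ]) / sum(gs)) / (rowSums(gf[ba, ]) / sum(gf)))
  expect_lt(abs(mean(fold) - cfg$bias_log2), 0.15)
  # null configuration: arms exchangeable, flags ~ alpha
  fs0 <- gen_fresh_vs_section(sim_config(n_genes = 6000, seed = 6,
                                         n_detect_artifacts = 0L,
                                         n_bias_artifacts = 0L))
  r0 <- section_bias_report(fs0$fresh, fs0$section)
  expect_lt(mean(r0$z_p < 0.01), 0.02)
})

test_that("ERCC generator honors expectation mode and Poisson regime", {
  ref <- data.frame(spike_id = c("ERCC-1", "ERCC-2", "ERCC-3"),
                    copies = c(4, 16, 64))
  cnt <- gen_ercc_counts(ref, capture_efficiency = 1, scale = 1,
                         expectation = TRUE)
  expect_equal(unname(cnt), c(4, 16, 64), ignore_attr = TRUE)
  expect_error(gen_ercc_counts(ref, capture_efficiency = 0), "efficiency")
  expect_error(gen_ercc_counts(ref, scale = -1), "scale")
  # least-squares refit on Poisson counts over the full copy span
  cnt2 <- gen_ercc_counts(seed = 8)
  m <- fit_copy_model(cnt2, ercc_reference())
  expect_equal(m$slope, 1, tolerance = 0.1)
})

test_that("Ct plate failures are the plate maxima", {
  pl <- gen_ct_plate(48, n_failures = 8, failure_shift = 8, seed = 2)
  expect_equal(sum(pl$failed), 8)
  expect_setequal(order(pl$ct, decreasing = TRUE)[1:8], which(pl$failed))
  pl0 <- gen_ct_plate(48, n_failures = 0, seed = 2)
  expect_false(any(pl0$failed))
  expect_error(gen_ct_plate(48, n_failures = 48), "n_failures")
  expect_error(gen_ct_plate(2), "n >= 3")
})

test_that("exon table decays toward the 5' end and junctions flank exons", {
  ex <- gen_exon_table(seed = 3)
  # exon order strictly increasing along each transcript
  ok <- vapply(split(ex$model, ex$model$transcript),
               function(tx) all(diff(sort(tx$exon_index)) == 1), logical(1))
  expect_true(all(ok))
  # junction ids reference exons of the same gene
  jid <- grep("\\|", rownames(ex$counts), value = TRUE)
  ab <- do.call(rbind, strsplit(jid, "|", fixed = TRUE))
  expect_true(all(sub("_e.*", "", ab[, 1]) == sub("_e.*", "", ab[, 2])))
  # mean detection rate falls with exon count (3' decay)
  tmm <- tmm_factors(ex$counts)
  mask <- tmm_detectable(tmm_values(ex$counts, tmm)$values)
  rates <- exon_detection_rates(mask[ex$model$exon_id, , drop = FALSE], ex$model)
  lo <- mean(rates$rate[rates$n_exons <= 5])
  hi <- mean(rates$rate[rates$n_exons > 10])
  expect_gt(lo, hi)
})
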