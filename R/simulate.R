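#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults mirror the
#' ovarian-section cohort the pipeline was built for: 44 growing oocytes
#' spanning 20-80 um, 57 granulosa cells in two positional groups with
#' 35 + 97 planted positional DEGs, 12,000 genes, 92 ERCC spike-ins, a
#' 48-well qPCR plate, 4 growth-retarded oocytes offset by 30 um and
#' 3 mixed oocyte/granulosa profiles.
#'
#' Counts are drawn by exponentiating a per-gene log2 mean (a 4-parameter
#' logistic trajectory of oocyte diameter for growth-program genes),
#' scaling to a log-normal per-cell library size, Poisson sampling, and
#' applying expression-dependent logistic dropout (midpoint log2 = 2,
#' steepness 1), which concentrates technical artifacts below
#' log2(RPM+1) of about 4 as observed in sectioned material.
#'
#' @param n_oocytes,n_granulosa,n_genes,n_spikes cohort dimensions.
#' @param n_neighboring granulosa cells directly apposed to the oocyte.
#' @param diameter_range observed oocyte diameter range, um.
#' @param noise_sd per-gene Gaussian noise on the log2 scale.
#' @param dropout_midpoint,dropout_steepness logistic dropout in the log2
#'   mean; detection probability `1 - 1/(1 + exp(s*(mu - m)))`.
#' @param n_retarded,retard_delta growth-retarded cells: effective
#'   (transcriptomic) diameter = observed - `retard_delta` um.
#' @param n_rising,n_falling numbers of growth-program genes with rising /
#'   falling logistic trajectories; amplitudes U(1.5, 8), steepness
#'   U(0.1, 0.3), inflections U(`d0_range`).
#' @param d0_range inflection-point spread, um. Spread across the growth
#'   range so the aggregate principal-component trend is near linear; the
#'   strongly diameter-correlated subsets then emerge with central
#'   inflections (~45 um).
#' @param n_oocyte_specific flat genes expressed only in oocytes
#'   (log2 6-9), the mixed-profile signature pool.
#' @param n_housekeeping very highly expressed flat genes (log2 9-13)
#'   shared by all cell types. They carry the bulk of the library, as
#'   ribosomal/mitochondrial genes do in real cells, which pins the
#'   per-million scale so that observed log2(RPM+1) tracks the latent
#'   log2 mean.
#' @param n_deg_neighboring,n_deg_nonneighboring planted positional DEGs.
#' @param deg_offset planted log2 offset of non-neighboring DEGs.
#' @param neighboring_deg_style `"zero_inflated"` (oocyte genes expressed
#'   in a random subset of neighboring cells only) or `"offset"` (plain
#'   log2 offset like the non-neighboring set).
#' @param zi_prob expression probability of a zero-inflated neighboring
#'   DEG within a neighboring cell.
#' @param n_mixed,mix_fraction,mix_inclusion mixed-profile cells: each
#'   oocyte gene is independently included with probability
#'   `mix_inclusion`; included genes receive `mix_fraction` of the
#'   oocyte-mean count rate on top of the granulosa profile (a partial
#'   fragment of adjacent oocyte cytoplasm).
#' @param n_cells_per_cohort cells per arm of the fresh/section contrast.
#' @param n_detect_artifacts,detect_drop planted section-specific
#'   detection-rate errors: absolute detection-rate reduction.
#' @param n_bias_artifacts,bias_log2 planted section-specific biases:
#'   recovered reads of a bias gene are binomially thinned by
#'   `2^bias_log2` in the section arm.
#' @param artifact_pool_log2 log2-mean band artifact genes are drawn
#'   from (default the low-expression band, where sectioning artifacts
#'   concentrate).
#' @param ct_plate_size,ct_base,ct_sd,ct_failure_shift qPCR plate model.
#' @param lib_size_mean,lib_size_sdlog log-normal library-size model.
#' @param spike_capture fraction of spike copies recovered as reads.
#' @param seed default stream seed used when a generator is called
#'   without one.
#' @param ... overrides.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_oocytes = 44L, n_granulosa = 57L,
                       n_neighboring = 20L,
                       n_genes = 12000L, n_spikes = 92L,
                       diameter_range = c(20, 80),
                       noise_sd = 0.5,
                       dropout_midpoint = 2, dropout_steepness = 1,
                       n_retarded = 4L, retard_delta = 30,
                       n_rising = 600L, n_falling = 400L,
                       d0_range = c(25, 70),
                       n_oocyte_specific = 200L,
                       n_housekeeping = 200L,
                       n_deg_neighboring = 35L, n_deg_nonneighboring = 97L,
                       deg_offset = 3.0,
                       neighboring_deg_style = c("zero_inflated", "offset"),
                       zi_prob = 0.6,
                       n_mixed = 3L, mix_fraction = 0.5, mix_inclusion = 0.6,
                       n_cells_per_cohort = 48L,
                       n_detect_artifacts = 50L, detect_drop = 0.4,
                       n_bias_artifacts = 100L, bias_log2 = -2.0,
                       artifact_pool_log2 = c(2.6, 3.3),
                       ct_plate_size = 48L, ct_base = 20, ct_sd = 0.5,
                       ct_failure_shift = 8,
                       lib_size_mean = 3e6, lib_size_sdlog = 0.2,
                       spike_capture = 0.1,
                       seed = 1L, ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg$neighboring_deg_style <- match.arg(neighboring_deg_style)
  if (cfg$n_retarded > cfg$n_oocytes) stop("n_retarded > n_oocytes")
  if (diff(cfg$diameter_range) <= 0) stop("degenerate diameter range")
  if (cfg$n_genes < cfg$n_rising + cfg$n_falling + cfg$n_oocyte_specific +
        cfg$n_housekeeping)
    stop("n_genes too small for the planted trajectory classes")
  if (cfg$mix_fraction < 0 || cfg$mix_fraction > 1) stop("mix_fraction in [0,1]")
  class(cfg) <- "sim_config"
  cfg
}

detect_prob <- function(mu, cfg)
  1 - 1 / (1 + exp(cfg$dropout_steepness * (mu - cfg$dropout_midpoint)))

# Deterministic per-gene trajectory model shared by the oocyte and
# granulosa generators (same gene panel, same parameters for a given
# config seed).
gene_model <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(cfg$seed, 101L))
  ng <- cfg$n_genes
  cls <- rep("flat", ng)
  i <- 1L
  take <- function(n) { out <- seq.int(i, length.out = n); i <<- i + n; out }
  ri <- take(cfg$n_rising); fa <- take(cfg$n_falling)
  sp <- take(cfg$n_oocyte_specific)
  hk <- take(cfg$n_housekeeping)
  cls[ri] <- "rising-sigmoid"; cls[fa] <- "falling-sigmoid"
  cls[sp] <- "oocyte-specific"; cls[hk] <- "housekeeping"
  A <- B <- k <- d0 <- numeric(ng)
  amp <- function(n) stats::runif(n, 1.5, 8)
  A[ri] <- stats::runif(length(ri), 0, 2); B[ri] <- A[ri] + amp(length(ri))
  B[fa] <- stats::runif(length(fa), 0, 2); A[fa] <- B[fa] + amp(length(fa))
  kk <- c(ri, fa)
  k[kk] <- stats::runif(length(kk), 0.1, 0.3)
  d0[kk] <- stats::runif(length(kk), cfg$d0_range[1], cfg$d0_range[2])
  A[sp] <- B[sp] <- stats::runif(length(sp), 6, 9)
  A[hk] <- B[hk] <- stats::runif(length(hk), 9, 13)
  fl <- which(cls == "flat")
  mu_flat <- ifelse(stats::runif(length(fl)) < 0.3, 0,
                    stats::runif(length(fl), 0.5, 8))
  A[fl] <- B[fl] <- mu_flat
  d0[k == 0] <- mean(cfg$d0_range)
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  # granulosa baseline: somatic flat genes shared; growth-program and
  # oocyte-specific genes silent in granulosa
  mu_gran <- ifelse(cls %in% c("flat", "housekeeping"), A, 0)
  list(gene_ids = gene_ids, class = cls, A = A, B = B, k = k, d0 = d0,
       mu_gran = mu_gran)
}

traj_mu <- function(gm, d) gm$A + (gm$B - gm$A) / (1 + exp(-gm$k * (d - gm$d0)))

# mean oocyte log2 profile over the observed diameter span (no noise)
oocyte_mean_profile <- function(gm, cfg) {
  ds <- seq(cfg$diameter_range[1], cfg$diameter_range[2], length.out = 25)
  rowMeans(vapply(ds, function(d) traj_mu(gm, d), numeric(cfg$n_genes)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Poisson counts from a log2-mean matrix (genes x cells) with logistic
# dropout and log-normal library sizes; returns integer matrix.
counts_from_log2 <- function(mu, cfg, lib = NULL) {
  nc <- ncol(mu)
  if (is.null(lib))
    lib <- round(stats::rlnorm(nc, log(cfg$lib_size_mean), cfg$lib_size_sdlog))
  keep <- matrix(stats::rbinom(length(mu), 1L, detect_prob(mu, cfg)),
                 nrow(mu), nc)
  lam <- sweep((2^mu - 1) / 1e6 * keep, 2, lib, "*")
  cnt <- matrix(stats::rpois(length(lam), lam), nrow(mu), nc)
  attr(cnt, "lib") <- lib
  cnt
}

spike_block <- function(cfg, n_cells, reference = NULL) {
  if (is.null(reference)) reference <- ercc_reference(cfg$n_spikes)
  lam <- reference$copies * cfg$spike_capture
  m <- matrix(stats::rpois(nrow(reference) * n_cells, rep(lam, n_cells)),
              nrow(reference), n_cells)
  rownames(m) <- reference$spike_id
  m
}

#' Synthetic ERCC spike-in reference
#'
#' @param n_spikes number of spike species; expected copies per reaction
#'   span `2^copy_log2_range` on an even log2 grid (a synthetic stand-in
#'   for the commercial mix's serial dilution series).
#' @param copy_log2_range log2 copy range.
#' @return data.frame with `spike_id` and `copies`.
#' @export
ercc_reference <- function(n_spikes = 92L, copy_log2_range = c(0, 12)) {
  data.frame(
    spike_id = sprintf("ERCC-%05d", seq_len(n_spikes)),
    copies = 2^seq(copy_log2_range[1], copy_log2_range[2],
                   length.out = n_spikes))
}

#' Simulate an oocyte cohort with diameter-driven transcriptomes
#'
#' Each growth-program gene follows the 4-parameter logistic
#' `A + (B - A) / (1 + exp(-k (d - d0)))` of the cell's effective
#' diameter; growth-retarded cells use effective = observed -
#' `retard_delta`. Gaussian log2 noise, library scaling, Poisson
#' sampling and logistic dropout are then applied, and ERCC spike-in
#' rows are appended.
#'
#' @param cfg a [sim_config()].
#' @param seed integer stream seed (defaults to `cfg$seed`).
#' @return list with `counts` (a [count_matrix()]), `records` (metadata
#'   data.frame) and `truth` (ground-truth record: per-gene class and
#'   trajectory parameters, true effective diameters, retarded flags and
#'   planted deltas, dropout parameters, seed).
#' @export
gen_oocyte_cohort <- function(cfg = sim_config(), seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, 202L))
  gm <- gene_model(cfg)
  no <- cfg$n_oocytes
  d_obs <- seq(cfg$diameter_range[1], cfg$diameter_range[2], length.out = no)
  eligible <- which(d_obs >= cfg$diameter_range[1] + cfg$retard_delta + 5)
  retarded <- if (cfg$n_retarded > 0) {
    if (length(eligible) < cfg$n_retarded)
      stop("diameter range too narrow to plant retarded cells")
    eligible[round(seq(1, length(eligible), length.out = cfg$n_retarded))]
  } else integer(0)
  d_eff <- d_obs
  d_eff[retarded] <- d_obs[retarded] - cfg$retard_delta
  mu <- vapply(d_eff, function(d) traj_mu(gm, d), numeric(cfg$n_genes))
  mu <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd), nrow(mu))
  mu[mu < 0] <- 0
  cnt <- counts_from_log2(mu, cfg)
  cells <- sprintf("ooc_%02d", seq_len(no))
  dimnames(cnt) <- list(gm$gene_ids, cells)
  sp <- spike_block(cfg, no); colnames(sp) <- cells
  cm <- count_matrix(rbind(cnt, sp))
  records <- data.frame(
    id = cells, cell_type = "oocyte", cohort = "section_alcohol",
    diameter_um = d_obs,
    follicle_diameter_um = d_obs * 3 + stats::rnorm(no, 0, 5),
    position = NA_character_,
    ct = stats::rnorm(no, cfg$ct_base, cfg$ct_sd),
    mapping_rate = stats::runif(no, 0.35, 0.55))
  truth <- list(
    kind = "oocyte_cohort", seed = seed,
    gene_class = stats::setNames(gm$class, gm$gene_ids),
    trajectory = data.frame(gene_id = gm$gene_ids, class = gm$class,
                            A = gm$A, B = gm$B, k = gm$k, d0 = gm$d0),
    observed_diameter = stats::setNames(d_obs, cells),
    effective_diameter = stats::setNames(d_eff, cells),
    retarded = stats::setNames(seq_len(no) %in% retarded, cells),
    retard_delta = cfg$retard_delta,
    dropout = list(midpoint = cfg$dropout_midpoint,
                   steepness = cfg$dropout_steepness))
  list(counts = cm, records = records, truth = truth)
}

#' Simulate a granulosa cohort with positional DEGs and mixed profiles
#'
#' Two positional groups (neighboring vs non-neighboring the oocyte).
#' Planted non-neighboring DEGs carry a fixed log2 offset; planted
#' neighboring DEGs are oocyte genes expressed in a random subset of
#' neighboring cells only (zero-inflated), reproducing their highly
#' heterogeneous appearance. Mixed-profile cells receive, for a random
#' subset of oocyte genes, a convex count-level admixture of the oocyte
#' mean profile.
#'
#' @inheritParams gen_oocyte_cohort
#' @return list with `counts`, `records`, `truth` (positions, planted
#'   DEG ids and directions, mixed flags with mixing fractions).
#' @export
gen_granulosa_cohort <- function(cfg = sim_config(), seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, 303L))
  gm <- gene_model(cfg)
  ng <- cfg$n_genes
  n <- cfg$n_granulosa; n_nb <- cfg$n_neighboring
  if (n_nb < 2 || n - n_nb < 2) stop("each positional group needs >= 2 cells")
  position <- rep(c("neighboring", "non_neighboring"), c(n_nb, n - n_nb))
  cells <- sprintf("gc_%02d", seq_len(n))

  flat_pool <- which(gm$class == "flat" & gm$mu_gran >= 4 & gm$mu_gran <= 6)
  deg_nn <- sort(sample(flat_pool, cfg$n_deg_nonneighboring))
  spec_pool <- which(gm$class == "oocyte-specific")
  deg_nb <- sort(sample(spec_pool, cfg$n_deg_neighboring))

  mu <- matrix(gm$mu_gran, ng, n)
  mu[deg_nn, position == "non_neighboring"] <-
    mu[deg_nn, position == "non_neighboring"] + cfg$deg_offset
  ooc_mu <- oocyte_mean_profile(gm, cfg)
  if (cfg$neighboring_deg_style == "zero_inflated") {
    nb_idx <- which(position == "neighboring")
    on_mask <- matrix(stats::rbinom(length(deg_nb) * length(nb_idx), 1L,
                                    cfg$zi_prob),
                      length(deg_nb), length(nb_idx))
    lvl <- matrix(stats::rnorm(length(on_mask), ooc_mu[deg_nb] - 1, 1),
                  length(deg_nb), length(nb_idx))
    mu[deg_nb, nb_idx] <- pmax(0, on_mask * lvl)
  } else {
    # plain-offset style: base level 4 in both groups, +offset in neighboring
    mu[deg_nb, ] <- 4
    mu[deg_nb, position == "neighboring"] <- 4 + cfg$deg_offset
  }
  mu <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd), ng, n)
  mu[mu < 0] <- 0
  lib <- round(stats::rlnorm(n, log(cfg$lib_size_mean), cfg$lib_size_sdlog))
  keep <- matrix(stats::rbinom(length(mu), 1L, detect_prob(mu, cfg)), ng, n)
  lam <- sweep((2^mu - 1) / 1e6 * keep, 2, lib, "*")

  mixed <- rep(FALSE, n)
  if (cfg$n_mixed > 0) {
    mixed[sample(seq_len(n), cfg$n_mixed)] <- TRUE
    ooc_genes <- which(gm$class != "flat")
    lam_ooc <- (2^ooc_mu - 1) / 1e6
    for (j in which(mixed)) {
      inc <- ooc_genes[stats::runif(length(ooc_genes)) < cfg$mix_inclusion]
      lam[inc, j] <- (1 - cfg$mix_fraction) * lam[inc, j] +
        cfg$mix_fraction * lam_ooc[inc] * lib[j]
    }
  }
  cnt <- matrix(stats::rpois(length(lam), lam), ng, n,
                dimnames = list(gm$gene_ids, cells))
  sp <- spike_block(cfg, n); colnames(sp) <- cells
  cm <- count_matrix(rbind(cnt, sp))
  records <- data.frame(
    id = cells, cell_type = "granulosa", cohort = "section_alcohol",
    diameter_um = NA_real_, follicle_diameter_um = NA_real_,
    position = position,
    ct = stats::rnorm(n, cfg$ct_base, cfg$ct_sd),
    mapping_rate = stats::runif(n, 0.25, 0.45))
  truth <- list(
    kind = "granulosa_cohort", seed = seed,
    position = stats::setNames(position, cells),
    deg_neighboring = gm$gene_ids[deg_nb],
    deg_nonneighboring = gm$gene_ids[deg_nn],
    deg_offset = cfg$deg_offset,
    mixed = stats::setNames(mixed, cells),
    mix_fraction = ifelse(mixed, cfg$mix_fraction, 0),
    oocyte_mean_log2 = stats::setNames(ooc_mu, gm$gene_ids),
    gene_class = stats::setNames(gm$class, gm$gene_ids))
  list(counts = cm, records = records, truth = truth)
}

#' Simulate a paired fresh vs sectioned cohort with planted artifacts
#'
#' Both arms share the gene panel and base expression model. In the
#' section arm a configured set of low-expressed genes receives an extra
#' dropout calibrated to an absolute detection-rate reduction
#' (`detect_drop`), and a second disjoint set has its recovered reads
#' binomially thinned by `2^bias_log2` (a log2 fold-change of read
#' recovery, the planted expression bias).
#'
#' @inheritParams gen_oocyte_cohort
#' @return list with `fresh`, `section` (both [count_matrix()]) and
#'   `truth` (artifact gene ids, planted gap and bias, base means).
#' @export
gen_fresh_vs_section <- function(cfg = sim_config(), seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, 404L))
  ng <- cfg$n_genes; n <- cfg$n_cells_per_cohort
  mu0 <- ifelse(stats::runif(ng) < 0.3, 0, stats::runif(ng, 0.5, 8))
  n_hk <- min(cfg$n_housekeeping, ng %/% 10)
  mu0[sample.int(ng, n_hk)] <- stats::runif(n_hk, 9, 13)
  gene_ids <- sprintf("gene_%05d", seq_len(ng))
  # artifacts live in the low-expression band by default (marginal
  # log2(RPM+1) < 4); the band is configurable for sensitivity tests
  pool <- which(mu0 >= cfg$artifact_pool_log2[1] &
                  mu0 <= cfg$artifact_pool_log2[2])
  n_art <- cfg$n_detect_artifacts + cfg$n_bias_artifacts
  if (length(pool) < n_art)
    stop("artifact pool too small; increase n_genes")
  art <- sample(pool, n_art)
  det_genes <- sort(art[seq_len(cfg$n_detect_artifacts)])
  bias_genes <- sort(art[cfg$n_detect_artifacts + seq_len(cfg$n_bias_artifacts)])

  draw_arm <- function(mu_vec, extra_drop = NULL, prefix) {
    mu <- matrix(mu_vec, ng, n) +
      matrix(stats::rnorm(ng * n, 0, cfg$noise_sd), ng, n)
    mu[mu < 0] <- 0
    lib <- round(stats::rlnorm(n, log(cfg$lib_size_mean), cfg$lib_size_sdlog))
    keep <- matrix(stats::rbinom(ng * n, 1L, detect_prob(mu, cfg)), ng, n)
    if (!is.null(extra_drop))
      keep <- keep * matrix(stats::rbinom(ng * n, 1L, 1 - extra_drop), ng, n)
    lam <- sweep((2^mu - 1) / 1e6 * keep, 2, lib, "*")
    cnt <- matrix(stats::rpois(ng * n, lam), ng, n,
                  dimnames = list(gene_ids, sprintf("%s_%02d", prefix, 1:n)))
    cnt
  }
  # analytic fresh detection probability at the mean library size, used to
  # convert the absolute planted gap into an extra dropout probability
  p_fresh <- detect_prob(mu0, cfg) *
    (1 - exp(-(2^mu0 - 1) / 1e6 * cfg$lib_size_mean))
  extra <- rep(0, ng)
  extra[det_genes] <- pmin(0.95, cfg$detect_drop / pmax(p_fresh[det_genes], 1e-6))
  fresh_cnt <- draw_arm(mu0, NULL, "fresh")
  sect_cnt <- draw_arm(mu0, extra, "sect")
  # expression bias: binomial thinning of recovered reads by 2^bias
  thin <- 2^cfg$bias_log2
  if (thin <= 1) {
    sect_cnt[bias_genes, ] <- matrix(
      stats::rbinom(length(bias_genes) * n, sect_cnt[bias_genes, ], thin),
      length(bias_genes), n)
  } else {
    fresh_cnt[bias_genes, ] <- matrix(
      stats::rbinom(length(bias_genes) * n, fresh_cnt[bias_genes, ], 1 / thin),
      length(bias_genes), n)
  }
  fresh <- count_matrix(fresh_cnt)
  section <- count_matrix(sect_cnt)
  truth <- list(
    kind = "fresh_vs_section", seed = seed,
    detect_artifacts = gene_ids[det_genes],
    planted_gap = cfg$detect_drop,
    bias_artifacts = gene_ids[bias_genes],
    planted_bias = cfg$bias_log2,
    base_log2 = stats::setNames(mu0, gene_ids))
  list(fresh = fresh, section = section, truth = truth)
}

#' Simulate ERCC spike-in read counts from known copies
#'
#' `counts ~ Poisson(efficiency x copies x scale)`; in expectation mode
#' the Poisson draw is skipped and the (rounded) expectation returned.
#'
#' @param reference data.frame from [ercc_reference()].
#' @param capture_efficiency fraction of copies converted to reads, in
#'   (0, 1].
#' @param scale reads per captured copy (sequencing depth factor), > 0.
#' @param seed integer seed.
#' @param expectation logical; skip sampling.
#' @return named numeric vector of spike counts; attributes record
#'   efficiency and scale.
#' @export
gen_ercc_counts <- function(reference = ercc_reference(),
                            capture_efficiency = 0.1, scale = 10,
                            seed = 1L, expectation = FALSE) {
  if (any(reference$copies <= 0)) stop("copies must be > 0")
  if (capture_efficiency <= 0 || capture_efficiency > 1)
    stop("capture_efficiency in (0, 1]")
  if (scale <= 0) stop("non-positive scale")
  lam <- capture_efficiency * reference$copies * scale
  cnt <- if (expectation) lam else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(stream_seed(seed, 505L))
    stats::rpois(length(lam), lam)
  }
  structure(stats::setNames(cnt, reference$spike_id),
            efficiency = capture_efficiency, scale = scale)
}

#' Simulate a qPCR Ct plate with planted amplification failures
#'
#' Successful wells draw `Normal(base_ct, sd)`; failed wells are shifted
#' by `+failure_shift` cycles (failures have less template, hence higher
#' Ct).
#'
#' @param n wells (>= 3).
#' @param base_ct,sd success distribution.
#' @param n_failures planted failures (< n).
#' @param failure_shift positive Ct shift of failures.
#' @param seed integer seed.
#' @return list with `ct` (numeric vector) and `failed` (logical truth).
#' @export
gen_ct_plate <- function(n = 48L, base_ct = 20, sd = 0.5, n_failures = 0L,
                         failure_shift = 8, seed = 1L) {
  if (n < 3) stop("n >= 3 required")
  if (n_failures >= n) stop("n_failures must be < n")
  if (failure_shift <= 0) stop("failure_shift must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, 606L))
  ct <- stats::rnorm(n, base_ct, sd)
  failed <- rep(FALSE, n)
  if (n_failures > 0) {
    failed[sample.int(n, n_failures)] <- TRUE
    ct[failed] <- ct[failed] + failure_shift
  }
  list(ct = ct, failed = failed)
}

#' Simulate an exon/junction count table with 3'-biased coverage
#'
#' Each gene carries 1-3 transcripts sharing 3'-end exons (transcripts
#' differ in how far they extend toward the 5' end). Expected exon
#' counts decay exponentially with the exon's distance from the 3' end
#' (`halflife` exons); junction counts derive from the flanking exons'
#' rates. Exon counts per chosen transcript are drawn so that ~94% of
#' genes have <= 20 exons.
#'
#' @param n_genes genes.
#' @param n_samples cells/samples.
#' @param base_log2 expected log2 count of a 3'-terminal exon (per-gene
#'   spread sd 1.5; the low absolute coverage puts the TMM > 2
#'   detectability boundary inside the 3'-5' decay, as in shallow
#'   per-exon data).
#' @param halflife 3' decay half-life, in exons.
#' @param seed integer seed.
#' @return list with `model` (data.frame: gene, transcript, exon_index
#'   from the 3' end, exon_id), `counts` (exon+junction count matrix,
#'   junction ids `"exonA|exonB"`) and `truth` (per-exon expected rate).
#' @export
gen_exon_table <- function(n_genes = 150L, n_samples = 5L, base_log2 = 1,
                           halflife = 5, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, 707L))
  rows <- list(); lam_exon <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%04d", g)
    # ~94% of genes <= 20 exons: geometric-ish exon count, 1..40
    n_ex_gene <- min(40L, 1L + stats::rgeom(1, 1 / 7))
    n_tx <- sample.int(3L, 1)
    lens <- sort(unique(pmax(1L, round(n_ex_gene * seq(1, 0.5, length.out = n_tx)))),
                 decreasing = TRUE)
    base <- base_log2 + stats::rnorm(1, 0, 1.5)
    for (t in seq_along(lens)) {
      tid <- sprintf("%s_t%d", gid, t)
      idx <- seq_len(lens[t])           # 1 = 3'-terminal exon, shared
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gid, transcript = tid, exon_index = idx,
        exon_id = sprintf("%s_e%02d", gid, idx))
    }
    lam_exon[[gid]] <- 2^(base - seq_len(max(lens)) / halflife * 1) |>
      stats::setNames(sprintf("%s_e%02d", gid, seq_len(max(lens))))
  }
  model <- do.call(rbind, rows)
  exon_ids <- unique(model$exon_id)
  lam <- unlist(lam_exon, use.names = TRUE)
  names(lam) <- sub("^g[0-9]+\\.", "", names(lam))
  lam <- lam[exon_ids]
  cnt_ex <- matrix(stats::rpois(length(lam) * n_samples, rep(lam, n_samples)),
                   length(lam), n_samples,
                   dimnames = list(exon_ids, sprintf("s%02d", seq_len(n_samples))))
  # junctions between consecutive exons within each transcript
  jrows <- unique(do.call(rbind, lapply(split(model, model$transcript), function(tx) {
    tx <- tx[order(tx$exon_index), ]
    if (nrow(tx) < 2) return(NULL)
    data.frame(a = tx$exon_id[-nrow(tx)], b = tx$exon_id[-1])
  })))
  if (!is.null(jrows) && nrow(jrows)) {
    lam_j <- 0.5 * pmin(lam[jrows$a], lam[jrows$b])
    jid <- paste0(jrows$a, "|", jrows$b)
    cnt_j <- matrix(stats::rpois(length(lam_j) * n_samples,
                                 rep(lam_j, n_samples)),
                    length(lam_j), n_samples,
                    dimnames = list(jid, colnames(cnt_ex)))
    cnt <- rbind(cnt_ex, cnt_j)
  } else cnt <- cnt_ex
  list(model = model, counts = cnt,
       truth = list(expected_rate = lam, halflife = halflife, seed = seed))
}
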