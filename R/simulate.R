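# Synthetic-data generator: every input the pipeline consumes, with known
# planted truth. The stated world is a clonal diatom ancestor whose only
# standing variation is heterozygosity at frequency 0.5, evolved as pooled
# populations under four thermal regimes, pooled-resequenced at mean depth
# ~25x with a realistic Illumina error rate of 0.1% per read; thermal
# performance assayed on a 4-45 C grid in 3 C steps with 6 biological
# replicates and ~10% multiplicative rate noise; P-I curves on the
# 0-2000 umol quanta m^-2 s^-1 step ladder; logistic growth series from a
# 100 cells/mL inoculum.

#' Simulation configuration
#'
#' Collects seeds, depths, error rates, planted truth and curve
#' parameters for all synthetic-data generators. Defaults are the stated
#' experimental world; override any field by name.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_treatments Number of selection regimes (default 4).
#' @param n_replicates_per_treatment Pooled populations per regime
#'   (default 3).
#' @param n_sites Total candidate SNV sites (default 1200).
#' @param n_het_sites Sites heterozygous (frequency 0.5) in the ancestor
#'   (default 1000).
#' @param n_denovo_per_population De-novo fixations (0 -> 1) planted per
#'   evolved population (default 5).
#' @param n_hetfix_per_population Heterozygosity-loss fixations
#'   (0.5 -> 1) planted per evolved population (default 20).
#' @param mean_depth Poisson rate of per-site read depth (default 25).
#' @param error_rate Per-read base substitution probability (default
#'   0.001; must be < 0.5).
#' @param qual_floor Additive floor of the simulated QUAL (QUAL =
#'   qual_floor + depth, a monotone function of depth; default 35 so
#'   non-degenerate records pass the default filter).
#' @param n_indels Indel records planted per sample to exercise the
#'   SnpGap filter (default 2).
#' @param tpc_truth Named list mapping treatment to an [ss_params()]
#'   truth; default: identical ancestor-like curves (Ea 1.08 eV, Eh 3.5
#'   eV, Th 303.15 K, rate 0.55 day^-1 at 18 C) in every treatment.
#' @param temp_grid_c Assay temperatures, default `seq(4, 45, by = 3)`.
#' @param n_tpc_replicates Biological replicates per treatment for rate
#'   assays (default 6).
#' @param rate_noise_sd SD of multiplicative lognormal rate noise
#'   (default 0.1).
#' @param pi_truth [pi_params()] truth for the P-I curve (default NPmax
#'   10, alpha 0.1, Iopt 400, R 2).
#' @param irradiance_grid Irradiance ladder (default 0-300 by 50, to 1000
#'   by 100, to 2000 by 200).
#' @param pi_noise_sd SD of additive Gaussian noise on O2 fluxes
#'   (default 0.2).
#' @param growth_truth List `(k, r, n0)` for logistic series (default
#'   1e6 cells/mL, 0.8 day^-1, 100 cells/mL).
#' @param time_grid Sampling days for growth series (default 12 points,
#'   days 0-22).
#' @param growth_noise_cv CV of multiplicative lognormal count noise
#'   (default 0.05).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_treatments = 4,
                       n_replicates_per_treatment = 3,
                       n_sites = 1200,
                       n_het_sites = 1000,
                       n_denovo_per_population = 5,
                       n_hetfix_per_population = 20,
                       mean_depth = 25,
                       error_rate = 0.001,
                       qual_floor = 35,
                       n_indels = 2,
                       tpc_truth = NULL,
                       temp_grid_c = seq(4, 45, by = 3),
                       n_tpc_replicates = 6,
                       rate_noise_sd = 0.1,
                       pi_truth = pi_params(np_max = 10, alpha = 0.1, i_opt = 400, r = 2),
                       irradiance_grid = c(seq(0, 300, by = 50),
                                           seq(400, 1000, by = 100),
                                           seq(1200, 2000, by = 200)),
                       pi_noise_sd = 0.2,
                       growth_truth = list(k = 1e6, r = 0.8, n0 = 100),
                       time_grid = seq(0, 22, by = 2),
                       growth_noise_cv = 0.05) {
  if (error_rate < 0 || error_rate >= 0.5) stop_input("'error_rate' must satisfy 0 <= e < 0.5")
  if (mean_depth <= 0) stop_input("'mean_depth' must be positive")
  if (n_het_sites > n_sites) stop_input("'n_het_sites' cannot exceed 'n_sites'")
  if (n_hetfix_per_population + n_denovo_per_population > n_sites) {
    stop_input("planted fixations exceed 'n_sites'")
  }
  if (n_hetfix_per_population > n_het_sites) {
    stop_input("'n_hetfix_per_population' cannot exceed 'n_het_sites'")
  }
  if (n_denovo_per_population > n_sites - n_het_sites) {
    stop_input("'n_denovo_per_population' cannot exceed the non-heterozygous site count")
  }
  treatments <- c("22C", "26C", "32C", "FS")[seq_len(min(n_treatments, 4))]
  if (n_treatments > 4) treatments <- c(treatments, paste0("T", 5:n_treatments))
  if (is.null(tpc_truth)) {
    tpc_truth <- setNames(rep(list(
      ss_params(ln_b_tc = log(0.55), ea = 1.08, eh = 3.5, th = 303.15)),
      length(treatments)), treatments)
  }
  structure(list(
    seed = as.integer(seed), treatments = treatments,
    n_replicates_per_treatment = n_replicates_per_treatment,
    n_sites = n_sites, n_het_sites = n_het_sites,
    n_denovo_per_population = n_denovo_per_population,
    n_hetfix_per_population = n_hetfix_per_population,
    mean_depth = mean_depth, error_rate = error_rate,
    qual_floor = qual_floor, n_indels = n_indels,
    tpc_truth = tpc_truth, temp_grid_c = temp_grid_c,
    n_tpc_replicates = n_tpc_replicates, rate_noise_sd = rate_noise_sd,
    pi_truth = pi_truth, irradiance_grid = irradiance_grid,
    pi_noise_sd = pi_noise_sd, growth_truth = growth_truth,
    time_grid = time_grid, growth_noise_cv = growth_noise_cv),
    class = "sim_config")
}

# read counts for one sample: depth Poisson(lambda) floored at 1, alt
# count binomial with the symmetric single-parameter error substitution
draw_reads <- function(f, lambda, err) {
  d <- pmax(rpois(length(f), lambda), 1L)
  p <- f * (1 - err) + (1 - f) * err
  a <- rbinom(length(f), d, p)
  list(d = d, a = a)
}

#' Simulate pooled-resequencing variant records with planted truth
#'
#' Generates one ancestor pool plus one evolved pool per treatment x
#' replicate. Ancestral allele frequencies are 0.5 at the heterozygous
#' sites and 0 elsewhere; each evolved population independently receives
#' planted heterozygosity-loss fixations (0.5 -> 1) and de-novo fixations
#' (0 -> 1). Per site and sample, depth `D ~ Poisson(mean_depth)` floored
#' at 1 and alt count `A ~ Binomial(D, f(1-e) + (1-f)e)`. QUAL is
#' `qual_floor + D`; indel records (with IDV) are planted near a few SNV
#' sites to exercise the SnpGap filter.
#'
#' @param config A [sim_config()].
#' @return List of class `pool_seq_sim`: `records`
#'   ([variant_records()]), `truth` (site, population, category, f_anc,
#'   f_evo; one row per site per evolved population), `samples` manifest
#'   (sample, treatment, replicate), `config`.
#' @export
simulate_pool_seq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_sites
  bases <- c("A", "C", "G", "T")
  pos <- 1000L + (seq_len(n) - 1L) * 50L
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  chrom <- rep("contig_1", n)
  sid <- paste(chrom, pos, sep = ":")

  het_sites <- sort(sample.int(n, config$n_het_sites))
  f_anc <- numeric(n)
  f_anc[het_sites] <- 0.5
  non_het <- setdiff(seq_len(n), het_sites)

  evolved <- expand.grid(replicate = seq_len(config$n_replicates_per_treatment),
                         treatment = config$treatments,
                         stringsAsFactors = FALSE)
  evolved$sample <- sprintf("%s_r%d", evolved$treatment, evolved$replicate)
  samples <- rbind(
    data.frame(sample = "anc_t0", treatment = "ancestor", replicate = 0L,
               stringsAsFactors = FALSE),
    evolved[, c("sample", "treatment", "replicate")])

  # indel positions: offset 4 bp from the first n_indels sites (within the
  # 10 bp SnpGap window, so those SNVs are dropped by the default filter)
  indel_near <- seq_len(min(config$n_indels, n))
  indel_pos <- pos[indel_near] + 4L

  rec <- list()
  truth <- list()
  anc_reads <- draw_reads(f_anc, config$mean_depth, config$error_rate)
  rec[["anc_t0"]] <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = config$qual_floor + anc_reads$d, is_indel = FALSE, idv = NA_integer_,
    sample = "anc_t0", dp = anc_reads$d, ad_ref = anc_reads$d - anc_reads$a,
    ad_alt = anc_reads$a, stringsAsFactors = FALSE)

  for (i in seq_len(nrow(evolved))) {
    s <- evolved$sample[i]
    f_evo <- f_anc
    hetfix <- sample(het_sites, config$n_hetfix_per_population)
    denovo <- sample(non_het, config$n_denovo_per_population)
    f_evo[hetfix] <- 1
    f_evo[denovo] <- 1
    reads <- draw_reads(f_evo, config$mean_depth, config$error_rate)
    rec[[s]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      qual = config$qual_floor + reads$d, is_indel = FALSE, idv = NA_integer_,
      sample = s, dp = reads$d, ad_ref = reads$d - reads$a,
      ad_alt = reads$a, stringsAsFactors = FALSE)
    category <- rep("absent", n)
    category[f_anc == 0.5] <- "unchanged_het"
    category[hetfix] <- "het_origin_fixed"
    category[denovo] <- "de_novo_fixed"
    truth[[s]] <- data.frame(site = sid, population = s, category = category,
                             f_anc = f_anc, f_evo = f_evo,
                             stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, rec)
  if (length(indel_pos)) {
    indels <- do.call(rbind, lapply(samples$sample, function(s) {
      d <- pmax(rpois(length(indel_pos), config$mean_depth), 1L)
      data.frame(chrom = "contig_1", pos = indel_pos,
                 ref = "A", alt = "AT",
                 qual = config$qual_floor + d, is_indel = TRUE,
                 idv = pmax(2L, as.integer(round(d / 2))),
                 sample = s, dp = d, ad_ref = as.integer(round(d / 2)),
                 ad_alt = d - as.integer(round(d / 2)),
                 stringsAsFactors = FALSE)
    }))
    records <- rbind(records, indels)
  }
  records <- records[order(records$sample, records$chrom, records$pos), ]
  rownames(records) <- NULL

  structure(list(records = variant_records(records),
                 truth = do.call(rbind, truth),
                 samples = samples, config = config),
            class = "pool_seq_sim")
}

#' Simulate thermal performance rate observations
#'
#' Rates are the treatment's Sharpe-Schoolfield truth evaluated on the
#' assay temperature grid, multiplied by lognormal noise
#' `exp(N(0, rate_noise_sd))`, replicated per biological replicate.
#'
#' @param config A [sim_config()].
#' @param flux Flux label recorded in the table (default `"growth"`).
#' @return data.frame: `temp_c`, `rate`, `flux`, `replicate`,
#'   `treatment`.
#' @export
simulate_tpc_data <- function(config, flux = "growth") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  grid <- expand.grid(temp_c = config$temp_grid_c,
                      replicate = seq_len(config$n_tpc_replicates),
                      treatment = config$treatments,
                      stringsAsFactors = FALSE)
  mu <- vapply(seq_len(nrow(grid)), function(i) {
    ss_log_rate(c_to_k(grid$temp_c[i]), config$tpc_truth[[grid$treatment[i]]])
  }, numeric(1))
  grid$rate <- exp(mu) * rlnorm(nrow(grid), 0, config$rate_noise_sd)
  grid$flux <- flux
  grid[, c("temp_c", "rate", "flux", "replicate", "treatment")]
}

#' Simulate photosynthesis-irradiance curves
#'
#' Net O2 flux from the photoinhibition truth on the irradiance ladder,
#' with additive Gaussian noise (`pi_noise_sd`), per treatment and
#' replicate.
#'
#' @param config A [sim_config()].
#' @return data.frame: `irradiance`, `net_o2`, `replicate`, `treatment`.
#' @export
simulate_pi_curves <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  grid <- expand.grid(irradiance = config$irradiance_grid,
                      replicate = seq_len(config$n_tpc_replicates),
                      treatment = config$treatments,
                      stringsAsFactors = FALSE)
  truth <- np_at_irradiance(grid$irradiance, config$pi_truth)
  grid$net_o2 <- truth + rnorm(nrow(grid), 0, config$pi_noise_sd)
  grid[, c("irradiance", "net_o2", "replicate", "treatment")]
}

#' Simulate logistic growth time series
#'
#' Cell counts from the logistic truth on the sampling grid, with
#' multiplicative lognormal noise of coefficient of variation
#' `growth_noise_cv`, per treatment and replicate.
#'
#' @param config A [sim_config()].
#' @return data.frame: `time_days`, `cells_per_ml`, `replicate`,
#'   `treatment`.
#' @export
simulate_growth_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  g <- config$growth_truth
  grid <- expand.grid(time_days = config$time_grid,
                      replicate = seq_len(config$n_tpc_replicates),
                      treatment = config$treatments,
                      stringsAsFactors = FALSE)
  truth <- logistic_growth(grid$time_days, g$k, g$r, g$n0)
  sdlog <- sqrt(log(1 + config$growth_noise_cv^2))
  grid$cells_per_ml <- truth * rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  grid[, c("time_days", "cells_per_ml", "replicate", "treatment")]
}
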