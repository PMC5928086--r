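test_that("distance_matrix computes squared Euclidean distances with masking", {
  fm <- cbind(s1 = c(0, 0.5, 1), s2 = c(0, 0.5, 0), s3 = c(0, 0.5, 1))
  rownames(fm) <- paste0("l", 1:3)
  d <- distance_matrix(fm)
  expect_equal(d["s1", "s2"], 1)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), colnames(fm)))
  # masked locus dropped before distances
  fm2 <- fm; fm2[3, 2] <- NA
  expect_message(d2 <- distance_matrix(fm2), "dropping 1")
  expect_equal(d2["s1", "s2"], 0)
  expect_error(distance_matrix(fm[, 1, drop = FALSE]), "2 samples")
})

test_that("two-level AMOVA matches a raw-data sums-of-squares oracle", {
  fm <- toy_freq_matrix(n_loci = 10, n_per_group = 3, seed = 3)
  treat <- toy_groups(3)
  res <- amova(distance_matrix(fm), treat, n_perm = 99, seed = 1)
  # oracle: per-locus ANOVA on the raw frequencies (independent of the
  # distance-matrix route)
  x <- t(fm)
  ss_t <- sum(scale(x, scale = FALSE)^2)
  ss_w <- sum(vapply(unique(treat), function(g) {
    sum(scale(x[treat == g, ], scale = FALSE)^2)
  }, numeric(1)))
  ss_b <- ss_t - ss_w
  ms_w <- ss_w / 4; ms_b <- ss_b / 1
  n0 <- (6 - (9 + 9) / 6) / 1
  tab <- res$table
  expect_equal(tab$ss[tab$component == "among_populations"], ss_w, tolerance = 1e-10)
  expect_equal(tab$ss[tab$component == "between_treatments"], ss_b, tolerance = 1e-10)
  expect_equal(tab$sigma2_raw[tab$component == "among_populations"], ms_w,
               tolerance = 1e-10)
  expect_equal(tab$sigma2_raw[tab$component == "between_treatments"],
               (ms_b - ms_w) / n0, tolerance = 1e-10)
  expect_equal(sum(tab$percent[tab$component != "total"]), 100, tolerance = 0.01)
})

test_that("three-level AMOVA partitions within-population variance", {
  set.seed(9)
  # 2 treatments x 2 populations x 3 sub-replicates
  n_loci <- 25
  treat <- rep(c("A", "B"), each = 6)
  pop <- rep(c("p1", "p2", "p3", "p4"), each = 3)
  pop_eff <- matrix(rnorm(n_loci * 4, 0, 0.15), n_loci, 4)
  fm <- sapply(seq_along(treat), function(i) {
    base <- ifelse(treat[i] == "A", 0.3, 0.7)
    base + pop_eff[, match(pop[i], unique(pop))] + rnorm(n_loci, 0, 0.05)
  })
  dimnames(fm) <- list(paste0("l", 1:n_loci), paste0("s", seq_along(treat)))
  res <- amova(distance_matrix(fm), treat, pop, n_perm = 199, seed = 5)
  tab <- res$table
  expect_setequal(tab$component,
                  c("within_populations", "among_populations",
                    "between_treatments", "total"))
  expect_equal(sum(tab$percent[tab$component != "total"]), 100, tolerance = 0.01)
  # strong planted treatment effect detected
  expect_lt(tab$p_value[tab$component == "between_treatments"], 0.05)
  # SS additivity against the direct total
  d2 <- distance_matrix(fm)
  ss_total <- sum(d2[upper.tri(d2)]) / ncol(fm)
  expect_equal(tab$ss[tab$component == "total"], ss_total, tolerance = 1e-10)
})

test_that("AMOVA handles degenerate input contracts", {
  fm <- toy_freq_matrix(n_loci = 8, n_per_group = 3, seed = 2)
  dm <- distance_matrix(fm)
  expect_error(amova(dm, rep("A", 6)), "treatment")
  # identical samples: zero components, percentages flagged undefined
  fm0 <- matrix(0.5, 6, 4, dimnames = list(paste0("l", 1:6), paste0("s", 1:4)))
  expect_warning(res0 <- amova(distance_matrix(fm0), rep(c("A", "B"), each = 2),
                               n_perm = 19),
                 "undefined")
  expect_true(all(res0$table$sigma2 == 0))
})

test_that("AMOVA permutation p-values are seed-stable and calibrated under the null", {
  fm <- toy_freq_matrix(n_loci = 20, n_per_group = 3, seed = 6)
  dm <- distance_matrix(fm)
  treat <- toy_groups(3)
  p1 <- amova(dm, treat, n_perm = 99, seed = 42)$table$p_value
  p2 <- amova(dm, treat, n_perm = 99, seed = 42)$table$p_value
  expect_identical(p1, p2)
  # null calibration: labels carry no signal; reject at ~5%
  set.seed(10)
  pvals <- replicate(120, {
    fmn <- matrix(runif(15 * 6, 0.2, 0.8), 15, 6,
                  dimnames = list(paste0("l", 1:15), paste0("s", 1:6)))
    tab <- amova(distance_matrix(fmn), treat, n_perm = 99)$table
    tab$p_value[tab$component == "between_treatments"]
  })
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 120) + 1e-9)
})

test_that("PERMANOVA and dispersion tests behave on planted structure", {
  # identical groups: pseudo-F ~ 0, p ~ 1
  fm_same <- matrix(rep(c(0.2, 0.5, 0.8), 6), 3, 6,
                    dimnames = list(paste0("l", 1:3), paste0("s", 1:6)))
  dm_same <- distance_matrix(fm_same)
  res_same <- permanova(dm_same, toy_groups(3), n_perm = 99, seed = 1)
  expect_true(is.na(res_same$pseudo_f) || res_same$pseudo_f < 1e-8 ||
                res_same$p_value > 0.9)

  # planted shift well above noise: detected
  fm_shift <- toy_freq_matrix(n_loci = 30, n_per_group = 4, shift = 0.4,
                              n_shift = 15, noise = 0.03, seed = 8)
  dm_shift <- distance_matrix(fm_shift)
  res <- permanova(dm_shift, toy_groups(4), n_perm = 199, seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$pseudo_f, 1)

  # dispersion: singleton group flagged
  expect_warning(dispersion_test(dm_shift, c(rep("A", 7), "B"), n_perm = 19),
                 "singleton")
  disp <- dispersion_test(dm_shift, toy_groups(4), n_perm = 199, seed = 3)
  expect_true(is.finite(disp$f))
  expect_true(!is.null(disp$tukey))
  expect_error(permanova(dm_shift, rep("A", 8)), "2 groups")
})

test_that("PCA equals principal coordinates on Euclidean distances", {
  fm <- toy_freq_matrix(n_loci = 25, n_per_group = 3, shift = 0.3,
                        n_shift = 5, seed = 12)
  p <- pca(fm)
  # score distances reproduce the plain distance matrix
  d_scores <- as.matrix(dist(p$scores))
  d_plain <- sqrt(distance_matrix(fm))
  expect_equal(max(abs(d_scores - d_plain)), 0, tolerance = 1e-8)
  # variance fractions non-increasing, sum <= 1; loadings orthonormal
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-9)
  g <- crossprod(p$loadings)
  expect_equal(g, diag(nrow(g)), tolerance = 1e-8, ignore_attr = TRUE)

  # 2-sample matrix: single nonzero component, separation = distance
  fm2 <- cbind(a = c(0, 1, 0.5), b = c(1, 0, 0.5))
  rownames(fm2) <- paste0("l", 1:3)
  p2 <- pca(fm2)
  expect_equal(p2$var_explained[1], 1)
  expect_equal(unname(abs(diff(p2$scores[, 1]))), sqrt(2), tolerance = 1e-10)
  expect_warning(pca(matrix(0.5, 3, 3, dimnames = list(1:3, 1:3))), "constant")
})

test_that("top loadings associate with the treatment that drives them", {
  set.seed(20)
  n_loci <- 50
  treat <- rep(c("X", "Y"), each = 3)
  fm <- matrix(runif(n_loci * 6, 0.45, 0.55), n_loci, 6,
               dimnames = list(paste0("l", 1:n_loci), paste0("s", 1:6)))
  # 5 diagnostic loci fixed in all and only treatment-X samples
  fm[1:5, treat == "X"] <- 1
  fm[1:5, treat == "Y"] <- 0
  p <- pca(fm)
  assoc <- top_loading_associations(p, fm, treat, n_top = 5, components = 1)
  expect_setequal(assoc$locus, paste0("l", 1:5))
  expect_true(all(assoc$treatment == "X"))
  # n_top = 0 gives an empty list; over-large n_top truncates
  expect_equal(nrow(top_loading_associations(p, fm, treat, n_top = 0)), 0)
  expect_warning(big <- top_loading_associations(p, fm, treat, n_top = 500,
                                                 components = 1),
                 "truncat")
  expect_equal(nrow(big), n_loci)
})

test_that("weighted KS enrichment separates high-scoring terms", {
  universe <- paste0("g", 1:100)
  scores <- setNames(seq(1, 0.1, length.out = 10), paste0("g", 1:10))
  ann <- rbind(
    data.frame(gene = paste0("g", 1:5), term = "hot"),     # the 5 top scorers
    data.frame(gene = paste0("g", 51:70), term = "cold"),  # unscored genes
    data.frame(gene = universe, term = "everything"))
  res <- weighted_ks_enrichment(scores, ann, universe)
  expect_lt(res$ks_p[res$term == "hot"], 0.01)
  # term = entire universe: no outside genes, D = 0, p = 1
  expect_equal(res$ks_p[res$term == "everything"], 1)
  expect_equal(res$ks_d[res$term == "everything"], 0)
  # column arithmetic: Exp = Ann * |scored| / |universe|
  expect_equal(res$ann[res$term == "hot"], 5)
  expect_equal(res$sig[res$term == "hot"], 5)
  expect_equal(res$exp[res$term == "hot"], 5 * 10 / 100)
  expect_equal(res$sig[res$term == "cold"], 0)
  # the Exp formula at catalogue scale: Ann=12, |sig|=10, universe=6000
  uni2 <- paste0("u", 1:6000)
  sc2 <- setNames(runif(10), paste0("u", 1:10))
  ann2 <- data.frame(gene = paste0("u", 100:111), term = "t")
  res2 <- weighted_ks_enrichment(sc2, ann2, uni2)
  expect_equal(res2$exp, 12 * 10 / 6000)
  # annotation outside the universe is rejected
  expect_error(weighted_ks_enrichment(sc2, data.frame(gene = "zz", term = "t"),
                                      uni2), "outside")
})

test_that("pipeline end-to-end: simulation to AMOVA and PCA association", {
  cfg <- sim_config(seed = 17, n_sites = 300, n_het_sites = 250,
                    n_replicates_per_treatment = 3, n_treatments = 2)
  sim <- simulate_pool_seq(cfg)
  calls <- call_fixation(sim$records, "anc_t0")
  evolved <- setdiff(sim$samples$sample, "anc_t0")
  fm <- build_frequency_matrix(sim$records, evolved, fixed_only = TRUE,
                               calls = calls)
  expect_gt(nrow(fm), 0)
  dm <- distance_matrix(fm)
  treat <- sim$samples$treatment[match(colnames(fm), sim$samples$sample)]
  res <- amova(dm, treat, n_perm = 99, seed = 1)
  expect_equal(sum(res$table$percent[res$table$component != "total"]), 100,
               tolerance = 0.01)
  p <- pca(fm)
  assoc <- top_loading_associations(p, fm, treat, n_top = 10)
  expect_equal(nrow(assoc), 20)
})
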