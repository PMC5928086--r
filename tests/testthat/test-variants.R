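test_that("filter_variants hand-applies every rule on a toy record set", {
  rec <- toy_records(list(
    list(1000, 50, 20, 10),               # clean SNV
    list(1100, 34.9, 20, 10),             # fails QUAL
    list(1200, 50, 20, 10, indel = TRUE, idv = 5), # indel record, dropped
    list(1208, 50, 20, 10),               # SNV 8 bp from the indel: SnpGap
    list(1300, 50, 20, 10),               # clean SNV
    list(1400, 50, 4, 2)                  # fails DP
  ))
  kept <- filter_variants(rec)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pos, c(1000, 1300))
})

test_that("filter boundaries are inclusive and SnpGap window is 10 bp", {
  rec <- toy_records(list(
    list(1000, 35.0, 5, 3),                      # both thresholds exactly met
    list(2000, 50, 20, 10, indel = TRUE, idv = 2),
    list(2010, 50, 20, 10),                      # exactly 10 bp away: dropped
    list(2011, 50, 20, 10)                       # 11 bp away: retained
  ))
  kept <- filter_variants(rec)
  expect_equal(kept$pos, c(1000, 2011))
  # IDV missing on an SNV passes; IDV below threshold fails
  rec2 <- toy_records(list(list(1000, 50, 20, 10, idv = 1L),
                           list(1100, 50, 20, 10)))
  expect_equal(filter_variants(rec2)$pos, 1100)
})

test_that("filter_variants is idempotent and validates sorting", {
  rec <- toy_records(list(list(1000, 50, 20, 10), list(1100, 34, 20, 10),
                          list(1200, 50, 20, 10, indel = TRUE, idv = 5)))
  once <- filter_variants(rec)
  expect_identical(filter_variants(once), once)
  bad <- rec[c(3, 1, 2), ]
  class(bad) <- c("variant_records", "data.frame")
  expect_error(filter_variants(bad), "sorted")
})

test_that("Clopper-Pearson CI reproduces the depth-dependent half-widths", {
  ci <- estimate_allele_frequency(c(5, 25, 50), c(10, 50, 100))
  expect_equal(ci$f_hat, c(0.5, 0.5, 0.5))
  expect_equal(round((ci$ci_high - ci$ci_low) / 2, 2), c(0.31, 0.14, 0.10))
  # normal approximation matches at 2 d.p. too
  cin <- estimate_allele_frequency(c(5, 25, 50), c(10, 50, 100), method = "normal")
  expect_equal(round((cin$ci_high - cin$ci_low) / 2, 2), c(0.31, 0.14, 0.10))
  # boundary cases
  b <- estimate_allele_frequency(10, 10)
  expect_equal(b$f_hat, 1)
  expect_equal(b$ci_high, 1)
  z <- estimate_allele_frequency(0, 0)
  expect_true(is.na(z$f_hat))
  expect_error(estimate_allele_frequency(5, 4), "a <= d")
})

test_that("95% CI covers the truth 94-97% of the time at D=30, f=0.4", {
  set.seed(123)
  a <- rbinom(10000, 30, 0.4)
  ci <- estimate_allele_frequency(a, rep(30, 10000))
  cover <- mean(ci$ci_low <= 0.4 & ci$ci_high >= 0.4)
  expect_gte(cover, 0.94)
  expect_lte(cover, 0.97)
})

test_that("detection-error probabilities match the binomial tail arithmetic", {
  expect_equal(round(prob_missed_het(10), 5), 0.00098)
  expect_equal(prob_missed_het(1), 0.5)
  expect_equal(prob_missed_het(20), 9.5367431640625e-07)
  expect_equal(prob_false_fixation(5, 0.01), 1e-10)
  expect_equal(prob_false_fixation(0, 0.37), 1)
  expect_equal(prob_false_fixation(5, 0.001), 1e-15)
  # strictly decreasing in depth
  d <- 0:40
  expect_true(all(diff(prob_missed_het(d)) < 0))
  expect_true(all(diff(prob_false_fixation(d, 0.01)) < 0))
})

test_that("call_fixation classifies the canonical criterion cases", {
  mk <- function(anc_a, anc_d, evo_a, evo_d) {
    anc <- toy_records(list(list(1000, 50, anc_d, anc_a)), sample = "anc")
    evo <- toy_records(list(list(1000, 50, evo_d, evo_a)), sample = "evo1")
    variant_records(rbind(anc, evo))
  }
  # de novo: ancestor 0/12, evolved 7/7
  call <- call_fixation(mk(0, 12, 7, 7), "anc")
  expect_equal(call$category, "de_novo_fixed")
  expect_true(all(unlist(call[, c("crit_i", "crit_ii", "crit_iii", "crit_iv", "crit_v")])))
  # het origin: ancestor 5/10, evolved 6/6
  expect_equal(call_fixation(mk(5, 10, 6, 6), "anc")$category, "het_origin_fixed")
  # ancestor depth below 10 -> not assessable
  expect_equal(call_fixation(mk(0, 8, 5, 5), "anc")$category, "not_assessable")
  # evolved depth below 5 -> not assessable
  expect_equal(call_fixation(mk(0, 12, 4, 4), "anc")$category, "not_assessable")
  # one non-alt read breaks criterion (iv)
  expect_equal(call_fixation(mk(0, 12, 6, 7), "anc")$category, "not_fixed")
  # het window boundary is inclusive: 3/10 = 0.3
  expect_equal(call_fixation(mk(3, 10, 6, 6), "anc")$category, "het_origin_fixed")
  # outside window: 2/10 = 0.2, evolved fixed -> not fixed under (ii)
  expect_equal(call_fixation(mk(2, 10, 6, 6), "anc")$category, "not_fixed")
  expect_error(call_fixation(mk(0, 12, 7, 7), "nope"), "unknown ancestor")
})

test_that("criterion (v) requires a filter pass in at least one population", {
  anc <- toy_records(list(list(1000, 50, 12, 0)), sample = "anc")
  evo <- toy_records(list(list(1000, 20, 7, 7)), sample = "evo1") # QUAL fails
  call <- call_fixation(variant_records(rbind(anc, evo)), "anc")
  expect_false(call$crit_v)
  expect_equal(call$category, "not_fixed")
})

test_that("coding-effect annotation translates codons strand-aware", {
  genome <- c(c1 = "NNATGGCTTGGTAANN") # CDS 3..14: ATG GCT TGG TAA
  gm <- data.frame(gene = "g1", chrom = "c1", start = 3, end = 14, strand = "+")
  # ATG -> ATA at CDS position 3 (genome pos 5): missense M -> I
  a <- annotate_coding_effect("c1", 5, "G", "A", gm, genome)
  expect_equal(a$effect, "missense")
  expect_equal(a$aa_ref, "M"); expect_equal(a$aa_alt, "I")
  # GCT -> GCC third position: synonymous (alanine)
  expect_equal(annotate_coding_effect("c1", 8, "T", "C", gm, genome)$effect,
               "synonymous")
  # TGG -> TGA: stop gained
  expect_equal(annotate_coding_effect("c1", 11, "G", "A", gm, genome)$effect,
               "stop_gained")
  # outside any CDS
  expect_equal(annotate_coding_effect("c1", 1, "N", "A", gm, genome)$effect,
               "non_coding")
  # minus strand: reverse complement of CDS 3..14 of
  # NNTTACCAAGCCATNN is ATG GCT TGG TAA again
  genome_m <- c(c1 = "NNTTACCAAGCCATNN")
  gm_m <- data.frame(gene = "g1", chrom = "c1", start = 3, end = 14, strand = "-")
  # genome pos 12 is the complement of codon1 pos 3 (G of ATG -> A gives ATA)
  am <- annotate_coding_effect("c1", 12, "C", "T", gm_m, genome_m)
  expect_equal(am$effect, "missense")
  expect_equal(am$aa_ref, "M"); expect_equal(am$aa_alt, "I")
  # CDS length not divisible by 3
  bad <- data.frame(gene = "gX", chrom = "c1", start = 3, end = 13, strand = "+")
  expect_error(annotate_coding_effect("c1", 5, "G", "A", bad, genome), "divisible")
})

test_that("build_frequency_matrix subsets and masks correctly", {
  anc <- toy_records(list(list(1000, 50, 12, 0), list(1100, 50, 12, 6),
                          list(1200, 50, 12, 0)), sample = "anc")
  evo <- toy_records(list(list(1000, 50, 8, 8), list(1100, 50, 8, 4),
                          list(1200, 50, 0, 0)), sample = "evo1")
  rec <- variant_records(rbind(anc, evo))
  calls <- call_fixation(rec, "anc")
  fm <- build_frequency_matrix(rec, c("anc", "evo1"))
  expect_equal(dim(fm), c(3L, 2L))
  expect_equal(fm["c1:1100", "evo1"], 0.5)
  # D = 0 cell is masked, not zero
  expect_true(is.na(fm["c1:1200", "evo1"]))
  # fixed_only keeps the single fixed locus
  fixed <- build_frequency_matrix(rec, c("anc", "evo1"), fixed_only = TRUE,
                                  calls = calls)
  expect_equal(rownames(fixed), "c1:1000")
  # non-silent filter
  eff <- data.frame(site = c("c1:1000", "c1:1100"),
                    effect = c("missense", "synonymous"))
  ns <- build_frequency_matrix(rec, c("anc", "evo1"),
                               effect_filter = "non_silent", effects = eff)
  expect_equal(rownames(ns), "c1:1000")
  expect_warning(
    build_frequency_matrix(rec, c("anc", "evo1"), effect_filter = "non_silent",
                           effects = data.frame(site = character(),
                                                effect = character())),
    "no loci")
})

test_that("VCF files round-trip through write_vcfs/read_vcf", {
  cfg <- sim_config(seed = 3, n_sites = 30, n_het_sites = 20,
                    n_denovo_per_population = 2, n_hetfix_per_population = 3,
                    n_replicates_per_treatment = 1)
  sim <- simulate_pool_seq(cfg)
  dir <- withr::local_tempdir()
  paths <- write_vcfs(sim$records, dir)
  back <- read_vcf(paths[["anc_t0"]])
  orig <- sim$records[sim$records$sample == "anc_t0", ]
  orig <- orig[order(orig$chrom, orig$pos), ]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back$pos, orig$pos)
  expect_equal(back$dp, orig$dp)
  expect_equal(back$ad_alt, orig$ad_alt)
  expect_equal(back$is_indel, orig$is_indel)
  expect_equal(back$qual, orig$qual)
})

test_that("read_vcf splits multi-allelic records and skips malformed AD", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsmp",
    "c1\t100\t.\tA\tG,T\t50\t.\t.\tDP:AD\t30:10,12,8",
    "c1\t200\t.\tA\tG\t50\t.\t.\tDP:AD\t30:oops"), path)
  expect_warning(rec <- read_vcf(path), "malformed")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$alt, c("G", "T"))
  expect_equal(rec$ad_alt, c(12, 8))
  expect_equal(rec$ad_ref, c(10, 10))
})
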