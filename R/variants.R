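# Variant filtering, binomial allele-frequency estimation, and fixation
# calling for pooled resequencing of experimentally evolved populations.
#
# The biological setting: a clonal ancestor whose only standing variation
# is heterozygosity (allele frequency 0.5), resequenced as a pool at t0
# and again per evolved population after selection. Reads at a site are
# treated as binomial draws from the pool's allele frequency, so the read
# proportion A/D estimates the frequency and exact binomial machinery
# quantifies its sampling error.

#' Filter variant records with bcftools-equivalent semantics
#'
#' Retains, per sample, single-nucleotide variants (REF and ALT single
#' bases in A/C/G/T) with `QUAL >= min_qual`, `DP >= min_dp`,
#' `IDV >= min_idv` *where the field is defined* (IDV is indel-specific;
#' absent values pass), not flagged as indels, and not within `snp_gap`
#' base pairs of any indel record on the same chromosome in the same
#' sample. Indel records themselves are dropped (they only inform the
#' proximity window). Input must be sorted by (chrom, pos) within sample.
#'
#' @param records A [variant_records()] table.
#' @param min_qual Minimum QUAL (inclusive), default 35.
#' @param min_dp Minimum depth (inclusive), default 5.
#' @param min_idv Minimum indel-supporting reads where IDV is present,
#'   default 2.
#' @param snp_gap Exclusion window (bp) around indel records, default 10.
#' @return The retained [variant_records()] rows. Idempotent.
#' @export
filter_variants <- function(records, min_qual = 35, min_dp = 5,
                            min_idv = 2, snp_gap = 10) {
  stopifnot(inherits(records, "variant_records"))
  if (nrow(records) == 0) return(records)
  for (s in unique(records$sample)) {
    rs <- records[records$sample == s, ]
    o <- order(rs$chrom, rs$pos)
    if (is.unsorted(o, strictly = FALSE) && any(o != seq_along(o))) {
      stop_input("records for sample '", s, "' are not sorted by (chrom, pos)")
    }
  }
  bases <- c("A", "C", "G", "T")
  is_snv <- records$ref %in% bases & records$alt %in% bases & !records$is_indel
  pass <- is_snv &
    !is.na(records$qual) & records$qual >= min_qual &
    records$dp >= min_dp &
    (is.na(records$idv) | records$idv >= min_idv)

  # SnpGap: drop SNVs within snp_gap bp of an indel on the same
  # chromosome, per sample (mirrors per-sample VCF filtering)
  indels <- records[records$is_indel, c("chrom", "pos", "sample")]
  if (nrow(indels)) {
    for (r in seq_len(nrow(indels))) {
      near <- records$sample == indels$sample[r] &
        records$chrom == indels$chrom[r] &
        abs(records$pos - indels$pos[r]) <= snp_gap
      pass <- pass & !near
    }
  }
  out <- records[pass, ]
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Binomial allele-frequency estimate with confidence interval
#'
#' The pooled-sequencing frequency estimate is the read proportion
#' `f_hat = A/D`, with `A ~ Binomial(D, f)`. The default interval is the
#' exact central Clopper-Pearson interval; a normal (Wald) approximation
#' is selectable. Both reproduce the textbook half-widths for `f = 0.5`:
#' about 0.31 at depth 10, 0.14 at 50 and 0.10 at 100.
#'
#' @param a Alt-supporting read count, `0 <= a <= d`.
#' @param d Total depth; `d = 0` yields a not-assessable result
#'   (all-`NA` estimate).
#' @param ci_level Confidence level, default 0.95.
#' @param method `"clopper-pearson"` (default) or `"normal"`.
#' @return data.frame with columns `f_hat`, `a`, `d`, `ci_low`, `ci_high`.
#' @examples
#' estimate_allele_frequency(5, 10) # half-width ~ 0.31
#' @export
estimate_allele_frequency <- function(a, d, ci_level = 0.95,
                                      method = c("clopper-pearson", "normal")) {
  method <- match.arg(method)
  if (length(a) != length(d)) stop_input("'a' and 'd' lengths differ")
  if (any(d < 0) || any(a < 0) || any(a > d)) stop_input("need 0 <= a <= d")
  alpha <- 1 - ci_level
  f <- ifelse(d > 0, a / d, NA_real_)
  if (method == "clopper-pearson") {
    lo <- ifelse(d == 0, NA_real_,
                 ifelse(a == 0, 0, qbeta(alpha / 2, a, d - a + 1)))
    hi <- ifelse(d == 0, NA_real_,
                 ifelse(a == d, 1, qbeta(1 - alpha / 2, a + 1, d - a)))
  } else {
    z <- -qnorm(alpha / 2)
    se <- sqrt(f * (1 - f) / d)
    lo <- pmax(0, f - z * se)
    hi <- pmin(1, f + z * se)
  }
  data.frame(f_hat = f, a = a, d = d, ci_low = lo, ci_high = hi)
}

#' @importFrom stats qnorm
NULL

#' Probability a heterozygous allele escapes detection
#'
#' For an allele at population frequency 0.5, the probability that none of
#' `d` binomially sampled reads carries it: `0.5^d`. This bounds the
#' false-negative risk of declaring a site absent in the ancestor at a
#' given depth (0.00098 at the 10x threshold).
#'
#' @param d Read depth(s), >= 0.
#' @return Probability (strictly decreasing in `d`).
#' @export
prob_missed_het <- function(d) {
  if (any(d < 0)) stop_input("'d' must be non-negative")
  0.5^d
}

#' Probability of falsely calling a fixed variant from sequencing error
#'
#' If every one of `d` reads at a site must support the variant and each
#' read errs independently with probability `err`, a false fixation call
#' requires all `d` reads to be erroneous: `err^d` (1e-10 at depth 5 with
#' a pessimistic 1% error rate).
#'
#' @param d Read depth(s), >= 0.
#' @param err Per-read error probability in [0, 1].
#' @return Probability.
#' @export
prob_false_fixation <- function(d, err) {
  if (any(d < 0)) stop_input("'d' must be non-negative")
  if (any(err < 0) || any(err > 1)) stop_input("'err' must lie in [0, 1]")
  err^d
}

#' Classify fixation of variants in evolved populations
#'
#' Applies the five fixation criteria per (site, evolved population):
#' (i) ancestral depth `D_t0 >= anc_depth`; (ii) for de-novo calls, no
#' ancestral alt reads (`A_t0 = 0`), or for heterozygous-origin calls,
#' ancestral frequency within `0.5 +/- het_window`; (iii) evolved depth
#' `D_p >= evo_depth`; (iv) every evolved read supports the variant
#' (`A_p/D_p = 1`, exactly); (v) the site passes [filter_variants()] in at
#' least one evolved population. Sites failing the depth thresholds are
#' `not_assessable`; otherwise `de_novo_fixed`, `het_origin_fixed` or
#' `not_fixed`. All five criterion booleans are recorded for audit.
#'
#' @param records Unfiltered [variant_records()] covering the ancestor and
#'   evolved samples.
#' @param ancestor Ancestor sample name.
#' @param evolved Evolved sample names (default: all non-ancestor
#'   samples).
#' @param anc_depth Minimum ancestral depth, default 10.
#' @param evo_depth Minimum evolved depth, default 5.
#' @param het_window Half-width of the ancestral heterozygosity window
#'   around 0.5, default 0.2 (boundaries inclusive).
#' @param ... Filter thresholds passed to [filter_variants()].
#' @return data.frame with columns `site`, `chrom`, `pos`, `population`,
#'   `category`, and criterion booleans `crit_i` .. `crit_v`.
#' @export
call_fixation <- function(records, ancestor, evolved = NULL,
                          anc_depth = 10, evo_depth = 5, het_window = 0.2, ...) {
  stopifnot(inherits(records, "variant_records"))
  samples <- unique(records$sample)
  if (!ancestor %in% samples) stop_input("unknown ancestor sample: ", ancestor)
  if (is.null(evolved)) evolved <- setdiff(samples, ancestor)
  if (!all(evolved %in% samples)) {
    stop_input("unknown evolved sample(s): ",
               paste(setdiff(evolved, samples), collapse = ", "))
  }

  snv <- records[!records$is_indel, ]
  sid <- site_id(snv)
  anc <- snv[snv$sample == ancestor, ]
  anc_idx <- setNames(seq_len(nrow(anc)), site_id(anc))

  # criterion (v): site passes filters in >= 1 evolved population
  filt <- filter_variants(records[records$sample %in% evolved, ], ...)
  pass_any <- unique(site_id(filt))

  out <- list()
  for (p in evolved) {
    ev <- snv[snv$sample == p, ]
    ev_sid <- site_id(ev)
    ai <- anc_idx[ev_sid]
    d0 <- ifelse(is.na(ai), 0L, anc$dp[ai])
    a0 <- ifelse(is.na(ai), NA_integer_, anc$ad_alt[ai])
    crit_i <- d0 >= anc_depth
    f0 <- ifelse(d0 > 0, a0 / d0, NA_real_)
    anc_absent <- crit_i & !is.na(a0) & a0 == 0
    anc_het <- crit_i & !is.na(f0) &
      f0 >= 0.5 - het_window & f0 <= 0.5 + het_window
    crit_ii <- anc_absent | anc_het
    crit_iii <- ev$dp >= evo_depth
    crit_iv <- ev$dp > 0 & ev$ad_alt == ev$dp
    crit_v <- ev_sid %in% pass_any

    category <- rep("not_fixed", nrow(ev))
    category[!crit_i | !crit_iii] <- "not_assessable"
    ok <- crit_i & crit_iii & crit_iv & crit_v
    category[ok & anc_absent] <- "de_novo_fixed"
    category[ok & anc_het & !anc_absent] <- "het_origin_fixed"

    out[[p]] <- data.frame(
      site = ev_sid, chrom = ev$chrom, pos = ev$pos, population = p,
      category = category,
      crit_i = crit_i, crit_ii = crit_ii, crit_iii = crit_iii,
      crit_iv = crit_iv, crit_v = crit_v,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the loci x samples allele-frequency matrix
#'
#' Frequencies are read proportions `A/D`; cells with zero or missing
#' depth are masked (`NA`), never coerced to 0. Optionally restricts loci
#' to those fixed in at least one evolved population and/or to non-silent
#' (missense or stop-gained) sites.
#'
#' @param records [variant_records()] for all samples.
#' @param samples Sample manifest (column order of the matrix); default
#'   all samples in `records`.
#' @param fixed_only If `TRUE`, keep only loci with >= 1 fixation call in
#'   `calls`.
#' @param calls Output of [call_fixation()]; required when
#'   `fixed_only = TRUE`.
#' @param effect_filter `"all"` (default) or `"non_silent"`.
#' @param effects data.frame with columns `site`, `effect`; required when
#'   `effect_filter = "non_silent"`.
#' @return A numeric matrix (loci x samples, dimnames set) with attribute
#'   `"manifest"`; zero retained loci gives a 0-row matrix with a
#'   warning.
#' @export
build_frequency_matrix <- function(records, samples = NULL, fixed_only = FALSE,
                                   calls = NULL, effect_filter = c("all", "non_silent"),
                                   effects = NULL) {
  stopifnot(inherits(records, "variant_records"))
  effect_filter <- match.arg(effect_filter)
  if (is.null(samples)) samples <- unique(records$sample)
  snv <- records[!records$is_indel & records$sample %in% samples, ]
  snv$site <- site_id(snv)
  loci <- unique(snv[order(snv$chrom, snv$pos), "site"])

  if (fixed_only) {
    if (is.null(calls)) stop_input("'calls' is required when fixed_only = TRUE")
    fixed_sites <- unique(calls$site[calls$category %in%
                                       c("de_novo_fixed", "het_origin_fixed")])
    loci <- intersect(loci, fixed_sites)
  }
  if (effect_filter == "non_silent") {
    if (is.null(effects)) stop_input("'effects' is required for the non-silent filter")
    ns <- unique(effects$site[effects$effect %in% c("missense", "stop_gained")])
    loci <- intersect(loci, ns)
  }
  if (!length(loci)) {
    warning("no loci retained; returning an empty matrix")
    return(structure(matrix(numeric(0), 0, length(samples),
                            dimnames = list(NULL, samples)),
                     manifest = samples))
  }
  fm <- matrix(NA_real_, length(loci), length(samples),
               dimnames = list(loci, samples))
  f <- ifelse(snv$dp > 0, snv$ad_alt / snv$dp, NA_real_)
  idx <- cbind(match(snv$site, loci), match(snv$sample, samples))
  keep <- !is.na(idx[, 1]) & !is.na(idx[, 2])
  fm[idx[keep, , drop = FALSE]] <- f[keep]
  attr(fm, "manifest") <- samples
  fm
}
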