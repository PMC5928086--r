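# Shared fixture builders; everything is generated in code.

# minimal variant_records table from a compact spec:
# each row of `...` is list(pos, qual, indel, dp, ad_alt, idv)
toy_records <- function(rows, sample = "s1", chrom = "c1",
                        ref = "A", alt = "G") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = chrom, pos = r[[1]],
               ref = if (isTRUE(r$indel)) "A" else ref,
               alt = if (isTRUE(r$indel)) "AT" else alt,
               qual = r[[2]], is_indel = isTRUE(r$indel),
               idv = r$idv %||% NA_integer_,
               sample = sample, dp = r[[3]],
               ad_ref = r[[3]] - r[[4]], ad_alt = r[[4]],
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$chrom, df$pos), ]
  variant_records(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-treatment frequency matrix with an optional planted between-group
# shift at the first `n_shift` loci
toy_freq_matrix <- function(n_loci = 40, n_per_group = 3, shift = 0,
                            n_shift = 0, noise = 0.05, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  base <- matrix(runif(n_loci, 0.2, 0.8), n_loci, n)
  fm <- base + matrix(rnorm(n_loci * n, 0, noise), n_loci, n)
  if (n_shift > 0) {
    fm[seq_len(n_shift), seq_len(n_per_group) + n_per_group] <-
      fm[seq_len(n_shift), seq_len(n_per_group) + n_per_group] + shift
  }
  fm <- pmin(pmax(fm, 0), 1)
  dimnames(fm) <- list(paste0("locus", seq_len(n_loci)), paste0("s", seq_len(n)))
  fm
}

toy_groups <- function(n_per_group = 3) rep(c("A", "B"), each = n_per_group)
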