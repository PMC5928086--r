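# Minimal coding-effect annotation for single-CDS gene models on small
# (synthetic) genomes. Translates the codon containing a substitution
# before and after the change, strand-aware. No splice sites, UTRs or
# multi-transcript genes.

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate the coding effect of a single-nucleotide substitution
#'
#' Classifies a substitution against single-CDS gene models as
#' `synonymous`, `missense`, `stop_gained` (or `stop_lost`), or
#' `non_coding` when the site falls in no CDS. The codon containing the
#' site is translated with the standard genetic code; minus-strand genes
#' are handled by reverse complement.
#'
#' @param chrom,pos,ref,alt The substitution (1-based VCF coordinates;
#'   single bases).
#' @param gene_models data.frame with columns `gene`, `chrom`, `start`,
#'   `end` (1-based inclusive CDS bounds), `strand` (`"+"`/`"-"`). CDS
#'   length must be divisible by 3.
#' @param genome Named character vector of chromosome sequences.
#' @return data.frame with columns `site`, `gene`, `effect`, `aa_ref`,
#'   `aa_alt` (amino acids `NA` for non-coding sites).
#' @export
annotate_coding_effect <- function(chrom, pos, ref, alt, gene_models, genome) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  bad_len <- (gene_models$end - gene_models$start + 1) %% 3 != 0
  if (any(bad_len)) {
    stop_input("CDS length not divisible by 3 for gene(s): ",
               paste(gene_models$gene[bad_len], collapse = ", "))
  }
  out_of_bounds <- gene_models$start < 1 |
    gene_models$end > nchar(genome[gene_models$chrom])
  if (any(out_of_bounds | is.na(out_of_bounds))) {
    stop_input("gene model outside genome bounds")
  }

  effect <- rep("non_coding", n)
  gene <- rep(NA_character_, n)
  aa_ref <- rep(NA_character_, n)
  aa_alt <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    hit <- which(gene_models$chrom == chrom[i] &
                   gene_models$start <= pos[i] & gene_models$end >= pos[i])
    if (!length(hit)) next
    gm <- gene_models[hit[1], ]
    seq_chr <- genome[[gm$chrom]]
    obs_ref <- substr(seq_chr, pos[i], pos[i])
    if (toupper(obs_ref) != toupper(ref[i])) {
      warning(sprintf("REF mismatch at %s:%d (genome %s, record %s)",
                      chrom[i], pos[i], obs_ref, ref[i]))
    }
    if (gm$strand == "+") {
      cds_off <- pos[i] - gm$start            # 0-based offset into CDS
      codon_start <- gm$start + (cds_off %/% 3) * 3
      codon <- substr(seq_chr, codon_start, codon_start + 2)
      within <- cds_off %% 3 + 1
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt[i]
    } else {
      cds_off <- gm$end - pos[i]
      codon_start_end <- gm$end - (cds_off %/% 3) * 3
      codon_fwd <- substr(seq_chr, codon_start_end - 2, codon_start_end)
      within_fwd <- 3 - cds_off %% 3
      alt_codon_fwd <- codon_fwd
      substr(alt_codon_fwd, within_fwd, within_fwd) <- alt[i]
      codon <- revcomp(codon_fwd)
      alt_codon <- revcomp(alt_codon_fwd)
    }
    a1 <- translate_codon(codon); a2 <- translate_codon(alt_codon)
    gene[i] <- gm$gene; aa_ref[i] <- a1; aa_alt[i] <- a2
    effect[i] <- if (is.na(a1) || is.na(a2)) "non_coding"
      else if (a1 == a2) "synonymous"
      else if (a2 == "*") "stop_gained"
      else if (a1 == "*") "stop_lost"
      else "missense"
  }
  data.frame(site = paste(chrom, pos, sep = ":"), gene = gene,
             effect = effect, aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE)
}
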