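# Minimal VCF v4.2 reader/writer for the pooled-resequencing records this
# pipeline exchanges: single-sample files with FORMAT fields DP and AD
# (ref,alt) and INFO fields INDEL/IDV. The representation is a long
# data.frame (class `variant_records`), one row per site x sample, which
# is the natural shape for per-population filtering and fixation calling.
# Coordinates are 1-based inclusive (VCF convention) throughout the
# records; the coding-effect annotator converts internally.

VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "qual", "is_indel", "idv",
                  "sample", "dp", "ad_ref", "ad_alt")

#' Assemble a variant_records table
#'
#' Validates and classes a long-format table of per-sample variant
#' observations. One row per site per sample; `idv` is `NA` for SNV-only
#' records (the field is indel-specific).
#'
#' @param df data.frame with columns chrom, pos, ref, alt, qual, is_indel,
#'   idv, sample, dp, ad_ref, ad_alt.
#' @return The validated data.frame with class `variant_records`.
#' @export
variant_records <- function(df) {
  missing_cols <- setdiff(VARIANT_COLS, names(df))
  if (length(missing_cols)) {
    stop_input("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- !is.na(df$dp) & (df$ad_alt > df$dp | df$ad_alt < 0)
  if (any(bad)) stop_input("alt allele depth must satisfy 0 <= AD <= DP")
  df <- df[, VARIANT_COLS]
  class(df) <- c("variant_records", "data.frame")
  df
}

site_id <- function(records) paste(records$chrom, records$pos, sep = ":")

#' Read a single-sample VCF file into a variant_records table
#'
#' Parses the plain-text VCF subset this pipeline writes: per-sample DP
#' and AD (ref,alt) FORMAT fields, INFO keys `INDEL` (flag) and `IDV`.
#' Multi-allelic records are split into one row per alternate allele,
#' dividing the corresponding AD entries. Records with malformed AD are
#' skipped with a warning.
#'
#' @param path Path to an uncompressed VCF file.
#' @param sample Sample name; defaults to the name in the VCF header.
#' @return A [variant_records()] table.
#' @export
read_vcf <- function(path, sample = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop_input("not a VCF file (no #CHROM header line): ", path)
  header <- strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) stop_input("VCF has no sample columns: ", path)
  if (is.null(sample)) sample <- header[10]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(variant_records(data.frame(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      qual = numeric(), is_indel = logical(), idv = integer(), sample = character(),
      dp = integer(), ad_ref = integer(), ad_alt = integer())))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  n_bad <- 0L
  for (li in seq_along(fields)) {
    f <- fields[[li]]
    info <- f[8]
    is_indel <- grepl("(^|;)INDEL(;|$|=)", info)
    idv <- if (grepl("IDV=", info)) {
      as.integer(sub(".*IDV=([0-9]+).*", "\\1", info))
    } else NA_integer_
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    smp <- strsplit(f[10], ":", fixed = TRUE)[[1]]
    dp_i <- match("DP", fmt); ad_i <- match("AD", fmt)
    if (is.na(dp_i) || is.na(ad_i)) { n_bad <- n_bad + 1L; next }
    ad <- suppressWarnings(as.integer(strsplit(smp[ad_i], ",", fixed = TRUE)[[1]]))
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    if (anyNA(ad) || length(ad) != length(alts) + 1L) { n_bad <- n_bad + 1L; next }
    rows[[li]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alts,
      qual = suppressWarnings(as.numeric(f[6])), is_indel = is_indel, idv = idv,
      sample = sample, dp = as.integer(smp[dp_i]),
      ad_ref = ad[1], ad_alt = ad[-1], stringsAsFactors = FALSE)
  }
  if (n_bad > 0) warning(sprintf("%d record(s) with malformed/absent AD skipped in %s", n_bad, path))
  variant_records(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

#' Write one VCF v4.2 file per sample
#'
#' Emits the same subset [read_vcf()] parses: QUAL, INFO `INDEL`/`IDV`,
#' FORMAT `DP:AD`. Records are written sorted by (chrom, pos).
#'
#' @param records A [variant_records()] table.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (named by sample).
#' @export
write_vcfs <- function(records, dir) {
  stopifnot(inherits(records, "variant_records"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in unique(records$sample)) {
    rs <- records[records$sample == s, ]
    rs <- rs[order(rs$chrom, rs$pos), ]
    info <- ifelse(rs$is_indel,
                   ifelse(is.na(rs$idv), "INDEL", sprintf("INDEL;IDV=%d", rs$idv)),
                   ifelse(is.na(rs$idv), ".", sprintf("IDV=%d", rs$idv)))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\t%s\tDP:AD\t%d:%d,%d",
                    rs$chrom, rs$pos, rs$ref, rs$alt, rs$qual, info,
                    rs$dp, rs$ad_ref, rs$ad_alt)
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=thermadapt",
      sprintf("##contig=<ID=%s>", unique(rs$chrom)),
      "##INFO=<ID=INDEL,Number=0,Type=Flag,Description=\"Indicates that the variant is an INDEL\">",
      "##INFO=<ID=IDV,Number=1,Type=Integer,Description=\"Maximum number of raw reads supporting an indel\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Number of high-quality bases\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", s))
    path <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(hdr, body), path)
    paths[s] <- path
  }
  invisible(paths)
}
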