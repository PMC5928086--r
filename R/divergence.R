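# Molecular divergence statistics on allele-frequency matrices:
# squared-Euclidean distances, hierarchical AMOVA with permutation
# significance, PERMANOVA and dispersion homogeneity (vegan-backed), PCA
# with loading->treatment association, and score-weighted KS enrichment.

#' Pairwise (squared) Euclidean distances between samples
#'
#' `d2(i, j) = sum over loci of (f_i - f_j)^2` on the columns of an
#' allele-frequency matrix. Loci with any masked cell are dropped
#' (complete-case deletion) with a message reporting the count.
#'
#' @param fm Loci x samples matrix (as from [build_frequency_matrix()]).
#' @param squared Return squared distances (default `TRUE`, the AMOVA
#'   convention) or plain Euclidean distances.
#' @return A symmetric matrix with attribute `"squared"`.
#' @export
distance_matrix <- function(fm, squared = TRUE) {
  if (ncol(fm) < 2) stop_input("need at least 2 samples")
  cc <- stats::complete.cases(fm)
  if (any(!cc)) {
    message(sprintf("dropping %d/%d loci with masked cells before distances",
                    sum(!cc), nrow(fm)))
    fm <- fm[cc, , drop = FALSE]
  }
  d <- as.matrix(stats::dist(t(fm), method = "euclidean"))
  if (squared) d <- d^2
  attr(d, "squared") <- squared
  d
}

# Sum of squares of a sample set from a squared-distance matrix:
# SS = (1 / n) * sum_{i<j} d2_ij
ss_from_d2 <- function(d2, idx) {
  n <- length(idx)
  if (n < 2) return(0)
  sum(d2[idx, idx][upper.tri(matrix(0, n, n))]) / n
}

amova_components <- function(d2, treatment, population) {
  N <- length(treatment)
  treat_levels <- unique(treatment)
  t_n <- length(treat_levels)
  pops <- paste(treatment, population, sep = "\r")
  pop_levels <- unique(pops)
  P <- length(pop_levels)

  ss_total <- ss_from_d2(d2, seq_len(N))
  ss_wt <- sum(vapply(treat_levels, function(g) {
    ss_from_d2(d2, which(treatment == g))
  }, numeric(1)))
  ss_bt <- ss_total - ss_wt

  if (P == N) {
    # two-level design: one sample per population; the within-treatment
    # term is "among populations within treatments"
    df_bt <- t_n - 1
    df_ap <- N - t_n
    ms_bt <- ss_bt / df_bt
    ms_ap <- ss_wt / df_ap
    n_g <- table(treatment)
    n0 <- (N - sum(n_g^2) / N) / df_bt
    sig_ap <- ms_ap
    sig_bt <- (ms_bt - ms_ap) / n0
    comps <- c(among_populations = sig_ap, between_treatments = sig_bt)
    df <- c(among_populations = df_ap, between_treatments = df_bt)
    ss <- c(among_populations = ss_wt, between_treatments = ss_bt)
  } else {
    # three-level: treatments / populations / sub-replicate samples
    ss_wp <- sum(vapply(pop_levels, function(pl) {
      ss_from_d2(d2, which(pops == pl))
    }, numeric(1)))
    ss_ap <- ss_wt - ss_wp
    df_bt <- t_n - 1
    df_ap <- P - t_n
    df_wp <- N - P
    if (df_ap <= 0 || df_wp <= 0) {
      stop_input("degenerate design: need >= 2 populations per treatment and >= 2 samples per population")
    }
    ms_bt <- ss_bt / df_bt
    ms_ap <- ss_ap / df_ap
    ms_wp <- ss_wp / df_wp
    n_p <- as.numeric(table(pops))
    names(n_p) <- names(table(pops))
    n_t <- tapply(rep(1, N), treatment, sum)
    pop_by_treat <- tapply(seq_len(N), treatment, function(ix) table(pops[ix]))
    s1 <- sum(vapply(treat_levels, function(g) {
      sum(pop_by_treat[[g]]^2) / n_t[[g]]
    }, numeric(1)))
    n_coef <- (N - s1) / df_ap
    n_coef2 <- (s1 - sum(n_p^2) / N) / df_bt
    n_coef3 <- (N - sum(n_t^2) / N) / df_bt
    sig_wp <- ms_wp
    sig_ap <- (ms_ap - ms_wp) / n_coef
    sig_bt <- (ms_bt - ms_wp - n_coef2 * sig_ap) / n_coef3
    comps <- c(within_populations = sig_wp, among_populations = sig_ap,
               between_treatments = sig_bt)
    df <- c(within_populations = df_wp, among_populations = df_ap,
            between_treatments = df_bt)
    ss <- c(within_populations = ss_wp, among_populations = ss_ap,
            between_treatments = ss_bt)
  }
  list(components = comps, df = df, ss = ss, ss_total = ss_total)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the molecular variance in a squared-Euclidean distance
#' matrix across a sampling hierarchy and tests each component by random
#' permutation. With one sample per population (the usual pooled-seq
#' design) the partition is two-level: among populations within
#' treatments, and between treatments. When populations carry sub-
#' replicate samples a three-level partition adds the within-population
#' term. Variance components are solved from expected mean squares with
#' unequal group sizes; negative estimates are reported raw but truncated
#' to zero for the percentage column.
#'
#' Permutation schemes: between-treatment significance permutes samples
#' without restriction; among-population significance permutes samples
#' across populations within their treatment; the within-population term
#' (three-level only) is not tested. `p = (n_ge + 1) / (n_perm + 1)`.
#'
#' @param dm Squared distance matrix from [distance_matrix()] (plain
#'   distances are squared with a message).
#' @param treatment Treatment label per sample (matrix column order).
#' @param population Population (biological replicate) label per sample;
#'   defaults to one population per sample.
#' @param n_perm Number of permutations, default 999.
#' @param seed Optional RNG seed for reproducible permutation p-values.
#' @return Object of class `amova_result`: `table` (component, df, ss,
#'   sigma2, sigma2_raw, percent, p_value), `n_perm`, `seed`.
#' @export
amova <- function(dm, treatment, population = NULL, n_perm = 999, seed = NULL) {
  if (!isTRUE(attr(dm, "squared"))) {
    message("distance matrix is not flagged squared; squaring entries")
    dm <- dm^2
  }
  N <- nrow(dm)
  if (length(treatment) != N) stop_input("'treatment' length must match the distance matrix")
  if (is.null(population)) population <- paste0("pop", seq_len(N))
  if (length(unique(treatment)) < 2) {
    stop_input("degenerate design at level 'treatment': need >= 2 treatments")
  }
  if (!is.null(seed)) set.seed(seed)

  obs <- amova_components(dm, treatment, population)
  comps <- obs$components

  total_raw <- sum(pmax(comps, 0))
  if (total_raw <= 0) {
    warning("all variance components are zero; percentages undefined")
    percent <- rep(NA_real_, length(comps))
  } else {
    if (any(comps < 0)) {
      message("negative variance component(s) truncated to 0 for percentages")
    }
    percent <- 100 * pmax(comps, 0) / total_raw
  }

  # permutation tests
  nm <- names(comps)
  p_values <- setNames(rep(NA_real_, length(comps)), nm)
  if (n_perm > 0) {
    ge <- setNames(numeric(length(comps)), nm)
    tested <- setdiff(nm, "within_populations")
    for (b in seq_len(n_perm)) {
      # between treatments: unrestricted permutation of samples
      perm <- sample.int(N)
      cb <- amova_components(dm, treatment[perm], population[perm])$components
      ge["between_treatments"] <- ge["between_treatments"] +
        (cb["between_treatments"] >= comps["between_treatments"])
      # among populations: permute samples within treatments
      perm2 <- seq_len(N)
      for (g in unique(treatment)) {
        ix <- which(treatment == g)
        perm2[ix] <- ix[sample.int(length(ix))]
      }
      ca <- amova_components(dm, treatment, population[perm2])$components
      ge["among_populations"] <- ge["among_populations"] +
        (ca["among_populations"] >= comps["among_populations"])
    }
    p_values[tested] <- (ge[tested] + 1) / (n_perm + 1)
    if (length(unique(population)) == N) {
      # two-level: within-treatment permutations cannot move samples
      # between populations of size one, so only the between-treatment
      # term is testable
      p_values["among_populations"] <- NA_real_
    }
  }

  tab <- data.frame(
    component = c(nm, "total"),
    df = c(obs$df, sum(obs$df)),
    ss = c(obs$ss, obs$ss_total),
    sigma2_raw = c(comps, sum(comps)),
    sigma2 = c(pmax(comps, 0), total_raw),
    percent = c(percent, if (all(is.na(percent))) NA_real_ else 100),
    p_value = c(p_values, NA_real_),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance (squared Euclidean distances)\n")
  tab <- x$table
  tab$sigma2 <- round(tab$sigma2, 4)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Permutations: %d%s\n", x$n_perm,
              if (!is.null(x$seed)) sprintf(" (seed %s)", x$seed) else ""))
  invisible(x)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Location test for group differences in distance space, delegated to
#' \code{vegan::adonis2} on the plain (unsquared) distances with a
#' seed-reproducible permutation scheme.
#'
#' @param dm Distance matrix from [distance_matrix()]; squared matrices
#'   are un-squared before the test.
#' @param groups Group label per sample.
#' @param n_perm Number of permutations, default 999.
#' @param seed Optional RNG seed.
#' @return List with `pseudo_f`, `r2`, `p_value`, `n_perm`, `seed`, and
#'   the underlying `vegan` table as `table`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  if (length(unique(groups)) < 2) stop_input("need >= 2 groups")
  if (min(table(groups)) < 2) stop_input("need >= 2 samples per group")
  if (isTRUE(attr(dm, "squared"))) dm <- sqrt(dm)
  if (!is.null(seed)) set.seed(seed)
  d <- stats::as.dist(dm)
  df <- data.frame(group = factor(groups))
  res <- vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  list(pseudo_f = res$F[1], r2 = res$R2[1], p_value = res$`Pr(>F)`[1],
       n_perm = n_perm, seed = seed, table = as.data.frame(res))
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether groups differ in spread (distance to group centroid in
#' principal-coordinate space), via \code{vegan::betadisper} with a
#' permutation F test and Tukey HSD post-hoc contrasts on the
#' dispersions. A group of size 1 has no dispersion and is flagged.
#'
#' @inheritParams permanova
#' @return List with `dispersions` (per-group means), `f`, `p_value`,
#'   `tukey` (pairwise table or `NULL`), `singleton_groups`, `n_perm`,
#'   `seed`.
#' @export
dispersion_test <- function(dm, groups, n_perm = 999, seed = NULL) {
  if (length(unique(groups)) < 2) stop_input("need >= 2 groups")
  if (isTRUE(attr(dm, "squared"))) dm <- sqrt(dm)
  singletons <- names(which(table(groups) < 2))
  if (length(singletons)) {
    warning("dispersion undefined for singleton group(s): ",
            paste(singletons, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(stats::as.dist(dm), group = factor(groups))
  pt <- vegan::permutest(bd, permutations = n_perm)
  tk <- tryCatch(TukeyHSD(bd)$group, error = function(e) NULL)
  list(dispersions = tapply(bd$distances, bd$group, mean),
       f = pt$tab$F[1], p_value = pt$tab$`Pr(>F)`[1],
       tukey = tk, singleton_groups = singletons,
       n_perm = n_perm, seed = seed)
}

#' Principal component analysis of an allele-frequency matrix
#'
#' PCA of the locus-centered frequency matrix with samples as
#' observations. On Euclidean distances this is equivalent to principal
#' coordinates analysis — pairwise distances among sample scores
#' reproduce [distance_matrix()] exactly — while also providing per-locus
#' loadings, which the treatment-association step needs.
#'
#' @param fm Loci x samples matrix; loci with masked cells are dropped as
#'   in [distance_matrix()].
#' @return Object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (loci x components, orthonormal columns),
#'   `var_explained`, `center` (per-locus means), `loci`, `samples`.
#' @export
pca <- function(fm) {
  if (ncol(fm) < 2 || nrow(fm) < 2) stop_input("need >= 2 samples and >= 2 loci")
  cc <- stats::complete.cases(fm)
  if (any(!cc)) {
    message(sprintf("dropping %d/%d loci with masked cells before PCA",
                    sum(!cc), nrow(fm)))
    fm <- fm[cc, , drop = FALSE]
  }
  x <- t(fm)                       # samples x loci
  if (all(abs(sweep(x, 2, colMeans(x))) < 1e-300)) {
    warning("constant frequency matrix: zero variance")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve, center = pc$center,
                 loci = rownames(fm), samples = colnames(fm)),
            class = "pca_result")
}

#' Associate top PCA loadings with treatments
#'
#' For each of the `n_top` loci with the largest absolute loading on each
#' of the first `components` axes, the associated treatment is the one
#' whose group mean of the centered allele frequency at that locus has
#' the largest absolute value — the group in which the locus deviates
#' most from the overall mean. Ties break by locus order.
#'
#' @param pca_res A [pca()] result.
#' @param fm The frequency matrix the PCA was computed from.
#' @param treatments Treatment label per sample (matrix column order).
#' @param n_top Number of top loci per axis (default 100; truncated with
#'   a warning when it exceeds the locus count).
#' @param components Number of leading axes to scan (default 2).
#' @return data.frame: `locus`, `component`, `loading`
#'   (absolute loading), `treatment`.
#' @export
top_loading_associations <- function(pca_res, fm, treatments,
                                     n_top = 100, components = 2) {
  stopifnot(inherits(pca_res, "pca_result"))
  if (length(treatments) != length(pca_res$samples)) {
    stop_input("'treatments' length must match the sample manifest")
  }
  if (n_top == 0) {
    return(data.frame(locus = character(), component = integer(),
                      loading = numeric(), treatment = character()))
  }
  loci <- pca_res$loci
  if (n_top > length(loci)) {
    warning("n_top exceeds locus count; truncating")
    n_top <- length(loci)
  }
  fm <- fm[loci, , drop = FALSE]
  centered <- fm - rowMeans(fm)
  treat_levels <- unique(treatments)
  group_means <- vapply(treat_levels, function(g) {
    rowMeans(centered[, treatments == g, drop = FALSE])
  }, numeric(length(loci)))

  components <- min(components, ncol(pca_res$loadings))
  out <- list()
  for (comp in seq_len(components)) {
    ld <- abs(pca_res$loadings[, comp])
    top <- order(ld, decreasing = TRUE)[seq_len(n_top)]
    assoc <- treat_levels[apply(abs(group_means[top, , drop = FALSE]), 1, which.max)]
    out[[comp]] <- data.frame(locus = loci[top], component = comp,
                              loading = ld[top], treatment = assoc,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score-weighted Kolmogorov-Smirnov term enrichment
#'
#' For each annotation term, compares the score distribution of
#' term-annotated genes against the remaining universe (genes without a
#' score contribute 0) with a two-sample KS test, so enrichment reflects
#' score magnitude, not membership alone. Also reports the classical
#' columns: `ann` (term genes in the universe), `sig` (term genes in the
#' scored set), `exp` (= ann x scored-set size / universe size).
#'
#' @param gene_scores Named numeric vector of scores for the significant
#'   (scored) gene set, e.g. absolute PCA loadings.
#' @param annotation data.frame with columns `gene`, `term`
#'   (pre-propagated if term-graph inheritance is wanted; no graph logic
#'   is applied here).
#' @param universe Character vector of all genes in the reference set.
#' @return data.frame per term: `term`, `ann`, `sig`, `exp`, `ks_d`,
#'   `ks_p`, ordered by `ks_p`. Terms with no annotated gene in the
#'   universe are skipped.
#' @export
weighted_ks_enrichment <- function(gene_scores, annotation, universe) {
  if (is.null(names(gene_scores)) || !length(gene_scores)) {
    stop_input("'gene_scores' must be a named numeric vector")
  }
  extra <- setdiff(annotation$gene, universe)
  if (length(extra)) {
    stop_input("annotated genes outside the universe: ",
               paste(head(extra, 5), collapse = ", "))
  }
  scores <- setNames(rep(0, length(universe)), universe)
  in_univ <- intersect(names(gene_scores), universe)
  scores[in_univ] <- gene_scores[in_univ]
  n_sig <- length(in_univ)

  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    genes <- unique(annotation$gene[annotation$term == tm])
    genes <- intersect(genes, universe)
    if (!length(genes)) return(NULL)
    inside <- scores[genes]
    outside <- scores[setdiff(universe, genes)]
    if (!length(outside)) {
      ks <- list(statistic = 0, p.value = 1)
    } else {
      ks <- suppressWarnings(ks.test(inside, outside, alternative = "two.sided"))
    }
    data.frame(term = tm, ann = length(genes),
               sig = sum(genes %in% in_univ),
               exp = length(genes) * n_sig / length(universe),
               ks_d = unname(ks$statistic), ks_p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$ks_p), ]
  rownames(out) <- NULL
  out
}
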