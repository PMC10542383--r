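#' Per-site Weir-Cockerham Fst
#'
#' The two-population, bi-allelic Weir-Cockerham theta estimator computed
#' per site from sample sizes, allele frequencies and observed
#' heterozygosity (the estimator behind standard per-SNP Fst scans). The
#' three variance components are returned alongside the ratio
#' `fst = a / (a + b + c)` so windowed estimates can be formed as
#' ratios of summed components. Sites monomorphic across both populations,
#' or with fewer than one called individual in either population, are
#' skipped. Per-site estimates may be slightly negative; they are not
#' clamped.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map data.frame.
#' @param pop_a,pop_b population labels to contrast (each may name several
#'   populations, e.g. a super-population).
#' @return data.frame: `chrom`, `pos`, `n_a`, `n_b` (called individuals),
#'   `a`, `b`, `c` (variance components), `fst`.
#' @export
weir_cockerham_fst <- function(gm, popmap, pop_a, pop_b) {
  idx <- function(pops) {
    s <- popmap$sample[popmap$population %in% pops |
                         popmap$super_population %in% pops]
    i <- match(s, gm$sample_ids)
    i <- i[!is.na(i)]
    if (!length(i)) stop("empty population: ", paste(pops, collapse = ", "))
    i
  }
  ga <- gm$gt[, idx(pop_a), drop = FALSE]
  gb <- gm$gt[, idx(pop_b), drop = FALSE]
  comp <- wc_components(ga, gb)
  keep <- comp$defined
  data.frame(chrom = gm$chrom, pos = gm$pos,
             n_a = comp$n1, n_b = comp$n2,
             a = comp$a, b = comp$b, c = comp$c,
             fst = comp$a / (comp$a + comp$b + comp$c))[keep, , drop = FALSE]
}

# Weir & Cockerham (1984) variance components for r = 2 populations,
# vectorized over sites. g1, g2: dosage matrices (sites x samples).
wc_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1))
  n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  defined <- n1 > 0L & n2 > 0L & pbar > 0 & pbar < 1 & nbar > 1
  list(n1 = n1, n2 = n2, a = a, b = b, c = c_, defined = defined)
}

#' Windowed Fst from per-site components
#'
#' Sliding-window Fst (default 10-kb windows, 2-kb step) computed as the
#' ratio of summed variance components — `sum(a) / sum(a + b + c)` over the
#' sites in each window, the standard ratio-of-averages estimator — never as
#' a mean of per-site ratios. Windows containing no retained variant are
#' omitted; windowed values may be slightly negative.
#'
#' @param site_fst output of [weir_cockerham_fst()] (single chromosome,
#'   sorted by position).
#' @param window,step window and step sizes in bp.
#' @param chrom_len optional chromosome length; defaults to the largest
#'   site position.
#' @return data.frame: `chrom`, `start`, `end`, `n_variants`, `fst`.
#' @export
windowed_fst <- function(site_fst, window = 10000L, step = 2000L,
                         chrom_len = NULL) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (length(unique(site_fst$chrom)) > 1L) {
    stop("windowed_fst expects a single chromosome")
  }
  if (is.unsorted(site_fst$pos)) stop("sites must be sorted by position")
  if (is.null(chrom_len)) chrom_len <- max(site_fst$pos)
  ca <- c(0, cumsum(site_fst$a))
  cabc <- c(0, cumsum(site_fst$a + site_fst$b + site_fst$c))
  cn <- 0:nrow(site_fst)
  starts <- seq.int(1L, max(1L, chrom_len), by = step)
  ends <- pmin(starts + window - 1L, chrom_len)
  lo <- findInterval(starts - 1L, site_fst$pos) + 1L
  hi <- findInterval(ends, site_fst$pos)
  n_var <- cn[hi + 1L] - cn[lo]
  keep <- n_var > 0L
  data.frame(chrom = if (nrow(site_fst)) site_fst$chrom[1] else character(0),
             start = starts, end = ends, n_variants = n_var,
             fst = (ca[hi + 1L] - ca[lo]) /
               (cabc[hi + 1L] - cabc[lo]))[keep, , drop = FALSE]
}

#' Empirical p-value against a null distribution
#'
#' Rank-based empirical p-value of observed statistics against a null set
#' (typically per-SNP Fst of intergenic SNPs), using the add-one rule
#' `p = (1 + #(null >= observed)) / (1 + N)` so that p is never 0 and lies
#' in `(0, 1]`.
#'
#' @param observed numeric vector of observed statistics.
#' @param null_values nonempty numeric null distribution.
#' @return numeric vector of p-values, monotone non-increasing in
#'   `observed`.
#' @export
empirical_p <- function(observed, null_values) {
  if (!length(null_values)) stop("null distribution is empty")
  snull <- sort(null_values)
  n <- length(snull)
  # #(null >= obs) = n - #(null < obs); left.open counts strict inequality
  n_ge <- n - findInterval(observed, snull, left.open = TRUE)
  (1 + n_ge) / (1 + n)
}

#' Null-based significance cutoff
#'
#' The statistic value whose empirical p-value equals `alpha`: the
#' `(1 - alpha)` quantile of the null distribution (the dashed cutoff line
#' of an Fst outlier scan).
#'
#' @param null_values numeric null distribution.
#' @param alpha significance level (default 0.05).
#' @export
empirical_cutoff <- function(null_values, alpha = 0.05) {
  stats::quantile(null_values, 1 - alpha, names = FALSE, type = 7)
}

#' Call differentiated regions from per-SNV p-values
#'
#' A candidate region passes when strictly more than half of its SNVs have
#' an empirical p-value below `p_cutoff`. Regions containing no SNV fail
#' and are flagged.
#'
#' @param regions data.frame: `chrom`, `start`, `end` (1-based closed).
#' @param snvs data.frame: `chrom`, `pos`, `p` — per-SNV empirical
#'   p-values.
#' @param p_cutoff per-SNV significance threshold (default 0.05).
#' @param frac_cutoff required fraction of significant SNVs (strict;
#'   default 0.5).
#' @return `regions` with added `n_snvs`, `frac_significant`, `pass`,
#'   `no_snvs` columns.
#' @export
call_differentiated_regions <- function(regions, snvs, p_cutoff = 0.05,
                                        frac_cutoff = 0.5) {
  out <- regions
  out$n_snvs <- 0L
  out$frac_significant <- NA_real_
  for (i in seq_len(nrow(regions))) {
    in_reg <- snvs$chrom == regions$chrom[i] &
      snvs$pos >= regions$start[i] & snvs$pos <= regions$end[i]
    out$n_snvs[i] <- sum(in_reg)
    if (out$n_snvs[i] > 0L) {
      out$frac_significant[i] <- mean(snvs$p[in_reg] < p_cutoff)
    }
  }
  out$no_snvs <- out$n_snvs == 0L
  out$pass <- !out$no_snvs & out$frac_significant > frac_cutoff
  out
}

#' Genome-wide pairwise Fst matrix
#'
#' Pairwise population Fst averaged over the genome as the ratio of summed
#' Weir-Cockerham components, optionally after the standard pre-filter for
#' distance matrices: randomly keeping 1 variant in `downsample` and
#' dropping MAF <= `maf` sites (seed-deterministic).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map.
#' @param downsample keep ~1/`downsample` variants (default 1: keep all).
#' @param maf drop sites with pooled minor-allele frequency below this
#'   (default 0: keep all).
#' @param seed RNG seed for the downsampling draw.
#' @return symmetric matrix of genome-wide Fst with zero diagonal.
#' @export
fst_matrix <- function(gm, popmap, downsample = 1, maf = 0, seed = 1L) {
  pops <- unique(popmap$population)
  if (downsample > 1 || maf > 0) {
    set.seed(seed)
    keep <- stats::runif(n_sites(gm)) < 1 / downsample
    f <- rowMeans(gm$gt, na.rm = TRUE) / 2
    keep <- keep & pmin(f, 1 - f) > maf
    gm <- genotype_matrix(gm$chrom[keep], gm$pos[keep], gm$ref[keep],
                          gm$alt[keep], gm$gt[keep, , drop = FALSE],
                          gm$sample_ids)
  }
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      s <- weir_cockerham_fst(gm, popmap, pops[i], pops[j])
      m[i, j] <- m[j, i] <- sum(s$a) / sum(s$a + s$b + s$c)
    }
  }
  m
}

#' Correlation of mapping bias with genetic distance
#'
#' Tests whether reference bias scales with genetic distance: for each
#' population `m`, the x coordinate is the Fst contrast
#' `Fst(m, ref_pop_a) - Fst(m, ref_pop_b)` (how much closer `m` is to the
#' population of reference B than of reference A) and the y coordinate is
#' the population mean mapping-statistic difference:
#'
#' * `metric = "uniqmap"`: `mean(uniqmap_ref_b - uniqmap_ref_a)` — expected
#'   to *decrease* with x (populations closer to reference A's population
#'   map better to reference A);
#' * `metric = "uniqclip"`: `mean(uniqclip_ref_a - uniqclip_ref_b)` —
#'   expected to *increase* with x (clipped alignments accumulate on the
#'   genetically distant reference).
#'
#' @param stats_df mapping statistics (see [read_mapping_stats()]).
#' @param fst_matrix symmetric population Fst matrix containing every
#'   population of `stats_df` plus the two reference populations.
#' @param ref_pop_a,ref_pop_b populations of origin of the two references.
#' @param metric `"uniqmap"` or `"uniqclip"`.
#' @return list: `points` (data.frame `population`, `x`, `y`), `r`
#'   (Pearson correlation), `p` (two-sided test p-value).
#' @export
mapping_bias_correlation <- function(stats_df, fst_matrix,
                                     ref_pop_a = "CHS", ref_pop_b = "CEU",
                                     metric = c("uniqmap", "uniqclip")) {
  metric <- match.arg(metric)
  pops <- unique(stats_df$population)
  check_fst_matrix(fst_matrix, c(ref_pop_a, ref_pop_b, pops))
  x <- fst_matrix[pops, ref_pop_a] - fst_matrix[pops, ref_pop_b]
  y <- vapply(pops, function(p) {
    s <- stats_df[stats_df$population == p, ]
    if (metric == "uniqmap") mean(s$uniqmap_ref_b - s$uniqmap_ref_a)
    else mean(s$uniqclip_ref_a - s$uniqclip_ref_b)
  }, numeric(1))
  ct <- stats::cor.test(x, y)
  list(points = data.frame(population = pops, x = as.numeric(x),
                           y = as.numeric(y), row.names = NULL),
       r = unname(ct$estimate), p = ct$p.value)
}
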