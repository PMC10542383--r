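#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object. All randomness flows from the single `seed`; two calls to any
#' generator with identical configs produce byte-identical output.
#'
#' The quartet generator emulates the four-taxon topology `((P1, P2), P3, O)`
#' used for archaic-introgression scans — a sub-Saharan African population as
#' P1, the test population as P2, an archaic hominin genome as P3 and
#' chimpanzee as outgroup. Default sample sizes (10, 20, 1, 5 diploids)
#' mirror that design: population panels for P1/P2, a single high-coverage
#' archaic genome, a small outgroup panel.
#'
#' @param seed integer seed (single RNG source for all draws).
#' @param n_p1,n_p2,n_p3,n_out diploid sample counts per taxon.
#' @param chrom chromosome name used in all outputs.
#' @param chrom_len chromosome length in bp.
#' @param site_density expected bi-allelic SNPs per bp (default 0.01 — one
#'   segregating site per 100 bp, the scale expected for a combined panel of
#'   dozens of modern genomes plus divergent archaic and outgroup genomes;
#'   ~100 sites per 10-kb window, so the 30-good-site filter passes).
#' @param gamma introgressed-replacement fraction inside planted tracts, in
#'   `[0, 1]`: each P2 haplotype allele in a tract is copied from the P3
#'   allele-frequency distribution with this probability.
#' @param tracts data.frame (`start`, `end`; 1-based closed) of planted
#'   introgression tracts in P2; must lie within the chromosome and not
#'   overlap.
#' @param anc_shape1,anc_shape2 Beta shape parameters of the ancestral
#'   derived-allele-frequency distribution (default Beta(0.2, 0.2), truncated
#'   to (0, 1), giving a realistic U-shaped site frequency spectrum).
#' @param drift_f named numeric: Balding-Nichols drift parameter F per taxon
#'   (`p1`, `p2`, `p3`, `out`). P1 and P2 share F = 0.1 so that Patterson's D
#'   is 0 in expectation without gene flow; the archaic taxon and outgroup
#'   are more diverged.
#' @param outgroup_anc_prob probability that the outgroup is fixed for the
#'   ancestral allele at a site (default 0.95).
#' @param depth_lambda mean genome-wide coverage for depth simulations.
#' @param depth_len length (bp) of the simulated specific-mapping depth
#'   track.
#' @param smr_regions data.frame (`start`, `end`) of planted
#'   reference-specific mapping regions within `1..depth_len`;
#'   non-overlapping.
#' @param smr_e relative coverage inside planted SMRs (default 1: full
#'   coverage maps only to this reference there).
#' @param background_e relative specific coverage outside SMRs (default
#'   0.05: stray reads only).
#' @param insertion_len length of the simulated insertion region (default
#'   21 kb, the scale of a large polymorphic insertion).
#' @param insertion_n_samples samples to genotype for the insertion.
#' @param insertion_af true insertion allele frequency used to draw planted
#'   genotypes when `insertion_genotypes` is `NULL`.
#' @param insertion_genotypes optional named integer vector in `{0, 1, 2}`
#'   fixing the planted insertion genotypes.
#' @param n_svs number of simulated structural variants.
#' @param sv_cluster optional `c(center, sd)`; when given, SV starts cluster
#'   around `center` instead of being uniform.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_p1 = 10L, n_p2 = 20L, n_p3 = 1L, n_out = 5L,
                       chrom = "chr1", chrom_len = 1000000L,
                       site_density = 0.01,
                       gamma = 0, tracts = NULL,
                       anc_shape1 = 0.2, anc_shape2 = 0.2,
                       drift_f = c(p1 = 0.1, p2 = 0.1, p3 = 0.5, out = 0.5),
                       outgroup_anc_prob = 0.95,
                       depth_lambda = 30, depth_len = 100000L,
                       smr_regions = NULL, smr_e = 1, background_e = 0.05,
                       insertion_len = 21000L, insertion_n_samples = 50L,
                       insertion_af = 0.3, insertion_genotypes = NULL,
                       n_svs = 200L, sv_cluster = NULL) {
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (min(n_p1, n_p2, n_p3, n_out) < 1L) stop("each taxon needs >= 1 sample")
  if (chrom_len < 1L || site_density <= 0) {
    stop("chrom_len and site_density must be positive")
  }
  if (is.null(tracts)) {
    tracts <- data.frame(start = integer(0), end = integer(0))
  }
  check_intervals(tracts, chrom_len, "tracts")
  if (is.null(smr_regions)) {
    smr_regions <- data.frame(start = integer(0), end = integer(0))
  }
  check_intervals(smr_regions, depth_len, "smr_regions")
  if (depth_lambda <= 0) stop("depth_lambda must be > 0")
  if (!is.null(insertion_genotypes) &&
      !all(insertion_genotypes %in% 0:2)) {
    stop("insertion_genotypes must be 0, 1 or 2")
  }
  stopifnot(all(c("p1", "p2", "p3", "out") %in% names(drift_f)))
  structure(list(
    seed = as.integer(seed), n_p1 = as.integer(n_p1),
    n_p2 = as.integer(n_p2), n_p3 = as.integer(n_p3),
    n_out = as.integer(n_out), chrom = chrom,
    chrom_len = as.integer(chrom_len), site_density = site_density,
    gamma = gamma, tracts = tracts, anc_shape1 = anc_shape1,
    anc_shape2 = anc_shape2, drift_f = drift_f,
    outgroup_anc_prob = outgroup_anc_prob, depth_lambda = depth_lambda,
    depth_len = as.integer(depth_len), smr_regions = smr_regions,
    smr_e = smr_e, background_e = background_e,
    insertion_len = as.integer(insertion_len),
    insertion_n_samples = as.integer(insertion_n_samples),
    insertion_af = insertion_af,
    insertion_genotypes = insertion_genotypes,
    n_svs = as.integer(n_svs), sv_cluster = sv_cluster
  ), class = "sim_config")
}

check_intervals <- function(df, len, what) {
  stopifnot(all(c("start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible())
  if (any(df$start < 1L | df$end > len | df$start > df$end)) {
    stop(what, " must be valid intervals within 1..", len)
  }
  o <- order(df$start)
  if (nrow(df) > 1L && any(df$start[o][-1] <= df$end[o][-nrow(df)])) {
    stop(what, " must not overlap")
  }
  invisible()
}

#' Simulate quartet genotypes with planted introgression
#'
#' Generates a bi-allelic genotype matrix for the four-taxon topology
#' `((P1, P2), P3, O)`. Per site, an ancestral derived-allele frequency is
#' drawn from a truncated Beta; each taxon's frequency drifts independently
#' under the Balding-Nichols model; the outgroup is fixed ancestral at
#' `outgroup_anc_prob` of sites. Inside planted tracts each P2 haplotype
#' allele is, with probability `gamma`, drawn from the P3 frequency instead
#' of the P2 frequency — the tract-copying model of introgression that
#' creates excess ABBA sharing. Genotypes are binomial draws per diploid
#' sample. The REF allele is ancestral, ALT derived.
#'
#' Random variates are drawn in an order that does not depend on `gamma`, so
#' runs at different `gamma` under the same seed are coupled: the set of
#' copied alleles at a lower gamma is a subset of the set at a higher gamma.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()]), `popmap` (data.frame:
#'   sample, population in `{P1, P2, P3, OUT}`, super_population), and
#'   `truth` (planted tracts, gamma, per-taxon true frequencies `p1..p4`,
#'   site positions).
#' @export
simulate_quartet_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_sites <- round(cfg$chrom_len * cfg$site_density)
  if (n_sites < 1L) stop("configuration yields zero sites")
  set.seed(cfg$seed)
  pos <- sort(sample.int(cfg$chrom_len, n_sites))
  trunc_beta <- function(n) {
    pmin(pmax(stats::rbeta(n, cfg$anc_shape1, cfg$anc_shape2), 1e-4),
         1 - 1e-4)
  }
  bn <- function(q, f) {
    # Balding-Nichols: Beta(q(1-f)/f, (1-q)(1-f)/f), mean q, var f q(1-q)
    stats::rbeta(length(q), q * (1 - f) / f, (1 - q) * (1 - f) / f)
  }
  q0 <- trunc_beta(n_sites)
  p1 <- bn(q0, cfg$drift_f[["p1"]])
  p2 <- bn(q0, cfg$drift_f[["p2"]])
  p3 <- bn(q0, cfg$drift_f[["p3"]])
  out_poly <- stats::runif(n_sites) > cfg$outgroup_anc_prob
  p4_drift <- bn(q0, cfg$drift_f[["out"]])
  p4 <- ifelse(out_poly, p4_drift, 0)

  g1 <- matrix(stats::rbinom(n_sites * cfg$n_p1, 2L, p1), n_sites, cfg$n_p1)
  g3 <- matrix(stats::rbinom(n_sites * cfg$n_p3, 2L, p3), n_sites, cfg$n_p3)
  g4 <- matrix(stats::rbinom(n_sites * cfg$n_out, 2L, p4),
               n_sites, cfg$n_out)
  # P2 at haplotype resolution so tract copying acts per allele. Donor
  # alleles are drawn from the *sampled* P3 genomes: an introgressed
  # haplotype matches the sequenced archaic individual, not just the latent
  # archaic allele frequency.
  n_hap <- 2L * cfg$n_p2
  p3_hat <- rowMeans(g3) / 2
  hap_native <- matrix(stats::rbinom(n_sites * n_hap, 1L, p2),
                       n_sites, n_hap)
  hap_donor <- matrix(stats::rbinom(n_sites * n_hap, 1L, p3_hat),
                      n_sites, n_hap)
  u <- matrix(stats::runif(n_sites * n_hap), n_sites, n_hap)

  in_tract <- rep(FALSE, n_sites)
  if (nrow(cfg$tracts)) {
    in_tract <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos, width = 1L),
      IRanges::IRanges(start = cfg$tracts$start, end = cfg$tracts$end))
  }
  copied <- u < cfg$gamma & in_tract
  hap <- ifelse(copied, hap_donor, hap_native)
  g2 <- hap[, seq_len(cfg$n_p2), drop = FALSE] +
    hap[, cfg$n_p2 + seq_len(cfg$n_p2), drop = FALSE]

  samples <- c(sprintf("P1_%02d", seq_len(cfg$n_p1)),
               sprintf("P2_%02d", seq_len(cfg$n_p2)),
               sprintf("P3_%02d", seq_len(cfg$n_p3)),
               sprintf("OUT_%02d", seq_len(cfg$n_out)))
  popmap <- data.frame(
    sample = samples,
    population = rep(c("P1", "P2", "P3", "OUT"),
                     c(cfg$n_p1, cfg$n_p2, cfg$n_p3, cfg$n_out)),
    super_population = rep(c("P1", "P2", "P3", "OUT"),
                           c(cfg$n_p1, cfg$n_p2, cfg$n_p3, cfg$n_out)),
    stringsAsFactors = FALSE)
  gm <- genotype_matrix(
    chrom = rep(cfg$chrom, n_sites), pos = pos,
    ref = rep("A", n_sites), alt = rep("G", n_sites),
    gt = cbind(g1, g2, g3, g4), sample_ids = samples)
  truth <- list(tracts = cfg$tracts, gamma = cfg$gamma, pos = pos,
                freq = data.frame(p1 = p1, p2 = p2, p3 = p3, p4 = p4))
  list(gm = gm, popmap = popmap, truth = truth)
}

#' Simulate depth tracks with planted SMRs and insertion genotypes
#'
#' Per-base depth is Poisson(`lambda * e`) where the relative coverage `e`
#' is 1 under normal mapping. Two planted feature classes are produced:
#'
#' * a reference-**specific** mapping track over `1..depth_len`, with
#'   `e = background_e` outside and `e = smr_e` inside the planted SMRs
#'   (regions where reads map to only one of two candidate references);
#' * per-sample tracks over a large-insertion region of length
#'   `insertion_len`, with `e = genotype / 2` — 0, 0.5 or 1 for absent,
#'   heterozygous and homozygous carriers of the insertion.
#'
#' `wg_mean` of every track is set to `depth_lambda`, the full-alignment
#' genome-wide mean.
#'
#' @param cfg a [sim_config()].
#' @return list with `specific` (a [depth_track()]), `insertion` (named list
#'   of per-sample [depth_track()]s over the insertion region) and `truth`
#'   (planted `smr_regions` and named `insertion_genotypes`).
#' @export
simulate_depth_track <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$depth_lambda <= 0) stop("depth_lambda must be > 0")
  set.seed(cfg$seed)
  e <- rep(cfg$background_e, cfg$depth_len)
  for (i in seq_len(nrow(cfg$smr_regions))) {
    e[cfg$smr_regions$start[i]:cfg$smr_regions$end[i]] <- cfg$smr_e
  }
  specific <- depth_track(cfg$chrom,
                          stats::rpois(cfg$depth_len, cfg$depth_lambda * e),
                          wg_mean = cfg$depth_lambda)
  geno <- cfg$insertion_genotypes
  if (is.null(geno)) {
    geno <- stats::rbinom(cfg$insertion_n_samples, 2L, cfg$insertion_af)
    names(geno) <- sprintf("S%03d", seq_along(geno))
  }
  insertion <- lapply(geno, function(g) {
    depth_track(cfg$chrom,
                stats::rpois(cfg$insertion_len, cfg$depth_lambda * g / 2),
                wg_mean = cfg$depth_lambda)
  })
  list(specific = specific, insertion = insertion,
       truth = list(smr_regions = cfg$smr_regions,
                    insertion_genotypes = geno))
}

#' Simulate a structural-variant call set
#'
#' SV starts are uniform along the chromosome (or Gaussian-clustered when
#' `cfg$sv_cluster` is set); lengths are 50 bp plus an exponential tail, so
#' every record satisfies the >= 50 bp size convention of long-read SV call
#' sets.
#'
#' @param cfg a [sim_config()].
#' @return data.frame `chrom`, `start`, `end` (1-based closed), `type`,
#'   `length`, sorted by start.
#' @export
simulate_sv_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_svs
  if (is.null(cfg$sv_cluster)) {
    start <- sample.int(cfg$chrom_len, n, replace = TRUE)
  } else {
    start <- round(stats::rnorm(n, cfg$sv_cluster[1], cfg$sv_cluster[2]))
    start <- pmin(pmax(start, 1L), cfg$chrom_len)
  }
  len <- 50L + round(stats::rexp(n, 1 / 450))
  type <- sample(c("INS", "DEL", "INV", "DUP"), n, replace = TRUE,
                 prob = c(0.45, 0.45, 0.05, 0.05))
  df <- data.frame(chrom = cfg$chrom, start = start,
                   end = pmin(start + len - 1L, cfg$chrom_len),
                   type = type, stringsAsFactors = FALSE)
  df$length <- df$end - df$start + 1L
  df[order(df$start), , drop = FALSE]
}

#' Simulate per-sample mapping statistics coupled to genetic distance
#'
#' Builds a mapping-statistics table whose population-level UniqMap
#' difference is a linear function of genetic distance:
#' `uniqmap_ref_b - uniqmap_ref_a = slope * (Fst(m, ref_pop_a) -
#' Fst(m, ref_pop_b)) + N(0, noise_sd)`, with per-sample jitter that cancels
#' in the population mean. The UniqClip difference gets the opposite slope,
#' reproducing the empirical sign pattern: populations genetically closer to
#' the reference's own population map better (more unique mappings, fewer
#' clipped reads). At `noise_sd = 0` the downstream correlation is exactly
#' +/-1.
#'
#' @param fst_matrix symmetric population-by-population Fst matrix with zero
#'   diagonal and dimnames; must contain `ref_pop_a` and `ref_pop_b`.
#' @param slope linear coefficient (percent UniqMap per unit Fst
#'   difference); negative values reproduce the observed direction.
#' @param noise_sd standard deviation of the population-level Gaussian
#'   noise; must be >= 0.
#' @param cfg a [sim_config()] (supplies the seed).
#' @param n_per_pop samples per population.
#' @param ref_pop_a,ref_pop_b populations of origin of the two candidate
#'   references.
#' @param base_uniqmap,base_uniqclip baseline percentages.
#' @return data.frame in [read_mapping_stats()] layout.
#' @export
simulate_mapping_stats <- function(fst_matrix, slope, noise_sd, cfg,
                                   n_per_pop = 5L,
                                   ref_pop_a = "CHS", ref_pop_b = "CEU",
                                   base_uniqmap = 92, base_uniqclip = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  check_fst_matrix(fst_matrix, c(ref_pop_a, ref_pop_b))
  set.seed(cfg$seed)
  pops <- rownames(fst_matrix)
  x <- fst_matrix[pops, ref_pop_a] - fst_matrix[pops, ref_pop_b]
  d_map <- slope * x + stats::rnorm(length(pops), 0, noise_sd)
  d_clip <- -slope * x + stats::rnorm(length(pops), 0, noise_sd)
  rows <- lapply(seq_along(pops), function(i) {
    ua <- base_uniqmap + stats::rnorm(n_per_pop, 0, 0.2)
    cb <- base_uniqclip + stats::rnorm(n_per_pop, 0, 0.05)
    data.frame(sample = sprintf("%s_%02d", pops[i], seq_len(n_per_pop)),
               population = pops[i],
               uniqmap_ref_a = ua, uniqmap_ref_b = ua + d_map[i],
               uniqclip_ref_a = cb + d_clip[i], uniqclip_ref_b = cb,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_fst_matrix <- function(m, need_pops = character(0)) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    stop("fst_matrix must be square with matching dimnames")
  }
  if (any(abs(m - t(m)) > 1e-12) || any(diag(m) != 0)) {
    stop("fst_matrix must be symmetric with zero diagonal")
  }
  miss <- setdiff(need_pops, rownames(m))
  if (length(miss)) stop("population(s) missing from fst_matrix: ",
                         paste(miss, collapse = ", "))
  invisible()
}

#' Random population Fst matrix
#'
#' Places populations on a one-dimensional genetic gradient and sets
#' `Fst(i, j)` proportional to the distance between them — a simple
#' isolation-by-distance surrogate for a genome-wide pairwise Fst matrix.
#' The first two populations are named after the reference populations and
#' anchored near the two ends of the gradient.
#'
#' @param n_pops number of populations (>= 3).
#' @param seed RNG seed.
#' @param max_fst largest pairwise Fst (default 0.2).
#' @param ref_pop_a,ref_pop_b names for the two anchored populations.
#' @return symmetric matrix with zero diagonal and population dimnames.
#' @export
random_fst_matrix <- function(n_pops = 30L, seed = 1L, max_fst = 0.2,
                              ref_pop_a = "CHS", ref_pop_b = "CEU") {
  stopifnot(n_pops >= 3L)
  set.seed(seed)
  t <- c(0.02, 0.98, stats::runif(n_pops - 2L))
  pops <- c(ref_pop_a, ref_pop_b,
            sprintf("POP%02d", seq_len(n_pops - 2L)))
  m <- max_fst * abs(outer(t, t, "-"))
  dimnames(m) <- list(pops, pops)
  m
}
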