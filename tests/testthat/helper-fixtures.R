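# Small builders shared across test files. Everything is generated in code;
# no fixture files.

# genotype matrix from a plain integer matrix (sites x samples)
toy_gm <- function(gt, pos = NULL, chrom = "chr1", dp = NULL, ad_alt = NULL,
                   samples = NULL) {
  gt <- as.matrix(gt)
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 100L
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(gt)))
  genotype_matrix(chrom = rep(chrom, nrow(gt)), pos = pos,
                  ref = rep("A", nrow(gt)), alt = rep("G", nrow(gt)),
                  gt = gt, sample_ids = samples, dp = dp, ad_alt = ad_alt)
}

toy_popmap <- function(samples, pops, super = pops) {
  data.frame(sample = samples, population = pops, super_population = super,
             stringsAsFactors = FALSE)
}

# write VCF text lines for hand-built records
write_vcf_lines <- function(records, samples, path,
                            format = "GT") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# interval overlap fraction helpers for recall/precision on region calls
overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# fraction of each query interval covered by any subject interval
covered_frac <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    ov <- sum(overlap_len(query$start[i], query$end[i],
                          subject$start, subject$end))
    ov / (query$end[i] - query$start[i] + 1)
  }, numeric(1))
}

# exhaustive oracle: walk candidate base sets with cumsum/split instead of
# the rle + IRanges path used by the implementation
brute_smr <- function(depth, wg_mean, min_len = 100L, merge_gap = 0L) {
  above <- which(depth > wg_mean / 2)
  if (!length(above)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  grp <- cumsum(c(1L, diff(above) > merge_gap + 1L))
  regs <- lapply(split(above, grp), function(b) {
    s <- min(b); e <- max(b)
    data.frame(start = s, end = e, mean_depth = mean(depth[s:e]))
  })
  df <- do.call(rbind, regs)
  df <- df[df$mean_depth > wg_mean / 2 & (df$end - df$start + 1L) >= min_len,
           , drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent Weir-Cockerham (1984) theta, coded scalar-by-scalar from the
# textbook formulas (r populations generalization specialized by hand),
# deliberately not sharing code with the vectorized implementation
wc_theta_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n_i <- c(length(g1), length(g2))
  p_i <- c(sum(g1) / (2 * length(g1)), sum(g2) / (2 * length(g2)))
  h_i <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  n_bar <- mean(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- n_bar / n_c * (s2 - 1 / (n_bar - 1) *
                        (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

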