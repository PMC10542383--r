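#' Read bi-allelic SNPs from a VCF file
#'
#' Ingests a VCF (v4.x) and returns a [genotype_matrix()] holding only
#' bi-allelic SNP records. Multi-allelic records and indels are skipped.
#' Missing genotypes (`./.`, `.|.` or half-calls such as `0/.`) become `NA`.
#' Per-genotype DP and AD fields are carried along when the FORMAT declares
#' them, so the masking rules of [mask_genotypes()] can be applied downstream.
#'
#' @param path path to a VCF file (plain text or bgzip).
#' @param region optional `"chrom:start-end"` string (1-based inclusive,
#'   VCF/samtools convention) restricting the sites returned.
#' @return A `genotype_matrix`. If the file contains no bi-allelic SNPs an
#'   empty matrix is returned with a warning.
#' @export
read_biallelic_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  keep <- vcfR::is.biallelic(v) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (!is.null(region)) {
    reg <- parse_region(region)
    keep <- keep & chrom == reg$chrom & pos >= reg$start & pos <= reg$end
  }
  if (!any(keep)) {
    warning("no bi-allelic SNPs in ", path)
    samples <- colnames(v@gt)[-1]
    return(genotype_matrix(character(0), integer(0), character(0),
                           character(0),
                           matrix(integer(0), 0, length(samples)),
                           sample_ids = samples))
  }
  v <- v[keep, ]
  gt_str <- vcfR::extract.gt(v, element = "GT")
  gt <- gt_to_dosage(gt_str)
  fmt <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
  dp <- ad_alt <- NULL
  if ("DP" %in% fmt) {
    dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
    dimnames(dp) <- NULL
  }
  if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(v, "AD")
    ad_alt <- suppressWarnings(
      apply(ad, 2, function(x) as.numeric(vapply(strsplit(x, ",", fixed = TRUE),
        function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
    )
    ad_alt <- matrix(ad_alt, nrow = nrow(gt))
  }
  genotype_matrix(chrom = v@fix[, "CHROM"], pos = as.integer(v@fix[, "POS"]),
                  ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                  gt = gt, sample_ids = colnames(v@gt)[-1],
                  dp = dp, ad_alt = ad_alt)
}

# "0/1", "1|1", "./.", "0/." -> 1, 2, NA, NA
gt_to_dosage <- function(gt_str) {
  alleles <- gsub("[|/]", "", gt_str)
  out <- matrix(NA_integer_, nrow(gt_str), ncol(gt_str))
  full <- !is.na(alleles) & alleles %in% c("00", "01", "10", "11")
  out[full] <- vapply(strsplit(alleles[full], ""),
                      function(a) sum(as.integer(a)), 1L)
  out
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region (want chrom:start-end): ", region)
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a minimal plain-text VCF with GT (and DP/AD when present) FORMAT
#' fields. Round-trips losslessly through [read_biallelic_vcf()] for the
#' fields the pipeline consumes.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biallelic_vcf <- function(gm, path) {
  has_depth <- !is.null(gm$dp) && !is.null(gm$ad_alt)
  fmt <- if (has_depth) "GT:DP:AD" else "GT"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=refbias",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_depth) {
    header <- c(header,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", gm$sample_ids),
                            collapse = "\t"))
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L],
                   nrow = nrow(gm$gt))
  gt_txt[is.na(gm$gt)] <- "./."
  if (has_depth) {
    dp_txt <- ifelse(is.na(gm$dp), ".", format(gm$dp, trim = TRUE,
                                               scientific = FALSE))
    ref_d <- gm$dp - gm$ad_alt
    ad_txt <- ifelse(is.na(gm$ad_alt) | is.na(gm$dp), ".",
                     paste0(format(ref_d, trim = TRUE, scientific = FALSE),
                            ",",
                            format(gm$ad_alt, trim = TRUE,
                                   scientific = FALSE)))
    gt_txt <- matrix(paste(gt_txt, dp_txt, ad_txt, sep = ":"),
                     nrow = nrow(gt_txt))
  }
  body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", fmt,
                apply(gt_txt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Mask unreliable genotypes by depth and allelic balance
#'
#' Applies the per-genotype quality rules used for large short-read cohorts:
#' a genotype becomes missing when its depth is below 10x or above 1.65 times
#' the sample's mean depth, and a heterozygous genotype becomes missing when
#' its alternate-allele depth fraction `DP_ALT / (DP_REF + DP_ALT)` exceeds
#' 0.8 or falls below 0.25. Boundary values are retained: DP exactly 10 and
#' alt fractions of exactly 0.8 or 0.25 survive (the thresholds are strict
#' inequalities).
#'
#' @param gm a [genotype_matrix()] carrying `dp` and `ad_alt` annotations.
#' @param per_sample_mean_depth numeric vector of genome-wide mean depths,
#'   one per sample (named or in `sample_ids` order).
#' @param min_dp,max_dp_factor,het_hi,het_lo the rule constants; defaults 10,
#'   1.65, 0.8, 0.25.
#' @return A `genotype_matrix` with failing genotypes set to `NA`. Never
#'   converts a missing genotype to a call.
#' @export
mask_genotypes <- function(gm, per_sample_mean_depth, min_dp = 10,
                           max_dp_factor = 1.65, het_hi = 0.8,
                           het_lo = 0.25) {
  if (is.null(gm$dp) || is.null(gm$ad_alt)) {
    stop("mask_genotypes requires DP and AD annotations on the matrix")
  }
  if (!is.null(names(per_sample_mean_depth))) {
    miss <- setdiff(gm$sample_ids, names(per_sample_mean_depth))
    if (length(miss)) stop("no mean depth for sample(s): ",
                           paste(miss, collapse = ", "))
    per_sample_mean_depth <- per_sample_mean_depth[gm$sample_ids]
  }
  if (length(per_sample_mean_depth) != length(gm$sample_ids)) {
    stop("need one mean depth per sample")
  }
  called <- !is.na(gm$gt)
  no_depth <- called & is.na(gm$dp)
  if (any(no_depth)) {
    idx <- which(no_depth, arr.ind = TRUE)[1, ]
    stop("missing DP for called genotype at site ", gm$chrom[idx[1]], ":",
         gm$pos[idx[1]], ", sample ", gm$sample_ids[idx[2]])
  }
  cap <- matrix(max_dp_factor * per_sample_mean_depth,
                nrow = nrow(gm$gt), ncol = ncol(gm$gt), byrow = TRUE)
  drop <- called & (gm$dp < min_dp | gm$dp > cap)
  het <- called & gm$gt == 1L
  af <- gm$ad_alt / gm$dp
  drop <- drop | (het & !is.na(af) & (af > het_hi | af < het_lo))
  gt <- gm$gt
  gt[drop] <- NA_integer_
  genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt, gt, gm$sample_ids,
                  dp = gm$dp, ad_alt = gm$ad_alt)
}

#' Classify SNPs by minor allele frequency
#'
#' Single-frequency classification labels a SNP `"rare"` (MAF < 0.01),
#' `"common"` (MAF > 0.05) or `"intermediate"`. When two call sets A and B are
#' compared (the reference-bias contrast), paired labels are returned:
#' `"Both-rare"`, `"A-rare/B-common"`, `"B-rare/A-common"`, `"A-unique"`
#' (absent from B), `"B-unique"`, or `"other"`.
#'
#' Inputs are alternate-allele frequencies; the minor allele frequency
#' `min(f, 1 - f)` is derived internally. `NA` marks a SNP absent from that
#' call set.
#'
#' @param freq_a alternate-allele frequency in call set A, in `[0, 1]` or `NA`.
#' @param freq_b optional frequency in call set B; when omitted the
#'   single-set labels are returned.
#' @param rare,common MAF thresholds (strict), defaults 0.01 and 0.05.
#' @return Character vector of class labels (vectorized over inputs).
#' @export
classify_maf <- function(freq_a, freq_b = NULL, rare = 0.01, common = 0.05) {
  chk <- function(f, nm) {
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop(nm, " must be in [0, 1] or NA")
    }
  }
  chk(freq_a, "freq_a")
  single <- function(f) {
    maf <- pmin(f, 1 - f)
    ifelse(maf < rare, "rare", ifelse(maf > common, "common", "intermediate"))
  }
  if (is.null(freq_b)) {
    if (anyNA(freq_a)) stop("freq_a must be non-missing for single-set labels")
    return(single(freq_a))
  }
  chk(freq_b, "freq_b")
  if (length(freq_a) != length(freq_b)) stop("freq_a and freq_b lengths differ")
  if (any(is.na(freq_a) & is.na(freq_b))) {
    stop("SNP missing from both call sets")
  }
  la <- single(freq_a)
  lb <- single(freq_b)
  out <- rep("other", length(freq_a))
  out[is.na(freq_b)] <- "A-unique"
  out[is.na(freq_a)] <- "B-unique"
  both <- !is.na(freq_a) & !is.na(freq_b)
  out[both & la == "rare" & lb == "rare"] <- "Both-rare"
  out[both & la == "rare" & lb == "common"] <- "A-rare/B-common"
  out[both & lb == "rare" & la == "common"] <- "B-rare/A-common"
  out
}

#' Write genomic regions as BED
#'
#' Regions are held internally as 1-based closed intervals and converted to
#' BED's 0-based half-open convention on write (start - 1, end unchanged), so
#' the 1-based interval \\[100, 200\\] becomes the BED line `99 200`.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` and
#'   optionally a numeric `score` (written as the 5th BED column with a `.`
#'   name placeholder in column 4).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  df <- data.frame(chrom = regions$chrom,
                   start = regions$start - 1L,
                   end = regions$end)
  if (!is.null(regions$score)) {
    df$name <- "."
    df$score <- regions$score
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based closed regions
#'
#' @param path BED3+ file; a numeric 5th column is read as `score`.
#' @return data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   `score` when present.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]))
  if (ncol(df) >= 5L) out$score <- as.numeric(df[[5]])
  out
}

#' Per-base depth track
#'
#' A depth track covers positions `1..length(depth)` of one chromosome with
#' nonnegative integer coverage, plus the sample's genome-wide mean depth
#' `wg_mean` used for scaling and thresholding.
#'
#' @param chrom chromosome name.
#' @param depth nonnegative integer vector, one value per base from
#'   position 1.
#' @param wg_mean positive genome-wide mean depth.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(chrom, depth, wg_mean) {
  if (any(depth < 0)) stop("depths must be nonnegative")
  if (!is.numeric(wg_mean) || wg_mean <= 0) stop("wg_mean must be > 0")
  structure(list(chrom = as.character(chrom), depth = as.numeric(depth),
                 wg_mean = as.numeric(wg_mean)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat("depth_track:", x$chrom, "1-", length(x$depth),
      sprintf("(mean %.2f, wg_mean %.2f)\n", mean(x$depth), x$wg_mean))
  invisible(x)
}

#' Read a samtools-depth style TSV as a depth track
#'
#' Expects the 3-column `samtools depth` dialect: chromosome, 1-based
#' position, integer depth. Positions absent from the file get depth 0, so a
#' file covering positions 1..10 but missing position 5 yields a track with 0
#' at that base.
#'
#' @param path TSV path.
#' @param wg_mean genome-wide mean depth for the sample (from the full
#'   alignment). If `NULL`, the mean of the returned track is used.
#' @param chrom_len track length; defaults to the largest position seen.
#' @return A [depth_track()].
#' @export
read_depth <- function(path, wg_mean = NULL, chrom_len = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("depth TSV must have 3 columns (chrom, pos, depth)")
  bad <- which(is.na(suppressWarnings(as.integer(df[[2]]))) |
                 is.na(suppressWarnings(as.numeric(df[[3]]))))
  if (length(bad)) stop("malformed depth line ", bad[1], " in ", path)
  if (length(unique(df[[1]])) != 1L) {
    stop("depth track must cover a single chromosome")
  }
  pos <- as.integer(df[[2]])
  if (is.null(chrom_len)) chrom_len <- max(pos)
  depth <- numeric(chrom_len)
  depth[pos] <- as.numeric(df[[3]])
  if (is.null(wg_mean)) wg_mean <- mean(depth)
  depth_track(df[[1]][1], depth, wg_mean)
}

#' Read a bedGraph file as a depth track
#'
#' Alternate depth reader: 4 columns (chrom, 0-based start, end, value),
#' intervals half-open. Uncovered bases get depth 0.
#'
#' @inheritParams read_depth
#' @export
read_bedgraph <- function(path, wg_mean = NULL, chrom_len = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 4L) stop("bedGraph must have 4 columns")
  if (length(unique(df[[1]])) != 1L) {
    stop("depth track must cover a single chromosome")
  }
  if (is.null(chrom_len)) chrom_len <- max(df[[3]])
  depth <- numeric(chrom_len)
  for (i in seq_len(nrow(df))) {
    depth[(df[[2]][i] + 1L):df[[3]][i]] <- df[[4]][i]
  }
  if (is.null(wg_mean)) wg_mean <- mean(depth)
  depth_track(df[[1]][1], depth, wg_mean)
}

#' Write a depth track as samtools-depth TSV
#'
#' Zero-depth positions are omitted, mirroring `samtools depth` output.
#'
#' @param track a [depth_track()].
#' @param path output path.
#' @export
write_depth <- function(track, path) {
  nz <- which(track$depth > 0)
  utils::write.table(
    data.frame(track$chrom, nz, track$depth[nz]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Three tab-separated columns: sample, population, super-population. Every
#' sample must appear exactly once.
#'
#' @param path TSV path (no header).
#' @return data.frame with columns `sample`, `population`, `super_population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop("popmap must have 3 columns")
  names(df) <- c("sample", "population", "super_population")
  dup <- df$sample[duplicated(df$sample)]
  if (length(dup)) stop("duplicate sample(s) in popmap: ",
                        paste(unique(dup), collapse = ", "))
  df
}

#' Write a population map TSV
#'
#' @param popmap data.frame as returned by [read_popmap()].
#' @param path output path.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(
    popmap[, c("sample", "population", "super_population")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-sample mapping statistics
#'
#' Tab-separated with a header line; required columns: `sample`,
#' `population`, `uniqmap_ref_a`, `uniqmap_ref_b`, `uniqclip_ref_a`,
#' `uniqclip_ref_b`. UniqMap columns are the percent of reads uniquely
#' mapped to each candidate reference; UniqClip the percent of uniquely
#' mapped reads with clipped alignments (from the CIGAR). All percentages
#' must lie in `[0, 100]`.
#'
#' @param path TSV path.
#' @return data.frame of mapping statistics.
#' @export
read_mapping_stats <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "population", "uniqmap_ref_a", "uniqmap_ref_b",
            "uniqclip_ref_a", "uniqclip_ref_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapping stats missing column(s): ",
                         paste(miss, collapse = ", "))
  pct <- unlist(df[, need[-(1:2)]])
  if (any(pct < 0 | pct > 100)) stop("percentages must be in [0, 100]")
  df
}
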