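test_that("read_biallelic_vcf keeps only bi-allelic SNPs and maps missing GTs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t1/2",   # tri-allelic: drop
    "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0",
    "chr1\t400\t.\tG\tGA\t.\tPASS\t.\tGT\t0/1\t0/0")    # indel: drop
  write_vcf_lines(recs, c("S1", "S2"), path)
  gm <- read_biallelic_vcf(path)
  expect_equal(length(gm$pos), 2L)
  expect_equal(gm$pos, c(100L, 300L))
  expect_equal(gm$gt[, "S1"], c(1L, NA))
  expect_equal(gm$gt[, "S2"], c(2L, 0L))
  expect_error(read_biallelic_vcf(tempfile()), "cannot read")
})

test_that("half-calls are missing and region restriction is 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".vcf")
  recs <- c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/.\t1|1",
    "chr1\t250\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1")
  write_vcf_lines(recs, c("S1", "S2"), path)
  gm <- read_biallelic_vcf(path)
  expect_true(is.na(gm$gt[1, "S1"]))   # "0/." is a half-call
  expect_equal(unname(gm$gt[1, "S2"]), 2L)     # phased separator accepted
  reg <- read_biallelic_vcf(path, region = "chr1:250-250")
  expect_equal(reg$pos, 250L)
  expect_error(read_biallelic_vcf(path, region = "chr1:abc"), "malformed")
})

test_that("VCF write/read round-trip is lossless for GT, DP and AD", {
  set.seed(11)
  n <- 40L; m <- 6L
  gt <- matrix(sample(c(0:2, NA), n * m, replace = TRUE), n, m)
  dp <- matrix(30L + sample(0:10, n * m, TRUE), n, m)
  ad <- matrix(0L, n, m)
  ad[which(gt == 1L)] <- 15L
  ad[which(gt == 2L)] <- dp[which(gt == 2L)]
  dp[is.na(gt)] <- NA; ad[is.na(gt)] <- NA
  gm <- toy_gm(gt, dp = dp, ad_alt = ad)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_biallelic_vcf(gm, path)
  back <- read_biallelic_vcf(path)
  expect_equal(unname(back$gt), unname(gm$gt))
  expect_equal(unname(back$dp), unname(gm$dp))
  expect_equal(unname(back$ad_alt), unname(gm$ad_alt))
  expect_equal(back$pos, gm$pos)
  expect_equal(back$ref, gm$ref)
})

test_that("genotype_matrix validates dimensions, values and position order", {
  expect_error(toy_gm(matrix(3L, 2, 2)), "0, 1, 2 or NA")
  expect_error(toy_gm(matrix(0L, 2, 2), pos = c(200L, 100L)),
               "strictly increasing")
  expect_error(genotype_matrix("chr1", 1L, "A", "G",
                               matrix(0L, 2, 1), "S1"),
               "sites x samples")
})

test_that("mask_genotypes applies depth and allelic-balance rules strictly", {
  # sample mean depth 30 -> cap at 49.5
  gt <- matrix(c(1L, 1L, 1L, 1L, 1L, 0L, NA), ncol = 1)
  dp <- matrix(c(9, 10, 50, 30, 30, 30, NA), ncol = 1)
  ad <- matrix(c(4, 5, 25, 27, 24, 0, NA), ncol = 1)
  gm <- toy_gm(gt, dp = dp, ad_alt = ad)
  m <- mask_genotypes(gm, c(S01 = 30))
  expect_true(is.na(m$gt[1, 1]))      # DP 9 < 10: missing
  expect_equal(unname(m$gt[2, 1]), 1L)        # DP exactly 10: retained
  expect_true(is.na(m$gt[3, 1]))      # DP 50 > 1.65 * 30: missing
  expect_true(is.na(m$gt[4, 1]))      # het alt fraction 0.9 > 0.8: missing
  expect_equal(unname(m$gt[5, 1]), 1L)        # het alt fraction 0.8 exactly: retained
  expect_equal(unname(m$gt[6, 1]), 0L)        # hom-ref untouched by balance rule
  expect_true(is.na(m$gt[7, 1]))      # missing stays missing
})

test_that("masking never rescues genotypes and non-missing count never grows", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 30L; m <- 4L
    gt <- matrix(sample(c(0:2, NA), n * m, TRUE), n, m)
    dp <- matrix(rpois(n * m, 25), n, m)
    ad <- matrix(rbinom(n * m, dp, 0.5), n, m)
    dp[is.na(gt)] <- NA
    gm <- toy_gm(gt, dp = dp, ad_alt = ad)
    masked <- mask_genotypes(gm, rep(25, m))
    was_na <- is.na(gm$gt)
    expect_true(all(is.na(masked$gt[was_na])))
    expect_lte(sum(!is.na(masked$gt)), sum(!is.na(gm$gt)))
    same <- !is.na(masked$gt)
    expect_equal(masked$gt[same], gm$gt[same])
  }
})

test_that("mask_genotypes errors identify the offending cell", {
  gm <- toy_gm(matrix(1L, 1, 1), dp = matrix(NA_real_, 1, 1),
               ad_alt = matrix(NA_real_, 1, 1))
  expect_error(mask_genotypes(gm, c(S01 = 30)), "chr1:100.*S01")
  gm2 <- toy_gm(matrix(1L, 1, 1))
  expect_error(mask_genotypes(gm2, 30), "requires DP and AD")
})

test_that("classify_maf single and paired labels follow the MAF thresholds", {
  expect_equal(classify_maf(0.005), "rare")
  expect_equal(classify_maf(0.995), "rare")       # MAF is min(f, 1-f)
  expect_equal(classify_maf(0.2), "common")
  expect_equal(classify_maf(0.03), "intermediate")
  expect_equal(classify_maf(0.01), "intermediate")  # boundary not rare
  expect_equal(classify_maf(0.005, 0.005), "Both-rare")
  expect_equal(classify_maf(0.008, 0.20), "A-rare/B-common")
  expect_equal(classify_maf(0.20, 0.008), "B-rare/A-common")
  expect_equal(classify_maf(0.03, NA), "A-unique")
  expect_equal(classify_maf(NA, 0.03), "B-unique")
  expect_equal(classify_maf(0.03, 0.04), "other")
  expect_error(classify_maf(1.2), "\\[0, 1\\]")
  expect_error(classify_maf(NA, NA), "both call sets")
})

test_that("paired classify_maf is symmetric under A/B swap with mirrored labels", {
  set.seed(3)
  fa <- c(runif(50), NA, 0.005)
  fb <- c(runif(50), 0.2, NA)
  ab <- classify_maf(fa, fb)
  ba <- classify_maf(fb, fa)
  mirror <- c("Both-rare" = "Both-rare",
              "A-rare/B-common" = "B-rare/A-common",
              "B-rare/A-common" = "A-rare/B-common",
              "A-unique" = "B-unique", "B-unique" = "A-unique",
              "other" = "other")
  expect_equal(unname(mirror[ab]), ba)
})

test_that("BED round-trip converts between 1-based closed and 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".bed")
  regions <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                        score = 0.5)
  write_bed(regions, path)
  line <- readLines(path)
  expect_equal(strsplit(line, "\t")[[1]][1:3], c("chr1", "99", "200"))
  back <- read_bed(path)
  expect_equal(back$start, 100L)
  expect_equal(back$end, 200L)
  expect_equal(back$score, 0.5)
})

test_that("read_depth fills absent positions with zero and validates input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", pos = c(1:4, 6:10), depth = 7L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tr <- read_depth(path)
  expect_equal(length(tr$depth), 10L)
  expect_equal(tr$depth[5], 0)
  expect_equal(tr$depth[4], 7)
  writeLines(c("chr1\t1\t5", "chr1\ttwo\t5"), path)
  expect_error(read_depth(path), "line 2")
})

test_that("bedGraph reader agrees with the samtools-depth reader", {
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeLines(c("chr1\t0\t5\t3", "chr1\t7\t10\t8"), p1)
  write.table(data.frame("chr1", c(1:5, 8:10), c(rep(3, 5), rep(8, 3))),
              p2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(read_bedgraph(p1)$depth, read_depth(p2)$depth)
})

test_that("depth track write/read round-trips", {
  tr <- depth_track("chr1", c(0, 3, 0, 5, 5), wg_mean = 4)
  path <- withr::local_tempfile()
  write_depth(tr, path)
  back <- read_depth(path, wg_mean = 4, chrom_len = 5)
  expect_equal(back$depth, tr$depth)
})

test_that("popmap reader enforces the one-population-per-sample invariant", {
  path <- withr::local_tempfile()
  writeLines(c("S1\tHan\tEAS", "S2\tCEU\tEUR"), path)
  pm <- read_popmap(path)
  expect_equal(pm$population, c("Han", "CEU"))
  writeLines(c("S1\tHan\tEAS", "S1\tCEU\tEUR"), path)
  expect_error(read_popmap(path), "duplicate sample")
})

test_that("mapping-stats reader checks columns and percentage ranges", {
  path <- withr::local_tempfile()
  df <- data.frame(sample = "a", population = "P", uniqmap_ref_a = 95,
                   uniqmap_ref_b = 94, uniqclip_ref_a = 2,
                   uniqclip_ref_b = 3)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_mapping_stats(path)$uniqmap_ref_a, 95)
  df$uniqmap_ref_a <- 101
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mapping_stats(path), "\\[0, 100\\]")
})
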