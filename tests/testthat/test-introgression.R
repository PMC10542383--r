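# brute-force per-site window accumulation used as the oracle for window_scan
brute_window_scan <- function(sites, window, step, min_good, chrom_len) {
  starts <- seq(1L, chrom_len, by = step)
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1L, chrom_len)
    sa <- sb <- sf <- 0
    n <- 0L
    for (i in seq_len(nrow(sites))) {
      if (sites$good[i] && sites$pos[i] >= s && sites$pos[i] <= e) {
        n <- n + 1L
        ab <- site_abba_baba(sites$p1[i], sites$p2[i], sites$p3[i],
                             sites$p4[i])
        sa <- sa + ab$abba
        sb <- sb + ab$baba
        sf <- sf + site_fd_denominator(sites$p1[i], sites$p2[i],
                                       sites$p3[i], sites$p4[i])
      }
    }
    data.frame(start = s, end = e, n_good_sites = n,
               sum_abba = sa, sum_baba = sb, sum_fd_den = sf)
  })
  df <- do.call(rbind, rows)
  df[df$n_good_sites >= min_good, , drop = FALSE]
}

random_sites <- function(n, chrom_len, seed) {
  set.seed(seed)
  data.frame(chrom = "chr1", pos = sort(sample.int(chrom_len, n)),
             p1 = runif(n), p2 = runif(n), p3 = runif(n),
             p4 = 0, good = runif(n) < 0.9)
}

test_that("site_frequencies polarizes on the outgroup and flags good sites", {
  # 4 diploids: P1, P2, P3, OUT — hand-countable
  gt <- rbind(c(0L, 2L, 2L, 0L),   # out all REF: derived = ALT; p2 = 1
              c(2L, 0L, 0L, 2L),   # out all ALT: flip; p1 = 0 derived
              c(1L, 1L, 2L, 1L),   # out 50/50: unpolarizable
              c(0L, 1L, 2L, 0L),
              c(NA, 1L, 1L, 0L))   # P1 uncalled: not good
  gm <- toy_gm(gt, samples = c("a", "b", "c", "d"))
  pm <- toy_popmap(c("a", "b", "c", "d"), c("P1", "P2", "P3", "OUT"))
  sf <- site_frequencies(gm, pm)
  expect_equal(sf$p4[1], 0)
  expect_equal(sf$p2[1], 1)
  expect_equal(sf$p1[2], 0)        # was fixed ALT, flipped to derived 0
  expect_equal(sf$p3[2], 1)        # was fixed REF -> derived 1 after flip
  expect_false(sf$good[3])         # polymorphic outgroup excluded
  expect_true(sf$good[4])
  expect_equal(sf$p2[4], 0.5)      # 1 of 2 P2 alleles, manual count
  expect_false(sf$good[5])
  expect_equal(sf$n1[5], 0L)
})

test_that("site_frequencies errors on an all-missing taxon", {
  gt <- cbind(c(NA, NA), c(0L, 1L), c(1L, 1L), c(0L, 0L))
  gm <- toy_gm(gt, samples = c("a", "b", "c", "d"))
  pm <- toy_popmap(c("a", "b", "c", "d"), c("P1", "P2", "P3", "OUT"))
  expect_error(site_frequencies(gm, pm), "no called genotypes")
  expect_error(site_frequencies(gm, pm,
                                taxa = list(p1 = "X", p2 = "P2", p3 = "P3",
                                            outgroup = "OUT")),
               "no samples")
})

test_that("site ABBA/BABA weights reproduce fixed patterns and direct arithmetic", {
  expect_equal(site_abba_baba(0, 1, 1, 0), data.frame(abba = 1, baba = 0))
  expect_equal(site_abba_baba(1, 0, 1, 0), data.frame(abba = 0, baba = 1))
  ab <- site_abba_baba(0.2, 0.8, 0.6, 0)
  expect_equal(ab$abba, 0.384)
  expect_equal(ab$baba, 0.024)
  expect_error(site_abba_baba(1.2, 0, 0, 0), "\\[0, 1\\]")
})

test_that("f_d denominator uses the max-frequency donor", {
  expect_equal(site_fd_denominator(0, 0.5, 1, 0), 1)    # pD = 1
  expect_equal(site_fd_denominator(0, 1, 1, 0), 1)      # full replacement
  # pD = 0.5: (0.5)(0.25)(1) - (0.5)(0.5)(0.5) = 0; the site contributes 0
  # to the f_d numerator as well
  expect_equal(site_fd_denominator(0.5, 0.5, 0.5, 0), 0)
  # symmetric in p2/p3 through pD
  expect_equal(site_fd_denominator(0.3, 0.9, 0.2, 0.1),
               site_fd_denominator(0.3, 0.2, 0.9, 0.1))
})

test_that("window_scan drops thin windows and handles the pure-ABBA case", {
  # 29 good sites in the first 10-kb window: absent from output
  sites <- data.frame(chrom = "chr1", pos = c(seq_len(29) * 300L, 20000L),
                      p1 = 0, p2 = 1, p3 = 1, p4 = 0, good = TRUE)
  w <- window_scan(sites, window = 10000L, step = 10000L, min_good = 30L,
                   chrom_len = 20000L)
  expect_false(1L %in% w$start)
  sites30 <- data.frame(chrom = "chr1", pos = seq_len(30) * 300L,
                        p1 = 0, p2 = 1, p3 = 1, p4 = 0, good = TRUE)
  w30 <- window_scan(sites30, window = 10000L, step = 10000L,
                     chrom_len = 10000L)
  expect_equal(nrow(w30), 1L)
  expect_equal(w30$D, 1)
  expect_equal(w30$fd, 1)
  expect_error(window_scan(sites30, window = 0), "positive")
  expect_error(window_scan(sites30[c(2, 1), ], window = 100),
               "sorted")
})

test_that("window sums match the brute-force per-site oracle exactly", {
  for (seed in 1:4) {
    sites <- random_sites(n = 200L, chrom_len = 30000L, seed = seed)
    got <- window_scan(sites, window = 10000L, step = 3000L, min_good = 5L,
                       chrom_len = 30000L)
    want <- brute_window_scan(sites, window = 10000L, step = 3000L,
                              min_good = 5L, chrom_len = 30000L)
    expect_equal(got$start, want$start)
    expect_equal(got$n_good_sites, want$n_good_sites)
    expect_equal(got$sum_abba, want$sum_abba)
    expect_equal(got$sum_baba, want$sum_baba)
    expect_equal(got$sum_fd_den, want$sum_fd_den)
  }
})

test_that("D stays in [-1, 1] and f_d in [0, 1] wherever defined", {
  sites <- random_sites(n = 500L, chrom_len = 50000L, seed = 17)
  w <- window_scan(sites, window = 5000L, step = 1000L, min_good = 5L)
  D <- w$D[!is.na(w$D)]
  expect_true(all(D >= -1 & D <= 1))
  fd <- w$fd[!is.na(w$fd)]
  expect_true(all(fd >= 0 & fd <= 1))
  expect_true(all(w$fd[!is.na(w$D) & w$D <= 0] == 0, na.rm = TRUE))
})

test_that("pIR calling merges abutting outliers and applies the length floor", {
  mk_windows <- function(starts, fd, window = 10000L) {
    data.frame(chrom = "chr1", start = starts, end = starts + window - 1L,
               n_good_sites = 50L, sum_abba = 1, sum_baba = 0,
               sum_fd_den = 1, D = 0.5, fd = fd)
  }
  # three overlapping outlier windows spanning 12 kb total: dropped
  w <- mk_windows(c(1L, 1001L, 2001L), fd = 0.9)
  expect_equal(nrow(call_pirs(w)), 0L)
  # eleven consecutive outlier windows spanning exactly 20 kb: one pIR
  w11 <- mk_windows(seq(1L, 10001L, by = 1000L), fd = 0.5)
  pir <- call_pirs(w11)
  expect_equal(nrow(pir), 1L)
  expect_equal(pir$start, 1L)
  expect_equal(pir$end, 20000L)
  expect_equal(pir$max_fd, 0.5)
  expect_equal(pir$n_windows, 11L)
  # f_d exactly at the cutoff is not an outlier
  w035 <- mk_windows(seq(1L, 30001L, by = 1000L), fd = 0.35)
  expect_equal(nrow(call_pirs(w035)), 0L)
  # windows with D <= 0 never seed a pIR
  wneg <- mk_windows(seq(1L, 30001L, by = 1000L), fd = 0.9)
  wneg$D <- -0.5
  expect_equal(nrow(call_pirs(wneg)), 0L)
  expect_error(call_pirs(w11[c(3, 1, 2), ]), "sorted")
})

test_that("pIR intervals equal the interval union of outlier windows", {
  set.seed(31)
  for (rep in 1:5) {
    starts <- seq(1L, 200000L, by = 1000L)
    fd <- ifelse(runif(length(starts)) < 0.15, 0.8, 0.1)
    w <- data.frame(chrom = "chr1", start = starts, end = starts + 9999L,
                    n_good_sites = 40L, sum_abba = 1, sum_baba = 0,
                    sum_fd_den = 1, D = 0.4, fd = fd)
    pir <- call_pirs(w, min_len = 1L)
    out <- w[w$fd > 0.35, ]
    want <- IRanges::reduce(IRanges::IRanges(out$start, out$end))
    expect_equal(pir$start, IRanges::start(want))
    expect_equal(pir$end, IRanges::end(want))
    expect_equal(sum(pir$n_windows), nrow(out))
  }
})
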