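#' Per-site derived-allele frequencies for the four-taxon test
#'
#' Computes derived-allele frequencies p1..p4 for the topology
#' `((P1, P2), P3, O)` at every site of a genotype matrix. The derived
#' allele is the allele *not* carried by the outgroup majority: when the
#' outgroup's alternate-allele frequency exceeds 0.5 the site is re-polarized
#' (frequencies flipped to `1 - f`). Frequencies are computed over
#' non-missing alleles only.
#'
#' A site is flagged `good` — usable by the ABBA-BABA statistics — when every
#' taxon has at least one called allele and the outgroup is close to
#' fixation (outgroup minor-allele frequency at most `outgroup_max_maf`);
#' sites with a polymorphic outgroup cannot be polarized reliably.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap population map data.frame (see [read_popmap()]).
#' @param taxa named list/vector mapping `p1`, `p2`, `p3`, `outgroup` to
#'   population labels in `popmap` (each may name several populations).
#' @param outgroup_max_maf polarization tolerance (default 0.1).
#' @return data.frame with columns `chrom`, `pos`, `p1`..`p4` (derived
#'   frequencies), `n1`..`n4` (called allele counts) and logical `good`.
#' @export
site_frequencies <- function(gm, popmap,
                             taxa = list(p1 = "P1", p2 = "P2", p3 = "P3",
                                         outgroup = "OUT"),
                             outgroup_max_maf = 0.1) {
  stopifnot(all(c("p1", "p2", "p3", "outgroup") %in% names(taxa)))
  cols_of <- function(pops) {
    s <- popmap$sample[popmap$population %in% pops]
    idx <- match(s, gm$sample_ids)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("no samples found for taxon population(s): ",
                           paste(pops, collapse = ", "))
    idx
  }
  taxon_freq <- function(pops) {
    g <- gm$gt[, cols_of(pops), drop = FALSE]
    n_called <- 2L * rowSums(!is.na(g))
    if (all(n_called == 0L)) stop("taxon has no called genotypes at any site")
    alt <- rowSums(g, na.rm = TRUE)
    list(f = ifelse(n_called > 0L, alt / n_called, NA_real_), n = n_called)
  }
  f1 <- taxon_freq(taxa$p1)
  f2 <- taxon_freq(taxa$p2)
  f3 <- taxon_freq(taxa$p3)
  f4 <- taxon_freq(taxa$outgroup)
  # polarize on the outgroup majority allele
  flip <- !is.na(f4$f) & f4$f > 0.5
  pol <- function(f) ifelse(flip, 1 - f, f)
  out_maf <- pmin(f4$f, 1 - f4$f)
  good <- f1$n > 0L & f2$n > 0L & f3$n > 0L & f4$n > 0L &
    !is.na(out_maf) & out_maf <= outgroup_max_maf
  data.frame(chrom = gm$chrom, pos = gm$pos,
             p1 = pol(f1$f), p2 = pol(f2$f), p3 = pol(f3$f), p4 = pol(f4$f),
             n1 = f1$n, n2 = f2$n, n3 = f3$n, n4 = f4$n,
             good = good)
}

#' Site-level ABBA and BABA weights
#'
#' Frequency-based ABBA-BABA contributions of one or more sites:
#' `abba = (1 - p1) p2 p3 (1 - p4)` and `baba = p1 (1 - p2) p3 (1 - p4)`.
#' For fixed patterns these reduce to the classical site counts: derived
#' shared P2-P3 gives (1, 0), derived shared P1-P3 gives (0, 1).
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in `[0, 1]` (vectorized),
#'   or a data.frame from [site_frequencies()] as the first argument.
#' @return data.frame with columns `abba`, `baba`.
#' @export
site_abba_baba <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL) {
  if (is.data.frame(p1)) {
    s <- p1
    p1 <- s$p1; p2 <- s$p2; p3 <- s$p3; p4 <- s$p4
  }
  check_freq(p1, p2, p3, p4)
  data.frame(abba = (1 - p1) * p2 * p3 * (1 - p4),
             baba = p1 * (1 - p2) * p3 * (1 - p4))
}

check_freq <- function(...) {
  f <- c(...)
  if (any(is.na(f)) || any(f < 0 | f > 1)) {
    stop("frequencies must be in [0, 1]")
  }
  invisible()
}

#' Site-level f_d denominator
#'
#' The dynamic-donor denominator of the modified D statistic: the
#' ABBA - BABA difference recomputed with both p2 and p3 replaced by
#' `pD = max(p2, p3)`, i.e. the value the numerator would take under
#' complete replacement of the recipient by the more derived of the two.
#'
#' @inheritParams site_abba_baba
#' @return numeric vector of denominators.
#' @export
site_fd_denominator <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL) {
  if (is.data.frame(p1)) {
    s <- p1
    p1 <- s$p1; p2 <- s$p2; p3 <- s$p3; p4 <- s$p4
  }
  check_freq(p1, p2, p3, p4)
  pd <- pmax(p2, p3)
  (1 - p1) * pd * pd * (1 - p4) - p1 * (1 - pd) * pd * (1 - p4)
}

#' Sliding-window ABBA-BABA scan
#'
#' Accumulates site ABBA, BABA and f_d-denominator weights over sliding
#' windows (default 10 kb, 1-kb step, anchored at position 1 of the
#' chromosome; the last partial window is kept) and derives per-window
#' Patterson's D and the modified statistic
#' `f_d = sum(abba - baba) / sum(denominator)`. Only `good` sites
#' contribute; windows with fewer than `min_good` good sites are discarded.
#' `f_d` is reported only where D > 0 and clamped to `[0, 1]`; windows with
#' D <= 0 get `f_d = 0`, and windows with no ABBA/BABA information have both
#' statistics `NA`.
#'
#' @param sites data.frame from [site_frequencies()], sorted by position
#'   (single chromosome).
#' @param window,step window and step sizes in bp.
#' @param min_good minimum good sites per retained window (default 30).
#' @param chrom_len optional chromosome length; defaults to the largest site
#'   position.
#' @return data.frame: `chrom`, `start`, `end` (1-based closed),
#'   `n_good_sites`, `sum_abba`, `sum_baba`, `sum_fd_den`, `D`, `fd`.
#' @export
window_scan <- function(sites, window = 10000L, step = 1000L,
                        min_good = 30L, chrom_len = NULL) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (length(unique(sites$chrom)) > 1L) {
    stop("window_scan expects a single chromosome")
  }
  if (is.unsorted(sites$pos)) stop("sites must be sorted by position")
  if (is.null(chrom_len)) chrom_len <- max(sites$pos)
  g <- sites[sites$good, , drop = FALSE]
  ab <- site_abba_baba(g)
  fden <- site_fd_denominator(g)
  # prefix sums over good sites; window sums by binary search on position
  ca <- c(0, cumsum(ab$abba))
  cb <- c(0, cumsum(ab$baba))
  cf <- c(0, cumsum(fden))
  cn <- 0:nrow(g)
  starts <- seq.int(1L, max(1L, chrom_len), by = step)
  ends <- pmin(starts + window - 1L, chrom_len)
  starts <- starts[starts <= chrom_len]
  lo <- findInterval(starts - 1L, g$pos) + 1L   # first good site >= start
  hi <- findInterval(ends, g$pos)               # last good site <= end
  n_good <- cn[hi + 1L] - cn[lo]
  keep <- n_good >= min_good
  sa <- ca[hi + 1L] - ca[lo]
  sb <- cb[hi + 1L] - cb[lo]
  sf <- cf[hi + 1L] - cf[lo]
  tot <- sa + sb
  D <- ifelse(tot > 0, (sa - sb) / tot, NA_real_)
  fd <- ifelse(is.na(D), NA_real_,
               ifelse(D > 0 & sf > 0, pmin(pmax((sa - sb) / sf, 0), 1), 0))
  data.frame(chrom = if (nrow(sites)) sites$chrom[1] else character(0),
             start = starts, end = ends, n_good_sites = n_good,
             sum_abba = sa, sum_baba = sb, sum_fd_den = sf,
             D = D, fd = fd)[keep, , drop = FALSE]
}

#' Call putative introgression regions from an f_d scan
#'
#' Outlier windows — `f_d` strictly above `cutoff` with D > 0 — are merged
#' whenever they overlap or abut, and merged intervals shorter than
#' `min_len` are dropped. Each retained region records its maximum window
#' f_d and the number of contributing windows.
#'
#' @param windows output of [window_scan()] for one chromosome, sorted by
#'   start.
#' @param cutoff empirical f_d outlier cutoff (default 0.35, strict).
#' @param min_len minimum merged region length in bp (default 20 kb).
#' @param gap maximum gap (bp) bridged when merging outlier windows
#'   (default 0: only overlapping or abutting windows merge).
#' @return data.frame: `chrom`, `start`, `end`, `max_fd`, `n_windows`.
#' @export
call_pirs <- function(windows, cutoff = 0.35, min_len = 20000L, gap = 0L) {
  if (length(unique(windows$chrom)) > 1L) {
    stop("call_pirs expects windows from a single chromosome")
  }
  if (is.unsorted(windows$start)) stop("windows must be sorted by start")
  out <- windows[!is.na(windows$fd) & windows$fd > cutoff &
                   !is.na(windows$D) & windows$D > 0, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), max_fd = numeric(0),
                      n_windows = integer(0))
  if (!nrow(out)) return(empty)
  ir <- IRanges::IRanges(start = out$start, end = out$end)
  merged <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  merged <- merged[IRanges::width(merged) >= min_len]
  if (!length(merged)) return(empty)
  hit <- IRanges::overlapsAny(ir, merged)
  grp <- findInterval(out$start, IRanges::start(merged))
  grp[!hit] <- NA
  data.frame(chrom = out$chrom[1],
             start = IRanges::start(merged), end = IRanges::end(merged),
             max_fd = as.numeric(tapply(out$fd[hit], grp[hit], max)),
             n_windows = as.integer(table(grp[hit])))
}
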