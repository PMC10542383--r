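#' Detect specific mapping regions from a depth track
#'
#' A specific mapping region (SMR) is a stretch of the genome covered by
#' reads that map to one candidate reference but not the other at more than
#' half the genome-wide coverage. Candidates are maximal runs of bases whose
#' specific depth strictly exceeds `wg_mean / 2`; runs separated by at most
#' `merge_gap` bases are merged; a merged region is retained when its mean
#' specific depth still exceeds `wg_mean / 2` and its length is at least
#' `min_len` (default 100 bp).
#'
#' `wg_mean` is the mean depth of the *full* alignment, not of the specific
#' track; pass `wg_mean` explicitly to override the track's own value.
#'
#' @param specific a [depth_track()] of reference-specific coverage.
#' @param min_len minimum region length in bp.
#' @param merge_gap maximum sub-threshold gap merged over (default 0).
#' @param wg_mean genome-wide full-alignment mean depth; defaults to
#'   `specific$wg_mean`.
#' @return data.frame: `chrom`, `start`, `end` (1-based closed),
#'   `mean_depth`, `length`.
#' @export
detect_smr <- function(specific, min_len = 100L, merge_gap = 0L,
                       wg_mean = specific$wg_mean) {
  if (is.null(wg_mean) || wg_mean <= 0) stop("wg_mean must be > 0")
  thr <- wg_mean / 2
  above <- specific$depth > thr
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_depth = numeric(0),
                      length = integer(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ir <- IRanges::IRanges(start = starts[r$values], end = ends[r$values])
  merged <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
  cs <- c(0, cumsum(specific$depth))
  s <- IRanges::start(merged)
  e <- IRanges::end(merged)
  mean_depth <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
  keep <- mean_depth > thr & (e - s + 1L) >= min_len
  if (!any(keep)) return(empty)
  data.frame(chrom = specific$chrom, start = s[keep], end = e[keep],
             mean_depth = mean_depth[keep],
             length = (e - s + 1L)[keep])
}

#' Scaled mean depth of a region
#'
#' Mean depth over a region divided by the sample's genome-wide mean depth.
#' Bases inside the region with no coverage data count as depth 0.
#'
#' @param track a [depth_track()].
#' @param start,end region bounds, 1-based closed, within the track.
#' @return scaled depth, a nonnegative real.
#' @export
scaled_region_depth <- function(track, start, end) {
  if (start > end) stop("empty region")
  if (start < 1L || end > length(track$depth)) {
    stop("region outside track range 1..", length(track$depth))
  }
  mean(track$depth[start:end]) / track$wg_mean
}

#' Genotype an insertion from scaled depth
#'
#' Presence/absence genotyping of a large insertion from read depth scaled
#' by genome-wide coverage: scaled depth in `[het_lo, het_hi]` (default
#' \\[0.4, 0.8\\], closed at both ends) is called heterozygous, above
#' `het_hi` homozygous for the insertion, below `het_lo` absent.
#'
#' @param scaled scaled depth value(s) from [scaled_region_depth()];
#'   nonnegative.
#' @param het_lo,het_hi heterozygous band bounds.
#' @return character vector in `{"absent", "heterozygous", "homozygous"}`.
#' @export
call_insertion_genotype <- function(scaled, het_lo = 0.4, het_hi = 0.8) {
  if (any(is.na(scaled)) || any(scaled < 0)) {
    stop("scaled depth must be nonnegative")
  }
  ifelse(scaled > het_hi, "homozygous",
         ifelse(scaled >= het_lo, "heterozygous", "absent"))
}

#' Per-population insertion allele frequencies
#'
#' Converts presence/absence genotype calls into an insertion allele
#' frequency per population: `(n_het + 2 n_hom) / (2 n_samples)`.
#'
#' @param calls data.frame with columns `sample` and `call` (values from
#'   [call_insertion_genotype()]).
#' @param popmap population map (see [read_popmap()]); every genotyped
#'   sample must appear in it. Populations with no genotyped sample get
#'   frequency `NA`.
#' @return data.frame: `population`, `n_samples`, `frequency`.
#' @export
population_insertion_frequency <- function(calls, popmap) {
  miss <- setdiff(calls$sample, popmap$sample)
  if (length(miss)) stop("sample(s) absent from popmap: ",
                         paste(miss, collapse = ", "))
  pop <- popmap$population[match(calls$sample, popmap$sample)]
  dose <- c(absent = 0L, heterozygous = 1L, homozygous = 2L)[calls$call]
  pops <- unique(popmap$population)
  n <- vapply(pops, function(p) sum(pop == p), 1L)
  ac <- vapply(pops, function(p) sum(dose[pop == p]), 1L)
  data.frame(population = pops, n_samples = n,
             frequency = ifelse(n > 0L, ac / (2 * n), NA_real_),
             row.names = NULL)
}
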