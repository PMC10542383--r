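#' Count structural variants per non-overlapping window
#'
#' Tiles a chromosome with non-overlapping windows (default 500 kb) and
#' counts the SV heterozygosity rate `h`: the number of SVs whose *start*
#' falls in each window (an SV spanning a boundary counts once, in the
#' window of its start). With `mode = "overlap"` an SV is instead counted in
#' every window it overlaps.
#'
#' @param svs data.frame with `chrom`, `start`, `end` (1-based closed; use
#'   [read_bed()] for BED-like input, whose 0-based start 500000 becomes
#'   1-based 500001 and therefore falls in the second 500-kb window).
#' @param chrom_len chromosome length in bp.
#' @param window_size window size in bp (default 500 kb).
#' @param mode `"start"` (default) or `"overlap"`.
#' @return data.frame: `chrom`, `start`, `end`, `h`. Under `"start"` mode
#'   the window counts always sum to `nrow(svs)`.
#' @export
count_svs_per_window <- function(svs, chrom_len, window_size = 500000L,
                                 mode = c("start", "overlap")) {
  mode <- match.arg(mode)
  if (length(unique(svs$chrom)) > 1L) stop("one chromosome at a time")
  if (any(svs$start < 1L) || any(svs$start > chrom_len)) {
    stop("SV start beyond chromosome bounds")
  }
  n_win <- ceiling(chrom_len / window_size)
  starts <- (seq_len(n_win) - 1L) * window_size + 1L
  ends <- pmin(starts + window_size - 1L, chrom_len)
  if (mode == "start") {
    idx <- (svs$start - 1L) %/% window_size + 1L
    h <- tabulate(idx, nbins = n_win)
  } else {
    wir <- IRanges::IRanges(start = starts, end = ends)
    sir <- IRanges::IRanges(start = svs$start,
                            end = pmin(svs$end, chrom_len))
    h <- IRanges::countOverlaps(wir, sir)
  }
  data.frame(chrom = if (nrow(svs)) svs$chrom[1] else "chr",
             start = starts, end = ends, h = as.integer(h))
}

#' Classify windows as heterozygous or homozygous
#'
#' A window with SV count `h >= threshold` (default 2) is labelled `"hete"`,
#' otherwise `"homo"` — the rule used to decide which 500-kb windows are
#' drawn as bubbles between two haplotype assemblies.
#'
#' @param counts output of [count_svs_per_window()].
#' @param threshold minimum `h` for a heterozygous window.
#' @return `counts` with an added `class` column.
#' @export
classify_windows <- function(counts, threshold = 2L) {
  counts$class <- ifelse(counts$h >= threshold, "hete", "homo")
  counts
}

#' Build a GFA 1.0 bubble graph from classified windows
#'
#' Renders the two-haplotype structure of a chromosome as an assembly
#' graph: maximal runs of homozygous windows collapse into a single segment
#' (one path shared by both haplotypes), and every heterozygous window
#' becomes a bubble — two parallel segments, one per haplotype — linked to
#' the flanking segments. Segment names encode `chrom:start-end:hap`
#' (hap `0` for shared, `1`/`2` for the bubble arms); sequences are omitted
#' (`*`) with `LN` length tags, and the window SV count is carried as an
#' `hc:i` tag so renderers can shade bubbles by heterozygosity rate.
#'
#' @param windows output of [classify_windows()]; windows must tile the
#'   chromosome contiguously.
#' @return character vector of GFA 1.0 lines (H, S and L records).
#' @export
build_bubble_gfa <- function(windows) {
  if (!nrow(windows)) stop("no windows")
  if (is.unsorted(windows$start) ||
      any(windows$start[-1] != windows$end[-nrow(windows)] + 1L)) {
    stop("windows must tile the chromosome contiguously")
  }
  chrom <- windows$chrom[1]
  # collapse homo runs into components; each hete window is its own bubble
  run <- cumsum(c(TRUE, windows$class[-1] == "hete" |
                    windows$class[-nrow(windows)] == "hete"))
  comp <- lapply(split(seq_len(nrow(windows)), run), function(i) {
    w <- windows[i, , drop = FALSE]
    list(start = w$start[1], end = w$end[nrow(w)],
         hete = w$class[1] == "hete", h = sum(w$h))
  })
  seg_name <- function(c, hap) {
    sprintf("%s:%d-%d:%d", chrom, c$start, c$end, hap)
  }
  segs <- character(0)
  links <- character(0)
  s_line <- function(c, hap) {
    sprintf("S\t%s\t*\tLN:i:%d\thc:i:%d", seg_name(c, hap),
            c$end - c$start + 1L, c$h)
  }
  for (c in comp) {
    segs <- c(segs, if (c$hete) c(s_line(c, 1L), s_line(c, 2L))
              else s_line(c, 0L))
  }
  ends_of <- function(c) {
    if (c$hete) c(seg_name(c, 1L), seg_name(c, 2L)) else seg_name(c, 0L)
  }
  if (length(comp) > 1L) {
    for (k in seq_len(length(comp) - 1L)) {
      for (a in ends_of(comp[[k]])) {
        for (b in ends_of(comp[[k + 1L]])) {
          links <- c(links, sprintf("L\t%s\t+\t%s\t+\t0M", a, b))
        }
      }
    }
  }
  c("H\tVN:Z:1.0", segs, links)
}

#' Write GFA lines to a file
#'
#' @param gfa character vector from [build_bubble_gfa()].
#' @param path output path.
#' @export
write_gfa <- function(gfa, path) {
  writeLines(gfa, path)
  invisible(path)
}

#' Alignment p-distance
#'
#' Pairwise divergence of two gapped, equal-length aligned sequences:
#' `mismatched bases / (aligned columns - gap columns)`. Columns containing
#' a gap (`-`) or an ambiguous base (`N`) in either sequence are excluded;
#' mismatches are counted over the remaining columns only. Case-insensitive.
#'
#' @param a,b aligned sequences (single strings over `A C G T N -`) of equal
#'   length.
#' @return divergence in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y)) stop("aligned sequences must have equal length")
  skip <- x %in% c("-", "N") | y %in% c("-", "N")
  if (any(x[skip] == "-" & y[skip] == "-")) {
    stop("alignment has a column with a gap in both sequences")
  }
  kept <- !skip
  if (!any(kept)) stop("no gap-free columns: p-distance undefined")
  sum(x[kept] != y[kept]) / sum(kept)
}
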