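#' Genotype matrix for bi-allelic SNPs
#'
#' The central container of the package: one row per bi-allelic SNP, one
#' column per sample, holding the count of alternate alleles (0, 1, 2) or
#' `NA` for a missing call. Per-genotype total depth (`dp`) and
#' alternate-allele depth (`ad_alt`) matrices are optional; they are required
#' only by [mask_genotypes()].
#'
#' Positions are 1-based (VCF convention) and strictly increasing within each
#' chromosome.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing per
#'   chromosome.
#' @param ref,alt single-base reference and alternate alleles per site.
#' @param gt integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param sample_ids character vector naming the columns of `gt`.
#' @param dp,ad_alt optional numeric matrices of the same shape as `gt`:
#'   total read depth and alternate-allele read depth per genotype.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `chrom`, `pos`, `ref`, `alt`, `gt`, `dp`, `ad_alt`, `sample_ids`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, sample_ids,
                            dp = NULL, ad_alt = NULL) {
  n_sites <- length(pos)
  gt <- as.matrix(gt)
  if (length(chrom) != n_sites || length(ref) != n_sites ||
      length(alt) != n_sites) {
    stop("chrom, pos, ref and alt must all have one entry per site")
  }
  if (nrow(gt) != n_sites || ncol(gt) != length(sample_ids)) {
    stop("gt must be a sites x samples matrix matching pos and sample_ids")
  }
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad)) stop("genotype values must be 0, 1, 2 or NA")
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  for (nm in c("dp", "ad_alt")) {
    m <- get(nm)
    if (!is.null(m) && !all(dim(m) == dim(gt))) {
      stop(nm, " must have the same dimensions as gt")
    }
  }
  mode(gt) <- "integer"
  dimnames(gt) <- list(NULL, sample_ids)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, dp = dp, ad_alt = ad_alt,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "sites x",
      length(x$sample_ids), "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  missing genotypes:", sum(is.na(x$gt)), "\n")
  cat("  depth annotations:", if (is.null(x$dp)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$pos), length(x$sample_ids))

n_sites <- function(gm) length(gm$pos)
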