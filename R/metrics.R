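#' Integrated CNA score
#'
#' Genomic-instability burden per sample: the sum over segments of
#' `|end - start| * |mean|`, divided by the total base-pair length of the
#' assembly. Bases not covered by any segment contribute 0 to the numerator,
#' and the assembly length (not the covered length) is the denominator, so
#' scores are comparable across samples with different coverage.
#'
#' @param profiles a [cna_profiles] object.
#' @return named numeric vector, one non-negative score per sample.
#' @examples
#' asm <- genome_assembly("toy", data.frame(chrom = "chr1", length = 1e7))
#' p <- cna_profiles(data.frame(sample_id = "S1", chrom = "chr1",
#'                              start = 0, end = 1e7, mean = 1), asm)
#' integrated_cna(p)  # 1
#' @export
integrated_cna <- function(profiles) {
  stopifnot(inherits(profiles, "cna_profiles"))
  seg <- profiles$segments
  if (nrow(seg) == 0L) stop("no segments: integrated CNA undefined")
  total <- genome_length(profiles$assembly)
  burden <- rowsum((seg$end - seg$start) * abs(seg$mean), seg$sample_id)
  stats::setNames(burden[, 1L] / total, rownames(burden))
}

#' Breakpoint counts and mean segment length
#'
#' A breakpoint is a boundary between two consecutive segments on the same
#' chromosome whose means differ by more than `tol`. Consecutive segments
#' with equal means (within `tol`) are treated as one event, since circular
#' binary segmentation emits such splits only through marker-count
#' bookkeeping.
#'
#' @param profiles a [cna_profiles] object.
#' @param tol tolerance below which adjacent means count as equal.
#' @return list with `per_chromosome` (data.frame `sample_id`, `chrom`,
#'   `breakpoints`), `total` (named vector per sample) and
#'   `mean_segment_length` (named vector, base pairs).
#' @export
count_breakpoints <- function(profiles, tol = 1e-9) {
  stopifnot(inherits(profiles, "cna_profiles"))
  seg <- profiles$segments
  samples <- profile_samples(profiles)
  if (nrow(seg) == 0L) {
    return(list(per_chromosome = data.frame(sample_id = character(),
                                            chrom = character(),
                                            breakpoints = integer()),
                total = stats::setNames(integer(0), character(0)),
                mean_segment_length = stats::setNames(numeric(0), character(0))))
  }
  n <- nrow(seg)
  same <- if (n > 1L) {
    seg$sample_id[-1L] == seg$sample_id[-n] & seg$chrom[-1L] == seg$chrom[-n]
  } else logical(0)
  is_bp <- c(FALSE, same & abs(seg$mean[-1L] - seg$mean[-n]) > tol)
  per <- stats::aggregate(
    list(breakpoints = as.integer(is_bp)),
    by = list(sample_id = seg$sample_id, chrom = seg$chrom), FUN = sum
  )
  per <- per[order(per$sample_id,
                   match(per$chrom, profiles$assembly$chromosomes$chrom)), ]
  rownames(per) <- NULL
  total <- stats::setNames(rep(0L, length(samples)), samples)
  tt <- tapply(as.integer(is_bp), seg$sample_id, sum)
  total[names(tt)] <- as.integer(tt)
  msl <- tapply(seg$end - seg$start, seg$sample_id, mean)
  list(per_chromosome = per, total = total,
       mean_segment_length = stats::setNames(as.double(msl), names(msl)))
}

#' Ratio of a gene's CNA to the outlier-robust chromosome maximum
#'
#' The robust chromosome maximum is the 95th percentile (the 5th percentile
#' from the top) of non-missing gene values on the gene's chromosome,
#' computed per sample, so single-gene outliers do not set the reference.
#' Samples whose robust maximum is not positive get an `NA` ratio and are
#' flagged.
#'
#' @param mat a `gene_cna_matrix`.
#' @param gene_id the target gene.
#' @param min_genes minimum number of informative genes required on the
#'   chromosome.
#' @return named numeric vector of per-sample ratios, with attribute
#'   `undefined` listing samples whose robust maximum was <= 0.
#' @export
locus_to_chrmax_ratio <- function(mat, gene_id, min_genes = 20L) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  i <- match(gene_id, rownames(mat$values))
  if (is.na(i)) stop("gene not in matrix: ", gene_id)
  chrom <- mat$genes$chrom[match(gene_id, mat$genes$gene_id)]
  on_chr <- mat$genes$gene_id[mat$genes$chrom == chrom]
  sub <- mat$values[on_chr, , drop = FALSE]
  if (min(colSums(!is.na(sub))) < min_genes) {
    stop("chromosome ", chrom, " has fewer than ", min_genes,
         " informative genes in some sample")
  }
  robust_max <- apply(sub, 2L, stats::quantile, probs = 0.95, na.rm = TRUE,
                      names = FALSE, type = 7)
  ratio <- mat$values[i, ] / robust_max
  bad <- robust_max <= 0
  ratio[bad] <- NA_real_
  attr(ratio, "undefined") <- colnames(mat$values)[bad]
  ratio
}
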