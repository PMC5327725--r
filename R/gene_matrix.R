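#' Convert segmented profiles to a gene-level CNA matrix
#'
#' Each gene's value in a sample is the overlap-length-weighted mean of the
#' segment means overlapping the gene body. Genes with no overlapping
#' segment in a sample are `NA`; downstream analyses impute explicitly (see
#' [impute_zero]).
#'
#' @param profiles a [cna_profiles] object.
#' @param genes a [gene_model] on the same assembly.
#' @return an object of class `gene_cna_matrix`: list with `values`
#'   (gene x sample numeric matrix), `genes`, `assembly`, and `sample_info`
#'   (`NULL` until annotated).
#' @export
segments_to_gene_matrix <- function(profiles, genes) {
  stopifnot(inherits(profiles, "cna_profiles"), inherits(genes, "gene_model"))
  if (nrow(genes) == 0L) stop("empty gene model")
  if (!identical(attr(genes, "assembly")$name, profiles$assembly$name)) {
    stop("profiles and gene model use different assemblies")
  }
  samples <- profile_samples(profiles)
  values <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  seg <- profiles$segments
  if (nrow(seg)) {
    gr_genes <- genes_granges(genes)
    gr_seg <- GenomicRanges::GRanges(
      seqnames = seg$chrom,
      ranges = IRanges::IRanges(start = seg$start + 1, end = seg$end)
    )
    ov <- GenomicRanges::findOverlaps(gr_genes, gr_seg)
    gi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_genes)[gi], IRanges::ranges(gr_seg)[si]
    ))
    key <- (match(seg$sample_id[si], samples) - 1L) * nrow(genes) + gi
    wsum <- rowsum(as.double(w), key)
    msum <- rowsum(as.double(w) * seg$mean[si], key)
    idx <- as.integer(rownames(wsum))
    values[idx] <- msum[, 1L] / wsum[, 1L]
  }
  structure(list(values = values, genes = genes,
                 assembly = profiles$assembly, sample_info = NULL),
            class = "gene_cna_matrix")
}

#' @export
print.gene_cna_matrix <- function(x, ...) {
  cat(sprintf("<gene_cna_matrix> %d genes x %d samples (%s), %d missing\n",
              nrow(x$values), ncol(x$values), x$assembly$name,
              sum(is.na(x$values))))
  invisible(x)
}

#' Impute missing gene values to the diploid log-ratio (0)
#'
#' Genes not covered by any segment in a sample carry no evidence of
#' alteration; for PCA and voting they are imputed to 0 (diploid). The
#' number of imputed cells is recorded in attribute `n_imputed` and
#' reported via `message()` when non-zero.
#'
#' @param mat a `gene_cna_matrix`.
#' @param quiet suppress the imputation message.
#' @return the matrix object with no missing values.
#' @export
impute_zero <- function(mat, quiet = FALSE) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  n <- sum(is.na(mat$values))
  if (n > 0L) {
    mat$values[is.na(mat$values)] <- 0
    if (!quiet) message("impute_zero: ", n, " missing values set to 0")
  }
  attr(mat, "n_imputed") <- n
  mat
}

#' Attach per-sample annotations
#' @param mat a `gene_cna_matrix`.
#' @param info data.frame with a `sample_id` column.
#' @return the annotated matrix object.
#' @export
annotate_samples <- function(mat, info) {
  stopifnot(inherits(mat, "gene_cna_matrix"), "sample_id" %in% names(info))
  mat$sample_info <- info[match(colnames(mat$values), info$sample_id), ,
                          drop = FALSE]
  mat
}

#' Write / read a gene x sample CNA matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#' @param mat a `gene_cna_matrix`.
#' @param path file path.
#' @export
write_gene_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  out <- data.frame(gene_id = rownames(mat$values), mat$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_matrix
#' @param genes the [gene_model] the rows belong to.
#' @export
read_gene_matrix <- function(path, genes) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  if (!all(rownames(values) %in% genes$gene_id)) {
    stop("matrix contains gene ids absent from the gene model")
  }
  structure(list(values = values, genes = genes,
                 assembly = attr(genes, "assembly"), sample_info = NULL),
            class = "gene_cna_matrix")
}
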