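#' Genome assembly
#'
#' A genome assembly is an ordered set of named chromosomes with lengths in
#' base pairs. It anchors coordinate validation for segments and gene loci
#' and supplies the denominator of the integrated CNA score.
#'
#' @param name single character label, e.g. `"hg19"` or `"synth1"`.
#' @param chromosomes data.frame with columns `chrom` (character, unique) and
#'   `length` (positive integer base pairs). Row order is the genome order.
#' @return an object of class `genome_assembly` with fields `name` and
#'   `chromosomes`.
#' @examples
#' genome_assembly("toy", data.frame(chrom = "chr1", length = 1e7))
#' @export
genome_assembly <- function(name, chromosomes) {
  stopifnot(is.character(name), length(name) == 1L)
  chromosomes <- as.data.frame(chromosomes)
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    stop("'chromosomes' needs columns 'chrom' and 'length'")
  }
  chromosomes$chrom <- as.character(chromosomes$chrom)
  chromosomes$length <- as.double(chromosomes$length)
  if (anyDuplicated(chromosomes$chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(chromosomes$length)) || any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(
    list(name = name, chromosomes = chromosomes[, c("chrom", "length")]),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf(
    "<genome_assembly> %s: %d chromosomes, %.1f Mbp\n",
    x$name, nrow(x$chromosomes), genome_length(x) / 1e6
  ))
  invisible(x)
}

#' Total assembly length in base pairs
#' @param assembly a `genome_assembly`.
#' @return numeric scalar.
#' @export
genome_length <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  sum(assembly$chromosomes$length)
}

chrom_length <- function(assembly, chrom) {
  i <- match(chrom, assembly$chromosomes$chrom)
  assembly$chromosomes$length[i]
}

#' Read a chromosome-length table
#'
#' Reads a two-column tab-separated table (`chrom<TAB>length`, no header) and
#' builds a [genome_assembly].
#'
#' @param path file path.
#' @param name assembly label; defaults to the file base name.
#' @return a `genome_assembly`.
#' @export
read_chrom_lengths <- function(path, name = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_assembly(name %||% sub("\\.[^.]*$", "", basename(path)), tab)
}

#' Write a chromosome-length table
#' @param assembly a `genome_assembly`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_lengths <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  utils::write.table(assembly$chromosomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct and validate a gene model
#'
#' A gene model is a table of gene loci on an assembly. Coordinates are
#' 0-based half-open throughout the package. An optional `ec` column carries
#' Enzyme Commission codes used for isoenzyme collapsing; `NA` means no
#' enzymatic annotation.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `ec`.
#' @param assembly the `genome_assembly` the loci live on.
#' @return a data.frame of class `gene_model`, sorted by genome order, with
#'   the assembly attached as attribute `assembly`.
#' @export
gene_model <- function(genes, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  genes <- as.data.frame(genes)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("gene model needs columns gene_id, chrom, start, end")
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.double(genes$start)
  genes$end <- as.double(genes$end)
  if (!"ec" %in% names(genes)) genes$ec <- NA_character_
  genes$ec <- as.character(genes$ec)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in gene model: ",
         genes$gene_id[anyDuplicated(genes$gene_id)][1L])
  }
  bad <- !genes$chrom %in% assembly$chromosomes$chrom
  if (any(bad)) {
    stop("gene ", genes$gene_id[bad][1L], " on unknown chromosome ",
         genes$chrom[bad][1L])
  }
  len <- chrom_length(assembly, genes$chrom)
  if (any(genes$start < 0 | genes$start >= genes$end | genes$end > len)) {
    stop("gene coordinates must satisfy 0 <= start < end <= chromosome length")
  }
  ord <- order(match(genes$chrom, assembly$chromosomes$chrom), genes$start,
               genes$end, genes$gene_id, method = "radix")
  genes <- genes[ord, c("gene_id", "chrom", "start", "end", "ec")]
  rownames(genes) <- NULL
  structure(genes, assembly = assembly, class = c("gene_model", "data.frame"))
}

#' Read a BED gene model
#'
#' Reads a BED4+ file (0-based half-open, name in column 4). Columns past the
#' fourth are ignored. Duplicate gene names or coordinates outside the
#' assembly are errors.
#'
#' @param path BED file path.
#' @param assembly target `genome_assembly`.
#' @param ec optional named character vector (or two-column data.frame
#'   `gene_id`, `ec`) of Enzyme Commission codes to attach.
#' @return a [gene_model].
#' @export
read_gene_model <- function(path, assembly, ec = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty BED file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 4L)) {
    stop("malformed BED line (need >= 4 columns): line ",
         which(ncol < 4L)[1L])
  }
  genes <- data.frame(
    gene_id = vapply(parts, `[[`, "", 4L),
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.double(vapply(parts, `[[`, "", 2L)),
    end = as.double(vapply(parts, `[[`, "", 3L))
  )
  if (anyNA(genes$start) || anyNA(genes$end)) stop("non-numeric BED coordinates")
  if (!is.null(ec)) {
    if (is.data.frame(ec)) ec <- stats::setNames(ec[[2L]], ec[[1L]])
    genes$ec <- unname(ec[genes$gene_id])
  }
  gene_model(genes, assembly)
}

#' Write a gene model as BED4 (plus an EC column when present)
#' @param genes a [gene_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  stopifnot(inherits(genes, "gene_model"))
  out <- data.frame(genes$chrom, format_bp(genes$start), format_bp(genes$end),
                    genes$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write EC annotation tables
#'
#' Tab-separated `gene_id<TAB>EC` with no header.
#' @param path file path.
#' @return data.frame with columns `gene_id`, `ec`.
#' @export
read_ec_table <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    col.names = c("gene_id", "ec"),
                    colClasses = "character")
}

#' @rdname read_ec_table
#' @param ec data.frame with columns `gene_id`, `ec`.
#' @export
write_ec_table <- function(ec, path) {
  utils::write.table(ec[, c("gene_id", "ec")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Integer-style formatting for base-pair coordinates stored as doubles.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    gene_id = genes$gene_id
  )
}
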