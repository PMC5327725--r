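#' Segmented copy-number profiles
#'
#' Container for one or more samples' segmented CNA profiles on a shared
#' assembly. Segments are stored 0-based half-open, sorted within sample by
#' genome order, and may not overlap within a sample and chromosome.
#' `mean` is the log2 copy-number ratio of the segment; `n_markers` is the
#' optional probe count and is never used in any computation.
#'
#' @param segments data.frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `mean` and optionally `n_markers`.
#' @param assembly the `genome_assembly` the segments live on.
#' @return an object of class `cna_profiles` with fields `assembly` and
#'   `segments`.
#' @export
cna_profiles <- function(segments, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  segments <- as.data.frame(segments)
  need <- c("sample_id", "chrom", "start", "end", "mean")
  if (!all(need %in% names(segments))) {
    stop("segments need columns sample_id, chrom, start, end, mean")
  }
  if (!"n_markers" %in% names(segments)) {
    segments$n_markers <- rep(NA_real_, nrow(segments))
  }
  segments$sample_id <- as.character(segments$sample_id)
  segments$chrom <- as.character(segments$chrom)
  for (cc in c("start", "end", "mean", "n_markers")) {
    segments[[cc]] <- as.double(segments[[cc]])
  }
  if (nrow(segments)) {
    bad <- !segments$chrom %in% assembly$chromosomes$chrom
    if (any(bad)) {
      stop("segment on unknown chromosome '", segments$chrom[bad][1L],
           "' (sample ", segments$sample_id[bad][1L], ")")
    }
    len <- chrom_length(assembly, segments$chrom)
    if (any(segments$start < 0 | segments$start >= segments$end |
              segments$end > len)) {
      stop("segment coordinates must satisfy 0 <= start < end <= chromosome length")
    }
    if (any(!is.na(segments$n_markers) & segments$n_markers < 1)) {
      stop("n_markers must be >= 1 when present")
    }
    ord <- order(segments$sample_id,
                 match(segments$chrom, assembly$chromosomes$chrom),
                 segments$start, method = "radix")
    segments <- segments[ord, c("sample_id", "chrom", "start", "end",
                                "n_markers", "mean")]
    rownames(segments) <- NULL
    ## overlap check within (sample, chrom) after sorting
    same <- segments$sample_id[-1L] == segments$sample_id[-nrow(segments)] &
      segments$chrom[-1L] == segments$chrom[-nrow(segments)]
    if (nrow(segments) > 1L &&
          any(same & segments$start[-1L] < segments$end[-nrow(segments)])) {
      i <- which(same & segments$start[-1L] < segments$end[-nrow(segments)])[1L]
      stop("overlapping segments in sample ", segments$sample_id[i + 1L],
           " on ", segments$chrom[i + 1L])
    }
  } else {
    segments <- segments[, c("sample_id", "chrom", "start", "end",
                             "n_markers", "mean")]
  }
  structure(list(assembly = assembly, segments = segments),
            class = "cna_profiles")
}

#' @export
print.cna_profiles <- function(x, ...) {
  cat(sprintf("<cna_profiles> %d samples, %d segments on %s\n",
              length(profile_samples(x)), nrow(x$segments), x$assembly$name))
  invisible(x)
}

#' Sample identifiers of a profile set
#' @param profiles a `cna_profiles` object.
#' @return character vector of sample ids (sorted).
#' @export
profile_samples <- function(profiles) {
  stopifnot(inherits(profiles, "cna_profiles"))
  sort(unique(profiles$segments$sample_id))
}

#' Subset a profile set by sample id
#' @param x a `cna_profiles` object.
#' @param samples character vector of sample ids to keep.
#' @param ... unused.
#' @export
subset_profiles <- function(x, samples, ...) {
  stopifnot(inherits(x, "cna_profiles"))
  cna_profiles(x$segments[x$segments$sample_id %in% samples, , drop = FALSE],
               x$assembly)
}

#' Read a SEG file
#'
#' Reads a tab-delimited SEG table (IGV dialect: header line, then sample,
#' chromosome, 1-based inclusive start/end, marker count, segment mean) into
#' a [cna_profiles] object with internal 0-based half-open coordinates.
#' Unknown chromosomes and within-sample overlaps are hard errors.
#'
#' @param path SEG file path.
#' @param assembly `genome_assembly` used to validate coordinates.
#' @return a `cna_profiles` object.
#' @export
read_seg <- function(path, assembly) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "numeric", "numeric"))
  if (ncol(tab) < 6L) stop("SEG file needs 6 columns: ", path)
  names(tab) <- c("sample_id", "chrom", "start", "end", "n_markers", "mean")
  bad <- !tab$chrom %in% assembly$chromosomes$chrom
  if (any(bad)) {
    stop("unknown chromosome '", tab$chrom[bad][1L], "' at line ",
         which(bad)[1L] + 1L, " of ", path)
  }
  tab$start <- tab$start - 1  # 1-based inclusive -> 0-based half-open
  cna_profiles(tab, assembly)
}

#' Write a SEG file
#'
#' Inverse of [read_seg]: emits the IGV SEG dialect (1-based inclusive
#' coordinates, `NA` for missing marker counts). `read_seg(write_seg(x))`
#' reproduces `x` exactly.
#'
#' @param profiles a `cna_profiles` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(profiles, path) {
  stopifnot(inherits(profiles, "cna_profiles"))
  seg <- profiles$segments
  out <- data.frame(
    Sample = seg$sample_id,
    Chromosome = seg$chrom,
    Start = format_bp(seg$start + 1),
    End = format_bp(seg$end),
    Num_Probes = ifelse(is.na(seg$n_markers), "NA", format_bp(seg$n_markers)),
    Segment_Mean = format(seg$mean, scientific = FALSE, trim = TRUE,
                          digits = 15)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
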