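#' Signed absolute minimum consistency score (SAMCS)
#'
#' Cross-cohort agreement for one gene: non-zero only when every cohort's
#' summary-signature value has the same strict sign, in which case it is
#' that sign times the minimum absolute value. A zero in any cohort zeroes
#' the score (zero has no sign), as does any sign disagreement.
#'
#' @param values numeric vector of per-cohort signature values (length >= 2).
#' @return numeric scalar.
#' @examples
#' samcs(c(0.3, 0.2, 0.5))   # 0.2
#' samcs(c(0.3, -0.2))       # 0
#' samcs(c(-0.3, -0.4, -0.1)) # -0.1
#' @export
samcs <- function(values) {
  if (length(values) < 2L) stop("samcs needs >= 2 cohort values")
  if (anyNA(values)) stop("samcs values must be non-missing")
  s <- sign(values)
  if (any(s == 0) || length(unique(s)) > 1L) return(0)
  s[1L] * min(abs(values))
}

#' Build a consistency signature from cohort summary signatures
#'
#' Applies [samcs] gene-wise across summary signatures that live on the same
#' gene model (map cross-species signatures first with
#' [map_across_species]). Only genes present with non-missing values in
#' every signature — the shared gene space — appear in the result; genes
#' outside it carry no cross-cohort evidence. A single signature is returned
#' unchanged (the consistency of one cohort is itself), which anchors step 1
#' of [sequential_consistency].
#'
#' @param signatures list of `summary_signature` objects.
#' @param genes the reference [gene_model] (defaults to the first
#'   signature's).
#' @return a data.frame of class `consistency_signature` with columns
#'   `gene_id`, `samcs`, and attributes `genes`, `cohorts`.
#' @export
build_consistency_signature <- function(signatures, genes = NULL) {
  stopifnot(length(signatures) >= 1L)
  genes <- genes %||% attr(signatures[[1L]], "genes")
  cohorts <- vapply(signatures, function(s) attr(s, "cohort") %||% "",
                    character(1))
  shared <- Reduce(intersect, lapply(signatures, function(s) {
    s$gene_id[!is.na(s$value)]
  }))
  if (!is.null(genes)) {
    shared <- genes$gene_id[genes$gene_id %in% shared]  # genome order
  }
  vals <- vapply(signatures, function(s) {
    s$value[match(shared, s$gene_id)]
  }, numeric(length(shared)))
  vals <- matrix(vals, nrow = length(shared))
  v <- if (length(signatures) == 1L) {
    vals[, 1L]
  } else {
    ## vectorized samcs over rows
    sg <- sign(vals)
    agree <- rowSums(sg == sg[, 1L]) == ncol(sg) & sg[, 1L] != 0
    ifelse(agree, sg[, 1L] * apply(abs(vals), 1L, min), 0)
  }
  structure(data.frame(gene_id = shared, samcs = as.double(v)),
            genes = genes, cohorts = cohorts,
            class = c("consistency_signature", "data.frame"))
}

#' Call conserved amplification / deletion regions
#'
#' Maximal same-direction runs of consecutive genes with `|SAMCS|` strictly
#' above `threshold` become candidate regions spanning from the first
#' member gene's start to the last member's end. Runs spanning less than
#' `min_span` are dropped; surviving same-direction regions separated by
#' less than `merge_gap` are combined (opposite directions are never
#' merged). Genes absent from the consistency signature do not break runs:
#' the merge rule alone governs gaps.
#'
#' @param consistency a `consistency_signature`.
#' @param genes the [gene_model] giving coordinates (defaults to the
#'   signature's).
#' @param threshold minimum `|SAMCS|` (strict) for membership.
#' @param min_span minimum region span in base pairs.
#' @param merge_gap regions of the same direction closer than this are
#'   merged.
#' @return data.frame of class `consistent_regions` with columns `chrom`,
#'   `start`, `end`, `direction` ("amplified"/"deleted"), `n_genes`,
#'   `min_abs_samcs`, `span`, `gene_ids` (comma-separated).
#' @export
call_consistent_regions <- function(consistency, genes = NULL,
                                    threshold = 0.05, min_span = 1e6,
                                    merge_gap = 1e6) {
  genes <- genes %||% attr(consistency, "genes")
  stopifnot(inherits(genes, "gene_model"))
  idx <- match(consistency$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("consistency signature has genes outside the gene model")
  df <- data.frame(gene_id = consistency$gene_id, samcs = consistency$samcs,
                   chrom = genes$chrom[idx], start = genes$start[idx],
                   end = genes$end[idx])
  df <- df[order(match(df$chrom, attr(genes, "assembly")$chromosomes$chrom),
                 df$start, df$end, method = "radix"), ]
  df$dir <- ifelse(abs(df$samcs) > threshold, sign(df$samcs), 0)
  regions <- list()
  for (chrom in unique(df$chrom)) {
    sub <- df[df$chrom == chrom, ]
    r <- rle(sub$dir)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0) next
      memb <- sub[starts[j]:stops[j], ]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chrom, start = min(memb$start), end = max(memb$end),
        direction = if (r$values[j] > 0) "amplified" else "deleted",
        n_genes = nrow(memb), min_abs_samcs = min(abs(memb$samcs)),
        gene_ids = paste(memb$gene_id, collapse = ",")
      )
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), n_genes = integer(),
               min_abs_samcs = numeric(), gene_ids = character())
  out <- out[out$end - out$start >= min_span, , drop = FALSE]
  out <- merge_regions(out, merge_gap)
  out$span <- out$end - out$start
  rownames(out) <- NULL
  structure(out, class = c("consistent_regions", "data.frame"))
}

## Combine same-direction regions on one chromosome separated by < gap.
merge_regions <- function(regions, gap) {
  if (nrow(regions) < 2L) return(regions)
  regions <- regions[order(regions$chrom, regions$start), ]
  keep <- list()
  cur <- regions[1L, ]
  for (i in seq.int(2L, nrow(regions))) {
    nxt <- regions[i, ]
    if (nxt$chrom == cur$chrom && nxt$direction == cur$direction &&
          nxt$start - cur$end < gap) {
      cur$end <- max(cur$end, nxt$end)
      cur$n_genes <- cur$n_genes + nxt$n_genes
      cur$min_abs_samcs <- min(cur$min_abs_samcs, nxt$min_abs_samcs)
      cur$gene_ids <- paste(cur$gene_ids, nxt$gene_ids, sep = ",")
    } else {
      keep[[length(keep) + 1L]] <- cur
      cur <- nxt
    }
  }
  keep[[length(keep) + 1L]] <- cur
  do.call(rbind, keep)
}

#' Read and filter an ortholog map
#'
#' Tab-separated `geneA<TAB>geneB` with no header. Pairs involving a gene
#' that appears more than once on either side (one-to-many or many-to-one)
#' are removed, with a message, so the retained map is strictly one-to-one.
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_a", "gene_b"),
                           colClasses = "character")
  filter_one_to_one(tab)
}

#' @rdname read_ortholog_map
#' @param map data.frame with columns `gene_a`, `gene_b`.
#' @export
filter_one_to_one <- function(map) {
  dup <- map$gene_a %in% map$gene_a[duplicated(map$gene_a)] |
    map$gene_b %in% map$gene_b[duplicated(map$gene_b)]
  if (any(dup)) {
    message("filter_one_to_one: removed ", sum(dup),
            " one-to-many/many-to-one pairs")
  }
  map[!dup, , drop = FALSE]
}

#' Carry a summary signature across species through an ortholog map
#'
#' Values are re-keyed from `gene_a` ids to `gene_b` ids (or the reverse
#' with `direction = "b_to_a"`). Genes without an ortholog are absent from
#' the output and therefore cannot contribute to cross-species consistency.
#'
#' @param signature a `summary_signature` (or `consistency_signature`).
#' @param map one-to-one ortholog data.frame (`gene_a`, `gene_b`).
#' @param target_genes the [gene_model] of the target species.
#' @param direction `"a_to_b"` maps `gene_a`-keyed values onto `gene_b` ids.
#' @return a `summary_signature` on the target gene model.
#' @export
map_across_species <- function(signature, map, target_genes,
                               direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  from <- if (direction == "a_to_b") map$gene_a else map$gene_b
  to <- if (direction == "a_to_b") map$gene_b else map$gene_a
  value_col <- if ("value" %in% names(signature)) "value" else "samcs"
  i <- match(signature$gene_id, from)
  keep <- !is.na(i)
  out <- data.frame(gene_id = to[i[keep]], value = signature[[value_col]][keep])
  if (!is.null(target_genes)) {
    out <- out[out$gene_id %in% target_genes$gene_id, , drop = FALSE]
    out <- out[order(match(out$gene_id, target_genes$gene_id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, mode = attr(signature, "mode") %||% "mapped",
            cohort = attr(signature, "cohort") %||% "", genes = target_genes,
            class = c("summary_signature", "data.frame"))
}

#' Genome fraction covered by consistent regions
#'
#' @param regions a `consistent_regions` data.frame (non-overlapping).
#' @param assembly the `genome_assembly` providing the denominator.
#' @return list with `fraction` (summed spans over total genome length) and
#'   `n_regions`.
#' @export
genome_fraction_consistent <- function(regions, assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  list(fraction = sum(regions$end - regions$start) / genome_length(assembly),
       n_regions = nrow(regions))
}

#' Sequential cohort-addition consistency
#'
#' Reproduces the stepwise restriction procedure: at step *k* the
#' consistency signature of the first *k* cohort signatures is built,
#' conserved regions are called, and the genome fraction they implicate is
#' reported, together with an optional caller-supplied evaluation (for
#' example enrichment signal strength of a gene set of interest). Cohorts
#' must be pre-ordered; [order_cohorts_by_pc1] implements the
#' decreasing-mean-PC1 ordering convention.
#'
#' @param signatures ordered named list of `summary_signature` objects on a
#'   shared gene model.
#' @param genes the reference [gene_model].
#' @param assembly the reference `genome_assembly`.
#' @param callback optional `function(consistency, regions)` returning a
#'   single number recorded per step.
#' @param threshold,min_span,merge_gap passed to [call_consistent_regions].
#' @return list with `steps` (data.frame: step, cohort, n_regions,
#'   genome_fraction, callback), `consistency` and `regions` (per-step
#'   lists).
#' @export
sequential_consistency <- function(signatures, genes, assembly,
                                   callback = NULL, threshold = 0.05,
                                   min_span = 1e6, merge_gap = 1e6) {
  stopifnot(length(signatures) >= 1L)
  labels <- names(signatures) %||% paste0("cohort", seq_along(signatures))
  cons_list <- vector("list", length(signatures))
  reg_list <- vector("list", length(signatures))
  rows <- vector("list", length(signatures))
  for (k in seq_along(signatures)) {
    cons <- build_consistency_signature(signatures[seq_len(k)], genes)
    regs <- call_consistent_regions(cons, genes, threshold, min_span,
                                    merge_gap)
    frac <- genome_fraction_consistent(regs, assembly)
    cons_list[[k]] <- cons
    reg_list[[k]] <- regs
    rows[[k]] <- data.frame(
      step = k, cohort = labels[k], n_regions = frac$n_regions,
      genome_fraction = frac$fraction,
      callback = if (is.null(callback)) NA_real_ else callback(cons, regs)
    )
  }
  list(steps = do.call(rbind, rows), consistency = cons_list,
       regions = reg_list)
}

#' Order cohorts by decreasing mean pan-cancer PC1 score
#'
#' @param pc1_scores named per-sample PC1 scores from a pooled (pan-cancer)
#'   PCA.
#' @param sample_cohorts named character vector: cohort label per sample id.
#' @return character vector of cohort labels, most signature-A-like first.
#' @export
order_cohorts_by_pc1 <- function(pc1_scores, sample_cohorts) {
  co <- sample_cohorts[names(pc1_scores)]
  m <- tapply(pc1_scores, co, mean)
  names(sort(m, decreasing = TRUE))
}

#' Export consistent regions as BED6
#'
#' Name column holds the direction; score is `1000 * min |SAMCS|` in the
#' region (capped at 1000); strand is `+` for amplified, `-` for deleted.
#'
#' @param regions a `consistent_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(
    regions$chrom, format_bp(regions$start), format_bp(regions$end),
    regions$direction,
    round(pmin(1000, 1000 * regions$min_abs_samcs)),
    ifelse(regions$direction == "amplified", "+", "-")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
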