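#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Collapse clustered isoenzyme loci
#'
#' Genes sharing an Enzyme Commission (EC) code whose consecutive
#' inter-gene gaps are below `window` (default 100 kb) are chained into one
#' locus, represented by the member with the largest absolute signature
#' value, so tandem isoenzyme clusters do not count as multiple independent
#' loci in gene-set enrichment. Chaining is transitive: A-B at 80 kb and
#' B-C at 80 kb collapse all three even though A-C is 160 kb apart.
#'
#' @param signature a `summary_signature` or `consistency_signature` (column
#'   `value` or `samcs`), or a `gene_cna_matrix` (representative chosen by
#'   largest mean absolute value).
#' @param genes a [gene_model] carrying `ec` annotations.
#' @param window maximum gap in base pairs between chained genes.
#' @return list with `signature` (collapsed, same class) or `matrix`, and
#'   `map` (data.frame `representative`, `member`).
#' @export
collapse_isoenzymes <- function(signature, genes, window = 1e5) {
  stopifnot(inherits(genes, "gene_model"))
  if (inherits(signature, "gene_cna_matrix")) {
    score <- rowMeans(abs(signature$values), na.rm = TRUE)
    ids <- rownames(signature$values)
  } else {
    vcol <- if ("value" %in% names(signature)) "value" else "samcs"
    score <- abs(signature[[vcol]])
    ids <- signature$gene_id
  }
  gi <- match(ids, genes$gene_id)
  if (anyNA(gi)) stop("signature contains genes outside the gene model")
  info <- data.frame(gene_id = ids, score = score, ec = genes$ec[gi],
                     chrom = genes$chrom[gi], start = genes$start[gi],
                     end = genes$end[gi])
  drop <- character(0)
  map <- list()
  for (ec in unique(info$ec[!is.na(info$ec)])) {
    sub <- info[!is.na(info$ec) & info$ec == ec, ]
    sub <- sub[order(sub$chrom, sub$start), ]
    if (nrow(sub) < 2L) next
    gap_break <- c(TRUE, sub$chrom[-1L] != sub$chrom[-nrow(sub)] |
                     sub$start[-1L] - sub$end[-nrow(sub)] >= window)
    grp <- cumsum(gap_break)
    for (g in unique(grp)) {
      memb <- sub[grp == g, ]
      if (nrow(memb) < 2L) next
      rep_id <- memb$gene_id[order(-memb$score, memb$start)][1L]
      map[[length(map) + 1L]] <- data.frame(representative = rep_id,
                                            member = memb$gene_id)
      drop <- c(drop, setdiff(memb$gene_id, rep_id))
    }
  }
  map <- if (length(map)) do.call(rbind, map) else
    data.frame(representative = character(), member = character())
  if (inherits(signature, "gene_cna_matrix")) {
    out <- signature
    keep <- !rownames(out$values) %in% drop
    out$values <- out$values[keep, , drop = FALSE]
    out$genes <- out$genes[!out$genes$gene_id %in% drop, , drop = FALSE]
    return(list(matrix = out, map = map))
  }
  out <- signature[!signature$gene_id %in% drop, , drop = FALSE]
  rownames(out) <- NULL
  list(signature = out, map = map)
}

#' Truncated CNA-GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov-style running sum over genes ranked by
#' decreasing consistency value. Set hits increment the sum in proportion
#' to `|value|^weight` (weight 1 by default, 0 giving the classic
#' unweighted statistic); misses decrement by `1/(N - Nh)`. Because genes
#' that are not consistent across cohorts all sit at zero with tied ranks,
#' the maximum deviation is taken over the strictly positive prefix of the
#' ranking only. If no gene is positive the score is 0 and flagged.
#'
#' @param values named numeric vector of consistency values (e.g. SAMCS).
#' @param set character vector of gene ids.
#' @param weight exponent on `|value|` for hit increments.
#' @return numeric scalar with attribute `flag` = "no_positive_prefix" when
#'   degenerate.
#' @export
cna_gsea_es <- function(values, set, weight = 1) {
  stopifnot(!is.null(names(values)))
  ord <- order(-values, names(values), method = "radix")
  v <- values[ord]
  hit <- names(v) %in% set
  if (!any(hit)) stop("gene set has no measured genes")
  npos <- sum(v > 0)
  if (npos == 0L) {
    out <- 0
    attr(out, "flag") <- "no_positive_prefix"
    return(out)
  }
  w <- abs(v)^weight
  hit_inc <- ifelse(hit, w, 0)
  denom_hit <- sum(hit_inc)
  if (denom_hit == 0) {
    ## all set genes sit at value 0: nothing in the informative prefix
    out <- 0
    attr(out, "flag") <- "no_positive_prefix"
    return(out)
  }
  if (!any(hit[seq_len(npos)])) {
    ## set entirely outside the positive prefix: no informative evidence
    out <- 0
    attr(out, "flag") <- "no_positive_prefix"
    return(out)
  }
  miss_dec <- ifelse(hit, 0, 1 / (length(v) - sum(hit)))
  running <- cumsum(hit_inc / denom_hit - miss_dec)
  ## the maximum deviation may be negative for sets depleted from the
  ## prefix; clamping it to zero would create a point mass that distorts
  ## the permutation null
  max(running[seq_len(npos)])
}

#' Mean-rank gene-set statistic
#'
#' The average rank of the set's genes in the decreasing-value ranking
#' (smaller is better). Exposed because the permutation test can compare
#' either the enrichment score or the average gene-set ranking.
#'
#' @inheritParams cna_gsea_es
#' @return numeric scalar.
#' @export
gsea_mean_rank <- function(values, set) {
  stopifnot(!is.null(names(values)))
  r <- rank(-values, ties.method = "average")
  hit <- names(values) %in% set
  if (!any(hit)) stop("gene set has no measured genes")
  mean(r[hit])
}

#' Permutation p-value for a gene set
#'
#' Compares the observed statistic with that of `n_perm` random gene sets
#' of equal size drawn without replacement from the measured-gene universe.
#' `p = (k + 1) / (n_perm + 1)` where `k` counts permutations at least as
#' extreme (ES: greater-or-equal; mean rank: less-or-equal), so p can never
#' be exactly zero.
#'
#' @inheritParams cna_gsea_es
#' @param n_perm number of random sets.
#' @param seed integer seed (the draw is fully reproducible).
#' @param statistic `"es"` (default) or `"mean_rank"`.
#' @return numeric p-value in (0, 1], with attributes `observed` and
#'   `n_perm`.
#' @export
permutation_pvalue <- function(values, set, n_perm = 1000, seed = 1,
                               statistic = c("es", "mean_rank"),
                               weight = 1) {
  statistic <- match.arg(statistic)
  universe <- names(values)
  m <- sum(universe %in% set)
  if (m == 0L) stop("gene set has no measured genes")
  obs <- if (statistic == "es") as.double(cna_gsea_es(values, set, weight))
  else gsea_mean_rank(values, set)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rs <- sample(universe, m)
      if (statistic == "es") as.double(cna_gsea_es(values, rs, weight))
      else gsea_mean_rank(values, rs)
    }, numeric(1))
  })
  k <- if (statistic == "es") sum(perm >= obs) else sum(perm <= obs)
  p <- (k + 1) / (n_perm + 1)
  attr(p, "observed") <- obs
  attr(p, "n_perm") <- n_perm
  p
}

#' Enrichment signal strength
#'
#' The negative log10 frequency of equivalent enrichment by chance.
#' @param p permutation p-value(s) in (0, 1].
#' @return `-log10(p)`.
#' @export
signal_strength <- function(p) -log10(as.double(p))

#' Mean signal strength of the top-k enriched sets
#' @param results data.frame with a `signal` column (as from [cna_gsea]).
#' @param k number of best sets to average.
#' @return numeric scalar.
#' @export
top_k_mean_signal <- function(results, k = 10L) {
  mean(sort(results$signal, decreasing = TRUE)[seq_len(min(k, nrow(results)))])
}

#' Benjamini-Hochberg q-values with redundant-set exclusion
#'
#' Standard BH q-values; additionally, for every set inside an exclusion
#' group (a family of mutually redundant sets, e.g. the several
#' glycolysis-gluconeogenesis collections), its q-value is recomputed on
#' the collection with the *other* group members removed, so redundant
#' near-copies of a pathway do not inflate each other's significance.
#'
#' @param pvalues named numeric vector.
#' @param exclusion_groups optional list of character vectors of set names.
#' @return named numeric q-values.
#' @export
bh_fdr <- function(pvalues, exclusion_groups = NULL) {
  q <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(exclusion_groups)) {
    for (grp in exclusion_groups) {
      grp <- intersect(grp, names(pvalues))
      for (s in grp) {
        keep <- setdiff(names(pvalues), setdiff(grp, s))
        q[s] <- stats::p.adjust(pvalues[keep], method = "BH")[s]
      }
    }
  }
  q
}

#' Gene-set enrichment over a consistency signature
#'
#' Runs the truncated enrichment statistic and its permutation test for
#' every set in a collection with at least `min_size` measured genes,
#' then attaches BH q-values (with optional exclusion groups) and signal
#' strengths. Deletion enrichment can be obtained by negating the
#' signature.
#'
#' @param consistency a `consistency_signature` (or any data.frame with
#'   `gene_id` and `samcs`/`value`).
#' @param collection named list of gene sets (e.g. from [read_gmt]).
#' @param n_perm permutations per set.
#' @param seed base seed; each set uses a derived child seed.
#' @param min_size minimum measured-gene overlap for a set to be analyzed.
#' @param exclusion_groups passed to [bh_fdr].
#' @param statistic,weight passed to [permutation_pvalue].
#' @return data.frame: `set`, `size`, `es`, `p`, `q`, `signal`, `rank`,
#'   `n_perm`, `seed`.
#' @export
cna_gsea <- function(consistency, collection, n_perm = 1000, seed = 1,
                     min_size = 7L, exclusion_groups = NULL,
                     statistic = "es", weight = 1) {
  vcol <- if ("samcs" %in% names(consistency)) "samcs" else "value"
  values <- stats::setNames(consistency[[vcol]], consistency$gene_id)
  sizes <- vapply(collection, function(s) sum(names(values) %in% s),
                  integer(1))
  keep <- names(collection)[sizes >= min_size]
  if (length(keep) == 0L) stop("no gene set passes the size filter")
  rows <- lapply(seq_along(keep), function(i) {
    nm <- keep[i]
    p <- permutation_pvalue(values, collection[[nm]], n_perm = n_perm,
                            seed = child_seed(seed, i),
                            statistic = statistic, weight = weight)
    data.frame(set = nm, size = sizes[[nm]],
               es = as.double(cna_gsea_es(values, collection[[nm]], weight)),
               p = as.double(p), n_perm = n_perm,
               seed = child_seed(seed, i))
  })
  out <- do.call(rbind, rows)
  out$q <- unname(bh_fdr(stats::setNames(out$p, out$set), exclusion_groups))
  out$signal <- signal_strength(out$p)
  ord <- order(out$p, -out$es, out$set, method = "radix")
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("set", "size", "es", "p", "q", "signal", "rank", "n_perm", "seed")]
}

#' Kolmogorov-Smirnov enrichment of labels along a ranking
#'
#' Tests whether binary labels (mutations, subtypes) concentrate at one end
#' of a sample ranking (samples pre-sorted, e.g. by PC1 score). The
#' statistic is the maximum absolute deviation between the labels'
#' cumulative distribution along the ranking and the uniform expectation;
#' significance comes from label permutations and the normalized enrichment
#' score is the statistic over the null mean.
#'
#' @param labels logical (or 0/1) vector in ranking order.
#' @param n_perm number of label shuffles.
#' @param seed integer seed.
#' @return list with `statistic`, `p` (add-one permutation p), `nes`,
#'   `n_labels`.
#' @export
ks_label_enrichment <- function(labels, n_perm = 1000, seed = 1) {
  labels <- as.logical(labels)
  n <- length(labels)
  m <- sum(labels)
  if (m == 0L || m == n) stop("labels must contain both classes")
  stat_fun <- function(lab) max(abs(cumsum(lab) / m - seq_len(n) / n))
  obs <- stat_fun(labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(labels)), numeric(1))
  })
  list(statistic = obs, p = (sum(perm >= obs) + 1) / (n_perm + 1),
       nes = obs / mean(perm), n_labels = m)
}

#' Write enrichment results
#' @param results data.frame from [cna_gsea].
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @export
write_enrichment <- function(results, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
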