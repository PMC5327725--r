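#' Signal-to-noise ratio between two sample groups
#'
#' `SNR = (mu1 - mu2) / (sd1 + sd2)`. When both standard deviations are zero
#' the value is 0 for equal means and a signed infinity otherwise.
#'
#' @param group1,group2 numeric vectors (each of length >= 2 for a finite
#'   standard deviation).
#' @return numeric scalar.
#' @export
snr <- function(group1, group2) {
  m1 <- mean(group1); m2 <- mean(group2)
  s <- stats::sd(group1) + stats::sd(group2)
  if (is.na(s)) stop("snr needs >= 2 values per group")
  if (s == 0) {
    if (m1 == m2) return(0)
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / s
}

#' Welch t-score between two sample groups
#'
#' `t = (mu1 - mu2) / sqrt(sd1^2/n1 + sd2^2/n2)`; used as the gene weight in
#' weighted gene voting.
#'
#' @inheritParams snr
#' @return numeric scalar.
#' @export
t_score <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("t_score needs >= 2 values per group")
  den <- sqrt(stats::var(group1) / n1 + stats::var(group2) / n2)
  num <- mean(group1) - mean(group2)
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

#' Collapse genes with identical profiles
#'
#' Genes whose value rows are identical across all samples (after rounding
#' to `digits` decimals, since level-3-style matrices are already rounded)
#' are collapsed to a single representative: the member with the lowest
#' genomic coordinate. The map allows loadings computed on the reduced
#' matrix to be re-expanded to every member.
#'
#' @param mat a `gene_cna_matrix` with no missing values.
#' @param digits decimals used for the equality test.
#' @return list with `matrix` (the reduced `gene_cna_matrix`) and `map`
#'   (data.frame `representative`, `member`).
#' @export
collapse_identical_genes <- function(mat, digits = 6L) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  if (anyNA(mat$values)) stop("impute missing values before collapsing")
  keys <- apply(round(mat$values, digits), 1L, paste, collapse = "\r")
  ## genes are in genome order, so the first member of each group is the
  ## lowest-coordinate one
  rep_idx <- !duplicated(keys)
  rep_of <- rownames(mat$values)[rep_idx][match(keys, keys[rep_idx])]
  map <- data.frame(representative = rep_of, member = rownames(mat$values))
  red <- mat
  red$values <- mat$values[rep_idx, , drop = FALSE]
  red$genes <- mat$genes[rep_idx, , drop = FALSE]
  list(matrix = red, map = map)
}

#' Extract a PCA CNA signature model
#'
#' Principal component analysis of the mean-centered gene x sample CNA
#' matrix (genes are variables, samples observations; centering only, no
#' per-gene scaling). Identical-profile genes are collapsed first and the
#' loadings re-expanded afterwards, so duplicated genes carry equal
#' loadings. Each component's sign is oriented so that the mean
#' `orientation_metric` of the top-decile-score samples is at least that of
#' the bottom decile; with the default metric (per-sample mean absolute CNA,
#' a gene-level analogue of the integrated CNA score — pass the true
#' integrated CNA when profiles are available) the unstable,
#' amplification-rich "signature A" end sits at positive scores.
#'
#' @param mat a `gene_cna_matrix`; missing values are imputed to 0 with a
#'   logged count.
#' @param n_components number of components to keep (default: all).
#' @param orientation_metric named per-sample numeric used by the sign
#'   convention; default `colMeans(abs(values))`.
#' @return an object of class `cna_pca` with fields `center` (per collapsed
#'   gene), `loadings` (collapsed gene x component, orthonormal),
#'   `loadings_expanded` (all genes), `scores` (sample x component),
#'   `var_explained`, `collapse_map`, `orientation` (+1/-1 per component),
#'   `genes`, `assembly`.
#' @export
run_pca <- function(mat, n_components = NULL, orientation_metric = NULL) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  mat <- impute_zero(mat, quiet = TRUE)
  if (ncol(mat$values) < 2L) stop("run_pca needs >= 2 samples")
  coll <- collapse_identical_genes(mat)
  x <- t(coll$matrix$values)  # samples x genes
  if (ncol(x) < 2L) stop("run_pca needs >= 2 distinct gene profiles")
  if (all(abs(x - mean(x)) < 1e-300)) stop("degenerate rank-0 matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components %||% ncol(pc$rotation), ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  metric <- orientation_metric %||% colMeans(abs(mat$values))
  metric <- metric[rownames(scores)]
  if (anyNA(metric)) stop("orientation_metric must cover all samples")
  orientation <- vapply(seq_len(k), function(j) {
    orient_sign(scores[, j], rownames(scores), metric)
  }, numeric(1))
  loadings <- sweep(loadings, 2L, orientation, `*`)
  scores <- sweep(scores, 2L, orientation, `*`)
  expand_idx <- match(coll$map$representative, rownames(coll$matrix$values))
  loadings_expanded <- loadings[expand_idx, , drop = FALSE]
  rownames(loadings_expanded) <- coll$map$member
  structure(list(
    center = stats::setNames(pc$center, rownames(coll$matrix$values)),
    loadings = loadings,
    loadings_expanded = loadings_expanded,
    scores = scores,
    var_explained = pc$sdev^2 / sum(pc$sdev^2),
    collapse_map = coll$map,
    orientation = orientation,
    orientation_metric = metric,
    genes = mat$genes,
    assembly = mat$assembly
  ), class = "cna_pca")
}

#' Identify the signature-carrying component
#'
#' The CNA signature axis is the component that tracks genomic instability:
#' among the first `k_max` components, the one whose scores correlate most
#' strongly with the orientation metric (integrated CNA by default). This
#' is usually PC1, but when a cohort's dominant variance direction is a
#' burden-neutral contrast (for example the mutually exclusive
#' amplification/deletion axis of signature B, whose two ends have similar
#' integrated CNA), the instability axis can surface as a later component.
#' The selected component is the one whose top score decile carries the
#' largest mean metric: only an axis that concentrates the most unstable
#' samples at its positive end attains the maximum. Ties keep the earlier
#' component.
#'
#' @param model a [run_pca] fit.
#' @param k_max number of leading components to consider.
#' @return integer component index.
#' @export
signature_component <- function(model, k_max = 5L) {
  stopifnot(inherits(model, "cna_pca"))
  metric <- model$orientation_metric
  k <- min(k_max, ncol(model$scores))
  n <- nrow(model$scores)
  d <- max(1L, ceiling(0.1 * n))
  top_burden <- vapply(seq_len(k), function(j) {
    ord <- order_by_score_desc(model$scores[, j], rownames(model$scores))
    mean(metric[ord[seq_len(d)]])
  }, numeric(1))
  which.max(top_burden)
}

## Sign convention for one component: compare the orientation metric between
## the top and bottom score deciles (ties broken by sample id). No flip on
## exact equality, so the rule is idempotent.
orient_sign <- function(score, ids, metric) {
  n <- length(score)
  d <- max(1L, ceiling(0.1 * n))
  ord <- order_by_score_desc(score, ids)
  top <- mean(metric[ord[seq_len(d)]])
  bot <- mean(metric[ord[seq.int(n - d + 1L, n)]])
  if (top < bot) -1 else 1
}

#' @export
print.cna_pca <- function(x, ...) {
  cat(sprintf(
    "<cna_pca> %d samples x %d collapsed genes (%d total), %d components\n",
    nrow(x$scores), nrow(x$loadings), nrow(x$loadings_expanded),
    ncol(x$loadings)
  ))
  cat("  PC1 variance explained:",
      sprintf("%.1f%%", 100 * x$var_explained[1L]), "\n")
  invisible(x)
}

#' Project new samples onto a fitted CNA PCA
#'
#' Scores are `(values - training center) %*% loadings` on the collapsed
#' gene space. Genes missing from `newdata` (or `NA`) are imputed to the
#' training center, i.e. contribute zero after centering.
#'
#' @param object a `cna_pca` model.
#' @param newdata a `gene_cna_matrix` (or bare gene x sample matrix) on the
#'   training gene model.
#' @param ... unused.
#' @return sample x component score matrix.
#' @export
predict.cna_pca <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "gene_cna_matrix")) newdata$values else newdata
  reps <- names(object$center)
  x <- matrix(rep(object$center, ncol(values)), nrow = length(reps),
              dimnames = list(reps, colnames(values)))
  hit <- intersect(reps, rownames(values))
  x[hit, ] <- values[hit, , drop = FALSE]
  x[is.na(x)] <- object$center[rep(seq_along(reps), ncol(values))][is.na(x)]
  t(sweep(x, 1L, object$center, `-`)) %*% object$loadings
}

#' @rdname predict.cna_pca
#' @param model a `cna_pca` model.
#' @export
project <- function(model, newdata) predict(model, newdata)

#' Summary signature of a cohort
#'
#' In mode `"snr_vs_normals"`, the per-gene signal-to-noise ratio of the top
#' `ceil(top_frac * n)` tumors by PC1 score against the normal samples,
#' divided by the maximum absolute SNR so values lie in `[-1, 1]`. In mode
#' `"pc_loadings"`, the chosen component's expanded loadings divided by the
#' maximum absolute loading.
#'
#' @param mat a `gene_cna_matrix` (missing values imputed to 0).
#' @param pc_scores named per-sample PC1 scores (ignored for
#'   `"pc_loadings"`).
#' @param normal_ids sample ids of the normal (non-tumor) samples; all other
#'   columns are tumors.
#' @param top_frac fraction of tumors forming the signature-defining set.
#' @param mode `"snr_vs_normals"` or `"pc_loadings"`.
#' @param model a `cna_pca`, required for mode `"pc_loadings"`.
#' @param component which component's loadings to use.
#' @param cohort cohort label stored with the signature.
#' @return a data.frame of class `summary_signature` with columns `gene_id`,
#'   `value`, and attributes `mode`, `cohort`, `genes`.
#' @export
core_signature <- function(mat, pc_scores = NULL, normal_ids = NULL,
                           top_frac = 0.10,
                           mode = c("snr_vs_normals", "pc_loadings"),
                           model = NULL, component = 1L, cohort = "") {
  mode <- match.arg(mode)
  if (mode == "pc_loadings") {
    stopifnot(inherits(model, "cna_pca"))
    v <- model$loadings_expanded[, component]
    v <- v[order(match(names(v), model$genes$gene_id))]
    value <- normalize_maxabs(v)
    out <- data.frame(gene_id = names(v), value = unname(value))
    genes <- model$genes
  } else {
    stopifnot(inherits(mat, "gene_cna_matrix"))
    mat <- impute_zero(mat, quiet = TRUE)
    samples <- colnames(mat$values)
    normal_ids <- intersect(normal_ids, samples)
    tumors <- setdiff(samples, normal_ids)
    if (length(tumors) < 10L || length(normal_ids) < 2L) {
      stop("core_signature needs >= 10 tumors and >= 2 normals")
    }
    sc <- pc_scores[tumors]
    if (anyNA(sc)) stop("pc_scores must cover all tumor samples")
    d <- ceiling(top_frac * length(tumors))
    if (d < 1L) stop("empty top set")
    top <- tumors[order_by_score_desc(sc, tumors)][seq_len(d)]
    vt <- mat$values[, top, drop = FALSE]
    vn <- mat$values[, normal_ids, drop = FALSE]
    m1 <- rowMeans(vt); m2 <- rowMeans(vn)
    s <- row_sds(vt) + row_sds(vn)
    raw <- ifelse(s == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                  (m1 - m2) / s)
    value <- normalize_maxabs(raw)
    out <- data.frame(gene_id = rownames(mat$values), value = unname(value))
    genes <- mat$genes
  }
  structure(out, mode = mode, cohort = cohort, genes = genes,
            class = c("summary_signature", "data.frame"))
}

row_sds <- function(m) {
  if (ncol(m) < 2L) return(rep(0, nrow(m)))
  sqrt(rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L))
}

## Scale a signed vector into [-1, 1] by its maximum absolute value;
## all-zero input stays zero, infinities map to +-1 (finite maxima are
## ignored in their presence).
normalize_maxabs <- function(v) {
  if (any(is.infinite(v))) {
    out <- ifelse(is.infinite(v), sign(v), 0)
    return(out)
  }
  m <- max(abs(v))
  if (m == 0) return(v)
  v / m
}

#' Write / read summary-signature TSV files
#'
#' Columns `gene_id`, `value`, `mode`, `cohort`.
#' @param signature a `summary_signature`.
#' @param path file path.
#' @export
write_signature <- function(signature, path) {
  out <- data.frame(gene_id = signature$gene_id, value = signature$value,
                    mode = attr(signature, "mode") %||% "",
                    cohort = attr(signature, "cohort") %||% "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param genes the [gene_model] the signature lives on.
#' @export
read_signature <- function(path, genes = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  structure(data.frame(gene_id = as.character(tab$gene_id),
                       value = tab$value),
            mode = as.character(tab$mode[1L]),
            cohort = as.character(tab$cohort[1L]), genes = genes,
            class = c("summary_signature", "data.frame"))
}

#' Ward hierarchical clustering of samples on correlation distance
#'
#' Samples are clustered with centered Pearson correlation distance
#' (`1 - cor`) and Ward's criterion with dissimilarities squared before
#' cluster updating (`hclust` method `"ward.D2"`). Gene rows that are zero
#' across all samples are removed before computing distances.
#'
#' @param mat a `gene_cna_matrix` (missing values imputed to 0).
#' @param k number of clusters.
#' @return named integer vector of cluster labels.
#' @export
hierarchical_cluster <- function(mat, k) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  mat <- impute_zero(mat, quiet = TRUE)
  v <- mat$values[rowSums(mat$values != 0) > 0L, , drop = FALSE]
  if (ncol(v) < k) stop("need at least k samples")
  d <- stats::as.dist(1 - stats::cor(v))
  stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
}

#' Concordance of clustering with a PCA-defined signature set
#'
#' For each cluster, the hypergeometric tail probability of drawing at least
#' the observed overlap with the signature set when sampling the cluster's
#' size from all samples. The minimum across clusters summarises how well
#' some cluster captures the set.
#'
#' @param labels named cluster labels (as from [hierarchical_cluster]).
#' @param signature_set character vector of sample ids (e.g. the top-decile
#'   PC1 samples).
#' @return list with `p` (the minimum tail probability), `per_cluster`
#'   (data.frame cluster, size, overlap, p).
#' @export
cluster_pca_concordance <- function(labels, signature_set) {
  samples <- names(labels)
  stopifnot(!is.null(samples), all(signature_set %in% samples))
  per <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    members <- samples[labels == cl]
    ov <- length(intersect(members, signature_set))
    data.frame(cluster = cl, size = length(members), overlap = ov,
               p = hypergeom_tail(ov, length(members), length(signature_set),
                                  length(samples)))
  }))
  list(p = min(per$p), per_cluster = per)
}

#' Paired "evolving signature" statistic
#'
#' For sublines profiled at two passages, the per-gene paired t-test of the
#' late against the early profile, reported as `-log10(p)` signed by the
#' mean late-minus-early difference (positive = amplifying, negative =
#' deleting). Genes with a zero difference in every pair score 0; genes with
#' a constant non-zero difference score signed infinity.
#'
#' @param mat a `gene_cna_matrix` containing both members of every pair.
#' @param pairs data.frame with columns `early` and `late` holding sample
#'   ids (>= 3 pairs).
#' @return named numeric vector of per-gene signed statistics.
#' @export
paired_evolution_signature <- function(mat, pairs) {
  stopifnot(inherits(mat, "gene_cna_matrix"),
            all(c("early", "late") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) stop("need >= 3 pairs")
  mat <- impute_zero(mat, quiet = TRUE)
  d <- mat$values[, as.character(pairs$late), drop = FALSE] -
    mat$values[, as.character(pairs$early), drop = FALSE]
  md <- rowMeans(d)
  sdd <- row_sds(d)
  stat <- numeric(nrow(d))
  degen <- sdd == 0
  stat[degen & md != 0] <- sign(md[degen & md != 0]) * Inf
  ok <- !degen
  tt <- md[ok] / (sdd[ok] / sqrt(n))
  p <- 2 * stats::pt(-abs(tt), df = n - 1L)
  stat[ok] <- sign(md[ok]) * -log10(p)
  stats::setNames(stat, rownames(d))
}

#' Balanced random sampling of tumors across cohorts
#'
#' Pan-cancer analyses sample the same number of tumors from every cohort so
#' large cohorts do not dominate the decomposition: `min(n_per_cohort)`
#' samples are drawn (without replacement) from each cohort under the given
#' seed.
#'
#' @param sample_cohorts named character vector: cohort label per sample id.
#' @param seed integer seed.
#' @return character vector of selected sample ids.
#' @export
balanced_sample <- function(sample_cohorts, seed) {
  ids <- names(sample_cohorts)
  stopifnot(!is.null(ids))
  n <- min(table(sample_cohorts))
  with_seed(seed, {
    unlist(lapply(sort(unique(sample_cohorts)), function(co) {
      pool <- sort(ids[sample_cohorts == co])
      sort(sample(pool, n))
    }), use.names = FALSE)
  })
}
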