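#' Train a weighted-gene-voting (WGV) model
#'
#' Golub-style voting adapted to continuous phenotype prediction: each gene
#' in the set gets weight `w_g = t_score(positive, negative)` and decision
#' midpoint `b_g = (mu_pos + mu_neg) / 2`, trained here on the
#' signature-defining tumors (e.g. top-decile PC1) against normals.
#'
#' @param mat a `gene_cna_matrix` (missing values imputed to 0).
#' @param positive_ids,negative_ids sample ids of the two training classes
#'   (each >= 2).
#' @param gene_set character vector of genes to vote with; must overlap the
#'   measured genes.
#' @param cohort label stored with the model.
#' @return object of class `wgv_model`: data.frame `gene`, `weight`,
#'   `midpoint` with attribute `cohort`.
#' @export
train_wgv <- function(mat, positive_ids, negative_ids, gene_set,
                      cohort = "") {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  mat <- impute_zero(mat, quiet = TRUE)
  if (length(positive_ids) < 2L || length(negative_ids) < 2L) {
    stop("both training classes need >= 2 samples")
  }
  genes <- intersect(gene_set, rownames(mat$values))
  if (length(genes) == 0L) stop("gene set not measured in the matrix")
  pos <- mat$values[genes, positive_ids, drop = FALSE]
  neg <- mat$values[genes, negative_ids, drop = FALSE]
  m1 <- rowMeans(pos); m2 <- rowMeans(neg)
  den <- sqrt(row_sds(pos)^2 / ncol(pos) + row_sds(neg)^2 / ncol(neg))
  w <- ifelse(den == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
              (m1 - m2) / den)
  if (any(is.infinite(w))) stop("degenerate gene with zero variance in both classes")
  structure(data.frame(gene = genes, weight = unname(w),
                       midpoint = unname((m1 + m2) / 2)),
            cohort = cohort, class = c("wgv_model", "data.frame"))
}

#' Predict continuous phenotype scores by weighted gene voting
#'
#' Per model, a sample's vote is
#' `sum_g w_g (x_g - b_g) / sum_g |w_g|`; with several models (one per
#' training cohort) the votes are averaged. The score is invariant to
#' rescaling any one model's weights by a positive constant.
#'
#' @param models a `wgv_model` or list of them.
#' @param mat a `gene_cna_matrix` of test samples (missing values imputed
#'   to 0).
#' @return named numeric vector of per-sample scores.
#' @export
predict_wgv <- function(models, mat) {
  stopifnot(inherits(mat, "gene_cna_matrix"))
  if (inherits(models, "wgv_model")) models <- list(models)
  stopifnot(length(models) >= 1L)
  mat <- impute_zero(mat, quiet = TRUE)
  votes <- vapply(models, function(m) {
    x <- mat$values[m$gene, , drop = FALSE]
    colSums(m$weight * (x - m$midpoint)) / sum(abs(m$weight))
  }, numeric(ncol(mat$values)))
  rowMeans(matrix(votes, ncol = length(models),
                  dimnames = list(colnames(mat$values), NULL)))
}

#' Export a WGV model as TSV (gene, weight, midpoint)
#' @param model a `wgv_model`.
#' @param path output path.
#' @export
write_wgv_model <- function(model, path) {
  utils::write.table(model, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Evaluate predictions against a measured phenotype
#'
#' Pearson correlation between scores and phenotype, with a permutation
#' p-value: the add-one fraction of score shuffles whose `|r|` reaches the
#' observed `|r|`.
#'
#' @param scores named or plain numeric predictions.
#' @param phenotype numeric measurements, same order/length (n >= 3).
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @return list with `r`, `p`, `n`.
#' @export
evaluate_prediction <- function(scores, phenotype, n_perm = 1000, seed = 1) {
  scores <- as.double(scores); phenotype <- as.double(phenotype)
  if (length(scores) != length(phenotype) || length(scores) < 3L) {
    stop("need paired vectors of length >= 3")
  }
  if (anyNA(scores) || anyNA(phenotype)) stop("inputs must be finite")
  r <- stats::cor(scores, phenotype)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(sample(scores), phenotype))
    }, numeric(1))
  })
  list(r = r, p = (sum(perm >= abs(r)) + 1) / (n_perm + 1),
       n = length(scores))
}

#' Windowed-correlation permutation control
#'
#' Controls for the general rise of predicted glycolysis with genomic
#' instability: samples are binned into contiguous windows of
#' `window_width` along the integrated-CNA axis, the Spearman correlation
#' between predictions and the target is computed per window with at least
#' `min_n` samples, and the global p-value is the add-one fraction of
#' prediction shuffles whose *maximum* per-window correlation reaches the
#' observed maximum — a family-wise "any window" null.
#'
#' @param scores numeric predictions (e.g. WGV votes).
#' @param target numeric per-sample quantity to correlate with (e.g. PC1
#'   score or measured phenotype).
#' @param integrated_cna numeric per-sample instability used for windowing.
#' @param window_width window width in integrated-CNA units.
#' @param min_n minimum samples per usable window; smaller windows are
#'   reported but excluded from both the observed and null maxima.
#' @param n_perm number of shuffles (the reference procedure used 1e6;
#'   default 10,000 at desk scale).
#' @param seed integer seed.
#' @return list with `windows` (data.frame `lo`, `hi`, `n`, `rho`, `used`),
#'   `max_rho`, `p`.
#' @export
windowed_correlation_test <- function(scores, target, integrated_cna,
                                      window_width = 0.1, min_n = 10L,
                                      n_perm = 10000, seed = 1) {
  stopifnot(length(scores) == length(target),
            length(scores) == length(integrated_cna))
  lo0 <- floor(min(integrated_cna) / window_width) * window_width
  breaks <- seq(lo0, max(integrated_cna) + window_width, by = window_width)
  bin <- findInterval(integrated_cna, breaks, rightmost.closed = TRUE)
  bins <- sort(unique(bin))
  idx_list <- lapply(bins, function(b) which(bin == b))
  tr_list <- lapply(idx_list, function(i) rank(target[i]))
  win <- data.frame(lo = breaks[bins], hi = breaks[bins + 1L],
                    n = lengths(idx_list))
  win$used <- win$n >= min_n
  if (!any(win$used)) stop("no window reaches min_n samples")
  rho_fun <- function(s) {
    max(vapply(which(win$used), function(j) {
      stats::cor(rank(s[idx_list[[j]]]), tr_list[[j]])
    }, numeric(1)))
  }
  win$rho <- NA_real_
  for (j in seq_len(nrow(win))) {
    if (win$n[j] >= 3L) {
      win$rho[j] <- stats::cor(rank(scores[idx_list[[j]]]), tr_list[[j]])
    }
  }
  obs <- rho_fun(scores)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) rho_fun(sample(scores)), numeric(1))
  })
  list(windows = win, max_rho = obs,
       p = (sum(perm >= obs) + 1) / (n_perm + 1))
}
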