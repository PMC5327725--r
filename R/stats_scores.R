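#' Senescence score of a growth curve
#'
#' Quantifies the growth dip a fibroblast subline suffers during
#' immortalization. `z` is the observed cumulative log2 growth at passages
#' `0..p` (so `z[1] = 0`); the ideal curve grows at the maximum observed
#' per-passage rate, `y(x) = x * max(diff(z))`. The score is the trapezoid
#' area between the two curves summed over passages `2..p` (as defined, the
#' first trapezoid is never counted), divided by `p`, then log2-transformed.
#' A subline that always grows at its maximum rate has zero area gap and
#' returns `-Inf`, the "no senescence" sentinel; downstream correlations
#' exclude such values with a logged count.
#'
#' @param z numeric vector of cumulative log2 growth, indexed passage
#'   `0..p` (`length(z) = p + 1`, `z[1] = 0`, `p >= 2`).
#' @return numeric scalar (possibly `-Inf`).
#' @examples
#' senescence_score(c(0, 2, 2, 2))  # log2(4/3)
#' @export
senescence_score <- function(z) {
  p <- length(z) - 1L
  if (p < 2L) stop("need at least 2 passages")
  if (abs(z[1L]) > 1e-12) stop("curve must start at 0")
  rate <- max(diff(z))
  y <- rate * (0:p)
  x <- 2:p + 1L  # indices of passages 2..p in the 1-based vector
  gap <- sum((y[x] + y[x - 1L]) / 2 - (z[x] + z[x - 1L]) / 2)
  if (gap <= 0) return(-Inf)
  log2(gap / p)
}

#' Senescence scores for a growth-curve table
#'
#' @param curves data.frame with columns `sample_id`, `passage`,
#'   `log2_cumulative_growth` (passage 0 row required per sample).
#' @return named numeric vector of scores.
#' @export
senescence_scores <- function(curves) {
  stopifnot(all(c("sample_id", "passage", "log2_cumulative_growth") %in%
                  names(curves)))
  out <- vapply(split(curves, curves$sample_id), function(cc) {
    cc <- cc[order(cc$passage), ]
    if (!identical(as.integer(cc$passage), seq.int(0L, nrow(cc) - 1L))) {
      stop("passages must be consecutive from 0 for sample ",
           cc$sample_id[1L])
    }
    senescence_score(cc$log2_cumulative_growth)
  }, numeric(1))
  out
}

#' Read / write growth-curve tables
#'
#' Tab-separated `sample_id<TAB>passage<TAB>log2_cumulative_growth` with a
#' header.
#' @param path file path.
#' @export
read_growth_curves <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "numeric"))
}

#' @rdname read_growth_curves
#' @param curves growth-curve data.frame.
#' @export
write_growth_curves <- function(curves, path) {
  utils::write.table(
    curves[, c("sample_id", "passage", "log2_cumulative_growth")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Rule-dispatched two-group comparison
#'
#' Test selection follows a fixed convention: if both groups pass the
#' Shapiro-Wilk normality check (p > 0.05), a two-sided Student's t-test;
#' otherwise a Mann-Whitney U test; if one group is a single observation,
#' its z-score against the other group's mean and standard deviation with a
#' two-sided normal p-value. Groups of size 2 cannot be tested for
#' normality and fall through to Mann-Whitney. The dispatch is a pure
#' function of the Shapiro p-values and group sizes.
#'
#' @param a,b numeric vectors (non-empty).
#' @param alternative passed to the two-sided tests; pre-registered
#'   directions can use `"less"`/`"greater"`.
#' @return list with `test` (name), `statistic`, `p`, plus the Shapiro
#'   p-values when computed.
#' @export
compare_groups <- function(a, b, alternative = "two.sided") {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(a) == 1L || length(b) == 1L) {
    single <- if (length(a) == 1L) a else b
    other <- if (length(a) == 1L) b else a
    if (length(other) < 2L) stop("cannot compare two singletons")
    z <- (single - mean(other)) / stats::sd(other)
    if (length(a) != 1L) z <- -z  # orient as a vs b
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    return(list(test = "z-score", statistic = unname(z), p = unname(p)))
  }
  sw <- function(x) {
    if (length(x) < 3L) return(0)  # can't confirm normality
    stats::shapiro.test(x)$p.value
  }
  pa <- sw(a); pb <- sw(b)
  if (pa > 0.05 && pb > 0.05) {
    ht <- stats::t.test(a, b, var.equal = TRUE, alternative = alternative)
    list(test = "t-test", statistic = unname(ht$statistic), p = ht$p.value,
         shapiro_p = c(pa, pb))
  } else {
    ht <- stats::wilcox.test(a, b, alternative = alternative, exact = FALSE)
    list(test = "mann-whitney", statistic = unname(ht$statistic),
         p = ht$p.value, shapiro_p = c(pa, pb))
  }
}

#' Fisher's combined probability
#'
#' `chi2 = -2 * sum(log(p))` on `2k` degrees of freedom, upper tail.
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @export
fisher_combined <- function(pvalues) {
  stopifnot(length(pvalues) >= 1L, all(pvalues > 0), all(pvalues <= 1))
  chi2 <- -2 * sum(log(pvalues))
  stats::pchisq(chi2, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Hypergeometric upper-tail overlap probability
#'
#' Probability of observing at least `overlap` common elements between a
#' set of size `set1` and a set of size `set2` drawn from a universe of
#' size `universe`.
#'
#' @param overlap observed overlap.
#' @param set1,set2 set sizes.
#' @param universe universe size.
#' @return p-value.
#' @export
hypergeom_tail <- function(overlap, set1, set2, universe) {
  stopifnot(overlap <= min(set1, set2), max(set1, set2) <= universe)
  stats::phyper(overlap - 1, set1, universe - set1, set2,
                lower.tail = FALSE)
}
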