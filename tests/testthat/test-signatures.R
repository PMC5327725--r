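test_that("snr and t-score match their formulas and library oracles", {
  # two-point groups with sd exactly 0.5 and means 1 and 0
  g1 <- 1 + c(-1, 1) * 0.5 / sqrt(2)
  g2 <- 0 + c(-1, 1) * 0.5 / sqrt(2)
  expect_equal(sd(g1), 0.5)
  expect_equal(snr(g1, g2), 1)
  expect_equal(snr(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(t_score(c(1, 2), c(1, 2)), 0)
  # mu1-mu2 = 1, sd = 1, n = 2 each: denominator sqrt(1/2 + 1/2) = 1
  a <- c(1.5 - sqrt(2) / 2, 1.5 + sqrt(2) / 2)
  b <- c(0.5 - sqrt(2) / 2, 0.5 + sqrt(2) / 2)
  expect_equal(sd(a), 1)
  expect_equal(t_score(a, b), 1)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    expect_equal(snr(x, y), (mean(x) - mean(y)) / (sd(x) + sd(y)),
                 tolerance = 1e-12)
    expect_equal(t_score(x, y), unname(t.test(x, y)$statistic),
                 tolerance = 1e-12)
  }
  # degenerate: zero spread
  expect_equal(snr(c(1, 1), c(1, 1)), 0)
  expect_equal(snr(c(2, 2), c(1, 1)), Inf)
})

test_that("identical-profile collapsing keeps the lowest-coordinate representative", {
  gm <- toy_gene_model(data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(0, 100, 200), end = c(50, 150, 250)
  ))
  v <- matrix(c(1, 1, 2,
                1, 1, 3), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cc <- collapse_identical_genes(toy_matrix(v, gm))
  expect_equal(rownames(cc$matrix$values), c("g1", "g3"))
  expect_equal(cc$map$representative[cc$map$member == "g2"], "g1")
  # all distinct -> identity map
  v2 <- matrix(1:6, 3, dimnames = dimnames(v))
  cc2 <- collapse_identical_genes(toy_matrix(v2, gm))
  expect_equal(cc2$map$representative, cc2$map$member)
  # near-equal beyond the rounding precision is NOT collapsed
  v3 <- v; v3[2, 1] <- v3[2, 1] + 1e-3
  cc3 <- collapse_identical_genes(toy_matrix(v3, gm))
  expect_equal(nrow(cc3$matrix$values), 3L)
  # but sub-rounding differences are
  v4 <- v; v4[2, 1] <- v4[2, 1] + 1e-9
  cc4 <- collapse_identical_genes(toy_matrix(v4, gm))
  expect_equal(nrow(cc4$matrix$values), 2L)
})

make_two_cloud <- function(n = 30, ngene = 40, sep = 2, seed = 5) {
  set.seed(seed)
  gm <- toy_gene_model(data.frame(
    gene_id = sprintf("g%03d", 1:ngene), chrom = "chr1",
    start = seq(0, by = 1e4, length.out = ngene),
    end = seq(0, by = 1e4, length.out = ngene) + 5e3
  ))
  direction <- c(rep(1, 10), rep(0, ngene - 10))
  cls <- rep(c(0, 1), each = n / 2)
  v <- sapply(seq_len(n), function(i) {
    cls[i] * sep * direction + rnorm(ngene, 0, 0.05)
  })
  dimnames(v) <- list(gm$gene_id, sprintf("s%02d", 1:n))
  list(mat = toy_matrix(v, gm), cls = cls)
}

test_that("PCA separates planted clouds, reconstructs, and orients deterministically", {
  tc <- make_two_cloud()
  p <- run_pca(tc$mat)
  # PC1 separates the two clouds completely
  s1 <- p$scores[, 1]
  expect_true(min(s1[tc$cls == 1]) > max(s1[tc$cls == 0]))
  # high-burden cloud at the positive end under the default metric
  expect_true(mean(s1[tc$cls == 1]) > 0)
  # planted direction dominates PC1 variance
  expect_gt(p$var_explained[1], 0.9)
  # loadings orthonormal; full reconstruction exact
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  coll <- collapse_identical_genes(impute_zero(tc$mat, quiet = TRUE))
  centered <- t(coll$matrix$values) -
    matrix(p$center, nrow(t(coll$matrix$values)), length(p$center),
           byrow = TRUE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(norm(recon - centered, "F") / norm(centered, "F"), 1e-8)
  # scores = centered data x loadings
  expect_equal(centered %*% p$loadings, p$scores, tolerance = 1e-10)
  # orientation flips when the metric is reversed
  metric <- colMeans(abs(tc$mat$values))
  p2 <- run_pca(tc$mat, orientation_metric = max(metric) - metric)
  expect_equal(p2$scores[, 1], -p$scores[, 1], tolerance = 1e-10)
  # determinism
  p3 <- run_pca(tc$mat)
  expect_identical(p3$scores, p$scores)
})

test_that("duplicated genes share loadings after re-expansion", {
  tc <- make_two_cloud(seed = 6)
  v <- tc$mat$values
  v["g002", ] <- v["g001", ]
  m <- toy_matrix(v, tc$mat$genes)
  p <- run_pca(m)
  expect_equal(p$loadings_expanded["g001", ], p$loadings_expanded["g002", ])
  expect_error(run_pca(toy_matrix(v * 0, tc$mat$genes)),
               "degenerate|distinct")
})

test_that("projection reproduces training scores and zeroes the center", {
  tc <- make_two_cloud(seed = 7)
  p <- run_pca(tc$mat)
  expect_equal(predict(p, tc$mat), p$scores, tolerance = 1e-10)
  center_mat <- matrix(p$center, ncol = 1,
                       dimnames = list(names(p$center), "c"))
  expect_equal(unname(predict(p, center_mat)[1, ]),
               rep(0, ncol(p$scores)), tolerance = 1e-10)
  # a signature-like new sample scores above diploid controls on PC1
  newd <- cbind(
    siglike = c(rep(2, 10), rep(0, 30)) + 0,
    dip = rep(0, 40)
  )
  rownames(newd) <- rownames(tc$mat$values)
  sc <- predict(p, newd)
  expect_gt(sc["siglike", 1], sc["dip", 1])
})

test_that("core signature normalizes top-decile SNR against normals", {
  set.seed(8)
  ngene <- 50; ntum <- 20; nnorm <- 5
  gm <- toy_gene_model(data.frame(
    gene_id = sprintf("g%03d", 1:ngene), chrom = "chr1",
    start = seq(0, by = 1e4, length.out = ngene),
    end = seq(0, by = 1e4, length.out = ngene) + 5e3
  ))
  amp <- 1:8  # planted block in the strong tumors
  strength <- c(seq(2, 1, length.out = ntum), rep(0, nnorm))
  v <- sapply(seq_len(ntum + nnorm), function(i) {
    x <- rnorm(ngene, 0, 0.05)
    x[amp] <- x[amp] + strength[i]
    x
  })
  dimnames(v) <- list(gm$gene_id, c(sprintf("t%02d", 1:ntum),
                                    sprintf("n%02d", 1:nnorm)))
  m <- toy_matrix(v, gm)
  pc1 <- setNames(strength[1:ntum], colnames(v)[1:ntum])
  normals <- sprintf("n%02d", 1:nnorm)
  sig <- core_signature(m, pc1, normals, cohort = "test")
  expect_equal(max(abs(sig$value)), 1)
  # planted genes occupy the top of the signature ranking
  expect_setequal(order(-sig$value)[seq_along(amp)], amp)
  expect_gt(min(sig$value[amp]), 3 * max(abs(sig$value[-amp])))
  # invariant to sample order
  perm <- sample(ncol(v))
  m2 <- toy_matrix(v[, perm], gm)
  sig2 <- core_signature(m2, pc1, normals, cohort = "test")
  expect_equal(sig2$value, sig$value)
  # tumors identical to normals -> all-zero signature
  v0 <- matrix(rep(v[, ntum + 1], ntum + nnorm), ngene,
               dimnames = dimnames(v))
  sig0 <- core_signature(toy_matrix(v0, gm), pc1, normals)
  expect_true(all(sig0$value == 0))
  # loadings mode scales the component to max |1|
  p <- run_pca(m)
  sigL <- core_signature(mode = "pc_loadings", model = p)
  expect_equal(max(abs(sigL$value)), 1)
  expect_error(core_signature(m, pc1, colnames(v)[1:(ntum + nnorm - 1)]),
               ">= 10 tumors")
})

test_that("signature TSV round-trips", {
  gm <- toy_gene_model(data.frame(gene_id = c("a", "b"), chrom = "chr1",
                                  start = c(0, 100), end = c(50, 200)))
  sig <- structure(data.frame(gene_id = c("a", "b"), value = c(0.25, -1)),
                   mode = "snr_vs_normals", cohort = "C1", genes = gm,
                   class = c("summary_signature", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, f)
  sig2 <- read_signature(f, gm)
  expect_equal(sig2$value, sig$value)
  expect_equal(attr(sig2, "cohort"), "C1")
})

test_that("Ward clustering on correlation distance recovers planted groups", {
  tc <- make_two_cloud(n = 20, seed = 9)
  labels <- hierarchical_cluster(tc$mat, 2)
  expect_equal(length(unique(labels[tc$cls == 0])), 1L)
  expect_equal(length(unique(labels[tc$cls == 1])), 1L)
  # a duplicated sample lands with its twin
  v <- cbind(tc$mat$values, dup = tc$mat$values[, 1])
  labs2 <- hierarchical_cluster(toy_matrix(v, tc$mat$genes), 2)
  expect_equal(unname(labs2["dup"]), unname(labs2[1]))
  # concordance p for a perfectly recovered set
  top <- names(labels)[tc$cls == 1]
  cc <- cluster_pca_concordance(labels, top)
  expect_equal(cc$p, 1 / choose(20, 10))
})

test_that("paired evolving-signature statistic is a signed log10 paired t", {
  set.seed(10)
  gm <- toy_gene_model(data.frame(
    gene_id = c("flat", "gain", "loss"), chrom = "chr1",
    start = c(0, 100, 200), end = c(50, 150, 250)
  ))
  n <- 5
  early <- matrix(rnorm(3 * n, 0, 0.01), 3,
                  dimnames = list(gm$gene_id, paste0("e", 1:n)))
  late <- early + c(0, 0.5, -0.5) + matrix(rnorm(3 * n, 0, 0.01), 3)
  late[1, ] <- early[1, ]
  colnames(late) <- paste0("l", 1:n)
  m <- toy_matrix(cbind(early, late), gm)
  pairs <- data.frame(early = paste0("e", 1:n), late = paste0("l", 1:n))
  st <- paired_evolution_signature(m, pairs)
  expect_equal(unname(st["flat"]), 0)
  expect_gt(st["gain"], 3)
  # antisymmetry between equal-magnitude gain and loss patterns
  expect_lt(st["loss"], -3)
  # library oracle
  tt <- t.test(late[2, ], early[2, ], paired = TRUE)
  expect_equal(unname(st["gain"]), -log10(tt$p.value), tolerance = 1e-10)
  expect_error(paired_evolution_signature(m, pairs[1:2, ]), ">= 3 pairs")
})

test_that("balanced sampling is seeded and cohort-balanced", {
  cohorts <- setNames(rep(c("A", "B", "C"), c(10, 6, 8)),
                      sprintf("s%02d", 1:24))
  s1 <- balanced_sample(cohorts, seed = 3)
  s2 <- balanced_sample(cohorts, seed = 3)
  expect_identical(s1, s2)
  expect_equal(unname(table(cohorts[s1])), rep(6L, 3), ignore_attr = TRUE)
})
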