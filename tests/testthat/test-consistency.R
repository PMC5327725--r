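test_that("SAMCS is the common-sign minimum and zero otherwise", {
  expect_equal(samcs(c(0.3, 0.2, 0.5)), 0.2)
  expect_equal(samcs(c(0.3, -0.2)), 0)
  expect_equal(samcs(c(-0.3, -0.4, -0.1)), -0.1)
  expect_equal(samcs(c(0, 0.4)), 0)
  expect_error(samcs(0.3), ">= 2")
  # permutation invariance and monotone non-increase under cohort addition
  set.seed(21)
  for (i in 1:50) {
    v <- round(runif(sample(2:6, 1), -1, 1), 2)
    expect_equal(samcs(v), samcs(sample(v)))
    expect_equal(samcs(v), oracle_samcs(v))
    expect_lte(abs(samcs(c(v, runif(1, -1, 1)))), abs(samcs(v)))
  }
})

toy_signature <- function(gene_ids, values, genes, cohort = "C") {
  structure(data.frame(gene_id = gene_ids, value = values),
            mode = "snr_vs_normals", cohort = cohort, genes = genes,
            class = c("summary_signature", "data.frame"))
}

grid_genes <- function(n, spacing = 1e5, width = 5e4, chrom_len = max(n * spacing, 1e6)) {
  toy_gene_model(data.frame(
    gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
    start = (0:(n - 1)) * spacing, end = (0:(n - 1)) * spacing + width
  ), toy_assembly(c(chr1 = chrom_len)))
}

test_that("consistency signature equals the gene-wise SAMCS oracle", {
  gm <- grid_genes(30)
  set.seed(22)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    sigs <- lapply(1:k, function(j) {
      toy_signature(gm$gene_id, round(runif(30, -1, 1), 2), gm,
                    paste0("C", j))
    })
    cons <- build_consistency_signature(sigs, gm)
    for (i in seq_len(30)) {
      v <- vapply(sigs, function(s) s$value[i], numeric(1))
      expect_equal(cons$samcs[i], oracle_samcs(v))
    }
  }
  # idempotence for a repeated identical signature
  s <- toy_signature(gm$gene_id, round(runif(30, -1, 1), 2), gm)
  cons2 <- build_consistency_signature(list(s, s), gm)
  expect_equal(cons2$samcs, s$value)
  # a single signature is returned unchanged
  cons1 <- build_consistency_signature(list(s), gm)
  expect_equal(cons1$samcs, s$value)
  # an all-zero cohort zeroes everything
  z <- toy_signature(gm$gene_id, rep(0, 30), gm)
  expect_true(all(build_consistency_signature(list(s, z), gm)$samcs == 0))
})

test_that("region calling applies threshold, span and merge rules", {
  # 16 consecutive genes at 0.1 spanning ~1.5 Mbp -> one amplified region
  gm <- grid_genes(20, spacing = 1e5, width = 5e4, chrom_len = 5e6)
  v <- rep(0, 20); v[3:18] <- 0.1
  cons <- build_consistency_signature(
    list(toy_signature(gm$gene_id, v, gm),
         toy_signature(gm$gene_id, v, gm)), gm)
  regs <- call_consistent_regions(cons, gm)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$direction, "amplified")
  expect_equal(regs$start, gm$start[3])
  expect_equal(regs$end, gm$end[18])
  expect_equal(regs$n_genes, 16L)
  # |SAMCS| exactly at the threshold is excluded (strict >)
  v2 <- v; v2[3:18] <- 0.05
  cons2 <- build_consistency_signature(
    list(toy_signature(gm$gene_id, v2, gm),
         toy_signature(gm$gene_id, v2, gm)), gm)
  expect_equal(nrow(call_consistent_regions(cons2, gm)), 0L)
  # two amplified runs separated by < 1 Mbp merge into one region
  gm3 <- grid_genes(40, spacing = 1e5, width = 5e4, chrom_len = 8e6)
  v3 <- rep(0, 40); v3[1:12] <- 0.2; v3[18:29] <- 0.2  # 0.5 Mbp gap
  cons3 <- build_consistency_signature(
    list(toy_signature(gm3$gene_id, v3, gm3),
         toy_signature(gm3$gene_id, v3, gm3)), gm3)
  regs3 <- call_consistent_regions(cons3, gm3)
  expect_equal(nrow(regs3), 1L)
  expect_equal(regs3$start, gm3$start[1])
  expect_equal(regs3$end, gm3$end[29])
  # opposite directions never merge
  v4 <- rep(0, 40); v4[1:12] <- 0.2; v4[18:29] <- -0.2
  cons4 <- build_consistency_signature(
    list(toy_signature(gm3$gene_id, v4, gm3),
         toy_signature(gm3$gene_id, v4, gm3)), gm3)
  regs4 <- call_consistent_regions(cons4, gm3)
  expect_equal(nrow(regs4), 2L)
  expect_setequal(regs4$direction, c("amplified", "deleted"))
})

test_that("region calling matches the interval-arithmetic oracle on random inputs", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(10:40, 1)
    gm <- grid_genes(n, spacing = 2e5, width = 1e5, chrom_len = 2e7)
    # blocky random signature so that >threshold runs exist
    v <- round(rep(runif(ceiling(n / 5), -0.4, 0.4),
                   each = 5)[seq_len(n)], 2)
    cons <- build_consistency_signature(
      list(toy_signature(gm$gene_id, v, gm),
           toy_signature(gm$gene_id, v, gm)), gm)
    regs <- call_consistent_regions(cons, gm, threshold = 0.05,
                                    min_span = 1e6, merge_gap = 1e6)
    orc <- oracle_regions(as.data.frame(gm)[, c("chrom", "start", "end")],
                          v, 0.05, 1e6, 1e6)
    if (is.null(orc) || nrow(orc) == 0) {
      expect_equal(nrow(regs), 0L)
    } else {
      expect_equal(nrow(regs), nrow(orc))
      expect_equal(regs$start, orc$start)
      expect_equal(regs$end, orc$end)
      expect_equal(regs$direction == "amplified", orc$direction > 0)
    }
  }
})

test_that("region calling is idempotent on its own indicator signature", {
  gm <- grid_genes(40, spacing = 1e5, width = 5e4, chrom_len = 8e6)
  v <- rep(0, 40); v[5:20] <- 0.3; v[30:40] <- -0.2
  cons <- build_consistency_signature(
    list(toy_signature(gm$gene_id, v, gm),
         toy_signature(gm$gene_id, v, gm)), gm)
  regs <- call_consistent_regions(cons, gm)
  # indicator: members keep their samcs, everything else zero
  member <- unlist(strsplit(regs$gene_ids, ","))
  v2 <- ifelse(gm$gene_id %in% member, cons$samcs, 0)
  cons2 <- structure(data.frame(gene_id = gm$gene_id, samcs = v2),
                     genes = gm,
                     class = c("consistency_signature", "data.frame"))
  regs2 <- call_consistent_regions(cons2, gm)
  expect_equal(regs2$start, regs$start)
  expect_equal(regs2$end, regs$end)
  expect_equal(regs2$direction, regs$direction)
})

test_that("ortholog mapping restricts to the shared one-to-one space", {
  gm <- grid_genes(10)
  sig <- toy_signature(gm$gene_id, seq(0.1, 1, 0.1), gm)
  # identity map
  map <- data.frame(gene_a = gm$gene_id, gene_b = gm$gene_id)
  out <- map_across_species(sig, map, gm)
  expect_equal(out$value, sig$value)
  # missing orthologs drop out
  map2 <- map[-c(3, 7), ]
  out2 <- map_across_species(sig, map2, gm)
  expect_equal(nrow(out2), 8L)
  expect_false(any(out2$gene_id %in% gm$gene_id[c(3, 7)]))
  # one-to-many pairs are removed up front
  map3 <- rbind(map, data.frame(gene_a = "g001", gene_b = "g999"))
  expect_message(f <- filter_one_to_one(map3), "removed 2")
  expect_false("g001" %in% f$gene_a)
})

test_that("sequential addition is monotone and collapses on contradiction", {
  gm <- grid_genes(40, spacing = 1e5, width = 5e4, chrom_len = 8e6)
  asm <- attr(gm, "assembly")
  base <- rep(0, 40); base[5:20] <- 0.3
  sigs <- lapply(1:5, function(i) {
    toy_signature(gm$gene_id, base + 0.01 * i, gm, paste0("C", i))
  })
  contra <- toy_signature(gm$gene_id, -(base + 0.01), gm, "C6")
  sq <- sequential_consistency(c(sigs, list(contra)), gm, asm)
  # genome fraction is non-increasing at every step
  expect_true(all(diff(sq$steps$genome_fraction) <= 1e-12))
  # planted region present through step 5, absent at step 6
  expect_true(all(sq$steps$n_regions[1:5] == 1))
  expect_equal(sq$steps$n_regions[6], 0)
  # per-gene |SAMCS| never increases when a cohort is added
  for (k in 2:6) {
    prev <- sq$consistency[[k - 1]]
    cur <- sq$consistency[[k]]
    expect_true(all(abs(cur$samcs) <=
                      abs(prev$samcs[match(cur$gene_id, prev$gene_id)]) + 1e-12))
  }
  # an all-zero cohort zeroes everything at its step
  sq0 <- sequential_consistency(
    list(A = sigs[[1]], Z = toy_signature(gm$gene_id, rep(0, 40), gm)),
    gm, asm)
  expect_equal(sq0$steps$genome_fraction[2], 0)
  # callback is evaluated per step
  sq1 <- sequential_consistency(sigs[1:2], gm, asm,
                                callback = function(cons, regs) nrow(regs))
  expect_equal(sq1$steps$callback, c(1, 1))
})

test_that("genome fraction counts region bases over assembly length", {
  asm <- toy_assembly(c(chr1 = 5e7, chr2 = 5e7))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  expect_equal(genome_fraction_consistent(empty, asm)$fraction, 0)
  one <- data.frame(chrom = "chr1", start = 1e7, end = 2e7)
  expect_equal(genome_fraction_consistent(one, asm)$fraction, 0.1)
  set.seed(24)
  for (rep in 1:10) {
    k <- sample(1:5, 1)
    starts <- sort(sample(seq(0, 4e7, by = 1e6), k))
    regs <- data.frame(chrom = sample(c("chr1", "chr2"), k, TRUE),
                       start = starts, end = starts + sample(1:5, k) * 1e5)
    expect_equal(genome_fraction_consistent(regs, asm)$fraction,
                 sum(regs$end - regs$start) / 1e8)
  }
})

test_that("cohort ordering follows decreasing mean PC1", {
  pc1 <- setNames(c(3, 2, -1, -2, 10, 0), sprintf("s%d", 1:6))
  co <- setNames(rep(c("X", "Y", "Z"), each = 2), names(pc1))
  expect_equal(order_cohorts_by_pc1(pc1, co), c("Z", "X", "Y"))
})

test_that("region BED export carries direction and scaled scores", {
  regs <- structure(data.frame(
    chrom = "chr1", start = 1e6, end = 3e6, direction = "deleted",
    n_genes = 5L, min_abs_samcs = 0.21, gene_ids = "a,b,c,d,e",
    span = 2e6
  ), class = c("consistent_regions", "data.frame"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regs, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(fields, c("chr1", "1000000", "3000000", "deleted", "210", "-"))
})
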