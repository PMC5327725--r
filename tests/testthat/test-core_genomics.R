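test_that("SEG reading applies the 1-based inclusive convention and groups samples", {
  asm <- toy_assembly(c(chr1 = 2e6))
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c(
    "Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    "S1\tchr1\t1\t1000000\t50\t0.5",
    "S2\tchr1\t1\t500000\t10\t0.1",
    "S2\tchr1\t500001\t1000000\t10\t0.9"
  ), f)
  p <- read_seg(f, asm)
  s1 <- p$segments[p$segments$sample_id == "S1", ]
  expect_equal(s1$start, 0)
  expect_equal(s1$end, 1e6)
  expect_equal(s1$mean, 0.5)
  s2 <- p$segments[p$segments$sample_id == "S2", ]
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$start, c(0, 5e5))  # sorted, adjacent
})

test_that("SEG rejects unknown chromosomes and within-sample overlaps", {
  asm <- toy_assembly(c(chr1 = 2e6))
  f <- withr::local_tempfile(fileext = ".seg")
  writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
               "S1\tchrX\t1\t100\t5\t0.2"), f)
  expect_error(read_seg(f, asm), "chrX")
  expect_error(
    cna_profiles(data.frame(sample_id = "S1", chrom = "chr1",
                            start = c(0, 50), end = c(100, 150),
                            mean = c(0, 1)), asm),
    "overlap"
  )
})

test_that("SEG round-trips are exact, including NA marker counts and empty sets", {
  asm <- toy_assembly()
  p <- cna_profiles(data.frame(
    sample_id = c("S1", "S1", "S2"), chrom = c("chr1", "chr2", "chr1"),
    start = c(0, 1000, 7), end = c(12345, 99999, 4001),
    n_markers = c(10, NA, 3), mean = c(0.5173, -1.25, 0)
  ), asm)
  f <- withr::local_tempfile(fileext = ".seg")
  write_seg(p, f)
  p2 <- read_seg(f, asm)
  expect_equal(p2$segments, p$segments)
  empty <- cna_profiles(data.frame(sample_id = character(),
                                   chrom = character(), start = numeric(),
                                   end = numeric(), mean = numeric()), asm)
  write_seg(empty, f)
  expect_equal(length(readLines(f)), 1L)  # header only
  expect_equal(nrow(read_seg(f, asm)$segments), 0L)
})

test_that("BED gene models parse, ignore extra columns, and reject duplicates", {
  asm <- toy_assembly()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tgeneA\t0\t+\tmore\tcols",
               "chr2\t0\t500\tgeneB"), f)
  gm <- read_gene_model(f, asm)
  expect_equal(gm$gene_id, c("geneA", "geneB"))
  expect_equal(gm$start[gm$gene_id == "geneA"], 100)
  expect_equal(gm$end[gm$gene_id == "geneA"], 200)
  writeLines(c("chr1\t100\t200\tgeneA", "chr1\t300\t400\tgeneA"), f)
  expect_error(read_gene_model(f, asm), "duplicate")
  # round trip
  f2 <- withr::local_tempfile(fileext = ".bed")
  gm1 <- toy_gene_model(data.frame(gene_id = c("a", "b"), chrom = "chr1",
                                   start = c(10, 5000), end = c(400, 9000)))
  write_gene_model(gm1, f2)
  gm2 <- read_gene_model(f2, asm)
  expect_equal(as.data.frame(gm2)[, 1:4], as.data.frame(gm1)[, 1:4])
})

test_that("gene matrix values are overlap-length-weighted segment means", {
  asm <- toy_assembly(c(chr1 = 1e6, chr2 = 1e6))
  gm <- toy_gene_model(data.frame(
    gene_id = c("inside", "split", "uncovered"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(100, 5000, 0), end = c(200, 6000, 100)
  ), asm)
  p <- cna_profiles(data.frame(
    sample_id = "S1", chrom = "chr1", start = c(0, 5400),
    end = c(5400, 10000), mean = c(0, 1)
  ), asm)
  m <- segments_to_gene_matrix(p, gm)
  expect_equal(m$values["inside", "S1"], 0)
  expect_equal(m$values["split", "S1"], 0.6)  # 40% at 0, 60% at 1
  expect_true(is.na(m$values["uncovered", "S1"]))
  expect_error(segments_to_gene_matrix(p, gm[0, ]), "empty")
})

test_that("gene matrix equals per-base averaging oracle on random small genomes", {
  set.seed(42)
  for (rep in 1:25) {
    len <- 2000L
    asm <- toy_assembly(c(chr1 = len))
    ng <- sample(2:10, 1)
    starts <- sort(sample(0:(len - 20L), ng))
    genes <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                        chrom = "chr1", start = starts,
                        end = pmin(starts + sample(5:200, ng, TRUE), len))
    gm <- toy_gene_model(genes, asm)
    cuts <- sort(sample(1:(len - 1), sample(0:9, 1)))
    bounds <- unique(c(0, cuts, len))
    segs <- data.frame(sample_id = "S1", chrom = "chr1",
                       start = bounds[-length(bounds)], end = bounds[-1],
                       mean = round(rnorm(length(bounds) - 1), 3))
    keep <- runif(nrow(segs)) > 0.3  # leave gaps
    if (!any(keep)) keep[1] <- TRUE
    segs <- segs[keep, ]
    p <- cna_profiles(segs, asm)
    m <- segments_to_gene_matrix(p, gm)
    for (i in seq_len(nrow(gm))) {
      expect_equal(
        m$values[gm$gene_id[i], "S1"],
        oracle_gene_value(gm$start[i], gm$end[i], segs$start, segs$end,
                          segs$mean),
        tolerance = 1e-12
      )
    }
  }
})

test_that("integrated CNA follows the length-weighted absolute-mean formula", {
  asm <- toy_assembly(c(chr1 = 1e7))
  p0 <- cna_profiles(data.frame(sample_id = "S", chrom = "chr1",
                                start = c(0, 5e6), end = c(5e6, 1e7),
                                mean = c(0, 0)), asm)
  expect_equal(unname(integrated_cna(p0)), 0)
  p1 <- cna_profiles(data.frame(sample_id = "S", chrom = "chr1",
                                start = 0, end = 1e7, mean = 1), asm)
  expect_equal(unname(integrated_cna(p1)), 1)
  asm2 <- toy_assembly(c(chr1 = 1e7, chr2 = 1e7))
  p2 <- cna_profiles(data.frame(sample_id = "S", chrom = c("chr1", "chr2"),
                                start = 0, end = 1e7, mean = c(-0.5, 0)),
                     asm2)
  expect_equal(unname(integrated_cna(p2)), 0.25)
})

test_that("integrated CNA is split-invariant and homogeneous in |mean|", {
  set.seed(7)
  asm <- toy_assembly(c(chr1 = 1e6))
  for (rep in 1:10) {
    cuts <- sort(sample(1:999999, 5))
    b <- c(0, cuts, 1e6)
    segs <- data.frame(sample_id = "S", chrom = "chr1",
                       start = b[-length(b)], end = b[-1],
                       mean = rnorm(length(b) - 1))
    base <- unname(integrated_cna(cna_profiles(segs, asm)))
    # split the first segment in two with the same mean
    s2 <- rbind(segs, segs[1, ])
    mid <- floor((segs$start[1] + segs$end[1]) / 2)
    s2$end[1] <- mid; s2$start[nrow(s2)] <- mid
    expect_equal(unname(integrated_cna(cna_profiles(s2, asm))), base,
                 tolerance = 1e-12)
    # homogeneity of degree 1
    s3 <- segs; s3$mean <- 3 * s3$mean
    expect_equal(unname(integrated_cna(cna_profiles(s3, asm))), 3 * base,
                 tolerance = 1e-12)
  }
})

test_that("breakpoints count mean-changing boundaries only", {
  asm <- toy_assembly(c(chr1 = 1e6, chr2 = 1e6))
  p <- cna_profiles(data.frame(
    sample_id = "S",
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0, 4e5, 6e5, 0), end = c(4e5, 6e5, 1e6, 1e6),
    mean = c(0.1, 0.8, 0.1, 0.3)
  ), asm)
  bp <- count_breakpoints(p)
  expect_equal(unname(bp$total["S"]), 2L)
  expect_equal(bp$per_chromosome$breakpoints[
    bp$per_chromosome$chrom == "chr2"], 0L)
  expect_equal(unname(bp$mean_segment_length["S"]), mean(c(4e5, 2e5, 4e5, 1e6)))
  # equal-mean boundary not counted
  p2 <- cna_profiles(data.frame(sample_id = "S", chrom = "chr1",
                                start = c(0, 5e5), end = c(5e5, 1e6),
                                mean = c(0.5, 0.5)), asm)
  expect_equal(unname(count_breakpoints(p2)$total["S"]), 0L)
  # all-different means: total = sum over chroms (n_seg - 1)
  p3 <- cna_profiles(data.frame(sample_id = "S", chrom = "chr1",
                                start = c(0, 2e5, 7e5),
                                end = c(2e5, 7e5, 1e6),
                                mean = c(0.1, 0.2, 0.3)), asm)
  expect_equal(unname(count_breakpoints(p3)$total["S"]), 2L)
})

test_that("locus-to-chromosome-max ratio uses the 95th percentile reference", {
  asm <- toy_assembly(c(chr1 = 1e6))
  n <- 100L
  gm <- toy_gene_model(data.frame(
    gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
    start = seq(0, by = 1e4, length.out = n) ,
    end = seq(0, by = 1e4, length.out = n) + 5e3
  ), asm)
  vals <- matrix(seq(0.01, 1, length.out = n), ncol = 1,
                 dimnames = list(gm$gene_id, "S1"))
  m <- toy_matrix(vals, gm)
  target <- gm$gene_id[which.min(abs(vals[, 1] - 0.5))]
  r <- locus_to_chrmax_ratio(m, target)
  expect_equal(unname(r["S1"]),
               vals[target, 1] / quantile(vals[, 1], 0.95, names = FALSE))
  # constant chromosome: ratio 1
  m2 <- toy_matrix(matrix(0.8, n, 1, dimnames = list(gm$gene_id, "S1")), gm)
  expect_equal(unname(locus_to_chrmax_ratio(m2, "g001")["S1"]), 1)
  # non-positive robust max flagged
  m3 <- toy_matrix(matrix(-0.2, n, 1, dimnames = list(gm$gene_id, "S1")), gm)
  r3 <- locus_to_chrmax_ratio(m3, "g001")
  expect_true(is.na(r3[["S1"]]))
  expect_equal(attr(r3, "undefined"), "S1")
})
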