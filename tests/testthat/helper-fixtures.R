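# Small builders and independent brute-force oracles shared across tests.
# Oracles deliberately use naive per-base / per-element loops so they stay
# independent of the package's vectorized implementations.

toy_assembly <- function(lengths = c(chr1 = 1e6, chr2 = 1e6)) {
  genome_assembly("toy", data.frame(chrom = names(lengths),
                                    length = unname(lengths)))
}

toy_gene_model <- function(df, assembly = toy_assembly()) {
  gene_model(df, assembly)
}

toy_matrix <- function(values, genes) {
  structure(list(values = values, genes = genes,
                 assembly = attr(genes, "assembly"), sample_info = NULL),
            class = "gene_cna_matrix")
}

# --- oracles ---------------------------------------------------------------

# per-base averaging oracle for gene-level CNA values (tiny genomes only)
oracle_gene_value <- function(gene_start, gene_end, seg_starts, seg_ends,
                              seg_means) {
  vals <- rep(NA_real_, gene_end - gene_start)
  for (i in seq_along(seg_starts)) {
    lo <- max(gene_start, seg_starts[i]); hi <- min(gene_end, seg_ends[i])
    if (lo < hi) vals[(lo - gene_start + 1):(hi - gene_start)] <- seg_means[i]
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

oracle_samcs <- function(v) {
  if (any(v == 0)) return(0)
  if (all(v > 0)) return(min(v))
  if (all(v < 0)) return(-min(abs(v)))
  0
}

# step-by-step running-sum oracle for the truncated enrichment score
oracle_es <- function(values, set, weight = 1) {
  ord <- order(-values, names(values), method = "radix")
  v <- values[ord]
  hit <- names(v) %in% set
  npos <- sum(v > 0)
  if (npos == 0 || !any(hit[seq_len(npos)]) || sum(abs(v[hit])^weight) == 0) {
    return(0)
  }
  running <- 0
  best <- -Inf
  denom <- sum(abs(v[hit])^weight)
  nmiss <- sum(!hit)
  for (i in seq_along(v)) {
    step <- if (hit[i]) abs(v[[i]])^weight / denom else -1 / nmiss
    running <- running + step
    if (i <= npos && running > best) best <- running
  }
  best
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- rep(NA_real_, n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[ord[i]] * n / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

oracle_hypergeom <- function(overlap, k1, k2, universe) {
  # exhaustive enumeration over the overlap distribution
  probs <- vapply(0:min(k1, k2), function(x) {
    choose(k1, x) * choose(universe - k1, k2 - x) / choose(universe, k2)
  }, numeric(1))
  sum(probs[(overlap:min(k1, k2)) + 1L])
}

# interval-arithmetic oracle for region calling (single direction handling)
oracle_regions <- function(gene_pos, samcs, threshold, min_span, merge_gap) {
  # gene_pos: data.frame chrom,start,end in genome order
  dir <- ifelse(abs(samcs) > threshold, sign(samcs), 0)
  regs <- NULL
  i <- 1
  n <- nrow(gene_pos)
  while (i <= n) {
    if (dir[i] != 0) {
      j <- i
      while (j < n && dir[j + 1] == dir[i] &&
               gene_pos$chrom[j + 1] == gene_pos$chrom[i]) j <- j + 1
      regs <- rbind(regs, data.frame(
        chrom = gene_pos$chrom[i], start = gene_pos$start[i],
        end = gene_pos$end[j], direction = dir[i]
      ))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(regs)) return(regs)
  regs <- regs[regs$end - regs$start >= min_span, , drop = FALSE]
  if (nrow(regs) < 2) return(regs)
  out <- regs[1, ]
  for (i in 2:nrow(regs)) {
    last <- nrow(out)
    if (regs$chrom[i] == out$chrom[last] &&
          regs$direction[i] == out$direction[last] &&
          regs$start[i] - out$end[last] < merge_gap) {
      out$end[last] <- regs$end[i]
    } else out <- rbind(out, regs[i, ])
  }
  out
}

# jaccard between two interval sets (base pairs)
interval_jaccard <- function(a, b) {
  inter <- 0
  for (i in seq_len(NROW(a))) {
    for (j in seq_len(NROW(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        inter <- inter +
          max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
      }
    }
  }
  un <- sum(a$end - a$start) + sum(b$end - b$start) - inter
  if (un == 0) return(1)
  inter / un
}

# build a cohort's summary signature the way the pipeline does
cohort_signature <- function(genome, spec, seed, cohort) {
  sim <- simulate_cohort(genome, spec, seed = seed, cohort = cohort)
  m <- segments_to_gene_matrix(sim$profiles, genome$genes)
  ic <- integrated_cna(sim$profiles)
  bp <- count_breakpoints(sim$profiles)$total
  p <- run_pca(m, orientation_metric = bp)
  comp <- signature_component(p)
  normals <- sim$truth$sample_id[sim$truth$class == "normal"]
  sig <- core_signature(m, p$scores[, comp], normals, cohort = cohort)
  list(sig = sig, sim = sim, mat = m, pca = p, component = comp,
       int_cna = ic, normals = normals)
}
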