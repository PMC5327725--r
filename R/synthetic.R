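#' Parameterization of a synthetic CNA cohort
#'
#' Bundles every constant the generator uses so a cohort is fully
#' reproducible from a spec plus a seed. Defaults emulate the structure the
#' signature analysis assumes: a five-chromosome 500 Mbp genome with about
#' two thousand genes; a "glycolysis-like" driver set laid across three
#' chromosomes that is recurrently amplified (+0.4 log2) in signature-A
#' samples, which also carry many subchromosomal breakpoints; signature-B
#' samples with fewer, larger events and a mutually exclusive alternate
#' amplification / deletion locus pair; near-diploid tumors and low-noise
#' normals. Signature-A samples are 10% of the tumors so the planted set
#' coincides with the top PC1 decile. Segment-mean noise (sd 0.05 for
#' tumors, 0.02 for normals) reflects post-segmentation means averaged over
#' many probes.
#'
#' @param n_sig_a,n_sig_b,n_diploid,n_normal class sizes (per cohort).
#' @param n_chromosomes,chrom_length genome shape (base pairs).
#' @param gene_spacing,gene_length,spacing_jitter gene tiling (base pairs;
#'   jitter as a fraction of spacing).
#' @param bp_rate_a,bp_rate_b,bp_rate_diploid,bp_rate_normal breakpoint
#'   rates per Mbp.
#' @param noise_sd_a,noise_sd_b,noise_sd_diploid,noise_sd_normal segment
#'   mean noise (log2 units).
#' @param effect planted amplification effect for signature A (log2).
#' @param b_effect planted effect at the signature-B loci (log2).
#' @param passenger_effect amplitude of the species-specific recurrent
#'   passenger regions carried by signature-A tumors (log2).
#' @param strength_range per-sample multiplier range on the planted effect.
#' @param phenotype_alpha,phenotype_sigma linear coupling and noise of the
#'   simulated phenotype on standardized signature strength.
#' @param label_slope,label_intercept logistic model of the binary
#'   ("p53-mutant-like") label on raw signature strength.
#' @param growth_passages,growth_rate,growth_coupling,growth_noise growth
#'   curve shape: passages, maximal log2 rate per passage, dip depth per
#'   unit integrated CNA, increment noise.
#' @param n_decoy_sets decoy gene sets of matched size.
#' @param mixed_fraction probability that a tumor draws both classes'
#'   planted events (off by default).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sig_a = 6L, n_sig_b = 14L, n_diploid = 40L,
                        n_normal = 10L, n_chromosomes = 5L,
                        chrom_length = 1e8, gene_spacing = 2.5e5,
                        gene_length = 2e4, spacing_jitter = 0.3,
                        bp_rate_a = 0.2, bp_rate_b = 0.02,
                        bp_rate_diploid = 0.02, bp_rate_normal = 0.01,
                        noise_sd_a = 0.05, noise_sd_b = 0.05,
                        noise_sd_diploid = 0.03, noise_sd_normal = 0.02,
                        effect = 0.4, b_effect = 0.4,
                        passenger_effect = 0.3,
                        strength_range = c(0.8, 1.2),
                        phenotype_alpha = 1, phenotype_sigma = 0.5,
                        label_slope = 6, label_intercept = -3,
                        growth_passages = 8L, growth_rate = 3,
                        growth_coupling = 30, growth_noise = 0.2,
                        n_decoy_sets = 50L, mixed_fraction = 0) {
  spec <- as.list(environment())
  stopifnot(spec$n_sig_a >= 1L, spec$n_normal >= 2L,
            all(unlist(spec[grep("rate|noise|effect", names(spec))]) >= 0))
  structure(spec, class = "cohort_spec")
}

#' Build the synthetic genome bundle
#'
#' Tiles genes with jittered spacing on the spec's chromosomes, plants the
#' driver intervals (three "glycolysis-like" amplification regions on
#' chr1-chr3, the signature-B alternate amplification locus on chr4 and
#' deletion locus on chr5), inserts one cluster of three same-EC isoenzyme
#' genes within 100 kb (for collapsing tests), and draws decoy gene sets of
#' matched size.
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @return list with `assembly`, `genes` ([gene_model]), `gene_sets` (named
#'   list; first set `GLYCO_LIKE`), `planted` (list of interval
#'   data.frames: `glyco`, `b_amp`, `b_del`), `ec_cluster` (gene ids).
#' @export
make_genome <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  assembly <- genome_assembly(
    "synthA", data.frame(chrom = chroms, length = spec$chrom_length)
  )
  genes <- with_seed(child_seed(seed, 1), {
    do.call(rbind, lapply(chroms, function(ch) {
      n <- floor(spec$chrom_length / spec$gene_spacing)
      starts <- (seq_len(n) - 1L) * spec$gene_spacing +
        round(stats::runif(n, 0, spec$spacing_jitter * spec$gene_spacing))
      ends <- pmin(starts + spec$gene_length, spec$chrom_length)
      data.frame(gene_id = sprintf("%s_g%04d", ch, seq_len(n)),
                 chrom = ch, start = starts, end = ends,
                 ec = NA_character_)
    }))
  })
  ## isoenzyme cluster: three same-EC genes, consecutive gaps < 100 kb
  ecc <- data.frame(
    gene_id = paste0("chr1_ec", 1:3), chrom = "chr1",
    start = 0.8 * spec$chrom_length + c(0, 4e4, 8e4),
    end = 0.8 * spec$chrom_length + c(0, 4e4, 8e4) + 2e4,
    ec = "2.7.1.1"
  )
  genes <- rbind(genes, ecc)
  stopifnot(spec$n_chromosomes >= 5L)
  L <- spec$chrom_length  # planted intervals scale with the genome
  planted <- list(
    glyco = data.frame(chrom = c("chr1", "chr2", "chr3"),
                       start = c(0.20, 0.50, 0.70) * L,
                       end = c(0.24, 0.54, 0.74) * L),
    b_amp = data.frame(chrom = "chr4", start = 0.300 * L, end = 0.325 * L),
    b_del = data.frame(chrom = "chr5", start = 0.600 * L, end = 0.625 * L),
    ## species-specific recurrent passengers: co-amplified in signature-A
    ## tumors of every same-species cohort, absent in a second species,
    ## so cross-species restriction has non-driver consistency to prune
    shared = data.frame(chrom = c("chr2", "chr4", "chr5"),
                        start = c(0.10, 0.60, 0.20) * L,
                        end = c(0.13, 0.63, 0.23) * L)
  )
  gm <- gene_model(genes, assembly)
  glyco_genes <- genes_in_intervals(gm, planted$glyco)
  ## distinct EC codes for the driver set (metabolic enzymes, no clustering)
  gm$ec[match(glyco_genes, gm$gene_id)] <-
    sprintf("1.1.1.%d", seq_along(glyco_genes))
  decoys <- with_seed(child_seed(seed, 2), {
    pool <- gm$gene_id
    sets <- lapply(seq_len(spec$n_decoy_sets), function(i) {
      sort(sample(pool, length(glyco_genes)))
    })
    names(sets) <- sprintf("DECOY_%02d", seq_len(spec$n_decoy_sets))
    sets
  })
  gene_sets <- c(list(GLYCO_LIKE = glyco_genes), decoys)
  list(assembly = assembly, genes = gm, gene_sets = gene_sets,
       planted = planted, ec_cluster = ecc$gene_id)
}

## gene ids whose body overlaps any of the given intervals
genes_in_intervals <- function(genes, intervals) {
  hit <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (genes$chrom == intervals$chrom[i] &
                    genes$start < intervals$end[i] &
                    genes$end > intervals$start[i])
  }
  genes$gene_id[hit]
}

#' Simulate a cohort of segmented CNA profiles
#'
#' Per sample, breakpoints are placed by a Poisson process at the class
#' rate, segment means are drawn around 0 at the class noise level (rounded
#' to four decimals, emulating level-3-style rounding), and the planted
#' events are overlaid: signature-A samples gain `effect * strength` on the
#' driver regions; signature-B samples gain the alternate amplification or
#' lose the deletion locus (mutually exclusive); near-diploid tumors and
#' normals carry no planted event.
#'
#' @param genome bundle from [make_genome] (or [simulate_mouse_cohort]).
#' @param spec a [cohort_spec].
#' @param seed integer seed.
#' @param cohort cohort label used as a sample-id prefix.
#' @return list with `profiles` ([cna_profiles]) and `truth` (data.frame
#'   `sample_id`, `class`, `strength`, `b_event`).
#' @export
simulate_cohort <- function(genome, spec = cohort_spec(), seed = 1,
                            cohort = "C1") {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- c(rep("sig_a", spec$n_sig_a), rep("sig_b", spec$n_sig_b),
               rep("diploid", spec$n_diploid), rep("normal", spec$n_normal))
  ids <- sprintf("%s_%s%02d", cohort,
                 c("A", "B", "D", "N")[match(classes, c("sig_a", "sig_b",
                                                        "diploid", "normal"))],
                 unlist(lapply(table(factor(classes, unique(classes))),
                               seq_len)))
  rate <- c(sig_a = spec$bp_rate_a, sig_b = spec$bp_rate_b,
            diploid = spec$bp_rate_diploid, normal = spec$bp_rate_normal)
  noise <- c(sig_a = spec$noise_sd_a, sig_b = spec$noise_sd_b,
             diploid = spec$noise_sd_diploid, normal = spec$noise_sd_normal)
  chroms <- genome$assembly$chromosomes
  res <- with_seed(child_seed(seed, 3), {
    seg_list <- vector("list", length(ids))
    strength <- numeric(length(ids))
    b_event <- rep(NA_character_, length(ids))
    for (i in seq_along(ids)) {
      cls <- classes[i]
      segs <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(ci) {
        len <- chroms$length[ci]
        k <- stats::rpois(1L, rate[[cls]] * len / 1e6)
        cuts <- sort(unique(round(stats::runif(k, 1, len - 1))))
        bounds <- c(0, cuts, len)
        data.frame(chrom = chroms$chrom[ci], start = bounds[-length(bounds)],
                   end = bounds[-1L],
                   mean = stats::rnorm(length(bounds) - 1L, 0, noise[[cls]]))
      }))
      mixed <- spec$mixed_fraction > 0 && cls %in% c("sig_a", "sig_b") &&
        stats::runif(1L) < spec$mixed_fraction
      if (cls == "sig_a" || (mixed && cls == "sig_b")) {
        s <- stats::runif(1L, spec$strength_range[1L], spec$strength_range[2L])
        strength[i] <- if (cls == "sig_a") s else strength[i]
        for (j in seq_len(nrow(genome$planted$glyco))) {
          segs <- overlay_interval(segs, genome$planted$glyco[j, ],
                                   spec$effect * s)
        }
        shared <- genome$planted$shared
        for (j in seq_len(NROW(shared))) {
          segs <- overlay_interval(segs, shared[j, ],
                                   spec$passenger_effect * s)
        }
      }
      if (cls == "sig_b" || (mixed && cls == "sig_a")) {
        s <- stats::runif(1L, spec$strength_range[1L], spec$strength_range[2L])
        amp <- stats::runif(1L) < 0.5
        if (cls == "sig_b") b_event[i] <- if (amp) "amp" else "del"
        if (amp) {
          segs <- overlay_interval(segs, genome$planted$b_amp,
                                   spec$b_effect * s)
        } else {
          segs <- overlay_interval(segs, genome$planted$b_del,
                                   -spec$b_effect * s)
        }
      }
      segs$mean <- round(segs$mean, 4L)
      segs$sample_id <- ids[i]
      seg_list[[i]] <- segs
    }
    list(segs = do.call(rbind, seg_list), strength = strength,
         b_event = b_event)
  })
  profiles <- cna_profiles(res$segs, genome$assembly)
  truth <- data.frame(sample_id = ids, class = classes,
                      strength = res$strength, b_event = res$b_event)
  list(profiles = profiles, truth = truth)
}

## Split segments at an interval's boundaries and shift the means inside.
overlay_interval <- function(segs, interval, delta) {
  ch <- interval$chrom[1L]; s <- interval$start[1L]; e <- interval$end[1L]
  hit <- which(segs$chrom == ch & segs$start < e & segs$end > s)
  if (!length(hit)) return(segs)
  pieces <- lapply(hit, function(i) {
    row <- segs[i, ]
    out <- list()
    if (row$start < s) {
      left <- row; left$end <- s
      out[[length(out) + 1L]] <- left
    }
    mid <- row
    mid$start <- max(row$start, s); mid$end <- min(row$end, e)
    mid$mean <- mid$mean + delta
    out[[length(out) + 1L]] <- mid
    if (row$end > e) {
      right <- row; right$start <- e
      out[[length(out) + 1L]] <- right
    }
    do.call(rbind, out)
  })
  rbind(segs[-hit, , drop = FALSE], do.call(rbind, pieces))
}

#' Simulate phenotypes coupled to signature strength
#'
#' The glycolytic phenotype is `alpha * z + N(0, sigma)` where `z` is the
#' cohort-standardized planted signature strength (so `alpha/sigma` is a
#' signal-to-noise ratio and the population correlation is
#' `alpha / sqrt(alpha^2 + sigma^2)`). A second, more weakly coupled
#' "growth" phenotype is emitted alongside.
#'
#' @param truth truth table from [simulate_cohort].
#' @param alpha,sigma coupling and noise (defaults from the spec).
#' @param seed integer seed.
#' @param spec optional [cohort_spec] supplying defaults.
#' @return data.frame `sample_id`, `phenotype_name`, `value` (long format).
#' @export
simulate_phenotypes <- function(truth, alpha = NULL, sigma = NULL, seed = 1,
                                spec = cohort_spec()) {
  alpha <- alpha %||% spec$phenotype_alpha
  sigma <- sigma %||% spec$phenotype_sigma
  z <- truth$strength
  z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
  with_seed(child_seed(seed, 4), {
    glyc <- alpha * z + stats::rnorm(length(z), 0, sigma)
    grow <- 0.5 * alpha * z + stats::rnorm(length(z), 0, sigma)
    rbind(
      data.frame(sample_id = truth$sample_id, phenotype_name = "glycolysis",
                 value = glyc),
      data.frame(sample_id = truth$sample_id, phenotype_name = "growth",
                 value = grow)
    )
  })
}

#' Simulate binary mutation-like labels
#'
#' Label probability is `plogis(intercept + slope * strength)`: with the
#' default intercept the background mutation rate is about 5% while
#' strongly signature-A samples are almost always labelled.
#'
#' @param truth truth table from [simulate_cohort].
#' @param slope,intercept logistic coefficients (defaults from the spec).
#' @param seed integer seed.
#' @param spec optional [cohort_spec] supplying defaults.
#' @return data.frame `sample_id`, `label` (logical).
#' @export
simulate_labels <- function(truth, slope = NULL, intercept = NULL, seed = 1,
                            spec = cohort_spec()) {
  slope <- slope %||% spec$label_slope
  intercept <- intercept %||% spec$label_intercept
  p <- stats::plogis(intercept + slope * truth$strength)
  with_seed(child_seed(seed, 5), {
    data.frame(sample_id = truth$sample_id,
               label = stats::runif(nrow(truth)) < p)
  })
}

#' Simulate dip-then-recover growth curves
#'
#' Cumulative log2 growth over `passages` passages: increments run at the
#' ideal rate minus a senescence dip whose depth scales with the sample's
#' integrated CNA (deeply rearranged genomes senesce hardest before
#' recovering), plus noise. Protected samples (the normals) stay flat-rated.
#'
#' @param int_cna named per-sample integrated CNA scores.
#' @param coupling dip depth per unit integrated CNA (log2 units).
#' @param seed integer seed.
#' @param passages,rate,noise curve shape (defaults from the spec).
#' @param protected sample ids whose dip is forced to 0.
#' @param spec optional [cohort_spec] supplying defaults.
#' @return data.frame `sample_id`, `passage`, `log2_cumulative_growth`.
#' @export
simulate_growth_curves <- function(int_cna, coupling = NULL, seed = 1,
                                   passages = NULL, rate = NULL,
                                   noise = NULL, protected = character(0),
                                   spec = cohort_spec()) {
  coupling <- coupling %||% spec$growth_coupling
  passages <- passages %||% spec$growth_passages
  rate <- rate %||% spec$growth_rate
  noise <- noise %||% spec$growth_noise
  ## bell-shaped dip profile over passages, peaking mid-derivation
  w <- stats::dnorm(seq_len(passages), mean = (passages + 1) / 2,
                    sd = passages / 5)
  w <- w / sum(w)
  with_seed(child_seed(seed, 6), {
    do.call(rbind, lapply(names(int_cna), function(id) {
      dip <- if (id %in% protected) 0 else coupling * int_cna[[id]]
      inc <- rate - dip * w * passages +
        stats::rnorm(passages, 0, noise)
      data.frame(sample_id = id, passage = 0:passages,
                 log2_cumulative_growth = c(0, cumsum(inc)))
    }))
  })
}

#' Simulate a synteny-shuffled second species
#'
#' The second ("mouse-like") genome is a block-shuffled image of the first:
#' the human genome is cut into fixed-size blocks which are permuted and
#' re-laid onto a new chromosome set, carrying the genes with them. The
#' ortholog map is the induced one-to-one pairing minus a dropout fraction.
#' Planted driver intervals map through the shuffle, so driver
#' amplifications recur at orthologous genes while passenger events are
#' drawn independently on the new genome — broken synteny then prunes
#' passenger consistency without touching the drivers.
#'
#' @param genome human bundle from [make_genome].
#' @param spec a [cohort_spec] (class structure and rates are reused).
#' @param seed integer seed.
#' @param block_size shuffled block size in base pairs.
#' @param n_chromosomes_target chromosome count of the second genome.
#' @param dropout fraction of gene pairs removed from the ortholog map.
#' @param cohort sample-id prefix.
#' @return list with `genome` (second-species bundle: `assembly`, `genes`,
#'   `planted`), `ortholog_map` (data.frame `gene_a` human, `gene_b`
#'   mouse), `profiles`, `truth`.
#' @export
simulate_mouse_cohort <- function(genome, spec = cohort_spec(), seed = 1,
                                  block_size = 1e7,
                                  n_chromosomes_target = 4L, dropout = 0.1,
                                  cohort = "MM") {
  chroms <- genome$assembly$chromosomes
  blocks <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(ci) {
    n <- ceiling(chroms$length[ci] / block_size)
    starts <- (seq_len(n) - 1L) * block_size
    data.frame(chrom = chroms$chrom[ci], start = starts,
               end = pmin(starts + block_size, chroms$length[ci]))
  }))
  nb <- nrow(blocks)
  perm <- with_seed(child_seed(seed, 7), sample.int(nb))
  ## deal permuted blocks onto target chromosomes as evenly as possible
  per_chr <- rep(nb %/% n_chromosomes_target, n_chromosomes_target)
  extra <- nb %% n_chromosomes_target
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1L
  tchrom <- rep(paste0("mchr", seq_len(n_chromosomes_target)), per_chr)
  blocks$new_chrom <- NA_character_
  blocks$new_start <- NA_real_
  offset <- stats::setNames(rep(0, n_chromosomes_target),
                            paste0("mchr", seq_len(n_chromosomes_target)))
  for (j in seq_len(nb)) {
    b <- perm[j]
    blocks$new_chrom[b] <- tchrom[j]
    blocks$new_start[b] <- offset[[tchrom[j]]]
    offset[tchrom[j]] <- offset[[tchrom[j]]] +
      (blocks$end[b] - blocks$start[b])
  }
  m_assembly <- genome_assembly("synthB", data.frame(
    chrom = names(offset), length = as.double(offset)
  ))
  map_point <- function(chrom, pos) {
    ## map human coordinates through the block shuffle (vectorized)
    bi <- match(paste(chrom, floor(pos / block_size)),
                paste(blocks$chrom, floor(blocks$start / block_size)))
    list(chrom = blocks$new_chrom[bi],
         pos = blocks$new_start[bi] + (pos - blocks$start[bi]))
  }
  hg <- genome$genes
  mp <- map_point(hg$chrom, hg$start)
  block_end <- blocks$new_start[match(
    paste(hg$chrom, floor(hg$start / block_size)),
    paste(blocks$chrom, floor(blocks$start / block_size))
  )] + (blocks$end - blocks$start)[match(
    paste(hg$chrom, floor(hg$start / block_size)),
    paste(blocks$chrom, floor(blocks$start / block_size))
  )]
  m_genes <- data.frame(
    gene_id = paste0("m_", hg$gene_id), chrom = mp$chrom,
    start = mp$pos,
    end = pmin(mp$pos + (hg$end - hg$start), block_end),
    ec = hg$ec
  )
  m_gm <- gene_model(m_genes, m_assembly)
  ## planted intervals mapped blockwise
  map_intervals <- function(iv) {
    do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
      hit <- blocks[blocks$chrom == iv$chrom[i] &
                      blocks$start < iv$end[i] &
                      blocks$end > iv$start[i], ]
      do.call(rbind, lapply(seq_len(nrow(hit)), function(j) {
        s <- max(iv$start[i], hit$start[j]); e <- min(iv$end[i], hit$end[j])
        data.frame(chrom = hit$new_chrom[j],
                   start = hit$new_start[j] + (s - hit$start[j]),
                   end = hit$new_start[j] + (e - hit$start[j]))
      }))
    }))
  }
  m_planted <- lapply(genome$planted, map_intervals)
  ## recurrent passengers are species-specific: none planted in species B
  m_planted$shared <- genome$planted$shared[0, ]
  keep <- with_seed(child_seed(seed, 8), {
    stats::runif(nrow(hg)) >= dropout
  })
  ortholog_map <- data.frame(gene_a = hg$gene_id[keep],
                             gene_b = paste0("m_", hg$gene_id[keep]))
  m_genome <- list(assembly = m_assembly, genes = m_gm,
                   gene_sets = lapply(genome$gene_sets,
                                      function(s) paste0("m_", s)),
                   planted = m_planted, ec_cluster = paste0("m_", genome$ec_cluster))
  sim <- simulate_cohort(m_genome, spec, seed = child_seed(seed, 9),
                         cohort = cohort)
  list(genome = m_genome, ortholog_map = ortholog_map,
       profiles = sim$profiles, truth = sim$truth)
}

#' Write phenotype / label tables
#'
#' Phenotypes: `sample_id<TAB>phenotype_name<TAB>value`; labels:
#' `sample_id<TAB>label`.
#' @param x data.frame from [simulate_phenotypes] or [simulate_labels].
#' @param path output path.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' @rdname read_ortholog_map
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
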