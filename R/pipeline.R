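#' Default pipeline configuration
#'
#' A plain list mirroring every stage default; serialize with
#' [yaml::write_yaml] and reload with [read_run_config]. Any entry can be
#' overridden.
#'
#' @param seed master seed; every stage derives child seeds from it.
#' @param n_cohorts number of same-species cohorts to simulate.
#' @param ... overrides for individual entries.
#' @return named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_cohorts = 4L, ...) {
  cfg <- list(
    seed = seed, n_cohorts = n_cohorts, with_second_species = TRUE,
    samcs_threshold = 0.05, min_span = 1e6, merge_gap = 1e6,
    top_frac = 0.10, n_perm = 1000, min_set_size = 7L,
    isoenzyme_window = 1e5, dropout = 0.1, block_size = 1e7,
    window_width = 0.1, window_min_n = 10L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Stages: simulate (genome, cohorts, second species, phenotypes, labels,
#' growth curves — all written as SEG/BED/GMT/TSV), per-cohort matrices and
#' PCA, summary signatures, pan-cancer cohort ordering, sequential
#' consistency with conserved-region calling, gene-set enrichment over the
#' final consistency signature, weighted-gene-voting phenotype prediction,
#' and per-sample scores. Every output file is listed with its MD5 hash in
#' `manifest.json`; re-running with the same config reproduces the hashes
#' byte-for-byte.
#'
#' @param config a [run_config] (or YAML path).
#' @param out_dir output directory (created).
#' @param spec optional [cohort_spec] overriding the generator defaults.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`signatures`,
#'   `sequential`, `enrichment`, `prediction`, `scores`, `manifest`, ...).
#' @export
run_pipeline <- function(config = run_config(), out_dir, spec = cohort_spec(),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  path <- function(...) file.path(out_dir, ...)
  yaml::write_yaml(unclass(config), path("config.yaml"))

  ## --- simulate ------------------------------------------------------
  say("simulate: genome + ", config$n_cohorts, " cohorts")
  genome <- make_genome(spec, seed = seed)
  write_chrom_lengths(genome$assembly, path("assembly.tsv"))
  write_gene_model(genome$genes, path("genes.bed"))
  ec <- genome$genes[!is.na(genome$genes$ec), c("gene_id", "ec")]
  write_ec_table(ec, path("ec.tsv"))
  write_gmt(genome$gene_sets, path("gene_sets.gmt"))
  cohort_names <- paste0("C", seq_len(config$n_cohorts))
  sims <- lapply(seq_len(config$n_cohorts), function(i) {
    simulate_cohort(genome, spec, seed = child_seed(seed, 10 + i),
                    cohort = cohort_names[i])
  })
  names(sims) <- cohort_names
  for (nm in cohort_names) {
    write_seg(sims[[nm]]$profiles, path(paste0(nm, ".seg")))
  }
  mouse <- NULL
  if (isTRUE(config$with_second_species)) {
    mouse <- simulate_mouse_cohort(genome, spec, seed = child_seed(seed, 20),
                                   block_size = config$block_size,
                                   dropout = config$dropout)
    write_seg(mouse$profiles, path("MM.seg"))
    write_gene_model(mouse$genome$genes, path("genes_mm.bed"))
    write_ortholog_map(mouse$ortholog_map, path("orthologs.tsv"))
  }
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  phen <- simulate_phenotypes(truth, seed = child_seed(seed, 30), spec = spec)
  write_phenotypes(phen, path("phenotypes.tsv"))
  labels <- simulate_labels(truth, seed = child_seed(seed, 31), spec = spec)
  utils::write.table(labels, path("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- matrices, PCA, signatures ------------------------------------
  say("signatures: per-cohort PCA + summary signatures")
  mats <- lapply(sims, function(s) {
    segments_to_gene_matrix(s$profiles, genome$genes)
  })
  intc <- lapply(sims, function(s) integrated_cna(s$profiles))
  ## orientation/selection metric: breakpoint totals (the operational
  ## discriminator of the dense-breakpoint signature-A pattern)
  bpt <- lapply(sims, function(s) count_breakpoints(s$profiles)$total)
  pcas <- lapply(cohort_names, function(nm) {
    run_pca(mats[[nm]], orientation_metric = bpt[[nm]])
  })
  names(pcas) <- cohort_names
  comps <- vapply(pcas, signature_component, integer(1))
  sigs <- lapply(cohort_names, function(nm) {
    normals <- sims[[nm]]$truth$sample_id[sims[[nm]]$truth$class == "normal"]
    core_signature(mats[[nm]], pcas[[nm]]$scores[, comps[[nm]]], normals,
                   top_frac = config$top_frac, cohort = nm)
  })
  names(sigs) <- cohort_names
  for (nm in cohort_names) {
    write_signature(sigs[[nm]], path(paste0("signature_", nm, ".tsv")))
  }

  ## pan-cancer ordering: balanced pooled PCA across cohorts
  tumor_ids <- truth$sample_id[truth$class != "normal"]
  pool_ids <- balanced_sample(
    stats::setNames(sub("_.*", "", tumor_ids), tumor_ids),
    seed = child_seed(seed, 40)
  )
  pooled <- mats[[1L]]
  pooled$values <- do.call(cbind, lapply(mats, function(m) m$values))
  pooled$values <- pooled$values[, pool_ids, drop = FALSE]
  pan <- run_pca(pooled, orientation_metric = unlist(unname(bpt))[pool_ids])
  cohort_order <- order_cohorts_by_pc1(
    pan$scores[, 1L], stats::setNames(sub("_.*", "", pool_ids), pool_ids)
  )
  ordered_sigs <- sigs[cohort_order]

  ## --- consistency ---------------------------------------------------
  say("consistency: sequential cohort addition")
  if (!is.null(mouse)) {
    m_normals <- mouse$truth$sample_id[mouse$truth$class == "normal"]
    m_mat <- segments_to_gene_matrix(mouse$profiles, mouse$genome$genes)
    m_pca <- run_pca(m_mat,
                     orientation_metric = count_breakpoints(mouse$profiles)$total)
    m_comp <- signature_component(m_pca)
    m_sig <- core_signature(m_mat, m_pca$scores[, m_comp], m_normals,
                            top_frac = config$top_frac, cohort = "MM")
    m_mapped <- map_across_species(m_sig, mouse$ortholog_map, genome$genes,
                                   direction = "b_to_a")
    attr(m_mapped, "cohort") <- "MM"
    ordered_sigs <- c(ordered_sigs, list(MM = m_mapped))
  }
  seqc <- sequential_consistency(ordered_sigs, genome$genes, genome$assembly,
                                 threshold = config$samcs_threshold,
                                 min_span = config$min_span,
                                 merge_gap = config$merge_gap)
  utils::write.table(seqc$steps, path("sequential.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  final_cons <- seqc$consistency[[length(seqc$consistency)]]
  final_regions <- seqc$regions[[length(seqc$regions)]]
  write_regions_bed(final_regions, path("regions.bed"))

  ## --- enrichment ----------------------------------------------------
  say("enrichment: permutation GSEA over the consistency signature")
  coll <- collapse_isoenzymes(final_cons, genome$genes,
                              window = config$isoenzyme_window)
  enr <- cna_gsea(coll$signature, genome$gene_sets, n_perm = config$n_perm,
                  seed = child_seed(seed, 50),
                  min_size = config$min_set_size)
  write_enrichment(enr, path("enrichment.tsv"))

  ## --- prediction ----------------------------------------------------
  say("prediction: weighted gene voting")
  glyco <- genome$gene_sets$GLYCO_LIKE
  models <- lapply(cohort_names, function(nm) {
    tr <- sims[[nm]]$truth
    normals <- tr$sample_id[tr$class == "normal"]
    tumors <- tr$sample_id[tr$class != "normal"]
    sc <- pcas[[nm]]$scores[tumors, comps[[nm]]]
    d <- ceiling(config$top_frac * length(tumors))
    top <- tumors[order_by_score_desc(sc, tumors)][seq_len(d)]
    train_wgv(mats[[nm]], top, normals, glyco, cohort = nm)
  })
  test_cohort <- cohort_names[1L]
  test_tumors <- sims[[test_cohort]]$truth$sample_id[
    sims[[test_cohort]]$truth$class != "normal"]
  votes <- predict_wgv(models, mats[[test_cohort]])[test_tumors]
  ph <- phen[phen$phenotype_name == "glycolysis", ]
  target <- ph$value[match(test_tumors, ph$sample_id)]
  eval <- evaluate_prediction(votes, target, n_perm = config$n_perm,
                              seed = child_seed(seed, 60))
  wind <- windowed_correlation_test(
    votes, pcas[[test_cohort]]$scores[test_tumors, comps[[test_cohort]]],
    intc[[test_cohort]][test_tumors],
    window_width = config$window_width, min_n = config$window_min_n,
    n_perm = config$n_perm, seed = child_seed(seed, 61)
  )
  jsonlite::write_json(
    list(pearson_r = eval$r, permutation_p = eval$p, n = eval$n,
         windowed_max_rho = wind$max_rho, windowed_p = wind$p),
    path("prediction.json"), auto_unbox = TRUE, digits = NA
  )

  ## --- per-sample scores --------------------------------------------
  say("scores: instability and senescence metrics")
  all_int <- unlist(unname(intc))
  bps <- lapply(sims, function(s) count_breakpoints(s$profiles))
  curves <- simulate_growth_curves(
    all_int, seed = child_seed(seed, 70),
    protected = truth$sample_id[truth$class == "normal"], spec = spec
  )
  write_growth_curves(curves, path("growth_curves.tsv"))
  sen <- senescence_scores(curves)
  score_tab <- data.frame(
    sample_id = names(all_int), integrated_cna = unname(all_int),
    breakpoints = unname(unlist(unname(lapply(bps, `[[`, "total")))[
      names(all_int)]),
    senescence = unname(sen[names(all_int)])
  )
  utils::write.table(score_tab, path("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- genome_view_report(final_cons, final_regions,
                               annotations = data.frame(
                                 gene_id = glyco, name = glyco))
  utils::write.table(report$track, path("genome_view.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- write_manifest(out_dir)
  invisible(list(genome = genome, sims = sims, mouse = mouse,
                 matrices = mats, pcas = pcas, signatures = sigs,
                 cohort_order = cohort_order, sequential = seqc,
                 enrichment = enr, models = models,
                 prediction = list(eval = eval, windowed = wind),
                 scores = score_tab, truth = truth, manifest = manifest))
}

#' Per-gene genome view of a consistency signature
#'
#' Tabulates the SAMCS track in genome order together with the region each
#' gene falls in (if any) and optional gene annotations; optionally draws a
#' base-graphics track plot.
#'
#' @param consistency a `consistency_signature`.
#' @param regions a `consistent_regions` data.frame.
#' @param annotations optional data.frame with `gene_id` and `name`.
#' @param plot_file optional PNG path for a static track plot.
#' @return list with `track` (data.frame) and `regions`.
#' @export
genome_view_report <- function(consistency, regions,
                               annotations = NULL, plot_file = NULL) {
  genes <- attr(consistency, "genes")
  stopifnot(inherits(genes, "gene_model"))
  idx <- match(consistency$gene_id, genes$gene_id)
  track <- data.frame(gene_id = consistency$gene_id,
                      chrom = genes$chrom[idx], start = genes$start[idx],
                      end = genes$end[idx], samcs = consistency$samcs)
  asm <- attr(genes, "assembly")
  track <- track[order(match(track$chrom, asm$chromosomes$chrom),
                       track$start), ]
  track$region <- NA_character_
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      hit <- track$chrom == regions$chrom[i] &
        track$start < regions$end[i] & track$end > regions$start[i]
      track$region[hit] <- sprintf("%s:%s-%s:%s", regions$chrom[i],
                                   format_bp(regions$start[i]),
                                   format_bp(regions$end[i]),
                                   regions$direction[i])
    }
  }
  if (!is.null(annotations)) {
    track$name <- annotations$name[match(track$gene_id, annotations$gene_id)]
  }
  rownames(track) <- NULL
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
    offs <- c(0, cumsum(asm$chromosomes$length))[
      match(track$chrom, asm$chromosomes$chrom)]
    x <- offs + (track$start + track$end) / 2
    graphics::plot(x, track$samcs, type = "h",
                   col = ifelse(is.na(track$region), "grey60",
                                ifelse(track$samcs > 0, "firebrick",
                                       "steelblue")),
                   xlab = "genome position", ylab = "SAMCS")
    graphics::abline(v = cumsum(asm$chromosomes$length), lty = 3)
  }
  list(track = track, regions = regions)
}

#' Write a manifest of an output directory
#'
#' Lists every file (relative path, size, MD5 hash); deterministic stages
#' reproduce hashes exactly under a fixed config.
#'
#' @param out_dir directory to index.
#' @return the manifest data.frame, invisibly; written to
#'   `manifest.json` inside `out_dir`.
#' @export
write_manifest <- function(out_dir) {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- data.frame(
    file = files,
    bytes = file.size(file.path(out_dir, files)),
    md5 = unname(tools::md5sum(file.path(out_dir, files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
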