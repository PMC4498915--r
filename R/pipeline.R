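# End-to-end workspace pipeline: simulate -> dge -> peaks -> motifs ->
# integrate -> report, with every intermediate written as versioned
# plain-text tables so stages can be inspected or rerun.

#' Run the full synthetic-workspace pipeline
#'
#' Chains every stage on one workspace directory: simulates the genome,
#' ChIP coverage, counts, developmental profiles and cilia evidence from the
#' configuration's master seed; writes them in standard formats (GFF3,
#' FASTA, bedGraph, TSV, JSON); reads them back; runs differential
#' expression, peak calling with reproducibility filtering, promoter
#' annotation, de novo motif discovery in peak sequences, promoter X-box
#' scanning and enrichment; and integrates everything into per-gene target
#' calls, a master report table and a summary JSON (including precision and
#' recall of the direct-target set against the planted regulon). All outputs
#' are deterministic functions of the configuration, so identical configs
#' produce byte-identical workspaces.
#'
#' @param workspace Directory to create/populate.
#' @param config A [sim_config()].
#' @param thresholds A [dge_thresholds()].
#' @param criteria A [profile_criteria()].
#' @param peak_p BH-adjusted bin significance cutoff for peak calling.
#' @param min_overlap_frac Reciprocal-overlap fraction for reproducibility.
#' @param em_max_sequences Cap on peak sequences used for motif discovery.
#' @param expressed_floor Mean normalized count defining the expressed-gene
#'   universe for enrichment tests.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every stage result (`sim`, `dge`, `sets`,
#'   `de_summary`, `peaks`, `annotated_peaks`, `peak_summary`, `targets`,
#'   `motif`, `xbox_hits`, `enrichment`, `profiles`, `calls`, `report`).
#' @export
run_pipeline <- function(workspace,
                         config = sim_config(),
                         thresholds = dge_thresholds(),
                         criteria = profile_criteria(),
                         peak_p = 0.01,
                         min_overlap_frac = 0.5,
                         em_max_sequences = 60,
                         expressed_floor = 1,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  ind <- file.path(workspace, "inputs")
  outd <- file.path(workspace, "results")
  dir.create(ind, recursive = TRUE, showWarnings = FALSE)
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)

  ## stage: simulate ---------------------------------------------------------
  say("simulate: genome, coverage, counts, profiles, evidence (seed ",
      config$seed, ")")
  sim <- simulate_genome(config)
  cov <- simulate_chip_coverage(sim$annotation, sim$regulon, config)
  cnt <- simulate_counts(sim$annotation, sim$regulon, config)
  prof <- simulate_dev_profiles(sim$annotation, sim$regulon, config)
  cil <- simulate_cilia_evidence(sim$annotation, sim$regulon, config)

  write_annotation(sim$annotation, file.path(ind, "annotation.gff3"))
  Biostrings::writeXStringSet(sim$genome, file.path(ind, "genome.fa"))
  write_bedgraph(cov$input, file.path(ind, "chip_input.bedgraph"))
  for (r in seq_along(cov$ip)) {
    write_bedgraph(cov$ip[[r]], file.path(ind, sprintf("chip_ip_rep%d.bedgraph", r)))
  }
  write_counts(cnt$counts, cnt$samples, file.path(ind, "counts.tsv"),
               file.path(ind, "samples.tsv"))
  write_table_tsv(prof, file.path(ind, "dev_profiles.tsv"))
  write_table_tsv(cil, file.path(ind, "cilia_evidence.tsv"))
  write_regulon(sim$regulon, file.path(ind, "regulon_truth.json"))
  cfg_out <- unclass(config)
  cfg_out$chrom_lengths <- as.list(cfg_out$chrom_lengths)
  jsonlite::write_json(cfg_out, file.path(ind, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## read inputs back (io round trip is part of the pipeline contract)
  annotation <- read_annotation(file.path(ind, "annotation.gff3"))
  genome <- Biostrings::readDNAStringSet(file.path(ind, "genome.fa"))
  names(genome) <- sub(" .*", "", names(genome))
  cc <- read_counts(file.path(ind, "counts.tsv"), file.path(ind, "samples.tsv"))
  input_trk <- read_bedgraph(file.path(ind, "chip_input.bedgraph"))
  ip_trks <- lapply(seq_along(cov$ip), function(r) {
    read_bedgraph(file.path(ind, sprintf("chip_ip_rep%d.bedgraph", r)))
  })
  profiles <- read_table_tsv(file.path(ind, "dev_profiles.tsv"))
  cilia <- read_table_tsv(file.path(ind, "cilia_evidence.tsv"))

  ## stage: dge --------------------------------------------------------------
  say("dge: exact tests at ", paste(unique(cc$samples$age), collapse = "/"))
  exon_len <- annotation$exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start), .groups = "drop")
  gene_lengths <- stats::setNames(exon_len$len, exon_len$gene_id)
  dge <- run_dge(cc$counts, cc$samples, thresholds, gene_lengths)
  sets <- call_de_sets(dge)
  dsum <- de_summary(dge, sets)
  for (age in unique(dge$table$age)) {
    write_table_tsv(dge$table[dge$table$age == age, ],
                    file.path(outd, sprintf("dge_%s.tsv", age)))
  }
  write_table_tsv(sets, file.path(outd, "de_sets.tsv"))
  write_table_tsv(dsum$curves, file.path(outd, "de_curves.tsv"))
  if (!is.null(dsum$venn)) write_table_tsv(dsum$venn,
                                           file.path(outd, "de_venn.tsv"))
  write_table_tsv(dsum$scatter, file.path(outd, "de_scatter.tsv"))
  write_table_tsv(dsum$ma, file.path(outd, "de_ma.tsv"))

  ## stage: peaks ------------------------------------------------------------
  say("peaks: ", length(ip_trks), " replicates")
  rep_peaks <- lapply(ip_trks, call_peaks, input = input_trk,
                      p_threshold = peak_p)
  for (r in seq_along(rep_peaks)) {
    write_narrowpeak(rep_peaks[[r]],
                     file.path(outd, sprintf("peaks_rep%d.narrowPeak", r)))
  }
  peaks <- if (length(rep_peaks) >= 2) {
    filter_reproducible(rep_peaks, min_overlap_frac)
  } else rep_peaks[[1]]
  write_narrowpeak(peaks, file.path(outd, "peaks_reproducible.narrowPeak"))
  ann_peaks <- annotate_peaks(peaks, annotation, config$promoter_window)
  write_table_tsv(ann_peaks, file.path(outd, "peak_annotation.tsv"))
  psum <- peak_summary(ann_peaks)
  write_table_tsv(psum$class_counts, file.path(outd, "peak_class_counts.tsv"))
  write_table_tsv(psum$rank_curve, file.path(outd, "peak_rank_curve.tsv"))
  write_table_tsv(psum$tss_histogram, file.path(outd, "peak_tss_histogram.tsv"))
  targets <- promoter_target_genes(ann_peaks)
  write_table_tsv(targets, file.path(outd, "chip_targets.tsv"))

  ## stage: motifs -----------------------------------------------------------
  say("motifs: discovery in ", min(nrow(peaks), em_max_sequences),
      " peak sequences, promoter scan")
  motif <- NULL
  width <- nchar(config$motif_consensus)
  if (nrow(peaks) >= 10) {
    top <- dplyr::arrange(peaks, .data$p_value) |>
      utils::head(em_max_sequences)
    half <- 100L
    peak_seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(top)), function(i) {
      ch <- top$chrom[i]
      s <- max(0L, top$summit[i] - half)
      e <- min(annotation$chrom_lengths[[ch]], top$summit[i] + half)
      as.character(Biostrings::subseq(genome[[ch]], s + 1L, e))
    }, character(1)))
    names(peak_seqs) <- top$peak_id
    motif <- discover_motif_em(peak_seqs, width = width, n_restarts = 3,
                               seed = substream_seed(config$seed, "em"),
                               max_iter = 200)
    pwm_used <- motif$pwm
  } else {
    pwm_used <- build_pwm(config$motif_consensus)
  }
  pwm_tab <- as_tibble(t(pwm_used$mat))
  pwm_tab <- dplyr::bind_cols(tibble(position = seq_len(nrow(pwm_tab))),
                              pwm_tab)
  write_table_tsv(pwm_tab, file.path(outd, "pwm_discovered.tsv"))

  prom_seqs <- promoter_sequences(genome, annotation, config$promoter_window)
  xbox_hits <- scan_pwm(prom_seqs, pwm_used)
  write_table_tsv(xbox_hits, file.path(outd, "xbox_hits.tsv"))
  xbox_genes <- unique(xbox_hits$seq_id)

  up <- config$promoter_window[["upstream"]]
  tss_profile <- positional_profile(
    xbox_hits, stats::setNames(rep(up, length(prom_seqs)), names(prom_seqs)),
    motif_width = width)
  write_table_tsv(tss_profile$histogram,
                  file.path(outd, "xbox_tss_histogram.tsv"))

  ## stage: integrate --------------------------------------------------------
  say("integrate: profiles, cilia, direct targets")
  prof_calls <- classify_profiles(profiles, criteria)
  write_table_tsv(prof_calls, file.path(outd, "profile_calls.tsv"))

  universe <- dge$dispersions$gene_id[dge$dispersions$mean_norm >=
                                        expressed_floor]
  calls <- call_direct_targets(
    genes = annotation$genes$gene_id,
    chip_targets = targets,
    de_sets = sets,
    xbox_genes = xbox_genes,
    profile_calls = prof_calls,
    cilia_evidence = cilia,
    regulon = sim$regulon
  )
  write_table_tsv(calls$table, file.path(outd, "target_calls.tsv"))

  ages <- sort(unique(sets$age))
  overlaps <- dplyr::bind_rows(lapply(ages, function(age) {
    dn <- intersect(de_set(sets, age, "down", 2), universe)
    tg <- intersect(targets$gene_id, universe)
    dplyr::bind_cols(tibble(comparison = paste0("targets_vs_down2_", age)),
                     compare_gene_sets(tg, dn, universe))
  }))
  write_table_tsv(overlaps, file.path(outd, "set_overlaps.tsv"))

  enr <- NULL
  dn30 <- de_set(sets, ages[length(ages)], "down", 2)
  fg <- intersect(dn30, universe)
  bgset <- setdiff(universe, fg)
  if (length(fg) > 0 && length(bgset) > 0) {
    enr <- motif_enrichment(fg, bgset, prom_seqs, pwm_used)
    jsonlite::write_json(
      list(table = enr$table, p_value = enr$p_value),
      file.path(outd, "motif_enrichment.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- summary_report(calls, dge, ann_peaks, xbox_hits, cilia)
  write_table_tsv(report, file.path(outd, "master_table.tsv"))

  summaries <- c(calls$summary, list(
    n_reproducible_peaks = nrow(peaks),
    peak_class_counts = stats::setNames(as.list(psum$class_counts$n),
                                        psum$class_counts$region_class),
    discovered_consensus = if (!is.null(motif)) motif$consensus else NA,
    inverted_repeat_score = if (!is.null(motif))
      motif$inverted_repeat_score else NA,
    motif_enrichment_p = if (!is.null(enr)) enr$p_value else NA,
    seed = config$seed
  ))
  jsonlite::write_json(summaries, file.path(outd, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    sim = sim, dge = dge, sets = sets, de_summary = dsum,
    rep_peaks = rep_peaks, peaks = peaks, annotated_peaks = ann_peaks,
    peak_summary = psum, targets = targets, motif = motif,
    xbox_hits = xbox_hits, enrichment = enr, profiles = prof_calls,
    calls = calls, report = report, summaries = summaries
  ))
}
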