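#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: genome layout, the
#' planted regulon, the X-box consensus, ChIP enrichment, negative-binomial
#' count parameters, developmental timepoints and the master seed. The
#' defaults define the reference study conditions used throughout the test
#' suite: 2,000 genes of which 200 form the planted regulon, 4-fold knockout
#' effects, 10x ChIP enrichment at mean bin depth 30, and the strand-aware
#' promoter window of 500 bp upstream to 50 bp downstream of the TSS.
#'
#' @param n_genes Number of non-overlapping gene models to place.
#' @param n_targets Number of regulon (direct-target) genes; must be
#'   `<= n_genes`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or
#'   `NULL` to size two chromosomes automatically to fit `n_genes`.
#' @param promoter_window Length-2 numeric `c(upstream, downstream)` in bp
#'   around the TSS (strand-aware).
#' @param motif_consensus DNA consensus planted in target promoters; the
#'   default is a perfect 14-bp inverted repeat with the canonical X-box
#'   structure.
#' @param exact_sites If `TRUE` (default) plant the exact consensus; if
#'   `FALSE` sample each planted site from a PWM peaked on the consensus.
#' @param nb_dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`).
#' @param n_reps_rna RNA-seq replicates per (genotype, age) group.
#' @param n_reps_chip ChIP IP replicates (>= 2 for reproducibility filtering).
#' @param library_sizes Optional per-sample relative library sizes for the
#'   count simulation (recycled across the `4 * n_reps_rna` samples); default
#'   all 1.
#' @param chip_enrichment Fold IP enrichment over input at planted sites
#'   (>= 1).
#' @param chip_depth Mean input coverage per bin (Poisson rate).
#' @param bin_bp Coverage bin width in bp.
#' @param gene_length Length of each simulated gene model in bp.
#' @param gene_margin Clear space kept on both sides of each gene so promoter
#'   windows never collide, in bp.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for per-gene
#'   baseline expression means.
#' @param effect_log2fc Magnitude of the planted knockout log2 fold-change.
#' @param frac_effect_p21 Fraction of regulon genes whose effect is present
#'   already at P21 (all carry it at P30).
#' @param frac_up_targets Fraction of regulon genes planted as upregulated in
#'   the knockout (the rest are downregulated).
#' @param n_indirect Number of non-regulon genes given knockout effects
#'   (differentially expressed without a promoter peak).
#' @param timepoints Ordered postnatal days of the developmental time course.
#' @param profile_noise_sdlog Log-normal noise sd on developmental profiles.
#' @param frac_rfx2_like_targets Fraction of regulon genes whose developmental
#'   profile follows the rising reference trajectory.
#' @param frac_unreliable Fraction of genes whose profile is scaled below the
#'   reliability floor (emulating unreliably low read values).
#' @param cilia_frac_regulon,cilia_frac_background Probability that a regulon
#'   / background gene carries ciliary evidence (gold-list membership or a
#'   high-confidence citation).
#' @param seed Master seed; every generator draws from a named substream
#'   derived from it, so modules can be regenerated independently.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, n_targets = 10, seed = 1)
#' cfg$promoter_window
sim_config <- function(n_genes = 2000,
                       n_targets = 200,
                       chrom_lengths = NULL,
                       promoter_window = c(upstream = 500, downstream = 50),
                       motif_consensus = "GTTGCCATGGCAAC",
                       exact_sites = TRUE,
                       nb_dispersion = 0.1,
                       n_reps_rna = 3,
                       n_reps_chip = 2,
                       library_sizes = NULL,
                       chip_enrichment = 10,
                       chip_depth = 30,
                       bin_bp = 50,
                       gene_length = 2000,
                       gene_margin = 600,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       effect_log2fc = 2,
                       frac_effect_p21 = 0.5,
                       frac_up_targets = 0.15,
                       n_indirect = 20,
                       timepoints = c(7, 14, 17, 21, 30),
                       profile_noise_sdlog = 0.1,
                       frac_rfx2_like_targets = 0.85,
                       frac_unreliable = 0.1,
                       cilia_frac_regulon = 0.6,
                       cilia_frac_background = 0.1,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, n_targets >= 0, n_targets <= n_genes,
    length(promoter_window) == 2, all(promoter_window >= 0),
    nchar(motif_consensus) >= 4,
    nb_dispersion > 0,
    n_reps_rna >= 1, n_reps_chip >= 1,
    chip_enrichment >= 1, chip_depth > 0, bin_bp >= 1,
    gene_length >= 1, gene_margin >= sum(promoter_window),
    n_indirect >= 0,
    all(diff(timepoints) > 0),
    cilia_frac_regulon >= 0, cilia_frac_regulon <= 1,
    cilia_frac_background >= 0, cilia_frac_background <= 1
  )
  if (!all(strsplit(toupper(motif_consensus), "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("motif_consensus must be a DNA string over ACGT", call. = FALSE)
  }
  if (is.null(chrom_lengths)) {
    # two chromosomes sized with ~20% slack over the minimum packing need
    slot <- gene_length + 2 * gene_margin
    per_chrom <- ceiling(n_genes / 2)
    len <- ceiling(per_chrom * slot * 1.2) + gene_margin
    chrom_lengths <- c(chr1 = len, chr2 = len)
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_targets = as.integer(n_targets),
    chrom_lengths = chrom_lengths,
    promoter_window = c(
      upstream = unname(promoter_window[1]),
      downstream = unname(promoter_window[2])
    ),
    motif_consensus = toupper(motif_consensus),
    exact_sites = isTRUE(exact_sites),
    nb_dispersion = nb_dispersion,
    n_reps_rna = as.integer(n_reps_rna),
    n_reps_chip = as.integer(n_reps_chip),
    library_sizes = library_sizes,
    chip_enrichment = chip_enrichment,
    chip_depth = chip_depth,
    bin_bp = as.integer(bin_bp),
    gene_length = as.integer(gene_length),
    gene_margin = as.integer(gene_margin),
    baseline_meanlog = baseline_meanlog,
    baseline_sdlog = baseline_sdlog,
    effect_log2fc = effect_log2fc,
    frac_effect_p21 = frac_effect_p21,
    frac_up_targets = frac_up_targets,
    n_indirect = as.integer(n_indirect),
    timepoints = timepoints,
    profile_noise_sdlog = profile_noise_sdlog,
    frac_rfx2_like_targets = frac_rfx2_like_targets,
    frac_unreliable = frac_unreliable,
    cilia_frac_regulon = cilia_frac_regulon,
    cilia_frac_background = cilia_frac_background,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  genes:", x$n_genes, " targets:", x$n_targets,
      " indirect DE:", x$n_indirect, "\n")
  cat("  chroms:", paste0(names(x$chrom_lengths), "=", x$chrom_lengths,
                          collapse = ", "), "\n")
  cat("  promoter window: -", x$promoter_window[["upstream"]], "/+",
      x$promoter_window[["downstream"]], " bp around TSS\n", sep = "")
  cat("  motif:", x$motif_consensus,
      if (x$exact_sites) "(exact sites)" else "(PWM-sampled sites)", "\n")
  cat("  NB dispersion:", x$nb_dispersion,
      " effect |log2FC|:", x$effect_log2fc, "\n")
  cat("  ChIP: enrichment", x$chip_enrichment, "x, depth", x$chip_depth,
      "/bin, bin", x$bin_bp, "bp,", x$n_reps_chip, "replicates\n")
  cat("  timepoints: P", paste(x$timepoints, collapse = ", P"), "\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Differential-expression thresholds
#'
#' The significance cutoff and the nested fold-change tiers used to define
#' down/up-regulated gene sets: raw p below `alpha` combined with fold-change
#' at or beyond each tier (2-, 3- and 10-fold by default).
#'
#' @param alpha Raw p-value cutoff (default 0.01).
#' @param fold_tiers Increasing fold-change tiers, all > 1.
#' @return A list of class `dge_thresholds`.
#' @export
dge_thresholds <- function(alpha = 0.01, fold_tiers = c(2, 3, 10)) {
  stopifnot(alpha > 0, alpha < 1, all(fold_tiers > 1), !is.unsorted(fold_tiers, strictly = TRUE))
  structure(list(alpha = alpha, fold_tiers = fold_tiers),
            class = "dge_thresholds")
}

#' Developmental profile-consistency criteria
#'
#' Thresholds deciding whether a gene's developmental expression trajectory is
#' consistent with activation by a factor that rises sharply before the last
#' timepoint: a reliability floor on peak RPKM, a minimum Pearson correlation
#' with the reference trajectory, and a minimum last/first fold rise.
#'
#' @param min_peak_rpkm Genes whose maximum RPKM across the time course falls
#'   below this floor are not evaluable.
#' @param min_correlation Minimum Pearson r with the reference trajectory.
#' @param min_rise_fold Minimum (last timepoint)/(first timepoint) fold rise.
#' @return A list of class `profile_criteria`.
#' @export
profile_criteria <- function(min_peak_rpkm = 1,
                             min_correlation = 0.8,
                             min_rise_fold = 4) {
  stopifnot(min_peak_rpkm > 0, min_rise_fold > 0,
            min_correlation >= -1, min_correlation <= 1)
  structure(list(min_peak_rpkm = min_peak_rpkm,
                 min_correlation = min_correlation,
                 min_rise_fold = min_rise_fold),
            class = "profile_criteria")
}

#' Derive a reproducible substream seed
#'
#' Hashes a stream name against a master seed so that each named generator
#' gets its own deterministic seed. Keeps the results of one generator
#' invariant to re-running the others.
#'
#' @param seed Integer master seed.
#' @param name Character stream name.
#' @return An integer in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "em") != substream_seed(1, "peaks")
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1048573
  as.integer((as.numeric(seed) * 1048583 + h) %% .Machine$integer.max)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(code)
}
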