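#' Genomic spans of planted binding sites
#'
#' Converts the gene-oriented planted offsets of a regulon table into genomic
#' intervals (0-based half-open), used both when enriching ChIP coverage and
#' when scoring peak recovery against the ground truth.
#'
#' @param annotation A `genome_annotation`.
#' @param regulon Regulon tibble from [simulate_genome()].
#' @param motif_width Width of the planted motif in bp.
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`.
#' @export
planted_site_spans <- function(annotation, regulon, motif_width = 14L) {
  tgt <- regulon[regulon$role == "target", ]
  if (nrow(tgt) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  g <- annotation$genes[match(tgt$gene_id, annotation$genes$gene_id), ]
  s0 <- ifelse(g$strand == "+",
               g$tss + tgt$site_offset,
               g$tss - tgt$site_offset - motif_width + 1L)
  tibble(gene_id = tgt$gene_id, chrom = g$chrom,
         start = as.integer(s0), end = as.integer(s0 + motif_width))
}

#' Simulate binned ChIP IP and input coverage tracks
#'
#' Input coverage is Poisson with mean `chip_depth` in every bin. Each IP
#' replicate is Poisson with mean `chip_depth * chip_enrichment` in bins
#' overlapping a planted binding site and `chip_depth` elsewhere. Replicates
#' draw from independent named substreams of the master seed. Bins are
#' `bin_bp` wide; a trailing partial bin at a chromosome end is dropped.
#'
#' @inheritParams planted_site_spans
#' @param config A [sim_config()] (uses `chip_depth`, `chip_enrichment`,
#'   `bin_bp`, `n_reps_chip`, `seed`).
#' @return A list with `ip` (list of coverage tibbles, one per replicate) and
#'   `input` (one coverage tibble); each tibble has columns `chrom`, `start`,
#'   `end`, `value`.
#' @export
simulate_chip_coverage <- function(annotation, regulon, config) {
  stopifnot(inherits(config, "sim_config"))
  bins <- coverage_bins(annotation$chrom_lengths, config$bin_bp)
  sites <- planted_site_spans(annotation, regulon,
                              nchar(config$motif_consensus))
  enriched <- bins_overlapping(bins, sites)

  input <- bins
  input$value <- with_substream(config$seed, "chip_input",
                                rpois(nrow(bins), config$chip_depth))
  ip <- lapply(seq_len(config$n_reps_chip), function(r) {
    trk <- bins
    lam <- rep(config$chip_depth, nrow(bins))
    lam[enriched] <- config$chip_depth * config$chip_enrichment
    trk$value <- with_substream(config$seed, paste0("chip_ip_rep", r),
                                rpois(nrow(bins), lam))
    trk
  })
  list(ip = ip, input = input)
}

coverage_bins <- function(chrom_lengths, bin_bp) {
  dplyr::bind_rows(lapply(names(chrom_lengths), function(ch) {
    n <- floor(chrom_lengths[[ch]] / bin_bp)
    tibble(chrom = ch,
           start = as.integer((seq_len(n) - 1L) * bin_bp),
           end = as.integer(seq_len(n) * bin_bp))
  }))
}

# logical index of bins overlapping any interval in `spans` (same convention)
bins_overlapping <- function(bins, spans) {
  hit <- rep(FALSE, nrow(bins))
  if (nrow(spans) == 0) return(hit)
  for (ch in unique(spans$chrom)) {
    b <- bins$chrom == ch
    if (!any(b)) next
    q <- IRanges::IRanges(start = bins$start[b] + 1L, end = bins$end[b])
    s <- spans[spans$chrom == ch, ]
    subj <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    hit[b] <- IRanges::overlapsAny(q, subj)
  }
  hit
}

#' Simulate a gene-by-sample RNA-seq count matrix
#'
#' Counts follow a negative binomial with mean
#' `baseline * 2^effect * library_size` and dispersion `nb_dispersion`
#' (variance `mu + alpha * mu^2`). Per-gene baselines are log-normal. The
#' planned effect of each regulon or indirect gene is applied only in KO
#' samples at its planned age; all other (gene, sample) means are the
#' baseline. The design is `{WT, KO} x {P21, P30} x n_reps_rna`.
#'
#' @inheritParams simulate_chip_coverage
#' @return A list with
#'   * `counts`: tibble, `gene_id` plus one integer column per sample,
#'   * `samples`: tibble `sample_id`, `genotype`, `age`, `replicate`,
#'     `library_size`.
#' @export
simulate_counts <- function(annotation, regulon, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes$gene_id
  n_rep <- config$n_reps_rna
  samples <- tidyr::expand_grid(
    genotype = c("WT", "KO"), age = c("P21", "P30"),
    replicate = seq_len(n_rep)
  ) |>
    dplyr::mutate(sample_id = paste(.data$genotype, .data$age,
                                    paste0("r", .data$replicate), sep = "_"))
  libs <- config$library_sizes
  if (is.null(libs)) libs <- rep(1, nrow(samples))
  samples$library_size <- rep_len(libs, nrow(samples))
  if (any(samples$library_size <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }

  eff <- matrix(0, nrow = length(genes), ncol = nrow(samples),
                dimnames = list(genes, samples$sample_id))
  reg_idx <- match(regulon$gene_id, genes)
  for (j in seq_len(nrow(samples))) {
    if (samples$genotype[j] != "KO") next
    e <- if (samples$age[j] == "P21") regulon$effect_log2fc_p21 else
      regulon$effect_log2fc_p30
    eff[reg_idx, j] <- e
  }

  counts <- with_substream(config$seed, "counts", {
    baseline <- rlnorm(length(genes), config$baseline_meanlog,
                       config$baseline_sdlog)
    mu <- baseline * 2^eff
    mu <- sweep(mu, 2, samples$library_size, `*`)
    if (any(mu < 0)) stop("negative NB means", call. = FALSE)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = length(genes), dimnames = dimnames(eff))
  })

  list(
    counts = dplyr::bind_cols(tibble(gene_id = genes),
                              as_tibble(counts)),
    samples = samples[, c("sample_id", "genotype", "age", "replicate",
                          "library_size")]
  )
}

#' Reference developmental trajectory
#'
#' The rising reference expression trajectory against which profile
#' consistency is judged: a logistic rise with half-maximum at postnatal day
#' 19 (between days 17 and 21, where the factor's own expression climbs
#' steeply) on a small basal floor, scaled to a maximum of 1.
#'
#' @param timepoints Postnatal days.
#' @return Numeric vector, one value per timepoint, max 1.
#' @export
#' @examples
#' reference_trajectory(c(7, 14, 17, 21, 30))
reference_trajectory <- function(timepoints) {
  v <- 0.05 + 0.95 / (1 + exp(-(timepoints - 19) / 1.5))
  v / max(v)
}

#' Simulate developmental expression profiles
#'
#' Each gene follows one of three shapes over the configured postnatal
#' timepoints: `rfx2_like` (the rising [reference_trajectory()]), `flat`
#' (constant), or `declining` (linear decrease to a basal floor), scaled by a
#' log-normal per-gene amplitude and perturbed by multiplicative log-normal
#' noise. Regulon genes follow their planned class; other genes are assigned
#' classes at background rates, and a configured fraction of genes is scaled
#' to unreliably low values (below the default reliability floor of 1 RPKM).
#'
#' @inheritParams simulate_chip_coverage
#' @return A long tibble: `gene_id`, `day`, `rpkm`, plus per-gene attributes
#'   `class` and `reliable` repeated along the time course.
#' @export
simulate_dev_profiles <- function(annotation, regulon, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes$gene_id
  tp <- config$timepoints
  ref <- reference_trajectory(tp)
  with_substream(config$seed, "profiles", {
    class <- sample(c("rfx2_like", "flat", "declining"), length(genes),
                    replace = TRUE, prob = c(0.2, 0.5, 0.3))
    names(class) <- genes
    class[regulon$gene_id] <- regulon$profile_class
    amp <- rlnorm(length(genes), log(30), 0.8)
    unreliable <- runif(length(genes)) < config$frac_unreliable
    amp[unreliable] <- runif(sum(unreliable), 0.05, 0.5)

    shape <- function(cl) {
      switch(cl,
             rfx2_like = ref,
             flat = rep(1, length(tp)),
             declining = 0.05 + 0.95 * (max(tp) - tp) / diff(range(tp)))
    }
    base <- t(vapply(class, shape, numeric(length(tp))))
    noise <- matrix(rlnorm(length(base), 0, config$profile_noise_sdlog),
                    nrow = nrow(base))
    rpkm <- base * amp * noise
    tibble(
      gene_id = rep(genes, each = length(tp)),
      day = rep(tp, times = length(genes)),
      rpkm = as.numeric(t(rpkm)),
      class = rep(unname(class), each = length(tp)),
      reliable = rep(!unreliable, each = length(tp))
    )
  })
}

#' Simulate ciliary-evidence annotations
#'
#' Emulates curated ciliary-gene resources: a boolean gold-standard list
#' membership and counts of low-, medium- and high-confidence citations per
#' gene. Regulon genes are cilia-positive (gold member or >= 1
#' high-confidence citation) at `cilia_frac_regulon`; background genes at
#' `cilia_frac_background`. Cilia-negative genes are never gold and never
#' high-cited.
#'
#' @inheritParams simulate_chip_coverage
#' @return A tibble: `gene_id`, `gold`, `low`, `medium`, `high`.
#' @export
simulate_cilia_evidence <- function(annotation, regulon, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes$gene_id
  is_target <- genes %in% regulon$gene_id[regulon$role == "target"]
  with_substream(config$seed, "cilia", {
    p <- ifelse(is_target, config$cilia_frac_regulon,
                config$cilia_frac_background)
    positive <- runif(length(genes)) < p
    gold <- positive & (runif(length(genes)) < 0.5)
    high <- integer(length(genes))
    high[positive] <- rpois(sum(positive), 1.5)
    # a positive gene that is not gold must carry >= 1 high-confidence citation
    need <- positive & !gold & high == 0
    high[need] <- 1L
    tibble(
      gene_id = genes,
      gold = gold,
      low = rpois(length(genes), 0.5),
      medium = rpois(length(genes), 0.3),
      high = as.integer(high)
    )
  })
}
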