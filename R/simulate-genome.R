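#' Simulate a compact annotated genome with a planted regulon
#'
#' Generates a genome of i.i.d. uniform ACGT sequence carrying `n_genes`
#' non-overlapping two-exon gene models with strand assigned ~50/50, and
#' plants exactly one X-box motif instance in the promoter of each of
#' `n_targets` regulon genes at a recorded TSS-relative offset. No instance
#' is planted anywhere else, so any other occurrence of the consensus is a
#' chance occurrence of the background model. The regulon table also records
#' the planned knockout log2 fold-changes at both ages and each target's
#' developmental profile class.
#'
#' All coordinates are 0-based half-open. The TSS of a `+` strand gene is its
#' leftmost base; of a `-` strand gene its rightmost base. Planted offsets are
#' gene-oriented (negative = upstream of the TSS) and always lie inside the
#' configured promoter window.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `annotation`: a `genome_annotation` (gene tibble, exon tibble,
#'     chromosome lengths),
#'   * `genome`: a [Biostrings::DNAStringSet] of chromosome sequences,
#'   * `regulon`: a tibble with one row per regulon or indirect-effect gene
#'     (`gene_id`, `role`, `site_offset`, `effect_log2fc_p21`,
#'     `effect_log2fc_p30`, `profile_class`).
#' @export
#' @examples
#' gen <- simulate_genome(sim_config(n_genes = 50, n_targets = 5, seed = 7))
#' gen$annotation$genes
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  up <- config$promoter_window[["upstream"]]
  down <- config$promoter_window[["downstream"]]
  L <- nchar(config$motif_consensus)
  if (down < L && up < L) {
    stop("promoter window too small to host the motif", call. = FALSE)
  }

  with_substream(config$seed, "genome", {
    genes <- place_gene_models(config)
    # strand ~50/50
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

    exons <- make_exons(genes, config$gene_length)
    annotation <- genome_annotation(genes[, c("gene_id", "chrom", "strand",
                                              "start", "end", "tss")],
                                    exons, config$chrom_lengths)

    # uniform background sequence per chromosome
    genome <- Biostrings::DNAStringSet(vapply(
      config$chrom_lengths,
      function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                          collapse = ""),
      character(1)
    ))
    names(genome) <- names(config$chrom_lengths)

    regulon <- plan_regulon(genes, config)

    # plant one motif instance per target promoter at the recorded offset
    tgt <- regulon[regulon$role == "target", ]
    if (nrow(tgt) > 0) {
      g <- genes[match(tgt$gene_id, genes$gene_id), ]
      site_seqs <- draw_site_sequences(nrow(tgt), config)
      for (i in seq_len(nrow(tgt))) {
        o <- tgt$site_offset[i]
        if (g$strand[i] == "+") {
          s0 <- g$tss[i] + o # 0-based genomic start
          word <- site_seqs[i]
        } else {
          s0 <- g$tss[i] - o - L + 1L
          word <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(site_seqs[i])))
        }
        ch <- g$chrom[i]
        Biostrings::subseq(genome[[ch]], start = s0 + 1L, width = L) <-
          Biostrings::DNAString(word)
      }
      regulon$site_seq <- NA_character_
      regulon$site_seq[regulon$role == "target"] <- site_seqs
    } else {
      regulon$site_seq <- character(0)
    }

    list(annotation = annotation, genome = genome, regulon = regulon)
  })
}

# Pack gene models left to right across chromosomes, keeping gene_margin of
# clear sequence on both sides of every gene so promoter windows never overlap
# a neighbouring model. Errors if the chromosomes cannot host n_genes.
place_gene_models <- function(config) {
  slot <- config$gene_length + 2L * config$gene_margin
  caps <- stats::setNames(pmax(0L, as.integer(floor(config$chrom_lengths / slot))),
                          names(config$chrom_lengths))
  if (sum(caps) < config$n_genes) {
    stop(sprintf(paste0("cannot place %d gene models of slot %d bp on ",
                        "chromosomes totalling %.0f bp (capacity %d); ",
                        "enlarge chrom_lengths or reduce n_genes"),
                 config$n_genes, slot, sum(config$chrom_lengths), sum(caps)),
         call. = FALSE)
  }
  rows <- list()
  remaining <- config$n_genes
  idx <- 1L
  for (ch in names(config$chrom_lengths)) {
    n_here <- min(remaining, caps[[ch]])
    if (n_here == 0) next
    starts <- config$gene_margin + (seq_len(n_here) - 1L) * slot
    rows[[ch]] <- tibble(
      gene_id = sprintf("gene%05d", idx - 1L + seq_len(n_here)),
      chrom = ch,
      start = as.integer(starts),
      end = as.integer(starts + config$gene_length)
    )
    idx <- idx + n_here
    remaining <- remaining - n_here
    if (remaining == 0) break
  }
  dplyr::bind_rows(rows)
}

# Two exons with an intron between; exon width 20% of gene length each.
make_exons <- function(genes, gene_length) {
  w <- max(50L, as.integer(round(gene_length * 0.2)))
  dplyr::bind_rows(
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$start, end = genes$start + w, exon_rank = 1L),
    tibble(gene_id = genes$gene_id, chrom = genes$chrom,
           start = genes$end - w, end = genes$end, exon_rank = 2L)
  ) |>
    dplyr::arrange(.data$gene_id, .data$start)
}

# Choose regulon members, planted offsets and planned effects.
plan_regulon <- function(genes, config) {
  up <- config$promoter_window[["upstream"]]
  down <- config$promoter_window[["downstream"]]
  L <- nchar(config$motif_consensus)
  target_ids <- sort(sample(genes$gene_id, config$n_targets))
  # gene-oriented offsets guaranteed inside the window on either strand
  off_lo <- -(up - 1L)
  off_hi <- down - L
  if (off_hi < off_lo) off_hi <- off_lo
  offsets <- sample(seq(off_lo, off_hi), config$n_targets, replace = TRUE)

  n_t <- config$n_targets
  sign_t <- ifelse(runif(n_t) < config$frac_up_targets, 1, -1)
  p21_on <- runif(n_t) < config$frac_effect_p21
  eff_p21 <- ifelse(p21_on, sign_t * config$effect_log2fc, 0)
  eff_p30 <- sign_t * config$effect_log2fc
  prof <- ifelse(runif(n_t) < config$frac_rfx2_like_targets, "rfx2_like",
                 sample(c("flat", "declining"), n_t, replace = TRUE))

  regulon <- tibble(
    gene_id = target_ids,
    role = "target",
    site_offset = as.integer(offsets),
    effect_log2fc_p21 = eff_p21,
    effect_log2fc_p30 = eff_p30,
    profile_class = prof
  )

  if (config$n_indirect > 0) {
    pool <- setdiff(genes$gene_id, target_ids)
    ind_ids <- sort(sample(pool, min(config$n_indirect, length(pool))))
    n_i <- length(ind_ids)
    sign_i <- sample(c(-1, 1), n_i, replace = TRUE)
    p21_i <- runif(n_i) < config$frac_effect_p21
    regulon <- dplyr::bind_rows(regulon, tibble(
      gene_id = ind_ids,
      role = "indirect",
      site_offset = NA_integer_,
      effect_log2fc_p21 = ifelse(p21_i, sign_i * config$effect_log2fc, 0),
      effect_log2fc_p30 = sign_i * config$effect_log2fc,
      profile_class = sample(c("rfx2_like", "flat", "declining"), n_i,
                             replace = TRUE, prob = c(0.3, 0.4, 0.3))
    ))
  }
  dplyr::arrange(regulon, .data$gene_id)
}

# Planted site sequences: exact consensus, or sampled column-wise from a PWM
# peaked on the consensus (0.85 on the consensus base).
draw_site_sequences <- function(n, config) {
  cons <- strsplit(config$motif_consensus, "")[[1]]
  if (config$exact_sites || n == 0) {
    return(rep(config$motif_consensus, n))
  }
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    paste(vapply(cons, function(b) {
      p <- stats::setNames(rep(0.05, 4), bases)
      p[b] <- 0.85
      sample(bases, 1, prob = p)
    }, character(1)), collapse = "")
  }, character(1))
}

#' Construct a genome annotation
#'
#' Lightweight container pairing a gene table with its exon table and the
#' chromosome lengths. Coordinates are 0-based half-open; `tss` is the
#' transcription start base (leftmost base on `+`, rightmost on `-`).
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`.
#' @param exons Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `exon_rank`; exons must be sorted, non-overlapping and inside the gene
#'   span.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, chrom_lengths) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "tss") %in%
                  names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id)) {
    stop("gene ids must be unique", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- genes$gene_id[!genes$strand %in% c("+", "-")][1]
    stop(sprintf("gene '%s' has unknown strand", bad), call. = FALSE)
  }
  if (!all(genes$chrom %in% names(chrom_lengths))) {
    stop("gene on unknown chromosome", call. = FALSE)
  }
  lens <- chrom_lengths[genes$chrom]
  if (any(genes$start < 0) || any(genes$end > lens)) {
    bad <- genes$gene_id[genes$start < 0 | genes$end > lens][1]
    stop(sprintf("gene '%s' extends beyond its chromosome", bad),
         call. = FALSE)
  }
  span <- genes[match(exons$gene_id, genes$gene_id), c("start", "end")]
  if (any(is.na(span$start)) ||
      any(exons$start < span$start | exons$end > span$end)) {
    bad <- exons$gene_id[is.na(span$start) |
                           exons$start < span$start | exons$end > span$end][1]
    stop(sprintf("exon of gene '%s' lies outside the gene span", bad),
         call. = FALSE)
  }
  tss_expect <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (any(genes$tss != tss_expect)) {
    bad <- genes$gene_id[genes$tss != tss_expect][1]
    stop(sprintf("gene '%s': tss inconsistent with strand convention", bad),
         call. = FALSE)
  }
  structure(list(genes = dplyr::arrange(genes, .data$gene_id),
                 exons = dplyr::arrange(exons, .data$gene_id, .data$start),
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes on ",
      length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  print(utils::head(x$genes, 5))
  invisible(x)
}

#' Strand-aware promoter windows
#'
#' Builds the genomic promoter interval of every gene: `upstream` bp before
#' and `downstream` bp after the TSS in gene orientation. On the `+` strand
#' the genomic interval is `[tss - upstream, tss + downstream)`; on the `-`
#' strand it mirrors to `[tss - downstream, tss + upstream)`. Every window has
#' length `upstream + downstream` and contains the TSS.
#'
#' @param annotation A `genome_annotation`.
#' @param window Length-2 numeric `c(upstream, downstream)` in bp.
#' @return A tibble: `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`.
#' @export
#' @examples
#' gen <- simulate_genome(sim_config(n_genes = 10, n_targets = 2, seed = 1))
#' promoter_windows(gen$annotation)
promoter_windows <- function(annotation, window = c(upstream = 500, downstream = 50)) {
  stopifnot(inherits(annotation, "genome_annotation"))
  up <- window[[1]]
  down <- window[[2]]
  g <- annotation$genes
  tibble(
    gene_id = g$gene_id,
    chrom = g$chrom,
    strand = g$strand,
    tss = g$tss,
    start = as.integer(ifelse(g$strand == "+", g$tss - up, g$tss - down)),
    end = as.integer(ifelse(g$strand == "+", g$tss + down, g$tss + up))
  )
}

#' Extract TSS-oriented promoter sequences
#'
#' Returns one sequence per gene covering its promoter window, reported in
#' gene orientation (reverse-complemented for `-` strand genes) so that
#' position 0 of each sequence is the upstream edge and the TSS sits
#' `upstream` bp in. Windows truncated by a chromosome edge are clipped.
#'
#' @inheritParams promoter_windows
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @return A named [Biostrings::DNAStringSet] (names = gene ids).
#' @export
promoter_sequences <- function(genome, annotation,
                               window = c(upstream = 500, downstream = 50)) {
  pw <- promoter_windows(annotation, window)
  lens <- annotation$chrom_lengths[pw$chrom]
  s <- pmax(pw$start, 0L)
  e <- pmin(pw$end, as.integer(lens))
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(pw)), function(i) {
    as.character(Biostrings::subseq(genome[[pw$chrom[i]]],
                                    start = s[i] + 1L, end = e[i]))
  }, character(1)))
  rc <- pw$strand == "-"
  if (any(rc)) seqs[rc] <- Biostrings::reverseComplement(seqs[rc])
  names(seqs) <- pw$gene_id
  seqs
}
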