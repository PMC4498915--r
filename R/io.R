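#' Read and write genome annotations as GFF3
#'
#' `write_annotation()` serialises a `genome_annotation` to GFF3 (1-based
#' closed coordinates, gene features with `ID` and exon features with
#' `Parent`); `read_annotation()` parses it back, converting to the internal
#' 0-based half-open convention and validating the gene model invariants
#' (unique ids, known strand, exons inside the gene span, TSS consistent with
#' strand). The round trip is the identity on the modelled fields.
#'
#' @param annotation A `genome_annotation`.
#' @param path File path of the GFF3 file.
#' @return `read_annotation()` returns a `genome_annotation`;
#'   `write_annotation()` returns `path` invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  e <- annotation$exons
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    type = "gene", ID = g$gene_id,
    seqinfo = GenomeInfoDb::Seqinfo(
      seqnames = names(annotation$chrom_lengths),
      seqlengths = as.integer(annotation$chrom_lengths))
  )
  e_strand <- g$strand[match(e$gene_id, g$gene_id)]
  gr_exons <- GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e_strand,
    type = "exon", ID = NA_character_,
    seqinfo = GenomeInfoDb::seqinfo(gr_genes)
  )
  gr_exons$Parent <- as.character(e$gene_id)
  gr_genes$Parent <- NA_character_
  gr <- c(gr_genes, gr_exons)
  gr <- gr[order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr),
                 match(gr$type, c("gene", "exon")))]
  rtracklayer::export(gr, path, format = "gff3")
  # add ##sequence-region pragmas (carrying chromosome lengths) and drop the
  # date stamp so identical annotations serialise byte-identically
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date") &
                   !startsWith(lines, "##source-version")]
  pragma <- sprintf("##sequence-region %s 1 %d",
                    names(annotation$chrom_lengths),
                    as.integer(annotation$chrom_lengths))
  writeLines(c(lines[1], pragma, lines[-1]), path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  is_exon <- gr$type == "exon"
  if (!any(is_gene)) stop("no gene features in GFF3", call. = FALSE)
  gg <- gr[is_gene]
  strands <- as.character(GenomicRanges::strand(gg))
  if (any(!strands %in% c("+", "-"))) {
    bad <- unlist(gg$ID)[!strands %in% c("+", "-")][1]
    stop(sprintf("gene '%s' has unknown strand", bad), call. = FALSE)
  }
  genes <- tibble(
    gene_id = as.character(unlist(gg$ID)),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    strand = strands,
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg)
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

  ge <- gr[is_exon]
  parent <- as.character(unlist(ge$Parent))
  exons <- tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(ge)),
    start = GenomicRanges::start(ge) - 1L,
    end = GenomicRanges::end(ge)
  ) |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon_rank = dplyr::row_number()) |>
    dplyr::ungroup()

  # chromosome lengths from ##sequence-region pragmas (rtracklayer drops
  # them), falling back to the observed gene extent
  hdr <- grep("^##sequence-region", readLines(path, n = 1000), value = TRUE)
  sl <- stats::setNames(rep(NA_real_, length(unique(genes$chrom))),
                        unique(genes$chrom))
  if (length(hdr) > 0) {
    parts <- strsplit(trimws(hdr), "\\s+")
    for (p in parts) {
      if (length(p) >= 4 && p[2] %in% names(sl)) sl[p[2]] <- as.numeric(p[4])
    }
  }
  if (any(is.na(sl))) {
    obs <- tapply(genes$end, genes$chrom, max)
    sl[is.na(sl)] <- obs[names(sl)[is.na(sl)]]
  }
  genome_annotation(genes, exons, sl)
}

#' Read and write coverage tracks as bedGraph
#'
#' Coverage tibbles use 0-based half-open bins (`chrom`, `start`, `end`,
#' `value`), matching bedGraph natively. `read_bedgraph()` rejects
#' overlapping bins.
#'
#' @param track Coverage tibble.
#' @param path bedGraph file path.
#' @return `read_bedgraph()` returns a coverage tibble; `write_bedgraph()`
#'   returns `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  trk <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "value"),
                         col_types = "ciid", comment = "track",
                         progress = FALSE)
  if (any(trk$start >= trk$end)) {
    stop("bedGraph interval with start >= end", call. = FALSE)
  }
  for (ch in unique(trk$chrom)) {
    x <- trk[trk$chrom == ch, ]
    x <- x[order(x$start), ]
    if (any(x$start[-1] < x$end[-nrow(x)])) {
      stop(sprintf("overlapping bedGraph bins on %s", ch), call. = FALSE)
    }
  }
  dplyr::arrange(trk, .data$chrom, .data$start)
}

narrowpeak_cols <- c("chrom", "start", "end", "name", "score", "strand",
                     "signalValue", "pValue", "qValue", "peak")

#' Read and write peak sets as narrowPeak
#'
#' The internal peak tibble (`peak_id`, `chrom`, `start`, `end`, `summit`,
#' `enrichment`, `p_value`, `q_value`) maps onto the 10-column ENCODE
#' narrowPeak schema: `signalValue` holds the IP/input enrichment, `pValue`
#' and `qValue` are -log10 transformed, and column 10 is the summit offset
#' from the peak start (-1 = unknown). Reading validates `start < end` and
#' that the summit lies inside the peak.
#'
#' @param peaks Peak tibble.
#' @param path narrowPeak file path.
#' @return `read_narrowpeak()` returns a peak tibble; `write_narrowpeak()`
#'   returns `path` invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = peaks$peak_id,
    score = as.integer(pmin(1000, round(-10 * log10(pmax(peaks$p_value,
                                                         1e-100))))),
    strand = ".",
    signalValue = round(peaks$enrichment, 6),
    pValue = round(-log10(pmax(peaks$p_value, 1e-300)), 6),
    qValue = if ("q_value" %in% names(peaks)) {
      round(-log10(pmax(peaks$q_value, 1e-300)), 6)
    } else -1,
    peak = as.integer(peaks$summit - peaks$start)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @export
read_narrowpeak <- function(path) {
  np <- readr::read_tsv(path, col_names = narrowpeak_cols,
                        col_types = "ciicicdddi", progress = FALSE)
  if (any(np$start >= np$end)) {
    stop("narrowPeak interval with start >= end", call. = FALSE)
  }
  if (any(np$peak != -1L & (np$peak < 0L | np$start + np$peak >= np$end))) {
    stop("narrowPeak summit offset outside the peak", call. = FALSE)
  }
  tibble(
    peak_id = np$name,
    chrom = np$chrom,
    start = np$start,
    end = np$end,
    summit = ifelse(np$peak == -1L,
                    as.integer(floor((np$start + np$end) / 2)),
                    np$start + np$peak),
    enrichment = np$signalValue,
    p_value = 10^(-np$pValue),
    q_value = ifelse(np$qValue < 0, NA_real_, 10^(-np$qValue))
  )
}

#' Read a BED6 interval file
#'
#' Returns intervals in the internal 0-based half-open convention (BED
#' native); a BED line `chr1 100 200` has length 100.
#'
#' @param path BED file path.
#' @return A tibble: `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (missing optional columns filled with defaults).
#' @export
read_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  ncol <- length(strsplit(first, "\t")[[1]])
  cols <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(ncol, 6))]
  types <- substr("ciicdc", 1, min(ncol, 6))
  bed <- readr::read_tsv(path, col_names = cols, col_types = types,
                         progress = FALSE)
  if (any(bed$start >= bed$end)) {
    stop("BED interval with start >= end", call. = FALSE)
  }
  if (!"name" %in% names(bed)) bed$name <- paste0("iv", seq_len(nrow(bed)))
  if (!"score" %in% names(bed)) bed$score <- 0
  if (!"strand" %in% names(bed)) bed$strand <- "."
  bed
}

#' Write and read the ground-truth regulon manifest
#'
#' The regulon table of [simulate_genome()] is serialised as JSON so that
#' downstream test oracles can score pipeline calls against the planted
#' truth without re-running the generator.
#'
#' @param regulon Regulon tibble.
#' @param path JSON file path.
#' @return `read_regulon()` returns the regulon tibble; `write_regulon()`
#'   returns `path` invisibly.
#' @export
write_regulon <- function(regulon, path) {
  jsonlite::write_json(regulon, path, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_regulon
#' @export
read_regulon <- function(path) {
  df <- jsonlite::fromJSON(path)
  out <- as_tibble(df)
  out$site_offset <- as.integer(out$site_offset)
  out
}

#' Read and write count matrices and sample sheets
#'
#' Counts travel as a TSV whose first column is `gene_id` followed by one
#' integer column per sample; the sample sheet is a TSV with `sample_id`,
#' `genotype`, `age`, `replicate`, `library_size`.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param samples Sample sheet tibble.
#' @param path,counts_path,samples_path File paths.
#' @return Readers return tibbles; writers return the path invisibly.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  readr::write_tsv(counts, counts_path)
  readr::write_tsv(samples, samples_path)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(counts_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  samples <- readr::read_tsv(samples_path, col_types = "cccid",
                             progress = FALSE)
  if (!setequal(setdiff(names(counts), "gene_id"), samples$sample_id)) {
    stop("count columns and sample sheet disagree", call. = FALSE)
  }
  list(counts = counts, samples = samples)
}

#' @rdname write_counts
#' @export
write_table_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
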