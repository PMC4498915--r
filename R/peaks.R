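# Windowed Poisson peak calling against an input control, replicate
# reproducibility filtering, and peak-to-gene annotation around the TSS.

#' Call peaks from binned IP and input coverage
#'
#' For every bin, the expected background is the input count rescaled to the
#' IP sequencing depth, floored at a global minimum (by default the
#' genome-wide rescaled input mean, so depleted bins cannot produce spurious
#' significance). The bin p-value is the Poisson upper tail of the IP count
#' at that expectation. Bins significant after Benjamini-Hochberg correction
#' within the replicate are merged into peaks when separated by at most
#' `merge_gap` non-significant bins. Each peak reports the centre of its
#' maximum-IP bin as the summit, its minimum bin p-value, and the IP/expected
#' ratio over its span as enrichment.
#'
#' @param ip,input Coverage tibbles (`chrom`, `start`, `end`, `value`) on
#'   identical binning.
#' @param p_threshold BH-adjusted significance cutoff for bins (default
#'   0.01).
#' @param merge_gap Maximum number of non-significant bins bridged when
#'   merging (default 1).
#' @param lambda_floor Minimum background expectation per bin; default the
#'   genome-wide rescaled input mean.
#' @return A peak tibble: `peak_id`, `chrom`, `start`, `end`, `summit`,
#'   `enrichment`, `p_value`, `q_value`.
#' @export
call_peaks <- function(ip, input, p_threshold = 0.01, merge_gap = 1,
                       lambda_floor = NULL) {
  if (nrow(input) == 0 || sum(input$value) == 0) {
    stop("empty input track: background undefined", call. = FALSE)
  }
  if (!identical(ip[, c("chrom", "start", "end")],
                 input[, c("chrom", "start", "end")])) {
    stop("IP and input tracks must share the same binning", call. = FALSE)
  }
  scale <- sum(ip$value) / sum(input$value)
  lambda <- input$value * scale
  if (is.null(lambda_floor)) lambda_floor <- mean(lambda)
  lambda <- pmax(lambda, lambda_floor)
  p <- ppois(ip$value - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- q < p_threshold

  peaks <- list()
  for (ch in unique(ip$chrom)) {
    sel <- which(ip$chrom == ch & sig)
    if (length(sel) == 0) next
    # bins are consecutive rows within a chromosome; bridge merge_gap bins
    grp <- cumsum(c(1, diff(sel) > merge_gap + 1))
    for (g in split(sel, grp)) {
      span <- seq(min(g), max(g))
      top <- g[which.max(ip$value[g])]
      peaks[[length(peaks) + 1]] <- tibble(
        chrom = ch,
        start = ip$start[min(g)],
        end = ip$end[max(g)],
        summit = as.integer(floor((ip$start[top] + ip$end[top]) / 2)),
        enrichment = sum(ip$value[span]) / sum(lambda[span]),
        p_value = min(p[g]),
        q_value = min(q[g])
      )
    }
  }
  out <- dplyr::bind_rows(peaks)
  if (nrow(out) == 0) {
    return(tibble(peak_id = character(), chrom = character(),
                  start = integer(), end = integer(), summit = integer(),
                  enrichment = numeric(), p_value = numeric(),
                  q_value = numeric()))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  dplyr::bind_cols(tibble(peak_id = sprintf("peak%05d", seq_len(nrow(out)))),
                   out)
}

#' Filter peaks for reproducibility across replicates
#'
#' Anchored on the replicate with the most peaks, keeps every anchor peak
#' that has, in each other replicate, a peak with reciprocal overlap (overlap
#' width relative to both peak widths) of at least `min_overlap_frac`. The
#' reported interval is the union of the anchor peak with its best partner in
#' each other replicate; summit, enrichment and p-value come from the anchor.
#'
#' @param peak_sets List of >= 2 peak tibbles (one per replicate).
#' @param min_overlap_frac Reciprocal overlap fraction required (default
#'   0.5).
#' @return A peak tibble of reproducible peaks.
#' @export
filter_reproducible <- function(peak_sets, min_overlap_frac = 0.5) {
  if (!is.list(peak_sets) || length(peak_sets) < 2) {
    stop("reproducibility needs >= 2 replicate peak sets", call. = FALSE)
  }
  n_peaks <- vapply(peak_sets, nrow, 1L)
  anchor_i <- which.max(n_peaks)
  anchor <- peak_sets[[anchor_i]]
  others <- peak_sets[-anchor_i]
  if (nrow(anchor) == 0) return(anchor)

  keep <- rep(TRUE, nrow(anchor))
  u_start <- anchor$start
  u_end <- anchor$end
  for (other in others) {
    matched <- rep(FALSE, nrow(anchor))
    for (ch in unique(anchor$chrom)) {
      ai <- which(anchor$chrom == ch)
      oi <- which(other$chrom == ch)
      if (length(ai) == 0 || length(oi) == 0) next
      a_r <- IRanges::IRanges(anchor$start[ai] + 1L, anchor$end[ai])
      o_r <- IRanges::IRanges(other$start[oi] + 1L, other$end[oi])
      hits <- IRanges::findOverlaps(a_r, o_r)
      if (length(hits) == 0) next
      ov <- IRanges::width(IRanges::pintersect(
        a_r[S4Vectors::queryHits(hits)], o_r[S4Vectors::subjectHits(hits)]))
      wa <- IRanges::width(a_r[S4Vectors::queryHits(hits)])
      wo <- IRanges::width(o_r[S4Vectors::subjectHits(hits)])
      ok <- ov / wa >= min_overlap_frac & ov / wo >= min_overlap_frac
      if (!any(ok)) next
      hdf <- tibble(a = S4Vectors::queryHits(hits)[ok],
                    o = S4Vectors::subjectHits(hits)[ok],
                    ov = ov[ok]) |>
        dplyr::group_by(.data$a) |>
        dplyr::slice_max(.data$ov, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      rows <- ai[hdf$a]
      matched[rows] <- TRUE
      u_start[rows] <- pmin(u_start[rows], other$start[oi][hdf$o])
      u_end[rows] <- pmax(u_end[rows], other$end[oi][hdf$o])
    }
    keep <- keep & matched
  }
  out <- anchor[keep, ]
  out$start <- u_start[keep]
  out$end <- u_end[keep]
  if (nrow(out) > 0) out$peak_id <- sprintf("rpeak%05d", seq_len(nrow(out)))
  out
}

#' Annotate peaks with genomic region classes and TSS distances
#'
#' Classifies each peak by its centre with precedence
#' promoter > exon > intron > intergenic: promoter if the centre falls in any
#' strand-aware promoter window, exon/intron if it falls inside a gene model,
#' intergenic otherwise — so the classes partition the peak set. Promoter
#' peaks are assigned to the gene with the nearest TSS among the windows
#' containing the centre; an exact distance tie assigns both genes and flags
#' the peak ambiguous. The signed TSS distance (centre minus TSS, sign
#' flipped on the minus strand so positive = downstream) is reported relative
#' to the assigned gene, or to the nearest TSS for non-promoter peaks.
#'
#' @param peaks Peak tibble.
#' @param annotation A `genome_annotation`.
#' @param window Promoter window `c(upstream, downstream)` in bp.
#' @return The peak tibble plus `center`, `region_class`, `gene_id`
#'   (comma-separated when ambiguous, `NA` for intergenic), `tss_distance`,
#'   `ambiguous`.
#' @export
annotate_peaks <- function(peaks, annotation,
                           window = c(upstream = 500, downstream = 50)) {
  stopifnot(inherits(annotation, "genome_annotation"))
  pw <- promoter_windows(annotation, window)
  genes <- annotation$genes
  exons <- annotation$exons
  n <- nrow(peaks)
  center <- as.integer(floor((peaks$start + peaks$end) / 2))
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  tss_dist <- rep(NA_real_, n)
  ambiguous <- rep(FALSE, n)

  signed_dist <- function(center, tss, strand) {
    d <- center - tss
    ifelse(strand == "-", -d, d)
  }

  for (i in seq_len(n)) {
    ch <- peaks$chrom[i]
    cc <- center[i]
    inwin <- which(pw$chrom == ch & pw$start <= cc & cc < pw$end)
    if (length(inwin) > 0) {
      region[i] <- "promoter"
      dd <- abs(cc - pw$tss[inwin])
      best <- inwin[dd == min(dd)]
      if (length(best) > 1) ambiguous[i] <- TRUE
      gene_id[i] <- paste(pw$gene_id[best], collapse = ",")
      tss_dist[i] <- signed_dist(cc, pw$tss[best[1]], pw$strand[best[1]])
      next
    }
    inex <- which(exons$chrom == ch & exons$start <= cc & cc < exons$end)
    if (length(inex) > 0) {
      region[i] <- "exon"
      gene_id[i] <- exons$gene_id[inex[1]]
    } else {
      ing <- which(genes$chrom == ch & genes$start <= cc & cc < genes$end)
      if (length(ing) > 0) {
        region[i] <- "intron"
        gene_id[i] <- genes$gene_id[ing[1]]
      }
    }
    gch <- genes[genes$chrom == ch, ]
    if (nrow(gch) > 0) {
      j <- which.min(abs(cc - gch$tss))
      tss_dist[i] <- signed_dist(cc, gch$tss[j], gch$strand[j])
    }
  }

  dplyr::bind_cols(peaks, tibble(center = center, region_class = region,
                                 gene_id = gene_id, tss_distance = tss_dist,
                                 ambiguous = ambiguous))
}

#' Summaries of an annotated peak set
#'
#' Region-class counts and fractions, the cumulative promoter fraction of
#' peaks ranked by increasing p-value, and a histogram of TSS distances of
#' promoter peaks.
#'
#' @param annotated Output of [annotate_peaks()].
#' @param bin_width TSS-distance histogram bin width in bp.
#' @return A list of tibbles: `class_counts`, `rank_curve`, `tss_histogram`.
#' @export
peak_summary <- function(annotated, bin_width = 50) {
  class_counts <- annotated |>
    dplyr::count(.data$region_class, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))

  ranked <- dplyr::arrange(annotated, .data$p_value)
  rank_curve <- tibble(
    rank = seq_len(nrow(ranked)),
    p_value = ranked$p_value,
    cum_promoter_fraction = cumsum(ranked$region_class == "promoter") /
      seq_len(nrow(ranked))
  )

  prom <- annotated[annotated$region_class == "promoter" &
                      !is.na(annotated$tss_distance), ]
  if (nrow(prom) > 0) {
    b <- floor(prom$tss_distance / bin_width) * bin_width
    tss_histogram <- tibble(bin_start = b) |>
      dplyr::count(.data$bin_start, name = "n") |>
      dplyr::arrange(.data$bin_start)
  } else {
    tss_histogram <- tibble(bin_start = numeric(), n = integer())
  }
  list(class_counts = class_counts, rank_curve = rank_curve,
       tss_histogram = tss_histogram)
}

#' Genes with a reproducible peak in their promoter window
#'
#' The promoter-target gene set: every gene whose strand-aware promoter
#' window contains the centre of at least one annotated promoter peak.
#' Peaks assigned ambiguously (centre equidistant from two TSSs) contribute
#' to both genes and the genes are flagged.
#'
#' @param annotated Output of [annotate_peaks()].
#' @return A tibble: `gene_id`, `n_peaks`, `ambiguous`.
#' @export
promoter_target_genes <- function(annotated) {
  prom <- annotated[annotated$region_class == "promoter", ]
  if (nrow(prom) == 0) {
    return(tibble(gene_id = character(), n_peaks = integer(),
                  ambiguous = logical()))
  }
  tidyr::separate_rows(prom[, c("gene_id", "ambiguous")], "gene_id",
                       sep = ",") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_peaks = dplyr::n(), ambiguous = any(.data$ambiguous),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_id)
}
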