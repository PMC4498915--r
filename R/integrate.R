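# Integration of binding, differential expression, motif, developmental
# profile and ciliary evidence into per-gene target calls.

#' Classify developmental profiles against the reference trajectory
#'
#' A gene is `not_evaluable` when its maximum RPKM over the time course is
#' below the reliability floor (emulating exclusion of unreliably low read
#' values). Otherwise it is `consistent` with activation by the factor when
#' its Pearson correlation with the reference trajectory meets
#' `min_correlation` and its last/first-timepoint fold rise meets
#' `min_rise_fold`; else `inconsistent`.
#'
#' @param profiles Long tibble `gene_id`, `day`, `rpkm`.
#' @param criteria A [profile_criteria()].
#' @param reference Reference trajectory values at the profile timepoints;
#'   default [reference_trajectory()] of the observed days.
#' @return A tibble: `gene_id`, `status`, `correlation`, `rise_fold`,
#'   `max_rpkm`.
#' @export
classify_profiles <- function(profiles, criteria = profile_criteria(),
                              reference = NULL) {
  stopifnot(all(c("gene_id", "day", "rpkm") %in% names(profiles)))
  wide <- profiles |>
    dplyr::select("gene_id", "day", "rpkm") |>
    dplyr::arrange(.data$gene_id, .data$day) |>
    tidyr::pivot_wider(names_from = "day", values_from = "rpkm")
  days <- sort(unique(profiles$day))
  if (is.null(reference)) reference <- reference_trajectory(days)
  stopifnot(length(reference) == length(days))
  m <- as.matrix(wide[, as.character(days)])

  max_rpkm <- apply(m, 1, max)
  corr <- suppressWarnings(apply(m, 1, function(v) cor(v, reference)))
  rise <- m[, ncol(m)] / pmax(m[, 1], 1e-9)
  status <- ifelse(
    max_rpkm < criteria$min_peak_rpkm, "not_evaluable",
    ifelse(!is.na(corr) & corr >= criteria$min_correlation &
             rise >= criteria$min_rise_fold, "consistent", "inconsistent"))
  tibble(gene_id = wide$gene_id, status = status,
         correlation = as.numeric(corr), rise_fold = as.numeric(rise),
         max_rpkm = as.numeric(max_rpkm))
}

#' Flag genes with ciliary evidence
#'
#' A gene is cilia-positive when it belongs to the gold-standard list or has
#' at least one high-confidence citation. Genes absent from the evidence
#' table are treated as negative (incomplete databases are not errors).
#'
#' @param genes Character vector of gene ids to flag.
#' @param evidence Tibble `gene_id`, `gold`, `low`, `medium`, `high`.
#' @return A tibble: `gene_id`, `cilia`.
#' @export
flag_cilia <- function(genes, evidence) {
  idx <- match(genes, evidence$gene_id)
  gold <- ifelse(is.na(idx), FALSE, evidence$gold[idx])
  high <- ifelse(is.na(idx), 0L, evidence$high[idx])
  tibble(gene_id = genes, cilia = gold | high >= 1)
}

#' Fraction of cilia-positive genes in each named set
#'
#' @param gene_sets Named list of gene-id vectors.
#' @param evidence Evidence tibble, see [flag_cilia()].
#' @return A tibble: `set`, `n`, `n_cilia`, `fraction`.
#' @export
cilia_fractions <- function(gene_sets, evidence) {
  dplyr::bind_rows(lapply(names(gene_sets), function(nm) {
    g <- gene_sets[[nm]]
    fl <- flag_cilia(g, evidence)
    tibble(set = nm, n = length(g), n_cilia = sum(fl$cilia),
           fraction = if (length(g)) mean(fl$cilia) else NA_real_)
  }))
}

#' Integrate all evidence into per-gene target calls
#'
#' Joins the promoter-peak (ChIP) target set, the tiered DE sets at both
#' ages, promoter X-box calls, developmental profile classifications and
#' cilia flags over a shared gene universe. A gene is a direct target when
#' it is a ChIP target and differentially expressed (any direction) at
#' either age. When the planted regulon is supplied, precision and recall of
#' the direct-target set against the true regulon are appended to the
#' summaries.
#'
#' @param genes Character vector: the gene universe.
#' @param chip_targets Tibble from [promoter_target_genes()] (or a character
#'   vector of gene ids).
#' @param de_sets Long set tibble from [call_de_sets()].
#' @param xbox_genes Character vector of genes with a promoter X-box hit.
#' @param profile_calls Tibble from [classify_profiles()] (optional).
#' @param cilia_evidence Evidence tibble (optional).
#' @param regulon Regulon tibble from [simulate_genome()] (optional).
#' @return A list of class `target_calls`: `table` (per-gene tibble) and
#'   `summary` (named list of headline counts and fractions).
#' @export
call_direct_targets <- function(genes, chip_targets, de_sets,
                                xbox_genes = character(),
                                profile_calls = NULL,
                                cilia_evidence = NULL,
                                regulon = NULL) {
  chip_ids <- if (is.data.frame(chip_targets)) chip_targets$gene_id else
    chip_targets

  de_dir <- function(age) {
    down <- de_set(de_sets, age, "down", min(de_sets$tier[de_sets$age == age]))
    up <- de_set(de_sets, age, "up", min(de_sets$tier[de_sets$age == age]))
    ifelse(genes %in% down, "down", ifelse(genes %in% up, "up", "none"))
  }
  de_tier <- function(age, dir_vec) {
    tier <- rep(NA_real_, length(genes))
    for (k in sort(unique(de_sets$tier))) {
      for (dir in c("down", "up")) {
        inset <- genes %in% de_set(de_sets, age, dir, k)
        tier[inset & dir_vec == dir] <- k
      }
    }
    tier
  }
  ages <- sort(unique(de_sets$age))
  tab <- tibble(gene_id = genes,
                is_chip_target = genes %in% chip_ids)
  for (age in ages) {
    dv <- de_dir(age)
    tab[[paste0("de_", tolower(age))]] <- dv
    tab[[paste0("tier_", tolower(age))]] <- de_tier(age, dv)
  }
  de_any <- rep(FALSE, length(genes))
  for (age in ages) de_any <- de_any | tab[[paste0("de_", tolower(age))]] != "none"
  tab$has_xbox <- genes %in% xbox_genes
  tab$profile_status <- if (!is.null(profile_calls)) {
    idx <- match(genes, profile_calls$gene_id)
    ifelse(is.na(idx), "not_evaluable", profile_calls$status[idx])
  } else NA_character_
  tab$cilia <- if (!is.null(cilia_evidence)) {
    flag_cilia(genes, cilia_evidence)$cilia
  } else NA
  tab$direct_target <- tab$is_chip_target & de_any

  down_dirs <- vapply(ages, function(a) paste0("de_", tolower(a)), "")
  direct_down <- tab$direct_target &
    Reduce(`|`, lapply(down_dirs, function(cl) tab[[cl]] == "down"))
  direct_up <- tab$direct_target &
    Reduce(`|`, lapply(down_dirs, function(cl) tab[[cl]] == "up"))

  summary <- list(
    n_genes = length(genes),
    n_chip_targets = sum(tab$is_chip_target),
    n_de = sum(de_any),
    n_direct_targets = sum(tab$direct_target),
    n_direct_down = sum(direct_down),
    n_direct_up = sum(direct_up),
    n_de_with_xbox = sum(de_any & tab$has_xbox)
  )
  if (!is.null(profile_calls)) {
    for (age in ages) {
      dn <- tab[[paste0("de_", tolower(age))]] == "down" & tab$direct_target
      ev <- dn & tab$profile_status != "not_evaluable"
      summary[[paste0("profile_consistent_down_", tolower(age))]] <- list(
        n_evaluable = sum(ev),
        n_consistent = sum(ev & tab$profile_status == "consistent"),
        fraction = if (sum(ev)) mean(tab$profile_status[ev] == "consistent")
        else NA_real_
      )
    }
  }
  if (!is.null(cilia_evidence)) {
    summary$cilia_fraction_direct_targets <-
      if (any(tab$direct_target)) mean(tab$cilia[tab$direct_target]) else
        NA_real_
    summary$cilia_fraction_background <-
      if (any(!tab$direct_target)) mean(tab$cilia[!tab$direct_target]) else
        NA_real_
  }
  if (!is.null(regulon)) {
    truth <- regulon$gene_id[regulon$role == "target"]
    pred <- tab$gene_id[tab$direct_target]
    tp <- length(intersect(pred, truth))
    summary$precision <- if (length(pred)) tp / length(pred) else NA_real_
    summary$recall <- if (length(truth)) tp / length(truth) else NA_real_
  }
  structure(list(table = tab, summary = summary), class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  s <- x$summary
  cat("<target_calls> ", s$n_genes, " genes: ", s$n_chip_targets,
      " ChIP targets, ", s$n_de, " DE, ", s$n_direct_targets,
      " direct targets (", s$n_direct_down, " down / ", s$n_direct_up,
      " up)\n", sep = "")
  if (!is.null(s$precision)) {
    cat("  vs planted regulon: precision ", round(s$precision, 3),
        ", recall ", round(s$recall, 3), "\n", sep = "")
  }
  invisible(x)
}

#' Overlap statistics of two gene sets
#'
#' Overlap count, Jaccard index, and hypergeometric p-values for enrichment
#' (upper tail) and depletion (lower tail) of the overlap given the
#' universe.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return A tibble with one row: `n_a`, `n_b`, `n_universe`, `overlap`,
#'   `jaccard`, `p_enrich`, `p_deplete`.
#' @export
#' @examples
#' compare_gene_sets(letters[1:5], letters[3:6], letters)
compare_gene_sets <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  n_a <- length(set_a)
  n_b <- length(set_b)
  N <- length(universe)
  un <- length(union(set_a, set_b))
  tibble(
    n_a = n_a, n_b = n_b, n_universe = N, overlap = k,
    jaccard = if (un) k / un else NA_real_,
    p_enrich = phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE),
    p_deplete = phyper(k, n_a, N - n_a, n_b, lower.tail = TRUE)
  )
}

#' Master per-gene report table
#'
#' One row per gene in the union of ChIP targets and DE genes, joining every
#' target-call field with fold-changes, p-values, promoter-peak coordinates,
#' X-box hit offsets and cilia evidence, in deterministic gene-id order.
#'
#' @param calls A `target_calls`.
#' @param dge A `dge_result`.
#' @param annotated_peaks Output of [annotate_peaks()].
#' @param xbox_hits Promoter scan hits ([scan_pwm()] on TSS-oriented
#'   promoter sequences).
#' @param cilia_evidence Evidence tibble (optional).
#' @return A tibble, one row per reported gene, columns in documented order.
#' @export
summary_report <- function(calls, dge, annotated_peaks, xbox_hits = NULL,
                           cilia_evidence = NULL) {
  tab <- calls$table
  keep <- tab$is_chip_target |
    Reduce(`|`, lapply(grep("^de_", names(tab), value = TRUE),
                       function(cl) tab[[cl]] != "none"))
  rep_tab <- tab[keep, ]

  dge_wide <- dge$table |>
    dplyr::select("gene_id", "age", "log2fc", "p_value", "q_value") |>
    tidyr::pivot_wider(names_from = "age",
                       values_from = c("log2fc", "p_value", "q_value"))
  names(dge_wide) <- tolower(names(dge_wide))
  rep_tab <- dplyr::left_join(rep_tab, dge_wide, by = "gene_id")

  prom <- annotated_peaks[annotated_peaks$region_class == "promoter", ]
  if (nrow(prom) > 0) {
    prom_first <- tidyr::separate_rows(prom, "gene_id", sep = ",") |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(gene_id = .data$gene_id,
                       peak_coords = paste0(.data$chrom, ":", .data$start,
                                            "-", .data$end),
                       peak_p_value = .data$p_value,
                       peak_tss_distance = .data$tss_distance)
    rep_tab <- dplyr::left_join(rep_tab, prom_first, by = "gene_id")
  } else {
    rep_tab$peak_coords <- NA_character_
    rep_tab$peak_p_value <- NA_real_
    rep_tab$peak_tss_distance <- NA_real_
  }

  if (!is.null(xbox_hits) && nrow(xbox_hits) > 0) {
    best_hit <- xbox_hits |>
      dplyr::group_by(gene_id = .data$seq_id) |>
      dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$gene_id, xbox_offset = .data$offset,
                       xbox_score = .data$score)
    rep_tab <- dplyr::left_join(rep_tab, best_hit, by = "gene_id")
  } else {
    rep_tab$xbox_offset <- NA_integer_
    rep_tab$xbox_score <- NA_real_
  }

  if (!is.null(cilia_evidence)) {
    rep_tab <- dplyr::left_join(
      rep_tab,
      cilia_evidence |>
        dplyr::select("gene_id", cilia_gold = "gold", cilia_low = "low",
                      cilia_medium = "medium", cilia_high = "high"),
      by = "gene_id")
  }
  dplyr::arrange(rep_tab, .data$gene_id)
}
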