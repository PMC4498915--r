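# Differential expression: median-of-ratios normalization, moment dispersion
# estimation with trend shrinkage, and a conditional negative-binomial exact
# test for two-group contrasts.

count_matrix <- function(counts) {
  stopifnot("gene_id" %in% names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  m
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median ratio of each
#' sample's counts to the per-gene geometric mean across samples, using only
#' genes with all-positive counts, then rescaled so the factors have
#' geometric mean 1. A single-sample matrix gets factor 1.
#'
#' @param counts Wide count tibble (`gene_id` + one column per sample) or a
#'   numeric matrix with genes as rows.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10L, 20L),
#'                          s2 = c(30L, 60L))
#' compute_size_factors(counts)
compute_size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  if (ncol(m) == 1) {
    return(stats::setNames(1, colnames(m)))
  }
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop(paste("no gene has positive counts in every sample;",
               "consider total-count normalization"), call. = FALSE)
  }
  lg <- log(m[usable, , drop = FALSE])
  ref <- rowMeans(lg) # log geometric mean per gene
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Per-gene dispersion with trend shrinkage
#'
#' Method-of-moments dispersion on size-factor-normalized counts, pooled
#' across replicate groups: for each group with >= 2 replicates,
#' `alpha_g = (var - mean * mean(1/sf)) / mean^2`; per-gene estimates are the
#' df-weighted average across groups, floored at zero. Raw estimates are then
#' shrunk toward a mean-dispersion trend (lowess of the raw estimates on log
#' mean) with `prior_df` prior degrees of freedom, and floored at `1e-8`.
#'
#' @param counts Wide count tibble or matrix.
#' @param size_factors Size factors as from [compute_size_factors()].
#' @param groups Factor/character vector assigning each sample to a replicate
#'   group.
#' @param prior_df Prior degrees of freedom pulling toward the trend
#'   (default 20).
#' @return A tibble: `gene_id`, `mean_norm`, `alpha_raw`, `alpha_trend`,
#'   `alpha` (shrunken, used for testing).
#' @export
estimate_dispersion <- function(counts, size_factors, groups, prior_df = 20) {
  m <- if (is.matrix(counts)) counts else count_matrix(counts)
  stopifnot(length(size_factors) == ncol(m), length(groups) == ncol(m))
  q <- sweep(m, 2, size_factors, `/`)
  groups <- as.character(groups)
  gs <- split(seq_len(ncol(m)), groups)
  gs <- gs[vapply(gs, length, 1L) >= 2]
  if (length(gs) == 0) {
    stop("need >= 2 replicates in at least one group", call. = FALSE)
  }

  num <- rep(0, nrow(m))
  den <- rep(0, nrow(m))
  df_tot <- 0
  for (idx in gs) {
    n_g <- length(idx)
    mu_g <- rowMeans(q[, idx, drop = FALSE])
    v_g <- apply(q[, idx, drop = FALSE], 1, stats::var)
    shot <- mu_g * mean(1 / size_factors[idx]) # Poisson part of the variance
    # E[mu_g^2] = mu^2 + var/n, so subtract v/n from the squared mean to
    # de-bias the moment estimator at small replicate numbers
    denom <- pmax(mu_g^2 - v_g / n_g, 0.5 * mu_g^2)
    a_g <- ifelse(mu_g > 0, (v_g - shot) / denom, 0)
    w <- n_g - 1
    num <- num + w * a_g
    den <- den + w
    df_tot <- df_tot + w
  }
  alpha_raw <- pmax(0, num / den)
  mean_norm <- rowMeans(q)

  # mean-dispersion trend on genes with signal
  ok <- mean_norm > 0
  if (sum(ok) >= 10) {
    lo <- stats::lowess(log10(mean_norm[ok]), alpha_raw[ok], f = 0.5)
    ux <- !duplicated(lo$x)
    trend_fun <- stats::approxfun(lo$x[ux], pmax(lo$y[ux], 1e-8), rule = 2)
    alpha_trend <- ifelse(ok, trend_fun(log10(pmax(mean_norm, 1e-8))),
                          median(alpha_raw[ok]))
  } else {
    alpha_trend <- rep(max(median(alpha_raw), 1e-8), nrow(m))
  }
  alpha <- pmax((df_tot * alpha_raw + prior_df * alpha_trend) /
                  (df_tot + prior_df), 1e-8)

  tibble(gene_id = rownames(m), mean_norm = mean_norm,
         alpha_raw = alpha_raw, alpha_trend = alpha_trend, alpha = alpha)
}

#' Negative-binomial exact test for a two-group contrast
#'
#' Conditions on the pooled total of the two groups: under the null of equal
#' means, the group-A sum given the total follows the distribution of one
#' NB(size `nA/alpha`, mean `sA * mu0`) variate conditioned on its sum with
#' an independent NB(size `nB/alpha`, mean `sB * mu0`) variate, where
#' `sA`/`sB` are the summed size factors (effective group sizes) and `mu0` is
#' the pooled normalized mean. The two-sided p-value is the total probability
#' of all allocations of the pooled total no more likely than the observed
#' one. As `alpha -> 0` this reduces to a conditional binomial test.
#'
#' @param counts_a,counts_b Integer count vectors for the two groups (one
#'   gene).
#' @param sf_a,sf_b Size factors of the samples in each group.
#' @param alpha Dispersion for this gene.
#' @return Two-sided p-value in (0, 1]. A zero pooled total returns 1.
#' @export
#' @examples
#' nb_exact_test(c(10L, 12L, 9L), c(50L, 55L, 60L), rep(1, 3), rep(1, 3), 0.1)
nb_exact_test <- function(counts_a, counts_b, sf_a = rep(1, length(counts_a)),
                          sf_b = rep(1, length(counts_b)), alpha = 1e-8) {
  stopifnot(length(counts_a) >= 1, length(counts_b) >= 1,
            length(sf_a) == length(counts_a), length(sf_b) == length(counts_b),
            alpha >= 0)
  ya <- sum(counts_a)
  yb <- sum(counts_b)
  s_total <- ya + yb
  if (s_total == 0) return(1)
  sa <- sum(sf_a)
  sb <- sum(sf_b)
  mu0 <- s_total / (sa + sb)
  size_a <- length(counts_a) / max(alpha, 1e-12)
  size_b <- length(counts_b) / max(alpha, 1e-12)
  a <- 0:s_total
  lp <- dnbinom(a, size = size_a, mu = sa * mu0, log = TRUE) +
    dnbinom(s_total - a, size = size_b, mu = sb * mu0, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  p_obs <- pr[ya + 1]
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Run differential expression for each age contrast
#'
#' Normalizes the count matrix by median-of-ratios, estimates shrunken
#' per-gene dispersions across all replicate groups, and applies the
#' negative-binomial exact test to the WT-vs-KO contrast at each age.
#' Fold-changes are computed from normalized group means with a pseudocount
#' of 0.5 (never from the test statistic); BH-adjusted q-values are reported
#' alongside the raw p-values used for set calls.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param samples Sample sheet with `sample_id`, `genotype` (WT/KO), `age`.
#' @param thresholds A [dge_thresholds()].
#' @param gene_lengths Optional named vector of gene lengths in bp (for
#'   RPKM); `NA` RPKM columns if omitted.
#' @param prior_df Dispersion shrinkage prior df, see [estimate_dispersion()].
#' @return An object of class `dge_result`: list with `table` (tibble:
#'   `gene_id`, `age`, `mean_norm`, `log2fc`, `p_value`, `q_value`,
#'   `rpkm_wt`, `rpkm_ko`), `size_factors`, `dispersions`, `thresholds`.
#' @export
run_dge <- function(counts, samples, thresholds = dge_thresholds(),
                    gene_lengths = NULL, prior_df = 20) {
  m <- count_matrix(counts)
  stopifnot(setequal(colnames(m), samples$sample_id))
  m <- m[, samples$sample_id, drop = FALSE]
  sf <- compute_size_factors(m)
  groups <- paste(samples$genotype, samples$age, sep = "_")
  disp <- estimate_dispersion(m, sf, groups, prior_df = prior_df)
  q <- sweep(m, 2, sf, `/`)

  total_reads <- colSums(m)
  len <- if (is.null(gene_lengths)) NULL else gene_lengths[rownames(m)]

  per_age <- lapply(sort(unique(samples$age)), function(age) {
    wt <- samples$sample_id[samples$genotype == "WT" & samples$age == age]
    ko <- samples$sample_id[samples$genotype == "KO" & samples$age == age]
    if (length(wt) == 0 || length(ko) == 0) return(NULL)
    mu_wt <- rowMeans(q[, wt, drop = FALSE])
    mu_ko <- rowMeans(q[, ko, drop = FALSE])
    p <- vapply(seq_len(nrow(m)), function(i) {
      nb_exact_test(m[i, wt], m[i, ko], sf[wt], sf[ko], disp$alpha[i])
    }, numeric(1))
    rpkm <- function(cols) {
      if (is.null(len)) return(rep(NA_real_, nrow(m)))
      r <- sweep(m[, cols, drop = FALSE] * 1e9, 2, total_reads[cols], `/`)
      rowMeans(r) / len
    }
    tibble(
      gene_id = rownames(m),
      age = age,
      mean_norm = (mu_wt + mu_ko) / 2,
      log2fc = log2((mu_ko + 0.5) / (mu_wt + 0.5)),
      p_value = p,
      q_value = p.adjust(p, method = "BH"),
      rpkm_wt = rpkm(wt),
      rpkm_ko = rpkm(ko)
    )
  })

  structure(list(
    table = dplyr::bind_rows(per_age),
    size_factors = sf,
    dispersions = disp,
    thresholds = thresholds
  ), class = "dge_result")
}

#' @export
print.dge_result <- function(x, ...) {
  cat("<dge_result> ", length(unique(x$table$gene_id)), " genes, ages: ",
      paste(unique(x$table$age), collapse = ", "), "\n", sep = "")
  print(utils::head(x$table))
  invisible(x)
}

#' Call tiered differential-expression sets
#'
#' For each age and fold tier k, the down-set is every gene with raw
#' `p < alpha` and fold-change at most `1/k` (log2fc <= -log2(k)); up-sets
#' are symmetric. Tiers are nested by construction: the 10-fold set is a
#' subset of the 3-fold set is a subset of the 2-fold set.
#'
#' @param dge A `dge_result`.
#' @param thresholds A [dge_thresholds()]; defaults to the thresholds stored
#'   in `dge`.
#' @return A long tibble: `age`, `direction` (down/up), `tier`, `gene_id`.
#' @export
call_de_sets <- function(dge, thresholds = dge$thresholds) {
  tab <- dge$table
  out <- list()
  for (age in unique(tab$age)) {
    t_age <- tab[tab$age == age & tab$p_value < thresholds$alpha, ]
    for (k in thresholds$fold_tiers) {
      out[[length(out) + 1]] <- tibble(
        age = age, direction = "down", tier = k,
        gene_id = t_age$gene_id[t_age$log2fc <= -log2(k)])
      out[[length(out) + 1]] <- tibble(
        age = age, direction = "up", tier = k,
        gene_id = t_age$gene_id[t_age$log2fc >= log2(k)])
    }
  }
  dplyr::bind_rows(out)
}

#' Extract one DE gene set
#'
#' @param sets Output of [call_de_sets()].
#' @param age,direction,tier Which set.
#' @return Character vector of gene ids.
#' @export
de_set <- function(sets, age, direction, tier = 2) {
  sets$gene_id[sets$age == age & sets$direction == direction &
                 sets$tier == tier]
}

#' Summaries of the differential-expression results
#'
#' Produces the plot-ready summary tables: cumulative gene counts as a
#' function of fold threshold (per age and direction), cross-age overlap
#' counts of the 2-fold sets (per direction), a P21-vs-P30 fold-change
#' scatter table for genes DE at either age, and an MA-style table (mean
#' normalized expression vs log2 fold-change).
#'
#' @param dge A `dge_result`.
#' @param sets Output of [call_de_sets()].
#' @param fold_grid Fold thresholds of the cumulative curve.
#' @return A list of tibbles: `curves`, `venn`, `scatter`, `ma`.
#' @export
de_summary <- function(dge, sets, fold_grid = c(2, 3, 5, 10, 20, 50)) {
  tab <- dge$table
  alpha <- dge$thresholds$alpha
  ages <- sort(unique(tab$age))

  curves <- tidyr::expand_grid(age = ages, direction = c("down", "up"),
                               fold_threshold = fold_grid) |>
    dplyr::rowwise() |>
    dplyr::mutate(n_genes = {
      t_age <- tab[tab$age == .data$age & tab$p_value < alpha, ]
      if (.data$direction == "down") {
        sum(t_age$log2fc <= -log2(.data$fold_threshold))
      } else {
        sum(t_age$log2fc >= log2(.data$fold_threshold))
      }
    }) |>
    dplyr::ungroup()

  venn <- NULL
  if (length(ages) == 2) {
    venn <- dplyr::bind_rows(lapply(c("down", "up"), function(dir) {
      s1 <- de_set(sets, ages[1], dir, 2)
      s2 <- de_set(sets, ages[2], dir, 2)
      tibble(direction = dir,
             n_age1 = length(s1), n_age2 = length(s2),
             n_both = length(intersect(s1, s2)))
    }))
    names(venn)[2:3] <- paste0("n_", tolower(ages))
  }

  de_any <- unique(sets$gene_id)
  wide <- tab |>
    dplyr::filter(.data$gene_id %in% de_any) |>
    dplyr::select("gene_id", "age", "log2fc") |>
    tidyr::pivot_wider(names_from = "age", values_from = "log2fc",
                       names_prefix = "log2fc_")
  names(wide) <- tolower(names(wide))

  ma <- tab[, c("gene_id", "age", "mean_norm", "log2fc", "p_value")]

  list(curves = curves, venn = venn, scatter = wide, ma = ma)
}
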