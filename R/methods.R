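# broom-style accessors and ggplot2 visualisations for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x A `dge_result`.
#' @param ... Unused.
#' @return The per-gene, per-age result tibble.
#' @export
tidy.dge_result <- function(x, ...) x$table

#' One-row summary of a differential-expression result
#'
#' @param x A `dge_result`.
#' @param ... Unused.
#' @return A tibble with one row per age: gene counts in the 2-fold down/up
#'   sets and the thresholds applied.
#' @export
glance.dge_result <- function(x, ...) {
  sets <- call_de_sets(x)
  dplyr::bind_rows(lapply(unique(x$table$age), function(age) {
    tibble(
      age = age,
      n_genes = sum(x$table$age == age),
      n_down2 = length(de_set(sets, age, "down", x$thresholds$fold_tiers[1])),
      n_up2 = length(de_set(sets, age, "up", x$thresholds$fold_tiers[1])),
      alpha = x$thresholds$alpha
    )
  }))
}

#' MA plot of a differential-expression result
#'
#' @param object A `dge_result`.
#' @param ... Unused.
#' @return A ggplot: log2 fold-change against mean normalized expression,
#'   faceted by age, significant genes highlighted.
#' @export
autoplot.dge_result <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       significant = .data$p_value < object$thresholds$alpha)
  ggplot2::ggplot(tab, ggplot2::aes(.data$mean_norm, .data$log2fc,
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$age)) +
    ggplot2::labs(x = "mean normalized expression", y = "log2 FC (KO/WT)",
                  colour = paste0("p < ", object$thresholds$alpha)) +
    ggplot2::theme_minimal()
}

#' Tidy a PWM into long format
#'
#' @param x A `pwm`.
#' @param ... Unused.
#' @return A tibble: `position`, `base`, `probability`.
#' @export
tidy.pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(ncol(x$mat)), each = 4),
    base = rep(rownames(x$mat), ncol(x$mat)),
    probability = as.numeric(x$mat)
  )
}

#' @rdname tidy.pwm
#' @export
tidy.motif_em <- function(x, ...) tidy(x$pwm)

#' One-row summary of a motif-discovery fit
#'
#' @param x A `motif_em`.
#' @param ... Unused.
#' @return A tibble: consensus, width, occurrence probability, log
#'   likelihood, number of EM iterations, inverted-repeat score.
#' @export
glance.motif_em <- function(x, ...) {
  tibble(
    consensus = x$consensus,
    width = ncol(x$pwm$mat),
    q = x$q,
    loglik = x$loglik,
    n_iter = length(x$loglik_trace),
    inverted_repeat_score = x$inverted_repeat_score
  )
}

#' Probability-matrix plot of a PWM or motif fit
#'
#' @param object A `pwm` or `motif_em`.
#' @param ... Unused.
#' @return A ggplot of per-position base probabilities.
#' @export
autoplot.pwm <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$position, .data$probability,
                               fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = "motif position", y = "probability") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.pwm
#' @export
autoplot.motif_em <- function(object, ...) autoplot(object$pwm, ...)

#' Tidy integrated target calls
#'
#' @param x A `target_calls`.
#' @param ... Unused.
#' @return The per-gene call tibble.
#' @export
tidy.target_calls <- function(x, ...) x$table

#' One-row summary of integrated target calls
#'
#' @param x A `target_calls`.
#' @param ... Unused.
#' @return A one-row tibble of the scalar headline counts (and precision /
#'   recall when a planted regulon was supplied).
#' @export
glance.target_calls <- function(x, ...) {
  s <- x$summary
  scal <- s[vapply(s, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  as_tibble(scal)
}

#' Histogram of peak-centre distances from the TSS
#'
#' @param annotated Output of [annotate_peaks()].
#' @param bin_width Bin width in bp.
#' @return A ggplot of promoter-peak TSS distances.
#' @export
plot_tss_distances <- function(annotated, bin_width = 50) {
  prom <- annotated[annotated$region_class == "promoter", ]
  ggplot2::ggplot(prom, ggplot2::aes(.data$tss_distance)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "peak centre - TSS (bp, downstream positive)",
                  y = "peaks") +
    ggplot2::theme_minimal()
}

#' Cumulative DE gene counts by fold threshold
#'
#' @param curves `curves` tibble from [de_summary()].
#' @return A ggplot of gene counts at or beyond each fold threshold.
#' @export
plot_de_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$fold_threshold, .data$n_genes,
                               colour = .data$age,
                               linetype = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fold-change threshold", y = "genes at or beyond") +
    ggplot2::theme_minimal()
}

#' Positional histogram of motif hits
#'
#' @param profile Output of [positional_profile()].
#' @param bin_width Bin width used (for bar width).
#' @return A ggplot of hit-centre distances from the anchor.
#' @export
plot_motif_positions <- function(profile, bin_width = 50) {
  ggplot2::ggplot(profile$histogram,
                  ggplot2::aes(.data$bin_start + bin_width / 2, .data$n)) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "darkorange") +
    ggplot2::labs(x = "motif centre - anchor (bp)", y = "hits") +
    ggplot2::theme_minimal()
}
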