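# Position weight matrices: construction, log-odds scanning on both strands,
# ZOOPS expectation-maximisation motif discovery, and set enrichment.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

seq_codes <- function(s) {
  match(strsplit(toupper(as.character(s)), "")[[1]], DNA_BASES)
}

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount/4) / (n + pseudocount)`,
#' so every column sums to one; with pseudocount 0 the matrix is the raw
#' frequency matrix, and as the pseudocount grows the columns approach
#' uniform.
#'
#' @param sites Character vector of equal-length DNA strings over ACGT.
#' @param pseudocount Total pseudocount spread over the four bases
#'   (default 0.5).
#' @param background Named base probabilities (sums to 1); default uniform.
#' @return An object of class `pwm`: list with `mat` (4 x L probabilities),
#'   `background`, `pseudocount`.
#' @export
#' @examples
#' build_pwm(c("ACGT", "ACGT", "ACGA"))
build_pwm <- function(sites, pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(length(sites) >= 1, pseudocount >= 0,
            abs(sum(background) - 1) < 1e-9)
  L <- unique(nchar(sites))
  if (length(L) != 1) stop("sites must share one length", call. = FALSE)
  codes <- vapply(sites, seq_codes, integer(L))
  if (anyNA(codes)) stop("sites must be over ACGT", call. = FALSE)
  counts <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L)) {
    tab <- tabulate(codes[j, ], nbins = 4)
    counts[, j] <- tab
  }
  new_pwm((counts + pseudocount / 4) / (length(sites) + pseudocount),
          background[DNA_BASES], pseudocount)
}

new_pwm <- function(mat, background, pseudocount = 0.5) {
  rownames(mat) <- DNA_BASES
  structure(list(mat = mat, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> width ", ncol(x$mat), ", consensus ", pwm_consensus(x),
      "\n", sep = "")
  print(round(x$mat, 3))
  invisible(x)
}

#' Consensus string of a PWM (per-column maximum base)
#' @param pwm A `pwm`.
#' @return A DNA string.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Maximum achievable log2-odds score of a PWM
#' @param pwm A `pwm`.
#' @param background Optional background overriding the PWM's own.
#' @return Score in bits.
#' @export
pwm_max_score <- function(pwm, background = pwm$background) {
  S <- log2(pwm$mat / background[DNA_BASES])
  sum(apply(S, 2, max))
}

# 4 x L log2-odds score matrix for the reverse strand: complement the rows
# and reverse the columns, so forward-coordinate scanning scores the reverse
# complement of the window.
revcomp_score_matrix <- function(S) {
  S[match(DNA_COMP[DNA_BASES], DNA_BASES), rev(seq_len(ncol(S))), drop = FALSE]
}

# scores of every offset of S (4 x L) along integer codes; NA codes (N) give
# -Inf so the position never passes a threshold
slide_scores <- function(codes, S) {
  L <- ncol(S)
  m <- length(codes) - L + 1
  if (m < 1) return(numeric(0))
  acc <- numeric(m)
  for (j in seq_len(L)) {
    v <- S[cbind(codes[j:(j + m - 1)], j)]
    acc <- acc + v
  }
  acc[is.na(acc)] <- -Inf
  acc
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every offset of every sequence as the sum of per-position log2
#' odds `log2(p_j(base) / background(base))`; the reverse strand is scored
#' on the reverse complement and reported in forward-strand coordinates.
#' Positions containing N never score. Hits are offsets scoring at least
#' `threshold` (default 60 percent of the PWM's maximum achievable score —
#' a permissive binary "contains the motif" call).
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param pwm A `pwm`.
#' @param threshold Minimum score in bits, or `NULL` for the 60% default.
#' @param background `NULL` to estimate a 0-order background from the
#'   scanned set (the default), or named base probabilities.
#' @return A tibble of hits: `seq_id`, `offset` (0-based, forward strand),
#'   `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = NULL, background = NULL) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  if (is.null(background)) background <- sequence_background(seqs)
  S <- log2(pwm$mat / background[DNA_BASES])
  if (is.null(threshold)) {
    threshold <- 0.6 * sum(apply(S, 2, max))
  }
  Sr <- revcomp_score_matrix(S)
  hits <- lapply(names(seqs), function(id) {
    codes <- seq_codes(seqs[[id]])
    fw <- slide_scores(codes, S)
    rv <- slide_scores(codes, Sr)
    rows <- list()
    hf <- which(fw >= threshold)
    if (length(hf)) {
      rows$f <- tibble(seq_id = id, offset = hf - 1L, strand = "+",
                       score = fw[hf])
    }
    hr <- which(rv >= threshold)
    if (length(hr)) {
      rows$r <- tibble(seq_id = id, offset = hr - 1L, strand = "-",
                       score = rv[hr])
    }
    dplyr::bind_rows(rows)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(seq_id = character(), offset = integer(),
                  strand = character(), score = numeric())
  }
  out
}

#' 0-order base composition of a sequence set
#' @param sequences Character vector or DNAStringSet.
#' @return Named probabilities over ACGT.
#' @export
sequence_background <- function(sequences) {
  tab <- table(factor(unlist(strsplit(toupper(as.character(sequences)), "")),
                      levels = DNA_BASES))
  p <- as.numeric(tab)
  if (sum(p) == 0) p <- rep(1, 4)
  stats::setNames(p / sum(p), DNA_BASES)
}

#' De novo motif discovery by ZOOPS expectation-maximisation
#'
#' Fits a zero-or-one-occurrence-per-sequence mixture: each sequence either
#' contains no motif occurrence (probability `1 - q`) or exactly one at a
#' uniformly chosen offset and strand. The E-step computes the posterior
#' over (absent, every offset x strand) under the current PWM and 0-order
#' background; the M-step re-estimates the PWM from posterior-weighted site
#' counts (so the likelihood never decreases) and `q` from the expected
#' occurrence probability; the `pseudocount` smooths only the final
#' reported PWM. Runs to a log-likelihood change below `tol` or `max_iter`
#' iterations; the best of `n_restarts` starting points by final likelihood
#' is returned. Starting points are the two most frequent words of the given
#' width across the sequence set plus random subsequences.
#'
#' @param sequences >= 10 sequences (character vector or DNAStringSet), each
#'   at least `width` long.
#' @param width Motif width (default 14).
#' @param n_restarts Number of starting points (default 4).
#' @param seed Seed for the random starting points.
#' @param max_iter,tol EM stopping rule.
#' @param pseudocount Smoothing pseudocount for the reported PWM.
#' @return A list of class `motif_em`: `pwm`, `consensus`, `q` (occurrence
#'   probability), `loglik`, `loglik_trace` (best restart),
#'   `inverted_repeat_score` (mean column-wise correlation between the PWM
#'   and its reverse complement), and `occurrences` (tibble: `seq_id`,
#'   `p_occurrence`, best `offset`, `strand`).
#' @export
discover_motif_em <- function(sequences, width = 14, n_restarts = 4,
                              seed = 1, max_iter = 500, tol = 1e-6,
                              pseudocount = 0.5) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  if (length(seqs) < 10) stop("need >= 10 sequences", call. = FALSE)
  if (any(nchar(seqs) < width)) {
    stop("every sequence must be at least `width` long", call. = FALSE)
  }
  codes <- lapply(seqs, seq_codes)
  bg <- sequence_background(seqs)
  lbg <- log(bg)

  starts <- em_start_words(seqs, width, n_restarts, seed)
  runs <- lapply(starts, function(word) {
    em_run(codes, width, word, bg, lbg, max_iter, tol, pseudocount)
  })
  best <- runs[[which.max(vapply(runs, function(r) r$loglik, numeric(1)))]]

  W <- best$W
  Wrc <- W[match(DNA_COMP[DNA_BASES], DNA_BASES),
           rev(seq_len(ncol(W))), drop = FALSE]
  ir <- mean(vapply(seq_len(ncol(W)), function(j) {
    suppressWarnings(cor(W[, j], Wrc[, j]))
  }, numeric(1)), na.rm = TRUE)

  pwm <- new_pwm(W, bg, pseudocount)
  structure(list(
    pwm = pwm,
    consensus = pwm_consensus(pwm),
    q = best$q,
    loglik = best$loglik,
    loglik_trace = best$trace,
    inverted_repeat_score = ir,
    occurrences = best$occurrences
  ), class = "motif_em")
}

#' @export
print.motif_em <- function(x, ...) {
  cat("<motif_em> consensus ", x$consensus, ", q = ", round(x$q, 3),
      ", logLik = ", round(x$loglik, 2),
      ", inverted-repeat score = ", round(x$inverted_repeat_score, 3),
      "\n", sep = "")
  invisible(x)
}

# starting words: the two most frequent width-mers, then random subsequences
em_start_words <- function(seqs, width, n_restarts, seed) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s) - width + 1
    if (n < 1) return(character(0))
    substring(s, 1:n, width:(width + n - 1))
  }))
  words <- words[!grepl("[^ACGT]", words)]
  tab <- sort(table(words), decreasing = TRUE)
  starts <- head(names(tab), 2)
  n_rand <- max(0, n_restarts - length(starts))
  if (n_rand > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    rand <- replicate(n_rand, {
      s <- sample(seqs, 1)
      o <- sample(nchar(s) - width + 1, 1)
      substr(s, o, o + width - 1)
    })
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    rand <- rand[!grepl("[^ACGT]", rand)]
    starts <- c(starts, rand)
  }
  unique(starts)
}

# one EM run from a seed word
em_run <- function(codes, width, word, bg, lbg, max_iter, tol, pseudocount) {
  W <- word_init_pwm(word, match_prob = 0.7)
  q <- 0.5
  n_seq <- length(codes)
  # constant background log-likelihood of every sequence (natural log)
  const_bg <- vapply(codes, function(cd) sum(lbg[cd]), numeric(1))
  trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    S <- log(W / bg[DNA_BASES]) # natural-log odds
    Sr <- revcomp_score_matrix(S)
    counts <- matrix(0, 4, width, dimnames = list(DNA_BASES, NULL))
    gamma_total <- 0
    occ_sum <- 0
    ll <- 0
    for (s in seq_len(n_seq)) {
      cd <- codes[[s]]
      fw <- slide_scores(cd, S)
      rv <- slide_scores(cd, Sr)
      m <- length(fw)
      lw_pos <- c(fw, rv) + log(q) - log(2 * m)
      lw_abs <- log1p(-q)
      mx <- max(lw_abs, lw_pos)
      z <- exp(lw_abs - mx) + sum(exp(lw_pos - mx))
      ll <- ll + mx + log(z) + const_bg[s]
      gam <- exp(lw_pos - mx) / z
      occ_sum <- occ_sum + sum(gam)
      # accumulate expected letter counts at each aligned column
      for (j in seq_len(width)) {
        lf <- cd[j:(j + m - 1)]
        cf <- tapply(gam[1:m], lf, sum)
        counts[as.integer(names(cf)), j] <- counts[as.integer(names(cf)), j] +
          cf
        # reverse-strand window at offset i covers the complement, reversed
        lr <- cd[(width - j + 1):(width - j + m)]
        comp <- c(4L, 3L, 2L, 1L)[lr]
        cr <- tapply(gam[(m + 1):(2 * m)], comp, sum)
        counts[as.integer(names(cr)), j] <- counts[as.integer(names(cr)), j] +
          cr
      }
      gamma_total <- gamma_total + sum(gam)
    }
    trace <- c(trace, ll)
    # exact MLE M-step (monotone in the likelihood); a tiny floor guards
    # against numerically vanished entries without meaningfully perturbing it
    W <- sweep(counts, 2, colSums(counts), `/`)
    W <- pmax(W, 1e-12)
    W <- sweep(W, 2, colSums(W), `/`)
    q <- min(max(occ_sum / n_seq, 1e-6), 1 - 1e-6)
    if (is.finite(ll_prev) && ll - ll_prev < tol) break
    ll_prev <- ll
  }
  # the reported PWM is pseudocount-smoothed for downstream scanning
  W <- sweep(counts + pseudocount / 4, 2, colSums(counts) + pseudocount, `/`)
  # final per-sequence occurrence summaries under the last parameters
  S <- log(W / bg[DNA_BASES])
  Sr <- revcomp_score_matrix(S)
  occ <- lapply(seq_len(n_seq), function(s) {
    cd <- codes[[s]]
    fw <- slide_scores(cd, S)
    rv <- slide_scores(cd, Sr)
    m <- length(fw)
    lw_pos <- c(fw, rv) + log(q) - log(2 * m)
    lw_abs <- log1p(-q)
    mx <- max(lw_abs, lw_pos)
    z <- exp(lw_abs - mx) + sum(exp(lw_pos - mx))
    best <- which.max(lw_pos)
    tibble(
      seq_id = names(codes)[s] %||% paste0("seq", s),
      p_occurrence = sum(exp(lw_pos - mx)) / z,
      offset = as.integer((best - 1) %% m),
      strand = if (best <= m) "+" else "-"
    )
  })
  list(W = W, q = q, loglik = trace[length(trace)], trace = trace,
       occurrences = dplyr::bind_rows(occ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

word_init_pwm <- function(word, match_prob = 0.7) {
  cd <- seq_codes(word)
  W <- matrix((1 - match_prob) / 3, 4, length(cd),
              dimnames = list(DNA_BASES, NULL))
  W[cbind(cd, seq_along(cd))] <- match_prob
  W
}

#' Motif enrichment of a foreground gene set
#'
#' Counts motif-containing promoters (>= 1 PWM hit at the scan threshold) in
#' disjoint foreground and background gene sets and tests enrichment with
#' the hypergeometric upper tail (one-sided Fisher test).
#'
#' @param fg,bg Disjoint character vectors of gene ids; `fg` must be
#'   non-empty.
#' @param promoters Named sequences (names = gene ids) covering `fg` and
#'   `bg`.
#' @param pwm A `pwm`.
#' @param threshold Scan threshold (see [scan_pwm()]).
#' @return A list: `table` (2 x 2 counts tibble), `p_value`.
#' @export
motif_enrichment <- function(fg, bg, promoters, pwm, threshold = NULL) {
  if (length(fg) == 0) stop("empty foreground set", call. = FALSE)
  if (length(intersect(fg, bg)) > 0) {
    stop("foreground and background must be disjoint", call. = FALSE)
  }
  seqs <- as.character(promoters)
  names(seqs) <- names(promoters)
  ids <- c(fg, bg)
  missing <- setdiff(ids, names(seqs))
  if (length(missing) > 0) {
    stop(sprintf("no promoter sequence for %d gene(s), e.g. '%s'",
                 length(missing), missing[1]), call. = FALSE)
  }
  hits <- scan_pwm(seqs[ids], pwm, threshold = threshold)
  has_motif <- ids %in% unique(hits$seq_id)
  k <- sum(has_motif[seq_along(fg)])
  K <- sum(has_motif)
  N <- length(ids)
  n <- length(fg)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(
    table = tibble(
      set = c("foreground", "background"),
      with_motif = c(k, K - k),
      without_motif = c(n - k, (N - n) - (K - k))
    ),
    p_value = p
  )
}

#' Positional profile of motif hits around an anchor
#'
#' Signed distances of hit centres from a per-sequence anchor (e.g. the TSS
#' position inside a promoter sequence, or the summit position inside a peak
#' sequence), histogrammed at `bin_width`. Sequences are assumed already
#' anchor-oriented (promoter sequences from [promoter_sequences()] are in
#' gene orientation), so no strand flip is applied here.
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param anchors Named numeric vector: anchor offset within each sequence.
#' @param motif_width Motif width (to centre the hit).
#' @param bin_width Histogram bin width in bp.
#' @return A list: `distances` (tibble `seq_id`, `distance`), `histogram`
#'   (tibble `bin_start`, `n`).
#' @export
positional_profile <- function(hits, anchors, motif_width, bin_width = 50) {
  if (nrow(hits) == 0) {
    return(list(distances = tibble(seq_id = character(), distance = numeric()),
                histogram = tibble(bin_start = numeric(), n = integer())))
  }
  a <- unname(anchors[hits$seq_id])
  d <- hits$offset + motif_width / 2 - a
  distances <- tibble(seq_id = hits$seq_id, distance = d)
  b <- floor(d / bin_width) * bin_width
  histogram <- tibble(bin_start = b) |>
    dplyr::count(.data$bin_start, name = "n") |>
    dplyr::arrange(.data$bin_start)
  list(distances = distances, histogram = histogram)
}
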