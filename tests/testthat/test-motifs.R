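# PWM construction and scanning, ZOOPS EM discovery, set enrichment

test_that("PWM probabilities follow the pseudocount formula", {
  # one-hot limit: pseudocount 0 puts all mass on the observed base
  p0 <- build_pwm(c("ACGT", "ACGT"), pseudocount = 0)
  expect_equal(unname(p0$mat[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(diag(p0$mat[c("A", "C", "G", "T"), ])), rep(1, 4))

  # generic case: (count + pc/4) / (n + pc)
  p <- build_pwm(c("AA", "AC", "GC"), pseudocount = 0.5)
  expect_equal(unname(p$mat["A", 1]), (2 + 0.125) / 3.5)
  expect_equal(unname(p$mat["G", 1]), (1 + 0.125) / 3.5)
  expect_equal(unname(p$mat["T", 1]), 0.125 / 3.5)
  expect_equal(unname(colSums(p$mat)), rep(1, 2), tolerance = 1e-12)

  # huge pseudocount limit: uniform columns
  pu <- build_pwm(c("AAAA"), pseudocount = 1e9)
  expect_equal(unname(pu$mat[, 1]), rep(0.25, 4), tolerance = 1e-6)

  expect_error(build_pwm(c("ACGT", "ACG")), "one length")
  expect_error(build_pwm("ACNT"), "ACGT")
})

test_that("scan scores equal the brute-force per-position log-odds sum", {
  set.seed(41)
  sites <- replicate(12, random_dna(8))
  pwm <- build_pwm(sites)
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  seqs <- stats::setNames(replicate(5, random_dna(50)), paste0("s", 1:5))

  # independent oracle: walk every window of every strand with strsplit
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle_score <- function(word, strand) {
    if (strand == "-") {
      word <- paste(rev(comp[strsplit(word, "")[[1]]]), collapse = "")
    }
    ch <- strsplit(word, "")[[1]]
    sum(vapply(seq_along(ch), function(j)
      log2(pwm$mat[ch[j], j] / bg[ch[j]]), 1))
  }
  hits <- scan_pwm(seqs, pwm, threshold = -Inf, background = bg)
  expect_equal(nrow(hits), 5 * (50 - 8 + 1) * 2)
  for (i in sample(nrow(hits), 40)) {
    word <- substr(seqs[hits$seq_id[i]], hits$offset[i] + 1,
                   hits$offset[i] + 8)
    expect_equal(hits$score[i], unname(oracle_score(word, hits$strand[i])),
                 tolerance = 1e-12)
  }
})

test_that("one-hot and uniform PWMs have the expected score anatomy", {
  one_hot <- build_pwm("ACGT", pseudocount = 0)
  # perfect match scores log2(1/0.25) per position = 2 * 4 = 8 bits;
  # ACGT is its own reverse complement so both strands hit
  h <- scan_pwm(c(x = "ACGT"), one_hot, threshold = 7.9,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(nrow(h), 2)
  expect_setequal(h$strand, c("+", "-"))
  expect_equal(h$score, c(8, 8))
  expect_equal(pwm_max_score(one_hot,
                             c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)), 8)

  # uniform PWM scores 0 everywhere against a uniform background
  unif <- new_pwm(matrix(0.25, 4, 6), c(A = .25, C = .25, G = .25, T = .25))
  hu <- scan_pwm(c(x = random_dna(30, seed = 5)), unif, threshold = -Inf,
                 background = c(A = .25, C = .25, G = .25, T = .25))
  expect_true(all(abs(hu$score) < 1e-12))
})

test_that("positions containing N never reach the threshold", {
  pwm <- build_pwm(c("ACGT", "ACGT"))
  h <- scan_pwm(c(x = "ANGTACGT"), pwm, threshold = 1,
                background = c(A = .25, C = .25, G = .25, T = .25))
  expect_true(all(h$offset == 4L))
})

test_that("a palindromic motif scores both strands identically", {
  pal <- "GTTGCCATGGCAAC"  # reverse complement of itself
  pwm <- build_pwm(rep(pal, 5))
  seq <- stats::setNames(paste0(random_dna(20, seed = 6), pal,
                                random_dna(20)), "s")
  h <- scan_pwm(seq, pwm, background = c(A = .25, C = .25, G = .25, T = .25))
  both <- h[h$offset == 20L, ]
  expect_setequal(both$strand, c("+", "-"))
  expect_equal(both$score[1], both$score[2], tolerance = 1e-12)
})

test_that("scanning the reverse complement mirrors hits across strands", {
  set.seed(44)
  pwm <- build_pwm(replicate(10, random_dna(9)))
  s <- random_dna(60)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s_rc <- paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  h1 <- scan_pwm(c(x = s), pwm, threshold = 2, background = bg)
  h2 <- scan_pwm(c(x = s_rc), pwm, threshold = 2, background = bg)
  expect_equal(nrow(h1), nrow(h2))
  # a forward hit at offset o maps to a reverse hit at L - w - o
  m1 <- h1[order(h1$offset, h1$strand), ]
  m2 <- h2[order(-h2$offset, h2$strand), ]
  expect_equal(m1$offset, 60 - 9 - m2$offset)
  expect_equal(sort(m1$score), sort(m2$score), tolerance = 1e-12)
})

test_that("EM recovers a planted palindrome and its likelihood never drops", {
  set.seed(45)
  pal <- "GTTGCCATGGCAAC"
  seqs <- vapply(1:30, function(i) {
    s <- random_dna(120)
    off <- sample(0:(120 - 14), 1)
    paste0(substr(s, 1, off), pal, substr(s, off + 15, 120))
  }, "")
  fit <- discover_motif_em(seqs, width = 14, n_restarts = 3, seed = 45,
                           max_iter = 100)
  expect_equal(fit$consensus, pal)
  expect_gt(fit$q, 0.8)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_gt(fit$inverted_repeat_score, 0.9)
  # the posterior localizes the occurrence in (almost) every sequence
  expect_gt(mean(fit$occurrences$p_occurrence > 0.5), 0.9)
})

test_that("EM on pure background finds no confident occurrence structure", {
  set.seed(46)
  seqs <- replicate(25, random_dna(100))
  fit <- discover_motif_em(seqs, width = 14, n_restarts = 2, seed = 46,
                           max_iter = 60)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  # whatever word it latches onto is not an inverted repeat
  expect_lt(fit$inverted_repeat_score, 0.9)
  expect_error(discover_motif_em(seqs[1:5]), ">= 10")
  expect_error(discover_motif_em(c(seqs, "ACGT")), "at least")
})

test_that("hypergeometric enrichment reproduces the closed-form worked case", {
  # universe 20, foreground 5, motif carriers 4, overlap 3:
  # P(X >= 3) = [C(4,3)C(16,2) + C(4,4)C(16,1)] / C(20,5) = 496/15504
  pal <- "GTTGCCATGGCAAC"
  pwm <- build_pwm(rep(pal, 3))
  set.seed(47)
  ids <- sprintf("g%02d", 1:20)
  proms <- stats::setNames(replicate(20, random_dna(200)), ids)
  carriers <- c("g01", "g02", "g03", "g06")
  for (g in carriers) {
    proms[g] <- paste0(substr(proms[g], 1, 80), pal,
                       substr(proms[g], 95, 200))
  }
  fg <- c("g01", "g02", "g03", "g04", "g05")
  res <- motif_enrichment(fg, setdiff(ids, fg), proms, pwm, threshold = 20)
  expect_equal(res$table$with_motif, c(3, 1))
  expect_equal(res$table$without_motif, c(2, 14))
  oracle <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
    choose(20, 5)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)

  expect_error(motif_enrichment(character(), ids, proms, pwm), "empty")
  expect_error(motif_enrichment(fg, ids, proms, pwm), "disjoint")
  expect_error(motif_enrichment(c(fg, "nope"), setdiff(ids, fg), proms, pwm),
               "no promoter sequence")
})

test_that("positional profiles centre hits and bin them on a fixed grid", {
  hits <- tibble::tibble(seq_id = c("a", "a", "b"),
                         offset = c(10L, 96L, 43L),
                         strand = c("+", "-", "+"),
                         score = 5)
  anchors <- c(a = 100, b = 50)
  pp <- positional_profile(hits, anchors, motif_width = 14, bin_width = 50)
  expect_equal(pp$distances$distance, c(10 + 7 - 100, 96 + 7 - 100,
                                        43 + 7 - 50))
  expect_equal(pp$histogram$bin_start, c(-100, 0))
  expect_equal(pp$histogram$n, c(1L, 2L))

  empty <- positional_profile(hits[0, ], anchors, 14)
  expect_equal(nrow(empty$distances), 0)
})
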