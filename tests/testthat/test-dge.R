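# normalization, dispersion, NB exact test and tiered set calls

# independent oracle: enumerate every allocation of the pooled total between
# the group sums and add up the probabilities of those no more likely than
# the observed split (plain loop, no shared code with the implementation)
enumerate_exact_p <- function(a, b, sfa, sfb, alpha) {
  S <- sum(a) + sum(b)
  if (S == 0) return(1)
  mu0 <- S / (sum(sfa) + sum(sfb))
  pr <- numeric(S + 1)
  for (k in 0:S) {
    pr[k + 1] <- dnbinom(k, size = length(a) / alpha, mu = sum(sfa) * mu0) *
      dnbinom(S - k, size = length(b) / alpha, mu = sum(sfb) * mu0)
  }
  pr <- pr / sum(pr)
  obs <- pr[sum(a) + 1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

test_that("size factors recover exact scaling and ignore all-zero rows", {
  set.seed(1)
  base <- matrix(rpois(200, 50), ncol = 2,
                 dimnames = list(sprintf("g%03d", 1:100), c("A", "B")))
  base[, 2] <- base[, 1] * 3
  sf <- compute_size_factors(base)
  expect_equal(unname(sf["B"] / sf["A"]), 3, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  with_zero <- rbind(base, zero1 = c(0L, 0L), zero2 = c(0L, 0L))
  expect_equal(compute_size_factors(with_zero), sf)

  single <- base[, 1, drop = FALSE]
  expect_equal(unname(compute_size_factors(single)), 1)

  allzero <- matrix(0L, 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  expect_error(compute_size_factors(allzero), "total-count")
})

test_that("size factors agree with the DESeq2 median-of-ratios up to scale", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(500 * 6, mu = rep(exp(runif(500, 2, 7)), 6), size = 5),
              ncol = 6, dimnames = list(NULL, paste0("s", 1:6)))
  depth <- c(1, 1.5, 0.7, 2, 1, 0.9)
  m <- matrix(rpois(length(m), sweep(m, 2, depth, `*`)), nrow = nrow(m),
              dimnames = dimnames(m))
  ours <- compute_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]), tolerance = 1e-8)
})

test_that("dispersion estimation hits the floor, the truth, and the Poisson limit", {
  # identical counts within groups -> zero variance -> floored raw estimate
  m <- matrix(rep(c(10L, 10L, 10L, 40L, 40L, 40L), 3), nrow = 3,
              byrow = TRUE, dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  d <- estimate_dispersion(m, rep(1, 6), rep(c("g1", "g2"), each = 3))
  expect_true(all(d$alpha_raw == 0))

  # simulated NB genes at alpha = 0.1: median estimate near the truth
  set.seed(3)
  n <- 10000
  mu <- exp(runif(n, 3, 6))
  sim <- matrix(rnbinom(n * 6, mu = rep(mu, 6), size = 10), ncol = 6,
                dimnames = list(sprintf("g%05d", 1:n), paste0("s", 1:6)))
  ds <- estimate_dispersion(sim, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_gt(median(ds$alpha), 0.08)
  expect_lt(median(ds$alpha), 0.12)

  # Poisson data: median estimate collapses toward zero
  simp <- matrix(rpois(n * 6, rep(mu, 6)), ncol = 6,
                 dimnames = dimnames(sim))
  dp <- estimate_dispersion(simp, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_lt(median(dp$alpha), 0.01)
})

test_that("exact test symmetry: balanced data gives p = 1, labels commute", {
  expect_equal(nb_exact_test(c(10L, 10L), c(10L, 10L), alpha = 0.1), 1)
  p_ab <- nb_exact_test(c(3L, 9L, 6L), c(20L, 30L, 25L), alpha = 0.2)
  p_ba <- nb_exact_test(c(20L, 30L, 25L), c(3L, 9L, 6L), alpha = 0.2)
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
  expect_equal(nb_exact_test(0L, 0L), 1)
})

test_that("exact test reduces to the doubled-tail binomial as alpha -> 0", {
  # A = 0, B = 20, equal effective sizes: conditional law is Binomial(20, 1/2);
  # oracle computed by enumerating all 21 allocations
  pr <- dbinom(0:20, 20, 0.5)
  oracle <- sum(pr[pr <= pr[1] * (1 + 1e-7)])
  p <- nb_exact_test(0L, 20L, 1, 1, alpha = 1e-10)
  expect_equal(p, oracle, tolerance = 1e-8)
})

test_that("exact test matches brute-force enumeration on random small cases", {
  set.seed(4)
  worst <- 0
  for (i in 1:50) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- as.integer(rnbinom(na, mu = runif(1, 1, 40), size = 5))
    b <- as.integer(rnbinom(nb, mu = runif(1, 1, 40), size = 5))
    sfa <- runif(na, 0.5, 2); sfb <- runif(nb, 0.5, 2)
    alpha <- runif(1, 0.01, 0.5)
    p1 <- nb_exact_test(a, b, sfa, sfb, alpha)
    p2 <- enumerate_exact_p(a, b, sfa, sfb, alpha)
    worst <- max(worst, abs(p1 - p2))
  }
  expect_lt(worst, 1e-10)
})

test_that("set calls apply the study thresholds and tiers are nested", {
  dge <- structure(list(
    table = tibble::tibble(
      gene_id = c("a", "b", "c", "d"),
      age = "P21",
      mean_norm = 100,
      log2fc = c(-2, -1.9, -3.5, 1.2),
      p_value = c(0.005, 0.5, 1e-6, 0.003),
      q_value = NA_real_, rpkm_wt = NA_real_, rpkm_ko = NA_real_),
    thresholds = dge_thresholds()), class = "dge_result")
  sets <- call_de_sets(dge)
  expect_true("a" %in% de_set(sets, "P21", "down", 2))
  expect_false("a" %in% de_set(sets, "P21", "down", 10))
  expect_false("b" %in% sets$gene_id)      # p too large
  expect_true("c" %in% de_set(sets, "P21", "down", 10))
  expect_true("d" %in% de_set(sets, "P21", "up", 2))
  # nesting
  for (dir in c("down", "up")) {
    s10 <- de_set(sets, "P21", dir, 10)
    s3 <- de_set(sets, "P21", dir, 3)
    s2 <- de_set(sets, "P21", dir, 2)
    expect_true(all(s10 %in% s3) && all(s3 %in% s2))
  }
  # empty result -> empty sets
  dge0 <- dge
  dge0$table <- dge$table[0, ]
  expect_equal(nrow(call_de_sets(dge0)), 0)
})

test_that("summary curves, venn and scatter follow their definitions", {
  dge <- structure(list(
    table = tibble::tibble(
      gene_id = rep(c("a", "b", "c", "d"), 2),
      age = rep(c("P21", "P30"), each = 4),
      mean_norm = 50,
      log2fc = c(-log2(2.5), -2, -log2(12), 0,
                 -1.5, -2, 0.1, -1.1),
      p_value = c(0.001, 0.001, 0.001, 0.9,
                  0.001, 0.001, 0.9, 0.001),
      q_value = NA_real_, rpkm_wt = NA_real_, rpkm_ko = NA_real_),
    thresholds = dge_thresholds()), class = "dge_result")
  sets <- call_de_sets(dge)
  s <- de_summary(dge, sets, fold_grid = c(2, 10))
  cur <- s$curves
  expect_equal(cur$n_genes[cur$age == "P21" & cur$direction == "down" &
                             cur$fold_threshold == 2], 3)
  expect_equal(cur$n_genes[cur$age == "P21" & cur$direction == "down" &
                             cur$fold_threshold == 10], 1)
  # down(P21) = {a,b,c}; down(P30) = {a,b,d} -> overlap 2
  expect_equal(s$venn$n_both[s$venn$direction == "down"], 2)
  expect_true(all(c("log2fc_p21", "log2fc_p30") %in% names(s$scatter)))
})

test_that("rescaling one sample moves only its size factor", {
  gen <- tiny_genome(seed = 23)
  cfg <- tiny_config(seed = 23)
  cnt <- simulate_counts(gen$annotation, gen$regulon, cfg)
  m <- as.matrix(cnt$counts[, -1])
  rownames(m) <- cnt$counts$gene_id
  sf1 <- compute_size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  sf2 <- compute_size_factors(m2)
  expect_equal(unname(sf2[3] / sf1[3] / (sf2[1] / sf1[1])), 4,
               tolerance = 1e-9)
  # p-values are stable under the rescaling up to integer conditioning
  sam <- cnt$samples
  wt <- sam$sample_id[sam$genotype == "WT" & sam$age == "P21"]
  ko <- sam$sample_id[sam$genotype == "KO" & sam$age == "P21"]
  p1 <- vapply(1:20, function(i)
    nb_exact_test(m[i, wt], m[i, ko], sf1[wt], sf1[ko], 0.1), 1)
  p2 <- vapply(1:20, function(i)
    nb_exact_test(m2[i, wt], m2[i, ko], sf2[wt] / exp(mean(log(sf2 / sf1))),
                  sf2[ko] / exp(mean(log(sf2 / sf1))), 0.1), 1)
  expect_gt(cor(log(p1), log(p2)), 0.95)
})

test_that("the exact test broadly agrees with the edgeR exact test", {
  skip_if_not_installed("edgeR")
  gen <- tiny_genome(n_genes = 80, n_targets = 10, seed = 24)
  cfg <- tiny_config(n_genes = 80, n_targets = 10, seed = 24)
  cnt <- simulate_counts(gen$annotation, gen$regulon, cfg)
  m <- as.matrix(cnt$counts[, -1])
  rownames(m) <- cnt$counts$gene_id
  sam <- cnt$samples
  keep <- sam$age == "P21"
  y <- edgeR::DGEList(m[, keep], group = sam$genotype[keep])
  y <- edgeR::calcNormFactors(y)
  sf <- rep(1, sum(keep))
  wt <- which(sam$genotype[keep] == "WT")
  ko <- which(sam$genotype[keep] == "KO")
  ours <- vapply(seq_len(nrow(m)), function(i)
    nb_exact_test(m[i, keep][wt], m[i, keep][ko], sf[wt], sf[ko], 0.1), 1)
  theirs <- edgeR::exactTest(y, dispersion = 0.1)$table$PValue
  # same ranking and similar scale
  expect_gt(cor(log(ours), log(theirs), method = "spearman"), 0.97)
})
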