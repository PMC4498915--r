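# profile classification, cilia flags, evidence integration and set overlap

test_that("profile classification applies floor, correlation and rise rules", {
  days <- c(7, 14, 17, 21, 30)
  ref <- reference_trajectory(days)
  prof <- dplyr::bind_rows(
    tibble::tibble(gene_id = "rising", day = days, rpkm = 10 * ref),
    tibble::tibble(gene_id = "weak", day = days, rpkm = 0.5 * ref),
    tibble::tibble(gene_id = "flat", day = days, rpkm = 5),
    tibble::tibble(gene_id = "falling", day = days, rpkm = rev(10 * ref)),
    tibble::tibble(gene_id = "shallow", day = days,
                   rpkm = 5 + 5 * ref)  # correlated but rise < 4-fold
  )
  cl <- classify_profiles(prof)
  get <- function(g) cl$status[cl$gene_id == g]
  expect_equal(get("rising"), "consistent")
  expect_equal(get("weak"), "not_evaluable")   # max rpkm below 1
  expect_equal(get("flat"), "inconsistent")
  expect_equal(get("falling"), "inconsistent")
  expect_equal(get("shallow"), "inconsistent")
  expect_equal(cl$correlation[cl$gene_id == "rising"], 1, tolerance = 1e-12)
  expect_gt(cl$rise_fold[cl$gene_id == "rising"], 4)
})

test_that("cilia flags follow gold-or-high-citation, absent genes negative", {
  ev <- tibble::tibble(
    gene_id = c("gold_only", "high_only", "low_only", "nothing"),
    gold = c(TRUE, FALSE, FALSE, FALSE),
    low = c(0L, 0L, 3L, 0L),
    medium = c(0L, 0L, 2L, 0L),
    high = c(0L, 2L, 0L, 0L))
  fl <- flag_cilia(c("gold_only", "high_only", "low_only", "nothing",
                     "not_in_db"), ev)
  expect_equal(fl$cilia, c(TRUE, TRUE, FALSE, FALSE, FALSE))

  fr <- cilia_fractions(list(a = c("gold_only", "low_only"),
                             b = character()), ev)
  expect_equal(fr$fraction[fr$set == "a"], 0.5)
  expect_true(is.na(fr$fraction[fr$set == "b"]))
})

test_that("direct-target logic is ChIP-bound AND differentially expressed", {
  genes <- c("both", "chip_only", "de_only", "neither", "both_up")
  de_sets <- tibble::tibble(
    age = c("P21", "P21", "P30"),
    direction = c("down", "up", "down"),
    tier = 2,
    gene_id = c("both", "both_up", "de_only"))
  calls <- call_direct_targets(genes, c("both", "chip_only", "both_up"),
                               de_sets, xbox_genes = "both")
  tab <- calls$table
  expect_equal(tab$direct_target,
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(tab$de_p21[tab$gene_id == "both"], "down")
  expect_equal(tab$de_p30[tab$gene_id == "both"], "none")
  expect_equal(calls$summary$n_direct_targets, 2)
  expect_equal(calls$summary$n_direct_down, 1)
  expect_equal(calls$summary$n_direct_up, 1)
  expect_equal(calls$summary$n_de_with_xbox, 1)

  # independent oracle: naive set intersection over genes
  chip <- c("both", "chip_only", "both_up")
  de_any <- unique(de_sets$gene_id)
  expect_setequal(tab$gene_id[tab$direct_target], intersect(chip, de_any))
})

test_that("profile and cilia summaries count only evaluable down targets", {
  genes <- paste0("g", 1:6)
  de_sets <- tibble::tibble(age = "P21", direction = "down", tier = 2,
                            gene_id = c("g1", "g2", "g3", "g4"))
  prof <- tibble::tibble(
    gene_id = genes,
    status = c("consistent", "inconsistent", "not_evaluable",
               "consistent", "consistent", "flat_ignored"),
    correlation = NA_real_, rise_fold = NA_real_, max_rpkm = NA_real_)
  ev <- tibble::tibble(gene_id = genes,
                       gold = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
                       low = 0L, medium = 0L, high = 0L)
  calls <- call_direct_targets(genes, chip_targets = c("g1", "g2", "g3", "g5"),
                               de_sets = de_sets, profile_calls = prof,
                               cilia_evidence = ev)
  # direct down targets: g1, g2, g3; evaluable: g1, g2 -> 1/2 consistent
  pc <- calls$summary$profile_consistent_down_p21
  expect_equal(pc$n_evaluable, 2)
  expect_equal(pc$n_consistent, 1)
  expect_equal(pc$fraction, 0.5)
  # cilia: direct targets {g1,g2,g3} -> 1/3; background {g4,g5,g6} -> 1/3
  expect_equal(calls$summary$cilia_fraction_direct_targets, 1 / 3)
  expect_equal(calls$summary$cilia_fraction_background, 1 / 3)
})

test_that("precision and recall against a planted regulon are exact", {
  genes <- paste0("g", 1:10)
  regulon <- tibble::tibble(gene_id = c("g1", "g2", "g3"), role = "target")
  de_sets <- tibble::tibble(age = "P30", direction = "down", tier = 2,
                            gene_id = c("g1", "g2", "g4"))
  calls <- call_direct_targets(genes, c("g1", "g2", "g4", "g5"), de_sets,
                               regulon = regulon)
  # predicted: {g1, g2, g4}; truth: {g1, g2, g3}
  expect_equal(calls$summary$precision, 2 / 3)
  expect_equal(calls$summary$recall, 2 / 3)
})

test_that("set comparison matches closed forms and full enumeration", {
  universe <- letters[1:20]
  # disjoint sets
  d <- compare_gene_sets(letters[1:5], letters[6:9], universe)
  expect_equal(d$overlap, 0)
  expect_equal(d$jaccard, 0)
  expect_equal(d$p_deplete, phyper(0, 5, 15, 4))
  # identical sets: P(overlap >= |A|) = 1 / C(N, |A|)
  s <- compare_gene_sets(letters[1:4], letters[1:4], universe)
  expect_equal(s$jaccard, 1)
  expect_equal(s$p_enrich, 1 / choose(20, 4), tolerance = 1e-12)
  # worked case: N = 20, |A| = 5, |B| = 4, overlap 3
  w <- compare_gene_sets(letters[1:5], c("a", "b", "c", "t"), universe)
  expect_equal(w$overlap, 3)
  oracle <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) /
    choose(20, 4)
  expect_equal(w$p_enrich, oracle, tolerance = 1e-12)
  expect_equal(oracle, 155 / 4845, tolerance = 1e-12)

  # enumeration oracle: tail sums of the hypergeometric pmf by brute force
  pmf <- vapply(0:4, function(k)
    choose(5, k) * choose(15, 4 - k) / choose(20, 4), 1)
  expect_equal(w$p_enrich, sum(pmf[4:5]), tolerance = 1e-12)
  expect_equal(w$p_deplete, sum(pmf[1:4]), tolerance = 1e-12)

  expect_error(compare_gene_sets(c("zz"), letters[1:3], universe), "subsets")
})

test_that("the master report is deterministic, complete and gene-ordered", {
  cfg <- tiny_config(n_genes = 60, n_targets = 10, seed = 60)
  gen <- simulate_genome(cfg)
  cnt <- simulate_counts(gen$annotation, gen$regulon, cfg)
  dge <- run_dge(cnt$counts, cnt$samples)
  sets <- call_de_sets(dge)
  cov <- simulate_chip_coverage(gen$annotation, gen$regulon, cfg)
  pks <- filter_reproducible(lapply(cov$ip, call_peaks, input = cov$input))
  ap <- annotate_peaks(pks, gen$annotation, cfg$promoter_window)
  chip <- promoter_target_genes(ap)
  prom <- promoter_sequences(gen$genome, gen$annotation, cfg$promoter_window)
  pwm <- build_pwm(rep(cfg$motif_consensus, 3))
  hits <- scan_pwm(prom, pwm)
  ev <- simulate_cilia_evidence(gen$annotation, gen$regulon, cfg)
  calls <- call_direct_targets(gen$annotation$genes$gene_id, chip, sets,
                               xbox_genes = unique(hits$seq_id),
                               cilia_evidence = ev, regulon = gen$regulon)
  rep1 <- summary_report(calls, dge, ap, hits, ev)
  rep2 <- summary_report(calls, dge, ap, hits, ev)
  expect_identical(rep1, rep2)
  expect_identical(rep1$gene_id, sort(rep1$gene_id))
  # every ChIP target and every DE gene is present
  expect_true(all(chip$gene_id %in% rep1$gene_id))
  expect_true(all(sets$gene_id %in% rep1$gene_id))
  expect_true(all(c("log2fc_p21", "log2fc_p30", "peak_coords",
                    "xbox_offset", "cilia_gold") %in% names(rep1)))
  # direct targets recover the planted regulon well even at this small scale
  expect_gt(calls$summary$precision, 0.8)
  expect_gt(calls$summary$recall, 0.8)
})
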