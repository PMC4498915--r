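# shared fixture builders; everything is generated in code at test time

tiny_config <- function(n_genes = 40, n_targets = 6, n_indirect = 3,
                        seed = 42, ...) {
  sim_config(n_genes = n_genes, n_targets = n_targets,
             n_indirect = n_indirect, seed = seed, ...)
}

tiny_genome <- function(...) simulate_genome(tiny_config(...))

# a hand-built two-gene annotation on one chromosome, one gene per strand
toy_annotation <- function(chrom_len = 30000) {
  genes <- tibble::tibble(
    gene_id = c("gplus", "gminus"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(10000L, 20000L),
    end = c(12000L, 22000L),
    tss = c(10000L, 21999L)
  )
  exons <- tibble::tibble(
    gene_id = rep(c("gplus", "gminus"), each = 2),
    chrom = "chr1",
    start = c(10000L, 11600L, 20000L, 21600L),
    end = c(10400L, 12000L, 20400L, 22000L),
    exon_rank = c(1L, 2L, 1L, 2L)
  )
  genome_annotation(genes, exons, c(chr1 = chrom_len))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
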