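test_that("generation is deterministic under (config, seed)", {
  cfg <- community_config(n_genomes = 2L, seed = 7)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(as.character(a$contigs), as.character(b$contigs))
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth$hidden_orfs$start, b$truth$hidden_orfs$start)
  sa <- simulate_psms(a); sb <- simulate_psms(b)
  expect_identical(sa$psms$peptide, sb$psms$peptide)
  expect_identical(sa$psms$score, sb$psms$score)
})

test_that("hidden ORFs are planted but absent from the gene models", {
  cm <- fixture_community()
  ho <- cm$truth$hidden_orfs
  expect_equal(nrow(ho), cm$config$n_genomes * cm$config$n_hidden_orfs)
  contigs <- as.character(cm$contigs)
  for (i in seq_len(nrow(ho))) {
    # not among predicted genes (no identical interval)
    expect_false(any(cm$genes$contig_id == ho$contig_id[i] &
                       cm$genes$start == ho$start[i] &
                       cm$genes$end == ho$end[i]))
    # present in sequence: valid start codon, in-frame stop, clean body
    cds <- substr(contigs[[ho$contig_id[i]]], ho$start[i] + 1L, ho$end[i])
    stopc <- substr(contigs[[ho$contig_id[i]]], ho$end[i] + 1L, ho$end[i] + 3L)
    if (ho$strand[i] == "-") {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(contigs[[ho$contig_id[i]]],
                                     ho$start[i] - 2L, ho$end[i]))))
      cds <- substr(rc, 1, nchar(rc) - 3L)
      stopc <- substr(rc, nchar(rc) - 2L, nchar(rc))
    }
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(stopc %in% c("TAA", "TAG", "TGA"))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_equal(aa, ho$aa[i])
  }
})

test_that("planted operons are recoverable by gene clustering", {
  cm <- fixture_community()
  cand <- cluster_genes(cm$genes, max_gap = 100)
  key <- function(d) sort(paste(d$contig_id, d$start, d$end, d$strand))
  expect_equal(key(cand), key(cm$truth$operons))
})

test_that("proteome holds translations of gene models only", {
  cm <- fixture_community()
  expect_setequal(names(cm$proteome), cm$genes$gene_id)
  # spot-check translations against the contig sequence (unshared genomes)
  g3 <- cm$genes[genome == "G03"][1:5]
  contigs <- as.character(cm$contigs)
  for (i in seq_len(nrow(g3))) {
    cds <- substr(contigs[[g3$contig_id[i]]], g3$start[i] + 1L, g3$end[i])
    if (g3$strand[i] == "-")
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    aa <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(cds))))
    expect_equal(as.character(cm$proteome[[g3$gene_id[i]]]), aa)
  }
})

test_that("zero shared-peptide rate yields single-genome accession sets", {
  sim <- fixture_sim()
  cm <- fixture_community()
  tgt <- sim$psms[is_decoy == FALSE]
  genomes_hit <- vapply(tgt$accessions, function(a)
    length(unique(cm$truth$genome_of[a])), integer(1))
  expect_true(all(genomes_hit == 1L))
})

test_that("shared peptides appear between the designated genome pair", {
  cfg <- community_config(seed = 3, shared_peptide_rate = 0.05)
  cm <- generate_community(cfg)
  pm <- cm$truth$peptide_map
  shared <- pm[, .(ng = data.table::uniqueN(cm$truth$genome_of[protein_id])),
               by = peptide][ng > 1]
  expect_gt(nrow(shared), 0)
  sim <- simulate_psms(cm)
  k <- vapply(sim$psms[is_decoy == FALSE]$accessions, function(a)
    length(unique(cm$truth$genome_of[a])), integer(1))
  expect_gt(sum(k > 1), 0)
})

test_that("phenotype-specific proteins stay silent off-phenotype", {
  sim <- fixture_sim()
  cm <- fixture_community()
  spec <- cm$truth$phenotype_specific
  phen <- setNames(sim$manifest$phenotype, sim$manifest$sample_id)
  for (i in seq_len(min(nrow(spec), 10))) {
    off <- names(phen)[phen != spec$phenotype[i]]
    expect_true(all(sim$protein_counts[spec$protein_id[i], off] == 0))
  }
})

test_that("planted blocks are more correlated within than between", {
  cfg <- community_config(seed = 5, n_samples_per_phenotype = 13L,
                          phenotype_specific_fraction = 0)
  cm <- generate_community(cfg)
  sim <- simulate_psms(cm)  # 52 samples
  bl <- cm$truth$blocks
  cc <- cor(t(log1p(sim$protein_counts[bl$protein_id, ])))
  same <- outer(bl$block_id, bl$block_id, "==")
  diag(same) <- NA
  within <- mean(cc[which(same)], na.rm = TRUE)
  between <- mean(cc[which(!same)], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("true abundance ratios are recovered by quantification", {
  cfg <- community_config(n_genomes = 2L, seed = 11,
                          genome_abundance = c(3, 1),
                          sample_log_sd = 0.05,
                          phenotype_specific_fraction = 0,
                          n_samples_per_phenotype = 10L,
                          mean_depth = 6000)
  cm <- generate_community(cfg)
  sim <- simulate_psms(cm)
  flt <- fdr_filter(sim$psms)$psms
  q <- quantify_genomes(flt, cm$truth$genome_of, cm$truth$proteome_size_aa)
  ratio <- sum(q$raw["G01", ]) / sum(q$raw["G02", ])
  expect_lt(abs(ratio - 3) / 3, 0.10)
})

test_that("expression-free proteins emit no PSMs", {
  sim <- fixture_sim()
  silent <- rownames(sim$protein_counts)[rowSums(sim$protein_counts) == 0]
  hit <- unique(unlist(fixture_filtered()$accessions))
  expect_length(intersect(silent, hit), 0)
})
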