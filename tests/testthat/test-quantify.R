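test_that("unique assignment separates the shared pool", {
  gm <- c(p1 = "A", p2 = "A", p3 = "B")
  psm <- make_psms("S1", "PEPK", c("p1", "p1;p2", "p1;p3"), 30)
  parts <- assign_unique(psm, gm)
  # p1 and p1;p2 are both unique to genome A
  expect_equal(parts$unique[genome == "A", count], 2L)
  expect_equal(nrow(parts$shared), 1L)
  expect_setequal(parts$shared$genomes[[1]], c("A", "B"))
  expect_error(assign_unique(make_psms("S1", "PEPK", "ghost", 30), gm),
               "ghost")
})

test_that("shared allocation follows proportional arithmetic", {
  uniq <- data.table::data.table(genome = c("A", "B"), sample_id = "S1",
                                 count = c(30L, 10L))
  shared <- data.table::data.table(sample_id = rep("S1", 4),
                                   genomes = rep(list(c("A", "B")), 4))
  res <- allocate_shared(shared, uniq)
  expect_equal(res$allocated[genome == "A", count], 3.0)
  expect_equal(res$allocated[genome == "B", count], 1.0)

  # all sharers without unique spectra: dropped and reported
  shared0 <- data.table::data.table(sample_id = "S1",
                                    genomes = list(c("C", "D")))
  res0 <- allocate_shared(shared0, uniq)
  expect_equal(nrow(res0$allocated), 0L)
  expect_equal(res0$dropped$count, 1L)

  # degenerate single-genome sharer gets the whole spectrum
  res1 <- allocate_shared(data.table::data.table(sample_id = "S1",
                                                 genomes = list("A")), uniq)
  expect_equal(res1$allocated$count, 1.0)
})

test_that("allocation is scale-free in the unique weights", {
  shared <- data.table::data.table(sample_id = rep("S1", 7),
                                   genomes = rep(list(c("A", "B", "C")), 7))
  u1 <- data.table::data.table(genome = c("A", "B", "C"), sample_id = "S1",
                               count = c(6L, 3L, 1L))
  u2 <- data.table::copy(u1)[, count := count * 13L]
  a1 <- allocate_shared(shared, u1)$allocated
  a2 <- allocate_shared(shared, u2)$allocated
  expect_equal(a1[order(genome), count], a2[order(genome), count])
})

test_that("spectra are conserved across unique + allocated + dropped", {
  set.seed(99)
  genomes <- LETTERS[1:5]
  gm <- setNames(rep(genomes, each = 2), paste0("p", 1:10))
  for (rep_i in 1:25) {
    n <- 200L
    acc <- vapply(seq_len(n), function(i)
      paste(sample(names(gm), sample(1:3, 1)), collapse = ";"), character(1))
    psm <- make_psms(sample(c("S1", "S2"), n, TRUE), "PEPK", acc,
                     score = 30)
    parts <- assign_unique(psm, gm)
    alloc <- allocate_shared(parts$shared, parts$unique)
    total <- sum(parts$unique$count) + sum(alloc$allocated$count) +
      sum(alloc$dropped$count)
    expect_equal(total, n, tolerance = 1e-9)
  }
})

test_that("with no shared peptides quantification equals unique counts", {
  cm <- fixture_community()
  psm <- fixture_filtered()
  parts <- assign_unique(psm, cm$truth$genome_of)
  expect_equal(nrow(parts$shared), 0L)
  q <- quantify_genomes(psm, cm$truth$genome_of, cm$truth$proteome_size_aa)
  per_genome <- parts$unique[, .(n = sum(count)), by = genome]
  expect_equal(rowSums(q$raw)[per_genome$genome], setNames(
    as.numeric(per_genome$n), per_genome$genome))
})

test_that("normalization follows the per-million-aa / depth formula", {
  m <- spectral_count_matrix(
    data.table::data.table(genome = "A", sample_id = "S1", count = 100),
    proteome_size_aa = c(A = 2e6), total_spectra = c(S1 = 1e4))
  expect_equal(unname(normalize_scm(m)["A", "S1"]), 0.005)
  # zero counts stay zero; doubling proteome size halves the value
  m2 <- spectral_count_matrix(
    data.table::data.table(genome = "A", sample_id = "S1", count = 100),
    proteome_size_aa = c(A = 4e6), total_spectra = c(S1 = 1e4))
  expect_equal(unname(normalize_scm(m2)["A", "S1"]), 0.0025)
  m0 <- spectral_count_matrix(
    data.table::data.table(genome = "A", sample_id = "S1", count = 0),
    proteome_size_aa = c(A = 2e6), total_spectra = c(S1 = 1e4))
  expect_equal(unname(normalize_scm(m0)["A", "S1"]), 0)
  bad <- spectral_count_matrix(
    data.table::data.table(genome = "A", sample_id = "S1", count = 1),
    proteome_size_aa = c(A = 0), total_spectra = c(S1 = 10))
  expect_error(normalize_scm(bad), "zero")
})

test_that("estimated genome abundances track the truth in rank", {
  cfg <- community_config(n_genomes = 4L, contigs_per_genome = 1L,
                          seed = 21, genome_abundance = c(8, 4, 2, 1),
                          phenotype_specific_fraction = 0,
                          n_samples_per_phenotype = 5L)
  cm <- generate_community(cfg)
  sim <- simulate_psms(cm)
  q <- quantify_genomes(fdr_filter(sim$psms)$psms, cm$truth$genome_of,
                        cm$truth$proteome_size_aa)
  est <- rowSums(q$raw)[rownames(sim$genome_abundance)]
  true <- rowSums(sim$genome_abundance)
  expect_gte(cor(est, true, method = "spearman"), 0.9)
})
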