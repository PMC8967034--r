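test_that("top-genome selection covers the spectral fraction", {
  tot <- c(a = 50, b = 30, c = 15, d = 5)
  expect_equal(select_top_genomes(tot, 0.80), c("a", "b"))
  expect_equal(select_top_genomes(c(only = 100), 0.80), "only")
  expect_equal(select_top_genomes(tot, 1.0), c("a", "b", "c", "d"))
  expect_equal(select_top_genomes(c(a = 10, b = 0), 1.0), "a")
  expect_equal(select_top_genomes(numeric(), 0.8), character())
})

test_that("six-frame translation matches codon-table lookups", {
  sf <- six_frame_translate("ATGGCC")
  expect_equal(unname(sf$aa["+1"]), "MA")
  expect_equal(unname(sf$aa["-1"]), "GH")  # revcomp GGCCAT -> GGC CAT
  expect_equal(unname(sf$aa["+2"]), "W")   # TGG CC -> W
  sf2 <- six_frame_translate("ATGTAAGGG")
  expect_equal(unname(sf2$aa["+1"]), "M*G")  # stop renders as separator
  expect_equal(six_frame_translate("AT")$aa, setNames(rep("", 6),
               c("+1", "+2", "+3", "-1", "-2", "-3")))
  # N-containing codons become X
  expect_equal(unname(six_frame_translate("ATGNNN")$aa["+1"]), "MX")
})

test_that("reverse-complement frames are a permutation of minus frames", {
  set.seed(12)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f <- six_frame_translate(s)$aa
    g <- six_frame_translate(rc)$aa
    expect_setequal(unname(f[c("-1", "-2", "-3")]),
                    unname(g[c("+1", "+2", "+3")]))
  }
})

test_that("frame-to-genomic mapping round-trips", {
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  sf <- six_frame_translate(s)
  for (fr in names(sf$aa)) {
    n_aa <- nchar(sf$aa[[fr]])
    if (n_aa < 2) next
    iv <- frame_to_genomic(fr, 1, n_aa, sf$length)
    expect_equal((iv[2] - iv[1]) %% 3, 0)
    sub <- substr(s, iv[1] + 1, iv[2])
    if (startsWith(fr, "-"))
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    # translating the mapped interval reproduces the frame translation
    expect_equal(unname(six_frame_translate(sub)$aa["+1"]), unname(sf$aa[[fr]]))
  }
})

test_that("ORF extraction anchors on the upstream start codon", {
  # layout (+1 frame): TAA | ATG GCT AAA GGT CCT | TAA
  s <- paste0("TAA", "ATG", "GCTAAAGGTCCT", "TAA", "GGG")
  sf <- six_frame_translate(s)
  # peptide "KG" sits at aa positions 4-5 of frame +1 ("*MAKGP*G")
  hit <- find_peptide_hits("AKG", list(c1 = sf))
  expect_equal(nrow(hit), 1L)
  orf <- extract_orf(sf, hit$frame, hit$aa_pos, "AKG")
  expect_equal(orf$aa, "MAKGP")
  expect_equal(orf$start, 3L); expect_equal(orf$end, 18L)
  expect_false(orf$start_missing)
  # no upstream start: segment starts at the contig edge
  s2 <- paste0("GCTAAAGGTCCT", "TAA")
  sf2 <- six_frame_translate(s2)
  h2 <- find_peptide_hits("AKG", list(c1 = sf2))
  orf2 <- extract_orf(sf2, h2$frame, h2$aa_pos, "AKG")
  expect_true(orf2$start_missing)
  expect_equal(orf2$aa, "AKGP")
})

test_that("novelty filter drops re-discoveries at the identity boundary", {
  set.seed(14)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aa20, 100, TRUE), collapse = "")
  mutate <- function(s, k) {
    pos <- sample(16:85, k)   # keep solid ends so SW spans the sequence
    ch <- strsplit(s, "")[[1]]
    for (i in pos) ch[i] <- sample(setdiff(aa20, ch[i]), 1)
    paste(ch, collapse = "")
  }
  proteome <- Biostrings::AAStringSet(c(ref = base))
  expect_false(novelty_filter(base, proteome))           # identical -> drop
  expect_false(novelty_filter(mutate(base, 30), proteome))  # 70% -> drop
  expect_true(novelty_filter(mutate(base, 31), proteome))   # 69% -> keep
  random <- paste(sample(aa20, 60, TRUE), collapse = "")
  expect_true(novelty_filter(random, proteome))          # unrelated -> keep
  # inverted (literal) reading keeps the re-discovery instead
  expect_true(novelty_filter(base, proteome, keep_matches = TRUE))
  expect_false(novelty_filter(random, proteome, keep_matches = TRUE))
})

test_that("relation classes follow strand and frame arithmetic", {
  genes <- data.table::data.table(
    gene_id = "g1", contig_id = "c1", start = 99L, end = 399L,
    strand = "+", source = "FGS")
  L <- 1000L
  # minus-strand ORF inside a plus-strand gene
  expect_equal(classify_orf_relation(
    list(contig_id = "c1", strand = "-", start = 150L, end = 210L),
    genes, L), "opposite_strand")
  # same strand, shifted by 1 nt: different frame
  expect_equal(classify_orf_relation(
    list(contig_id = "c1", strand = "+", start = 100L, end = 220L),
    genes, L), "same_strand_diff_frame")
  # same strand, same frame: not a frame conflict
  expect_equal(classify_orf_relation(
    list(contig_id = "c1", strand = "+", start = 102L, end = 222L),
    genes, L), "no_overlap")
  # intergenic desert
  expect_equal(classify_orf_relation(
    list(contig_id = "c1", strand = "+", start = 600L, end = 690L),
    genes, L), "no_overlap")
})

test_that("planted hidden ORFs are rescued exactly, none hallucinated", {
  cm <- fixture_community()
  sim <- fixture_sim()
  orfs <- rescue_orfs(sim$rescue_psms, cm$contigs, cm$genes, cm$proteome,
                      cm$truth$contig_genome)
  truth <- cm$truth$hidden_orfs
  expect_equal(nrow(orfs), nrow(truth))          # recall 1.0
  m <- merge(orfs, truth, by = c("contig_id", "start"))
  expect_equal(nrow(m), nrow(truth))             # intervals exact
  expect_equal(m$end.x, m$end.y)
  expect_equal(m$strand.x, m$strand.y)
  expect_equal(m$aa.x, m$aa.y)
  expect_equal(m$relation, m$class)              # construction class
  # every supporting peptide is a substring of its ORF
  for (i in seq_len(nrow(orfs)))
    expect_true(all(vapply(orfs$peptides[[i]], grepl, logical(1),
                           x = orfs$aa[i], fixed = TRUE)))
  # withholding the evidence: zero rescues
  none <- rescue_orfs(sim$rescue_psms[0], cm$contigs, cm$genes,
                      cm$proteome, cm$truth$contig_genome)
  expect_equal(nrow(none), 0L)
})

test_that("ORF grouping is single-linkage at the identity threshold", {
  set.seed(15)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- paste(sample(aa20, 50, TRUE), collapse = "")
  variant <- function() {
    ch <- strsplit(base, "")[[1]]
    pos <- sample(50, 7)  # ~86% identity to base, ~74% to each other
    for (i in pos) ch[i] <- sample(setdiff(aa20, ch[i]), 1)
    paste(ch, collapse = "")
  }
  fam <- c(base, replicate(7, variant()))
  lone <- replicate(3, paste(sample(aa20, 50, TRUE), collapse = ""))
  orfs <- data.table::data.table(
    orf_id = sprintf("o%02d", seq_along(c(fam, lone))), aa = c(fam, lone))
  grp <- cluster_orfs(orfs, 0.7)
  expect_equal(data.table::uniqueN(stats::na.omit(grp$cluster_id)), 1L)
  expect_equal(sum(!is.na(grp$cluster_id)), length(fam))
  # identical sequences: one group; dissimilar: none
  same3 <- data.table::data.table(orf_id = c("a", "b", "c"),
                                  aa = rep(base, 3))
  expect_equal(sum(!is.na(cluster_orfs(same3)$cluster_id)), 3L)
  expect_true(all(is.na(cluster_orfs(
    data.table::data.table(orf_id = c("a", "b"),
                           aa = c(lone[1], lone[2])))$cluster_id)))
})

test_that("rescued ORFs export to GFF3 and FASTA", {
  cm <- fixture_community()
  sim <- fixture_sim()
  orfs <- rescue_orfs(sim$rescue_psms, cm$contigs, cm$genes, cm$proteome,
                      cm$truth$contig_genome)
  gff <- withr::local_tempfile(fileext = ".gff3")
  faa <- withr::local_tempfile(fileext = ".faa")
  write_rescued_orfs(orfs, gff, faa)
  back <- read_gene_models(gff)
  expect_equal(nrow(back), nrow(orfs))
  expect_equal(sort(back$start), sort(orfs$start))
  expect_true(any(grepl("rescued=true", readLines(gff))))
  seqs <- read_proteome(faa)
  expect_setequal(names(seqs), orfs$orf_id)
})
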