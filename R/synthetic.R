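## Synthetic community generator: emits contigs (FASTA), gene models (GFF3),
## a predicted proteome, and per-sample PSM tables, together with the full
## ground truth (operons, hidden ORFs, co-expression blocks, phenotype-
## specific sets, realized genome abundances) so every downstream stage can
## be tested without external MS data.

#' Configuration of a synthetic community
#'
#' All knobs of the generator in one validated object. Defaults describe a
#' small but structurally complete community: a handful of genomes, operons
#' planted as same-strand gene runs with intergenic gaps at most 100 bases,
#' hidden ORFs of the three relation classes, negative-binomial spectral
#' counts over a phenotype-structured log-normal abundance model, planted
#' co-expression blocks, and a two-Gaussian target/decoy score model.
#'
#' @param n_genomes number of genomes.
#' @param contigs_per_genome,genes_per_contig community geometry.
#' @param gene_len_aa range of protein lengths (amino acids).
#' @param operons_per_contig planted operons per contig.
#' @param operon_size range of genes per operon.
#' @param operon_gap range of intra-operon intergenic gaps (bases, <= 100).
#' @param intergenic_gap range of non-operon gaps (bases, > 100).
#' @param n_hidden_orfs hidden ORFs per genome, cycling through
#'   `hidden_orf_classes`.
#' @param hidden_orf_classes placement classes for hidden ORFs.
#' @param phenotypes phenotype vocabulary.
#' @param n_samples_per_phenotype samples per phenotype.
#' @param mean_depth expected identified target PSMs per sample.
#' @param genome_log_sd log-sd of per-genome base abundances.
#' @param genome_abundance optional explicit per-genome relative abundances
#'   (overrides the log-normal draw).
#' @param sample_log_sd per-sample log-normal jitter of genome abundance.
#' @param nb_dispersion negative-binomial size parameter of spectral counts.
#' @param block_count,block_size planted co-expression blocks per genome.
#' @param rho_block latent correlation of block members, in \[0, 1).
#' @param block_log_sd log-scale amplitude of the block factor.
#' @param phenotype_specific_fraction fraction of each genome's proteins
#'   expressed in exactly one phenotype.
#' @param shared_peptide_rate fraction of the first shared-pair genome's
#'   peptides duplicated into the second (0 disables sharing).
#' @param shared_genome_pair indices of the genome pair sharing peptides.
#' @param target_score,decoy_score mean and sd of the target/decoy score
#'   Gaussians.
#' @param decoy_fraction decoy PSMs as a fraction of target PSMs.
#' @param hidden_orf_psms,hidden_orf_samples PSMs per hidden-ORF peptide and
#'   number of samples carrying them.
#' @param ensure_operon_support guarantee every operon member at least 2
#'   spectra in at least 2 samples (the support rule's stated world).
#' @param seed integer RNG seed; identical (config, seed) pairs give
#'   byte-identical outputs.
#' @return a validated `community_config` list.
#' @export
community_config <- function(n_genomes = 3L,
                             contigs_per_genome = 2L,
                             genes_per_contig = 15L,
                             gene_len_aa = c(60L, 140L),
                             operons_per_contig = 2L,
                             operon_size = c(3L, 5L),
                             operon_gap = c(10L, 80L),
                             intergenic_gap = c(150L, 400L),
                             n_hidden_orfs = 3L,
                             hidden_orf_classes = c("opposite_strand",
                                                    "same_strand_diff_frame",
                                                    "no_overlap"),
                             phenotypes = c("healthy", "CD", "UC", "AL"),
                             n_samples_per_phenotype = 5L,
                             mean_depth = 3000,
                             genome_log_sd = 1,
                             genome_abundance = NULL,
                             sample_log_sd = 0.3,
                             nb_dispersion = 5,
                             block_count = 2L,
                             block_size = 5L,
                             rho_block = 0.8,
                             block_log_sd = 1,
                             phenotype_specific_fraction = 0.2,
                             shared_peptide_rate = 0,
                             shared_genome_pair = c(1L, 2L),
                             target_score = c(30, 4),
                             decoy_score = c(18, 4),
                             decoy_fraction = 0.3,
                             hidden_orf_psms = 2L,
                             hidden_orf_samples = 2L,
                             ensure_operon_support = TRUE,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genomes >= 1, contigs_per_genome >= 1, genes_per_contig >= 2,
            operon_gap[2] <= 100, intergenic_gap[1] > 100,
            rho_block >= 0, rho_block < 1,
            n_samples_per_phenotype >= 1, mean_depth > 0,
            shared_peptide_rate >= 0, shared_peptide_rate < 1,
            hidden_orf_classes %in% c("opposite_strand",
                                      "same_strand_diff_frame", "no_overlap"))
  if (!is.null(genome_abundance))
    stopifnot(length(genome_abundance) == n_genomes, genome_abundance > 0)
  class(cfg) <- "community_config"
  cfg
}

#' Built-in community presets
#'
#' `"small"` is the fixture preset used throughout the test-suite and the
#' synthetic pipeline mode: 3 genomes, 20 samples over 4 phenotypes,
#' generating in a few seconds.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return a `community_config`.
#' @export
community_preset <- function(name = "small", seed = 1L) {
  switch(name,
         small = community_config(seed = seed),
         stop("unknown preset: ", name))
}

## ---- sequence helpers -----------------------------------------------------

AA_PLAIN <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]  # no K/R (cleavage), no P

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## codon -> aa lookup (standard code; stops render as "*", fuzzy codons "X")
GC_VEC <- Biostrings::GENETIC_CODE

translate_chr <- function(s) {
  n <- nchar(s) - nchar(s) %% 3
  if (n < 3) return("")
  aa <- unname(GC_VEC[substring(s, seq(1L, n, 3L), seq(3L, n, 3L))])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## random protein built from tryptic units: each unit is 6-12 plain residues
## followed by K or R, so the zero-missed-cleavage digest is the unit list.
random_protein <- function(len_aa) {
  units <- character()
  total <- 0L
  while (total < len_aa) {
    u <- paste0(paste(sample(AA_PLAIN, sample(6:12, 1), replace = TRUE),
                      collapse = ""),
                sample(c("K", "R"), 1))
    units <- c(units, u)
    total <- total + nchar(u)
  }
  paste(units, collapse = "")
}

## reverse-translate an aa string with random synonymous codons
reverse_translate <- function(aa, codons = .codon_table()) {
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) sample(codons[[a]], 1), character(1)),
        collapse = "")
}

## tryptic digestion: cleave after K/R unless followed by P
#' In-silico tryptic digestion
#'
#' Cleaves after K/R (not before P), returning peptides with up to
#' `max_missed` missed cleavages within the given length window.
#'
#' @param aa protein sequence (single string).
#' @param max_missed maximum missed cleavages (default 2).
#' @param len_range peptide length window (default 7-40).
#' @return character vector of peptides (may be empty).
#' @export
digest_tryptic <- function(aa, max_missed = 2L, len_range = c(7L, 40L)) {
  chars <- strsplit(aa, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(character())
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[chars[pmin(cut_after + 1L, n)] != "P" | cut_after == n]
  bounds <- unique(c(0L, cut_after, n))
  frag_start <- head(bounds, -1L) + 1L
  frag_end <- tail(bounds, -1L)
  k <- length(frag_start)
  peps <- character()
  for (i in seq_len(k)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > k) break
      p <- substr(aa, frag_start[i], frag_end[j])
      if (nchar(p) >= len_range[1] && nchar(p) <= len_range[2])
        peps <- c(peps, p)
    }
  }
  unique(peps)
}

## hidden-ORF body over {A,G,P,R} with GC-only codons: no stop codon can
## arise in any frame on either strand inside the body.
CG_CODONS <- list(A = c("GCC", "GCG"), G = c("GGC", "GGG"),
                  P = c("CCC", "CCG"), R = c("CGC", "CGG"))

random_orf_body <- function(n_units = 3L) {
  units <- vapply(seq_len(n_units), function(i) {
    len <- sample(8:11, 1)
    ## unit-initial residue must not be P, or cleavage after the preceding
    ## R is suppressed and units merge beyond the peptide length window
    paste0(sample(c("A", "G"), 1),
           paste(sample(c("A", "G", "P"), len - 1L, replace = TRUE),
                 collapse = ""), "R")
  }, character(1))
  paste(units, collapse = "")
}

cg_reverse_translate <- function(aa) {
  paste(vapply(strsplit(aa, "")[[1]],
               function(a) sample(CG_CODONS[[a]], 1), character(1)),
        collapse = "")
}

## ---- community generation -------------------------------------------------

#' Generate a synthetic community with ground truth
#'
#' Lays out genes contig by contig (operons as same-strand runs with gaps at
#' most 100 bases, everything else separated by larger gaps), embeds hidden
#' ORFs that are present in the contig sequence but absent from the gene
#' models, and derives the predicted proteome by translating the gene models
#' from the final sequence. Deterministic under `config$seed`.
#'
#' @param config a [community_config()].
#' @return an object of class `synthetic_community`: list with `contigs`
#'   (DNAStringSet), `genes` (gene-model data.table with a `genome` column),
#'   `proteome` (AAStringSet, gene models only), `truth` (ground-truth list)
#'   and `config`.
#' @export
generate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  codons <- .codon_table()
  stops <- c("TAA", "TAG", "TGA")

  genes <- list(); contig_seqs <- character(); gaps <- list()
  operons <- list(); op_n <- 0L
  for (g in seq_len(config$n_genomes)) {
    genome_id <- sprintf("G%02d", g)
    for (cc in seq_len(config$contigs_per_genome)) {
      contig_id <- sprintf("%s_c%d", genome_id, cc)
      ## unit layout: operon runs + singletons
      sizes <- integer()
      remaining <- config$genes_per_contig
      for (k in seq_len(config$operons_per_contig)) {
        s <- sample(config$operon_size[1]:config$operon_size[2], 1)
        if (remaining - s >= 1L) { sizes <- c(sizes, s); remaining <- remaining - s }
      }
      units <- sample(c(as.list(sizes), rep(list(1L), remaining)))
      pos <- sample(80:150, 1)
      pieces <- list(paste(sample(c("A", "C", "G", "T"), pos, replace = TRUE),
                           collapse = ""))
      gi <- 0L
      for (u in units) {
        strand <- sample(c("+", "-"), 1)
        op_genes <- character()
        for (k in seq_len(u)) {
          gap <- if (k == 1L)
            sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1)
          else sample(config$operon_gap[1]:config$operon_gap[2], 1)
          gap_seq <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                           collapse = "")
          if (k == 1L)
            gaps[[length(gaps) + 1L]] <- data.table::data.table(
              contig_id = contig_id, start = pos, end = pos + gap)
          pieces[[length(pieces) + 1L]] <- gap_seq
          pos <- pos + gap
          gi <- gi + 1L
          gene_id <- sprintf("%s_g%03d", contig_id, gi)
          prot <- random_protein(sample(config$gene_len_aa[1]:config$gene_len_aa[2], 1))
          cds <- paste0("ATG", reverse_translate(prot, codons), sample(stops, 1))
          seg <- if (strand == "+") cds else revcomp_chr(cds)
          pieces[[length(pieces) + 1L]] <- seg
          genes[[length(genes) + 1L]] <- data.table::data.table(
            gene_id = gene_id, contig_id = contig_id, start = pos,
            end = pos + nchar(cds), strand = strand, source = "FGS",
            genome = genome_id)
          pos <- pos + nchar(cds)
          op_genes <- c(op_genes, gene_id)
        }
        if (u >= 2L) {
          op_n <- op_n + 1L
          operons[[op_n]] <- data.table::data.table(
            operon_id = sprintf("OP%03d", op_n), contig_id = contig_id,
            strand = strand, gene_ids = list(op_genes))
        }
      }
      tail_pad <- sample(80:150, 1)
      pieces[[length(pieces) + 1L]] <- paste(
        sample(c("A", "C", "G", "T"), tail_pad, replace = TRUE), collapse = "")
      contig_seqs[[contig_id]] <- paste(unlist(pieces), collapse = "")
      stopifnot(nchar(contig_seqs[[contig_id]]) == pos + tail_pad)
    }
  }
  genes <- data.table::rbindlist(genes)
  gaps <- data.table::rbindlist(gaps)
  gaps[, gap_id := .I]

  ## ---- hidden ORFs ----
  hidden <- list()
  host_used <- character()
  gaps_used <- integer()
  for (g in seq_len(config$n_genomes)) {
    genome_id <- sprintf("G%02d", g)
    for (i in seq_len(config$n_hidden_orfs)) {
      cls <- config$hidden_orf_classes[
        (i - 1L) %% length(config$hidden_orf_classes) + 1L]
      emb <- embed_hidden_orf(contig_seqs, genes,
                              gaps[!gap_id %in% gaps_used], genome_id, cls,
                              host_used)
      contig_seqs[[emb$contig_id]] <- emb$seq
      if (!is.na(emb$gap_id)) gaps_used <- c(gaps_used, emb$gap_id)
      if (!is.na(emb$host)) host_used <- c(host_used, emb$host)
      hidden[[length(hidden) + 1L]] <- data.table::data.table(
        orf_id = sprintf("%s_orf%02d", genome_id, i), genome = genome_id,
        contig_id = emb$contig_id, strand = emb$strand,
        start = emb$start, end = emb$end, aa = emb$aa, class = cls,
        host_gene = emb$host)
    }
  }
  hidden <- data.table::rbindlist(hidden)
  contig_len <- nchar(contig_seqs)
  ## frame label: +1..+3 / -1..-3
  hidden[, frame := ifelse(strand == "+",
                           start %% 3L + 1L,
                           -((contig_len[contig_id] - end) %% 3L + 1L))]

  ## ---- proteome from final sequence ----
  prot_seq <- vapply(seq_len(nrow(genes)), function(i) {
    cds <- substr(contig_seqs[[genes$contig_id[i]]],
                  genes$start[i] + 1L, genes$end[i])
    if (genes$strand[i] == "-") cds <- revcomp_chr(cds)
    aa <- translate_chr(cds)
    aa <- sub("\\*$", "", aa)
    if (grepl("\\*", aa))
      stop("internal error: gene ", genes$gene_id[i], " has internal stop")
    aa
  }, character(1))
  names(prot_seq) <- genes$gene_id

  ## hidden ORF peptides (zero missed cleavages), kept only when they occur
  ## exactly once across the entire six-frame translation space -- the
  ## rescue stage requires a unique stop-bounded segment per peptide
  frame_space <- unlist(lapply(contig_seqs, function(s)
    six_frame_translate(s)$aa), use.names = FALSE)
  n_occurrences <- function(p) sum(vapply(frame_space, function(faa)
    length(gregexpr(p, faa, fixed = TRUE)[[1]]) *
      (regexpr(p, faa, fixed = TRUE) > 0), integer(1)))
  hidden_peps <- lapply(seq_len(nrow(hidden)), function(i) {
    peps <- digest_tryptic(hidden$aa[i], max_missed = 0L)
    peps <- peps[vapply(peps, n_occurrences, integer(1)) == 1L]
    head(peps, 2L)
  })
  hidden[, peptides := hidden_peps]
  if (any(lengths(hidden_peps) == 0L))
    stop("infeasible layout: hidden ORF without unique peptides")

  ## ---- expression structure (truth) ----
  blocks <- list(); pheno_specific <- list()
  op_members <- unlist(lapply(operons, function(o) o$gene_ids[[1]]))
  for (g in seq_len(config$n_genomes)) {
    genome_id <- sprintf("G%02d", g)
    gp <- genes[genome == genome_id, gene_id]
    free <- setdiff(gp, op_members)
    n_spec <- floor(config$phenotype_specific_fraction * length(gp))
    spec <- sample(free, min(n_spec, length(free)))
    if (length(spec))
      pheno_specific[[genome_id]] <- data.table::data.table(
        protein_id = spec,
        phenotype = sample(config$phenotypes, length(spec), replace = TRUE))
    free <- setdiff(free, spec)
    for (b in seq_len(config$block_count)) {
      if (length(free) < config$block_size) break
      memb <- sample(free, config$block_size)
      free <- setdiff(free, memb)
      blocks[[paste0(genome_id, "_B", b)]] <- data.table::data.table(
        protein_id = memb, block_id = paste0(genome_id, "_B", b))
    }
  }
  blocks <- data.table::rbindlist(blocks)
  pheno_specific <- if (length(pheno_specific))
    data.table::rbindlist(pheno_specific)
  else data.table::data.table(protein_id = character(), phenotype = character())

  operons <- data.table::rbindlist(operons)
  operons[, `:=`(start = vapply(gene_ids, function(ids)
                   min(genes[gene_id %in% ids, start]), integer(1)),
                 end = vapply(gene_ids, function(ids)
                   max(genes[gene_id %in% ids, end]), integer(1)))]

  ## peptide -> protein map from the final digests (<= 2 missed cleavages)
  pep_map <- data.table::rbindlist(lapply(names(prot_seq), function(p) {
    peps <- digest_tryptic(prot_seq[[p]], max_missed = 2L)
    if (!length(peps)) return(NULL)
    data.table::data.table(peptide = peps, protein_id = p)
  }))

  ## optional shared peptides between the designated genome pair
  if (config$shared_peptide_rate > 0 && config$n_genomes >= 2) {
    pair <- sprintf("G%02d", config$shared_genome_pair)
    src <- genes[genome == pair[1], gene_id]
    dst <- setdiff(genes[genome == pair[2], gene_id], host_used)
    src_peps <- unique(pep_map[protein_id %in% src & !grepl("P$", peptide),
                               peptide])
    n_share <- max(1L, floor(config$shared_peptide_rate * length(src_peps)))
    share <- sample(src_peps, min(n_share, length(src_peps)))
    for (p in share) {
      tgt <- sample(dst, 1)
      prot_seq[[tgt]] <- paste0(prot_seq[[tgt]], p)
      extra <- digest_tryptic(prot_seq[[tgt]], max_missed = 2L)
      pep_map <- unique(rbind(pep_map[protein_id != tgt],
                              data.table::data.table(peptide = extra,
                                                     protein_id = tgt)))
    }
    ## note: shared proteins' aa changed; their gene DNA is NOT rewritten --
    ## sharing is a property of the proteome used for searching.
  }

  proteome <- Biostrings::AAStringSet(unlist(prot_seq))
  truth <- list(
    genome_of = setNames(genes$genome, genes$gene_id),
    contig_genome = setNames(genes$genome[!duplicated(genes$contig_id)],
                             genes$contig_id[!duplicated(genes$contig_id)]),
    contig_lengths = contig_len,
    proteome_size_aa = tapply(nchar(prot_seq), genes$genome, sum),
    operons = operons,
    hidden_orfs = hidden,
    blocks = blocks,
    phenotype_specific = pheno_specific,
    peptide_map = pep_map)
  structure(list(contigs = Biostrings::DNAStringSet(unlist(contig_seqs)),
                 genes = genes, proteome = proteome, truth = truth,
                 config = config),
            class = "synthetic_community")
}

## place one hidden ORF; returns new contig seq + coordinates
embed_hidden_orf <- function(contig_seqs, genes, gaps, genome_id, cls,
                             host_used, max_try = 200L) {
  body <- random_orf_body(sample(3:4, 1))
  core <- paste0("ATG", cg_reverse_translate(body))   # coding part
  block <- paste0("TAA", core, "TAA")                 # stop-bounded
  blen <- nchar(block)
  if (cls == "no_overlap") {
    cand <- gaps[startsWith(contig_id, genome_id) & end - start >= blen + 20L]
    stopifnot(nrow(cand) > 0)
    row <- cand[sample(.N, 1)]
    off <- sample(10:(row$end - row$start - blen - 10L), 1)
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") block else revcomp_chr(block)
    s <- row$start + off
    seq <- contig_seqs[[row$contig_id]]
    substr(seq, s + 1L, s + blen) <- ins
    return(list(contig_id = row$contig_id, seq = seq, strand = strand,
                start = s + 3L, end = s + 3L + nchar(core),
                aa = paste0("M", body), host = NA_character_,
                gap_id = row$gap_id))
  }
  ## overlap classes: embed inside a host gene, keep the host readable
  hosts <- genes[genome == genome_id & end - start >= blen + 30L &
                   !gene_id %in% host_used]
  stopifnot(nrow(hosts) > 0)
  for (t in seq_len(max_try)) {
    h <- hosts[sample(.N, 1)]
    orf_strand <- if (cls == "opposite_strand")
      setdiff(c("+", "-"), h$strand) else h$strand
    ## offset of the block within the contig
    lo <- h$start + 6L
    hi <- h$end - blen - 6L
    if (hi <= lo) next
    s <- sample(lo:hi, 1)
    if (cls == "same_strand_diff_frame") {
      ## the ORF's coding part occupies [s+3, s+blen-3); it must be out of
      ## frame with the host CDS on the shared strand
      ok_frame <- if (h$strand == "+") (s + 3L - h$start) %% 3L != 0L
                  else (h$end - (s + blen - 3L)) %% 3L != 0L
      if (!ok_frame) next
    }
    ins <- if (orf_strand == "+") block else revcomp_chr(block)
    seq <- contig_seqs[[h$contig_id]]
    substr(seq, s + 1L, s + blen) <- ins
    ## host must stay stop-free internally
    cds <- substr(seq, h$start + 1L, h$end)
    if (h$strand == "-") cds <- revcomp_chr(cds)
    aa <- sub("\\*$", "", translate_chr(cds))
    if (grepl("\\*", aa) || !nzchar(aa)) next
    ## the coding part occupies [s+3, s+blen-3) on the contig in both cases
    return(list(contig_id = h$contig_id, seq = seq, strand = orf_strand,
                start = s + 3L, end = s + blen - 3L,
                aa = paste0("M", body), host = h$gene_id,
                gap_id = NA_integer_))
  }
  stop("infeasible layout: could not embed hidden ORF (", cls, ") in ",
       genome_id)
}

#' Write community files to disk
#'
#' Emits `contigs.fna`, `genes.gff3`, `proteome.faa` in the exact dialects
#' the I/O layer reads.
#'
#' @param community a `synthetic_community`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named file paths.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(contigs = file.path(dir, "contigs.fna"),
             genes = file.path(dir, "genes.gff3"),
             proteome = file.path(dir, "proteome.faa"))
  write_fasta(community$contigs, paths["contigs"])
  write_gene_models(community$genes[, .(gene_id, contig_id, start, end,
                                        strand, source)], paths["genes"])
  write_fasta(community$proteome, paths["proteome"])
  invisible(paths)
}

## ---- PSM simulation -------------------------------------------------------

#' Simulate PSM tables from a synthetic community
#'
#' Draws per-protein per-sample spectral counts from the expression model
#' (log-normal genome abundances with per-sample jitter, planted block
#' factors, phenotype-specific zeroing, negative-binomial counting), emits
#' one target PSM row per spectral count with the peptide drawn from the
#' protein's tryptic digest and the accession set expanded to all proteins
#' containing that peptide, appends decoy records from the decoy score
#' Gaussian, and emits a separate rescue table of PSMs hitting hidden-ORF
#' peptides (absent from the predicted proteome).
#'
#' @param community a `synthetic_community`.
#' @param config defaults to `community$config`.
#' @return object of class `synthetic_psms`: list with `psms` (psm_table),
#'   `rescue_psms` (psm_table of hidden-ORF evidence), `manifest`
#'   (sample_id/phenotype), `genome_abundance` (genomes x samples realized
#'   relative abundance), `protein_counts` (proteins x samples true counts).
#' @export
simulate_psms <- function(community, config = community$config) {
  stopifnot(inherits(community, "synthetic_community"))
  set.seed(config$seed + 1003L)
  truth <- community$truth
  genes <- community$genes
  phen <- rep(config$phenotypes, each = config$n_samples_per_phenotype)
  samples <- sprintf("S%03d", seq_along(phen))
  manifest <- data.table::data.table(sample_id = samples, phenotype = phen)

  genomes <- sprintf("G%02d", seq_len(config$n_genomes))
  base <- if (!is.null(config$genome_abundance))
    config$genome_abundance / sum(config$genome_abundance)
  else {
    b <- rlnorm(config$n_genomes, 0, config$genome_log_sd)
    b / sum(b)
  }
  names(base) <- genomes
  jitter <- matrix(rlnorm(length(genomes) * length(samples),
                          0, config$sample_log_sd),
                   length(genomes), length(samples),
                   dimnames = list(genomes, samples))
  ab <- sweep(base * jitter, 2, colSums(base * jitter), "/")

  prots <- genes$gene_id
  plen <- nchar(as.character(community$proteome[prots]))
  w <- unlist(lapply(genomes, function(g) {
    idx <- genes$genome == g
    plen[idx] / sum(plen[idx])
  }))
  names(w) <- unlist(lapply(genomes, function(g) prots[genes$genome == g]))
  w <- w[prots]

  ## block factors
  block_of <- setNames(truth$blocks$block_id, truth$blocks$protein_id)
  block_ids <- unique(truth$blocks$block_id)
  zb <- matrix(rnorm(length(block_ids) * length(samples)),
               length(block_ids), length(samples),
               dimnames = list(block_ids, samples))
  spec_of <- setNames(truth$phenotype_specific$phenotype,
                      truth$phenotype_specific$protein_id)

  counts <- matrix(0L, length(prots), length(samples),
                   dimnames = list(prots, samples))
  for (s in seq_along(samples)) {
    lam <- config$mean_depth * ab[genes$genome, s] * w
    in_block <- prots %in% names(block_of)
    if (any(in_block)) {
      z <- zb[block_of[prots[in_block]], s]
      eps <- rnorm(sum(in_block))
      fac <- exp(config$block_log_sd *
                   (sqrt(config$rho_block) * z +
                      sqrt(1 - config$rho_block) * eps))
      lam[in_block] <- lam[in_block] * fac
    }
    is_spec <- prots %in% names(spec_of)
    if (any(is_spec)) {
      off <- spec_of[prots[is_spec]] != phen[s]
      lam[is_spec][off] <- 0
    }
    counts[, s] <- rnbinom(length(lam), mu = lam, size = config$nb_dispersion)
  }
  if (config$ensure_operon_support && nrow(truth$operons)) {
    op_members <- unique(unlist(truth$operons$gene_ids))
    sup <- samples[seq_len(min(2L, length(samples)))]
    counts[op_members, sup] <- pmax(counts[op_members, sup], 2L)
  }

  ## peptide universe per protein
  pep_by_prot <- split(truth$peptide_map$peptide, truth$peptide_map$protein_id)
  prots_of_pep <- split(truth$peptide_map$protein_id, truth$peptide_map$peptide)

  rows <- list()
  for (s in seq_along(samples)) {
    nz <- which(counts[, s] > 0L)
    if (!length(nz)) next
    pep <- unlist(lapply(nz, function(i) {
      u <- pep_by_prot[[prots[i]]]
      if (is.null(u)) return(character())
      sample(u, counts[i, s], replace = TRUE)
    }))
    if (!length(pep)) next
    rows[[s]] <- data.table::data.table(
      spectrum_id = sprintf("%s_%06d", samples[s], seq_along(pep)),
      sample_id = samples[s], peptide = pep,
      accessions = prots_of_pep[pep],
      score = rnorm(length(pep), config$target_score[1],
                    config$target_score[2]),
      is_decoy = FALSE)
  }
  psms <- data.table::rbindlist(rows)

  ## decoys
  n_dec_total <- round(config$decoy_fraction * nrow(psms))
  if (n_dec_total > 0L) {
    ds <- sample(samples, n_dec_total, replace = TRUE)
    dec <- data.table::data.table(
      spectrum_id = sprintf("%s_D%06d", ds, seq_len(n_dec_total)),
      sample_id = ds,
      peptide = vapply(seq_len(n_dec_total), function(i)
        paste(sample(AA_PLAIN, 9, replace = TRUE), collapse = ""),
        character(1)),
      accessions = as.list(paste0("XXX_", sample(prots, n_dec_total,
                                                 replace = TRUE))),
      score = rnorm(n_dec_total, config$decoy_score[1],
                    config$decoy_score[2]),
      is_decoy = TRUE)
    psms <- rbind(psms, dec)
  }
  data.table::setorder(psms, sample_id, spectrum_id)
  data.table::setattr(psms, "class", c("psm_table", "data.table", "data.frame"))

  ## rescue evidence: PSMs on hidden-ORF peptides, against the 6-frame space
  rrows <- list()
  ho <- truth$hidden_orfs
  for (i in seq_len(nrow(ho))) {
    for (p in ho$peptides[[i]]) {
      for (s in samples[seq_len(min(config$hidden_orf_samples,
                                    length(samples)))]) {
        for (k in seq_len(config$hidden_orf_psms)) {
          rrows[[length(rrows) + 1L]] <- data.table::data.table(
            spectrum_id = sprintf("%s_R%s_%s_%d", s, ho$orf_id[i],
                                  substr(p, 1, 4), k),
            sample_id = s, peptide = p,
            accessions = list(paste0("SIXFRAME|", ho$contig_id[i])),
            score = rnorm(1, config$target_score[1], config$target_score[2]),
            is_decoy = FALSE)
        }
      }
    }
  }
  rescue <- if (length(rrows)) data.table::rbindlist(rrows)
            else empty_psm_table()
  data.table::setattr(rescue, "class",
                      c("psm_table", "data.table", "data.frame"))

  structure(list(psms = psms[], rescue_psms = rescue[], manifest = manifest,
                 genome_abundance = ab, protein_counts = counts),
            class = "synthetic_psms")
}

#' Write simulated PSM tables to disk
#'
#' One TSV per sample (the dialect [read_psm_table()] expects) plus
#' `manifest.csv` and `rescue_psms.tsv`.
#'
#' @param sim a `synthetic_psms` object.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_psm_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(sim$psms$sample_id))
    write_psm_table(sim$psms[sample_id == s],
                    file.path(dir, paste0(s, ".psm.tsv")))
  write_psm_table(sim$rescue_psms, file.path(dir, "rescue_psms.tsv"))
  data.table::fwrite(sim$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}
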