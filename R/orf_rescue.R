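## Six-frame ORF rescue: peptides identified against a six-frame translation
## of the genome, but absent from the predicted proteome, anchor open reading
## frames that de novo gene predictors missed.

#' Top genomes covering a spectral fraction
#'
#' Smallest prefix of genomes, sorted by decreasing spectral count, whose
#' cumulative share of the sample's spectra reaches `coverage`.
#'
#' @param totals named numeric vector of per-genome spectra in one sample,
#'   or a genomes x samples matrix (then a per-sample list is returned).
#' @param coverage required cumulative fraction (default 0.80).
#' @return character vector of genome ids (or a named list of them).
#' @export
select_top_genomes <- function(totals, coverage = 0.80) {
  if (is.matrix(totals))
    return(lapply(setNames(colnames(totals), colnames(totals)),
                  function(s) select_top_genomes(totals[, s], coverage)))
  totals <- totals[totals > 0]
  if (!length(totals)) return(character())
  ord <- order(-totals, names(totals))
  cum <- cumsum(totals[ord]) / sum(totals)
  names(totals)[ord][seq_len(which(cum >= coverage - 1e-12)[1])]
}

#' Six-frame translation of a contig
#'
#' Translates the three frames of both strands with the bacterial code
#' (start-codon handling is deferred to [extract_orf()]); stop codons render
#' as `*`, codons containing N as `X`. Frames are labelled +1, +2, +3
#' (offsets 0..2 on the given strand) and -1, -2, -3 (offsets 0..2 on the
#' reverse complement).
#'
#' @param dna contig sequence (character or DNAString).
#' @return object of class `six_frame`: list with `aa` (named character
#'   vector of 6 translations), `nt` (the frame-local nucleotide strings)
#'   and `length` (contig length).
#' @export
six_frame_translate <- function(dna) {
  s <- as.character(dna)
  L <- nchar(s)
  rc <- if (L) revcomp_chr(s) else s
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  nt <- setNames(vapply(1:6, function(i) {
    src <- if (i <= 3) s else rc
    off <- (i - 1L) %% 3L
    if (L - off < 3) "" else substr(src, off + 1L, L)
  }, character(1)), frames)
  aa <- vapply(nt, translate_chr, character(1))
  structure(list(aa = aa, nt = nt, length = L), class = "six_frame")
}

#' Map frame-local amino-acid positions to genomic coordinates
#'
#' @param frame frame label (`"+1"`..`"-3"`).
#' @param aa_start,aa_end 1-based inclusive aa positions within the frame.
#' @param contig_length contig length in bases.
#' @return integer c(start, end), 0-based half-open genomic interval.
#' @export
frame_to_genomic <- function(frame, aa_start, aa_end, contig_length) {
  f <- abs(as.integer(frame))
  off <- f - 1L
  if (startsWith(frame, "-")) {
    c(contig_length - off - 3L * aa_end,
      contig_length - off - 3L * (aa_start - 1L))
  } else {
    c(off + 3L * (aa_start - 1L), off + 3L * aa_end)
  }
}

#' Locate peptides in six-frame space
#'
#' @param peptides character vector.
#' @param six_frames named list of `six_frame` objects (per contig).
#' @return data.table peptide/contig_id/frame/aa_pos (1-based aa position of
#'   the peptide start within the frame), one row per occurrence.
#' @export
find_peptide_hits <- function(peptides, six_frames) {
  out <- list()
  for (cid in names(six_frames)) {
    sf <- six_frames[[cid]]
    for (fr in names(sf$aa)) {
      for (p in unique(peptides)) {
        hit <- gregexpr(p, sf$aa[[fr]], fixed = TRUE)[[1]]
        if (hit[1] == -1L) next
        out[[length(out) + 1L]] <- data.table::data.table(
          peptide = p, contig_id = cid, frame = fr, aa_pos = as.integer(hit))
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(peptide = character(),
                                  contig_id = character(),
                                  frame = character(), aa_pos = integer()))
  data.table::rbindlist(out)
}

## stop-bounded segment of a frame containing aa position `pos`:
## returns c(first_aa, last_aa) 1-based inclusive (stars excluded)
segment_bounds <- function(frame_aa, pos) {
  stars <- c(0L, which(strsplit(frame_aa, "")[[1]] == "*"),
             nchar(frame_aa) + 1L)
  lo <- max(stars[stars < pos])
  hi <- min(stars[stars > pos])
  c(lo + 1L, hi - 1L)
}

#' Extract the ORF around a peptide hit
#'
#' Within the stop-bounded segment containing the peptide, the ORF runs from
#' the first (5'-most) ATG/GTG/TTG start codon at or upstream of the peptide
#' to the segment's closing stop. Without any upstream start the ORF begins
#' at the segment start and is flagged `start_missing`.
#'
#' @param sf a `six_frame` object for the contig.
#' @param frame frame label.
#' @param aa_pos 1-based aa position of the peptide within the frame.
#' @param peptide the peptide (for the within-segment assertion).
#' @return list: `start`, `end` (0-based half-open genomic), `strand`,
#'   `frame`, `aa` (ORF sequence), `start_missing`, `aa_range` (frame-local).
#' @export
extract_orf <- function(sf, frame, aa_pos, peptide = NULL) {
  faa <- sf$aa[[frame]]
  seg <- segment_bounds(faa, aa_pos)
  if (!is.null(peptide)) {
    stopifnot(aa_pos + nchar(peptide) - 1L <= seg[2])
  }
  fnt <- sf$nt[[frame]]
  starts <- c("ATG", "GTG", "TTG")
  orf_from <- NA_integer_
  for (a in seg[1]:aa_pos) {
    if (substr(fnt, 3L * a - 2L, 3L * a) %in% starts) { orf_from <- a; break }
  }
  start_missing <- is.na(orf_from)
  if (start_missing) orf_from <- seg[1]
  gen <- frame_to_genomic(frame, orf_from, seg[2], sf$length)
  list(start = gen[1], end = gen[2],
       strand = if (startsWith(frame, "-")) "-" else "+",
       frame = frame, aa = substr(faa, orf_from, seg[2]),
       start_missing = start_missing, aa_range = c(orf_from, seg[2]))
}

#' Identity of a candidate against a predicted proteome
#'
#' Best local Smith-Waterman alignment (BLOSUM62, gap open 11 / extend 1)
#' of the candidate against each predicted protein; identity is counted as
#' identical aligned positions over the length of the shorter sequence.
#'
#' @param aa candidate sequence.
#' @param proteome `AAStringSet` (or named character) of predicted proteins.
#' @return maximum identity fraction over the proteome (0 when empty).
#' @export
max_identity <- function(aa, proteome) {
  if (is.character(proteome)) proteome <- Biostrings::AAStringSet(proteome)
  if (!length(proteome) || !nchar(aa)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    pattern = proteome, subject = Biostrings::AAString(aa),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  nm <- Biostrings::nmatch(aln)
  shorter <- pmin(nchar(as.character(proteome)), nchar(aa))
  max(nm / shorter)
}

#' Novelty filter for rescued ORF candidates
#'
#' A candidate that aligns to any predicted protein of the same genome with
#' identity at or above `min_identity` is a re-discovery of an existing gene
#' model and is dropped; otherwise it is kept as novel. `keep_matches`
#' inverts the direction (keeping only re-discoveries).
#'
#' @param aa candidate ORF sequence.
#' @param proteome predicted proteins of the same genome.
#' @param min_identity identity threshold (default 0.70).
#' @param keep_matches invert the filter direction.
#' @return TRUE to keep the candidate.
#' @export
novelty_filter <- function(aa, proteome, min_identity = 0.70,
                           keep_matches = FALSE) {
  rediscovery <- max_identity(aa, proteome) >= min_identity
  if (keep_matches) rediscovery else !rediscovery
}

#' Classify a rescued ORF against predicted gene models
#'
#' `same_strand_diff_frame` when the ORF overlaps (>= 1 bp) a same-strand
#' gene in a different reading frame; `opposite_strand` when it overlaps a
#' gene on the other strand; `no_overlap` otherwise. When both overlap types
#' occur, `precedence` decides (default `same_strand_diff_frame`).
#'
#' @param orf list or one-row data.frame with `contig_id`, `strand`,
#'   `start`, `end`.
#' @param genes `gene_models` table.
#' @param contig_length contig length (for minus-strand frame arithmetic).
#' @param precedence which class wins when both apply.
#' @return one of `"opposite_strand"`, `"same_strand_diff_frame"`,
#'   `"no_overlap"`.
#' @export
classify_orf_relation <- function(orf, genes, contig_length,
                                  precedence = c("same_strand_diff_frame",
                                                 "opposite_strand")) {
  precedence <- match.arg(precedence)
  g <- genes[genes$contig_id == orf$contig_id &
               genes$start < orf$end & genes$end > orf$start, ]
  if (!nrow(g)) return("no_overlap")
  same <- g[g$strand == orf$strand, ]
  opp <- nrow(g) > nrow(same)
  ssdf <- FALSE
  if (nrow(same)) {
    orf_frame <- genomic_frame(orf$start, orf$end, orf$strand, contig_length)
    gene_frames <- genomic_frame(same$start, same$end, same$strand,
                                 contig_length)
    ssdf <- any(gene_frames != orf_frame)
  }
  if (ssdf && opp)
    return(precedence)
  if (ssdf) return("same_strand_diff_frame")
  if (opp) return("opposite_strand")
  "no_overlap"
}

#' Rescue ORFs from peptide evidence
#'
#' End-to-end rescue: locates the given peptides in six-frame space, keeps
#' peptides found in exactly one stop-bounded segment, extracts one ORF per
#' segment (all peptides of a segment attach to it), applies the minimum
#' length and the novelty filter against the predicted proteome of the same
#' genome, and classifies each surviving ORF against the gene models.
#'
#' @param rescue_psms `psm_table` (or data.table with `peptide`,
#'   `sample_id`) of PSMs identified against the six-frame database.
#' @param contigs `DNAStringSet` or named character vector.
#' @param genes `gene_models` table.
#' @param proteome predicted proteome (`AAStringSet`), names = gene ids.
#' @param genome_of_contig named vector contig -> genome; genome of a gene is
#'   taken from its contig.
#' @param min_identity novelty threshold (default 0.70).
#' @param min_len_aa minimum ORF length (default 20 aa).
#' @param keep_matches invert the novelty filter (see [novelty_filter()]).
#' @return data.table of rescued ORFs: `orf_id`, `contig_id`, `strand`,
#'   `frame`, `start`, `end`, `aa`, `peptides` (list), `psm_count`,
#'   `n_samples`, `start_missing`, `relation`.
#' @export
rescue_orfs <- function(rescue_psms, contigs, genes, proteome,
                        genome_of_contig, min_identity = 0.70,
                        min_len_aa = 20L, keep_matches = FALSE) {
  empty <- data.table::data.table(
    orf_id = character(), contig_id = character(), strand = character(),
    frame = character(), start = integer(), end = integer(), aa = character(),
    peptides = list(), psm_count = integer(), n_samples = integer(),
    start_missing = logical(), relation = character())
  if (nrow(rescue_psms) == 0L) return(empty)
  peptides <- unique(rescue_psms$peptide)
  pep_psms <- rescue_psms[, .(psm_count = .N,
                              n_samples = data.table::uniqueN(sample_id)),
                          by = peptide]
  sfs <- lapply(as.list(as.character(contigs)), six_frame_translate)
  hits <- find_peptide_hits(peptides, sfs)
  if (!nrow(hits)) return(empty)
  ## segment identity per hit
  hits[, seg_start := vapply(seq_len(.N), function(i)
    segment_bounds(sfs[[contig_id[i]]]$aa[[frame[i]]], aa_pos[i])[1],
    integer(1))]
  hits[, seg_key := paste(contig_id, frame, seg_start)]
  n_seg <- hits[, .(n = data.table::uniqueN(seg_key)), by = peptide]
  ambiguous <- n_seg[n > 1L, peptide]
  if (length(ambiguous))
    warning(length(ambiguous), " peptide(s) found in multiple six-frame ",
            "segments; skipped")
  hits <- hits[!peptide %in% ambiguous]
  if (!nrow(hits)) return(empty)
  genome_of_gene <- setNames(unname(genome_of_contig[genes$contig_id]),
                             genes$gene_id)
  prot_chr <- setNames(as.character(proteome), names(proteome))
  out <- list()
  for (sk in unique(hits$seg_key)) {
    hh <- hits[seg_key == sk]
    cid <- hh$contig_id[1]; fr <- hh$frame[1]
    anchor <- hh[which.min(aa_pos)]
    orf <- extract_orf(sfs[[cid]], fr, anchor$aa_pos, anchor$peptide)
    if (nchar(orf$aa) < min_len_aa) next
    gme <- genome_of_contig[[cid]]
    same_genome <- prot_chr[!is.na(genome_of_gene[names(prot_chr)]) &
                              genome_of_gene[names(prot_chr)] == gme]
    if (!novelty_filter(orf$aa, same_genome, min_identity, keep_matches))
      next
    rel <- classify_orf_relation(
      list(contig_id = cid, strand = orf$strand,
           start = orf$start, end = orf$end),
      genes, contig_length = sfs[[cid]]$length)
    peps <- sort(unique(hh$peptide))
    out[[length(out) + 1L]] <- data.table::data.table(
      contig_id = cid, strand = orf$strand, frame = fr,
      start = orf$start, end = orf$end, aa = orf$aa,
      peptides = list(peps),
      psm_count = sum(pep_psms[peptide %in% peps, psm_count]),
      n_samples = max(pep_psms[peptide %in% peps, n_samples]),
      start_missing = orf$start_missing, relation = rel)
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, contig_id, start, frame)
  res[, orf_id := sprintf("RESCUED%04d", .I)]
  data.table::setcolorder(res, "orf_id")
  res[]
}

#' Cluster rescued ORFs by sequence identity
#'
#' Single-linkage grouping on pairwise local-alignment identity (over the
#' shorter sequence) at or above `min_identity`; groups need at least 2
#' members, everything else stays unclustered.
#'
#' @param orfs rescued-ORF table (needs `orf_id`, `aa`).
#' @param min_identity identity threshold (default 0.70).
#' @return data.table orf_id/cluster_id (`NA` for singletons).
#' @export
cluster_orfs <- function(orfs, min_identity = 0.70) {
  n <- nrow(orfs)
  out <- data.table::data.table(orf_id = orfs$orf_id,
                                cluster_id = NA_character_)
  if (n < 2L) return(out)
  aas <- Biostrings::AAStringSet(setNames(orfs$aa, orfs$orf_id))
  edges <- list()
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = aas[(i + 1L):n], subject = aas[[i]], type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    idn <- Biostrings::nmatch(aln) /
      pmin(nchar(orfs$aa[(i + 1L):n]), nchar(orfs$aa[i]))
    hit <- which(idn >= min_identity)
    if (length(hit))
      edges[[length(edges) + 1L]] <- cbind(orfs$orf_id[i],
                                           orfs$orf_id[i + hit])
  }
  if (!length(edges)) return(out)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  comp <- igraph::components(g)
  grp <- split(names(comp$membership), comp$membership)
  grp <- grp[lengths(grp) >= 2L]
  for (k in seq_along(grp))
    out[orf_id %in% grp[[k]], cluster_id := sprintf("ORFGRP%03d", k)]
  out[]
}

#' Write rescued ORFs as GFF3 and FASTA
#'
#' GFF3 feature type CDS with attributes `rescued=true`, `relation` and
#' `psm_count`; the FASTA holds the amino-acid sequences.
#'
#' @param orfs rescued-ORF table from [rescue_orfs()].
#' @param gff_path,faa_path output paths (either may be NULL to skip).
#' @export
write_rescued_orfs <- function(orfs, gff_path = NULL, faa_path = NULL) {
  if (!is.null(gff_path)) {
    gm <- data.table::data.table(
      gene_id = orfs$orf_id, contig_id = orfs$contig_id,
      start = orfs$start, end = orfs$end, strand = orfs$strand,
      source = "proteoscape")
    write_gene_models(gm, gff_path, feature_type = "CDS",
                      extra = data.frame(rescued = rep("true", nrow(orfs)),
                                         relation = orfs$relation,
                                         psm_count = orfs$psm_count))
  }
  if (!is.null(faa_path))
    write_fasta(Biostrings::AAStringSet(setNames(orfs$aa, orfs$orf_id)),
                faa_path)
  invisible(NULL)
}
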