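## Operon candidates: maximal runs of same-contig, same-strand genes whose
## consecutive intergenic gaps are at most `max_gap` bases, then filtered by
## metaproteomic spectral support.

#' Cluster adjacent genes into operon candidates
#'
#' Genes are grouped per contig and strand and sorted by start; a candidate
#' is a maximal run where every adjacent intergenic gap (next start minus
#' previous end) is at most `max_gap`. Overlapping same-strand genes count
#' as gap 0 (with a warning). Runs of a single gene are discarded.
#'
#' @param genes `gene_models` data.table (0-based half-open coordinates).
#' @param max_gap maximum intergenic distance in bases (default 100).
#' @return data.table with `operon_id`, `contig_id`, `strand`, `start`,
#'   `end`, `gene_ids` (list column), `n_members`.
#' @export
cluster_genes <- function(genes, max_gap = 100L) {
  g <- data.table::as.data.table(genes)
  data.table::setorder(g, contig_id, strand, start, gene_id)
  out <- list()
  warned <- FALSE
  for (grp in split(g, by = c("contig_id", "strand"), sorted = TRUE)) {
    if (nrow(grp) < 2L) next
    gap <- grp$start[-1] - grp$end[-nrow(grp)]
    if (any(gap < 0) && !warned) {
      warning("overlapping same-strand genes; treating gap as 0")
      warned <- TRUE
    }
    gap <- pmax(gap, 0L)
    run <- cumsum(c(0L, as.integer(gap > max_gap)))
    for (r in split(seq_len(nrow(grp)), run)) {
      if (length(r) < 2L) next
      out[[length(out) + 1L]] <- data.table::data.table(
        contig_id = grp$contig_id[1], strand = grp$strand[1],
        start = min(grp$start[r]), end = max(grp$end[r]),
        gene_ids = list(grp$gene_id[r]), n_members = length(r))
    }
  }
  if (!length(out))
    return(data.table::data.table(operon_id = character(),
                                  contig_id = character(), strand = character(),
                                  start = integer(), end = integer(),
                                  gene_ids = list(), n_members = integer()))
  res <- data.table::rbindlist(out)
  data.table::setorder(res, contig_id, start, strand)
  res[, operon_id := sprintf("OC%04d", .I)]
  data.table::setcolorder(res, "operon_id")
  res[]
}

#' Split operon candidates by spectral support
#'
#' A member gene is "evidenced" when it has at least `min_spectra` spectra in
#' each of at least `min_samples` samples; a candidate is supported when the
#' evidenced fraction of its members reaches `min_fraction`.
#'
#' @param candidates output of [cluster_genes()].
#' @param counts proteins x samples spectral count matrix.
#' @param min_samples,min_spectra,min_fraction the support rule (defaults
#'   2 samples, 2 spectra per supporting sample, half of the members).
#' @return the candidates with added columns `evidenced_members` and
#'   `supported` (logical); supported and unsupported rows partition the
#'   input.
#' @export
filter_spectral_support <- function(candidates, counts, min_samples = 2L,
                                    min_spectra = 2L, min_fraction = 0.5) {
  evidenced <- function(p) {
    if (!p %in% rownames(counts)) return(FALSE)
    sum(counts[p, ] >= min_spectra) >= min_samples
  }
  res <- data.table::copy(candidates)
  res[, evidenced_members := vapply(gene_ids, function(ids)
    sum(vapply(ids, evidenced, logical(1))), integer(1))]
  res[, supported := evidenced_members / n_members >= min_fraction]
  res[]
}

#' Match two operon lists by genomic overlap
#'
#' Candidate pairs on the same contig are matched greedily by decreasing
#' overlap length (ties toward the leftmost pair); each operon matches at
#' most once. Two criteria: `"region70"` requires overlap >
#' 0.70 x the smaller span; `"half_smaller"` requires overlap >= 0.5 x the
#' smaller span.
#'
#' @param list_a,list_b data.tables with `contig_id`, `start`, `end` (`a` is
#'   "ours", `b` the external prediction).
#' @param criterion `"region70"` or `"half_smaller"`.
#' @param min_overlap_frac overrides the criterion's fraction if not NULL.
#' @return list with `matches` (data.table a_idx/b_idx/overlap) and
#'   `agreement` (matched fraction of `list_a`).
#' @export
operon_overlap <- function(list_a, list_b,
                           criterion = c("region70", "half_smaller"),
                           min_overlap_frac = NULL) {
  criterion <- match.arg(criterion)
  pairs <- list()
  for (i in seq_len(nrow(list_a))) for (j in seq_len(nrow(list_b))) {
    if (list_a$contig_id[i] != list_b$contig_id[j]) next
    ov <- min(list_a$end[i], list_b$end[j]) -
      max(list_a$start[i], list_b$start[j])
    if (ov <= 0) next
    smaller <- min(list_a$end[i] - list_a$start[i],
                   list_b$end[j] - list_b$start[j])
    frac <- ov / smaller
    hit <- if (!is.null(min_overlap_frac)) frac >= min_overlap_frac
           else if (criterion == "region70") frac > 0.70
           else ov >= 0.5 * smaller
    if (hit)
      pairs[[length(pairs) + 1L]] <- data.table::data.table(
        a_idx = i, b_idx = j, overlap = ov,
        left = min(list_a$start[i], list_b$start[j]))
  }
  matches <- data.table::data.table(a_idx = integer(), b_idx = integer(),
                                    overlap = integer())
  if (length(pairs)) {
    pairs <- data.table::rbindlist(pairs)
    data.table::setorder(pairs, -overlap, left, a_idx, b_idx)
    used_a <- logical(nrow(list_a)); used_b <- logical(nrow(list_b))
    keep <- integer()
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$a_idx[k]; j <- pairs$b_idx[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- used_b[j] <- TRUE
      keep <- c(keep, k)
    }
    matches <- pairs[keep, .(a_idx, b_idx, overlap)]
  }
  list(matches = matches,
       agreement = if (nrow(list_a)) nrow(matches) / nrow(list_a) else NA_real_)
}

#' Write operon candidates as CSV
#'
#' Columns: contig, strand, start, end, gene_ids (comma-joined), supported,
#' evidenced_members.
#'
#' @param candidates (supported-annotated) candidate table.
#' @param path output CSV path.
#' @export
write_operons <- function(candidates, path) {
  dt <- data.table::data.table(
    operon_id = candidates$operon_id,
    contig = candidates$contig_id, strand = candidates$strand,
    start = candidates$start, end = candidates$end,
    gene_ids = vapply(candidates$gene_ids, paste, character(1),
                      collapse = ","),
    supported = if ("supported" %in% names(candidates))
      candidates$supported else NA,
    evidenced_members = if ("evidenced_members" %in% names(candidates))
      candidates$evidenced_members else NA)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read an external operon list (e.g. fgenesB output)
#'
#' @param path CSV with columns contig, start, end (1-based closed or
#'   0-based half-open per `coords`).
#' @param coords coordinate convention of the file.
#' @return data.table contig_id/start/end in 0-based half-open coordinates.
#' @export
read_operon_list <- function(path, coords = c("0based", "1based")) {
  coords <- match.arg(coords)
  dt <- data.table::fread(path)
  nm <- names(dt)
  cid <- nm[grepl("contig", nm, ignore.case = TRUE)][1]
  out <- data.table::data.table(contig_id = as.character(dt[[cid]]),
                                start = as.integer(dt$start),
                                end = as.integer(dt$end))
  if (coords == "1based") out[, start := start - 1L]
  out[]
}
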