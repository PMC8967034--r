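## Spectral allocation: unique spectra first, then weighted assignment of
## multi-mapped spectra by same-sample unique counts, then normalization by
## proteome size (per million amino acids) and per-sample identified spectra.

#' Assign uniquely mapped spectra to genomes
#'
#' A PSM contributes one count to a genome in its sample iff all of its
#' accessions map to that single genome. PSMs whose accessions span several
#' genomes are returned as the shared pool for [allocate_shared()].
#'
#' @param psm an FDR- and QC-filtered `psm_table`.
#' @param genome_map named character vector, accession -> genome id.
#' @return list with `unique` (data.table genome/sample_id/count) and
#'   `shared` (data.table sample_id, genomes list column, one row per PSM).
#' @export
assign_unique <- function(psm, genome_map) {
  all_acc <- unique(unlist(psm$accessions))
  orphans <- setdiff(all_acc, names(genome_map))
  if (length(orphans))
    stop("accession(s) absent from genome map: ",
         paste(head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ...")
  gsets <- lapply(psm$accessions, function(a) unique(unname(genome_map[a])))
  k <- lengths(gsets)
  uniq <- data.table::data.table(
    genome = unlist(gsets[k == 1L]),
    sample_id = psm$sample_id[k == 1L])
  uniq <- uniq[, .(count = .N), by = .(genome, sample_id)]
  shared <- data.table::data.table(
    sample_id = psm$sample_id[k > 1L],
    genomes = gsets[k > 1L])
  list(unique = uniq, shared = shared)
}

#' Allocate multi-mapped spectra by unique-count weights
#'
#' Each shared spectrum over genomes g1..gk is split in proportion to the
#' genomes' unique counts in the same sample; genomes with zero unique counts
#' in the sharing set receive nothing, and a spectrum all of whose sharers
#' have zero unique counts is dropped (such genomes are not considered
#' further).
#'
#' @param shared the shared pool from [assign_unique()].
#' @param unique_counts the `unique` table from [assign_unique()].
#' @return list with `allocated` (data.table genome/sample_id/count, counts
#'   fractional) and `dropped` (data.table sample_id/count).
#' @export
allocate_shared <- function(shared, unique_counts) {
  u <- unique_counts
  key <- paste(u$genome, u$sample_id)
  uvec <- setNames(u$count, key)
  alloc <- list(); drop_n <- integer()
  if (nrow(shared)) {
    for (i in seq_len(nrow(shared))) {
      gs <- shared$genomes[[i]]
      s <- shared$sample_id[i]
      w <- uvec[paste(gs, s)]
      w[is.na(w)] <- 0
      if (sum(w) == 0) {
        drop_n[s] <- (if (is.na(drop_n[s])) 0L else drop_n[s]) + 1L
        next
      }
      alloc[[length(alloc) + 1L]] <- data.table::data.table(
        genome = gs, sample_id = s, count = w / sum(w))
    }
  }
  allocated <- if (length(alloc)) {
    a <- data.table::rbindlist(alloc)
    a <- a[count > 0, .(count = sum(count)), by = .(genome, sample_id)]
    a
  } else data.table::data.table(genome = character(), sample_id = character(),
                                count = numeric())
  dropped <- data.table::data.table(sample_id = names(drop_n),
                                    count = unname(drop_n))
  list(allocated = allocated, dropped = dropped)
}

#' Build a spectral count matrix
#'
#' Combines unique and allocated counts into a genomes x samples matrix with
#' the metadata needed for normalization.
#'
#' @param unique_counts,allocated count tables (genome/sample_id/count).
#' @param proteome_size_aa named vector of proteome sizes in amino acids.
#' @param total_spectra named vector of identified spectra per sample; when
#'   `NULL`, column sums are used.
#' @return a `spectral_count_matrix`: numeric matrix with attributes
#'   `proteome_size_aa`, `total_spectra`, `normalized`.
#' @export
spectral_count_matrix <- function(unique_counts, allocated = NULL,
                                  proteome_size_aa = NULL,
                                  total_spectra = NULL) {
  cnt <- if (is.null(allocated)) unique_counts
         else rbind(unique_counts, allocated)
  cnt <- cnt[, .(count = sum(count)), by = .(genome, sample_id)]
  gl <- sort(unique(cnt$genome)); sl <- sort(unique(cnt$sample_id))
  m <- matrix(0, length(gl), length(sl), dimnames = list(gl, sl))
  m[cbind(match(cnt$genome, gl), match(cnt$sample_id, sl))] <- cnt$count
  if (is.null(total_spectra)) total_spectra <- colSums(m)
  structure(m,
            proteome_size_aa = proteome_size_aa,
            total_spectra = total_spectra,
            normalized = "none",
            class = c("spectral_count_matrix", "matrix", "array"))
}

#' Normalize a spectral count matrix
#'
#' `"proteome"` divides by proteome size and rescales to counts per million
#' amino acids; `"depth"` divides by the total identified spectra of the
#' sample; `"both"` (the default) applies proteome-size normalization first,
#' then depth: value' = (value / proteome_size_aa * 1e6) / total_spectra.
#'
#' @param m a `spectral_count_matrix`.
#' @param by which normalization to apply.
#' @return the normalized matrix (same class, `normalized` attribute set).
#' @export
normalize_scm <- function(m, by = c("both", "proteome", "depth")) {
  by <- match.arg(by)
  out <- unclass(m)
  if (by %in% c("both", "proteome")) {
    ps <- attr(m, "proteome_size_aa")
    if (is.null(ps)) stop("proteome sizes missing")
    ps <- ps[rownames(out)]
    if (any(is.na(ps) | ps == 0)) stop("proteome size missing or zero for: ",
      paste(rownames(out)[is.na(ps) | ps == 0], collapse = ", "))
    out <- sweep(out, 1, ps, "/") * 1e6
  }
  if (by %in% c("both", "depth")) {
    ts <- attr(m, "total_spectra")
    if (is.null(ts)) stop("per-sample totals missing")
    ts <- ts[colnames(out)]
    if (any(is.na(ts) | ts == 0)) stop("sample total missing or zero")
    out <- sweep(out, 2, ts, "/")
  }
  structure(out,
            proteome_size_aa = attr(m, "proteome_size_aa"),
            total_spectra = attr(m, "total_spectra"),
            normalized = by,
            class = class(m))
}

#' Genome-level quantification, end to end
#'
#' Runs [assign_unique()] and [allocate_shared()] and assembles raw and
#' normalized genome x sample matrices.
#'
#' @param psm filtered `psm_table`.
#' @param genome_map accession -> genome named vector.
#' @param proteome_size_aa named vector, amino acids per genome.
#' @return list with `raw` and `normalized` matrices, plus the `dropped`
#'   report from allocation.
#' @export
quantify_genomes <- function(psm, genome_map, proteome_size_aa = NULL) {
  parts <- assign_unique(psm, genome_map)
  alloc <- allocate_shared(parts$shared, parts$unique)
  total <- table(psm$sample_id)
  total_spectra <- setNames(as.numeric(total), names(total))
  raw <- spectral_count_matrix(parts$unique, alloc$allocated,
                               proteome_size_aa = proteome_size_aa,
                               total_spectra = total_spectra)
  norm <- if (!is.null(proteome_size_aa)) normalize_scm(raw, "both") else NULL
  list(raw = raw, normalized = norm, dropped = alloc$dropped)
}

#' Protein-level spectral counts
#'
#' Counts each PSM toward every protein accession it matches (the usual
#' spectral-counting convention for building per-protein expression
#' profiles). Returns a proteins x samples integer matrix.
#'
#' @param psm filtered `psm_table`.
#' @param proteins optional protein universe for the row set.
#' @return integer matrix proteins x samples.
#' @export
protein_count_matrix <- function(psm, proteins = NULL) {
  long <- data.table::data.table(
    protein_id = unlist(psm$accessions),
    sample_id = rep(psm$sample_id, lengths(psm$accessions)))
  cnt <- long[, .(count = .N), by = .(protein_id, sample_id)]
  pl <- if (is.null(proteins)) sort(unique(cnt$protein_id)) else proteins
  sl <- sort(unique(psm$sample_id))
  m <- matrix(0L, length(pl), length(sl), dimnames = list(pl, sl))
  hit <- cnt$protein_id %in% pl
  m[cbind(match(cnt$protein_id[hit], pl), match(cnt$sample_id[hit], sl))] <-
    cnt$count[hit]
  m
}

#' Write a count matrix as TSV
#'
#' Rows are genomes/proteins, columns are samples; first column `id`. A JSON
#' sidecar (same path + `.json`) records the normalization state and
#' metadata.
#'
#' @param m a matrix (optionally a `spectral_count_matrix`).
#' @param path output TSV path.
#' @export
write_count_matrix <- function(m, path) {
  dt <- data.table::data.table(id = rownames(m))
  for (cn in colnames(m)) dt[[cn]] <- unname(m[, cn])
  data.table::fwrite(dt, path, sep = "\t")
  meta <- list(normalized = attr(m, "normalized") %||% "none",
               proteome_size_aa = as.list(attr(m, "proteome_size_aa")),
               total_spectra = as.list(attr(m, "total_spectra")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
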