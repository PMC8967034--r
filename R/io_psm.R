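#' Column dialect for PSM tables
#'
#' Describes how the columns of a tab-separated PSM table map onto the fields
#' of a PSM record. Defaults follow the MSGF+ TSV layout: one row per PSM,
#' protein accessions concatenated with a separator, decoys marked by an
#' accession prefix, and a score where higher is better (e.g. a transformed
#' spectral E-value).
#'
#' @param spectrum_id,sample_id,peptide,protein,score column names in the file.
#' @param is_decoy optional column name holding a logical decoy flag. When
#'   `NULL` (the default) decoy status is derived from `decoy_prefix`: a PSM
#'   is a decoy iff all of its accessions carry the prefix.
#' @param accession_sep separator between multiple accessions in the protein
#'   column.
#' @param decoy_prefix accession prefix marking decoy (reversed) proteins.
#' @return a named list of class `psm_dialect`.
#' @export
psm_dialect <- function(spectrum_id = "SpecID", sample_id = "Sample",
                        peptide = "Peptide", protein = "Protein",
                        score = "Score", is_decoy = NULL,
                        accession_sep = ";", decoy_prefix = "XXX_") {
  structure(list(spectrum_id = spectrum_id, sample_id = sample_id,
                 peptide = peptide, protein = protein, score = score,
                 is_decoy = is_decoy, accession_sep = accession_sep,
                 decoy_prefix = decoy_prefix),
            class = "psm_dialect")
}

#' Read a PSM table
#'
#' Parses a tab-separated PSM table (MSGF+-style, one row per PSM) into a
#' `psm_table`: a data.table with columns `spectrum_id`, `sample_id`,
#' `peptide`, `accessions` (list column of character vectors), `score` and
#' `is_decoy`. Rows with an empty peptide or an empty accession field are
#' skipped with a warning naming their line numbers.
#'
#' @param path path to a TSV file with a header row.
#' @param dialect a [psm_dialect()] mapping file columns to record fields.
#' @return a `psm_table` (data.table).
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  stopifnot(inherits(dialect, "psm_dialect"))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = dialect$peptide))
  if (nrow(dt) == 0L) {
    warning("empty PSM table: ", path)
    return(empty_psm_table())
  }
  required <- c(dialect$spectrum_id, dialect$sample_id, dialect$peptide,
                dialect$protein, dialect$score, dialect$is_decoy)
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("PSM table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  as_psm_table(dt, dialect, origin = path)
}

empty_psm_table <- function() {
  out <- data.table::data.table(
    spectrum_id = character(), sample_id = character(), peptide = character(),
    accessions = list(), score = numeric(), is_decoy = logical())
  data.table::setattr(out, "class", c("psm_table", class(out)))
  out[]
}

as_psm_table <- function(dt, dialect, origin = "<data>") {
  out <- data.table::data.table(
    spectrum_id = as.character(dt[[dialect$spectrum_id]]),
    sample_id   = as.character(dt[[dialect$sample_id]]),
    peptide     = toupper(as.character(dt[[dialect$peptide]])),
    score       = as.numeric(dt[[dialect$score]]))
  acc_raw <- as.character(dt[[dialect$protein]])
  out[, accessions := strsplit(acc_raw, dialect$accession_sep, fixed = TRUE)]
  out[, accessions := lapply(accessions, function(a) a[!is.na(a) & a != ""])]
  if (is.null(dialect$is_decoy)) {
    out[, is_decoy := vapply(accessions, function(a)
      length(a) > 0L && all(startsWith(a, dialect$decoy_prefix)), logical(1))]
  } else {
    out[, is_decoy := as.logical(dt[[dialect$is_decoy]])]
  }
  bad <- which(is.na(out$peptide) | out$peptide == "" |
                 lengths(out$accessions) == 0L)
  if (length(bad)) {
    warning("skipping ", length(bad), " malformed PSM row(s) in ", origin,
            " (line ", paste(bad + 1L, collapse = ", "), ")")
    out <- out[-bad]
  }
  data.table::setattr(out, "class", c("psm_table", class(out)))
  out[]
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: serializes a `psm_table` back to the TSV
#' dialect, joining accessions with the dialect separator.
#'
#' @param psm a `psm_table`.
#' @param path output path.
#' @param dialect a [psm_dialect()].
#' @export
write_psm_table <- function(psm, path, dialect = psm_dialect()) {
  out <- data.table::data.table(
    V1 = psm$spectrum_id, V2 = psm$sample_id, V3 = psm$peptide,
    V4 = vapply(psm$accessions, paste, character(1),
                collapse = dialect$accession_sep),
    V5 = psm$score)
  data.table::setnames(out, c(dialect$spectrum_id, dialect$sample_id,
                              dialect$peptide, dialect$protein, dialect$score))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter PSMs at a target-decoy false discovery rate
#'
#' Finds the most permissive score threshold at which the estimated FDR,
#' computed as (number of decoy records at or above the threshold) / (number
#' of target records at or above the threshold), does not exceed `fdr`, and
#' returns the target records passing it. Decoys are excluded from the kept
#' set. With `level = "peptide"` the threshold is computed on the best score
#' per peptide and target PSMs of surviving peptides are kept.
#'
#' @param psm a `psm_table` with `is_decoy` flags.
#' @param fdr the FDR ceiling, in (0, 1). Default 0.01.
#' @param level `"psm"` (default) or `"peptide"`.
#' @return list with elements `psms` (kept target records) and `threshold`
#'   (the score threshold; `Inf` when no threshold attains the FDR).
#' @export
fdr_filter <- function(psm, fdr = 0.01, level = c("psm", "peptide")) {
  stopifnot(fdr > 0, fdr < 1)
  level <- match.arg(level)
  if (!any(!psm$is_decoy)) {
    warning("no target records; returning empty set")
    return(list(psms = empty_psm_table(), threshold = Inf))
  }
  units <- if (level == "peptide") {
    psm[, .(score = max(score), is_decoy = all(is_decoy)), by = peptide]
  } else {
    psm[, .(score, is_decoy)]
  }
  ord <- order(units$score, decreasing = TRUE)
  sc <- units$score[ord]
  dec <- units$is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  # candidate thresholds at the last index of each tied score block
  last_of_block <- c(sc[-1] != sc[-length(sc)], TRUE)
  ratio <- ifelse(n_tgt == 0, Inf, n_dec / n_tgt)
  ok <- which(last_of_block & ratio <= fdr)
  if (!length(ok)) {
    warning("FDR ", fdr, " unattainable at any score threshold")
    return(list(psms = empty_psm_table(), threshold = Inf))
  }
  threshold <- sc[max(ok)]
  kept <- if (level == "peptide") {
    good_pep <- units$peptide[units$score >= threshold & !units$is_decoy]
    psm[!is_decoy & peptide %in% good_pep]
  } else {
    psm[!is_decoy & score >= threshold]
  }
  data.table::setattr(kept, "class", class(empty_psm_table()))
  list(psms = kept[], threshold = threshold)
}

#' Sample quality control by unique peptide count
#'
#' Keeps samples in which at least `min_unique_peptides` distinct peptide
#' sequences were identified (after FDR filtering). Peptide identity ignores
#' modifications and charge: equality of the plain sequence string.
#'
#' @param psm an FDR-filtered `psm_table`.
#' @param min_unique_peptides minimum distinct peptides per sample
#'   (default 1000).
#' @return character vector of kept sample ids.
#' @export
qc_filter_samples <- function(psm, min_unique_peptides = 1000L) {
  if (nrow(psm) == 0L) return(character())
  n <- psm[, .(n_pep = data.table::uniqueN(peptide)), by = sample_id]
  sort(n[n_pep >= min_unique_peptides, sample_id])
}

#' Read a sample manifest
#'
#' CSV with columns `sample_id,phenotype[,fraction_of]`. When `fraction_of`
#' is present, rows are MS fractions and the column names the sample each
#' fraction belongs to; [merge_fractions()] collapses fraction ids in a PSM
#' table accordingly.
#'
#' @param path CSV path.
#' @return data.table with columns `sample_id`, `phenotype` and optionally
#'   `fraction_of`.
#' @export
read_sample_manifest <- function(path) {
  m <- data.table::fread(path, colClasses = "character")
  if (!all(c("sample_id", "phenotype") %in% names(m)))
    stop("manifest must have columns sample_id, phenotype")
  m
}

#' Merge fractionated samples
#'
#' Replaces fraction ids in `sample_id` by their parent sample, following the
#' `fraction_of` column of the manifest.
#'
#' @param psm a `psm_table`.
#' @param manifest manifest from [read_sample_manifest()].
#' @return the `psm_table` with collapsed sample ids.
#' @export
merge_fractions <- function(psm, manifest) {
  if (!"fraction_of" %in% names(manifest)) return(psm)
  map <- manifest$fraction_of
  names(map) <- manifest$sample_id
  map[is.na(map) | map == ""] <- names(map)[is.na(map) | map == ""]
  hit <- psm$sample_id %in% names(map)
  psm[hit, sample_id := map[sample_id]]
  psm[]
}

#' Validate a PSM table against a manifest
#'
#' Checks that every sample id occurring in the PSM table is declared in the
#' manifest.
#'
#' @param psm a `psm_table`.
#' @param manifest manifest from [read_sample_manifest()].
#' @return invisibly `TRUE`; errors listing unknown samples otherwise.
#' @export
check_manifest <- function(psm, manifest) {
  unknown <- setdiff(unique(psm$sample_id), manifest$sample_id)
  if (length(unknown))
    stop("sample id(s) absent from manifest: ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}
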