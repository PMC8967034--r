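## Function annotation: COG hit filtering with the category-S fallback,
## parsimonious (MinPath-style) pathway minimization, and COG-category
## relative-abundance profiles.

#' Read a COG/KO hit table
#'
#' DIAMOND/BLAST tabular style TSV with a header; required columns `query`,
#' `cog_id`, `domain_coverage` (fraction of the reference domain covered by
#' the alignment) and `e_value`; optional `category` (COG single-letter
#' categories).
#'
#' @param path TSV path.
#' @return data.table of hits.
#' @export
read_hit_table <- function(path) {
  dt <- data.table::fread(path)
  need <- c("query", "cog_id", "domain_coverage", "e_value")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("hit table missing column(s): ",
                         paste(miss, collapse = ", "))
  dt
}

#' Filter COG hits and assign categories
#'
#' A hit survives when the alignment covers at least `min_coverage` of the
#' COG domain length and its e-value is at most `max_evalue`. Proteins with
#' no surviving hit are assigned category `"S"` (function unknown).
#'
#' @param hits hit table (see [read_hit_table()]).
#' @param proteins the full protein universe (so unhit proteins get S).
#' @param min_coverage domain-coverage threshold (default 0.5).
#' @param max_evalue e-value ceiling (default 0.01).
#' @return data.table protein_id/cog_id/category; one row per surviving hit
#'   plus an S row for each protein without one.
#' @export
filter_cog_hits <- function(hits, proteins = NULL, min_coverage = 0.5,
                            max_evalue = 0.01) {
  keep <- hits[domain_coverage >= min_coverage & e_value <= max_evalue]
  out <- data.table::data.table(protein_id = keep$query,
                                cog_id = keep$cog_id,
                                category = if ("category" %in% names(keep))
                                  keep$category else NA_character_)
  universe <- unique(c(proteins, hits$query))
  unhit <- setdiff(universe, out$protein_id)
  if (length(unhit))
    out <- rbind(out, data.table::data.table(protein_id = unhit,
                                             cog_id = NA_character_,
                                             category = "S"))
  data.table::setorder(out, protein_id)
  out[]
}

#' Parsimonious pathway minimization
#'
#' Finds a minimum-cardinality set of pathways whose union covers every
#' coverable function (the MinPath idea: the naive function-to-pathway map
#' overestimates pathways). Exact branch-and-bound when at most
#' `exact_limit` candidate pathways are involved; greedy set cover beyond
#' that, flagged in the result.
#'
#' @param functions character vector of observed function ids (COG/KO).
#' @param pathway_map named list pathway -> character vector of functions.
#' @param exact_limit maximum candidate count for the exact solver.
#' @return list: `pathways` (minimal set), `unexplained` (functions in no
#'   pathway), `method` ("exact" or "greedy").
#' @export
minimize_pathways <- function(functions, pathway_map, exact_limit = 20L) {
  functions <- unique(functions)
  cover <- lapply(pathway_map, intersect, functions)
  cover <- cover[lengths(cover) > 0]
  coverable <- unique(unlist(cover))
  unexplained <- setdiff(functions, coverable)
  if (!length(cover))
    return(list(pathways = character(), unexplained = unexplained,
                method = "exact"))
  ## drop dominated duplicates (same covered set -> keep first name)
  keys <- vapply(cover, function(s) paste(sort(s), collapse = "|"),
                 character(1))
  cover <- cover[!duplicated(keys)]
  if (length(cover) <= exact_limit) {
    sel <- set_cover_exact(cover, coverable)
    method <- "exact"
  } else {
    sel <- set_cover_greedy(cover, coverable)
    method <- "greedy"
  }
  list(pathways = sort(sel), unexplained = unexplained, method = method)
}

## exact minimum set cover by depth-first branch and bound
set_cover_exact <- function(cover, universe) {
  nm <- names(cover)
  best <- set_cover_greedy(cover, universe)  # upper bound
  recurse <- function(chosen, remaining, avail) {
    if (!length(remaining)) {
      if (length(chosen) < length(best)) best <<- chosen
      return()
    }
    if (length(chosen) + 1L >= length(best)) {
      ## one more pick must finish the cover to improve
      full <- avail[vapply(cover[avail], function(s)
        all(remaining %in% s), logical(1))]
      if (length(full) && length(chosen) + 1L < length(best))
        best <<- c(chosen, full[1])
      return()
    }
    ## branch on an uncovered element: one of its covering sets must be in
    el <- remaining[1]
    for (p in avail[vapply(cover[avail], function(s) el %in% s, logical(1))]) {
      recurse(c(chosen, p), setdiff(remaining, cover[[p]]),
              setdiff(avail, p))
    }
  }
  recurse(character(), universe, nm)
  best
}

set_cover_greedy <- function(cover, universe) {
  chosen <- character()
  remaining <- universe
  while (length(remaining)) {
    gain <- vapply(cover, function(s) length(intersect(s, remaining)),
                   integer(1))
    if (max(gain) == 0L) break
    ## ties: pathway name order, for determinism
    top <- sort(names(gain)[gain == max(gain)])[1]
    chosen <- c(chosen, top)
    remaining <- setdiff(remaining, cover[[top]])
  }
  chosen
}

#' Read a pathway map
#'
#' Two-column TSV `pathway_id`, `function_id`.
#'
#' @param path TSV path.
#' @return named list pathway -> functions.
#' @export
read_pathway_map <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("pathway_id", "function_id") %in% names(dt)))
    stop("pathway map needs columns pathway_id, function_id")
  split(dt$function_id, dt$pathway_id)
}

#' COG-category relative-abundance profile of a genome
#'
#' Attributes each protein's spectra to its COG category letter(s) -- multi-
#' letter categories are split equally across letters -- and normalizes the
#' resulting vector to sum 1.
#'
#' @param spectra named numeric vector, protein -> total spectral count.
#' @param assignments data.table protein_id/category (from
#'   [filter_cog_hits()]; first row per protein is used).
#' @return named numeric vector over category letters, summing to 1.
#' @export
cog_category_profile <- function(spectra, assignments) {
  if (!length(spectra) || sum(spectra) == 0)
    stop("no spectra: cannot profile an unexpressed genome")
  first <- assignments[!duplicated(protein_id)]
  cat_of <- setNames(first$category, first$protein_id)
  acc <- numeric()
  for (p in names(spectra)) {
    cats <- if (p %in% names(cat_of)) cat_of[[p]] else NA_character_
    if (is.na(cats) || !nzchar(cats)) cats <- "S"
    letters_ <- strsplit(cats, "")[[1]]
    share <- spectra[[p]] / length(letters_)
    for (l in letters_) acc[l] <- (if (is.na(acc[l])) 0 else acc[l]) + share
  }
  acc <- acc[order(names(acc))]
  acc / sum(acc)
}
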