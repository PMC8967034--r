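## Host phenotype specificity: normalized Shannon entropy of a protein's
## expression proportions across the phenotypes where it is expressed.
## HPS = -sum_j p_ij * log_N(p_ij), in [0, 1]; 0 = all mass in one
## phenotype, 1 = uniform over the N phenotypes with nonzero expression.

#' Host phenotype specificity of one expression profile
#'
#' @param p numeric vector of per-phenotype proportions. Zero entries are
#'   removed before N is determined (N is the number of phenotypes the
#'   protein is found expressed in); the rest are renormalized to sum to 1.
#' @param n_base optional logarithm base overriding N (set this to the full
#'   phenotype vocabulary size to measure specificity against the vocabulary
#'   rather than the support).
#' @return HPS in \[0, 1\]. By convention 0 when N = 1 (log base 1 is
#'   degenerate; expression confined to a single phenotype is maximally
#'   specific).
#' @examples
#' compute_hps(c(0.25, 0.25, 0.25, 0.25))  # 1
#' compute_hps(c(1, 0, 0))                 # 0
#' @export
compute_hps <- function(p, n_base = NULL) {
  p <- p[!is.na(p) & p > 0]
  if (!length(p)) stop("HPS undefined: no phenotype with nonzero expression")
  p <- p / sum(p)
  N <- if (is.null(n_base)) length(p) else n_base
  if (N <= 1L || length(p) == 1L && is.null(n_base)) return(0)
  h <- -sum(p * log(p)) / log(N)
  min(max(h, 0), 1)
}

#' HPS table for a protein count matrix
#'
#' Sums depth-normalized spectral counts per phenotype for every protein and
#' scores each with [compute_hps()].
#'
#' @param counts proteins x samples matrix of depth-normalized counts.
#' @param manifest data.table with `sample_id`, `phenotype`.
#' @param genome_of optional named vector protein -> genome for the output.
#' @param vocabulary_n use the full phenotype vocabulary size as the entropy
#'   base instead of each protein's support size (default FALSE).
#' @param min_expression minimum per-phenotype total to count as expressed.
#' @return data.table protein_id, genome_id, N, HPS.
#' @export
hps_table <- function(counts, manifest, genome_of = NULL,
                      vocabulary_n = FALSE, min_expression = 0) {
  stopifnot(all(colnames(counts) %in% manifest$sample_id))
  phen <- setNames(manifest$phenotype, manifest$sample_id)[colnames(counts)]
  groups <- split(seq_len(ncol(counts)), phen)
  per_ph <- vapply(groups, function(ix)
    rowSums(counts[, ix, drop = FALSE]), numeric(nrow(counts)))
  if (nrow(counts) == 1L) per_ph <- matrix(per_ph, nrow = 1,
                                           dimnames = list(rownames(counts),
                                                           names(groups)))
  per_ph[per_ph <= min_expression] <- 0
  keep <- rowSums(per_ph) > 0
  base_n <- if (vocabulary_n) length(unique(manifest$phenotype)) else NULL
  out <- data.table::data.table(
    protein_id = rownames(per_ph)[keep],
    N = rowSums(per_ph[keep, , drop = FALSE] > 0),
    HPS = apply(per_ph[keep, , drop = FALSE], 1, compute_hps,
                n_base = base_n))
  if (!is.null(genome_of))
    out[, genome_id := unname(genome_of[protein_id])]
  out[]
}

#' Per-genome HPS summary
#'
#' Mean HPS per genome, boxplot-ready.
#'
#' @param hps output of [hps_table()] including `genome_id`.
#' @return data.table genome_id, n_proteins, mean_hps, median_hps.
#' @export
hps_genome_summary <- function(hps) {
  stopifnot("genome_id" %in% names(hps))
  hps[, .(n_proteins = .N, mean_hps = mean(HPS), median_hps = median(HPS)),
      by = genome_id]
}
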