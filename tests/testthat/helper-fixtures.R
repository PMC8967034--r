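# Shared fixtures, memoized so the community is generated once per run.

.fx <- new.env(parent = emptyenv())

fixture_community <- function() {
  if (is.null(.fx$cm))
    .fx$cm <- generate_community(community_config(seed = 7))
  .fx$cm
}

fixture_sim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- simulate_psms(fixture_community())
  .fx$sim
}

fixture_filtered <- function() {
  if (is.null(.fx$flt))
    .fx$flt <- fdr_filter(fixture_sim()$psms)$psms
  .fx$flt
}

fixture_protein_counts <- function() {
  if (is.null(.fx$pm))
    .fx$pm <- protein_count_matrix(fixture_filtered())
  .fx$pm
}

# a bare psm_table from plain vectors (accessions as "A;B" strings)
make_psms <- function(sample_id, peptide, accessions, score,
                      is_decoy = FALSE, spectrum_id = NULL) {
  n <- max(length(sample_id), length(peptide), length(accessions),
           length(score))
  dt <- data.table::data.table(
    spectrum_id = spectrum_id %||% sprintf("spec%04d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    peptide = rep_len(peptide, n),
    accessions = strsplit(rep_len(accessions, n), ";", fixed = TRUE),
    score = rep_len(score, n),
    is_decoy = rep_len(is_decoy, n))
  data.table::setattr(dt, "class", c("psm_table", "data.table", "data.frame"))
  dt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force maximum clique size on an adjacency matrix (<= ~15 nodes)
brute_max_clique_size <- function(adj) {
  n <- nrow(adj)
  # node -> bitmask of neighbours
  nb <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1, which(adj[v, ] > 0) - 1L)), numeric(1))
  best <- 0L
  for (s in seq_len(2^n) - 1L) {
    memb <- which(bitwAnd(s, bitwShiftL(1, seq_len(n) - 1L)) > 0)
    if (length(memb) <= best) next
    ok <- all(vapply(memb, function(v)
      bitwAnd(s, nb[v] + bitwShiftL(1, v - 1L)) == s, logical(1)))
    if (ok) best <- length(memb)
  }
  best
}

# brute-force minimum set cover size (small instances)
brute_set_cover_size <- function(cover, universe) {
  nm <- names(cover)
  k <- length(nm)
  best <- Inf
  for (s in seq_len(2^k) - 1L) {
    pick <- nm[bitwAnd(s, bitwShiftL(1, seq_len(k) - 1L)) > 0]
    if (length(pick) >= best) next
    if (all(universe %in% unlist(cover[pick]))) best <- length(pick)
  }
  best
}

random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}
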