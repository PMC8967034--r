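## Protein co-expression networks: edges where sparCC rho >= threshold,
## modules seeded by iteratively removed maximum cliques, remaining nodes
## attached to the seed module they share the most edges with.

#' Build a co-expression network from a correlation matrix
#'
#' @param corr square symmetric correlation matrix with dimnames.
#' @param threshold minimum correlation for an edge (default 0.3; an edge is
#'   drawn when rho >= threshold). Isolated nodes are retained.
#' @return an igraph graph with edge attribute `rho` and graph attribute
#'   `threshold`.
#' @export
build_network <- function(corr, threshold = 0.3) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (is.null(rownames(corr)))
    rownames(corr) <- colnames(corr) <- paste0("p", seq_len(nrow(corr)))
  adj <- corr
  adj[] <- as.numeric(corr >= threshold)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  ee <- igraph::as_edgelist(g)
  igraph::E(g)$rho <- corr[cbind(ee[, 1], ee[, 2])]
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

## deterministic choice among maximum cliques: lexicographically smallest
## sorted member-name vector
pick_clique <- function(cliques) {
  keys <- vapply(cliques, function(cl)
    paste(sort(names(cl)), collapse = "\r"), character(1))
  cliques[[order(keys)[1]]]
}

#' Extract protein modules by iterative maximum-clique mining
#'
#' Repeatedly finds a maximum clique of at least `min_clique` nodes, records
#' it as a seed module, and removes its nodes from the graph. Every leftover
#' node that shares at least one edge with a seed module is then attached to
#' the module it shares the most edges with (ties broken toward the larger
#' module, then the smaller module id). Nodes with no edge into any seed
#' module end up in no module.
#'
#' @param network igraph graph from [build_network()].
#' @param min_clique minimum seed clique size (default 3).
#' @return data.table with columns `module_id`, `protein_id`, `role`
#'   (`"seed"` or `"attached"`).
#' @export
extract_modules <- function(network, min_clique = 3L) {
  g <- network
  seeds <- list()
  repeat {
    if (igraph::vcount(g) == 0L) break
    cl <- igraph::largest_cliques(g)
    if (!length(cl) || length(cl[[1]]) < min_clique) break
    members <- sort(names(pick_clique(cl)))
    seeds[[length(seeds) + 1L]] <- members
    g <- igraph::delete_vertices(g, members)
  }
  if (!length(seeds))
    return(data.table::data.table(module_id = character(),
                                  protein_id = character(),
                                  role = character()))
  module_ids <- sprintf("M%03d", seq_along(seeds))
  out <- data.table::rbindlist(lapply(seq_along(seeds), function(i)
    data.table::data.table(module_id = module_ids[i],
                           protein_id = seeds[[i]], role = "seed")))
  seeded <- out$protein_id
  rest <- setdiff(igraph::V(network)$name, seeded)
  if (length(rest)) {
    adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
    sizes <- lengths(seeds)
    att <- lapply(rest, function(v) {
      shared <- vapply(seeds, function(m) sum(adj[v, m]), numeric(1))
      if (max(shared) == 0) return(NULL)
      best <- which(shared == max(shared))
      if (length(best) > 1L) best <- best[sizes[best] == max(sizes[best])]
      best <- best[1L]  # smallest module id among remaining ties
      data.table::data.table(module_id = module_ids[best], protein_id = v,
                             role = "attached")
    })
    att <- data.table::rbindlist(att[!vapply(att, is.null, logical(1))])
    out <- rbind(out, att)
  }
  data.table::setorder(out, module_id, role, protein_id)
  out[]
}

#' Assign a dominant phenotype to a module
#'
#' A phenotype is assigned when its samples carry at least `dominance` of the
#' module members' total (normalized) spectra; otherwise none.
#'
#' @param members character vector of module protein ids.
#' @param counts proteins x samples matrix of normalized counts.
#' @param manifest data.table sample_id/phenotype.
#' @param dominance required spectral fraction (default 0.75).
#' @return the phenotype label, or `NA_character_`.
#' @export
assign_module_phenotype <- function(members, counts, manifest,
                                    dominance = 0.75) {
  members <- intersect(members, rownames(counts))
  if (!length(members)) return(NA_character_)
  tot <- colSums(counts[members, , drop = FALSE])
  phen <- setNames(manifest$phenotype, manifest$sample_id)[colnames(counts)]
  by_ph <- tapply(tot, phen, sum)
  if (sum(by_ph) == 0) return(NA_character_)
  frac <- by_ph / sum(by_ph)
  if (max(frac) >= dominance) names(frac)[which.max(frac)] else NA_character_
}

#' Suggest pathways for unannotated module members
#'
#' Guilt-by-association: an unannotated protein inherits the union of the
#' pathways of the annotated proteins it shares a module edge with. Proteins
#' with no annotated neighbours (or in fully unannotated modules) receive
#' nothing.
#'
#' @param modules module table from [extract_modules()].
#' @param network the igraph network the modules were extracted from.
#' @param annotations named list protein -> character vector of pathways
#'   (missing or empty entries mean unannotated).
#' @return named list: unannotated protein -> suggested pathway set.
#' @export
suggest_pathways <- function(modules, network, annotations) {
  has_ann <- function(p) !is.null(annotations[[p]]) &&
    length(annotations[[p]]) > 0
  out <- list()
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  for (m in unique(modules$module_id)) {
    memb <- modules[module_id == m, protein_id]
    ann_memb <- memb[vapply(memb, has_ann, logical(1))]
    for (u in setdiff(memb, ann_memb)) {
      nb <- ann_memb[adj[u, ann_memb] > 0]
      if (length(nb))
        out[[u]] <- sort(unique(unlist(annotations[nb])))
    }
  }
  out
}

#' Export a network as an edge-list TSV
#'
#' @param network igraph graph with `rho` edge attribute.
#' @param path output path.
#' @export
write_network <- function(network, path) {
  ee <- igraph::as_edgelist(network)
  dt <- data.table::data.table(protein_a = ee[, 1], protein_b = ee[, 2],
                               rho = igraph::E(network)$rho)
  data.table::setorder(dt, protein_a, protein_b)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Export a network as GraphML
#'
#' @inheritParams write_network
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
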