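test_that("sparcc gives rho = 1 for identical components", {
  set.seed(1)
  x <- matrix(rpois(6 * 40, 60), 6, 40)
  x[2, ] <- x[1, ]  # identical rows: zero log-ratio variance
  rho <- sparcc(x)
  expect_equal(unname(rho[1, 2]), 1)
  # proportional rows approach 1 as the pseudocount vanishes
  y <- x; y[2, ] <- 3L * y[1, ]
  expect_gt(sparcc(y, pseudocount = 1e-6)[1, 2], 0.999)
})

test_that("sparcc falls back to CLR-Pearson for tiny component sets", {
  set.seed(2)
  x <- matrix(rpois(3 * 30, 50), 3, 30)
  expect_warning(r <- sparcc(x), "CLR")
  expect_equal(dim(r), c(3, 3))
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
})

test_that("sparcc stays near zero under an independent null", {
  set.seed(7)
  basis <- matrix(rlnorm(10 * 150, 5, 1), 10, 150)
  counts <- round(sweep(basis, 2, colSums(basis), "/") * 3e4)
  r <- sparcc(counts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.4)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.15)
})

test_that("network edges obey the threshold inclusively", {
  corr <- diag(3)
  rownames(corr) <- colnames(corr) <- c("a", "b", "c")
  corr["a", "b"] <- corr["b", "a"] <- 0.31
  corr["a", "c"] <- corr["c", "a"] <- 0.29
  g <- build_network(corr, 0.3)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  expect_equal(igraph::vcount(g), 3L)  # isolated node retained
  # boundary: threshold 1 keeps only exact-1 correlations
  corr["a", "c"] <- corr["c", "a"] <- 1
  expect_equal(igraph::ecount(build_network(corr, 1.0)), 1L)
  # all-zero matrix: edgeless
  z <- matrix(0, 3, 3); diag(z) <- 1
  expect_equal(igraph::ecount(build_network(z, 0.3)), 0L)
})

test_that("module extraction matches hand-derived cases", {
  tri <- matrix(0, 3, 3, dimnames = list(c("a","b","c"), c("a","b","c")))
  tri[upper.tri(tri)] <- 1; tri <- tri + t(tri); diag(tri) <- 1
  g <- build_network(tri, 0.5)
  m <- extract_modules(g)
  expect_equal(sort(m$protein_id), c("a", "b", "c"))
  expect_equal(unique(m$module_id), "M001")

  # K4 {a,b,c,d} plus e adjacent to a,b -> one module of 5
  nodes <- c("a", "b", "c", "d", "e")
  adj <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  adj[c("a","b","c","d"), c("a","b","c","d")] <- 1
  adj["e", c("a","b")] <- adj[c("a","b"), "e"] <- 1
  diag(adj) <- 1
  m2 <- extract_modules(build_network(adj, 0.5))
  expect_equal(sort(m2$protein_id), nodes)
  expect_equal(m2[protein_id == "e", role], "attached")
  expect_equal(length(unique(m2$module_id)), 1L)

  # two disjoint triangles -> two disjoint modules
  adj2 <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  adj2[1:3, 1:3] <- 1; adj2[4:6, 4:6] <- 1; diag(adj2) <- 1
  m3 <- extract_modules(build_network(adj2, 0.5))
  expect_equal(length(unique(m3$module_id)), 2L)
  expect_equal(anyDuplicated(m3$protein_id), 0L)
})

test_that("first seed clique matches a brute-force maximum clique", {
  set.seed(17)
  for (i in 1:50) {
    adj <- random_graph(sample(5:10, 1), runif(1, 0.3, 0.7))
    oracle <- brute_max_clique_size(adj)
    g <- build_network(adj + diag(nrow(adj)), 0.5)
    m <- extract_modules(g, min_clique = 2L)
    first <- if (nrow(m)) sum(m$module_id == "M001" & m$role == "seed") else 0L
    if (oracle >= 2L) expect_equal(first, oracle) else expect_equal(first, 0L)
  }
})

test_that("modules are node-disjoint subsets of the network", {
  pm <- fixture_protein_counts()
  cm <- fixture_community()
  prots <- intersect(names(cm$truth$genome_of)[cm$truth$genome_of == "G01"],
                     rownames(pm))
  r <- sparcc(pm[prots, ])
  g <- build_network(r, 0.3)
  m <- extract_modules(g)
  expect_equal(anyDuplicated(m$protein_id), 0L)
  expect_true(all(m$protein_id %in% igraph::V(g)$name))
})

test_that("planted co-expression blocks land in one module", {
  cfg <- community_config(seed = 5, n_samples_per_phenotype = 25L,
                          phenotypes = c("healthy", "CD"),
                          phenotype_specific_fraction = 0)
  cm <- generate_community(cfg)
  sim <- simulate_psms(cm)  # 50 samples
  bl <- cm$truth$blocks[startsWith(block_id, "G01")]
  prots <- names(cm$truth$genome_of)[cm$truth$genome_of == "G01"]
  x <- sim$protein_counts[prots, ]
  x <- x[rowSums(x) > 0, ]
  m <- extract_modules(build_network(sparcc(x), 0.3))
  for (b in unique(bl$block_id)) {
    memb <- bl[block_id == b, protein_id]
    hit <- m[protein_id %in% memb, module_id]
    expect_gte(max(table(hit)) / length(memb), 0.8)
  }
})

test_that("module phenotype assignment follows the dominance rule", {
  counts <- rbind(p1 = c(9, 9, 1, 1), p2 = c(9, 9, 0, 2))
  colnames(counts) <- paste0("S", 1:4)
  man <- data.table::data.table(sample_id = paste0("S", 1:4),
                                phenotype = c("AL", "AL", "CD", "CD"))
  expect_equal(assign_module_phenotype(c("p1", "p2"), counts, man, 0.75),
               "AL")
  # uniform spread: none
  u <- rbind(p1 = c(5, 5, 5, 5))
  colnames(u) <- paste0("S", 1:4)
  expect_true(is.na(assign_module_phenotype("p1", u, man, 0.75)))
  # all spectra in one CD sample
  one <- rbind(p1 = c(0, 0, 7, 0))
  colnames(one) <- paste0("S", 1:4)
  expect_equal(assign_module_phenotype("p1", one, man, 0.75), "CD")
})

test_that("pathway suggestion is the union over annotated neighbours", {
  nodes <- c("u", "v", "w", "x")
  adj <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  adj["u", c("v", "w")] <- adj[c("v", "w"), "u"] <- 1
  adj["v", "w"] <- adj["w", "v"] <- 1
  diag(adj) <- 1
  net <- build_network(adj, 0.5)
  mods <- extract_modules(net, min_clique = 3L)
  ann <- list(v = "Glycolysis", w = c("TCA"))
  sug <- suggest_pathways(mods, net, ann)
  expect_setequal(sug$u, c("Glycolysis", "TCA"))
  # fully unannotated module: nothing suggested
  expect_length(suggest_pathways(mods, net, list()), 0)
  # x is isolated: no module, no suggestion
  expect_false("x" %in% names(sug))
})
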