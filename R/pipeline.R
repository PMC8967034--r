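## End-to-end orchestration. Each stage reads its inputs from the artifact
## directory and writes its outputs there, so stages are individually
## re-runnable from their predecessors; run_full_analysis() chains them and
## records a manifest with row counts and checksums.

#' Pipeline configuration
#'
#' Houses every stage threshold in one validated, JSON-serializable object.
#' Defaults are the study-scale values: 1% FDR, 1,000 unique peptides per
#' sample, sparCC edge threshold 0.3, operon gap 100 bases, the 2-spectra /
#' 2-samples / half-members support rule, 70% novelty identity and 80%
#' spectral coverage for genome selection.
#'
#' @param synthetic synthetic preset name (e.g. `"small"`) or `NULL` to read
#'   files. The `"small"` preset lowers `min_unique_peptides` to 200: its
#'   community's peptide universe is far below the study's per-sample depth.
#' @param seed integer seed for every stochastic stage.
#' @param fdr PSM false discovery rate.
#' @param min_unique_peptides sample QC threshold.
#' @param sparcc_threshold correlation threshold for network edges.
#' @param min_clique minimum module seed clique.
#' @param dominance module phenotype dominance fraction.
#' @param operon_gap maximum intergenic gap within an operon (bases).
#' @param support_min_samples,support_min_spectra,support_min_fraction the
#'   operon spectral-support rule.
#' @param novelty_identity ORF-rescue novelty identity threshold.
#' @param coverage cumulative spectral coverage for top-genome selection.
#' @param n_top_genomes cap on genomes taken into the network stage.
#' @param paths named list of input paths for non-synthetic runs: `psm_dir`,
#'   `manifest`, `contigs`, `gff`, `proteome`, `protein_genome`, `hits`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = "small", seed = 1L, fdr = 0.01,
                            min_unique_peptides = if (identical(synthetic, "small")) 200L else 1000L,
                            sparcc_threshold = 0.3, min_clique = 3L,
                            dominance = 0.75, operon_gap = 100L,
                            support_min_samples = 2L,
                            support_min_spectra = 2L,
                            support_min_fraction = 0.5,
                            novelty_identity = 0.70, coverage = 0.80,
                            n_top_genomes = 100L, paths = list()) {
  cfg <- as.list(environment())
  stopifnot(fdr > 0, fdr < 1, sparcc_threshold >= -1, sparcc_threshold <= 1,
            operon_gap >= 0, support_min_fraction >= 0,
            support_min_fraction <= 1, novelty_identity > 0,
            novelty_identity <= 1, coverage > 0, coverage <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @return `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
  cfg
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

## ---- stages ---------------------------------------------------------------

stage_simulate <- function(out, config) {
  community <- generate_community(community_preset(config$synthetic,
                                                   seed = config$seed))
  sim <- simulate_psms(community)
  write_community(community, out)
  write_psm_tables(sim, file.path(out, "psms"))
  data.table::fwrite(sim$manifest, file.path(out, "manifest.csv"))
  gm <- data.table::data.table(protein_id = names(community$truth$genome_of),
                               genome = unname(community$truth$genome_of))
  data.table::fwrite(gm, file.path(out, "protein_genome.tsv"), sep = "\t")
  data.table::fwrite(synth_hit_table(community, config$seed),
                     file.path(out, "hits.tsv"), sep = "\t")
  invisible(community)
}

## deterministic toy annotation table for the synthetic mode: ~2/3 of
## proteins get a passing COG hit, the rest fail one of the two rules
synth_hit_table <- function(community, seed) {
  set.seed(seed + 7001L)
  prots <- names(community$proteome)
  cats <- c("C", "E", "G", "J", "K", "L", "M", "P", "T", "GT")
  n <- length(prots)
  data.table::data.table(
    query = prots,
    cog_id = sprintf("COG%04d", sample(4000L, n, replace = TRUE)),
    category = sample(cats, n, replace = TRUE),
    domain_coverage = round(runif(n, 0.1, 1), 3),
    e_value = signif(10^runif(n, -30, 1), 3))
}

stage_filter <- function(out, config) {
  files <- list.files(file.path(out, "psms"), pattern = "^S.*\\.psm\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no PSM tables under ", file.path(out, "psms"))
  psm <- data.table::rbindlist(lapply(files, read_psm_table))
  data.table::setattr(psm, "class", c("psm_table", "data.table", "data.frame"))
  flt <- fdr_filter(psm, fdr = config$fdr)
  keep <- qc_filter_samples(flt$psms,
                            min_unique_peptides = config$min_unique_peptides)
  if (!length(keep))
    stop("all samples discarded by QC (min_unique_peptides = ",
         config$min_unique_peptides, "); nothing to analyze")
  kept <- flt$psms[sample_id %in% keep]
  write_psm_table(kept, file.path(out, "filtered_psms.tsv"))
  writeLines(keep, file.path(out, "qc_samples.txt"))
  invisible(kept)
}

read_filtered <- function(out) {
  read_psm_table(file.path(out, "filtered_psms.tsv"))
}

read_genome_map <- function(out) {
  gm <- data.table::fread(file.path(out, "protein_genome.tsv"))
  setNames(gm$genome, gm$protein_id)
}

stage_quantify <- function(out, config) {
  psm <- read_filtered(out)
  genome_map <- read_genome_map(out)
  proteome <- read_proteome(file.path(out, "proteome.faa"))
  sizes <- tapply(Biostrings::width(proteome),
                  genome_map[names(proteome)], sum)
  q <- quantify_genomes(psm, genome_map, proteome_size_aa = sizes)
  write_count_matrix(q$raw, file.path(out, "genome_counts.tsv"))
  write_count_matrix(q$normalized, file.path(out, "genome_counts_norm.tsv"))
  pm <- protein_count_matrix(psm)
  write_count_matrix(pm, file.path(out, "protein_counts.tsv"))
  invisible(q)
}

read_count_tsv <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

stage_hps <- function(out, config) {
  pm <- read_count_tsv(file.path(out, "protein_counts.tsv"))
  manifest <- read_sample_manifest(file.path(out, "manifest.csv"))
  psm <- read_filtered(out)
  depth <- table(psm$sample_id)
  norm <- sweep(pm, 2, as.numeric(depth[colnames(pm)]), "/")
  genome_map <- read_genome_map(out)
  h <- hps_table(norm, manifest, genome_of = genome_map)
  data.table::fwrite(h, file.path(out, "hps.tsv"), sep = "\t")
  invisible(h)
}

stage_network <- function(out, config) {
  pm <- read_count_tsv(file.path(out, "protein_counts.tsv"))
  gc <- read_count_tsv(file.path(out, "genome_counts.tsv"))
  manifest <- read_sample_manifest(file.path(out, "manifest.csv"))
  genome_map <- read_genome_map(out)
  top <- names(sort(rowSums(gc), decreasing = TRUE))
  top <- head(top, config$n_top_genomes)
  edges <- list(); mods <- list()
  for (g in top) {
    prots <- rownames(pm)[genome_map[rownames(pm)] == g]
    samples <- colnames(gc)[gc[g, ] > 0]
    x <- pm[prots, samples, drop = FALSE]
    x <- x[rowSums(x) > 0, , drop = FALSE]
    if (nrow(x) < 4L || ncol(x) < 3L) next
    rho <- sparcc(x)
    net <- build_network(rho, threshold = config$sparcc_threshold)
    mt <- extract_modules(net, min_clique = config$min_clique)
    if (nrow(mt)) {
      mt[, module_id := paste0(g, "_", module_id)]
      depth_norm <- sweep(pm[, samples, drop = FALSE], 2,
                          pmax(colSums(pm[, samples, drop = FALSE]), 1), "/")
      ph <- vapply(split(mt$protein_id, mt$module_id), function(mm)
        assign_module_phenotype(mm, depth_norm, manifest,
                                dominance = config$dominance), character(1))
      mt[, phenotype := unname(ph[module_id])]
      mods[[g]] <- mt
    }
    ee <- igraph::as_edgelist(net)
    if (nrow(ee))
      edges[[g]] <- data.table::data.table(genome = g, protein_a = ee[, 1],
                                           protein_b = ee[, 2],
                                           rho = igraph::E(net)$rho)
  }
  modules <- if (length(mods)) data.table::rbindlist(mods) else
    data.table::data.table(module_id = character(), protein_id = character(),
                           role = character(), phenotype = character())
  edge_dt <- if (length(edges)) data.table::rbindlist(edges) else
    data.table::data.table(genome = character(), protein_a = character(),
                           protein_b = character(), rho = numeric())
  data.table::fwrite(modules, file.path(out, "modules.tsv"), sep = "\t")
  data.table::fwrite(edge_dt, file.path(out, "network_edges.tsv"), sep = "\t")
  invisible(modules)
}

stage_operons <- function(out, config) {
  genes <- read_gene_models(file.path(out, "genes.gff3"))
  pm <- read_count_tsv(file.path(out, "protein_counts.tsv"))
  cand <- cluster_genes(genes, max_gap = config$operon_gap)
  cand <- filter_spectral_support(
    cand, pm, min_samples = config$support_min_samples,
    min_spectra = config$support_min_spectra,
    min_fraction = config$support_min_fraction)
  write_operons(cand, file.path(out, "operons.csv"))
  write_operons(cand[supported == TRUE],
                file.path(out, "operons_supported.csv"))
  invisible(cand)
}

stage_rescue <- function(out, config) {
  rescue <- read_psm_table(file.path(out, "psms", "rescue_psms.tsv"))
  contigs <- read_contigs(file.path(out, "contigs.fna"))
  genes <- read_gene_models(file.path(out, "genes.gff3"))
  proteome <- read_proteome(file.path(out, "proteome.faa"))
  genome_map <- read_genome_map(out)
  ## contig -> genome via the genes it carries
  g1 <- genes[!duplicated(contig_id)]
  contig_genome <- setNames(unname(genome_map[g1$gene_id]), g1$contig_id)
  orfs <- rescue_orfs(rescue, contigs, genes, proteome, contig_genome,
                      min_identity = config$novelty_identity)
  write_rescued_orfs(orfs, gff_path = file.path(out, "rescued_orfs.gff3"),
                     faa_path = file.path(out, "rescued_orfs.faa"))
  invisible(orfs)
}

stage_annotate <- function(out, config) {
  hits <- read_hit_table(file.path(out, "hits.tsv"))
  pm <- read_count_tsv(file.path(out, "protein_counts.tsv"))
  genome_map <- read_genome_map(out)
  assign <- filter_cog_hits(hits, proteins = rownames(pm))
  data.table::fwrite(assign, file.path(out, "cog_assignments.tsv"),
                     sep = "\t")
  totals <- rowSums(pm)
  profs <- list()
  for (g in unique(genome_map[rownames(pm)])) {
    sp <- totals[genome_map[names(totals)] == g]
    sp <- sp[sp > 0]
    if (!length(sp)) next
    pr <- cog_category_profile(sp, assign)
    profs[[g]] <- data.table::data.table(genome = g, category = names(pr),
                                         fraction = unname(pr))
  }
  prof <- data.table::rbindlist(profs)
  data.table::fwrite(prof, file.path(out, "cog_profiles.tsv"), sep = "\t")
  invisible(prof)
}

## ---- driver ---------------------------------------------------------------

PIPELINE_STAGES <- c("simulate", "filter", "quantify", "hps", "network",
                     "operons", "rescue", "annotate")

#' Run the full analysis
#'
#' Executes the stages in order -- synthetic simulation (or input staging),
#' FDR + QC filtering, genome quantification, HPS, co-expression networks and
#' modules, operon candidates, ORF rescue, annotation profiles -- and writes
#' `manifest.json` recording the seed, per-artifact row counts and MD5
#' checksums. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out output directory.
#' @param stages subset of stages to run (default: all applicable).
#' @return invisibly, the manifest list.
#' @export
run_full_analysis <- function(config = pipeline_config(), out,
                              stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  for (st in stages) {
    if (st == "simulate") {
      if (is.null(config$synthetic)) {
        stage_fail("stage-inputs", stage_inputs(out, config))
      } else {
        stage_fail("simulate", stage_simulate(out, config))
      }
      next
    }
    fn <- switch(st, filter = stage_filter, quantify = stage_quantify,
                 hps = stage_hps, network = stage_network,
                 operons = stage_operons, rescue = stage_rescue,
                 annotate = stage_annotate,
                 stop("unknown stage: ", st))
    stage_fail(st, fn(out, config))
  }
  manifest <- pipeline_manifest(out, config)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## copy/link externally supplied inputs into the artifact directory
stage_inputs <- function(out, config) {
  p <- config$paths
  need <- c("psm_dir", "manifest", "contigs", "gff", "proteome",
            "protein_genome")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing input path(s): ", paste(miss, collapse = ", "))
  dir.create(file.path(out, "psms"), showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(p$psm_dir, full.names = TRUE))
    file.copy(f, file.path(out, "psms", basename(f)), overwrite = TRUE)
  file.copy(p$manifest, file.path(out, "manifest.csv"), overwrite = TRUE)
  file.copy(p$contigs, file.path(out, "contigs.fna"), overwrite = TRUE)
  file.copy(p$gff, file.path(out, "genes.gff3"), overwrite = TRUE)
  file.copy(p$proteome, file.path(out, "proteome.faa"), overwrite = TRUE)
  file.copy(p$protein_genome, file.path(out, "protein_genome.tsv"),
            overwrite = TRUE)
  if (!is.null(p$hits))
    file.copy(p$hits, file.path(out, "hits.tsv"), overwrite = TRUE)
  invisible(NULL)
}

pipeline_manifest <- function(out, config) {
  arts <- list.files(out, recursive = TRUE)
  arts <- setdiff(arts, "manifest.json")
  info <- lapply(arts, function(a) {
    path <- file.path(out, a)
    n <- tryCatch({
      if (grepl("\\.(tsv|csv|txt)$", a)) length(readLines(path)) - 1L
      else if (grepl("\\.(gff3|faa|fna)$", a)) length(readLines(path))
      else NA_integer_
    }, error = function(e) NA_integer_, warning = function(w) NA_integer_)
    list(rows = n, md5 = unname(tools::md5sum(path)))
  })
  names(info) <- arts
  list(seed = config$seed, synthetic = config$synthetic %||% NA,
       artifacts = info)
}

## ---- command-line entry ---------------------------------------------------

#' Command-line entry point
#'
#' Verbs: `all` plus the individual stage names; `--synthetic small`,
#' `--config cfg.json`, `--seed N`, `--out DIR`. Installed as
#' `inst/scripts/proteoscape-cli.R`. Exit codes: 0 ok, 1 user error,
#' 2 internal error.
#'
#' @param argv character vector of arguments (default: command line).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(argv)) stop("usage: <verb> [--synthetic small] ",
                            "[--config cfg.json] [--seed N] --out DIR",
                            call. = FALSE)
    verb <- argv[1]
    opt <- function(flag, default = NULL) {
      i <- which(argv == flag)
      if (length(i)) argv[i[1] + 1L] else default
    }
    out <- opt("--out")
    if (is.null(out)) stop("--out is required", call. = FALSE)
    cfg_path <- opt("--config")
    config <- if (!is.null(cfg_path)) read_pipeline_config(cfg_path)
              else pipeline_config(synthetic = opt("--synthetic", "small"))
    seed <- opt("--seed")
    if (!is.null(seed)) config$seed <- as.integer(seed)
    stages <- if (verb == "all") PIPELINE_STAGES
              else if (verb %in% PIPELINE_STAGES) verb
              else stop("unknown verb: ", verb, call. = FALSE)
    message("[proteoscape] running: ", paste(stages, collapse = ", "),
            " (seed ", config$seed, ") -> ", out)
    run_full_analysis(config, out, stages = stages)
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage:|required|unknown verb", conditionMessage(e))) 1L else 2L
  })
  invisible(code)
}
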