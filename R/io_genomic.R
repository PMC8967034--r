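#' Read gene models from GFF3
#'
#' Imports CDS/gene features from a GFF3 file into a `gene_models` table with
#' 0-based half-open coordinates (GFF3 is 1-based closed; `start0 = start-1`,
#' `end0 = end`). Columns: `gene_id`, `contig_id`, `start`, `end`, `strand`,
#' `source`.
#'
#' @param path GFF3 path.
#' @param feature_type feature types to keep (default CDS and gene).
#' @return a data.table of gene models, sorted by contig then start.
#' @export
read_gene_models <- function(path, feature_type = c("CDS", "gene")) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  gm <- data.table::data.table(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    source = as.character(gr$source))
  data.table::setorder(gm, contig_id, start, gene_id)
  gm[]
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]; converts internal 0-based half-open
#' coordinates back to GFF3 1-based closed.
#'
#' @param genes a `gene_models` data.table.
#' @param path output path.
#' @param feature_type the GFF3 feature type to emit (default `"CDS"`).
#' @param extra optional data.frame of additional attribute columns, one row
#'   per gene (e.g. `rescued`, `relation`, `psm_count`).
#' @export
write_gene_models <- function(genes, path, feature_type = "CDS", extra = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$source <- if ("source" %in% names(genes)) genes$source else "proteoscape"
  gr$type <- feature_type
  if (feature_type == "CDS") gr$phase <- 0L
  gr$ID <- genes$gene_id
  if (!is.null(extra)) for (nm in names(extra)) {
    S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reading frame of a genomic interval
#'
#' Frame index in 0..2 relative to the contig: `start %% 3` on the plus
#' strand, `(contig_length - end) %% 3` on the minus strand (distance of the
#' first transcribed base from the 3' contig end), for 0-based half-open
#' intervals.
#'
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param contig_length length of the contig in bases (required for `-`).
#' @return integer frame in 0..2.
#' @export
genomic_frame <- function(start, end, strand, contig_length = NA_integer_) {
  ifelse(strand == "+", start %% 3L, (contig_length - end) %% 3L)
}

#' Read sequences from FASTA
#'
#' Thin wrappers over Biostrings readers; names are truncated at the first
#' whitespace, matching common search-engine behaviour.
#'
#' @param path FASTA path.
#' @return a `DNAStringSet` / `AAStringSet`.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_contigs
#' @export
read_proteome <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param x a `DNAStringSet`/`AAStringSet` or named character vector.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- if (all(grepl("^[ACGTN]*$", x))) Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
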