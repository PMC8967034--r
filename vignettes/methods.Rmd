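---
title: "Models and methods behind proteoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proteoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(proteoscape)
```

This vignette is the package's own account of the statistics and
conventions it implements: what each stage assumes, which parameters
matter, what the synthetic generator does and does not emulate, and where
the design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. PSM filtering

**Target-decoy FDR.** `fdr_filter()` estimates the false discovery rate at
a score threshold *t* as `#decoys(score >= t) / #targets(score >= t)` and
returns the most permissive threshold keeping that ratio at or below the
requested level (default 1%). This simple D/T estimator was chosen over
the (2D)/(T+D) variant; both are in common use and the choice is exposed
in one place. Filtering is at PSM level by default; `level = "peptide"`
computes the threshold on best-score-per-peptide collapsed records, since
search engines and studies differ on which level they control.

Degenerate inputs follow the contract: no targets, or decoys uniformly
outscoring targets, yield an empty kept set with a warning rather than an
error — a sample with a broken search is a data problem, not a programming
error.

**Sample QC.** A sample is kept when it has at least
`min_unique_peptides` distinct peptide *sequences* (default 1,000;
modifications and charge are ignored for peptide identity). Fractionated
samples are merged by the caller via the manifest's `fraction_of` column
before QC.

## 2. Spectral allocation and normalization

Uniquely mapping spectra (all accessions in one genome) are counted first.
Each multi-mapped spectrum is then split across its candidate genomes in
proportion to their **same-sample** unique counts; if every sharer has
zero unique counts the spectrum is dropped and reported. Weighting within
the sample (rather than pooling across samples) keeps the estimate a
per-sample abundance; pooled weighting would couple samples through the
allocation step. Fractional counts are kept as reals downstream — nothing
in HPS, module extraction, or operon support requires integers.

Normalization is `(count / proteome_size_aa) * 1e6 / total_spectra`:
counts per million amino acids of predicted proteome, then per-sample
depth. Proteome size is the summed length of predicted proteins.

Conservation (`unique + allocated + dropped = total`) holds exactly in
exact arithmetic and to floating-point round-off (~1e-9 relative) in
practice; the tests assert it at that tolerance.

## 3. Host phenotype specificity

For a protein expressed in *N* phenotypes with depth-normalized
proportions *p*, `compute_hps()` returns the base-*N* Shannon entropy
`-sum(p * log(p)) / log(N)`. *N* defaults to the support size — the number
of phenotypes with nonzero expression — which is the more literal reading
of "phenotypes a protein was found expressed in"; `n_base` lets callers
use the full vocabulary size instead. When *N* = 1 the log base is
degenerate and HPS is defined as 0: expression confined to one phenotype
is maximally specific. The "expressed" threshold is > 0 normalized
spectra, configurable via `min_expression`.

One property worth flagging: the *N*-normalized entropy is **not**
monotone under merging phenotypes. Merging the two minor phenotypes of
(0.9, 0.05, 0.05) raises HPS from 0.359 to 0.469, because the `log N`
denominator shrinks faster than the entropy. The un-normalized entropy is
monotone, and that is the property the test suite asserts.

## 4. sparCC correlations and modules

`sparcc()` implements the compositional correlation estimator from
log-ratio variances: `t_ij = Var(log((x_i + pc)/(x_j + pc)))` across
samples, basis variances solved from the linear system implied by the
sparse-correlation assumption, `rho_ij = (w_i + w_j - t_ij) /
(2 sqrt(w_i w_j))` clipped to [-1, 1]. The strongest pair is iteratively
excluded from the basis system and the system re-solved (defaults:
pseudocount 1, 20 iterations, exclusion threshold 0.1 — the original
estimator's defaults). No Dirichlet resampling is performed, which makes
the estimate deterministic. With fewer than 4 components the basis system
is under-determined and the function falls back to Pearson correlation of
CLR-transformed counts, with a warning.

Correlation inputs are **raw** spectral counts: the estimator is
compositional-aware by construction, and normalized values would re-insert
the per-sample totals it is designed to cancel.

Estimator noise is worth stating plainly: each pairwise `rho` carries
sampling error of roughly `sqrt(2/N_samples)`. At 200 samples that is
~0.1 per pair, so the *maximum* absolute correlation among 190 null pairs
concentrates near 0.25 — a null network at threshold 0.3 stays almost
empty, but individual null correlations up to ~0.3 are expected, not a
bug.

**Modules.** `extract_modules()` repeatedly takes a maximum clique (exact
enumeration via igraph's Bron–Kerbosch; ties broken by lexicographically
smallest member set, so extraction is deterministic) of size at least
`min_clique = 3` — a bare edge is not treated as a module — removes it,
and repeats. Remaining nodes attach to the seed module they share the most
edges with (ties: larger module, then smaller module id); nodes with no
edge into any seed stay unassigned. Modules are therefore node-disjoint by
construction. A module is assigned a phenotype when that phenotype's
samples carry at least 75% (`dominance`) of the members' spectra — the
source of this analysis gives no number; 0.75 is a deliberate "clearly
dominant" choice and is configurable. Pathway suggestions for unannotated
members are the union over annotated proteins they share a module edge
with — plain guilt-by-association, reported as hints, never as calls.

## 5. Operons

Candidates are maximal same-contig, same-strand gene runs with intergenic
gaps (next start − previous end, on 0-based half-open coordinates) of at
most 100 bases — gap between gene boundaries, not midpoints, which is the
natural operon-distance convention. Overlapping same-strand genes count as
gap 0 with a warning. Singleton runs are discarded: an operon needs at
least two genes.

Support: a member is *evidenced* with ≥ 2 spectra in each of ≥ 2 samples
("2 spectra per sample" read as per supporting sample, the stricter and
more literal reading); a candidate is *supported* when at least half its
members are evidenced. Supported and unsupported candidates partition the
input.

For comparison against external predictions, `operon_overlap()` offers
`region70` (overlap > 70% of the smaller span — the denominators were
unstated upstream, the smaller span is the choice that makes the criterion
symmetric and attainable by nested operons) and `half_smaller` (overlap ≥
half the smaller span). Matching is greedy by overlap length, one match
per operon.

## 6. Six-frame ORF rescue

Contigs are translated in all six frames (`+1..+3` at offsets 0–2 on the
given strand, `-1..-3` on the reverse complement); stops render as
segment separators. A peptide absent from the predicted proteome anchors
an ORF inside its stop-bounded segment: from the 5'-most ATG/GTG/TTG at or
upstream of the peptide (bacterial start codons) to the segment's closing
stop, the stop codon excluded from the reported interval. Peptides found
in more than one segment are skipped with a warning — an ambiguous anchor
cannot support a unique ORF. ORFs shorter than 20 aa are discarded
(they cannot reliably carry a tryptic peptide).

**Novelty filter.** A candidate aligning to any predicted protein of the
same genome at ≥ 70% identity is a re-discovery and is *dropped*. The
upstream description of this step reads, literally, as the opposite
(keeping the matches), which contradicts its own stated purpose of finding
missed ORFs; the drop-the-matches direction is implemented as the default
and the literal reading is available via `keep_matches = TRUE`. Alignment
is local Smith–Waterman (BLOSUM62, gap open 11 / extend 1); identity is
counted as identical aligned positions over the *shorter* sequence — the
stricter of the two published conventions, chosen so that a short
candidate fully contained in a longer protein cannot evade the filter.

Relation classes: `same_strand_diff_frame` when the ORF overlaps a
same-strand gene in a different frame (frame = start mod 3 on `+`,
(contig length − end) mod 3 on `-`); `opposite_strand` when it overlaps a
gene on the other strand; `no_overlap` otherwise. When both apply, the
same-strand frame conflict wins by default — it is the more specific
relationship. ORF grouping is single-linkage at the same 70% identity
threshold, with groups of at least two members reported.

## 7. Annotation

COG hits survive with domain coverage ≥ 50% *and* e-value ≤ 0.01 (the
"minimum e-value of 0.01" is read as a ceiling, the conventional
direction); proteins without surviving hits fall into category S.
Multi-letter categories split spectra equally across letters — whether the
original analysis split or duplicated was unstated, and splitting keeps
profiles summing to one. Pathway minimization is minimum set cover: exact
branch-and-bound for at most 20 candidate pathways, greedy beyond, with
the method flagged in the result. Functions in no pathway are returned as
unexplained rather than silently dropped.

## 8. The synthetic community

The generator is a first-class module, not a fixture: it emits FASTA
contigs, GFF3 gene models, a predicted proteome, per-sample PSM TSVs and a
ground-truth object, all deterministic under `(config, seed)`.

What it emulates, and the stated-world defaults:

* **Geometry** — 3 genomes × 2 contigs × 15 genes (the `"small"` preset,
  20 samples over 4 phenotypes, generating in a few seconds); operons
  planted as same-strand runs with intra-operon gaps of 10–80 bases and
  everything else separated by 150–400 bases, so gap-clustering at 100
  bases recovers exactly the planted set.
* **Expression** — per-genome log-normal abundances (log-sd 1) with
  per-sample log-normal jitter (log-sd 0.3); per-protein expected counts
  proportional to protein length within the genome; negative-binomial
  counting (size 5) for the over-dispersion spectral counts show in
  practice; ~3,000 expected identified PSMs per sample. Planted
  co-expression blocks (2 per genome, 5 proteins, latent-factor
  correlation 0.8) and phenotype-specific proteins (20% of each genome,
  zero expression off-phenotype).
* **Peptides** — proteins are built from tryptic units (6–12 plain
  residues + K/R) and digested in silico (cleave after K/R, not before P,
  ≤ 2 missed cleavages, lengths 7–40), so the peptide universe is known
  exactly; PSM accession sets are expanded to every protein containing the
  peptide, which realizes shared peptides when the sharing rate is
  positive.
* **Hidden ORFs** — 3 per genome, cycling through the three relation
  classes. ORF bodies use GC-only codons (alanine/glycine/proline/arginine),
  which cannot form a stop codon in any frame on either strand, so an ORF
  can be embedded inside a host gene — opposite strand or shifted frame —
  while the host stays translatable; the host's protein is re-derived from
  the final sequence. Each ORF is framed by planted stops and starts with
  ATG immediately after the upstream stop, so the extracted interval
  equals the planted interval exactly. ORF peptides are kept only when
  they occur exactly once in the whole six-frame space.
* **Scores** — targets N(30, 4), decoys N(18, 4), decoys at 30% of target
  count: separated enough that a 1% FDR threshold exists, overlapping
  enough that the threshold is data-dependent.
* **Support guarantee** — operon members are floored at 2 spectra in the
  first 2 samples, making "all members evidenced" a construction-time
  guarantee rather than a sampling accident.

What it does **not** emulate: m/z spectra, retention behaviour,
intensity-based quantification, modification-bearing peptides, chimeric
spectra, or realistic amino-acid composition of the hidden ORFs (their
4-letter alphabet is a construction device). A green end-to-end test
establishes that the pipeline's logic is faithful to its contracts on data
whose truth is known — not that any biological conclusion from real data
is correct.

The `"small"` pipeline preset sets the QC threshold to 200 unique
peptides: the community's whole peptide universe (~1,000 peptides) is of
the same order as the study-scale per-sample threshold of 1,000, which
remains the package default for real data.

## 9. Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts to and
  from 1-based closed at the boundary.
* `sparcc()` clamps non-positive solved basis variances to 1e-12 before
  the square root, and stops excluding pairs when any component would drop
  below two usable pairs.
* Allocation treats a shared spectrum over a single genome as a unique
  spectrum (degenerate but legal input).
* Set-cover ties (greedy) and clique ties (extraction) break
  lexicographically, so every result is reproducible run to run.
* `operon_overlap()` resolves equal-overlap ties toward the leftmost pair.

## 10. Known limitations

* Protein-level inference (parsimony grouping of ambiguous peptides) is
  out of scope; protein counts credit each PSM to every matching protein.
* sparCC p-values/bootstrap are not implemented; the 0.3 edge threshold is
  the only significance control, as in the upstream analysis.
* The exact set-cover solver is exponential in the worst case and is
  capped at 20 candidate pathways; beyond that the greedy result is
  flagged rather than silently trusted.
* `max_identity()` compares a candidate against every predicted protein of
  its genome; at desk scale this is fast, at study scale a k-mer prefilter
  would be the first optimization.
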