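---
title: "Methods: marker-gene quantification and SIP enrichment in isosip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gene quantification and SIP enrichment in isosip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind
`isosip`: the translated marker-gene search, the recA-normalized
carrier statistic, the DNA-SIP enrichment caller, the gene-cluster
screen, and the synthetic-data generator that the test suite uses as
ground truth. It is the place where genuinely open design choices are
recorded, with their rationale.

## 1. Translated homology search

### Model

Shotgun reads are translated in all six frames (`six_frame_translate`);
codons containing an ambiguity translate to `X`, stop codons to `*`.
Each frame sharing an exact amino-acid k-mer (default `seed_k = 5`)
with a query protein is aligned by affine-gap Smith–Waterman
(`local_align`; BLOSUM62, gap open 11 / extend 1, a gap of length L
costing `11 + L`). Raw scores are converted to expectations with the
Karlin–Altschul form `E = K · m · n · e^(−λS)` using the standard
gapped-search constants λ = 0.267 nats per score unit and K = 0.041,
where `m` is the query length and `n` the total number of translated
residues actually scanned in the run (for L-bp reads, `6 · Σ L / 3`).
Hits with `E ≤ 1e−4` (target marker) or `E ≤ 1e−6` (normalization
marker) are kept, at most one per (query, read): best score, ties to
the lowest frame index.

### Numerical choices

* **Stop codons.** Instead of splitting each frame at `*` and searching
  the fragments separately, the scoring matrix assigns `*` a score of
  −10000 against everything. A local alignment therefore never crosses
  a stop, which is mathematically identical to independent fragment
  search but needs no coordinate bookkeeping.
* **Seeding.** The exact 5-mer pre-filter makes the search linear in
  the data while keeping sensitivity: an error-free read overlapping a
  marker by ≥ 45 codons always contains many exact 5-mers, and at the
  default substitution rate (0.005/base) the chance that every 5-residue
  window of a 50-codon frame is disrupted is negligible. The oracle
  tests bypass seeding by calling `local_align` directly.
* **Identity.** Percent identity is matches over aligned columns (gaps
  included), the same convention as BLAST's `pident`.
* **Verification.** Candidate target-marker hits are re-aligned (the
  translated read segment, not the nucleotide read) against a curated
  verification set; hits below 50% best identity are discarded
  (strictly: 49.9% is discarded, 50.0% kept), and survivors are
  deduplicated to one per read — "unique hits" — keyed on read id with
  best E-value winning and ties broken by query id. Normalization-marker
  (recA) hits are deduplicated the same way but not identity-verified;
  the verification step in the underlying protocol applies to the
  target marker only.

## 2. The percent-carriers statistic

Unique verified target hits and unique normalization hits are scaled by
sequencing depth (`N_min / N_i`, smallest metagenome over metagenome i)
and by reference gene length (`L_min / L_gene`, in residues), then
summed per metagenome, and the statistic is
`100 · target_scaled / norm_scaled`.

The length normalization has two defensible readings, and the package
exposes both (`length_norm` in `normalize_hits`):

* `"global"` (default): `L_min` is the shortest gene across **both**
  marker sets. Hit counts are proportional to gene length (a read
  overlapping a longer gene is more likely), so dividing each gene's
  count by its own length — which is what the global `L_min` does, up
  to a constant that cancels in the ratio — is what makes an isoA total
  and a recA total commensurable as genome-count proxies. With one
  query per set (IsoA-like 497 aa, RecA-like 353 aa) the per-set
  reading would apply no correction at all and inflate the percentage
  by roughly the length ratio (~1.4×).
* `"per_set"`: `L_min` within each role's own gene set — the reading in
  which each marker family is only made internally consistent. Useful
  when the two families' totals are calibrated externally.

The statistic interprets recA as strictly single-copy; the generator
enforces one recA per genome so that on synthetic data the statistic is
exactly "% of genomes carrying isoA" and recovery can be tested against
the seeded truth.

## 3. DNA-SIP enrichment analysis

### Fraction identification

`identify_fractions` reproduces the "plot DNA vs density" step. Both
profiles are smoothed with a 3-point moving average (ends kept). The
**light** window is the full-width-half-maximum band around the ¹²C
control's DNA peak (≥ 50% of peak signal; ties between equal peaks go
to the denser one) — the band a bench scientist would pick as "the 12C
peak fractions". The **heavy** window is found on the *excess* of the
labeled profile over the control (normalized shapes): the largest local
maximum above the light peak that carries at least 0.5% of total DNA
mass; the window spans the contiguous excess band (≥ 5% of the peak
excess) and is pooled out to the dense end of the gradient, as heavy
fractions are pooled before sequencing. Pooled-band windows, rather
than single-fraction windows, are essential when several labeled taxa
with different GC band at different heavy densities. If no excess peak
resolves (no labeling), the heavy window falls back to a fixed
+0.030 – +0.040 g ml⁻¹ offset from the light peak, with a warning.

### Calling labeled taxa

Per taxon, `fc = (RA_H + ε)/(RA_L + ε)` with pseudocount ε = 1e−4
(about one read in a 10⁴-read amplicon sample; it bounds fold-changes
computed from zero abundances). Defaults `min_fold_13C = 5` and
`min_control_ratio = 2` are interpretive: the underlying decision logic
is verbal (tens-fold enrichment is decisive; a 2.2-fold enrichment
matched exactly by the ¹²C control is not confirmable), and these are
the loosest round thresholds that reproduce both verdicts. They are
parameters of `enrichment_params`, and the enrichment TSV's provenance
line flags them as interpretive. Unfractionated relative abundance is
carried as supporting evidence only; it never changes a call.

The ¹²C control is what gives the caller its specificity: a high-GC
unlabeled taxon can band at heavy densities and show a large `fc_13C`,
but it shows the same ratio in the control gradient, failing the
`fc_13C/fc_12C ≥ 2` criterion (and conversely, genuinely labeled taxa
collapse back to light densities in the control). In control-free
tables the fold threshold alone decides, which is noticeably weaker.

## 4. Gene-cluster screening and ANI

Annotated proteins are aligned against an iso-pathway reference panel;
the best reference assigns the gene, and the E-value assigns the tier:
`restrictive` below 1e−40, `permissive` below 1e−10 (restrictive ⊂
permissive by construction). Genes on a contig at most `max_gap` bp
apart (default 5,000 bp — clusters in known degraders are contiguous;
no distance rule is stated anywhere, so this is a permissive round
figure) form clusters, strand-agnostically and never bridged across
contigs. Classification per contig: `complete` (all of isoABCDEF plus
all of isoGHIJ clustered), `putative_novel` (full core, and *no*
isoGHIJ homolog anywhere in the input — the pattern of candidate novel
pathway variants), `core_only` (full core, partial extended set),
`partial`, `none`. Only `complete` and `putative_novel` have fixed
external definitions; the remaining labels are this package's reading.

MAG quality gates use strict inequalities exactly as printed
(completeness > 75, contamination < 10 by default; the stricter
reassembly gate is `contamination_max = 5`), so boundary values fail.

`compute_ani` implements the classical fragment recipe: genome A cut
into consecutive 1020-bp fragments (final partial fragment dropped),
each fragment locally aligned to genome B, fragments retained at ≥ 30%
identity over ≥ 70% of their length, ANI = mean identity of retained
fragments. For tractability each fragment is anchored in B by an exact
14-nt seed (probed every 32 bp, both strands) and aligned only to the
anchored window (±100 bp); at the ≤ 5% divergences where ANI is
meaningful an anchor exists with near certainty, and a fragment with no
anchor anywhere is exactly the kind of unrelated sequence the retention
criteria would discard anyway — two random genomes yield an undefined
ANI, flagged with a warning, rather than a number.

## 5. The synthetic-data generator

The generator is the package's ground truth and defines the study
conditions the tests assume:

* **Communities.** `n_taxa` genomes; exactly
  `round(n_taxa · carrier_fraction)` carry one isoA copy; all carry one
  recA. Abundances are symmetric Dirichlet(1) by default (log-normal
  and equal options). Per-taxon GC is uniform on 0.35–0.65, the span of
  typical soil/phyllosphere bacteria.
* **Genomes.** Background is i.i.d. nucleotides; marker genes are
  reverse-translated with synonymous codons weighted toward the genome
  GC (bacterial code, table 11). Because codon structure caps how far a
  coding sequence can track extreme GC, the background GC is
  compensated so the whole genome lands within ±0.02 of target. Marker
  placement is uniform, non-overlapping, random strand, recorded in a
  truth table.
* **Reads.** Sampled per genome proportionally to
  abundance × genome length, uniform position, random strand, i.i.d.
  substitutions (default 0.005/base, a post-QC short-read error level);
  default length 143 bp, a realistic post-QC mean. Provenance (taxon,
  position, strand, error count) is retained for truth-based testing
  and is not part of any emitted FASTQ.
* **Gradients.** Mean buoyant density is linear:
  `1.660 + 0.098·GC + 0.036·label_atom_fraction` g ml⁻¹ — the classical
  CsCl GC relation plus a full-¹³C shift of 0.036 g ml⁻¹; all three
  constants are configurable because the underlying experiment reports
  only the identification procedure, not numbers. Each taxon's DNA
  forms a Gaussian band (SD 0.005 g ml⁻¹, a realistic diffusion-driven
  width) integrated over 12 fractions spanning 1.690–1.760 g ml⁻¹
  (typical SIP practice), with the outermost fractions absorbing the
  tails so mass is conserved exactly; fraction 1 is the densest, the
  order in which fractions are drawn from the tube. The allocation is
  deterministic given the model; the `seed` argument exists for API
  symmetry.

**What the generator does not emulate** — and hence what passing tests
do not demonstrate about real data: amplicon chimeras and PCR bias,
indels and quality-dependent error structure, genome repeats and
strain-level variation, gradient asymmetries and wall effects,
between-replicate compositional noise, and real phylogenetic sequence
structure (references are fixed synthetic proteins; homology here means
literal sequence similarity, not evolutionary relatedness). The
pipeline's statistical behaviour (counting, normalization, windowing,
thresholds) is exercised; classifier-like generalization to real
communities is not.

## 6. Problem sizes and validation design

The test suite validates each operation against an independent oracle
where one exists: an exhaustive dynamic-programming Smith–Waterman in
plain R (score equality on hundreds of random instances up to length
30), codon-by-codon translation, binomial sampling bounds, and
Biostrings' `pairwiseAlignment` as an independent identity oracle for
the verification step. End-to-end recovery runs use synthetic
communities at the two habitat carrier levels (1% and 0.2% of genomes)
with 200,000 reads of 150 bp — large enough that the percent-carriers
estimate has a few-percent relative sampling error at the soil level
while still running in minutes on one CPU — and ten replicate SIP
simulations with two fully labeled taxa at ~6.7% relative abundance
each. Tolerances on recovered quantities are 3 binomial standard
deviations of the underlying hit counts, i.e. pure sampling error;
systematic bias would fail them. Exact-arithmetic checks (matrix
scores, strict threshold boundaries, 1019/1020 fragment identity) use
no tolerance at all.

## 7. Known limitations

* Karlin–Altschul constants are the standard gapped BLOSUM62 values,
  not estimated for this exact scoring system; E-values are calibrated
  in the sense that the empirical null (10⁵ random reads) produces no
  hits at the cutoffs, but they are approximations.
* The seeded search can in principle miss a true hit whose every exact
  5-mer is disrupted by errors; at realistic error rates this is
  negligible, and the sensitivity property is tested at error rate 0
  where it is exact.
* The percent-carriers statistic inherits the single-copy-recA
  assumption; multi-copy normalization markers would inflate the
  denominator (deliberately out of scope).
* `fold_enrichment` operates on relative abundances, so strong
  enrichment of one taxon necessarily depresses the fold-changes of
  others (compositional coupling); the ¹²C control mitigates but does
  not remove this.
* The ANI anchor requires one exact 14-mer per fragment; genomes more
  than ~15–20% diverged may return undefined ANI where a full
  BLAST-based implementation would still align a few fragments. At
  those distances ANI is outside its meaningful range anyway.
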