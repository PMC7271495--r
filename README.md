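# isosip

Detection and quantification of isoprene-degrading bacteria in shotgun
metagenomes and DNA stable-isotope probing (DNA-SIP) experiments.

Isoprene is the most abundant biogenic volatile organic compound on
Earth, and bacteria that consume it carry a distinctive marker: *isoA*,
the gene encoding the α-subunit of isoprene monooxygenase (IsoMO, a
soluble diiron monooxygenase whose six-gene core cluster *isoABCDEF* is
conserved across known degraders). `isosip` implements the computational
workflow used to ask, for a given environment: *which* taxa actively
assimilate isoprene (DNA-SIP heavy/light enrichment), *how many*
bacteria have the genetic potential to degrade it (a translated
marker-gene screen normalized to the single-copy gene *recA*), and *do
recovered genomes carry the degradation gene cluster* (homolog screening
of annotated contigs/MAGs, plus fragment-based average nucleotide
identity). A synthetic-data module generates communities, genomes with
planted marker genes, shotgun reads, and isopycnic gradient profiles, so
the entire pipeline is testable against known ground truth without any
sequence download.

It is aimed at environmental microbiologists working on the microbial
isoprene sink (soils, the phyllosphere) and, more generally, anyone who
wants a self-contained, validated implementation of functional
marker-gene quantification from unassembled reads.

## The statistics at the core

**Percent of bacteria carrying the marker.** Reads are translated in six
frames and searched with Smith–Waterman local alignment (BLOSUM62, gap
open 11 / extend 1) against IsoA query proteins; significance uses the
Karlin–Altschul expectation `E = K·m·n·e^(−λS)` with the standard gapped
parameters (λ = 0.267, K = 0.041) and the search space `n` equal to the
translated residues actually scanned. Candidate hits (E ≤ 1e−4) are
verified against a curated IsoA set and discarded below 50% amino-acid
identity; surviving hits are deduplicated to one per read. With unique
verified isoA hits `T` and unique recA hits `R` (E ≤ 1e−6), scaled by
sequencing depth (`N_min/N_i`) and reference gene length
(`L_min/L_gene`),

```
% bacteria containing isoA = 100 · T_scaled / R_scaled
```

Because essentially every bacterial genome carries exactly one *recA*,
the denominator counts genomes, and the ratio reads as a percentage of
bacteria.

**SIP enrichment calls.** For each taxon the heavy/light fold-change
`fc = (RA_H + ε)/(RA_L + ε)` is computed in the ¹³C incubation and, when
available, in the ¹²C control. A taxon is called *labeled* when
`fc_13C ≥ 5` and `fc_13C/fc_12C ≥ 2`; a fold-change matched by the
control is *not confirmed* — the logic that separates genuinely active
degraders from taxa that merely band at high density.

## Worked example

The shipped demo configuration simulates a 20-taxon community in which
10% of genomes carry one *isoA* copy and two taxa (`taxon003`,
`taxon007`) are fully ¹³C-labelled, generates 4,000 shotgun reads,
and runs the full screen → verify → normalize → SIP workflow:

```r
library(isosip)
cfg <- yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                   package = "isosip"))
cfg$outdir <- tempfile()
res <- run_pipeline(cfg)
res$abundance
#>   metagenome_id raw_target_hits raw_norm_hits scaled_target_hits
#> 1           mg1              19           201           13.49497
#>   scaled_norm_hits pct_carriers
#> 1              201     6.713915
res$enrichment[res$enrichment$call == "labeled",
               c("taxon", "fc_13C", "fc_12C", "call")]
#>      taxon     fc_13C      fc_12C    call
#> 3 taxon003   35.39412 0.004548897 labeled
#> 7 taxon007 1281.78737 0.004480165 labeled
```

Reading the output: 19 reads carried verified IsoA-like segments and 201
carried RecA-like segments; after depth/length scaling the pipeline
estimates that 6.7% of genomes in the community carry *isoA* — the
seeded truth (the summed relative abundance of the two carrier genomes
under this seed) is 6.5%. The SIP stage recovers exactly the two
labelled taxa: both are strongly enriched in the heavy fractions of the
¹³C gradient (fold-changes 35 and 1282) but not in the ¹²C control, so
both are called labeled and every unlabelled taxon is not.

All outputs (reads as FASTQ, hit tables in a blast-outfmt-6-like layout,
fraction profiles, the enrichment table) are written as TSV under
`cfg$outdir`, each with a provenance comment recording version, seed and
parameters. A thin command-line wrapper with `simulate | search |
quantify | sip | screen | ani | run` subcommands ships in
`inst/scripts/isosip.R`.

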