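# abcsurvey

Genome-wide survey tools for the ATP-binding cassette (ABC) transporter
gene family, for comparative genomicists characterizing a family in a
newly annotated plant genome. From standard inputs — protein FASTA, CDS
FASTA, GFF3 annotation, a subfamily-labelled reference-panel FASTA, and
optionally a genes × tissues TPM matrix and a qPCR Ct table — the package

* identifies family members by conserved-motif and domain-architecture
  scanning (Walker A `G..G.GK[S/T]`, Walker B, the LSGGQ ABC signature,
  Kyte–Doolittle transmembrane-helix clusters) and classifies each
  member's topology (full/half transporter, forward/reverse, soluble,
  TMD-only);
* assigns subfamilies (A–G, I) by nearest labelled reference under global
  alignment distance, with a neighbor-joining tree, and names members by
  chromosome position (`famB1`, `famB2`, ...);
* computes gene-structure statistics (exons, introns, UTR fraction),
  chromosomal distribution with a parameterized terminal-region share,
  and ExPASy-style protein properties (average-mass MW; pI by bisection
  with the EMBOSS pKa set);
* detects collinear blocks by dynamic-programming anchor chaining over
  gene ranks and classifies every member's duplication type with the
  MCScanX-style precedence **WGD/segmental > tandem > proximal >
  dispersed > singleton**;
* estimates Ka/Ks with the Nei–Gojobori (1986) method — fractional site
  counting, equal-weight minimal mutational pathways, Jukes–Cantor
  correction d = −(3/4) ln(1 − 4p/3) — discards saturated pairs
  (Ks > 2), and dates duplications by the synonymous clock
  **T = Ks / (2λ)** with λ = 6.5 × 10⁻⁹ substitutions/site/year;
* classifies tissue-expression patterns (ubiquitous / silent /
  tissue-specific / other) from TPM matrices and analyzes qPCR stress
  courses with **2^−ΔΔCt** fold changes plus Tukey-HSD compact-letter
  significance groups.

Every stage is paired with a seeded synthetic-data generator
(`simulate_genome()`, `simulate_expression_matrix()`,
`simulate_qpcr_table()`) that plants known duplications, divergences,
expression categories and fold changes, so the whole pipeline is testable
end to end without downloading a genome.

## Worked example

Simulate a small genome with one planted event of each duplication type,
then run the full survey:

```r
library(abcsurvey)

sim <- simulate_genome(genome_sim_config(
  n_chromosomes = 4, chrom_length = 3e6, n_background_genes = 60, seed = 7,
  events = list(
    planted_duplication("B", "tandem",    0.3, 0.2),
    planted_duplication("C", "proximal",  0.4, 0.2, intervening_genes = 4),
    planted_duplication("G", "dispersed", 0.5, 0.3),
    planted_duplication("A", "segmental", 0.3, 0.2,
                        block_size = 6, n_family = 2)
  )
))
survey <- run_survey(sim, out_dir = "survey_out")
summary(survey)
```

```
ABC-transporter family survey
  members: 10 of 82 genes
  subfamilies: A=4 B=2 C=2 D=0 E=0 F=0 G=2 I=0
  duplication types: singleton=0 dispersed=2 proximal=2 tandem=2 wgd_segmental=4
  UTR fraction: 100 %
  terminal-region share: 100 %
  Ka/Ks summary (Ks <= 2 ):
              n    ks_min    ks_max   ks_mean omega_mean t_min_mya t_max_mya
dispersed     1 0.5160514 0.5160514 0.5160514 0.19481806  39.69626  39.69626
proximal      1 0.3364580 0.3364580 0.3364580 0.16408171  25.88139  25.88139
tandem        1 0.3560666 0.3560666 0.3560666 0.09844186  27.38974  27.38974
wgd_segmental 2 0.2770981 0.3672981 0.3221981 0.12134530  21.31524  28.25370
```

All ten planted family members are recovered (none of the 72 background
genes is), each duplication type matches its planted event, and the
estimated Ks values sit near their simulated targets (0.3–0.5) with
ω ≪ 1, the signature of the purifying selection the generator imposed.
`survey_out/` holds `report.json` plus per-stage TSVs
(`members.tsv`, `duplicates.tsv`, `kaks.tsv`, `blocks.tsv`, ...) and the
Newick tree.

Single stages work standalone:

```r
ng86(codon_align("GGTGGTGGT", "GGCGGTGGT"))
#> NG86 Ka/Ks over 3 codon columns
#>   S = 3.000  N = 6.000  Sd = 1.000  Nd = 0.000
#>   Ks = 0.4408  Ka = 0.0000  Ka/Ks = 0.0000
divergence_time(0.3561)   # 27.4 MYA at the default clock rate
```

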