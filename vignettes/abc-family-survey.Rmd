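---
title: "Methods: genome-wide ABC-transporter family surveys with abcsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide ABC-transporter family surveys with abcsurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcsurvey)
```

## Scope and model of the survey

ATP-binding cassette (ABC) transporters couple ATP hydrolysis at
nucleotide-binding domains (NBDs) to substrate transport through
transmembrane domains (TMDs). Plant genomes carry large ABC repertoires
(one to several hundred genes, organized into subfamilies A–G and I), and
a standard comparative-genomics survey of the family proceeds through a
fixed sequence of stages: identify members from the annotated proteome,
classify subfamilies, describe gene structure and chromosomal
distribution, type each member's duplication history from genome
collinearity, date duplications from synonymous divergence, and classify
tissue-expression patterns; a qPCR stage quantifies stress responses of
candidate genes. `abcsurvey` implements that survey as a tested pipeline
over standard inputs (protein FASTA + CDS FASTA + GFF3, a labelled
reference-panel FASTA, a TPM matrix, a Ct table) and pairs every stage
with a seeded synthetic-data generator so each algorithm has a
parameter-recovery test that needs no downloads.

## Member identification

Family membership is decided by domain architecture rather than by
profile-HMM search: the scanner is self-contained, its decisions are
reproducible from the patterns printed below, and it plays the same
validation role (presence of the conserved domains) that HMM/Pfam
filtering plays in survey practice.

* **Motifs.** Walker A is the classical `G..G.GK[S/T]`; Walker B renders
  (R/K)X~3~GX~3~L(hydrophobic)~3~ with the hydrophobic set LIVMF; the ABC
  signature uses the canonical LSGGQ consensus
  (`[LIVMFY]S[SG]G.[QRKE]`). Q-loop and H-loop patterns are package
  heuristics — their consensus is not standardized — and deliberately play
  no part in the acceptance rule. Wildcards are implemented as `[^X]` so
  the unknown residue X never matches. All patterns are fixed-length, and
  the scanner is verified against a position-by-position sliding-window
  oracle.
* **Transmembrane helices.** Windowed Kyte–Doolittle hydropathy (window
  19, threshold 1.6) marks candidate regions; runs of qualifying window
  centres are expanded by half a window, trimmed of individually
  hydrophilic flanking residues, and split to plausible helix lengths
  (15–30 aa).
* **Architecture.** An NBD is called where Walker A co-occurs with the
  signature or Walker B within 250 residues downstream; a TMD where ≥ 4
  predicted helices cluster within a 350-residue span (transporter TMDs
  carry 4–6 helices). The ordered segments give the topology class
  (full/half, forward/reverse, soluble, TMD-only). Candidates with at
  least one NBD are accepted; TMD-only proteins are accepted only when the
  reference panel contains a TMD-only member at ≥ 40% alignment identity,
  mirroring the lone-TMD ABCI members known in plants. Because the exact
  published rule for combining domain-database evidence is never stated in
  survey papers, this explicit rule is the package's own acceptance
  criterion; on synthetic data it attains sensitivity 1.0 on planted
  members and ≥ 99% rejection of random background proteins.

Subfamilies are assigned by nearest labelled reference under global
pairwise alignment distance (1 − identity/100; BLOSUM62, gap open 10,
extend 0.5), with ties broken toward the earlier panel entry and flagged.
A neighbor-joining tree over candidates and references accompanies the
assignment; NJ on additive distances provably returns the generating
topology with exact branch lengths, which the test suite confirms for
4–8-taxon trees. A maximum-likelihood tree with bootstrap support would
add nothing to nearest-reference assignment while costing determinism, so
it is deliberately out of scope. Members are named `famX1..famXn` within
each subfamily following chromosome order (natural sort, so Chr2 precedes
Chr10) and start coordinate.

Physicochemical properties use ExPASy-style conventions: molecular weight
as the sum of average residue masses plus one water; pI by bisection on
the Henderson–Hasselbalch net charge with the EMBOSS pKa set (termini
8.6/3.6; side chains D 3.9, E 4.1, C 8.5, Y 10.1, H 6.5, K 10.8, R 12.5)
to |charge| < 10^-4^.

## Gene structure and chromosomal distribution

Coordinates are 0-based half-open internally and 1-based inclusive in
GFF3, converting only at the I/O boundary; round-trips are byte-stable.
One mRNA per gene is assumed; when several are present the longest CDS is
primary. Exon count, intron count (= exons − 1) and UTR presence are
summarized per gene and per family. "Located at chromosome ends" has no
standard definition, so the terminal-region statistic is parameterized:
a gene is terminal when its midpoint lies within `terminal_fraction`
(default 0.25) of either chromosome end, and the reported share always
names the window used. Gene rank — the ordinal position by start
coordinate among a chromosome's genes, ignoring strand — is the distance
measure used downstream, matching collinearity practice.

## Duplication typing

Homolog pairs come from global protein alignment (identity ≥ 40%, up to 5
partners per gene). A 4-mer containment prefilter (threshold 0.05) screens
the quadratic pair space first: family homologs above 70% identity share
roughly a quarter of their 4-mers while unrelated proteins share well
under 1%, so the filter removes nearly all background alignments without
losing true pairs.

Collinear blocks are found by dynamic-programming chaining of anchors
(homolog pairs with gene-rank coordinates): within each chromosome pair,
the longest chain with both ranks strictly monotone (increasing, or
decreasing for inverted blocks) and consecutive gaps ≤ 25 ranks is
extracted repeatedly; chains with ≥ 5 anchors become blocks, and each
anchor belongs to at most one block. Self-hits and near-diagonal
same-chromosome anchors (tandem-array redundancy) are removed before
chaining. The DP is verified against an independent longest-chain search
on instances up to 30 anchors.

Every family member then receives exactly one duplication type with the
MCScanX-style precedence **WGD/segmental > tandem > proximal > dispersed >
singleton**: block anchor membership first; otherwise a homolog at rank
distance ≤ 1 on the same chromosome (tandem), ≤ 10 (proximal), anywhere
(dispersed), or none (singleton). All windows are configuration-exposed
because published surveys rarely state them; the defaults (top 5 hits,
min 5 anchors, max gap 25, proximal window 10, strict adjacency for
tandem) follow common MCScanX practice. Cross-genome synteny reuses the
same chaining and classifies family matches as one-to-one, one-to-many or
many-to-one from partner counts inside blocks.

## Ka/Ks and divergence times

The Nei–Gojobori (1986) method is implemented from its definition:

* **Sites.** Per codon and position, the fraction of the three possible
  nucleotide changes that is synonymous, summed and averaged between the
  two sequences; changes creating a stop codon count as nonsynonymous
  (the common convention; switchable). S + N = 3 × codon columns always.
* **Differences.** For each codon pair, synonymous/nonsynonymous step
  counts are averaged over all minimal mutational pathways with equal
  weight (2 pathways for two differences, 6 for three); pathways through
  stop codons are excluded, falling back to all pathways when every one is
  blocked. The 61 × 61 tables are verified against exhaustive enumeration.
* **Correction.** Jukes–Cantor, d = −(3/4) ln(1 − 4p/3); proportions at or
  beyond 3/4 raise an explicit error distinct from the saturation flag.

Codon alignments are built by aligning the proteins and back-translating,
dropping every gapped column; a `positional` mode pairs codons by position
for sequences known to be indel-free. Pairs with Ks > 2 are flagged
saturated and excluded from all summary statistics, the standard guard
against substitution saturation.

Divergence time uses the synonymous clock T = Ks/(2λ), reported in MYA,
with λ = 6.5 × 10^-9^ synonymous substitutions per site per year (the
standard legume rate) as the default. The clock formula is sometimes
printed with the 10^-6^ MYA conversion folded into the denominator; this
package computes T in years first and scales to MYA, the reading
consistent with published endpoint pairs such as Ks 1.57 ↔ ~120 MYA and
Ks 0.07 ↔ ~5.4 MYA.

## Expression patterns

A gene is *expressed* in a tissue when its median TPM exceeds `tau`;
`tau = 0` by default — the only rule under which a "not expressed" gene
has exactly all-zero medians — and exposed because published surveys
rarely state their cutoff. Categories are mutually exclusive and
exhaustive: ubiquitous (all tissues), silent (none), tissue-specific
(exactly one), other. Classification always uses raw TPM; log~2~(TPM+1)
is for display only. Membership counts per tissue and per expression
breadth k sum to the gene total by construction.

## qPCR analysis

Relative expression follows 2^−ΔΔCt^ with amplification efficiency fixed
at 2: ΔCt = Ct(target) − Ct(reference) per replicate, ΔΔCt against the
mean control ΔCt *at the same timepoint* (a time-zero baseline is
available as an option; the matched-control baseline is the default
because stress-course designs carry an explicit untreated series).
Significance letters come from one-way ANOVA with Tukey HSD and an
insert-and-absorb compact-letter display, the conventional machinery
behind lettered bar plots; two groups share a letter exactly when their
Tukey p ≥ α, which the tests verify exhaustively for up to six groups.
When all groups have zero variance the letters fall back to exact
equality of means. Because a figure's letters can compare either
timepoints within a gene or treatment versus control, both statistics are
emitted (letters across timepoints; Welch t per timepoint).

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions of the survey it emulates:

* **Genomes.** Background genes have uniform random codon composition
  (150–450 residues), guaranteeing < 30% identity to anything planted;
  planted family members derive from subfamily archetypes carrying the
  canonical domain layout (full forward transporters for A–C, half for D,
  soluble for E/F/I, reverse for G) with fixed motif islands, so the
  identification stage has exact ground truth. Planted events place
  tandem pairs at adjacent ranks, proximal pairs separated by ≥ 2
  background genes, dispersed pairs on different chromosomes, and
  segmental blocks of ≥ 5 genes duplicated in order onto another
  chromosome (so default chaining recovers them). Gene models carry
  exons, introns and UTRs, with a small UTR-dropout fraction mirroring
  the handful of UTR-less members real surveys report. All genes, ranks
  and coordinates round-trip through the annotation I/O.
* **CDS evolution.** `evolve_cds_pair()` runs a per-codon continuous-time
  model: each single-nucleotide neighbour is reached at rate
  `target_ks/3` when synonymous and `target_omega × target_ks/3` when
  nonsynonymous (stop-creating changes at rate 0 when forbidden), for
  unit time. This makes the expected synonymous density equal `target_ks`
  — precisely the quantity NG86 estimates — without rate heterogeneity.
  An `invariant_codons` option disallows nonsynonymous changes at chosen
  codons, modelling the site-specific purifying selection that keeps
  Walker/signature motifs intact in real families; the genome generator
  uses it for motif islands so planted members never lose their
  diagnostic domains. Recovery tests run the generator *without* that
  protection.
* **Expression and qPCR.** The expression generator plants exact category
  counts (the packaged template is 51 ubiquitous / 29 silent / 18
  tissue-specific over 15 tissues, the published pattern of a 255-member
  family); the Ct generator follows the 2^−ΔΔCt^ model with Gaussian
  noise on every measured Ct and triplicate samples by default.

All randomness flows from a single integer seed; identical seed and
configuration give byte-identical files.

## Numerical choices and problem sizes

* Percentage shares use half-up decimal rounding (`round_half_up()`),
  which reproduces printed tallies such as 69.41% (177/255) and 0.296%
  (255/86,247); base R's banker's rounding does not.
* The pI bisection terminates at |net charge| < 10^-4^ (about 10^-6^ pH
  resolution); charge is strictly monotone in pH, so the root is unique.
* Nearest-reference ties break toward the earlier panel entry and are
  flagged rather than silently resolved.
* Parameter-recovery suites use 100 simulated 300-codon pairs per
  (Ks, ω) cell over Ks ∈ {0.1, 0.5, 1.0} × ω ∈ {0.2, 1.0}, a ~500-gene
  genome with a 2/2/4/18 tandem/proximal/dispersed/WGD planted mix (a
  1/10-scale version of a published 20/17/41/177 inventory), and 100
  noisy qPCR simulations; these sizes hold Monte-Carlo error comfortably
  below the tested tolerances while keeping the default suite fast.
* Ka/Ks recovery is measured on the positional codon pairing: the
  generator simulates no indels, and at ω = 1, Ks = 1 proteins fall to
  ~37% identity, where a global protein alignment introduces spurious
  gaps that corrupt the estimate. On the true pairing all six cells
  recover within 10% relative bias. The pipeline's `kaks_table()` still
  uses protein-guided alignment, since real data contains indels.

## What the synthetic tests do and do not show

The generator emulates the *structure* of real inputs — gene models with
consistent coordinates, homology with known divergence, collinear blocks,
category-clean expression, a noise-free-invertible Ct model — but not
their full texture: no rate heterogeneity among sites or lineages, no
transition/transversion bias, no isoforms, no transposons or assembly
gaps, uniform codon usage in background genes, and expression categories
planted rather than emergent. Passing tests therefore demonstrate that
the algorithms are implemented correctly (they recover known truth under
the stated model), not that the biological conclusions of any particular
survey are robust to annotation errors, alignment ambiguity or expression
normalization choices. On real data the HMM-based identification the
scanner replaces may differ at the margins (very divergent NBDs, exotic
architectures), and NG86 itself is known to drift at high divergence —
the reason the Ks > 2 discard rule exists.

## Known limitations

* No maximum-likelihood Ka/Ks (GY94-style) or
  transition/transversion-weighted NG variants; universal genetic code
  only (the table is config-extensible).
* No bootstrap support values on the NJ tree.
* No subcellular-localization prediction; the member table reserves an
  annotation column.
* Block chaining is gene-rank-based; base-pair distances are not used.
* The qPCR model fixes amplification efficiency at 2.

## A worked example

```{r example, eval = FALSE}
library(abcsurvey)

sim <- simulate_genome(genome_sim_config(
  n_chromosomes = 4, chrom_length = 3e6, n_background_genes = 60, seed = 7,
  events = list(
    planted_duplication("B", "tandem", 0.3, 0.2),
    planted_duplication("C", "proximal", 0.4, 0.2, intervening_genes = 4),
    planted_duplication("G", "dispersed", 0.5, 0.3),
    planted_duplication("A", "segmental", 0.3, 0.2,
                        block_size = 6, n_family = 2)
  )
))
survey <- run_survey(sim, out_dir = "survey_out")
summary(survey)
```

The report object carries every tally with its recomputed share, and
`write_genome()` / `run_survey(out_dir = )` serialize all stages as TSV,
JSON and Newick for downstream plotting.
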