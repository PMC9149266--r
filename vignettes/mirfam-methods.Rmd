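---
title: "Methods: homology-based discovery and characterization of plant miRNA families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based discovery and characterization of plant miRNA families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mirfam` implements, at desk scale, the standard computational workflow by
which conserved plant miRNA families (miR166 being the motivating example)
are discovered in a newly assembled genome and characterized: homology
scanning with known precursors, secondary-structure screening of candidate
hairpins, placement of mature miRNAs on the precursor arms, UPGMA
phylogenetics, promoter cis-element prevalence, target prediction with an
expectation-style penalty, DICE/Nei similarity clustering of target-function
profiles, and stem-loop RT-qPCR fold-change analysis. Every stage can be
exercised on synthetic inputs with known ground truth, so the whole pipeline
is testable without any external database.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, together with what the synthetic data
do and do not emulate.

# Homology scanning

Candidate loci are found by exact Smith–Waterman local alignment of known
precursor sequences against genome scaffolds, both strands, with affine
gaps. We deliberately use the exact dynamic program rather than a heuristic
seeded search: at the scale of this analysis (a handful of ~100-nt queries
against scaffolds) the quadratic DP costs nothing, is fully verifiable
against enumeration, and has no seeding artifacts.

* Scoring defaults: match `+2`, mismatch `-1`, gap open `-5`, gap extend
  `-1`; a gap run of length $k$ costs `gap_open` $+ k\,\cdot$ `gap_extend`.
* Identity is matches over aligned columns (gaps count against identity);
  coverage is the aligned fraction of the query. Defaults
  `min_identity = 0.85`, `min_coverage = 0.8` reflect the identity range
  (63–90%) typical of cross-species precursor homology while rejecting
  short spurious local matches, whose coverage is far below 0.8.
* Multiple copies of a query in one scaffold are found by iterative
  masking: the best local alignment is reported, hard-masked with `N`
  (which no alignment column may touch), and the scan repeats until the
  best remaining alignment no longer covers the query.
* Hits whose intervals overlap by at least 50% reciprocally are one locus;
  the best-scoring hit is kept. This prevents duplicate candidates when
  several related queries hit the same locus.
* Coordinates are 0-based half-open internally and 1-based inclusive in all
  reports.

The identity/coverage thresholds and the flank width added to extracted
candidates are parameters, not claims: no published values exist for the
screening step this reimplements.

# Hairpin folding and the MFEI screen

Folding is an energy-weighted Nussinov dynamic program: over all nested
(pseudoknot-free) structures with hairpin loops of at least `min_loop = 3`
unpaired bases, minimize the sum of base-pair energies GC $-3.0$, AU $-2.0$,
GU $-1.0$ kcal/mol. This model is chosen because it is *fully verifiable*:
the test suite enumerates every nested structure of random short strings and
confirms the DP optimum. The trade-off is explicit: absolute energies are
not comparable to nearest-neighbour (Turner-model) values from a
thermodynamic folder, so every downstream energy threshold is an exposed
parameter, and a thermodynamic folder can be substituted upstream of the
screen without any interface change (fold results are plain
sequence/structure/energy records).

Screening statistics:

* **MFE** — the minimized pair-energy sum (≤ 0).
* **GC** — fraction of G+C.
* **MFEI** — $(|\mathrm{MFE}|/\mathrm{length} \times 100)/(\mathrm{GC}
  \times 100)$, reported positive. MFEI separates genuine miRNA precursors
  from tRNA/rRNA/mRNA folds; accepted precursors typically score ≥ 0.85,
  which is the default `min_mfei` (taken from the smallest value among
  accepted miR166-class precursors, and flagged as a parameter rather than
  a claim).
* **NM** — the number of mature-duplex positions not engaged in a WC or G:U
  pair with the opposite mature span; the 5′ and 3′ spans are counted
  separately and the larger count is reported, so a perfect duplex gives 0
  and fully unpaired spans give the mature length. The default `max_nm = 4`
  is inclusive (published miR166-class precursors show NM up to 4). Whether
  bulges and loops are counted identically is not standardized anywhere we
  know of; the column-counting rule above is declared.

Arm extraction parses the dot-bracket string: the candidate must fold into a
single stem-loop, whose 5′/3′ arms are the paired flanks of the unique
hairpin loop (interior-loop and bulge columns belong to the arms).
Structures with more than one hairpin loop are flagged "not a simple
stem-loop". One refinement proved necessary: because the Nussinov model
attaches no penalty to loops, its optima decorate long unpaired stretches
with isolated single pairs, each of which would technically create an extra
hairpin loop. Topology is therefore judged on *stacked* pairs only (pairs
with at least one stacked neighbour), the familiar no-lonely-pairs
convention of thermodynamic folders. Two genuinely stacked stems side by
side are still rejected.

Mature placement slides each 20–24-nt reference mature along the precursor
without gaps (published mature-homolog comparisons report only substitutive
mismatches), keeps the reference with the fewest substitutions per arm
(ties: reference order, then leftmost window), assigns the arm by the window
midpoint relative to the loop, and reports nothing above `max_mismatch = 3`.
When only one arm carries an annotation, the opposite duplex span is the
star span — the range of pairing partners of the annotated span — which is
the standard miRNA* definition and keeps NM insensitive to small pairing
shifts.

# UPGMA phylogenetics

Distances are p-distances (proportion of differing columns among columns
where both sequences have a residue; any gap excludes the column). The
distance model used by the original desktop programs is not published, so
the simplest declared model was chosen; clade topologies of any particular
published figure are consequently not a validation surface — only the
algorithmic properties are.

UPGMA is arithmetic-mean agglomeration: merge the closest pair, heights are
half the merge distance, inter-cluster distances are size-weighted averages.
Ties are broken by the lexicographically smallest pair of cluster labels (a
cluster is labelled by its smallest leaf), and children are ordered by
label, which canonicalizes the Newick output. Trees are ultrametric by
construction (asserted to 1e-9 in the tests, and cross-checked against
average-linkage `hclust` heights).

Bootstrap support resamples alignment columns with replacement; the support
of an internal node is the percentage of replicate trees containing the
same leaf set. Replicates that produce an undefined distance (no comparable
columns for some pair) are redrawn. With one replicate supports are 0 or
100 by construction; the default in the bundled pipeline is 100 replicates,
a size chosen so the full synthetic run stays interactive.

# Promoter cis-element prevalence

Promoters are scanned for exact IUPAC-degenerate motif matches on both
strands (overlaps allowed, 1-based positions, minus-strand hits located by
the start of the reverse-complement occurrence on the given sequence).
Whether single-stranded scanning was used in the original analyses is
unstated; both-strand scanning is the default and a flag turns it off.

The element dictionary ships as an editable TSV (name, IUPAC pattern,
category) with consensus strings following the public PlantCARE motif
descriptions; since no motif sequences are printed in the motivating study,
none of the default consensi is load-bearing — all validation uses either
toy motifs or the transcribed presence matrix directly. The category map
is: gibberellin {GARE-motif, P-box}; methyl jasmonate {TGACG-motif,
CGTCA-motif}; salicylic acid {TCA-element}; auxin {TGA-box, TGA-element,
AuxRR-core}; abscisic acid {ABRE}; defense/stress {TC-rich}; drought {MBS};
low temperature {LTR}; anaerobic induction {ARE}.

A promoters × categories presence matrix (cell TRUE iff ≥ 1 hit of any
motif of the category) feeds the prevalence summary: count, n, and percent
with *half-up* rounding to one decimal, so 7/9 prints as 77.8 — base R's
round-to-even would disagree at some boundaries. The bundled 9 × 9 matrix of
phytohormone- and defense-related elements in miR166 promoter regions
reproduces the published prevalence arithmetic exactly (77.8% gibberellin
and ABA, 66.7% MeJA and auxin, 4/3/2 promoters with drought/low-temperature/
defense elements, anaerobic-induction elements in all nine).

# Target prediction

miRNA:transcript duplexes are scored by an additive expectation penalty:
mismatch 1.0, G:U wobble 0.5, each bulged base 2.0, Watson–Crick 0;
penalties at miRNA positions 2–13 (the seed, counted from the 5′ end) are
doubled. Sites at or below the cutoff (default 5.0) are reported with an
inhibition mode: translational repression iff any non-WC state occurs at
the central positions 9–11, cleavage otherwise. These weights mirror the
publicly described psRNATarget-style penalty system and are all exposed as
configuration.

The scan evaluates every ungapped transcript window plus variants with at
most one single-base bulge on either strand — the dominant geometry of
plant miRNA target sites — which keeps the search space small enough that
the test suite can compare against brute-force window evaluation.
Overlapping candidate spans collapse to the best (ties to the leftmost).
Transcripts are scanned on the given (sense) strand only.

# DICE/Nei similarity of target-function profiles

Functional similarity between miRNAs is computed from presence/absence
profiles over target-gene function labels: DICE similarity
$S = 2|A \cap B| / (|A| + |B|)$, Nei-style distance $D = -\ln S$, and UPGMA
clustering of $D$. The transform is fixed as $-\ln S$ because it is Nei's
standard form and matches internally consistent published
similarity/distance pairs (e.g. 0.28 ↔ 1.27, 0.36 ↔ 1.02); published
tables also contain pairs inconsistent with *any* single transform
(independent rounding in the original software is the likely cause), so
full-matrix reproduction is deliberately not a validation target.
Zero-similarity pairs have infinite distance; before clustering these are
replaced by a configurable cap (default 10.0) with a warning, keeping the
tree defined while making the substitution visible.

# Stem-loop RT-qPCR analysis

Relative quantification is classic $2^{-\Delta\Delta C_t}$ against a
small-RNA reference gene (U6 by default) with the 0-h sample as control:

1. technical replicates are averaged first;
2. $\Delta C_t = \bar{C_t}(\mathrm{gene}) - \bar{C_t}(\mathrm{reference})$
   within each (treatment, timepoint, biological replicate);
3. $\Delta\Delta C_t$ subtracts the mean control $\Delta C_t$; the
   per-replicate fold is $2^{-\Delta\Delta C_t}$, and mean/SD are taken
   over biological replicates, making the biological replicate the unit of
   error and fixing the control mean fold at 1 in the zero-noise limit.

Amplification efficiency is fixed at 2.0 (perfect doubling) and exposed as
a parameter; no efficiency correction is applied. Significance letters come
from one-way ANOVA on log₂ folds per biological replicate (log folds, not
raw folds: Ct-scale Gaussian noise makes log₂ errors additive, so the
variance is stabilized) followed by Tukey's HSD over all timepoint pairs;
letters are assigned greedily from the highest mean, a group joining an
existing letter class only when it differs significantly from no member.

# The synthetic-data generators

The generators define the conditions under which the pipeline is validated;
their defaults are fixed, not tuned.

* **Genome**: i.i.d. uniform A/C/G/T scaffolds with reference precursors
  implanted at recorded loci, strands uniform, independent per-base
  substitution probability `mutation_rate` (default scenarios use 5%, the
  divergence scale at which cross-species precursor homology is still
  detectable at 85% identity). Implants never overlap; placement re-draws
  on collision and fails explicitly after bounded retries. Uniform
  background is the simplest null that cannot systematically mimic
  implants; real genome composition (repeats, isochores, GC heterogeneity)
  is deliberately *not* emulated, so recovery results say nothing about
  repeat-induced false positives in real assemblies.
* **Reference hairpin family**: random 40-nt arms ending in a GC clamp, a
  12-nt all-A loop, and the reverse-complemented arm with two
  substitutions in its outer half. The all-A loop cannot pair with itself,
  and opening the GC clamp is strictly unfavourable, so the designed
  optimum is a single long stem-loop; mature 21-mers sit four bases off
  the loop junction, where their duplex is insensitive to loop-adjacent
  rearrangements. At 5% implant mutation, an occasional implant draws
  enough substitutions concentrated in the mature duplex to exceed NM 4,
  or forms a genuine stacked side hairpin — such implants *should* fail
  the declared screen, and across many seeds roughly one run in six
  contains one.
* **Promoters**: for every TRUE cell of a specification matrix, a concrete
  instantiation of one motif of that category is planted at a recorded
  position and strand; FALSE cells are guaranteed motif-free for their
  category. Chance background occurrences of unwanted motifs are removed
  by point substitutions outside planted sites (with whole-promoter
  redraws as fallback), and the finished set is verified by re-scanning,
  making presence/absence validation exact rather than probabilistic.
* **Transcripts**: each planted site is the reverse complement of the
  miRNA with substitutions chosen to realize a requested expectation
  penalty exactly: whole points from non-seed mismatches, then seed
  mismatches; a half-point remainder uses a G:U wobble. Mismatches are
  created by setting the site base equal to the miRNA base, which can
  neither pair nor wobble for any nucleotide.
* **Ct tables**: within each (treatment, timepoint, biological replicate)
  sample, all genes share one Gaussian sample shift (library input;
  cancels in the ΔCt), the target baseline is lowered by log₂ of the true
  fold, and each technical replicate adds independent Gaussian noise on
  the Ct scale (default SD 0.2 cycles, a typical qPCR repeatability
  figure). Polymerase-efficiency variation is not modelled. The default
  experiment design uses the timepoint grids of a five-stress experiment
  (freezing/cold/heat/drought/salt) and fold magnitudes in the 4–38×
  range typical of abiotic-stress miRNA induction, with three biological
  × three technical replicates.

# Numerical choices and degenerate inputs

* Fold traceback ties prefer the pair with the smaller 5′ index; sequences
  shorter than `min_loop + 2` return the all-dots structure at energy 0.
* `U`/`T` are interchangeable at every input boundary; genomic work is in
  the DNA alphabet, folding and mature reporting in RNA.
* MFEI is undefined at GC = 0 and fails explicitly.
* UPGMA refuses non-symmetric or non-finite inputs; p-distance fails when
  no gap-free column exists.
* All randomness is seeded; every generator is byte-reproducible, and the
  pipeline derives per-stage seeds deterministically from one root seed.
* Problem sizes in the bundled runs — 2 × 2 kb scaffolds, 3–5 implants,
  ~100-nt precursors, 9 × 1600-bp promoters, 100 bootstrap replicates, 200
  Monte-Carlo qPCR repeats — were chosen so a full synthetic study runs
  interactively on a laptop while every statistic retains enough
  resolution to detect implementation errors.

# Known limitations

* The folding model omits stacking, dangles, and loop penalties; its MFE
  values are model-specific numbers, useful for screening only after the
  thresholds are calibrated to the model (the shipped defaults are
  calibrated to the Nussinov energies above).
* Homology scanning is exact but quadratic; it is not intended for
  chromosome-scale scans, where a seeded aligner should feed its candidate
  windows into the same screen.
* Target scoring ignores site accessibility and hybridization energy;
  validation against degradome data is out of scope.
* The bootstrap resamples alignment columns independently, which
  understates support for very short alignments with correlated columns.
* The compact letter display is greedy from the highest mean; it is the
  conventional display but not guaranteed to be the minimal letter cover.
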