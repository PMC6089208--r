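---
title: "Methods: identifying and characterizing plant nsLTP families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing plant nsLTP families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsLTPscan)
```

# The problem

Non-specific lipid transfer proteins (nsLTPs) are small secreted plant
proteins that bind and shuttle hydrophobic ligands. They matter to plant
breeders because many of them respond to biotic and abiotic stress, and to
allergologists because several are food allergens. The family is defined
not by overall sequence conservation — which is poor — but by an
eight-cysteine motif (8CM),

```
C -Xn- C -Xn- CC -Xn- CXC -Xn- C -Xn- C
```

whose eight cysteines form four disulfide bridges that stabilize a
hydrophobic cavity. Annotating the family in a newly sequenced genome is a
multi-stage desk exercise: find candidate proteins carrying the motif,
discard look-alikes (protease inhibitors, seed storage proteins, hybrid
proline-rich proteins), characterize the mature proteins, sort them into
the family types, and relate them to genome context and expression. This
package implements that workflow end to end, with a synthetic-data
generator that plants known answers so every stage can be validated
exactly.

The package ships a transcription of the published 89-member cabbage
(*Brassica oleracea*) nsLTP catalog (`loadReferenceCatalog()`), which
anchors the catalog-level computations: 89 entries in types 1, 2, C, D, E,
G and X, with signal-peptide lengths of 17–34 residues, 57 basic and 32
acidic isoelectric points, and 74 entries with an Arabidopsis ortholog
across 42 distinct genes.

# Motif detection

`findEightCM()` searches for eight cysteines satisfying the structural
constants of the motif — cysteines 3 and 4 adjacent (CC), cysteines 5 and
6 separated by exactly one residue (CXC) — with the five variable gaps
each in `[minGap, maxGap]`. Gaps count residues strictly between the
flanking cysteines, so the CC dyad has gap 0 and the CXC triplet gap 1;
only the five variable gaps form the spacing signature. The default
bounds (2, 40) bracket all spacings observed in the family types (5–29)
with margin.

When a sequence admits several eight-cysteine assignments, the detector
returns the lexicographically smallest position vector
(leftmost-then-most-compact). This choice is deterministic, favours an
N-terminal mature domain — which is where the motif sits after the signal
peptide — and is directly checkable against exhaustive enumeration of all
8-subsets of cysteines; the test suite verifies that equivalence on
hundreds of random sequences. Extra cysteines outside the matched backbone
are allowed, because type G proteins carry long C-terminal extensions.

Per-type spacing grammars ship as a YAML config (`ltpGrammars()`), one
allowed-value set per variable gap. The printed family tables list
discrete observed spacings rather than ranges; the grammar file keeps them
discrete but is user-replaceable, so a re-analysis can widen them to
ranges if desired.

# The filter cascade

`runFilterCascade()` applies, in the narrative order of a family
annotation:

1. **essential cysteines** — no 8CM, no family membership;
2. **N-terminal signal sequence** — nsLTPs are secreted precursors;
3. **similarity exclusion** — candidates resembling user-supplied
   protease-inhibitor / storage-protein references are discarded
   (identity ≥ 0.40 and coverage of the shorter sequence ≥ 0.75, both
   configurable);
4. **hybrid proline-rich proteins** — an 8CM-bearing protein whose
   pre-motif region is ≥ 20 residues and ≥ 25% proline is a HyPRP, not an
   nsLTP.

Every rejected protein carries exactly one reason — the first failing
stage — and kept plus rejected always partition the input.

The signal-peptide and GPI calls are deliberately simple, documented
heuristics rather than re-implementations of neural-network predictors:
a signal peptide requires a hydrophobic core (≥ 8 consecutive residues,
mean Kyte–Doolittle hydropathy ≥ 1.6, starting within 12 residues of the
optional charged N-region) and a cleavage site 3–12 residues downstream
whose −3 and −1 residues are small (A/G/S/C/T); a GPI anchor requires a
C-terminal hydrophobic stretch (≥ 8 residues, mean ≥ 1.5 within the final
25) preceded 8–12 residues upstream by a small omega residue
(A/G/S/N/D/C). When several cleavage sites satisfy the rule the most
N-terminal one is reported, which makes the call deterministic. Users with
access to dedicated predictors can bypass both heuristics entirely via the
`externalCalls` table of `runFilterCascade()`; the cascade logic is
unchanged either way. The HyPRP thresholds (20 residues, 25% proline) and
the exclusion-stage identity floor (0.40 — set above the 0.30 typing floor
so genuine family members are not over-excluded, and conservative below
typical paralog identity) are this package's operationalization of
categories that the literature names but does not quantify; all are
config-exposed.

# Physicochemistry

`matureSequence()` removes the signal peptide; the GPI tail of type G
proteins is *not* trimmed, because published mature lengths for
GPI-anchored members do not state whether the anchor signal downstream of
the omega site was removed — we record the convention rather than guess.
`averageMass()` sums average (not monoisotopic) residue masses plus one
water, matching the convention of the standard pI/Mw web calculators used
for published catalogs. `isoelectricPoint()` finds the root of the
Henderson–Hasselbalch net-charge curve by bisection on pH ∈ [0, 14]
(charge tolerance 1e-4, ≤ 100 iterations); the curve is strictly
decreasing so the root is unique. The default pKa set is Bjellqvist's
(with residue-specific N-terminal values), again matching the web
calculators; EMBOSS and IPC-protein sets are selectable for sensitivity
analysis. The tests pin the bisection root to a 0.001-pH grid scan of the
charge curve within 0.01 pH units.

# Type assignment

Classification is two-round: GPI-anchored proteins are type G outright;
the rest are compared by pairwise identity against typed exemplar sets.
A type is a candidate when its best exemplar identity reaches the floor
(0.30 by default); among candidates the highest mean identity wins, with
ties broken by spacing-grammar compatibility and then lexicographically.
Below the floor, the protein is listed individually as type X.

Two design choices deserve justification. First, identities come from
pairwise Needleman–Wunsch alignments (BLOSUM62, gap open 10, extend 0.5)
rather than a multiple sequence alignment: pairwise identities are
order-independent, dependency-free and exactly reproducible, at the cost
of being slightly higher than MSA-column identities; the 0.30 floor is
configurable to compensate. Second, the identity denominator is aligned
columns excluding terminal gap columns, which protects short type 2
sequences from being penalized for length differences. Alignment coverage
(used in the similarity-exclusion and orthology stages) is the fraction of
the shorter sequence's residues inside the non-terminal columns.

The packaged exemplars are synthetic, grammar-conforming sequences (see
below), suitable for validating the machinery; production use should
supply curated Arabidopsis or rice references via the `exemplars`
argument.

`njTree()` (neighbor joining on `1 − identity`, delegated to ape) gives a
quick clustering view; it is a utility, not a replacement for
maximum-likelihood phylogenetics.

# Genome context

A tandem array is operationalized as a maximal run of family genes on one
chromosome with ≤ 1 intervening non-family gene and ≤ 100 kb between
consecutive members — the literature reports tandem counts without a
numeric rule, so both knobs are explicit config. Orthology uses reciprocal
best hits under global-alignment score with identity ≥ 0.30 and coverage
≥ 0.75 floors; alignment statistics (e-values) are intentionally out of
scope, with identity and coverage standing in for them. Collinearity uses
gene-rank windows (10 ranks, ≥ 3 anchors per block, inversion-tolerant)
rather than base-pair windows, making it robust to annotation density.

# Expression

FPKM is computed as `1e9 * count / (length * library_size)`. A gene is
*expressed* in an organ when its replicate-averaged FPKM is ≥ 1 — the
boundary is inclusive — and *organ-specific* when expressed in exactly
one organ. Whether published organ calls averaged replicates first is
typically unstated; averaging is this package's declared choice.

Differential expression uses an exact conditional binomial test: replicate
counts are summed per condition and the condition-B count is tested
against the pooled total with success probability equal to B's share of
the summed library sizes. Fold changes are computed on replicate-mean
FPKM with a pseudocount of 1 (finite for on/off genes), and a gene is a
DEG when BH-adjusted q < 0.05 **and** |log2 FC| > 1, the fold-change
bound strict. This is a deliberately simple, fully specified substitute
for count-model packages: its planted-truth recovery — not equality with
any particular negative-binomial implementation — is the validation
target.

A calibration caveat, stated openly: the binomial test is exact under
Poisson sampling but anticonservative under overdispersion. At the
generator's default dispersion (0.1) the p-values alone would call many
nulls; specificity is carried by the fold-change gate, and the tests
verify both regimes — false-discovery calibration under the test's own
Poisson model, and planted four-fold recovery with ≤ 1 median false call
at dispersion 0.1 over 20 simulations.

# Promoter scanning

`scanPromoter()` does exact IUPAC matching (no position-weight scoring, in
keeping with pattern-based plant cis-element databases) on both strands,
reporting reverse-strand hits in forward coordinates; an `N` in the
promoter matches nothing, while ambiguity codes in the *pattern* expand
normally. Hits are 1-based, the R/Bioconductor convention used throughout
the package. The shipped dictionary (ABRE, MBS, LTR, TC-rich, WUN-motif,
ARE, GC-motif) covers the stress categories commonly summarized in family
surveys; it is a small default meant to be replaced by a database export.
The default promoter length for simulation is 1500 bp.

# The synthetic-data generator

`simulateProteome()` and its siblings generate every input with planted
ground truth, and in strict mode (the default) run the corresponding
detector on each product at creation time, so a generator/detector drift
fails loudly.

Design points:

* **Per-type templates.** Each type has a deterministic template mature
  sequence (`typeTemplates()`, fixed internal seed); simulated members
  take region-wise prefixes of it (gap lengths drawn uniformly from the
  type's grammar) with 12% point substitutions. This emulates the
  within-family identity (~0.85–0.9) against cross-family identity
  (~0.1–0.2) that makes identity-based typing work on real families.
* **Cysteine-free fillers.** Filler regions never contain C, so the
  planted backbone is the unique eight-cysteine assignment and motif
  recovery can be asserted exactly. Fillers also exclude strongly
  hydrophobic residues, so they cannot mimic a signal-peptide core or a
  GPI tail.
* **Outliers.** Planted type-X proteins use a filler alphabet disjoint
  from the templates (H/R/Y/W), keeping their best identity to every
  exemplar safely below the 0.30 floor while still carrying a valid 8CM
  and signal peptide.
* **Engineered termini.** Signal peptides (length uniform on 17–34) are
  built backwards from the heuristic: M, a hydrophobic core, then A-Q-A
  so the (−3,−1) rule fires exactly at the planted cleavage site. Type G
  precursors append a 40–60 residue extension, a glycine omega site, ten
  Q/E spacer residues and a ten-residue hydrophobic tail, which the GPI
  heuristic recognizes at the planted omega.
* **Decoys** are engineered to fail exactly one cascade stage: a mutated
  backbone cysteine (leaving seven), a charged/polar N-terminus, a
  30-residue one-third-proline pre-motif region, or a near-copy of an
  exclusion reference.
* **Genome layout.** The default tandem specification plants five
  two-gene and two three-gene arrays (16 genes in 7 arrays), with array
  members 20 kb apart (≤ 1 intervening gene) and everything else isolated
  by ≥ 4 background genes at 120 kb spacing.
* **Counts.** Negative-binomial with dispersion 0.1, baseline 20 FPKM,
  library size 2e7, gene lengths uniform on 500–2000 bp; organ-specific
  genes at 50 FPKM in their organ and 0.1 elsewhere; differential genes
  at a 4-fold effect between the first two groups. With 3 replicates
  these sizes give near-certain recovery of 4-fold effects while keeping
  the simulations fast.

What passing on synthetic data does **not** show: the generator's residue
composition is unrealistic (restricted filler alphabets), its signal
peptides and GPI tails are engineered to the package's own heuristics
rather than to predictor training data, and its expression model has no
sample correlation structure or length bias. Synthetic validation
demonstrates that the machinery is correct, not that the heuristics match
dedicated predictors on real proteomes — for real analyses, plug in
external predictor calls and curated exemplars.

# Problem sizes

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: 500 random
sequences and 500 grammar-generated precursors for motif validation, a
65-protein proteome (50 true, 15 decoys) for the cascade, 190 proteins
(30 per type plus 10 outliers) for typing, 200 random peptides for the pI
oracle, and 20 replicate simulations of 100 genes for differential
expression.

# Known limitations

* The signal-peptide and GPI heuristics are transparent approximations;
  on real proteomes they will disagree with neural-network predictors on
  borderline sequences. The pluggable `externalCalls` path exists for
  exactly that reason.
* Pairwise-identity typing depends on exemplar quality; with the shipped
  synthetic exemplars it validates the machinery only.
* The exact binomial DEG test ignores biological overdispersion (see
  above); it is a documented, reproducible baseline, not a replacement
  for count-model inference.
* The packaged catalog supports catalog-level computations only: the
  published table prints mature lengths, masses and pI values but not
  sequences, so per-protein physicochemistry of the real family cannot be
  recomputed from the fixture.
* One published catalog row (BoLTPg25) prints an intron count of 2 with
  four intron positions; the fixture preserves the row verbatim and the
  package does not force the two fields to agree.
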