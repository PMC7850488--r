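---
title: "Methods: multiparametric missense mutation scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric missense mutation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmms)
```

## The problem and the model

Glycine decarboxylase (GLDC) carries hundreds of known missense mutations
causing non-ketotic hyperglycinemia (NKH), with clinical severity ranging
from attenuated to fatal. The package implements a severity scale for such
mutations and propagates it to predictions about engineered mouse models.

Each mutation is reduced to a vector of binary indicators
$x_p \in \{0,1\}$ over a parameter registry. Two scores follow:

* **MMS** $= \sum_p s_p x_p$, with unit signs $s_p = +1$ except the
  conserved-substitution parameter ($s_p = -1$), the one indicator that
  argues for tolerance. MMS is an integer in $[-1, 17]$ for the canonical
  registry; tables of all theoretical mutations conventionally clamp it at
  0 (`computeMMS(..., clamp = TRUE)`).
* **WMMS** $= \sum_p w_p x_p$, with coefficients $w_p$ trained by ordinary
  least squares of clinical outcome scores (COS, a 0–12 severity scale
  assigned to homozygous patient mutations) on the parameter matrix.

The clinical link is the regression of WMMS on COS over homozygous
mutations, `WMMS = 0.76·COS − 2.5` (r² 0.9). Evaluated at the clinical
cutoff COS = 5 it yields WMMS 1.3, the attenuated/severe transition used
throughout (`outcomeModel()`, `wmmsThreshold()`).

Key modelling assumptions, stated explicitly:

1. The parameter indicators are binary and act additively; no
   interactions are modelled. A double mutation therefore cannot be
   scored — the weights were trained on single-point mutations — and the
   selection functions reject it by construction (labels encode exactly
   one substitution).
2. COS of control polymorphisms is 0 in training. The training data pair
   patient mutations (COS > 0) with benign control polymorphisms whose
   target value is never stated; 0 is the only choice consistent with
   negative WMMS predicting reduced pathogenesis.
3. The intercept is fitted but excluded from the score, so an all-zero
   parameter vector scores exactly 0 and negative WMMS are meaningful.
   `computeWMMS(..., includeIntercept = TRUE)` exists for sensitivity
   checks.
4. Phenotype is linear in WMMS between the two validated anchors
   (see "Outcome interpolation" below).

## Saturation mutagenesis

`enumerateMissense()` substitutes each of the three alternative bases at
every cDNA position, translates, and classifies. Conventions:

* **Stop codons.** A trailing stop codon supplied with the sequence is
  trimmed at construction (recorded in the object), so census totals are
  exactly $3L$ over coding positions and the category partition
  (silent + nonsense + leader-excluded + missense) is exact. An internal
  stop is an error: the reference frame must be intact.
* **Classification priority.** Silent and nonsense changes are classified
  first; the leader filter (default 35 N-terminal residues, the
  mitochondrial targeting peptide) then removes only *missense* changes at
  leader residues. This makes the partition unambiguous and reproduces
  hand enumeration on toy sequences.
* **Deduplication.** Different nucleotide changes can yield the same
  protein mutation. The collapse keys on (position, ref, alt) and keeps
  the first cDNA provenance (lowest cDNA position, then alphabetical
  alternative base — deterministic). `collapse = FALSE` retains every
  provenance row, which matters for the codon-availability parameter:
  protein-level parameters are identical across provenances, so collapsing
  loses nothing else. The census records both the raw and the unique
  count, so either counting convention can be checked.
* Coordinates are 1-based and inclusive for both cDNA and protein.

## Cross-species mapping

`buildMap()` interprets a pairwise alignment column by column; an
insertion in the target shifts downstream numbering (the mouse GLDC
five-glycine insertion at positions 43–47 is the motivating case) and gap
columns are unmappable. A mutation maps only when the aligned target
residue is *identical* to its reference residue; a conservative
substitution does not count. This strict-identity rule is the one
consistent with the reported exclusion of non-conserved residues from
mapping.

Alignment computation is delegated: any pre-computed aligned FASTA is
accepted (`readProteinAlignment()`), and a self-contained global
Needleman–Wunsch (BLOSUM62, affine gaps 10/0.5, via Biostrings) is
provided for tests. Alignments from different programs are not guaranteed
identical, which is why mapping accepts an externally supplied alignment
as primary input.

## The parameter registry

The exact identities and conditions of all 18 parameters are supplementary
material not reproduced here, so the registry is configuration, not code
(`inst/extdata/parameter_registry.yaml`): the engine evaluates whatever
the registry declares, and synthetic registries of any width can be built
(`makeRegistry()`) for testing. The shipped canonical registry
instantiates the four named categories as:

| category     | parameters (condition) |
|--------------|------------------------|
| stability    | ddG very destabilizing (< −5 kcal/mol), destabilizing ([−5, −1.5)), stabilizing ((1.5, 5]), very stabilizing (> 5) |
| position     | helix, sheet, dimerization interface, active site (per-residue annotations) |
| conservation | ConSurf grade 9, grade 8, grade 7 |
| property     | proline, glycine, size, polarity, charge change (built-in tables) |
| evolution    | conserved substitution (BLOSUM62 score > 0; sign −1) |
| translation  | rare codon (mutant codon usage < 8 per thousand) |

Numerical choices:

* **ddG bands.** "Destabilizing" is *strictly below* −1.5 kcal/mol, so
  the destabilizing band is $[-5, -1.5)$ and −1.5 itself is unchanged;
  −5 exactly is destabilizing, not very destabilizing. Only the
  destabilizing-side edges are published; the stabilizing side mirrors
  them at +1.5 and +5 and is an assumption of this artifact, overridable
  in the registry thresholds.
* **Property tables.** Size classes cut residue volume (Zamyatnin) at 110
  and 160 Å³; polarity is the standard polar/nonpolar split; charge counts
  His as positive. Proline/glycine changes fire when either residue is
  involved. Swapping tables is a config change (`aaProperties()` documents
  the shipped one).
* **Conservation grades.** Single-grade conditions (9, 8, 7) rather than
  bands; whether the original conditions were thresholds or bands is not
  recoverable, and single grades keep the three indicators disjoint.
* **Missing data.** A mutation absent from a provider table is an error
  naming the mutation and parameter — never a silent 0 — because a zero
  indicator is a substantive claim.
* ΔΔG and conservation values are *consumed* from provider tables
  (structure-prediction and conservation servers produce them); the
  package does not compute them from first principles. Hydrogen-bond
  reasoning is contextual and deliberately outside the registry.

The active-site region is derived from structure
(`computeActiveSite()`): a residue is included iff any of its atoms lies
within the cutoff (default 5 Å) of any atom of the catalytic lysine or of
a named bound cofactor (PLP) / substrate. The implementation is an exact
all-atom distance computation, checked against a brute-force $O(n^2)$
oracle in tests.

`phiCorrelation()` implements the phi coefficient from the 2×2 counts;
a constant vector leaves it undefined and returns `NA` with a warning
rather than a number.

## Training and concordance

`trainWeights()` is deterministic OLS; exact collinearity is reported
with the offending columns rather than silently dropping them. Exact
correspondence between human and mouse WMMS (`scoreConcordance()`) is
counted after rounding to 2 decimals, the precision at which WMMS values
are reported; the rounding is configurable.

## Selection models

*Attenuated ranking* (`rankAttenuated()`): Score A is min–max
normalization of mouse WMMS over the cohort — the published description
fixes only the endpoints (top = 1, bottom = 0), and min–max is the
normalization that reproduces both when scores are negative (value/max
would not). Score B is $1 - |mWMMS - hWMMS| / \max|mWMMS - hWMMS|$,
cohort-relative because no absolute scale for the difference is given;
it is 1 exactly when the species' scores agree, and all 1 when every
pair agrees. Ties share the better (minimum) rank and are ordered by
label, deterministically.

*Severe selection* (`scoreSevereCriteria()`): five binary criteria —
WMMS ≥ threshold (default 9.94, the lead candidate's score), residue
conserved across species, mouse WMMS equal to human (2-decimal rounding),
alternate residue not proline (proline substitutions are destabilizing
enough to risk lethality), and active-site membership. A non-conserved
residue has no human score and forces the alignment criterion to 0.
Reachability by a single nucleotide substitution is implicit when
candidates come from `enumerateMissense()`.

Active-site versus non-active-site score distributions are compared with
Welch's unpaired two-tailed t-test (the groups' variances differ), via
`stats::t.test`; tests verify against the textbook formula.

## Outcome interpolation and colony statistics

Two engineered mice anchor the phenotype scale: WMMS −0.87 → 26% prenatal
fatality and 31% postnatal hydrocephalus; WMMS 10 → 90% prenatal fatality
(the cap observed for the severe double mutant). Between the anchors
`predictOutcomes()` interpolates *linearly* — the disease scale is
described as linear in WMMS, but no interpolant is printed, so linearity
is the minimal consistent choice and is recorded here prominently.
Hydrocephalus is returned as the constant 31% baseline without formate
(34% with formate, alongside 29% fatality, the rescued state): only those
two hydrocephalus values are reported anywhere, and no interpolation is
supportable. Scores outside $[-0.87, 10]$ are out of the validated range
and produce a class but no percentages. Band edges are inclusive on the
attenuated side so that the validated −0.87 anchor classifies attenuated.

`prenatalLethality()` is the shortfall of homozygotes against the
Mendelian 25%: $100(1 - (hom/total)/0.25)$, floored at 0.
`mendelianChisq()` is the Pearson goodness-of-fit against 1:2:1 (df 2).

## The synthetic fixture generator

`generateFixture()` produces the material the tests run on, emulating the
*structure* of the real study inputs:

* a "human-like" cDNA (default 60 codons — long enough to span the
  insertion point, small enough for brute-force oracles) and a
  "mouse-like" copy with one in-frame 15-nt glycine insertion after codon
  42 plus ~8% missense codon substitutions, mirroring the five-glycine
  insertion and ~92% identity of the real orthologue pair;
* a Bernoulli(0.3) binary parameter matrix (default 40 × 18 — the order
  of the homozygous training set, and 0.3 a realistic per-parameter
  firing rate for pathogenic missense sets);
* planted Gaussian weights (sd 1.5, the scale of trained coefficients)
  recorded alongside for recovery tests;
* COS values generated by inverting the clinical line
  (COS = (WMMS + 2.5)/0.76) plus Gaussian noise (default sd 0.5 COS
  units), clamped to the 0–12 scale.

Regeneration under the same seed is byte-identical. What the fixtures do
**not** emulate: real ΔΔG or conservation distributions, correlated
parameters (real indicators correlate; Bernoulli columns are
independent), the length and composition of real GLDC (1020 residues),
or the published per-mutation tables. Passing tests therefore demonstrate
that the machinery is correct — enumeration, mapping, scoring, training,
selection and prediction arithmetic — not that the package reproduces
per-mutation values of the real protein, which require the original
supplementary tables and sequences as inputs.

## Problem sizes and test design

The test suite runs entirely on generated data: toy cDNAs (2–60 codons)
against brute-force enumeration oracles, one 1020-codon cDNA for
throughput, random gapped alignments against a column-walk oracle,
500-replicate weight-recovery and 500-replicate slope-recovery Monte
Carlo runs at noise sd 0.5, and 200-replicate 3-SE coverage checks —
sizes chosen to exercise every code path and keep the full suite under a
minute on one CPU. Every non-trivial expected value is computed by an
independent oracle (hand-built codon table, naive string mutator,
normal-equations solve, textbook Welch and chi-square formulas, the
closed-form df-2 chi-square tail) and frozen in the tests.

## Known limitations

* ΔΔG, conservation grades and structural annotations are inputs; their
  quality bounds the scores.
* The registry's exact published composition is supplementary material;
  the shipped canonical registry instantiates the named categories with
  documented, configurable conditions and should be replaced by the
  original conditions where those are available.
* Weights are protein-specific: coefficients trained on one protein's
  clinical data do not transfer.
* The outcome model covers WMMS $[-0.87, 10]$ only, one genetic
  background, and a single scored postnatal phenotype (hydrocephalus);
  seizure/cognition domains and sex effects are out of scope.
* Double or compound mutations are unsupported by design (additive
  single-substitution model).
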