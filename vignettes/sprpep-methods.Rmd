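---
title: "Sequence-structure models of drug-resistance substitutions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-structure models of drug-resistance substitutions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprpep)
```

## The problem and the modeling idea

Missense variants in drug-target proteins — single amino-acid
substitutions (AAS) — are a dominant cause of acquired resistance to
targeted inhibitors, the canonical example being substitutions in the
ABL1 tyrosine kinase that abolish the response of chronic myeloid
leukemia to imatinib or dasatinib. Given a catalogue of substitutions
labeled resistant / non-resistant, the task is to predict the label of a
new substitution from sequence alone.

`sprpep` treats the problem chemographically rather than with
sequence-level features. Each substitution is represented by a short
peptide centered on the mutated residue, with the *alternate* residue
applied; that peptide is expanded into its full structural formula —
an explicit-hydrogen molecular graph — and described by substructure
descriptors. A Bayes-like scorer over those descriptors produces a
resistance score, calibrated into a pair of class-membership estimates
(`Pa`, `Pi`). The pipeline is therefore:

1. **windows** — substitution-centered mutant peptides of odd nominal
   length 3–31;
2. **molgraph** — peptide assembly from residue templates, SD file I/O
   (MOL V2000 read, V3000 read/write) with annotation tags;
3. **mna** — Multilevel Neighborhoods of Atoms descriptors, levels 0–15;
4. **spr** — the classifier: frequency counts, B-score, leave-one-out
   (LOO) calibration, prediction with an applicability-domain count;
5. **evaluation** — LOO / stratified k-fold AUC, confusion metrics,
   threshold scans, and the window-length x level grid search;
6. **synthetic** — a seeded generator of study-scale fixtures with a
   plantable context signal.

## Peptide windows

`extract_window()` cuts `(length - 1)/2` flanking residues on each side
of the substituted position and applies the alternate residue at the
center. Near a terminus the window is truncated asymmetrically, never
padded: padding would have to invent atoms, and invented atoms would
generate descriptors that no real peptide has. The true
`center_offset` and the nominal versus actual length are retained (and
written as SD tags) so truncation is always visible downstream. The
training instance is the mutant window only; the wild-type twin is not
added as a paired example. Sequences containing nonstandard residues
(U, O, X, ambiguity codes) are rejected outright — there is no
structural template for them, and silently dropping records would bias
class counts.

## From sequence to structural formula

Each residue template is a free neutral amino acid with every hydrogen
explicit; condensation removes the carboxyl OH of residue *i* and one
amine hydrogen of residue *i + 1* (one water per peptide bond) and adds
the amide bond. Termini stay free and neutral (NH2 / COOH). Conventions,
chosen once for determinism:

* **Protonation.** All ionizable groups are built neutral (Asp/Glu
  COOH, Lys NH2, Arg guanidine, His as the N&epsilon;2-H tautomer).
  Physiological charge states would be pH-dependent and would make
  descriptor generation non-deterministic across conventions; the
  charge-mark machinery still exists and is exercised by tests.
* **Bond orders** are stored for file fidelity (aromatic rings in
  Kekulé form) but never consulted by descriptor generation.
* **Stereochemistry** is not encoded anywhere; structures differing
  only stereochemically are equivalent by construction.
* **Cysteine** keeps a free thiol; windows are linear fragments, so no
  disulfides.

Ring membership is derived by bridge detection (igraph): an atom is
in a ring exactly when one of its incident edges is not a bridge. The
tests check this against an independent edge-removal reachability
oracle and against exhaustive expectations on all twenty templates.

SD records are written as MOL V3000 connection tables with all-zero
coordinates (these are connectivity-only structures) and the tags
`POSITION`, `GENE`, `REF_AA`, `ALT_AA`, `EFFECT`, `NOMINAL_LENGTH`,
`CENTER_OFFSET`. The reader also accepts V2000, fills implicit
hydrogens up to neutral valence, and can remap foreign tag names via
`tag_map` — third-party SD sets rarely share a tag vocabulary, and the
label tag of an external training file can simply be pointed at
`EFFECT`.

## MNA descriptors

The level-0 descriptor of an atom is its *mark*: `-` if the atom is not
in a ring, then the element symbol, then a charge suffix (`[+1]`,
`[-1]`, ...) only when the formal charge is non-zero. The level-k
descriptor is

```
mark( D1 D2 ... Dd )
```

where `Di` are the level-(k-1) descriptors of the immediate neighbors,
concatenated in byte-wise lexicographic order. Bond types never enter.
Two details are package conventions where the field's usage is loose:

* the charge suffix notation `[+n]`/`[-n]` (with neutral construction
  it never appears on standard inputs, but it is defined and tested);
* sorting is byte-wise on the descriptor strings (C locale), which
  fixes a total order — `-` sorts before letters.

A structure is represented by its **set of unique descriptors** at one
level; multiplicities are kept only for diagnostics. Descriptor
identity is plain string equality: correctness then rests on the
recursion, which the tests pin against a naive exponential
re-implementation on random graphs (levels 0–6) and against invariance
under random atom renumbering. The implementation is iterative and
reuses the level-(k-1) strings, so one sweep serves all levels of a
grid search.

One fidelity note: per-structure descriptor counts reported by the
reference implementation of this method appear to pool several levels
(they exceed the atom count of the peptide). `sprpep` keeps strict
single-level sets — the level is a model coordinate, not an
accumulation range. This is the cleaner definition and is applied
uniformly to training and query structures, but absolute descriptor
counts are not comparable with tools that pool levels.

## The classifier

With `N` training structures, `Nk` of them resistant, `Ni(D)`
containing descriptor `D` and `Nik(D)` both resistant and containing
`D`, the scorer uses plain frequency estimates `P(A) = Nk/N` and
`P(A|D) = Nik/Ni` — deliberately unsmoothed; `arcsin(+/-1)` is finite,
so extreme probabilities are admissible. For a query with `m`
descriptors known to the model:

```
S0 = 2 P(A) - 1
S  = sin( mean_i arcsin( 2 P(A|Di) - 1 ) )
B  = (S - S0) / (1 - S S0)
```

`B` is a hyperbolic-tangent-style contrast between evidence and prior:
0 when the query's descriptors carry no information beyond the prior,
+1/-1 at certainty. Numerical guards: `B = 0` when `S = S0` (within
floating-point equality) or when `m = 0`; the ratio is clamped to
[-1, 1]; the degenerate denominator `1 - S*S0 = 0` can only occur
together with `S = S0` and therefore also yields 0. Descriptors never
seen in training are *excluded* from the mean — they have no defined
conditional probability — and surfaced as `n_new_descriptors`, the
package's applicability-domain measure: the larger it is, the further
the query sits from the training chemistry, independent of how
confident `B` looks.

### Pa/Pi calibration

The reference method reports `Pa` and `Pi` as class-membership measures
interpretable as first/second-kind error probabilities, but its exact
calibration is unpublished. `sprpep` uses empirical mid-rank CDFs of
the leave-one-out B-scores:

```
Pa(B) = ( #{resistant LOO scores < B} + ties/2 ) / Nk
Pi(B) = ( #{non-resistant LOO scores > B} + ties/2 ) / (N - Nk)
```

This choice is monotone in `B` (so `Pa > Pi` is a proper crossing
rule), uses scores of held-out structures rather than resubstitution
scores (which would be optimistically shifted), and handles ties
half-weighted, consistently with the AUC. It is the package's main
fidelity risk against the reference tool: identical count tables will
give identical B rankings but not necessarily identical Pa values.
Ranking-based results (AUC, threshold-scan shapes) are robust to this;
absolute Pa cut-offs are convention-dependent.

The LOO scores come from count decrement/restore — remove the
structure's contribution from `N`, `Nk`, `Ni`, `Nik`, score it, put the
counts back — which the tests verify is *exactly* equal to refitting
from scratch per held-out structure. A descriptor whose `Ni` drops to
zero under exclusion is treated as unseen for that query, which is what
a genuine refit would do.

## Evaluation conventions

* **AUC** is the Mann–Whitney pair statistic (ties half), computed from
  average ranks and checked against pair enumeration. Ranking uses the
  raw B-score: under the mid-rank calibration `Pa - Pi` is a monotone
  function of `B`, so the AUC is independent of the calibration
  convention.
* **k-fold CV** (default k = 20) stratifies by class with a seeded
  shuffle, distributes remainders round-robin, refits per fold and
  pools all held-out scores into one AUC. With `k = N` it reduces
  exactly to LOO, which is tested. No fold protocol is canonical for
  this method; seeding makes ours reproducible.
* **The grid search** scans odd window lengths 3–31 against levels
  1–15 and ranks cells by the arithmetic mean of per-endpoint LOO AUCs,
  ties broken toward smaller level, then smaller length (prefer the
  cheaper model when indistinguishable).
* **Threshold scans** report the default `Pa > Pi` rule plus fixed Pa
  cut-offs 0.3–0.9; `confusion_metrics()` computes sensitivity,
  specificity and balanced accuracy. The scan tolerates single-class
  inputs (NA metrics) while `confusion_metrics()` itself is strict.

## The synthetic generator

`simulate_resistance_data()` emulates the *shape* of the real training
resource: one kinase-sized protein (default 1130 residues, uniform
residue composition), 660 substitutions at distinct positions, a small
positive class (expected 84/660 ≈ 12.7%), and a learnable
sequence-context signal — a motif residue (default tryptophan) within
`motif_radius = 2` positions of the substitution raises the resistance
probability to `signal_strength`, a baseline rate applies elsewhere.
The signal is contextual by design: residue identity near the center is
exactly what window descriptors can encode, so recovery of the planted
window length and a high LOO AUC are meaningful end-to-end checks.

Parameter rationale, fixed once:

* Under uniform composition the motif context prevalence is
  `q = 1 - (19/20)^4 ≈ 0.185` for radius 2. The strongest coupling
  compatible with the 84/660 prevalence is `signal_strength ≈ 0.687`
  (`q x s <= 84/660`); the default 0.68 sits just inside it, leaving a
  baseline rate of ~0.0014. Feasibility is evaluated against the
  theoretical `q`, not the realized sample, so the expected positive
  fraction is met in expectation and infeasible requests fail
  deterministically.
* In motif mode the alternate residue is drawn from the non-reference
  residues *excluding* the motif residues. Otherwise roughly 5% of
  records would receive the motif at the mutated center by chance,
  uncorrelated with the label, diluting the planted signal with an
  artifact of the generator rather than a property of the science.
* Uniform composition keeps the null distribution simple;
  `composition = "natural"` exists for realism but is not the default.

What the generator does **not** emulate: mutational hotspots and
position clustering, class labels driven by 3D energetics, homologous
or duplicated sequence context, and multiple endpoints with correlated
labels. A high AUC on synthetic data therefore demonstrates that the
pipeline recovers a context signal it is able to represent — not that
real resistance is this easy.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated
data: the study-scale checks use 660 substitutions at window length 5
and level 2 (seconds per LOO fit), the grid-recovery checks use 200
substitutions over five lengths, and oracle comparisons use graphs of
4–9 atoms at levels 0–6 — sizes chosen so the whole suite exercises
every code path in a few minutes while keeping the statistical checks
well-powered. Every stochastic step (protein, positions, labels, fold
assignment, permutation nulls) flows from explicit integer seeds;
rerunning any pipeline with the same seed is bit-identical, which is
itself a tested invariant.

## Known limitations

* The Pa/Pi calibration is a reconstruction (see above); absolute Pa
  values are not comparable with the reference implementation.
* Single-level descriptor sets (see the fidelity note): per-structure
  descriptor counts are smaller than tools that pool levels 1..k.
* Neutral protonation is a convention, not a claim about solution
  chemistry; models trained on files with other protonation conventions
  should be rebuilt from sequence rather than mixed.
* Descriptor strings grow roughly geometrically with level; levels
  beyond ~8 on 31-mers are computable but slow and rarely informative,
  since the neighborhood then spans most of the peptide.
* Truncated terminal windows keep their true center but have fewer
  atoms; their descriptors differ systematically from interior windows.
  This is intended (free termini are real chemistry) but means models
  should be trained and queried at the same nominal length.
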