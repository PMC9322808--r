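---
title: "Learned chemical binding similarity: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned chemical binding similarity: model, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecbscreen)
```

## The model

ECBS (evolutionary chemical binding similarity) reframes ligand-based
virtual screening as *pair classification*. Instead of asking "how similar
is library compound $x$ to reference ligand $r$?" with a fixed metric, it
asks "how likely is it that $(x, r)$ is the kind of pair whose members
bind the same or evolutionarily related targets?" and learns that
likelihood from labelled pairs.

The pieces, in the order the pipeline runs them:

**Homology graph.** Targets are nodes; an undirected edge joins two
targets whose fractional sequence identity meets a threshold $\tau$
(default 0.4). "Evolutionarily related to $t$" means $\{t\} \cup
\mathcal{N}(t)$ — the target itself (the *identical* clause) plus its
direct neighbours. One hop, not transitive closure: the phrase "a target
and its homologous proteins" reads as direct homologs of the focal
target, and transitive closure across a dense family would quietly pool
ligands of proteins with no detectable similarity to the focal target. A
`transitive = TRUE` flag exists for users who disagree.

**ERCP enumeration.** For focal target $t$, the ligand universe $U$ is
every compound with an active record against a target in
$\{t\} \cup \mathcal{N}(t)$. Positives are all $\binom{|U|}{2}$ unordered
pairs within $U$. Negatives pair $u \in U$ with a compound $d \notin U$
such that no target of $d$ is related to any target of $u$ — a compound
whose activity profile gives no reason to expect shared binding.
Negatives are sampled uniformly without replacement to
$\mathrm{round}(\rho \cdot |positives|)$ with $\rho = 1$ by default, under
a mandatory seed: the negative sample is part of the model definition, so
it must be reproducible.

**Pair featurization.** For fingerprints $a, b \in \{0,1\}^L$ the feature
vector is $[\,a \wedge b,\; a \oplus b,\; T(a,b),\; \min(|a|,|b|),\;
\max(|a|,|b|),\; |a \wedge b|\,]$, length $2L + 4$. Every block is
invariant under argument swap, which is what makes the emitted score
symmetric *by construction* rather than by averaging two asymmetric
evaluations. (A scalar block of raw $|a|, |b|$ would break this — swapping
arguments would permute the two features — hence min/max.)

**Ensemble classifier.** The default learner is penalized logistic
regression (`glmnet`, ridge by default, predictions taken at
$\lambda = 0.01$), wrapped in a bootstrap ensemble of $B = 10$ members;
the ECBS score is the mean positive-class probability, so it lives in
$[0,1]$ with no extra calibration map. The contract is only "probabilistic
binary classifier": logistic regression on the AND/XOR expansion is
linear in *pairwise bit interactions*, which is exactly the signal a
shared substructure plants, and it is fast, deterministic, and available
in the offline stack. Gradient boosting or random forests could be
substituted behind the same `ecbs_training_config()` surface without
touching any caller.

**Held-out evaluation.** `train_ecbs_model()` reports `cv_auroc` from a
*compound-disjoint* split: a fraction (default 0.25) of compounds is set
aside, test pairs are pairs with **both** members held out, and pairs
straddling the split are discarded. Random pair-level splits look better
and are wrong: the same molecule appearing on both sides lets the model
recognize the molecule rather than generalize the relation.

**Screening and aggregation.** Every library compound is scored against
every reference ligand and assigned the **maximum** pairwise score as its
final binding score, with the arg-max reference recorded (ties to the
lexicographically smallest reference id). Max aggregation is the standard
similarity-ensemble choice: one genuinely analogous reference ligand is
sufficient evidence, and averaging would dilute it with irrelevant
references. Ranks are a strict permutation — ties broken by ascending
compound id — so downstream `top_k` stages are unambiguous.

**Funnel.** Ordered stages narrow the ranked list: `score_cutoff`,
`top_k`, `keep_list`. The keep-list stage deliberately models expert
manual selection as *externally supplied input*: a screening tool should
record that a human intervened, not simulate the intervention.

## Tunable parameters

| parameter | default | units / range | why this default |
|---|---|---|---|
| fingerprint radius | 2 | bond steps | ECFP4-equivalent, the de-facto standard for binding-similarity work |
| fingerprint length $L$ | 2048 (chemistry), 512 (synthetic worlds) | bits | 2048 is conventional; 512 keeps simulated suites fast with negligible collision effect at simulated densities |
| identity threshold $\tau$ | 0.4 | fraction | conventional "clear homology" heuristic; no value is prescribed by the method itself |
| negative ratio $\rho$ | 1.0 | negatives/positive | balanced classes; probabilities stay roughly calibrated |
| ensemble size $B$ | 10 | members | variance reduction plateaus quickly for bagged linear models |
| ridge $\lambda$ | 0.01 | — | mild shrinkage; large enough for stability on a few hundred pairs, small enough not to flatten separable signal |
| test fraction | 0.25 | of compounds | enough test pairs to estimate AUROC without starving training on small ligand sets |

## What the synthetic generator emulates — and what it does not

`generate_world()` builds target families with block-structured pairwise
identity (within-family 0.6, across 0.1), plants a disjoint random bit
motif per family, and generates actives as `motif bits (each kept with
probability motif_strength) ∪ background bits (density 0.05)`; decoys are
background-only. This emulates the *logical* structure of a screening
benchmark: shared substructures among ligands of homologous targets,
chemically unrelated decoys, tunable signal strength. Deliberately not
emulated: realistic physicochemical property distributions,
property-matched decoys (DUD-E style), activity cliffs, assay noise, or
correlated fingerprint bits from real substructure hashing. A green test
therefore establishes that the machinery recovers planted signal under
its own assumptions — not that it would achieve any particular enrichment
on a real campaign. The `smiles_mode = "fragment"` variant swaps planted
bits for actual scaffold fragments parsed and fingerprinted by RDKit
(compounds are dot-disconnected fragment unions), so the CLI path is
tested end to end on real chemistry, at the cost of a coarser notion of
motif.

**Evaluation holdout.** `screen_synthetic_world()` holds out half of every
target's ligands and half of the decoys *before* training; only held-out
compounds are screened. This matters: a compound that participated in any
training pair is recognized by a memorizing classifier, and in early
development the no-signal world scored AUROC ≈ 0.8 through exactly that
leak. With the holdout, `motif_strength = 0` worlds sit at AUROC ≈ 0.5 as
they must.

## Numerical and degenerate-input choices

- Tanimoto of two all-zero fingerprints is defined as 0 (avoids 0/0; two
  featureless molecules carry no evidence of similarity).
- All-gap global alignments (no aligned positions) get identity 0;
  alignment identity is matches / alignment length (PID1) under BLOSUM62
  with gap open 10 / extend 0.5.
- Bootstrap resamples are redrawn (up to 100 times) until both classes
  have ≥ 2 members; the full training set is the final fallback. Training
  aborts if the input pairs are single-label; it falls back to training
  on all pairs (with a warning, `cv_auroc = NA`) only when the
  compound-disjoint *split* leaves fewer than 2 pairs of a label.
- Invalid SMILES in a library are skipped with a warning naming line
  numbers (a 10^5-compound screen should not die on one bad record);
  invalid reference ligands abort, because one corrupt reference poisons
  every max-aggregated score.
- Scores are written at 6 decimals; result files are written in binary
  mode so they are byte-identical across runs and platforms for fixed
  inputs.
- Seeds: every stochastic step (negative sampling, holdout split,
  bootstrap) runs under a locally scoped RNG that restores the caller's
  `.Random.seed`, so library calls never perturb user code.

## Design decisions that were genuinely open

- **Chemistry backend.** No maintained R implementation of circular
  fingerprints exists in this stack, so ingestion and fingerprinting
  delegate to RDKit through a small `python` bridge
  (`inst/python/rdkit_bridge.py`). Everything downstream — pair logic,
  learning, screening, metrics — is pure R, and placeholder-mode synthetic
  worlds never invoke the bridge.
- **Learner choice.** The original method family uses tree ensembles; the
  contract here is only a probabilistic pair classifier, and bagged ridge
  logistic regression on the interaction expansion meets it with exact
  determinism and no extra dependency. This is a declared substitution,
  not a reconstruction.
- **Negative eligibility.** "Shares no related target" is evaluated
  against *all* targets of each universe compound, not only the focal
  set, so a promiscuous ligand cannot appear as its own negative.
- **CLI `train` takes `--compounds`.** Training needs structures for
  every paired compound (homolog ligands and negatives), which references
  + library files do not guarantee; an explicit structure file was the
  honest interface.

## Known limitations

- Pairwise alignment identity is computed with a single fixed scoring
  scheme; users with rigorous homology needs should supply a precomputed
  identity table (the interface exists for exactly that reason).
- The featurization doubles fingerprint length; at $L = 2048$ and
  $10^5$-compound libraries the score matrix is computed in one pass and
  memory-heavy — chunked scoring would be the first scaling improvement.
- Fragment-mode synthetic compounds are disconnected fragment unions:
  valid, parseable, and motif-bearing, but not drug-like molecules.
- Model archives are R RDS files: portable across this package's
  versions only as far as the stored `glmnet` objects are.
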