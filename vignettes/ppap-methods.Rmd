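---
title: "Predicting plant type III PKS reaction types: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant type III PKS reaction types: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ppap)
```

## The problem

Plant type III polyketide synthases (PKSs) are a paralogous enzyme family:
duplicated genes have repeatedly and independently acquired similar
catalytic functions, so overall sequence similarity — homology searches,
phylogenetic placement — is a poor predictor of what reaction a given
paralog performs. A reaction type is written as a hyphen-joined triplet
`starter-extension-cyclization`: `R-4-C` is a chalcone-synthase-like enzyme
(ring starter, four keto groups, Claisen cyclization), `R-4-A` a
stilbene-synthase-like enzyme (aldol cyclization), `R-2-X` a
diketide-forming enzyme without cyclization. Everything else — lactonizing,
short-chain and long-chain starter enzymes — is grouped as `other`.

This package classifies a query protein into one of those four groups by
combining two complementary similarity measures and a cascade of linear
discriminants.

## The model

### Area profiles

Four short segments ("Areas 1–4"), identified from 3D-structural differences
between Claisen- and aldol-cyclizing enzymes, carry most of the
discriminative signal. For each target reaction type, the package extracts
the Area columns from that type's family alignment (anchored on a reference
sequence's residue numbering), concatenates a chosen combination — the
default is Area 1 + 3 + 4, the combination with the clearest separation;
Area 2 is excluded because aldol-cyclizing enzymes often share the
`TTSGVDM` Area-2 motif with chalcone synthases — and builds a profile from
the segment alignment. A query aligned into the family is scored by the
profile; scores below zero, or "no match", are clamped to zero before any
further use.

Two profile backends sit behind one interface. The default (`"pssm"`) is a
position-specific score model: Laplace-smoothed match-state emission
probabilities over the 20 standard residues, scored as summed log-odds
against a uniform background, with no insert/delete states. It is pure R,
deterministic and has no external dependencies. The `"hmmer"` backend
drives HMMER 3 (`hmmbuild`/`hmmsearch`) when the engine is installed and
uses its bit scores; both backends obey the same clamping rule.

### Correlated mutation analysis

Compensatory mutations leave a statistical trace: pairs of alignment
columns whose residues co-vary. For each family alignment (terminal and
>80%-gapped internal columns removed) the package computes mutual
information between every pair of columns,

$$MI(i,j) = \sum_{X}\sum_{Y} p_{ij}(X,Y)\,
  \log\frac{p_{ij}(X,Y)}{p_i(X)\,p_j(Y)},$$

over the symbols observed at each column (the gap counts as a symbol),
subtracts the average product correction
$APC(i,j) = \overline{MI(i,\cdot)}\,\overline{MI(j,\cdot)}/\overline{MI}$
to remove shared background and phylogenetic signal ($MIp = MI - APC$),
standardizes $MIp$ over all pairs (population SD), and keeps pairs with
$Z > 3$.

The logarithm base is the natural log throughout. The base is never stated
in the defining formulas and cancels in the Z-score selection; it does
affect the absolute scale of the correlation score below, which is why it
is fixed and documented here.

### Correlation score

Each reaction type gets a correlation model: residue frequencies $p_i(X)$
at every filtered column and pair frequencies $p_{ij}(X,Y)$ at every
selected pair, tabulated from the family alignment and smoothed additively.
A query aligned into the family scores

$$S_{cor} = \frac{1}{C} \sum_{(i,j) \in A}
  \log\frac{p_{ij}(X_q, Y_q)}{p_i(X_q)\,p_j(Y_q)},$$

where $A$ is the selected pair set and $C = |A|$ normalizes models with
different pair counts. Smoothing uses a 21-symbol alphabet (20 residues +
gap), $\alpha = 1/21$ for single frequencies and
$\beta = \alpha^2/(N + 2\alpha d_s)$ for pairs, with $N$ the number of
training sequences and $d_s = 21$. That particular $\beta$ makes a
never-observed pair of never-observed residues satisfy
$p_{ij}/(p_i p_j) = 1$ exactly, so unknown residues contribute nothing to
the score rather than penalizing the query; the identity holds to machine
precision for all $N$ and is asserted in the test suite. An `X` (unknown
residue) in a query is treated as never-observed for the same reason.

### The classifier cascade

A query's six features are the three clamped profile scores and the three
correlation scores against the R-4-A, R-4-C and R-2-X models. Features are
standardized with the training means and SDs, and three binary Fisher
discriminants ("target vs rest", pooled within-class covariance, decision
boundary midway between projected class means shifted by the log prior
ratio, priors proportional to class sizes) are applied in the fixed order
R-4-A → R-4-C → R-2-X. The first "yes" fixes the label; all-"no" means
`other`. All three binary outcomes are always recorded, and a prediction
notes when more than one classifier fired (the cascade order then
arbitrates; the order follows the convention used throughout the original
analysis, and ties are a measure-zero event with real scores).

Long-chain-starter sequences (`L-*`/`Lh-*`) are deliberately excluded from
discriminant fitting but still evaluated — a correct pipeline classifies
them as `other` without ever training on them. Sequences are assigned to
binary classes by their group label, with `R-2d-X` folded into `R-2-X`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `area_combo` | `Area1+Area3+Area4` | segments concatenated for profiles |
| `z_threshold` | 3.0 | MIp Z cutoff for pair selection (dimensionless) |
| `gap_fraction` | 0.8 | max column gap fraction kept for CMA |
| `backend` | `"pssm"` | profile engine (`"hmmer"` optional) |
| `align_method` | `"builtin"` | query-to-alignment adapter |
| `alpha` | 1/21 | single-residue pseudocount weight (fixed) |
| `beta` | derived | pair pseudocount; see identity above |

The defaults 3.0, 0.8 and Area 1 + 3 + 4 are the published operating point
of the method and are not meant to be tuned per dataset.

## Numerical and design choices

* **Coordinates.** All column and residue indices are 1-based, matching R
  convention; area maps are 1-based inclusive residue ranges on the
  ungapped reference.
* **Terminal trimming.** The original data preparation removed terminal
  gapped positions "manually". The deterministic stand-in here drops
  leading/trailing columns until the first column whose gap fraction is at
  or below `gap_fraction`, then applies the internal threshold.
* **Query addition.** The preferred adapter is `mafft --add` (with
  `--keeplength`, so model columns survive). The builtin fallback is a
  profile-to-sequence global alignment with affine gaps (BLOSUM62, open 11,
  extend 1) implemented in C++; it maps the query onto existing columns and
  drops query residues that would need new columns, reporting how many.
  Both routes leave the stored model columns valid — this "column
  reconciliation" rule is the package's own decision where the original
  description is silent, and it is tested by round-tripping training
  sequences.
* **Ties and degenerate inputs.** Best-profile ties break by the fixed
  label order with a warning; all-zero profile scores return an explicit
  `UNCLASSIFIED` sentinel; a singular pooled covariance in the discriminant
  falls back to a small ridge ($\lambda = 10^{-6}\,\mathrm{tr}(S)/p$) with
  a warning; constant-MIp inputs are an error rather than a silent zero
  division.
* **Leave-one-out discipline.** In every cross-validation fold, all
  artifacts whose training set the held-out sequence could have touched —
  its family's alignment, profile, column filter, pair selection
  (re-thresholded on the reduced alignment) and correlation model, plus the
  standardizer and all three discriminants — are rebuilt without it.
  Models of the other families are reused unchanged, which is identical to
  a full rebuild because the held-out sequence was never among their
  inputs; a per-fold audit asserts this from recorded training ids and
  provenance hashes.

## The synthetic benchmark

The original training data are curated database sequences; to keep every
stage testable without downloads, the package generates synthetic
paralogous families that emulate the structure the method exploits:

* five families (R-4-A-, R-4-C-, R-2-X-like and two `other` families) of
  20 sequences on a 120-residue scaffold;
* all families descend from one ancestral scaffold — each family consensus
  keeps an ancestral residue with probability 0.7, and each sequence keeps
  its family consensus with probability 0.85. These rates were chosen once
  to mimic the inter-family (~50–70%) and within-family identity of real
  paralog families, and make cross-family query alignment meaningful;
* family-specific Area motifs at conservation 0.9. The R-4-C-like family
  carries the canonical `TTSGVDM` (Area 2) and `LKDVPG` (Area 4) motifs;
  the R-4-A-like family shares `TTSGVDM` (which is why Area 2 is excluded
  from the default combination); the R-2-X-like family's Area 1 is only
  modestly conserved (0.6) and resembles the R-4-C residues — mirroring
  the conservation pattern of the real families;
* ten planted covarying column pairs per family, each drawn from a joint
  distribution concentrated on four residue combinations (MI = ln 4 ≈ 1.39
  nats). Four combinations rather than two is a deliberate calibration:
  across the ~5000 candidate pairs of a 100-column alignment, the
  finite-sample MIp null at n = 50 leaves a handful of background pairs
  above Z = 3, and the planted couplings must stand clearly above that
  tail for selection to be both sensitive and precise;
* deletions at rate 0.01 per background column, only outside Areas and
  planted pairs, so truth alignments stay exact. Insertion events are not
  simulated; deletions already force the query aligner to do real work.

What passing tests on this benchmark show — and what they do not: the
synthetic families have exact alignments, independent sequences (no
phylogenetic correlation), and cleanly planted signal, so results here
demonstrate the correctness and internal consistency of every stage, not
the accuracy the method would reach on real, tree-correlated families with
alignment uncertainty.

```{r benchmark, eval = FALSE}
bench <- generate_benchmark(seed = 42)
fit <- ppap_fit(bench$sequences, bench$alignments, bench$map,
                reference = bench$reference)
report <- loocv(bench$sequences, bench$alignments, bench$map,
                bench$reference)
tidy(report)
autoplot(report)
```

## Problem sizes and validation harnesses

Leave-one-out cross-validation rebuilds models for 100 folds on the default
benchmark; repeated random sub-sampling draws, per reaction type and
repetition, `ceiling(n/2)` training sequences (the decimal is rounded up,
so 13 sequences give 7 train / 6 test), with 10 repetitions and a single
master seed from which per-repetition streams are derived. Pair-recovery
properties are measured on families of 50 sequences over 100 columns with
10 planted pairs, averaged over 10 seeds. These sizes are the package's
default study conditions; they run comfortably on a single CPU.

## Known limitations

* Sequences are simulated independently; there is no tree-based evolution,
  so the APC correction faces a milder null here than on real families.
* The exact Area 1–4 residue ranges on the *M. sativa* CHS2 reference are
  defined in the structural literature; the shipped
  `area_map_chs2_reconstructed.json` is a reconstructed approximation and
  must be verified against that literature before use on real sequences
  (synthetic benchmarks use their own map).
* Lactonizing types that differ from a main type by a handful of residues
  are intrinsically hard for this feature set, and multifunctional enzymes
  are assigned their main reaction type only.
* The builtin query aligner is gapless with respect to new columns; a
  query with a genuine insertion relative to the family loses those
  residues from scoring (with a message). Use the `mafft` adapter when
  insertions matter.
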