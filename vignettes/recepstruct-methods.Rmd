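---
title: "Methods: geometric features and regression workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric features and regression workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recepstruct)
```

This vignette documents the model behind `recepstruct`: what each geometric
feature measures and under which assumptions, the statistical workflow and
its numerical choices, what the synthetic generators emulate (and what they
deliberately do not), and the design decisions taken where more than one
defensible convention exists.

## The measurement model

The package operates on *predicted* structures of two kinds: an
ectodomain–ligand complex (two or four receptor chains plus ligand chains)
and a transmembrane-domain (TMD) dimer emitted by a TM-packing predictor in
its membrane frame (membrane normal along Z). Six features are measured per
receptor design.

### Secondary-structure anchoring of the ECD distance

The ECD distance anchors not on the chain terminus — predicted ectodomain
models typically end in disordered tails whose coordinates are unreliable —
but on the *last residue inside a secondary-structure element*. Element
membership is assigned by a hydrogen-bond-pattern method in the
Kabsch–Sander tradition:

- the amide hydrogen (absent from most predicted models) is placed 1.01 Å
  from N along the bisector of the N→C(prev) and N→CA directions;
- a hydrogen bond between the CO of residue *i* and the NH of residue *j*
  exists when the electrostatic energy
  `0.084 · 332 · (1/d(ON) + 1/d(CH) − 1/d(OH) − 1/d(CN))` falls below a
  threshold (default −0.5 kcal/mol, configurable via `energy_threshold`);
- helix (H) arises from consecutive i→i+4 turns (i→i+3 and i→i+5 accepted
  equivalently, which absorbs 3₁₀/π termini), strand (E) from parallel or
  antiparallel bridge patterns, everything else is coil (C); H wins on
  overlap.

Both branches were validated during development against an independent DSSP
implementation on constructed fixtures: a 20-residue ideal helix (interior
labeled H by both) and a two-strand antiparallel sheet (central residues E
by both). Because assigners can disagree within one or two residues at
element termini, a terminal-residue choice — and hence the ECD distance —
can shift by a few Å relative to a viewer's cartoon assignment; the
1 Å-scale agreement seen on idealized fixtures should not be over-read for
real predicted models. A chain with *no* structured residue raises an
error; silently falling back to the terminus would measure a different
quantity.

### Contacts

A contact is an unordered inter-chain atom pair with van der Waals overlap
`r_i + r_j − d_ij ≥ overlap_cutoff`. Two readings of the upstream
convention exist; the package defaults to the viewer-default reading
`overlap_cutoff = −0.40` Å (atoms up to 0.4 Å apart beyond their radii sum
still count) and exposes the strict `+0.40` reading through
`contact_params()`. Radii default to C 1.70, N 1.55, O 1.52, S 1.80, P
1.80, H 1.20, fallback 1.70 Å and are user-overridable
(`vdw_radius_table()`); hydrogens participate exactly when present in the
file. Pairs four or fewer covalent bonds apart are excluded; since bonds
are only ever inferred within a chain (sum of single-bond covalent radii +
0.4 Å), this exclusion is vacuous for inter-chain contacts but is enforced
so the contract holds on any input. Ligand chains never enter the count.

### TMD angles

The *crossing angle* is the angle between the two helix axes — each the
principal direction of 4-residue sliding-window-averaged Cα positions,
oriented N→C — folded to [0°, 90°], with sign given by the handedness of
the packing: `sign((u₁ × u₂) · w)` where `w` connects the axis centroids.
This is chain-swap invariant, and the synthetic dimer generator is
calibrated to it (constructed +40° is recovered as +40° ± 2°). The exact
sign convention of the upstream TM predictor is not published; ours is
documented and construction-validated instead.

The *exit angle* is the angle in [0°, 180°] between the XY-plane
projections of the final-residue Cα→C vectors of the two chains, from the
arccosine of the normalized dot product (clamped to [−1, 1]). It is
deliberately frame-dependent: it only means something in the membrane frame
the TM predictor emits. Re-oriented structures give incomparable values; a
full-3D variant (`project = FALSE`) exists but is labeled non-standard. A
projected vector shorter than 1e−6 Å (a Cα→C bond pointing along the
membrane normal) is a degenerate-geometry error rather than a number.

### Averaging rules

TM dimer predictions depend on sequence input order, so heterodimeric TMD
pairs are modeled in both orders and the four TMD features are element-wise
arithmetic means (contact counts may therefore be non-integral).
Heterotetrameric ECD complexes (two α and two β receptor chains around a
dimeric ligand) use the perfect α–β matching minimizing the summed terminal
distance — an exhaustive choice between the two possible matchings — and
report the mean of the two matched pairs' features.

## The regression workflow

For a family of designs with features `X` and performance `y` (on-state
signal or fold induction):

1. **Transform**: reporter-scale signals are right-skewed; `log_dv = TRUE`
   applies log10. The base is a convention only — R², p-values, and the
   selected feature set are provably invariant to it, and the test suite
   asserts this.
2. **Standardize**: columns to mean 0, *sample* sd 1 (denominator n−1; the
   source convention is unstated, the choice is configurable in effect via
   pre-scaled input and is inference-neutral).
3. **Fit**: OLS with intercept via SVD pseudo-inverse. Rank-deficient
   designs — guaranteed when a full one-hot encoding (no dropped reference
   level) meets an intercept — receive the minimum-norm solution with
   residual df `n − rank` and a recorded `rank_deficient` flag, mirroring
   what permissive OLS software does silently. Inference is Student-t:
   two-sided p-values and 95% CIs on the residual df.
4. **Reduce**: first the collinearity screen — while any `VIF ≥ 10`
   (`VIF_j = 1/(1 − R²_j)`, feature j on all others), remove the largest
   (ties: the later column in declared order, a deterministic convention);
   then backward elimination — refit and remove the largest-p feature
   while `p ≥ α = 0.05` (same tie-break). The intercept is never removed;
   eliminating everything yields an intercept-only fit with a flag rather
   than an error. Categorical models skip the VIF phase by default
   (`categorical_vif = TRUE` restores it), matching the workflow this
   package re-implements, where VIF screening is described for structural
   features only.
5. **Combine**: optionally refit on the union of the reduced structural
   and reduced categorical feature sets.

Every removal is recorded (feature, criterion, value) in a trace; the JSON
report embeds the configuration snapshot, and identical inputs and
configuration produce byte-identical reports — there is no randomness
anywhere in this module.

## One-hot encoding of design identity

Categorical features encode *which* domain sits on *which* chain role: one
binary column per (role × ECD level) and (role × TMD level), plus ligand
columns only when the family spans more than one ligand. All levels are
kept — no reference level is dropped — so each factor's columns sum to 1
per row. This reproduces the column counts of the families it models
(12 for a 2-ECD/3-TMD/2-ligand family, 13 with three ligands, 10 with one)
at the cost of deliberate rank deficiency, handled as above.

## What the synthetic generators emulate

`ideal_helix()` builds backbone-only poly-Ala helices from standard
internal coordinates (φ = −57°, ψ = −47°, textbook bond geometry), then
re-parameterizes to the rise/twist/radius lattice (defaults 1.5 Å, 100°,
2.3 Å). The defaults reproduce canonical α-helix geometry closely enough
that the hydrogen-bond assigner labels the interior H — which is the point:
fixtures must exercise the same code paths as real models.

`make_tmd_dimer()` poses two helices at a chosen axis separation, crossing
angle, and phase in the membrane frame; `make_ecd_complex()` numerically
solves (by 1-D root finding over the axis separation, with the z-offset
determined by the terminal-distance constraint) for a pose meeting a target
terminal Cα distance within 0.1 Å *and* a target closest-approach gap.
Infeasible combinations — a terminal distance too short for the requested
gap, or so long that the chains no longer overlap — raise errors rather
than approximating. Wide-separation fixtures therefore use longer chains.

Because the helices carry no side chains, inter-chain vdW contacts vanish
beyond ~7.5 Å axis separation — real TM dimers pack near 9–10 Å via side
chains. The synthetic family generator (`demo_dataset()`) consequently
places its dimers at 5.5–7.5 Å so that contact counts vary; this is a
stated property of the synthetic world, chosen once, not a tuning knob.

`simulate_performance()` draws `y = β₀ + Zβ + ε` with Gaussian ε on the
log10 scale and exponentiates (`10^y`) to produce the right-skewed signal
distributions typical of reporter data; log-transforming recovers the
linear model exactly. Every generator is a pure function of its parameters
and seed.

**What a green test establishes — and does not.** The synthetic structures
are idealized: no side chains, no loops, no prediction noise, no
disordered tails, exact membrane frames. Green tests establish that the
measurement and selection machinery is correct on geometry whose ground
truth is known by construction, and that the workflow recovers planted
coefficient supports at realistic n (32) and signal-to-noise. They do not
establish that predicted structures of real receptors are accurate, nor
that the specific published reproduction values would be met — those
require the original structure archives and empirical performance tables,
which are external inputs.

## Numerical choices and degenerate inputs

- PDB parsing is fixed-column (wwPDB v3.3); only MODEL 1 is read; altloc
  keeps the highest-occupancy conformer, ties to file order; coordinates
  are written with three decimals, so round trips are exact to 1e−3 Å.
- Bond inference: sum of single-bond covalent radii + 0.4 Å; isolated
  atoms are degree-0 nodes, never errors; inter-chain bond distance is ∞.
- `acos` arguments are clamped to [−1, 1] before every angle.
- VIF under perfect collinearity reports +∞ (not an exception); the
  reduction loop stops at one remaining feature.
- Chains with fewer than 3 complete-backbone residues are assigned all-C
  with a warning, not an error; residues with incomplete backbones are
  coil and excluded from the hydrogen-bond search.
- `n ≤ k + 1` raises an insufficient-df error unless `force = TRUE`, which
  returns coefficients without inference.

## Known limitations

- The secondary-structure assigner is a three-state simplification;
  single-residue bridges are labeled E, and assigner disagreement near
  element termini propagates into the ECD distance (typically 1–2 residues,
  up to a few Å).
- The exit angle inherits the TM predictor's frame; there is no in-package
  membrane-frame detection for arbitrarily oriented structures.
- Contact counts depend on the radius table and on whether the input model
  carries hydrogens; both are configurable, neither is canonicalized.
- The regression workflow is deliberately plain OLS with stepwise
  reduction — interpretable, but subject to the usual selection
  instabilities at small n; the traces exist so that any reported model
  can be audited step by step.
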