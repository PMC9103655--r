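---
title: "Multi-fingerprint consensus target fishing and bioactivity profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-fingerprint consensus target fishing and bioactivity profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligfish)
```

## The model

`ligfish` answers two questions about a query small molecule by reverse
ligand-based screening against a curated activity library: *which protein
targets might it bind* (target fishing) and *how potently* (bioactivity
profiling). Both rest on one assumption — the similarity principle: a
molecule that closely resembles the known actives of a target is likely
to share their activity. Everything downstream is a careful aggregation
of 2D fingerprint similarities; there is no docking, no learned model,
and the package makes no claim for query chemotypes absent from the
library (see Limitations).

### The fingerprint panel

Each molecule is encoded as 13 binary fingerprints. Using many unrelated
fingerprint families, rather than one, makes the consensus robust: a
spurious high similarity in one hashed space rarely survives twelve
others. The panel mixes four families:

* **structural keys** — `pubchem` (count-threshold keys over element,
  ring, bond-order and branching counts), `klekota_roth` (a curated
  SMARTS key set of functional groups and rings), `pattern` and
  `substructure` (OpenBabel FP4/FP3 SMARTS sets), `cdk_maccs` (MACCS);
* **hashed linear paths** — `fp2` (OpenBabel FP2), `rdkit7` (paths up to
  7 atoms with bond orders), `graph` (paths up to 6 atoms, bond orders
  ignored), `hybridization` (paths with sp/sp2/sp3 atom invariants);
* **circular environments** — `mfp1`, `featmfp1` (OpenBabel ECFP2/ECFP4);
* **pairs and torsions** — `ap_bits` (ChemmineR atom pairs), `tt_bits`
  (hashed 4-atom torsions with element/degree/pi invariants).

Kinds without a native generator in the installed toolkits are computed
by the package directly from the kekulized heavy-atom graph; each slot is
an independent, documented 2D fingerprint, and the panel's bit patterns
are frozen by golden-file tests. Bit lengths range from 48 (the SMARTS
key set) to 4096 (circular); lengths, parameters and backends are all in
`default_fingerprint_config()` and are recorded in every saved library
bundle, so a bundle can never be scored with a mismatched panel.

Similarity within a kind is the Tanimoto coefficient
$T(A,B) = |A \wedge B| / |A \vee B|$, computed on packed bit vectors with
a popcount table (the set-based brute force survives as the test oracle).
Two all-zero fingerprints score 0, not 1: a featureless pair must not
fabricate evidence. Stereochemistry is retained in the canonical SMILES
identity but the panel is strictly 2D, so stereoisomers score alike —
documented behaviour, not an accident. Multi-fragment inputs (salts) are
reduced to the largest fragment before fingerprinting, since activity
libraries describe the parent compound.

### The consensus score

For query $q$ and target $t$ with ligand set $L(t)$, each kind $k$
contributes its best similarity $s_k = \max_{l \in L(t)} T_k(q, l)$, and

$$\mathrm{score}(q,t) \;=\; \#\{\,k : s_k \ge \theta_k\,\} \in \{0,\dots,13\}.$$

This max-then-count form is the one reading of an integer score bounded
by the panel size that is consistent with per-fingerprint over/under-
threshold evidence flags: the score *is* the number of green flags on the
best-matching ligands. It also gives two properties the test suite
asserts as invariants: raising any $\theta_k$ can only lower scores, and
adding a ligand to a target can only raise them. A query identical to a
known ligand scores exactly 13.

Targets are ranked by descending score; ties break by descending mean of
the per-kind maxima, then lexicographic target id, so results are
byte-reproducible. The report holds at least `min_reported_targets` rows
(default 30) but always every target flagged reliable
(score ≥ `reliability_min_score`).

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `thresholds` (per kind) | 0.6 | Tanimoto | flag cutoff per fingerprint kind |
| `reliability_min_score` | 7 | kinds | reliable = strict majority of 13 |
| `min_reported_targets` | 30 | targets | minimum report length |
| `neighbor_min_similarity` | 0.5 | mean Tanimoto | neighbour admission for potency prediction |
| `weight_power` | 3 | – | sharpness of similarity weighting |
| `min_neighbors` | 1 | ligands | minimum evidence for a prediction |

The 0.6 threshold sits in the band where 2D Tanimoto similarity is
conventionally read as "same series" for hashed fingerprints while
staying meaningful for short key sets; 0.6 uniformly across kinds keeps
the score interpretable (it counts kinds, not a weighted blend), and the
per-kind override exists precisely because key-based and hashed kinds
saturate differently. The reliability cutoff 7 demands a strict majority
of the 13 kinds. These are deliberate package choices, made once; the
config file and `show_config()` print them all.

### Bioactivity profiling

Potency measurements are close to log-normal, so all averaging happens on
the pActivity scale, $p = 9 - \log_{10}(\mathrm{nM})$ (1 nM ↦ 9, 1 µM ↦
6). For a target and an activity type among IC50/EC50/Ki/Kd, the
neighbour set is the target's ligands having a curated record of that
type with mean 13-kind similarity at least `neighbor_min_similarity`.
Each neighbour contributes its most potent (minimum nM) record, weighted
by $w_i = \bar{s}_i^{\,3}$; with $\tau_i = w_i / \sum_j w_j$ the model
reports

$$\hat{p} = \sum_i \tau_i\, p_i, \qquad
  \sigma^2 = \sum_i \tau_i\, (p_i - \hat{p})^2 ,$$

converting $\hat{p}$ back to nM for display. $\sigma_p$ for a target is
the *smallest* $\sigma^2$ among its predicted types — the best-supported
prediction — and targets are ranked by ascending $\sigma_p$. $\tau_i$ is
attached to each neighbour row as its normalized evidence weight. The
weighted mean keeps predictions inside the neighbours' observed range,
scaling every activity by 10 shifts the prediction by exactly 10× while
leaving $\sigma^2$ unchanged, and as `weight_power` grows the prediction
converges to the nearest neighbour's value — all property-tested.

Two caveats are inherent to these definitions. A single-neighbour
prediction has variance 0, so singleton evidence ranks as confidently as
perfect consensus; the neighbour tables (and `n_neighbors` in
`tidy()` output) are the antidote and should be read alongside
$\sigma_p$. And $\sigma_p$ measures neighbour *agreement*, not accuracy:
a tight series of mismeasured values would rank well.

## Data model and curation

Reference data arrive as three ChEMBL-style raw tables (targets, ligands,
activity records). Curation applies a fixed battery in a fixed order —
target type (single protein / protein complex), ligand molecule type
(small molecule), prodrug flag, confidence > 5, relation "=", type in the
four supported ones, units nM, positive value, no inactivity comment —
and logs rejections per rule. The "inactivity comment" rule matches a
configurable term list (default: *inactive*, *not active*,
*inconclusive*), case-insensitively, because no canonical term list
exists. A ninth explicit rule rejects non-positive values rather than
hiding them in the units check. Duplicate (ligand, target, type) records
are all retained; aggregation to the "best" (minimum nM) value happens
only at display and prediction time. Organism is stored but never
filtered on.

The curated library precomputes the full fingerprint panel for every
ligand exactly once and persists as a plain-text single-directory bundle
(JSON manifest with layout version, parameters and build metadata; CSV
tables; hex-encoded fingerprint block) that round-trips bit-identically.

## The synthetic fixture generator

The generator stands in for a live ChEMBL extraction and is first-class,
tested code. It emulates exactly the structure the method assumes:

* each target owns a distinct scaffold from a 48-scaffold pool (16 ring
  systems, their phenyl-linked and anilide-linked analogues), decorated
  with enumerated substituent chains into a congeneric series — giving
  the designed high intra-target / low inter-target similarity
  (`intra_inter_similarity_check()` measures the separation, about 0.83
  vs 0.39 mean similarity on the standard fixture);
* activities are log-normal around a per-target true mean pActivity drawn
  from 6–9 (1 µM to 1 nM, the span typical of lead-like series), with
  noise sd 0.3 pActivity units — roughly the inter-assay reproducibility
  of public potency data;
* a documented fraction of extra records each violates exactly one
  curation rule (relation ">", units "uM", confidence 3, comment
  "inactive", a prodrug-flagged ligand, a non-protein target), so the
  filter battery can be checked against a designed quota;
* all randomness flows from the single spec seed; the same spec yields
  byte-identical tables.

What the fixtures deliberately do **not** model: censored measurements
("<"/">"), inter-laboratory variance structure, assay artifacts, shared
ligands between targets (real polypharmacology), and chemotype diversity
within a target. Passing the recovery benchmarks therefore shows the
pipeline is correct and well-calibrated *under the similarity principle's
ideal conditions*; it does not certify accuracy on real screening data,
where series overlap and activity cliffs blur the separation the
fixtures build in.

## Numerical choices and degenerate inputs

* Tanimoto of two empty fingerprints is defined as 0; unions are computed
  as $n_a + n_b - |A \wedge B|$ in integer arithmetic, so similarities
  are exact ratios.
* Ranking ties (equal score, equal $\sigma_p$) always fall back to a
  deterministic secondary key and finally the target id; repeated runs
  are byte-identical.
* Single-atom molecules carry empty atom-pair/torsion fingerprints
  (no pairs or 4-paths exist); they score 0 in those kinds.
* Invalid structures are hard errors in single-query mode and collected,
  per-record, in batch mode (file reading and `cmd_screen`), which never
  aborts on one bad record.
* A library with zero surviving records builds and saves as a valid empty
  bundle, with a warning.
* Problem sizes in the shipped tests: the standard fixture is 8 targets ×
  5 ligands, the report-size check uses 40 targets × 3 ligands, and the
  stochastic recovery benchmark runs 10 seeds of 6 targets × 5 ligands
  with one held-out query per target — recovery of the true mean
  pActivity within 2 sd in ≥ 90% of cases and rank-1 target recovery in
  ≥ 95%, measured jointly across the seeds.

## Design decisions that were genuinely open

* **Score form.** An integer 0–13 with per-kind flags admits essentially
  one definition (count of over-threshold per-kind maxima); a weighted or
  averaged score would not be integral nor match the flag semantics.
* **τ.** Reported per neighbour as the normalized evidence weight
  $w_i/\sum w$: it is the quantity that actually enters the prediction,
  sums to 1 per table, and reads directly as "how much this ligand
  determined the number".
* **σ\_p as a minimum over types.** The best-supported type is what a
  practitioner acts on; ranking by it keeps the summary ordering
  consistent with the per-type tables shown beneath it.
* **Largest-fragment standardization.** No desalting convention is
  universal; largest-organic-fragment is the least surprising for
  activity libraries and is logged whenever applied.
* **CLI as functions first.** `cmd_predict()`, `cmd_build_library()` and
  `cmd_screen()` return exit codes and are fully testable in-process;
  the `inst/cli/ligfish` script is a flag parser and nothing else. The
  optional HTTP adapter over the same three-field request was left out
  deliberately — the library and CLI are the artifact.

## Limitations

Predictions are only as good as the neighbourhood: a query chemotype
absent from the library yields low scores everywhere (correctly) and no
potency estimate. The method cannot see activity cliffs — a small change
that destroys activity — because fingerprint similarity stays high.
σ\_p = 0 from a single neighbour overstates confidence, and mixing assay
conditions inside an activity type is inherited from the source data.
For real use, library scale matters (the shipped fixtures are
deliberately small); the packed-bit scoring path is vectorized per kind
and scales linearly in library ligands.
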