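---
title: "Motif-based screening for candidate Plk1 substrates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based screening for candidate Plk1 substrates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plkscreen)
```

## The screening problem

Polo-like kinase 1 (Plk1) phosphorylates serine/threonine residues in a
preferred sequence context, and its polo-box domain (PBD) docks onto sites
primed by another kinase; engagement of the PBD relieves autoinhibition of
the kinase domain. A protein is therefore a plausible Plk1 substrate when it
carries **both** signatures:

* the kinase consensus phosphorylation motif
  `[E/D] - X - [pS/pT] - [I/L/V/M] - X - [E]`, and
* the PBD recognition motif `S - [pS/pT] - [P/X]`,

and when its annotations place it where Plk1 acts — the cell cycle, with a
role in cancer. `plkscreen` turns this reasoning into a reproducible filter
cascade over a proteome:

1. **(i) motif presence** — at least one kinase-motif window whose
   phosphoacceptor position is an exact S/T match;
2. **(ii) similarity** — best window identity with the consensus of at
   least 0.80;
3. **(iii) enrichment** — membership in an annotation-term cluster whose
   by-chance probability passes the 0.1 discard rule;
4. **(iv) PBD motif** — at least one exact PBD recognition window;
5. **(v) localization** — at least one annotation in every required
   namespace (cell-cycle phase and cancer by default).

Survivor sets are nested by construction, so the per-stage counts form a
non-increasing funnel, and the final candidates are ranked deterministically.

## Motif scanning

Motifs are compiled from the field's bracket notation into per-position
allowed-residue sets; `X` (bare or as a bracket alternative) is a wildcard
covering the whole 20-letter alphabet, and the `p` prefix marks the
phosphoacceptor, whose set must lie inside `{S, T}`. Scanning is an
exhaustive sliding window at step 1: every window of motif length is
evaluated, and all qualifying windows are reported, including overlapping
ones. We deliberately use an exhaustive scan rather than a heuristic local
alignment search: a six-residue degenerate pattern is not faithfully
searchable by seed-and-extend heuristics, while the exhaustive scan is
exact, reproducible and strictly more sensitive. A substitution mode is
available to approximate alignment-style scoring: a position also counts as
matched when the window residue scores positively against an allowed
residue in BLOSUM62. Because the BLOSUM62 diagonal is positive, the
substitution-mode hit set always contains the identity-mode hit set.

**The 80% rule.** Identity is computed as matched positions over *all*
motif positions, wildcards counting as matches, and the threshold is
applied inclusively (`>= 0.80`). For the six-position kinase motif this
admits exactly one mismatch among the constrained non-phosphoacceptor
positions (1, 4 and 6); a window scoring 5/6 ≈ 0.833 passes at 0.80 and
fails at 1.0. The phosphoacceptor is exempt from mismatching — it is a hard
constraint applied in the scanner, not part of the tolerance. This is the
only reading under which a sub-100% threshold on this motif has any effect
while preserving the phosphosite, and it is validated exhaustively over all
20^4 assignments of the constrained positions in the test suite.

**Degenerate inputs.** Sequences shorter than the motif yield an empty hit
table, not an error. Ambiguity letters (`B`, `Z`, `U`, `X`) and the stop
character (`*`) are legal in input and match only wildcard positions in
identity mode; in substitution mode a residue absent from the matrix (such
as `U`) raises a matrix error. Coordinates are 1-based inclusive
throughout.

**PBD motif.** The third position is written `[P/X]`: proline is preferred,
not required, so the default ("relaxed") reading is a wildcard, with
`pbd_strict = TRUE` restricting it to `{P}`. Since the relaxed motif has
only one constrained position besides the phosphoacceptor, a fractional
threshold is meaningless on a 3-mer; stage iv requires an exact match
(similarity 1.0). No spacing constraint between the kinase and PBD motifs
is imposed by default — how far a priming site may sit from the
phosphosite is not established — but `spacing = c(min_gap, max_gap)` on
the phosphoacceptor distance is available.

## Cluster enrichment

Stage-ii survivors are grouped into one cluster per (namespace, term) pair
over the three GO namespaces. Each cluster is scored with the upper-tail
hypergeometric probability

$$P(X \ge k) = \sum_{x=k}^{\min(n,K)} \frac{\binom{K}{x}\binom{N-K}{n-x}}{\binom{N}{n}},$$

where $N$ is the number of annotated proteins in the reference set, $K$ the
term's carriers in that set, $n$ the annotated proteins among the hits and
$k$ the term's carriers among the hits. The test is one-tailed because the
screen asks only about over-representation, and the sum is evaluated in
log-space so that extreme tails remain finite. Proteins without any
annotation in the chosen namespaces are excluded from $n$: the statistic is
defined over annotated proteins. Clusters with $p > 0.1$ are discarded
(inclusively at the boundary: $p = 0.1$ survives). No multiple-testing
correction is applied by default, matching the flat discard rule;
Benjamini–Hochberg adjustment is an explicit opt-in (`adjust_p`). Clusters
may overlap — a protein can belong to several — and ties in $p$ are broken
by descending $k$, then term name, so output order is deterministic.

The implementation is validated against exhaustive enumeration of all
$\binom{N}{n}$ draws for every parameter combination with $N \le 12$ (to
12 significant digits), against `stats::phyper` on random parameters, and
for calibration: on randomly assigned terms the p-values are
stochastically no smaller than uniform (one-sided Kolmogorov–Smirnov over
600 null terms).

## Ranking

The source screens of this kind prioritize final hits manually; to keep the
pipeline deterministic we rank by (descending best similarity, ascending
minimum retained-cluster p-value, descending PBD hit count, ascending
protein identifier). The last key makes the order total, so re-running a
screen reproduces byte-identical outputs.

## The synthetic world

No deposited accession reproduces the original screen's proteome snapshot,
so validation uses a generator whose statistical structure matches what the
screen assumes: `n_planted` true substrates carrying one exact instance of
each motif at recorded, non-overlapping positions, over a background of
i.i.d. random sequences. Key defaults, chosen once as the package's study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_proteins`, `n_planted` | 500, 50 | large enough for stable funnel statistics, small enough to re-run hundreds of times |
| `length_mean`, `length_sd` | 250, 50 residues | protein-scale lengths at which the chance-hit rate per protein stays below saturation, so each stage remains discriminative |
| `background_frequencies` | uniform 0.05 | makes the analytic window-rate oracle exact; a biased preset can be supplied |
| `near_miss_rate` | 0.05 | background proteins receive a window mutated at exactly one constrained non-phosphoacceptor position — the minimal perturbation separating the 0.8 and 1.0 thresholds |
| `phase_mixture` | G1 .10, S .15, G2 .25, M .25, cytokinesis .15, checkpoint .10 | weighted toward G2/M, where this kinase is most active |
| `q_pos` / `q_neg` | 1.0 / 0.05 | planted / background probability of the enriched "cell cycle" term |
| `cancer_rate_pos` / `cancer_rate_neg` | 1.0 / 0.05 | same for the cancer flag |
| `bg_phase_rate` | 0.10 | background proteins occasionally carry a phase term, so stage v is non-trivial |
| `n_noise_terms` | 20 at density 0.05 | null annotation terms cycling through the GO namespaces |

Two of these deserve justification. First, `q_pos` and `cancer_rate_pos`
default to 1 rather than some high-but-imperfect rate: the generator's
central contract is that planted substrates survive all five stages *by
construction*, giving a sensitivity of exactly 1.0 against which any
regression is visible. With, say, `q_pos = 0.95` over 50 planted proteins,
full recovery would hold in fewer than one run in ten — annotation
incompleteness is a legitimate experiment, but it should be an explicit
choice (`q_pos < 1`), not silent noise in the baseline. Second,
`length_mean = 250`: under the 0.8 threshold the chance qualification rate
is $3.3\times10^{-3}$ per window, so at 250 residues roughly half the
background passes stage ii. Much longer backgrounds would saturate stage ii
and dilute the enrichment contrast; the chosen length keeps the planted
cell-cycle cluster's p-value far below the 0.1 rule across seeds (it passes
in well over 95 of 100 seeded replicates) without making the background
trivially rejectable.

The generator records ground truth (insertion coordinates, windows, phases,
terms) and near-miss bookkeeping, and is byte-reproducible for a fixed
seed. What it does **not** emulate: real residue composition and repeats,
domain architecture, disorder, hierarchical ontologies, or correlated
annotations. Passing tests on this world therefore demonstrate the
*algorithmic* correctness and calibration of the cascade, not the biological
precision/recall the screen would achieve on a real proteome.

The analytic oracle `expected_hit_rate()` gives the exact per-window
qualification probability under the i.i.d. background by summing over the
subsets of constrained positions allowed to mismatch; for the kinase motif
at uniform frequencies this is $10^{-4}$ at threshold 1.0 and
$33\times10^{-4}$ at 0.8 (one mismatch allowed among positions with
mismatch-to-match odds 9, 4 and 19). Monte-Carlo checks on $10^6$ windows
agree within three binomial standard deviations.

## Numerical choices

* Similarity fractions and thresholds are compared with a $10^{-9}$
  epsilon (`sims >= threshold - 1e-9`), so `5/6 >= 0.8333...` and the
  inclusive boundaries at 0.80 and $p = 0.1$ are decided consistently in
  double precision.
* The hypergeometric tail is summed in log-space with a max-shift
  (log-sum-exp); the result is clamped to $(0, 1]$.
* All writers are deterministic: fixed column order, 6-significant-digit
  float formatting, LF endings, sorted GMT terms and members. Run
  manifests additionally carry a wall-clock timestamp and input digests;
  the byte-identity guarantee covers the data files, not the manifest.
* Validation problem sizes: the enumeration oracle covers all
  $N \le 12$; scanner/oracle equivalence uses 200 random triples of length
  up to 200; threshold semantics are exhaustive over $20^4$ windows;
  background statistics use 1,000 proteins of length 500; recovery and
  cluster-retention use the default 500-protein world over 100 seeds.

## Known limitations

* The similarity index is a per-position identity fraction, not a
  probabilistic motif model; position-specific scoring and
  accessibility/disorder context are out of scope.
* Annotation terms are flat labels; no ontology-graph propagation is
  performed, and the annotated-universe size $N$ is taken from the
  annotation set (or overridden), not estimated.
* The original screen's downstream structural arm (modeling, docking,
  molecular dynamics) and cross-predictor consensus are intentionally not
  reproduced; this package covers the sequence-and-annotation screen.
* The manual curation steps of the original funnel (cluster refinement and
  intersection) are represented only by their algorithmic core — counts,
  the by-chance probability, the discard rule and the namespace
  requirements — so absolute funnel sizes on real data are not comparable
  to manually curated ones.

## A worked run

```{r example, eval = FALSE}
world <- generate_world(synthetic_spec())
res <- run_screen(world$proteome, world$annotations, pipeline_config())
res                       # funnel counts and final candidate number
head(res$retained_clusters[, c("term", "N", "K", "n", "k", "p_value")])
head(res$candidates[!is.na(res$candidates$rank),
                    c("protein_id", "best_similarity", "phases", "rank")])
```
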