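---
title: "Assessing predicted homo-oligomer assemblies with oligoqc"
author: "oligoqc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted homo-oligomer assemblies with oligoqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoqc)
```

## The problem

Many proteins function only as oligomers. The KCTD-family proteins are a
canonical example: an N-terminal BTB/POZ domain drives assembly into
C5-symmetric homo-pentamers, followed (after a hinge) by a structurally
diverse C-terminal domain (CTD) that in many family members forms a
propeller-like ring with a β-strand-lined central cavity. Structure
predictors can now propose models for such assemblies directly, but each
model needs a verdict: is the predicted oligomer *reliable*, is it *stable*
in the predicted stoichiometry, is the ring *closed* or *open*, and does the
model survive molecular-dynamics scrutiny? `oligoqc` packages that
assessment as reproducible, tested code operating on the predictor's
standard outputs (coordinates with per-residue pLDDT, PAE matrices) and on
multi-model PDB trajectories.

## The confidence statistic and its grading

Let $E_{ij}$ be the predicted aligned error (Å) between residues $i$ and
$j$. Because PAE is asymmetric, each unordered pair is first symmetrized —
by the mean of $E_{ij}$ and $E_{ji}$ by default (`pair_symmetrization`;
`min` and `ordered` are available, the choice is not settled by any
convention we know of). For a block $B$ of residue pairs the statistic is

$$ f_B \;=\; 100 \cdot \frac{\#\{(i,j) \in B : \bar E_{ij} < \tau\}}{|B|}, $$

with $\tau = 10$ Å (`pae_threshold`). Five blocks are formed from a domain
map applied identically to every chain: intra-BTB and intra-CTD (same-chain
pairs, diagonal excluded), inter-BTB and inter-CTD (distinct-chain pairs),
and an informational cross-domain block (BTB vs CTD over all chains) that
never enters grading. Hinge and unmapped residues are excluded everywhere.

Both inequalities are deliberately strict: a pair at exactly 10.0 Å is not
counted, and a block at exactly 65.0 % is not reliable. Grading is

* **R** — every graded block has $f_B > 65$ (`reliable_percent`);
* **PR** — every intra block $> 65$ and every inter block $> 40$
  (`partial_percent`);
* **U** — otherwise;

with stability **S** iff the grade is R or PR. The 40 % PR band is our own
plumbing: the partially-reliable verdict is, in practice, a visual-inspection
call, so its exact boundary is not recoverable; we fixed a value, exposed it
in `analysis_config()`, and echo it into every report so the choice is
auditable.

Two further choices were genuinely open. *Which chain pairs pool into the
inter blocks*: we default to adjacent chains in ring order (`adjacency =
"cyclic"`), since adjacent-subunit contacts are what distinguish a closed C5
ring; `all_pairs` is available and is the right choice for non-ring
assemblies. *Sub-stoichiometry*: whole inter-chain quadrants (all residue
pairs between two chains) are scored with the same statistic, an edge is
drawn when a quadrant exceeds `reliable_percent`, and the connected
components of the chain graph are reported — five chains splitting into
{2, 2, 1} is the classic dimer-propensity signature.

## Superposition

`kabsch_fit()` is the closed-form least-squares rigid fit with the
reflection branch forced to a proper rotation ($\det R = +1$).
`refine_fit()` adds iterative outlier rejection: fit, compute per-pair
deviations $d_i$, drop pairs with $d_i > \overline{d} + k\,\mathrm{sd}(d)$
($k$ = `reject_sigma`, default 2), refit, stop when the retained set is
stable or after `max_cycles` (default 5). Two numerical details matter.
First, the cutoff is centered on the mean deviation: deviations are
nonnegative, so under homogeneous noise their standard deviation is far
smaller than their mean and an uncentered $k\,\mathrm{sd}(d)$ cutoff rejects
*every* pair. Second, the cutoff is floored at 0.01 Å so that numerically
exact fits (deviations ~1e-15) do not reject everything; `reject_sigma = 0`
bypasses the floor and falls through to the documented fallback (warn,
return the unrefined fit).

`oligomer_fit()` handles the chain-identity ambiguity of homo-oligomer
comparisons in two stages: a single monomer pair is refined to define the
aligned core, then the whole assembly is fitted under every candidate chain
mapping — the $2n$ cyclic relabelings by default, all $n!$ bijections on
request (capped at $n \le 7$) — and the minimum-RMSD mapping wins. On
genuinely Cn-symmetric inputs the cyclic search provably contains the
optimum; the test suite checks it against the exhaustive search. Residues
are paired by residue-number intersection; cross-protein correspondence
(different sequences) is out of scope and would need an external structural
aligner.

## Assembly geometry

`estimate_symmetry()` orders chains by centroid azimuth about the principal
axis of the chain centroids, fits each chain onto its ring neighbor, and
pools the per-step rotation angles (circular mean) and axes. The symmetry
RMSD is the residual of superposing the assembly onto itself advanced one
ring step — exactly 0 for a perfect Cn ring.

Interfaces use Shrake–Rupley solvent accessibility on a deterministic
Fibonacci sphere: vdW radii C 1.70, N 1.55, O 1.52, S 1.80 Å (others 1.8 Å
with a warning), probe 1.4 Å, 960 points per atom — standard constants. The
buried area per subunit of a chain pair is the mean over the two chains of
(isolated SASA − SASA in the pair).

`detect_open_assembly()` calls a ring open when its weakest adjacent
interface is *both* below `rel_cutoff` (0.25) times the median adjacent
buried area *and* below `abs_cutoff` (200 Å²). The conjunction is
deliberate: a uniformly weak but intact ring (every interface small) should
not be called open, and an assembly with one collapsed contact satisfies
both conditions. Both cutoffs are our own defaults, configurable and logged.

`pore_profile()` slices the assembly into 1 Å slabs along the symmetry axis
and reports, per slab, the minimum over atoms of (distance from axis − vdW
radius), floored at 0 and capped at `max_radius` (30 Å, also the value
reported for empty slabs). The axis sign is canonicalized by the third
moment of the axial coordinate so the profile is invariant under rigid
motions of the input.

`assign_ss()` is a Cα-only, P-SEA-style assignment chosen so that reduced
and synthetic models work (hydrogen-bond methods need backbone amides):
helix windows require d(i,i+3) = 5.0 ± 0.6 Å and d(i,i+4) = 6.2 ± 0.7 Å
over runs of ≥ 4, strand windows d(i,i+2) = 6.7 ± 0.6 Å over runs of ≥ 3,
plus d(i,i+3) > 8.5 Å where defined as the low-curvature check (no published
constant exists for the latter; the value separates ideal strands, ≈ 10 Å,
from helices, ≈ 5 Å, with a wide margin). Chain gaps (consecutive Cα > 4.5 Å)
break runs and are flagged. The windows are strict: moderate coordinate
noise (≳ 0.5 Å) erodes assigned content quickly, which is acceptable for
trend analysis (the trajectory tests only assert monotone degradation) but
means absolute H/E percentages from noisy frames should not be
over-interpreted.

## Trajectory analysis

`rmsd_series()` fits each frame onto the reference (frame 1, "the starting
model", by default) over a selection and reports the RMSD series; the
trajectory mean is labelled low (< 3 Å), limited (3–6 Å) or high, with
boundaries assigned to the larger band (a mean of exactly 3.0 Å is
"limited"). RMSDs are Cα-only, unweighted — mass weighting is a
convention choice the source protocols leave unstated, and Cα-only is what
the superposition module already computes. A separate `fit_selection`
argument lets you fit on one region and measure another; this is how the
CTD-vs-BTB rotation mode is exposed (fit on the BTB ring, measure the CTD
ring). `closest_to_average()` fits all frames to frame 1, averages, and
returns the first frame at minimum RMSD to the average. Frame indices are
1-based throughout, the R convention.

## What the synthetic generator does — and does not — establish

The generator produces the *statistical* structure the analyses assume, not
physical realism. A chain is an ideal α-helix (BTB body), a short connector
(hinge), and a β-hairpin of two ideal extended strands (CTD body), Cα-only,
with synthetic pLDDT ~ Normal(85, 5) in the B-factor column. Assemblies are
exact 360/n rotations at `ring_radius` (default 18 Å) plus iid Gaussian
coordinate noise (default 0.2 Å, a thermal scale); an open ring displaces
the last chain radially (15 Å in the fixtures, enough to sever both of its
interfaces). PAE matrices are block-Normal with means per class — defaults
4 Å intra, 6 Å inter, 8 Å cross-domain, 12 Å hinge, noise 1 Å — left
unsymmetrized as real dialects are, with the diagonal pinned at 0.5 Å; the
cross-domain default is low because a confidently predicted *rigid* assembly
has low expected error between all of its parts, and the degraded regimes
raise it together with the inter blocks. Trajectories superpose iid thermal
noise on an optional sinusoidal rigid rotation of all CTD atoms about the
symmetry axis.

A green end-to-end test therefore establishes that the pipeline recovers
planted block structure, symmetry, openness and motion modes from data with
exactly the assumed error model. It does not establish anything about real
predictor outputs: real PAE matrices have textured, rank-deficient error
patterns, real interfaces are chemically heterogeneous, and real MD noise is
correlated. Grades on real models inherit all the caveats of the 65 % rule
itself. The generator's expected grade (`expected_grade()`) is computed in
closed form from the block means — $100\,\Phi((\tau - \mu)/\sigma)$ per
block — so recovery tests compare against an analytic label, not against
the code under test.

## Numerical and degenerate-input choices

* Residue indexing: author numbering (1-based) is authoritative; internal
  indices run over the concatenated chain order, the same order the PAE
  matrix uses, enforced by a shared segmentation object.
* Alternate locations keep the highest-occupancy conformer (ties: first
  encountered); insertion codes sort after the blank code.
* Collinear point sets are fitted anyway but flagged; fits need ≥ 3 pairs.
* PAE dialect checks: non-square payloads and unfillable triplet arrays are
  format errors naming the file; diagonals above 5 Å warn (wrong dialect).
* All generators are pure functions of (spec, seed); reports are
  deterministic and byte-identical across reruns.

## Known limitations

* No all-atom realism anywhere in the synthetic world (Cα-only, element C);
  SASA on synthetic data exercises only the carbon radius.
* No sequence-independent structural alignment; cross-protein comparisons
  need externally supplied correspondences.
* The pore profile is an axial radius profile, not a cavity volume, and
  assumes an essentially axial channel.
* Binary trajectory formats (XTC/DCD) are not read; convert to multi-model
  PDB upstream.
* `pairwise_identity()` reports identity over alignment columns excluding
  terminal gaps by default; other denominators give different numbers for
  the same alignment, so always state the convention when quoting values.
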