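---
title: "Methods: per-residue domain prediction with mRMR-ranked features and bagged trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-residue domain prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(domainsweep)
```

# The problem and the model

A protein domain is a compact structural and functional unit; given only
sequence-derived information, we ask for every residue whether it lies
inside a domain. `domainsweep` treats this as supervised binary
classification of residues followed by a smoothing step, under three
modeling assumptions:

1. **Locality.** A residue's domain membership is predictable from a
   fixed window of sequence context (13, 15 or 17 residues centered on
   it). Odd window sizes and per-residue classification imply centering;
   there is no mechanism for long-range context beyond the window.
2. **Feature sufficiency.** The available per-residue descriptors —
   evolutionary conservation (20 PSSM scores), intrinsic disorder,
   physicochemical character (the five standardized Atchley factors),
   secondary structure and solvent accessibility — carry the local
   signal. The package does not run PSI-BLAST or the structure
   predictors; it consumes their outputs as files, or emulates them
   synthetically.
3. **Run structure.** True domains are long contiguous runs, so isolated
   dissenting calls inside a long run are more likely errors than real
   features; this licenses the run-length refinement.

## Encoding

Each residue contributes a 31-channel block: `pssm_1..pssm_20` (columns
fixed to PSI-BLAST order `A R N D C Q E G H I L K M F P S T W Y V`, so
`pssm_13` always refers to methionine regardless of how the input file
orders its columns), `disorder_1` in [0, 1], `aaf_1..aaf_5` (Atchley
factors; standardized, unitless), `ss_1..ss_3` (H/E/O one-hot) and
`sa_1..sa_2` (buried/exposed one-hot). The window sample for residue
*i* is the subsite-major concatenation of the blocks of residues
*i − h .. i + h* (*h* = (*w* − 1)/2): 403 features at *w* = 13.
Positions beyond the chain termini are the nominal residue `X`, whose
block is identically zero — as is the block of any real `X` in the
input. Feature names follow `AA<subsite>_<type>_<index>`.

Near-duplicate windows can inflate apparent accuracy, so
`dedupeSamples()` offers a greedy, order-dependent surrogate for
identity clustering of the window *w*-mers: a sample is dropped when its
residue string matches a retained same-label sample at a fraction of
positions at or above the threshold (`X` never matches). The default
threshold of 1.0 removes exact duplicates only; a production analysis
against real sequence collections would use a dedicated clustering tool
and a stricter threshold.

## mRMR feature ranking

Relevance and redundancy are plug-in mutual-information estimates in
nats. Continuous features are discretized into three states at
mean ± `kSigma`·sd (`kSigma = 1` by default, the convention of the
widely used mRMR implementation); inputs that are already discrete —
one-hot channels, constants, integer codes — keep one state per distinct
value, so a constant has arity 1 and binaries keep arity 2. The greedy
ranking seeds with the most relevant feature and then maximizes
D − R; ties break toward the lower feature index, making the ordering
deterministic. The log base cancels from the ordering (it scales D and
R jointly); the test suite asserts this.

## The forest

The classifier is bagging of fully grown decision trees, written from
first principles rather than delegated to a library, because the exact
procedure *is* the method: N bootstrap draws with replacement per tree,
m = ⌊log₂ M⌋ + 1 features drawn at each node (9 when M = 403, 5 when
M = 31), split thresholds at midpoints between consecutive distinct
sorted values, impurity measured by entropy (information gain; Gini is
available as an option), no pruning, majority vote over the default 10
trees.

Two growth details deserve explanation:

* **Zero-gain splits.** An impure node is split on the best candidate
  even when the information gain is exactly zero; a node becomes a leaf
  only when class-pure or when none of its *m* sampled features can
  separate its samples. A gain-must-be-positive rule would leave
  parity-style interactions (XOR) unlearnable — both first splits gain
  nothing individually — contradicting what a "fully grown, unpruned"
  tree means. Growth terminates regardless, because every split
  strictly shrinks both children.
* **Tie votes.** With an even tree count, a tied vote returns the
  negative class. In this task negatives are the safer default for a
  coin-flip call, and the rule is deterministic.

Per-tree seeds derive from the master seed; node-level feature draws
use a per-tree Mersenne Twister stream in compiled code, so refitting
with the same seed reproduces bit-identical trees on any platform.

## Cross-validation, IFS and winnowing

5-fold cross-validation partitions samples uniformly at random into
folds whose sizes differ by at most one, trains a forest on four folds,
tests on the fifth, and pools the confusion counts. Metrics are
Sn = TP/(TP+FN), Sp = TN/(TN+FP), Ac = (TP+TN)/total, and the MCC with
the convention that a zero factor under the square root yields MCC = 0.

The IFS scan evaluates the nested prefixes of the mRMR list in steps of
5 features — ⌊N/5⌋ subsets, so exactly 80 for the 403-feature window;
the trailing N mod 5 features are never scanned. All subsets share one
fold partition so that curve rows are comparable. The optimal set is
the smallest subset attaining the maximal MCC. The final winnowing
walks the curve comparing neighboring MCC values: block *i* (features
5(*i*−1)+1 … 5*i*) is kept iff MCC(S_i) > MCC(S_{i−1}); block 1 is
always kept, since the rule defines keep/discard only for blocks with a
predecessor and an empty final set would be useless.

**Window overlap and leakage.** Windows centered on neighboring
residues share 30 of their 31-channel subsites, and neighboring labels
are strongly autocorrelated. Under a *sample-level* partition a forest
can therefore recognize a test window through its overlap with training
windows and inherit the neighbor's label — measurable skill even when
features carry no class information at all. The default partition
remains sample-level (it is the protocol this family of methods
historically used, and its optimistic bias is part of what an IFS curve
on such data means), but `fiveFoldCV(groups = ...)` assigns whole
groups (typically proteins) to folds. The package's own no-signal
control and planted-recovery checks use protein-grouped folds, where a
no-signal configuration scores MCC ≈ 0 as it should.

## Scanning refinement

Per-residue calls are coded `1` (domain) / `2` (non-domain). A single
left-to-right pass examines each position on the working track: a `2`
preceded by a run of ≥ 5 consecutive `1`s and followed (from the next
position) by ≤ 3 consecutive `2`s becomes `1`; a `1` preceded by ≥ 5
consecutive `2`s and followed by ≤ 2 consecutive `1`s becomes `2`.
Three readings were genuinely open and are resolved as follows:
"more than four" is ≥ 5, "less than four" is ≤ 3, "less than three" is
≤ 2 (the literal reading); the examined position is excluded from its
own following run (the only reading under which the two run
measurements are disjoint); and the scan is one pass whose earlier
flips can extend later preceding runs (no fixpoint iteration — the
procedure is described as a single scan, and a fixpoint variant can
erase entire legitimate short segments). A consequence worth knowing:
the scan never changes a position strictly inside a same-code run of
length ≥ 6, which the test suite asserts on random tracks. Maximal `1`
runs of the refined track are the reported domain regions.

# The synthetic generator

`simConfig()`/`generateProteins()` emulate the study conditions
offline. Protein lengths are uniform on a configurable range (default
80–200 residues over 20 proteins, ≈ 2 000–3 000 residues — sizes chosen
so the full pipeline runs in seconds to minutes on one core; the
no-signal control uses 30 proteins of 140–190 residues, ≈ 5 000).
Architectures alternate linker/domain segments with geometric lengths
(means 15 and 60, echoing typical linker and domain scales); the first
segment's state is drawn from the stationary distribution
(P(domain) = 60/75), which makes the label process stationary along the
chain — otherwise terminus proximity, visible to the classifier through
window padding, would predict labels even in a configuration with no
feature effects.

Class-conditional signal is injected per channel, in units of the
within-class standard deviation: PSSM channels are integer-rounded
Gaussians (sd 2) with configurable domain-vs-linker mean shifts
(default +0.5 sd on channels 1–4); disorder is a clamped Gaussian with
domain residues 1 sd more ordered; secondary structure and solvent
accessibility have class-conditional state probabilities (domains more
regular and more buried, mirroring what is seen in real proteins); the
Atchley channels are shifted indirectly, by tilting the domain residue
composition with weights ∝ exp(Σ θ_k f_k) — the factor channels are
deterministic functions of residue identity, so this is the only
honest way to move them. `plantChannels`/`plantEffect` add a designated
shift to chosen PSSM channels; the corresponding center-subsite window
features (`AA7_pssm_c` at w = 13) are the designated features a ranking
should recover, and `plantCheck()` measures that recall.

**What passing tests do and do not show.** The generator produces
conditionally independent residues given the class — real conservation
profiles are autocorrelated, real disorder predictors smooth their
scores, and real domain boundaries are not geometric renewals. Passing
the planted-recovery and null checks therefore validates the
*machinery* (encoding, ranking, cross-validation, refinement) and its
statistical calibration, not biological accuracy on real proteomes,
which would require the external predictors and a curated benchmark.

# Numerical and interface choices

* PSSM input uses the log-odds score columns of the PSI-BLAST ASCII
  matrix by default; the weighted-percentage block can be selected
  (`scores = "percent"`), since either is defensible and files contain
  both. The parser never reorders rows and remaps columns from the
  file's own header.
* Characters outside the 20-letter alphabet become `X` (with a warning)
  rather than an error, consistent with `X` being the pipeline's
  nominal padding residue.
* Coordinates are 1-based inclusive in every file format; internal
  arrays are 0-based only inside the compiled tree code.
* Ties: mRMR argmax → lowest feature index; optimal IFS subset →
  smallest subset on an MCC plateau; forest vote → negative class;
  tree split → first-seen candidate at equal gain.
* Degenerate inputs: constant features get arity 1 and contribute zero
  mutual information; a single-class training fold warns and still
  evaluates; MCC with a zero denominator factor is 0.
* Problem sizes in the shipped checks: mutual information is verified
  against direct summation on 1 000 random tables; the greedy ranking
  against exhaustive recomputation on ≤ 8 features × 50 instances;
  planted recovery on ≈ 2 000 residues with ten 3-sd channels; the
  refinement on 200 noisy tracks (segments ≥ 8, ≤ 10% flips).

# Known limitations

* The dedup is greedy and order-dependent; it stands in for proper
  identity clustering and is not suitable for building a
  publication-grade non-redundant benchmark.
* Sample-level CV on sliding windows is optimistically biased (see
  above); grouped CV is provided but not the default.
* The forest offers no probability calibration or variable-importance
  measures; ranking interpretation should rely on the mRMR/MaxRel
  lists and the IFS curve.
* The synthetic generator's independence assumptions understate the
  redundancy structure of real features; mRMR behavior on real data
  will face much stronger inter-feature correlation.
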