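# domainsweep

Per-residue prediction of protein domain regions from sequence-derived
features, for structural bioinformaticians who want a transparent,
fully self-contained implementation of the classic
mRMR + random-forest + incremental-feature-selection recipe for
sequence labeling.

Protein domains are the structural and functional units of proteins.
`domainsweep` frames domain prediction as binary classification of every
residue — inside an annotated domain interval (*positive*) or not
(*negative*) — followed by a run-length smoothing step that turns
per-residue calls into contiguous domain regions.

## The method

**Encoding.** Each residue is described by 31 feature channels: 20 PSSM
conservation scores (from a PSI-BLAST position-specific scoring matrix,
columns in PSI-BLAST order A R N D C Q E G H I L K M F P S T W Y V), an
intrinsic disorder score in [0, 1], the five standardized Atchley
amino-acid factors (polarity, secondary-structure propensity, molecular
volume, codon diversity, electrostatic charge), a 3-state secondary
structure one-hot (H/E/O → 100/010/001) and a 2-state solvent
accessibility one-hot (buried/exposed → 10/01). A residue's sample is
the flattened, subsite-major window of the *w* residues centered on it
(*w* ∈ {13, 15, 17}; 31·13 = 403 features for the default window).
Window positions past the sequence ends are padded with the nominal
residue `X`, whose feature block is all zeros. Feature names follow the
`AA<subsite>_<type>_<index>` scheme, so `AA1_pssm_13` is conservation
against methionine at subsite 1.

**Feature ranking (mRMR).** With mutual information
I(x, y) = Σ p(x, y) log [ p(x, y) / (p(x) p(y)) ], each feature *f* has
relevance D = I(f, c) to the class *c* and redundancy
R = (1/|G_s|) Σ_{g ∈ G_s} I(f, g) against the already-selected set G_s.
The greedy ranking repeatedly picks argmax (D − R). Continuous features
are discretized into three states at mean ± k·sd (k = 1 by default); the
MaxRel list (sorted by D alone) is reported alongside.

**Classifier.** A random forest in the original bagging form, written
from first principles: each of the (default 10) trees grows on a
bootstrap replicate of the N training cases, draws m = ⌊log₂ M⌋ + 1
random features at every node (9 for M = 403), splits on maximum
information gain over midpoint thresholds, is never pruned, and the
ensemble predicts by majority vote (ties → negative).

**Incremental feature selection.** Nested prefixes of the mRMR list
(step 5: S₁ = top 5, S₂ = top 10, …, ⌊N/5⌋ subsets — 80 for N = 403) are
each evaluated by 5-fold cross-validation, yielding an IFS curve of
sensitivity, specificity, accuracy and Matthews correlation coefficient
(MCC). The subset with maximal MCC is the optimal set; a final
winnowing pass keeps each 5-feature block only if it raised the MCC
over its predecessor subset.

**Refinement.** Per-residue calls become a code track (`1` = domain,
`2` = not). One left-to-right scan flips a `2` after ≥ 5 consecutive
`1`s when followed by ≤ 3 consecutive `2`s, and a `1` after ≥ 5
consecutive `2`s when followed by ≤ 2 consecutive `1`s; maximal `1`
runs are then reported as domain regions.

Because PSI-BLAST, a disorder predictor and a secondary-structure
predictor are external tools, the package ships a synthetic generator
(`simConfig()` / `generateProteins()`) that emulates all their
per-residue outputs with controllable class-conditional signal, so the
entire pipeline is testable offline.

## Worked example

```r
library(domainsweep)

cfg <- simConfig(nProteins = 8L, lengthRange = c(60L, 120L),
                 plantChannels = c(4L, 13L), plantEffect = 2, seed = 7L)
sim <- generateProteins(cfg)
sim$proteins
#> ProteinSet with 8 protein(s), 18 domain interval(s)
#>   SYN0001: 101 aa, 1 domain(s)
#>   SYN0002: 88 aa, 1 domain(s)
#>   ...

res <- runPipeline(sim$proteins, sim$blocks,
                   pipelineConfig(seed = 1L, step = 25L))
res$report
#>  refinement        Sn        Sp        Ac       MCC
#>          no 0.9807692 0.8546512 0.9516129 0.8611721
#>         yes 0.9842657 0.8372093 0.9502688 0.8568744

head(mrmrTable(res$ranked), 3)
#>      feature round      score
#>   AA7_pssm_4     1 0.19450720
#>  AA7_pssm_13     2 0.11631664
#>  AA8_pssm_13     3 0.08733595
```

The report is the per-residue confusion summary over out-of-fold
predictions, before and after the scanning refinement: here ~95% of
residues are called correctly with MCC ≈ 0.86. The two planted PSSM
channels (4 and 13) surface immediately as the top mRMR picks at the
window center (subsite 7 of 13), which is exactly the designed signal.
`res$regions` holds the predicted domain intervals per protein, and
`summarizeFeatures(res$finalFeatures, 13)` tabulates the winnowed
feature set by type, subsite and PSSM residue.

A command-line driver wraps the same stages as subcommands
(`simulate encode rank ifs winnow train predict refine evaluate run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","domainsweep.R",package="domainsweep"))')" \
    simulate --out-dir fixtures --seed 3 --n-proteins 10
```

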