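---
title: "Methods: defensin repertoire classification, selection scans, functional divergence and dimer geometry"
author: "defevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defensin repertoire classification, selection scans, functional divergence and dimer geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defevol)
```

# Scope

The primate α-/θ-defensin (*DEFA*/*DEFT*) multigene family evolves by
birth-and-death: repeated duplication, rapid divergence of the mature
antimicrobial peptide, and frequent pseudogenization.  `defevol` packages the
four computational procedures such a study rests on, plus a synthetic-data
generator so that every stage can be exercised and validated without any
external download:

1. **Repertoire rules** — classify coding sequences into functional genes and
   pseudogenes, validate the cysteine motifs of α- and θ-defensin mature
   peptides, and model θ-defensin maturation.
2. **Selection scans** — Nei–Gojobori (1986) Ka/Ks over sliding windows of a
   codon alignment, with a directional bootstrap test of the average ratio
   against 1.
3. **Functional divergence** — transform pairwise type-I divergence
   coefficients into additive distances and solve per-cluster functional
   branch lengths by least squares on a star topology.
4. **Dimer geometry** — superpose two-chain structures on the dimer
   interface and extract per-frame flexibility metrics from coordinate
   trajectories.

Upstream steps that established tools already provide — alignment, tree
inference, codon-model ML fits (PAML-style site models), estimation of the
divergence coefficients themselves, homology modelling and molecular
dynamics — are deliberately out of scope; their outputs are this package's
inputs.

# Repertoire model

A defensin precursor is a signal peptide, a prosegment, and a mature
peptide.  The default partition places the signal at alignment columns 1–19,
the prosegment at 20–64 and the mature peptide from 65 to the end (94
columns by default).  These boundaries are a configurable convention, not a
biological constant: published fragment labels (prosegment windows such as
26–35 and 56–65, mature-peptide sites from 65 on) pin the architecture only
approximately, and `precursor_partition()` accepts any contiguous spans.

**Classification.** `classify_coding_sequence()` calls a sequence functional
when its frame carries no internal stop codon and its length deviates from
the expected codon count by a multiple of three.  A non-multiple-of-three
deviation is a frameshift; an internal stop is a premature stop, reported
with the first offending codon.  One exception encodes the birth of
θ-defensins: a stop at the θ-defining site (alignment position 77) whose 12
upstream residues begin with a valid θ-nonapeptide motif creates a
*functional* θ precursor rather than a pseudogene — the stop is what
terminates the precursor after the nonapeptide unit.  A stop anywhere else
(for example codon 17, the recurrent *DEFT* pseudogenizing lesion in great
apes) always pseudogenizes, because it truncates the precursor before the
mature peptide.

**Motifs.** The α-defensin mature peptide carries six conserved cysteines in
the arrangement `C-x-C-x(3,4)-C-x(9)-C-x(6,9)-C-C`; the validator requires
all six anchors, with the final two adjacent, as in the human mature peptides
(e.g. HNP1 `...LWAFCC`).  The θ-defensin nonapeptide motif is
`x-C-x-C-x(4)-C` (three anchors over nine residues), with a 13-residue
variant `x-C-x-C-x(8)-C` observed in colobus.  Spacer positions match any
residue including the unknown symbol `X`; an anchor must be a literal `C`.

**Maturation.** The θ-defensin is the only known cyclic mammalian peptide:
an 18-residue head-to-tail ligation of two nonapeptides (identical for a
homodimer-derived peptide, different for a heterodimer).  Each unit is
excised from a 12-residue precursor tail by removing the three C-terminal
residues (typically `RLL` or `QLL`); `excise_nonapeptide()` implements the
positional rule and reports the removed tail.  `mature_theta()` forms the
cycle and assigns the tridisulfide ladder.  The pairing of the ladder is not
uniquely determined by sequence alone, so the connectivity is a parameter:
the default `"antiparallel"` pairs A-Cys1–B-Cys3, A-Cys2–B-Cys2,
A-Cys3–B-Cys1 (consistent with the head-to-tail topology of the backbone);
`"parallel"` is available.  Whether the colobus 13-mer variant undergoes the
same 3-residue trim is unknown; the excision function is length-12-strict
and simply refuses other lengths rather than guessing.

# Nei–Gojobori Ka/Ks and the sliding-window scan

`codon_sites()` counts, for each sense codon, the synonymous site content
*S* as the per-position fraction of synonymous single-base changes among
changes that do not create a stop codon, and *N* = 3 − *S*; with this
denominator-reduction convention every sense codon carries exactly three
sites.  `codon_diffs()` averages synonymous/nonsynonymous step counts over
all *k*! single-step pathways between two codons differing at *k* positions,
excluding pathways that pass through a stop (and falling back to all
pathways in the rare case every one does).  Both functions are verified in
the test suite against a brute-force enumerator over the complete genetic
code (all 61 sense codons and all 61 × 61 pairs).

`pairwise_ng86()` sums sites (averaged between the two sequences) and
differences over the codons of a column span, skipping codons with a gap or
ambiguity in either row (pairwise deletion), and applies the Jukes–Cantor
correction *d* = −(3/4) ln(1 − (4/3) *p*) to each proportion.  The result is
flagged undefined when *S* = 0, *N* = 0, or a proportion reaches 3/4 (the
correction diverges); undefined values propagate as `NA`, never as zero.

`window_scan()` slides a 10-residue window in 5-residue steps (both
configurable) along the amino-acid columns; trailing windows shorter than
the window size are dropped, so a 100-column alignment yields 19 windows
(1–10 … 91–100).  Per window it reports mean pairwise amino-acid identity
(pairwise gap exclusion) and three averages kept deliberately separate:

* `avg_Ka`, `avg_Ks` — means over all pairs with defined rates;
* `avg_KaKs` — by default the **mean of per-pair ratios** over pairs with
  defined rates and Ks > 0.

The ratio-of-means alternative (`ratio_method = "ratio_of_means"`, the mean
Ka divided by the mean Ks) is provided because the two conventions behave
differently: the mean of ratios follows the convention of per-pair ratio
tables but is biased upward in small windows (the expectation of a ratio
with a noisy denominator exceeds the ratio of expectations), while the ratio
of means is nearly unbiased.  See the calibration discussion below.

**Bootstrap test.** For a window with a defined average, `bootstrap_test()`
resamples the *N* sequences with replacement, recomputes the window average
per replicate (pairs formed by two copies of the same original sequence are
excluded; replicates whose average is undefined are redrawn up to
`max_redraws` times, then dropped), fits a normal distribution to the
replicate averages by mean and standard deviation, and reports the one-sided
tail probability beyond 1 on the null side: for an observed average above 1
the alternative is "Ka/Ks > 1" and *p* = P(X ≤ 1); below 1, the mirror.
The p-value comes from the fitted normal, not the empirical quantile, and a
degenerate fit (SD = 0) gives *p* ∈ {0, 0.5, 1} by the point-mass rule.  The
resampling RNG is always seeded and the seed is recorded in report headers.

**Calibration.** The package's own calibration experiment (run by the
acceptance script and asserted in the test suite) simulates neutral families
— ω = 1 in every region, a 12-leaf star tree with branch length 0.3, 94
codons — and counts positive-selection calls (direction `greater`, *p* <
0.05) on the whole-alignment average; 200 families with 200 bootstrap
replicates each keep the experiment inside a minute.  Applied to the
ratio-of-means average, whose null distribution is centred at the tested
threshold of 1, the empirical type-I error sits near the nominal 5% level.
Applied to the mean-of-ratios average the same test rejects more often —
not because the bootstrap is wrong, but because that statistic's null
expectation lies above 1; its "significance" therefore mixes selection
signal with estimator bias, which is worth remembering when reading per-pair
ratio tables.  Both rates are computed and reported by
`scripts/acceptance.R`.

# Functional distances and star branch lengths

Given pairwise type-I functional-divergence coefficients θ(i,j) ∈ [0, 1)
(estimated upstream; consumed here as a plain table), the functional
distance is d_F = −ln(1 − θ) and is assumed additive on a star:
d_F(A,B) = b_F(A) + b_F(B).  `star_branch_lengths()` minimizes the sum of
squared residuals by an exact least-squares solve (QR on the pair-incidence
design matrix).  For three clusters the solution is the classical
half-difference formula and residuals vanish identically; for more clusters
residuals and their maximum are reported.  Negative branch lengths are
mathematically possible and are reported with a warning rather than
constrained away — a negative value flags a non-additive coefficient table,
which the user should see, not have silently repaired.  For three clusters
exact solve and generic least squares coincide, so the distinction has no
numerical consequence.

A worked consequence of additivity: myeloid branch lengths of 0.94, 0.32 and
0.46 imply pairwise distances 1.26, 1.40 and 0.78 — a range of 0.78–1.40 —
and feeding those distances back recovers the branch lengths exactly.  For
the enteric clusters (3.41, 0.53, 0.17) additivity gives a range of
0.70–3.94; a published range of 0.69–3.93 for the same branch lengths is a
0.01 rounding artifact of reporting distances and branch lengths at two
decimals independently.  The package documents this discrepancy in its
output notes instead of correcting either number.

# Dimer geometry

α-defensin dimers are held together by four intermolecular backbone hydrogen
bonds between residues 18 and 20 of the two chains (HNP4 numbering);
residues 11 and 22 are the distal tips of the two flexible loops.
`superpose_interface()` performs a rigid-body least-squares fit (orthogonal
Procrustes via SVD, with the determinant sign guard against reflections)
over a default selection of the backbone N, CA, C and O atoms of residues 18
and 20 in both chains.  Whether the original interface alignment used whole
backbone or donor/acceptor atoms only is not documented anywhere; the whole
backbone of both residues is the stabler default and the selection is a
parameter.  `frame_metrics()` extracts, per frame, the distances
A22Cα–B22Cα and A11Cα–B11Cα and the signed torsion over A11Cα, A22Cα,
B22Cα, B11Cα (atan2 formula, degrees in (−180, 180]); the torsion is
invariant under reversal of the four-point order.  `trajectory_summary()`
reports mean, sample SD, minimum and maximum per metric; the dihedral is
summarized on its absolute value because a sign convention depends on
arbitrary chain labelling, while the per-frame signed values are retained.

Structures come from fixed-column ATOM-record files; multi-MODEL files are
read as trajectories with MODEL index = frame index, which keeps the format
plain-text and tool-agnostic.  Residue-correspondence maps onto the
reference numbering are supplied per structure (`numbering_map`), because
published renumberings of homologs onto HNP4 positions are not printed
anywhere; chain assignment defaults to file order and is overridable.

# The synthetic-data generator

`simulate_family()` evolves an ancestral sense-codon sequence along a known
tree.  Per branch and codon site the number of proposal events is Poisson
with mean equal to the branch length; each event proposes a uniform
single-nucleotide change; stop-creating proposals are rejected (the event is
consumed); synonymous proposals are accepted with probability min(1, 1/ω)
and nonsynonymous ones with min(1, ω), where ω is the dN/dS dial of the
region the site falls in.  This accept/reject scheme was chosen over a full
codon rate matrix for transparency: the realized Ka/Ks tracks ω in both
regimes, it cannot generate stops or indels, and its output is codon-aligned
by construction.  The defaults are the package's study conditions: 94
codons, signal/prosegment/mature ω of 0.2/0.5/2.0 (a conserved signal
peptide and a positively selected mature peptide), a 12-leaf star tree with
branch length 0.3, seed mandatory.  Under these conditions the mature-region
windows exceed the signal-region windows in average Ka/Ks in essentially
every simulated family, and across seeds the realized mature-region Ka/Ks
lies within a factor of two of the dialled ω — a loose band, as the
generator's proposal process and the counting estimator are different
objects.

What the generator does **not** emulate: codon frequency bias,
transition/transversion asymmetry, indel evolution along the tree,
rate variation beyond the three-region partition, alignment error, or
recombination between paralogs.  Passing the recovery and calibration tests
therefore shows the estimators are correct for sequences evolving under this
idealized process — not that real defensin alignments satisfy its
assumptions.

`inject_lesion()` superimposes the three mutational events of the family's
birth-and-death process on a simulated (or real) sequence: a premature stop
(`TAA` at a chosen codon), a 1–2 nt deletion (frameshift), or the
θ-deriving stop at position 77 that leaves the 12-residue tail upstream
intact.  `simulate_trajectory()` produces near-rigid dimer trajectories from
the deterministic `synthetic_dimer_reference()` geometry (an idealized
hairpin dimer with the interface at residues 18/20 and loop tips at residue
11; it is a synthetic stand-in, not a model of any deposited structure) by
independent Gaussian jitter, with separate loop and core sigmas; frame 1 is
always the unperturbed reference.  A distance whose two endpoints are
jittered with per-coordinate σ has SD ≈ √2·σ, which the recovery tests use
as their oracle.

# Numerical choices and problem sizes

* All file and report coordinates are 1-based inclusive; window rows print
  `start`/`end` columns matching the `56–65` fragment-label style.
* Undefined statistics are `NA` in memory and `"NA"` in TSV output.
* Every report begins with comment lines recording package version, stage,
  the full parameter set and the seed, so a report is reproducible from its
  own header; re-running any stage with identical inputs and seed reproduces
  byte-identical output.
* Oracle-equivalence tolerances are 1e-10–1e-12 (pure floating-point
  agreement); geometric rigid-invariance tolerances are 1e-6–1e-8 (torsion
  of nearly-collinear points amplifies rounding).
* Test and acceptance problem sizes — 200 calibration families × 200
  bootstrap replicates, 50 recovery families, 500 random oracle pairs — were
  chosen so the whole suite runs in well under a minute at desk scale while
  keeping binomial uncertainty on the calibrated rate near ±2%.
  Production analyses should use the 1000-replicate bootstrap default.

# Known limitations

* The Nei–Gojobori estimator is a counting method: no
  transition/transversion weighting, no codon-frequency correction; for
  strongly biased data a codon-model ML fit is the right tool and is out of
  scope here.
* The bootstrap resamples sequences, not phylogenetically independent
  contrasts; shared ancestry among close paralogs makes the replicate pool
  less variable than a true independent sample, and the normal fit can be
  liberal in small windows (see the calibration discussion).
* The star model for functional distances ignores hierarchical structure
  among clusters; residuals (reported) are the diagnostic.
* The mean-of-ratios average excludes Ks = 0 pairs, which discards exactly
  the pairs with the strongest apparent nonsynonymous excess; the pair count
  used is reported per window so the exclusion is visible.
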