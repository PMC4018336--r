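# defevol

Molecular-evolution toolkit for the primate α-/θ-defensin (*DEFA*/*DEFT*)
multigene family — and for anyone studying a multigene family under
birth-and-death evolution who needs the same four procedures on codon
alignments, divergence-coefficient tables and structure trajectories.

Defensins are small cationic antimicrobial peptides synthesized as
signal + prosegment + mature precursors.  The family's hallmarks — rapid
divergence of the mature peptide, recurrent pseudogenization, and the birth
of the cyclic θ-defensin from an α-defensin precursor truncated by a
nonsense mutation — call for four kinds of computation, all implemented
here and all exercisable on built-in synthetic data:

* **Repertoire rules** (`classify_coding_sequence`, `validate_motif`,
  `excise_nonapeptide`, `mature_theta`): functional-gene vs pseudogene
  calls (premature stop with its codon site, frameshift against an expected
  codon length, and the θ-deriving stop at position 77 that *creates* a
  functional θ precursor when the upstream nonapeptide motif is intact);
  the six-cysteine α-mature motif `C-x-C-x(3,4)-C-x(9)-C-x(6,9)-C-C` and the
  three-cysteine θ-nonapeptide motif `x-C-x-C-x(4)-C`; maturation of two
  nonapeptides into the cyclic octadecapeptide with its tridisulfide ladder.
* **Selection scans** (`window_scan`, `kaks_region`, `bootstrap_test`):
  Nei–Gojobori (1986) Ka/Ks — per-codon site counts with stop-excluded
  denominators, k!-pathway averaging of differences, Jukes–Cantor correction
  d = −(3/4)·ln(1 − (4/3)p) — over 10-residue windows stepped by 5, with a
  seeded directional bootstrap of the average Ka/Ks against 1 (resample N
  sequences, refit a normal to the replicate averages, one-sided tail beyond
  1 on the null side).
* **Functional divergence** (`fd_star`, `star_branch_lengths`): the distance
  transform d_F = −ln(1 − θ) of type-I functional-divergence coefficients
  and the star-additive decomposition d_F(A,B) = b_F(A) + b_F(B), solved for
  per-cluster branch lengths b_F by exact least squares, with residual
  diagnostics and negative-branch warnings.
* **Dimer geometry** (`superpose_interface`, `frame_metrics`,
  `trajectory_summary`): Kabsch superposition on the dimer interface
  (backbone of residues 18/20, HNP4 numbering, in both chains) and per-frame
  flexibility metrics — the A22Cα–B22Cα and A11Cα–B11Cα distances and the
  A11Cα–A22Cα–B22Cα–B11Cα torsion — from single- or multi-MODEL coordinate
  files.

A seeded generator (`simulate_family`, `inject_lesion`,
`simulate_trajectory`, `synthetic_dimer_reference`) produces codon families
evolving under region-specific dN/dS (defaults: signal ω = 0.2, prosegment
0.5, mature 2.0 over 94 codons), pseudogenizing lesions, and jittered dimer
trajectories, so the whole pipeline runs without downloads.  See the
methods vignette (`vignettes/defensin-evolution.Rmd`) for the models,
conventions and limitations.

## Worked example

Solve functional branch lengths from a coefficient table (here the bundled
synthetic example, whose coefficients imply additive distances):

```r
library(defevol)
tab <- read_theta_table(system.file("extdata", "theta_synthetic_example.tsv",
                                    package = "defevol"))
fit <- fd_star(tab)
summary(fit)
#> Functional branch lengths (star least squares):
#> DEFA1 DEFA4 DEFA8
#>  0.94  0.32  0.46
#> max |residual| = 2.22e-16
#> pairwise dF range: 0.78-1.4
```

The branch lengths say DEFA1's evolutionary-rate profile has shifted at many
more sites than DEFA4's or DEFA8's; a zero residual means the three pairwise
distances are exactly star-additive (always true for three clusters).

Scan a simulated family for regional selection contrasts:

```r
aln <- simulate_family(n = 12, branch_length = 0.3, seed = 42)
sc <- window_scan(aln, replicates = 1000, seed = 42)
head(as.data.frame(sc)[, c(1:6, 11)], 3)
#>   start end identity_pct avg_Ka avg_Ks avg_KaKs  p_value
#> 1     1  10         90.3 0.0488  0.166    0.319 3.50e-07
#> 2     6  15         88.5 0.0589  0.105    0.477 3.61e-04
#> 3    11  20         93.3 0.0336  0.082    0.279 5.99e-05
tail(as.data.frame(sc)[, c(1:6, 11)], 3)
#>    start end identity_pct avg_Ka avg_Ks avg_KaKs p_value
#> 15    71  80         63.5  0.222  0.177     1.45  0.1669
#> 16    76  85         55.3  0.275  0.132     1.86  0.1493
#> 17    81  90         54.1  0.308  0.173     1.79  0.0805
```

Signal-peptide windows (1–19) show high identity and Ka/Ks well below 1
(small p-values in the `less` direction: significant purifying selection);
mature-peptide windows (65–94) show eroded identity and average Ka/Ks near
the dialled ω = 2, though with 12 sequences and 10-codon windows the
bootstrap rarely certifies Ka/Ks > 1 — positive-selection power at this
depth is limited, which is the honest read of such scans.

Mature a θ-defensin:

```r
mature_theta("RCICRRGVC", "RCVCTRGVC")
#> cyclic octadecapeptide (head-to-tail): RCICRRGVCRCVCTRGVC
#>   tridisulfide ladder (antiparallel): 2-18, 4-13, 9-11
```

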