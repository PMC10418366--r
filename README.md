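# chisno

Chi1 rotamer overlap analysis of pH-induced active-site destabilization.

## What it is for

Cysteine proteases such as insect cathepsin L lose activity in strongly
acidic environments even though their fold survives: molecular-dynamics
simulations under discrete protonation schemes show the damage is local —
the catalytic histidine's side chain leaves its catalytically competent
rotamer.  `chisno` is the post-processing side of that analysis.  It takes
per-residue χ1 side-chain dihedral time series (the output of the GROMACS
`chi` utility, or any delimited time/angle table) from trajectories run
under two protonation conditions and answers three questions:

1. **Which residues' rotameric states reorganize on acidification?**
   For every residue it bins the χ1 distribution of each replicate and
   computes the *integral of non-overlapping*

   S_NO(p, q) = Σᵢ |pᵢ − qᵢ| / Σᵢ (pᵢ + qᵢ) = 1 − Σᵢ min(pᵢ, qᵢ)·Δ

   between condition-paired replicates (0 for identical distributions,
   1 for disjoint ones; Δ is the bin width and the second equality holds
   for unit-area densities).  Residues with S_NO > 0.5 in at least 2 of 3
   replicate pairs are flagged as pH-responsive.
2. **How unstable is the native rotamer?**  Frames are classified into
   disjoint angular windows (native in-site well near χ1 = 190°,
   out-of-site well near 285° by default); the package reports native-state
   occupancy, mean dwell time, and the number of sustained violation
   events (excursions out of the native window lasting at least 1 ns).
3. **What do the protonation schemes imply for net charge?**  Discrete
   charge assignments for pH 7 (Asp/Glu −1, His 0, Lys/Arg +1),
   pH 2 "all" (Asp/Glu 0, His/Lys/Arg +1) and pH 2 "his" (pH 7 plus one
   protonated catalytic histidine) are applied to a sequence or to bare
   ionizable counts, with point mutations in `V277A` notation.

Because χ1 is circular, distributions that straddle the ±180° seam are
first normalized by *doubling and stacking*: every angle is duplicated at
`a` and `a + 360` and the contiguous 360° window whose boundary falls in
the widest empty arc of the data is kept, so no rotamer well is ever split.

A synthetic trajectory generator (von Mises rotamer wells + Markov
switching) reproduces the statistical structure the analysis assumes — a
single stable well in the neutral condition, stochastic two-well switching
in the acidic one — so the entire pipeline is testable without trajectory
data.

## Worked example

Generate a synthetic two-condition study (20 residues, three replicates of
1000 frames each, residue 7 planted as pH-responsive), run the full
analysis, and compute the charge roster:

```r
library(chisno)

ds <- make_study_set(n_residues = 20, responsive_ids = 7, base_seed = 11)
manifest <- write_study_set(ds, "study")
report <- run_pipeline(manifest, sequence = synthetic_mature_fasta(),
                       mutations = c("V277A", "V277D", "V277H"))
report
#> <sno_report>
#>   residues: 20; replicate pairs: 3 (matched)
#>   mean S_NO over all pairs: 0.081 +/- 0.133
#>   responsive residues (S_NO > 0.5 in >= 2 pairs): 7
#>   charge table:
#>    variant  scheme net_charge
#> 1       WT     pH7        -15
#> 2       WT pH2_all         11
#> 3       WT pH2_his        -14
#> 4    V277A     pH7        -15
#> 5    V277A pH2_all         11
#> 6    V277A pH2_his        -14
#> 7    V277D     pH7        -16
#> 8    V277D pH2_all         11
#> 9    V277D pH2_his        -15
#> 10   V277H     pH7        -15
#> 11   V277H pH2_all         12
#> 12   V277H pH2_his        -14
```

The selection rule recovers exactly the planted residue: its three
matched-pair S_NO values average 0.65 ± 0.05 (the out-of-site stationary
occupancy of the acidic regime is 2/3, and for well-separated wells S_NO
approximately equals the occupancy shift), while all 19 unresponsive
residues stay near the sampling-noise floor (~0.08).  Its rotamer traces
under the acidic condition show 22, 19 and 21 sustained (≥ 1 ns)
violations of the native window; the neutral condition shows none.  The
charge table reproduces the WT net charges −15 / +11 / −14 under the three
schemes and the mutant shifts (V277D: −16 at pH 7; V277H: +12 at
pH 2 all).

`write_report(report, "out/")` serializes `report.tsv`, `selection.tsv`,
`stability.tsv`, `charges.tsv`, `report.json` and `run.log`.  A thin
command-line wrapper with `generate` / `analyze` / `charges` / `sno` verbs
is installed at `system.file("scripts", "chisno.R", package = "chisno")`.

Note on the packaged FASTA: `synthetic_mature_fasta()` points to a
*synthetic* stand-in chain that carries the studied enzyme's exact
ionizable composition (14 Asp, 10 Glu, 2 His, 4 Lys, 5 Arg) and catalytic
triad positions under precursor numbering — it is for exercising the
charge arithmetic, not a biological sequence.

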