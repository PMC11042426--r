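# snoglyc

Non-targeted, isomer-sensitive N-glycome analysis from PGC-LC-MS/MS data.

## The problem

Released, chemically reduced N-glycans analyzed by porous-graphitic-carbon
LC coupled to tandem MS produce hundreds of thousands of MS/MS spectra per
study, most of which do not derive from glycans at all (peptides, hexose
oligomers from glycogen breakdown, chemical noise). Conventional glycomics
workflows extract only known, anticipated glycan masses and so cannot
discover non-canonical structures. `snoglyc` implements the opposite,
data-driven strategy for glycomics practitioners:

1. **Diagnostic-ion profiling.** Every MS/MS scan is screened for a panel
   of 49 glycan oxonium fragment ions (±0.05 amu). The reduced-end GlcNAc
   oxonium ion at 224.1118 amu is specific for reduced N- (and O-) glycan
   precursors.
2. **SNOG scoring.** Each spectrum gets a *SNOG score* — the relative
   intensity of the 224.1118 reporter within the scan,

   `SNOG = I(224.1118 ± 0.05) / TIC(scan)`,

   and each sub-structure-specific diagnostic ion analogously yields an
   *eSNOG score* with its own empirical cut-off. Spectra/bins with
   SNOG < 0.03 are rejected as non-glycan.
3. **Precursor histograms.** Charge-deconvoluted, deisotoped MS1 features
   are summed over the whole chromatographic run into fixed mass bins
   (1000–5000 amu on the [M+H]+ scale, bin width 0.1 amu), thresholded at
   a cumulative intensity of 5×10⁶, and filtered by the SNOG evidence of
   the MS/MS spectra attached to each bin.
4. **Annotation.** A canonical N-glycan composition database enumerated
   *in silico* under biosynthetic constraints (chitobiose + trimannosyl
   core, antenna/sialylation/fucosylation budgets) explains most bins;
   the rest are flagged *unknown* — the hunting ground for rare epitopes.
5. **Stratification.** eSNOG cut-offs classify bins (multi-label) into
   distal-fucosylated, Neu5Gc-, Neu5Ac-sialylated, alpha-galactosylated,
   oligomannosidic and undecorated categories, and screen for rare
   epitopes (HNK-1, sulfated HexNAc, fucosylated LacdiNAc, Lewis Y,
   di-sialyl Lewis C, O-acetylated sialic acids, Sda, sialyl-HexNAc).
6. **Isomer profiles.** Retention times are normalized to the Man5
   (Hex5HexNAc2) apex of the same run; per-mass elution profiles on a
   common relative-retention grid separate isobaric structure isomers
   (e.g. α2,3- vs α2,6-sialylation, Lewis X vs blood-group H).
7. **Comparison.** TIC-normalized sample×bin matrices, Pearson
   correlation, and Ward (`ward.D2`) clustering with Newick export.

A seeded synthetic-data generator (`sample_spec()`, `mouse_panel()`,
`simulate_sample()`) emulates all of the above with known ground truth, so
the entire pipeline is testable without instrument data.

## Worked example

```r
library(snoglyc)

# composition-level mass chemistry
precursor_mass("Hex5HexNAc4Fuc1Neu5Ac2")   # reduced [M+H]+
#> 2371.8638                                 (prints as 2371.9 at 1 dp)

# simulate a kidney-like sample and run the full pipeline
panel <- mouse_panel(seed = 7)
kidney <- panel[[3]]
out <- run_pipeline(kidney)     # simulate -> score -> bin -> threshold ->
                                # attach -> SNOG-filter -> annotate -> classify
out$report
#> <stratification report> kidney
#>   distal_fucose     40.4% of TIC (2 bins)
#>   neu5gc            18.3% of TIC (1 bins)
#>   neu5ac             0.0% of TIC (0 bins)
#>   alpha_gal          8.3% of TIC (1 bins)
#>   oligomannose      18.3% of TIC (1 bins)
#>   undecorated       14.7% of TIC (1 bins)

rs <- rare_screen(out$hist, out$scores)
rs[rs$tic_fraction > 0, c("feature", "tic_fraction", "n_bins")]
#>   feature tic_fraction n_bins
#> 1    hnk1   0.09174312      1
```

The fractions are TIC shares of the SNOG-filtered precursor histogram;
categories overlap (a bin can be both fucosylated and sialylated), so they
need not sum to 100%. The HNK-1 hit is the glucuronylated glycan the
generator planted; its precursor mass is not explainable by the canonical
composition database, exactly how rare epitopes surface in real data.

Real data enter through `read_mgf()` (MGF tandem spectra, e.g. from PEAKS
or MSConvert) and `read_features()` (charge-deconvoluted MS1 feature CSV,
DeCon2-style or the generic dialect). A command-line front end wrapping
these functions ships at `inst/cli/snoglyc.R`
(`profile` / `aggregate` / `annotate` / `stratify` / `isomers` /
`compare` / `simulate`).

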