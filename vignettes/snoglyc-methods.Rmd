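---
title: "Methods: scoring, binning and stratifying a non-targeted N-glycome"
author: "snoglyc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, binning and stratifying a non-targeted N-glycome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoglyc)
```

## Scope and model

`snoglyc` analyzes released, borohydride-reduced N-glycans measured by
PGC-LC-MS/MS in DDA mode. It works at **composition level**: a glycan is a
count vector over Hex, HexNAc, Fuc (dHex), Neu5Ac, Neu5Gc, HexA, sulfate
and O-acetyl. Topology and linkage are out of scope; isobaric structural
isomers are addressed chromatographically (see *Isomer profiles*).

All masses are monoisotopic. Residue masses are dehydrated sums of IUPAC
atom masses; an intact glycan adds one water (18.010565), reduction adds
two hydrogens (2.015650), and each charge adds one proton (1.007276):

* reduced precursor: `m/z = (Σ residues + 18.010565 + 2.015650 + z·1.007276)/z`
* B-type oxonium fragment: `m/z = Σ residues + 1.007276`
* reduced-end Y fragment: `m/z = Σ residues + 18.010565 + 2.015650 + 1.007276`

A note on the tabulated diagnostic masses: the reduced-end entries split
into two groups — some (183.0863, 312.1289, 328.1238) agree with the
alditol arithmetic above to the fifth decimal, while others (224.1118,
370.1697, 792.3234) sit ~0.0011 amu below it. We keep the chemically
correct +2 H alditol convention everywhere; the registry invariants
therefore use 0.002 amu tolerance for oxonium ions and 0.005 amu for
reduced-end ions. At the workflow's ±0.05 amu matching tolerance the
difference has no downstream effect.

## SNOG and eSNOG scores

The N-glycan reporter is the oxonium ion of the reduced-end GlcNAc,
224.1118 amu. For a spectrum $s$ with peaks $(m_i, I_i)$ and a diagnostic
ion $f$:

$$\mathrm{eSNOG}(s, f) \;=\; \frac{\sum_{|m_i - m_f| \le 0.05} I_i}{\sum_i I_i}$$

and SNOG is the eSNOG of the reporter. Two choices here were genuinely
open:

* **Denominator.** We use the scan TIC, making the score scale-invariant
  and bounded in [0, 1]; a base-peak denominator is available via
  `run_config(score_denominator = "base_peak")`.
* **Window aggregation.** All peaks in the ±0.05 amu window are *summed*
  rather than taking the maximum; this is robust to split centroids.

Per-spectrum scores are aggregated to mass bins as the intensity-weighted
mean (precursor intensity as weight when available, else uniform);
max-aggregation is available via `attach_spectra(aggregate = "max")`.
Bins with aggregated SNOG < 0.03, and bins with no attached MS/MS
evidence at all, are rejected. The 0.03 operating point ships as the
default registry cut-off; all per-ion eSNOG cut-offs are editable TSV
defaults (0.01 per non-reporter ion) meant to be recalibrated per
instrument, since diagnostic ions differ widely in their relative
intensities.

## Precursor mass grid

Deconvoluted MS1 features are summed into fixed bins of width 0.1 amu
(half width 0.05) spanning 1000–5000 amu on the [M+H]+ scale, centers at
`1000.0 + k·0.1`. Anchoring the grid at 1000.0 makes one-decimal printed
precursor masses coincide with bin centers and makes binning reproducible
and order-independent. Bins below a cumulative intensity of 5×10⁶ are
removed *before* SNOG filtering (the thresholding and filtering steps are
logged separately, so the order can be audited).

Each bin also stores its **intensity-weighted mean feature mass**, and
database annotation matches candidate compositions against that measured
mass rather than the grid center. This matters for masses that fall near
a bin boundary: the center can be up to half a bin width away from the
true mass, which would spuriously push edge-straddling compositions
outside the ±0.05 amu annotation tolerance.

## The canonical composition database

The enumeration rules are a package design choice (no authoritative rule
set exists at composition level): an N-glycan has a chitobiose core
(2 HexNAc) and trimannosyl core (3 Hex); non-core HexNAc forms up to 4
antennae plus at most one bisecting GlcNAc; each antenna may carry up to
two hexoses (Gal + alpha-Gal), with two additional unprocessed hybrid-arm
mannoses allowed for structures of at most two non-core HexNAc; sialic
acids are capped by the antenna count (`allow_disialyl = TRUE` grants one
extra for di-sialyl antennae); fucoses are capped at antennae + 1 (core);
the oligomannose/paucimannose series is Hex 3–9 with HexNAc 2, at most
one (core) fucose and no sialic acid. Extended residues (HexA, sulfate,
acetyl) are deliberately **excluded** from the canonical set: glycans
carrying them surface as *unknown* bins and are then mined via their
diagnostic ions, which mirrors how rare epitopes are actually discovered.
With the default bounds the enumeration yields on the order of 2×10³
compositions in ~1.1×10³ mass bins; the exact counts are reported by the
acceptance script as a diagnostic, not asserted, because they are a
direct function of the chosen rule bounds.

## Stratification

A bin receives a category label when **one** attached spectrum passes the
category ion's eSNOG cut-off (the quorum is configurable via
`min_spectra`; one is the permissive default because DDA often samples a
precursor only once). Categories are multi-label; `undecorated` is the
complement of the five positive categories. Sialic-acid categories accept
either the intact oxonium ion or its water-loss satellite (292.1027 /
274.0921 for Neu5Ac; 308.0976 / 290.087 for Neu5Gc). Oligomannose is the
one composition-based category (HexNAc 2, Hex 4–9 on the bin annotation),
since oligomannose glycans produce no distinctive decoration ion.

## Isomer profiles

Retention times are normalized as a **ratio** to the Man5 apex of the
same run — relative retention is the standard scale-invariant choice and
cancels uniform gradient drift. Profiles are built from MS1 features (not
MS/MS triggers) for quantitative fidelity, resampled by local summation
onto a fixed grid of step 0.005 relative-retention units spanning 0–3
(optional window-3 moving-average smoothing, off by default so that
profile area exactly equals the summed feature intensity). Profile
similarity is cosine similarity on the shared grid.

## Cross-sample comparison

Samples are compared as TIC-normalized bin vectors over the union of bin
centers (absent bins are zero): Pearson correlation and Ward (`ward.D2`)
clustering on Euclidean distances, exported as Newick with merge heights
as branch lengths. Clustering the normalized bin vectors directly is the
default; a t-SNE embedding in front of the clustering is deliberately not
the default because it is stochastic and adds nothing testable.

## The synthetic-data generator

`simulate_sample()` emulates exactly the data model the pipeline
consumes: per-glycan MS1 features distributed over isomer modes at
Man5-relative retention positions; DDA MS/MS spectra (charge 2) whose
peaks always include the 224.1118 reporter (SNOG ≥ 0.05 by construction)
plus one diagnostic ion per declared feature tag and the reduced-end Y
ion; and hexose-oligomer contaminant ladders (163.0601, 325.1129,
487.1657 oxonium series) whose spectra lack the reporter. Noise defaults:
intensity CV 10%, m/z jitter SD 0.005 amu (well inside the ±0.05
tolerance), RT jitter SD 1 s. Feature intensities are rescaled so each
glycan's total is exact, which is what makes TIC-fraction recovery a
sharp property. The observed mass of a feature cluster is drawn **once**
and shared by its MS1 slices and its MS/MS triggers — deconvolution
reports a consensus mass per envelope and the instrument isolates the
same ion it later fragments — so MS1 bins and their MS/MS evidence
co-locate even for masses that fall within the jitter of a bin boundary.

The generator does **not** emulate chromatographic peak shapes, isotope
envelopes, adducts, in-source fragmentation or co-isolation. Passing the
synthetic acceptance properties therefore demonstrates the correctness of
the scoring/binning/stratification logic under controlled noise, not
performance on raw instrument data; on real data the empirical eSNOG
cut-offs and the deconvolution quality dominate.

`mouse_panel()` fixes six tissue archetypes (serum-like Neu5Gc dominance,
brain-like Neu5Ac + bisecting + di-sialyl antennae, kidney-like antennary
fucose + HNK-1, pancreas-like alpha-Gal + sulfated HexNAc, seminal-
vesicle-like Lewis Y, liver-like heavy hexose-oligomer background at
~1.8×10⁸ total ladder intensity, which makes ~70–80% of its raw precursor
bins contaminant-only). Glycan intensities sit between 7×10⁶ and 4×10⁷ so
every planted bin clears the 5×10⁶ threshold. All randomness derives from
the spec's single seed; identical seeds give byte-identical outputs.

## Problem sizes and numerics

The shipped tests and the acceptance script run the six-tissue panel in
duplicate (12 samples, ~20 features and ~12 spectra per clean sample,
~150 features for the contaminated liver) and enumerate the default
database (~2×10³ compositions); the whole suite completes in well under a
minute on one CPU. Degenerate inputs are handled explicitly: all-zero
spectra raise an undefined-score error rather than returning NaN; samples
without any reporter-containing spectrum yield a flagged (`degenerate`)
profile report; empty histograms refuse TIC normalization; Man5 absence
raises an error instructing manual reference entry. Grid centers are
rounded to a canonical double so bin identities compare exactly across
code paths.

## Known limitations

* Composition-level only; no topology inference, no SNFG rendering.
* Core vs antennary fucose, and Lewis X vs blood-group H, cannot be
  separated by the 512.1974 ion alone — only by elution profiles against
  a user-supplied retention library.
* The default eSNOG cut-offs (0.01) are placeholders for per-instrument
  empirical calibration.
* The canonical database's composition count depends directly on the
  chosen biosynthetic bounds; it approximates, but does not reproduce,
  any particular published database.
* MGF and deconvoluted-CSV are the only input formats; vendor raw files
  and mzML must be converted upstream.
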