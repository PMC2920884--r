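---
title: "chromkit: models, algorithms and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromkit: models, algorithms and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromkit)
```

`chromkit` edits and analyzes nominal-mass GC/MS chromatograms. This
vignette is the package's own account of its models and algorithms: what
each component assumes, which parameters matter, and why the defaults are
what they are. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The object model and its unit conventions

A `chromatogram` is an ordered list of scans with strictly increasing
retention times, plus free-form metadata, an optional baseline (one value
per scan) and a peak list. A scan is one retention-time point holding a
centroided `mass_spectrum`: a set of ions keyed by nominal (integer) m/z
with double-precision abundances.

Two unit conventions run through everything and are deliberate choices
rather than facts about any file format:

* **Retention times are integer milliseconds.** Integer times give robust
  equality tests (round-trip comparisons can use `identical()`), cover
  realistic runs without overflow, and match the millisecond granularity of
  common acquisition software. Formats that store seconds (mzXML durations,
  ANDI `scan_acquisition_time`) are converted on import and export.
* **m/z values are positive integers** (nominal mass, the resolution of
  quadrupole and ion-trap instruments). Importers round fractional m/z
  half-up and merge collisions by *summing* abundances. In-memory editing
  via `set_ion()` instead *replaces* the abundance at an m/z (last write
  wins); `add_ion()` is the explicit merge-add path importers use. Keeping
  the two semantics separate avoids silent double-counting in user code.

Abundances are arbitrary intensity units, stored as doubles even where a
format supplies 32-bit floats.

Every filter and detector operates on a `chromatogram_selection`: a
retention-time window plus optional include/exclude ion sets. Operations
must leave scans outside the window bit-identical; the test suite asserts
this for every registered filter.

## File formats

Three formats are supported behind a converter registry with content-based
probing (`probe()` sniffs the XML root element or the NetCDF `CDF` magic
bytes and falls back to the file extension; unreadable content is reported
as `unknown`, never an error).

**mzXML.** A minimal mzXML 3.x subset: `msRun`/`scan` elements with peaks
base64-encoded in network byte order as interleaved (m/z, intensity)
floats. The writer defaults to `precision="64"`: 32-bit floats can only
represent ~7 significant digits, and the package's round-trip contract is
1e-9 relative on abundances, which only 64-bit payloads can honour.
Precision 32 remains available as a write option and both precisions (plus
zlib-compressed payloads) are accepted on read.

**ANDI-MS NetCDF.** The AIA variable layout: `scan_acquisition_time`
(seconds), `scan_index`, `point_count`, `mass_values`, `intensity_values`,
written as classic NetCDF-3. No NetCDF library is available to R in this
package's dependency footprint, so `chromkit` includes a small NetCDF-3
classic codec (`R/netcdf3.R`) covering exactly what ANDI files need:
fixed-size dimensions, global text attributes and non-record int/float/
double variables. The test suite cross-checks written files against an
independent NetCDF implementation.

**Native XML** (extension `.chrom.xml`), the only format that persists the
*entire* model — metadata, baseline and peak list — with full double
precision (`%.17g`). Schema, version `"1.0"`:

```
<chromatogram version="1.0">
  <metadata>  <entry key="...">...</entry> ...              </metadata>
  <scans count="N">
    <scan rt_ms="...">  <ion mz="..." abundance="..."/> ... </scan> ...
  </scans>
  <baseline> v1 v2 ... vN </baseline>                       <!-- optional -->
  <peaks>                                                   <!-- optional -->
    <peak start_scan=".." apex_scan=".." stop_scan=".."
          bg_start=".." bg_stop=".." area=".." integrator_id="..">
      <profile> p1 p2 ... </profile>
    </peak> ...
  </peaks>
</chromatogram>
```

A chromatogram "stored in a directory" is supported as recursive probing
(`list_importable()`); multi-file assembly of a single chromatogram is out
of scope.

## Filters

Filters are registered by id (`list_filters()`, `register_filter()`) and
return a modified copy of the chromatogram.

**Savitzky–Golay smoothing** (`savitzky-golay`; `window` odd ≥ 5, default
9; `poly_order` 2 … window − 2, default 2). The filter smooths the *TIC*
with the central Savitzky–Golay convolution coefficients (obtained from
`signal::sgolay`) and rescales each scan's spectrum by
`smoothed TIC / original TIC`, so relative ion patterns are preserved
exactly. Smoothing per ion trace would be equally defensible but costs
|ions| × |scans| fits and changes spectra shapes; the TIC convention is
cheap and keeps spectra usable for library matching afterwards. The first
and last `(window − 1)/2` scans of the selection are left unsmoothed rather
than smoothed with asymmetric edge filters, which would bias edge values;
the contract is simpler to state and to test. Zero-TIC scans are untouched
and negative smoothed values are clamped to 0. Savitzky–Golay filters
reproduce polynomials up to the fit order exactly, which is the basis of
the correctness tests.

**Background removal** (`remove-background`). For every m/z observed in
the window, the minimum of that ion's trace over the window (counting 0
where the ion is absent from a scan) is subtracted from that ion at every
scan, floored at 0. This implements a constant-background-per-fragment
model — the right shape for column bleed and carrier contaminants. It is a
per-ion filter by design: a TIC-level subtraction could not tell a bleed
ion from a coeluting analyte fragment.

**Mean normalization** (`mean-normalize`; `target` > 0, default 1000).
Multiplies every abundance in the window by `target / mean(TIC)`; errors on
all-zero selections.

**Baseline subtraction** (`subtract-baseline`) is registered as a filter
too; like all filters it is selection-local (only scans in the window are
scaled and their baseline zeroed), while `subtract_baseline()` on a
chromatogram applies it to the full range.

## Baseline detection

The reference detector (`moving-min`) is a centered moving minimum of the
TIC over `window_scans` (odd, default 31), optionally followed by a moving
average of the same width, clamped so the baseline never exceeds the TIC.
It was chosen as the reference because its behaviour has closed-form bounds
on synthetic inputs: on a peak-free linear drift `a + b·t` the recovered
baseline deviates by at most `|b| · window_scans · Δt / 2`, and under an
isolated peak narrower than the window it stays near the true background.
The smoothing pass runs only where the full window fits — truncated edge
windows would add lag beyond the documented bound. Baselines are TIC-level
(one value per scan), not per-ion; per-ion baselines would interact
confusingly with the per-ion background filter. Subtraction is
proportional: each spectrum is scaled by `max(TIC − baseline, 0) / TIC`,
consistent with the TIC convention used by the smoothing filter.
Alternative detectors plug in via `register_baseline_detector()`.

## Peak detection, integration and geometry

Detection and integration are separate actions by design: detectors of any
kind produce `Peak` objects with the area unset, and `integrate_all()`
applies one registered integrator to the whole list, recording the same
`integrator_id` on every peak, so areas are comparable regardless of which
detector found which peak. The acceptance suite integrates peak lists from
two different detectors and checks both the shared id and agreement of
every area with a quadrature oracle.

**First-derivative detector** (`first-derivative`). The TIC in the
selection is Savitzky–Golay smoothed (order 2, `smooth_window`, default 9);
candidates are the spans between the local smoothed-TIC minima flanking
each +→− zero crossing of the first derivative. The noise level is
`1.4826 · median(|d − median(d)|)` — a robust MAD estimate — computed over
the derivative of the **raw** TIC. Differencing removes slow baseline
trends; the median makes the estimate insensitive to the minority of scans
on peak flanks; and using the raw rather than the smoothed trace matters:
smoothing shrinks the derivative noise faster than it shrinks the peak-like
excursions it creates, so a smoothed-derivative estimate understates noise
and lets pure-noise bumps pass the threshold. A candidate is kept iff its
apex height above the local valley-to-valley background is at least
`snr_threshold` (default 5) times the noise level and its span is at least
`min_width_scans` (default 3). When two kept candidates share a valley scan
the later one starts one scan after it, keeping spans non-overlapping.

A `Peak` stores the **raw TIC profile** over its span together with the
linear background line joining the TIC at its start and stop scans (classic
valley-to-valley). Apex maximality is therefore judged *above the
background line*; integrators and geometry both work on
`profile − background`. Storing the raw profile keeps the stored numbers
identical to the chromatogram and makes "profile equal to the background
line integrates to zero" an exact identity.

**Trapezoidal integrator** (`trapezoid`). Trapezoidal rule over the actual
scan times on `max(profile − background, 0)`; areas are abundance·seconds.
On a sampled Gaussian the error is second-order in the scan interval, which
the tests verify against the closed-form partial area (via the Gaussian
CDF) so that span-truncation error cannot mask the convergence order.

**Geometry** (`compute_geometry()`). Flank tangents are least-squares lines
through the background-corrected profile points lying between 15% and 85%
of apex height on each flank. The band avoids both baseline curvature near
the valleys and the rounded apex, where a Gaussian's flanks stop being
straight; 15–85% is this package's convention, documented here. The width
at 50% height interpolates linearly between the bracketing scans on each
flank; the tangent width (`width_0`) spans the two tangents' intersections
with the background line. For a Gaussian, width₅₀ = 2.35482 σ; for a
triangle the tangents reproduce the sides exactly — both are test oracles.

## Spectrum comparison and identification

Two match factors are built in, both over the union of the two spectra's
nominal masses with zeros for missing ions, both in [0, 1], both symmetric:

* `cosine`: the normalized dot product Σaᵢbᵢ / (‖a‖·‖b‖); invariant under
  scaling either spectrum.
* `euclidean`: spectra are scaled to unit maximum abundance and the score
  is 1 − d/√(2n) over the n-point union, where d is the Euclidean distance
  (two vectors in [0,1]ⁿ are at most √n ≤ √(2n) apart, so the score stays
  in [0, 1]).

`identify_peak()` scores a query against every entry of an MSP library,
filters by `min_score` and sorts descending with ties in library order.
The library reader parses the NIST MSP text dialect (`Name:`,
`Num Peaks:`, m/z–intensity pairs separated by semicolons or whitespace)
and applies the same nominal-mass merge policy as the file importers.
Further measures plug in via `register_measure()`.

## Editing sessions

`edit_session()` owns a working copy of a chromatogram plus the active
selection. `apply_edit()` runs a registered filter on the selection;
`undo()`/`redo()` move between states. Reversibility is implemented with
**deep snapshots**, not algebraic inverses: smoothing and clamping filters
are not invertible, and R's copy-on-write semantics make snapshots cheap to
take (the full chromatogram is held in memory regardless). The costs are
memory proportional to the undo depth — which is why reversibility can be
disabled (`reversibility = FALSE`, stacks stay empty) and capped
(`undo_limit`, oldest snapshot dropped first). A new apply clears the redo
stack. Operations are atomic: filters work on a copy, so a failing
operation leaves model and stacks untouched. Observers registered with
`on_selection_changed()` are called, in registration order, after every
selection change, apply, undo and redo.

## The synthetic-data generator

`generate_chromatogram()` builds the TIC as
`offset + slope·t + Σ heightₖ · exp(−(t − apexₖ)²/2σₖ²)` plus Gaussian
noise on the background component, which is carried by a fixed background
ion (default m/z 44, a ubiquitous CO₂-like signal); each peak's share of
the TIC is spread over its ion pattern. Every fixture returns machine-
readable ground truth (true apex scans, heights, analytic areas
`height·σ·√(2π)`, baseline parameters), and identical seeds give
bit-identical chromatograms via an RNG-state-preserving seed wrapper.

The standard study condition (`three_peak_spec()`) is three Gaussian peaks
of σ = 10 scans and heights 1e5/8e4/1.2e5 on a background of 500 with noise
σ = 100, sampled at 1 scan/s over 300 scans — an apex signal-to-noise
around 1000, typical of well-behaved GC/MS peaks.

What the generator emulates: Gaussian elution profiles, linear baseline
drift, white detector noise, fixed relative fragmentation patterns. What it
does **not** emulate: peak tailing (exponentially modified Gaussians),
co-elution and deconvolution problems, concentration-dependent spectral
skew, mass-dependent noise, or realistic fragmentation chemistry. Passing
tests therefore demonstrate correctness of the *algorithms' contracts* on
well-posed inputs, not detector performance on pathological real-world
chromatograms.

## Numerical choices and problem sizes

* Round-trip contracts: retention times exact; abundances 1e-9 relative
  (hence 64-bit mzXML payloads and `%.17g` in native XML); cross-format TIC
  1e-6 relative.
* Degenerate inputs: empty spectra have total signal 0; zero-TIC scans are
  never rescaled; all-zero selections refuse normalization; `scan_nearest`
  ties resolve to the earlier scan; `order()`'s stable sort keeps library
  ties in library order.
* The MAD noise floor falls back to a machine-epsilon-scale value on
  noise-free fixtures so the SNR rule stays well-defined.
* Test problem sizes — 20–40-scan fixtures for format work, 300-scan
  three-peak fixtures (100 seeds) for detector recovery, 10-step random
  edit walks — were chosen so the full suite and the acceptance script each
  run in well under two minutes on a single core while still exercising
  every contract at its stated tolerance.

## Known limitations

Profile-mode (continuum) spectra, accurate mass, MSⁿ, mzML/indexed mzXML,
vendor binary formats, deconvolution-based detection, retention-index
calibration and whole-chromatogram fingerprint identification are all out
of scope. The native XML schema is original to this package and versioned
so later revisions can migrate it.
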