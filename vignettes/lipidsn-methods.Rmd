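---
title: "Direct-infusion glycerolipid annotation and acyl-editing route search: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct-infusion glycerolipid annotation and acyl-editing route search: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsn)
```

## The measurement model

Direct-infusion (shotgun) ESI-MS of polar glycerolipids on a
triple-quadrupole instrument gives four kinds of evidence, and the package
keeps them strictly separate because each resolves a different level of
structure:

* a **Q1 survey** sees intact ions and resolves nothing but mass;
* a **precursor-ion scan** for the phosphocholine cation (*m/z* 184.07)
  restricts the survey to choline-headed lipids (PC);
* a **neutral-loss scan** of 162 Da (one hexose) restricts it to the
  galactolipids MGDG and DGDG;
* a **product-ion scan** of one precursor reveals the acyl chains as
  carboxylate anions, and their positions through fragment intensities.

Annotation against calculated m/z therefore happens at the *composition*
level ("PC 36:6" — total carbons : total double bonds): acyl-chain isomers
of one composition are exactly isobaric, so the candidate index carries one
entry per (class, composition, scan mode, adduct). Chains and sn positions
are only ever claimed after a product-ion scan: the chain multiset is the
unique isomer from the pool whose carboxylates are all present, and the
position follows from the intensity convention below.

Masses are assembled element-wise from hard-coded standard monoisotopic
atomic masses (C 12 exactly, H 1.0078250319, O 15.9949146, N 14.0030740,
P 30.9737615, S 31.9720707, Na 22.9897693; the same table ships as
`inst/extdata/atomic_masses.tsv`). Ion m/z subtracts (adds) the electron
mass 0.00054858 for cations (anions); without this correction the
phosphocholine fragment would not round to the conventional 184.07 at four
decimals (it computes to 184.0733). Species formulas follow the
condensation bookkeeping

glycerol (C3H8O3) + head group + Σ acyl (free acid) − (n_acyl + n_head) · H2O,

which fixes the head-group blocks to phosphocholine C5H14NO4P,
phosphoethanolamine C2H8NO4P, glycerophosphate C3H9O6P, inositolphosphate
C6H13O9P, galactose C6H12O6 (twice-condensed digalactose for DGDG), and
sulfoquinovose C6H12O8S; PC(16:0/16:0) then totals C40H80NO8P,
733.5622 Da.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| matching tolerance | 0.01 | Da | unit-resolution QTRAP-class instrument; masses printed to two decimals |
| positional ratio r (generator) | 2.0 | — | sn-2 : sn-1 carboxylate intensity; a repo convention, see below |
| positional threshold τ | 1.5 | — | min max/min ratio to call sn-2; below it the call is ambiguous |
| isotopic overlap window | 0.02 | Da | flags pairs whose spacing is within 0.02 Da of the M+2 spacing 2 × 1.003355 |
| ¹³C abundance p | 0.0107 | — | binomial isotope envelope M, M+1, M+2 |
| acyl pool | 12 chains | — | 14:0, 16:0–16:3, 18:1–18:4, 20:4, 20:5, 22:6 |
| elongation cap | 20 | carbons | the elongation step modeled is C18→C20 on acyl-CoA |
| desaturation caps | 18:4, 20:5 | — | maximal unsaturation per chain length on PC |

The positional convention — the sn-2 acyl yields the more intense
carboxylate, with r = 2.0 in the generator and τ = 1.5 in the assigner —
is a deliberate, explicit package convention: the literature on
positional diagnosis by fragment intensity is instrument- and
collision-energy-dependent and no single ratio is canonical. Both numbers
are arguments, and the generator and assigner read the same constant, so
the pair stays internally consistent; swapping in a different rule only
touches `generate_product_scan()`/`assign_positions()`.

Default adducts per mode are also configurable. The precursor-184 scan is
matched as [M+H]+ and the negative Q1 as [M−H]−; the neutral-loss 162 scan
is *generated* as [M+H]+ but *matched* as both [M+H]+ and [M+Na]+, because
which adduct carries the galactolipid signal under acidified infusion
solvent is instrument-dependent. Negative Q1 candidates deliberately
include PE alongside SQDG/PG/PI: PE would be visible in that mode if
present, which turns "no PE detected" into a real negative result rather
than an artifact of gating.

## The synthetic-data generator

`packaged_fixtures()` encodes two rosters that emulate the polar-lipid
profile of an EPA-rich pennate diatom: a phospholipid fraction of 11 PC +
2 PG + 1 PI, and a glycolipid fraction of 8 MGDG + 5 DGDG + 3 SQDG. The
class-wise counts and the structural constraints are the fixed study
conditions; the exact chain identities are a package choice from the
default pool under those constraints (shipped as
`inst/extdata/fsolaris_roster.tsv`, a synthetic stand-in — the real
species lists exist only as figure labels):

* every MGDG, DGDG, SQDG, PG and PI carries a C16 acyl at sn-2;
* C18 acyls occur only at the sn-2 position of PCs (so some PCs are
  eukaryotic-type);
* every EPA-containing eukaryotic PC carries EPA at sn-1, and
  PC 20:5/20:5 is present;
* no PE species, no 22:6 (kept in the pool for candidate generation but
  absent from the rosters);
* within each detection mode all roster species are mutually non-isobaric
  by more than 0.02 Da, so zero-noise recovery is well-posed at the
  default tolerance.

Relative abundances were fixed once in (0.3, 1.0] to look like a survey
spectrum with an order-of-magnitude dynamic range; they carry no
information the pipeline uses beyond peak heights. Decoy (noise) peaks are
drawn uniformly over m/z 400–1000 but never within 0.05 Da of a true
peak, which keeps the zero-noise equivalence of annotation meaningful at
the 0.01 Da tolerance. All randomness is seeded per (fixture, scan mode),
so identical specifications produce byte-identical files.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: ionization-efficiency differences between
classes and chain lengths, in-source fragmentation, chemical noise
correlated with true peaks, isotope envelopes beyond M+2, and mass
calibration drift. Recovery rates on these fixtures are upper bounds.

## Numerical and algorithmic choices

* The candidate index is sorted by m/z and queried by binary search
  (`findInterval`); tests assert exact agreement with a linear scan.
* Ties within a peak's tolerance window are all reported, ranked by
  absolute error, and flagged `ambiguous_multi_candidate`; the profile
  counts such a peak once, toward the best-ranked candidate, so species
  counts are deterministic.
* A species seen in several scans or adducts is deduplicated on
  (class, composition) — profile counts are species counts, not peak
  counts.
* Isotopic M+2 overlap (a homologue one double bond more saturated sits
  9 mDa from the M+2 of its neighbor) is *flagged*, never deleted: the
  fractionation upstream of infusion, not the software, is the remedy.
* The route search is a layered breadth-first search over canonicalized
  pool states (sorted species strings plus a sorted acyl-CoA reservoir).
  States reached in earlier layers are closed; alternative equal-length
  paths are kept so that *all* minimal routes are returned, and a
  configurable state cap turns explosion into an explicit error. The
  single-witness EPA-reachability query uses the fully deduplicated
  variant and returns one shortest route.
* The acyl-CoA reservoir is non-depleting (catalytic amounts are
  unobserved); PC/LPC/DAG/TAG/FFA are stoichiometric. This keeps the
  state space finite and matches the qualitative nature of the scheme.
* Triacyl positional calls identify the sn-2 chain only; sn-1 vs sn-3 is
  reported unresolved, matching the reporting granularity of the
  measurement.
* Degenerate inputs: symmetric compositions (identical chains) are
  positionally resolved without ratios — which also means that at r = 1
  only species with distinct chains become ambiguous; an absent
  carboxylate gives an ambiguous call with a missing-fragment note; an
  empty spectrum annotates to an empty table; a target already present in
  the start pool yields one zero-length route.

## Design decisions that were genuinely open

* **Assembly rule edge cases.** The C16-vs-C18/C20 sn-2 rule says nothing
  about C14 or C22; the package classifies sn-2 carbons ≤ 16 as
  prokaryotic (the plastid pathway exports acyls up to C16) and ≥ 18,
  including 22:6, as eukaryotic.
* **PDAT/DGAT acylation position.** Both sn-3 and sn-1 acylation are
  described for these enzymes; the package acylates sn-3 by default with
  an sn-1 variant behind `pdat_position = "sn1"`.
* **Acyl-editing step counting.** The deacylation/reacylation cycle is
  counted as two elementary steps (PLA, then LPCAT forward); the search
  may also use the LPCAT reverse reaction as a one-step deacylation,
  which is why two distinct three-step routes to DAG 20:5/16:1 exist and
  both are returned.
* **ω-series and double-bond positions are not modeled.** Chains are
  (carbons : double bonds) only; "20:5" denotes EPA by convention. The
  ω3/ω6 desaturation branches collapse onto a single (c:d) → (c:d+1)
  operator, capped at 18:4 and 20:5.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
two fixtures of 14 and 16 species, survey scans of 3–13 peaks plus up to
40 decoys, candidate indexes of a few hundred entries (12-chain pool,
7 classes), product scans of 2–4 fragments, and route searches to depth 4
(exhaustively cross-checked against depth-4 enumeration) plus one
reachability query that closes in 7 steps. Everything completes in
seconds on one CPU.

## Known limitations

Composition-level annotation cannot distinguish isobaric chain isomers
without a product scan, and the isomer identification assumes the true
chains are in the configured pool. Quantification, adduct-abundance
modeling, ether/odd-chain/oxidized lipids, sphingolipids and multiply
charged ions are out of scope. The reaction network is qualitative — no
kinetics or fluxes — and galactosyltransfer onto DAG is not simulated;
DAG products are reported as the available precursors for chloroplast
lipids.
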