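---
title: "Hierarchical multi-scale models of the physical genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-scale models of the physical genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromo3d)
```

## The model

chromo3d represents a genome's physical structure as a hierarchy of four
scales, each a coarse view of the one below it:

1. **Nuclear scale.** Each chromosome is a giant-loop random walk: chromatin
   is organised into Mbp-scale loops attached to a backbone, and each loop
   is modelled as a closed random walk of fixed-length steps confined to the
   nuclear sphere. One walk step represents `step_bp` (default 30 kbp) of
   sequence and `step_length_nm` (default 150 nm) of space.
2. **Fiber scale.** The putative 30 nm chromatin fiber: the nuclear polyline
   subdivided to one point per `bp_per_point` (default 1,200 bp, roughly six
   nucleosome repeats), with small isotropic jitter.
3. **Nucleosome scale.** Nucleosome core particles (NCPs) placed along the
   fiber, by default tiling the chromosome with a `repeat_bp` = 200 bp
   repeat: a 147 bp wrap plus a 53 bp linker. Each record stores a start
   coordinate, its linker length, and a local orthonormal frame whose third
   axis is the NCP cylinder axis.
4. **DNA (atomic) scale.** Per-bp coordinate frames and pseudo-atoms.
   This scale is *never stored*: it is synthesized on demand from the
   nucleosome records, which is the key to compact whole-genome storage.
   Wrapped bp follow the canonical NCP superhelix (1.65 left-handed turns,
   radius 4.18 nm, pitch 2.39 nm over 147 bp); linker bp interpolate
   between the flanking wrap endpoints with spherically interpolated
   orientation; DNA outside the outermost nucleosomes extends as straight
   B-DNA (0.34 nm rise, 10.5 bp/turn).

Only the three coarse scales are serialized, as gzip-compressed XML with a
block index for range queries. Storing every atom instead would cost
`3e9 bp x 20 atoms/bp x 3 coords x 4 bytes` = 720 GB for a human genome;
the hierarchical store measures about 0.2 bytes/bp on a 10 Mbp fixture,
i.e. roughly 0.6 GB extrapolated to 3 Gbp — a better than 1000-fold
reduction (`storage_stats()` reports the exact numbers for any store).

## Coordinate conventions

All internal genomic coordinates are 0-based half-open, the UCSC BED
convention. The CLI-facing helpers (`parse_range()`, the command layer)
accept the 1-based inclusive `chrom:start-end` strings used by genome
browsers and figure legends and convert immediately. WIG declarations are
1-based per the format definition and converted on parse. All lengths are
nm internally; PDB and XYZ exports convert to Angstrom (x10).

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `loop_size_bp` | 3,000,000 | bp | giant-loop size at nuclear scale |
| `step_bp` | 30,000 | bp | sequence per nuclear walk step |
| `step_length_nm` | 150 | nm | spatial walk step |
| `nucleus_radius_nm` | 5,000 | nm | confining sphere |
| `bp_per_point` | 1,200 | bp | fiber resolution |
| `jitter_nm` | 3 | nm | fiber jitter sd |
| `repeat_bp` | 200 | bp | nucleosome repeat (147 wrap + linker) |
| `nucleosomes_per_turn` | 6 | — | solenoid density along the fiber |
| `radius_nm`, `pitch_nm`, `turns` | 4.18, 2.39, 1.65 | nm, nm, turns | NCP superhelix |
| `rise_nm`, `bp_per_turn` | 0.34, 10.5 | nm, bp | B-DNA helix |
| `max_dna_bp` | 100,000 | bp | largest DNA-scale window |

The nuclear-scale defaults are literature-plausible values for a polymer
model of interphase chromatin rather than measured constants; they are
recorded in every manifest and freely configurable. The NCP and B-DNA
defaults are canonical crystallographic/solution values. The fiber jitter
default (3 nm) is deliberately small against the 15 nm fiber radius so
that each fiber point remains a faithful anchor for the roughly six
nucleosomes of its segment — the package treats "every fiber point is
within one fiber radius of the centroid of its anchored nucleosome
origins" as a structural contract and tests it.

## Numerical choices

* **Closed loops.** A giant loop must satisfy two constraints at once:
  every step has exactly `step_length_nm` length, and the loop returns
  exactly to its anchor. We generate such closed equilateral walks by
  alternating projection between the zero-sum constraint and the sphere of
  fixed step lengths, iterating to a closure residual below 1e-9 of a
  step. Loop accounting is: each full loop consumes
  `loop_size_bp / step_bp` steps, one backbone step joins consecutive
  loop anchors, and any trailing remainder of the chromosome forms an
  open partial walk, so the total step count is exactly
  `ceil(length / step_bp)`.
* **Confinement.** Whole loops are resampled (up to 60 draws) until they
  fit in the nuclear sphere, with a radial contraction fallback; backbone
  and tail steps use per-step rejection with a reflection fallback. This
  keeps the walk seedable and step lengths exact in all but pathological
  geometries.
* **Superhelix centering.** With 1.65 (non-integer) turns, the mean of
  147 bp positions on an axis-centered superhelix sits about 0.7 nm off
  the axis. DNA synthesis therefore centers each wrap so that the bp
  centroid coincides with the stored record origin, making the record
  origin the literal centroid of its DNA — the property the cross-scale
  tests assert (to 0.5 nm). `wrap_superhelix()` exposes both conventions
  (`center = "axis"` for pure geometry, `"centroid"` for synthesis).
* **Linker blending.** Linker DNA is a straight segment between the
  flanking wrap endpoints: origins interpolate linearly, orientations
  spherically (quaternion slerp). There is no bending-energy model; the
  linker is a smooth geometric splice, not a mechanical prediction.
* **Store precision.** Positions are written at 3 decimals in nm
  (0.5 pm quantization, far below any geometric tolerance used);
  orientation unit vectors at 6 decimals, and frames are re-orthonormalized
  on read so frame invariants hold to 1e-9 after a round trip. Compression
  is plain gzip via `memCompress` with no embedded timestamps, so writing
  the same model twice is byte-identical — stores are diff-stable.
* **Chunked determinism.** `synthesize_frames()` computes each wrap,
  linker, or flank purely from the records that bound it, so querying a
  range in chunks concatenates to bitwise-identical coordinates.
* **bp conservation.** With default tiling from position 0,
  `sum(wrap + linker) == chromosome length` exactly (the final linker
  absorbs the remainder). With explicit user positions the identity
  becomes `first_start + sum(wrap + linker) == length`, and the leading
  gap is tracked as a leading linker element for annotation purposes.

## What the synthetic generators emulate

`synth_genome()`, `synth_nucleosome_positions()` and `synth_tracks()`
generate every input the toolkit consumes: chromosome tables (and
optionally random FASTA), statistically plausible nucleosome positions
(truncated-normal repeat lengths, clamped to keep a minimum 10 bp linker),
and annotation tracks — single-bp SNPs, TSSs with zero-mean normal signed
expression log-ratios, binding sites a configurable fraction of which is
planted within the proximity threshold of a TSS, and fixedStep WIG scores.
Each generator is a pure function of its arguments and seed.

What they do *not* emulate: sequence-dependent nucleosome positioning,
clustering of regulatory sites, expression correlation structure, or any
real genome's karyotype. Passing tests therefore demonstrate that the
geometry, bookkeeping, formats and statistics of the pipeline are correct
under stated conditions — not that the model reproduces measured chromatin
conformation. The model is descriptive above the NCP scale by design and
can ingest externally inferred structures (e.g. conformation-capture-based
paths) as replacement coarse scales.

## Demonstration statistics

* **Rotational phasing** (`snp_phase_report()`): a SNP at offset `k` from
  its wrap start presents phase `(k * 360 / 10.5) mod 360` degrees around
  the helix, plus an axial coordinate along the NCP axis. Linker SNPs are
  reported as such with the nearest record.
* **Proximity rule** (`proximity_classify()`): a binding site is "near" a
  TSS iff the minimum bp gap between the site midpoint and any TSS is
  strictly below 10 kbp. The midpoint convention is a design decision (the
  measurement point was genuinely open); the threshold and strictness are
  configurable arguments.
* **Signed coloring** (`colorize()`): positive values shade toward green,
  negative toward red, zero is neutral gray, and saturation is monotone in
  `|value|` with the maximum absolute value fully saturated.

## Design choices that were genuinely open

* The exact giant-loop parameters of the representative model are not
  published; we ship configurable literature-scale defaults and record
  them in the manifest rather than claiming fidelity to any one dataset.
* "20 atoms/bp" is implemented as a reduced two-strand representation
  (10 pseudo-atoms per strand tracing phosphate, sugar and base positions
  at B-DNA backbone radius and groove asymmetry). The template is plain
  data and can be replaced by any user template, including an all-atom
  one, without touching the geometry code.
* The store schema is a clean-room design; it makes no file-level
  compatibility claim with any other tool's XML dialect.
* PDB exports re-center selections on their centroid by default because
  model coordinates live in nuclear space (tens of thousands of Angstrom),
  which would overflow the fixed 8.3 coordinate columns; pass
  `center = FALSE` to keep absolute coordinates for small models.

## Problem sizes used in the test-suite

The package's own checks run on synthetic fixtures sized for sharp
statistical power at desk scale: 2-20 kbp toy chromosomes for exact
bookkeeping identities, a 1 Mbp chromosome for cross-scale consistency
(every one of its ~5,000 nucleosomes is checked), 200 replicates of
1,000-step walks for the ideal-chain statistic, and a 10 Mbp chromosome
for storage extrapolation. The storage figures extrapolate per-bp cost
measured at 10 Mbp to 3 Gbp; per-bp cost is essentially scale-free here
because the store is dominated by the nucleosome records (one per 200 bp).

## Known limitations

* No chromatin mechanics, energetics or dynamics: the model is geometric.
* No inter-chromosome excluded volume; territories may overlap.
* Histone proteins are not modelled (NCPs render as cylinders); no
  all-atom nucleotide chemistry.
* Linker DNA ignores bending stiffness; kinked linkers between distant
  wrap endpoints are geometrically smooth but not mechanically relaxed.
* `bigWig`/`bigBed` binary tracks, GFF, and track hubs are out of scope;
  BED, WIG and bedGraph cover the supported annotation inputs.

## A complete round trip

```{r example, eval = FALSE}
genome <- synth_genome(lengths = 2e5, seed = 1)
model <- build_genome_model(genome, seed = 1)

dir <- tempfile("model")
write_model(model, dir)
storage_stats(read_model(dir))

tracks <- synth_tracks(2e5, n_snps = 4, seed = 2)
snp_phase_report(tracks$snps, model$chromosomes$chr1$nucleosomes)

atoms <- synthesize_dna(model, parse_range("chr1:1-147"))
write_pdb(atoms, file.path(dir, "ncp.pdb"))
```
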