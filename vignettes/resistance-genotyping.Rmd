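---
title: "Codon-level Vkorc1 resistance genotyping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level Vkorc1 resistance genotyping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkorcall)
library(dplyr)
```

## The problem

Anticoagulant rodenticides (ARs) kill by inhibiting VKOR, the vitamin K
epoxide reductase complex; point mutations in *Vkorc1*, the gene encoding its
main subunit, blunt anticoagulant binding and are the dominant mechanism of
heritable resistance in brown rats (*Rattus norvegicus*), black rats
(*R. rattus*) and house mice (*Mus musculus*). Resistance surveys genotype
wild-caught rodents by Sanger-sequencing the three *Vkorc1* exons, assembling
the coding sequence (CDS) per animal, and tabulating codon-level variants per
species. `vkorcall` implements that pipeline end to end, plus a geometric
triage of mutations against a protein-ligand complex that decides which
mutations are worth docking simulations.

## Sequence model and its assumptions

**Coordinates.** Everything is expressed in CDS coordinates: 1-based,
counted from the first base of the start codon. Codon *i* occupies positions
$3i-2..3i$ and the amino-acid index equals the codon index, so "codon 139"
is residue 139. The reference set (`load_reference()`) is the coordinate
frame: per species one unambiguous CDS whose length is divisible by 3 and an
exon partition that tiles it exactly. Both rat species are genotyped against
a single shared rat reference — a deliberate convention that makes
species-correlated codon usage visible as high-frequency "variants" rather
than hiding it in two reference frames; the one amino-acid difference
between the two rat wild types (codon 90, Ile in the brown rat and Leu in
the black rat) is carried in the catalogue as a *species-fixed* site rather
than as a polymorphism.

**Zygosity from IUPAC codes.** A diploid Sanger consensus encodes a
heterozygous site as an ambiguity symbol (double peak A/T is written W). The
caller inverts that encoding and nothing more:

* unambiguous non-reference base → homozygous alternate;
* two-base symbol containing the reference base → ref/alt heterozygote;
* anything else (two-base symbol excluding the reference, or a 3–4-base
  symbol) → *complex*: reported, but excluded from frequency counts;
* `N` → no-call, skipped with a warning.

There is no peak-height or read-depth model: the input is an already-called
consensus, and the package does not pretend to information it does not have.
A codon holding two or more heterozygous positions cannot be phased from a
single consensus; all candidate alleles are listed, `phase_ambiguous` is
set, and the codon is excluded from single-mutation counts with a report
line. Compound heterozygosity *across* codons (e.g. mice carrying both
L128S and Y139C) is reported per animal; phase across codons is unknown and
stated as such.

**Labels are derived, never trusted.** Mutation identity is keyed by
(species, codon, reference codon, alternate codon). Display labels like
`Y139F` are always re-derived with the standard genetic code. Printed labels
in the shipped catalogue are retained for comparison and flagged when they
disagree with translation — the shipped catalogue contains exactly one such
row, the codon-12 silent change whose source table prints an Ala/Ala label
although both codons (CGG/CGA) encode arginine; the derived label `R12R` is
used throughout and the discrepancy is surfaced by a warning and a
`label_consistent = FALSE` flag rather than silently "fixed".

## Exon location and assembly

Each amplicon contains one exon plus non-exonic flanks, on an unknown
strand. The reference exon is aligned semi-globally (free end gaps on the
amplicon side) against both strands, scoring +1 for any IUPAC-compatible
pair — so heterozygous positions never penalise placement — and −1
otherwise, with gap opening −5 and gap extension −1. The higher-scoring
strand wins; an exact tie keeps the forward strand with a warning.
Acceptance requires identity (compatible positions over the reference exon
length) of at least 0.90 **and** a gap-free alignment:

* identity below threshold on both strands → `exon not found`;
* gapped best alignment at acceptable identity → `indel-containing
  amplicon`, and the sample is quarantined. Every catalogued resistance
  variant is a substitution, so indel calling is deliberately out of scope;
  quarantining is safer than calling through a frame problem.

The 0.90 threshold and the gap penalties are declared defaults, not values
inferred from any particular survey; they are exposed as parameters. The
brute-force property tests score *every* window on both strands and require
the aligner to agree exactly, and random padding up to 200 nt and random
strand flips must leave the extraction bit-identical.

Assembly concatenates the three extracted exons in exon order and is keyed
by `sample_id` everywhere — the historical practice of keeping three FASTA
files "in the same sample order" is replaced by explicit keys so order bugs
cannot exist.

Species identification from COI barcodes is a minimal percent-identity
classifier: global alignment against a species-labelled panel, assignment at
≥ 98% identity (a conventional barcode-gap threshold, configurable), ties
broken by panel order and flagged.

## Cohort statistics

For each species and mutation key the summary counts homozygous and
heterozygous carriers; the frequency cell is
$100 \cdot (\mathrm{homo}+\mathrm{het})/n$ over the species census
(animals with no variants still count in the denominator). Resistance
prevalence is the fraction of animals carrying ≥ 1 variant whose catalogue
status is `resistance_associated` — *only* that status: novel and
literature-known-but-unproven mutations are listed, never counted toward
prevalence. Each animal counts once regardless of how many resistance
variants it carries.

Printed values use half-up rounding at a per-species precision (default one
decimal for rats, two for mice, matching the convention of the tables this
layout mirrors; configurable via `digits`). Full-precision values are kept
alongside in the TSV output, and prevalence is rounded to two decimals.

## Structural triage

The triage decision for a mutated residue is purely positional:

* `read_structure()` parses a PDB (first model; alternate locations resolved
  by highest occupancy, ties to altloc A) and tags a ligand chosen by
  configuration — the ligand's residue name is never hard-coded;
* `ligand_neighborhood()` returns protein residues with any heavy atom
  within a cutoff (default 5 Å) of any ligand heavy atom; hydrogens are
  ignored everywhere, since predicted models lack them;
* `kabsch_superpose()` is a reflection-free least-squares rigid
  superposition (SVD of the cross-covariance, determinant forced to +1) with
  atom pairing by residue number (configurable offset) over a backbone,
  sidechain-heavy-atom or all-heavy-atom selection — the exact selection
  behind any published binding-site RMSD is survey-specific, so it is a
  parameter, not a constant. Collinear point sets are an error, and the
  reported transform reproduces the reported RMSD to machine precision;
* `detect_hbonds()` lists polar (N/O/S) heavy-atom pairs within 3.5 Å —
  a distance-only criterion with no angle term, again because the models
  carry no hydrogens;
* `triage_mutations()` marks a residue `suitable` for docking iff it is in
  the contact set, otherwise `not_suitable` with the annotated structural
  region (cap domain, ER-luminal, cytoplasmic interface, membrane) as the
  reason. Region boundaries are a config table; the shipped
  `vkor_regions_illustrative.tsv` is an illustrative annotation of VKOR
  topology, not a published one.

Contact sets and H-bond lists are verified against $O(n^2)$ all-pairs scans,
and the Kabsch RMSD against an independent rotation-grid +
Nelder–Mead minimiser (agreement within $10^{-3}$ Å), on toy structures
written by the package's own fixture writer.

## The synthetic cohort generator

`build_fixture_spec()` encodes a deterministic 67-animal cohort — 24 brown
rats, 35 black rats, 8 mice — whose per-animal genotype assignments
aggregate exactly to the published per-species homozygote/heterozygote
counts and honour the published co-occurrence constraints: no brown rat
carries both R61W and Y139F, exactly three mice are heterozygous for both
L128S and Y139C (hence 6/8 resistant mice), and the black-rat silent
background (A12A, A41A, L94L, I107I, T137T, A143A …) runs at the printed
rates. Which *individual* animal carries which silent variant is not
published; those joints are fixed arbitrarily but deterministically, and the
constructor re-counts its own output against the declared aggregates and
fails loudly on any mismatch.

`simulate_cohort()` turns a spec into data: planted genotypes are applied to
the reference CDS (heterozygotes as IUPAC codes, exactly as a Sanger
consensus would show them), the CDS is cut at exon boundaries, each exon is
wrapped in random padding (default 20–60 nt per side) and half the amplicons
are reverse-complemented; a COI barcode per animal diverges < 1% from its
species panel record. Identical seeds give byte-identical output.

What the generator deliberately does **not** emulate: chromatogram noise and
base-calling errors, indels, primer sequences, contamination, or real
GenBank sequence content — the shipped references are synthetic frames with
every catalogued wild-type codon planted at its published position inside
otherwise random stop-free codons (filenames say `synthetic_`). Passing the
round-trip tests therefore demonstrates that the pipeline's logic is exact
on clean consensus input; it says nothing about trace quality, and real
surveys must still gate their reads upstream.

## Numerical and degenerate-input choices

* Half-up decimal rounding (`floor(x·10^d + 0.5)/10^d`) for printed cells;
  ties like 62.5 at 0 decimals round up.
* Strand-score ties prefer `+` with a warning; altloc occupancy ties prefer
  `A`.
* Stop-creating substitutions are classified `nonsense` even though none
  occur in the shipped catalogue.
* Empty cohorts summarise to empty tables with prevalence 0 over the census.
* Reference validation errors name the offending position (ambiguity code,
  tiling gap/overlap, non-multiple-of-3 length).

## Problem sizes used by the shipped tests

The test suite regenerates everything: the full 67-animal fixture pipeline
runs once per session; the round-trip property sweeps 20 seeds of six-animal
cohorts with padding up to 200 nt; oracle comparisons use amplicons of a few
hundred nt and toy structures of ≤ 100 atoms. These sizes were chosen as the
smallest that exercise every code path, including both strands, all three
exon partitions and every catalogue row.

## Known limitations

* No indel calling, no quality scores, no population phasing.
* Zygosity trusts the consensus caller's ambiguity codes entirely.
* The percent-identity species classifier is not a placement method; it
  assumes the panel contains the true species.
* Docking itself (grids, search, binding energies) is explicitly out of
  scope; the structural module ends at the suitability decision.
* The shipped region annotation is illustrative; real triage reasons should
  come from a curated topology for the structure in use.
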