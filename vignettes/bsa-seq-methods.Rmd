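---
title: "Mapping a dominant locus by BSA-Seq: models and methods"
author: "bsaseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant locus by BSA-Seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaseqr)
```

## The experimental design this package models

bsaseqr analyses bulked segregant sequencing (BSA-Seq) of an F2 population
from a biparental cross, phrased throughout for the system it was built
around: leaf trichomes in Chinese cabbage (*Brassica rapa* ssp.
*pekinensis*). A hairy parent (W30-like) is crossed to a glabrous parent
(082-like); the F1 is selfed; the trait is controlled by a single dominant
allele, so the F2 segregates 3 hairy : 1 glabrous. Equal-mass DNA pools of
50 trichome-leaved plants (the AL bulk) and 50 glabrous plants (the GL
bulk) are sequenced to ~78x and ~76x alongside the parents (~27x), variants
are called jointly, and the analysis starts from that VCF.

## The statistic

At each biallelic site the **SNP-index** of a bulk is the fraction of its
reads carrying the hairy parent's allele, and

$$\Delta(\text{SNP-index}) = \text{index}_{AL} - \text{index}_{GL}.$$

The index is read-frequency based, not genotype-call based: a pool of 50
plants has an allele *frequency*, not a diploid genotype. Under a dominant
single-gene model the expectations are sharp. Among hairy F2 plants the
causal genotypes are 1/3 homozygous and 2/3 heterozygous, so the AL bulk's
frequency of the hairy allele at a fully linked marker is
$(2\cdot\tfrac13 + 1\cdot\tfrac23)/2 = \tfrac23$; the GL bulk is entirely
homozygous recessive, frequency 0. Hence $\Delta \approx 2/3$ at the locus
and $\Delta \approx 0$ at unlinked markers, decaying with recombination
fraction $r$ as $\Delta(r) = \tfrac23 - \tfrac43 r$. Orientation matters:
deltas are signed so that linkage to the hairy allele is positive, which is
what makes a right-tail threshold meaningful. Sites where the hairy parent
is heterozygous cannot be oriented and are dropped (and counted). The same
formula applied to indel-class records is the indel-index; the two streams
are analysed in parallel.

## Marker screening

Before index computation, sites are screened in a fixed order:
missing bulk depths (index undefined); per-bulk total depth < 5x
(`min_bulk_depth`, the conventional floor for pooled calls); parents, when
present, not homozygous for different alleles; and bulk genotype
consistency — a site is kept only when the two bulks' calls differ or at
least one bulk is called heterozygous, since a segregating pool should not
look like two identical homozygotes. Bulk genotypes come from the VCF `GT`
when present, otherwise from an allele-depth majority vote with ties called
heterozygous. The per-rule rejection tally is part of the output, and
screening is idempotent.

## Windows, smoothing, thresholds, regions

Per-site deltas are noisy (binomial read sampling at ~78x gives a per-site
SD near 0.08), so the genome scan aggregates and smooths:

* **Sliding windows in marker rank**: 5 consecutive markers advancing by 2
  (`window_size`, `step`), the classic QTL-seq scheme. A trailing partial
  window is emitted whenever markers would otherwise be uncovered, so
  scaffolds carrying one or two markers remain visible.
* **Per-chromosome LOESS** (locally linear, exact "direct" surface) of the
  window mean delta on the window midpoint. Chromosomes with fewer than
  three windows keep their raw means, and the span is raised to cover at
  least four windows so tiny scaffolds stay fittable. The default
  `loess_span = 0.3` is a deliberate compromise: smaller spans track the
  peak with less attenuation but let read noise through; larger spans
  flatten the peak and drag the empirical threshold down. At the default
  fixture scale (about 200 windows per chromosome) 0.3 suppresses window
  noise to roughly the 0.01 level while keeping the smoothed peak near 0.6.
* **Threshold**: either a fixed delta cutoff (`fixed_threshold`, default
  0.99 — the published fixed rule for this experiment) or, by default, the
  empirical right tail: the $(1 - 0.001)$ linear-interpolation quantile of
  the genome-wide smoothed deltas. The two published rules (0.99 fixed and
  a 0.1%-tail value of 0.525) are not reconcilable on one scale, so both
  are first-class and the run manifest records which was used. On default
  simulations the empirical threshold lands near 0.6 — the same scale as
  the published 0.525.
* **Region extraction is per marker** (`extract_level = "marker"`): a site
  whose delta exceeds the threshold is significant, and significant sites
  closer than `merge_gap_bp` merge into one region spanning the outermost
  member sites. This is the reading under which the reported region
  geometry reproduces exactly: two significant markers 7 bp apart give a
  7-bp region, while a lone significant marker is widened to ±50 kb
  (`flank_bp`), giving 100,001-bp regions whose starts can be negative near
  a scaffold edge (reported unclamped, with a clamped column alongside;
  lengths always come from the unclamped inclusive span,
  `end - start + 1`). Window-level significance (`extract_level =
  "window"`) is retained as an option, but with a 0.1% tail over roughly a
  thousand windows it marks a single window by construction, and the LOESS
  argmax sits a median 130–280 kb from the true locus in simulation — too
  imprecise to contain the locus reliably.

Two numerical conventions worth stating: significance is strict
(`statistic > threshold`), and the flank is a reporting convention — on the
unflanked spans (`span_start`/`span_end`) raising the threshold can only
shrink coverage, which is the monotonicity property the tests assert. The
flanked report can grow locally when a two-site cluster loses a member and
the survivor gains its ±50 kb, which is why the invariant is stated on raw
spans.

`merge_gap_bp = 500000` was fixed by a design study with the simulator:
500 kb is about 2 cM at the default marker density — comfortably inside the
scale over which linkage holds significant markers together, and well below
the megabase-scale separations that must remain distinct regions (the
reported experiment keeps two regions 1.46 Mb apart on one chromosome
unmerged). At 250 kb, clusters split across chance gaps and the true locus
falls between fragments in more than 10% of simulated experiments; at
500 kb recovery is essentially complete.

## Annotation

A gene belongs to a region when their inclusive intervals share at least
one base (any-overlap, not containment). GO classification is consumed from
a user-supplied gene-to-term table — never computed by sequence search,
which is database-version dependent — and tallied per namespace
(biological process, cellular component, molecular function), with
unannotated candidates listed rather than counted. The
trichome-morphogenesis term GO:0010090 is flagged in the tally when
present, since it is the headline annotation for this trait.

## Supporting statistics

`segregation_test()` is the plain Pearson chi-square (df = 1, no continuity
correction — the field default for segregation counts) against candidate
ratios, selecting the best as the largest p-value; on the observed 212:82
it retains 3:1 with $\chi^2 = 1.31$, $p = 0.25$. `relative_expression()`
implements $2^{-\Delta\Delta C_t}$ with technical replicates averaged per
sample before $\Delta C_t$, normalization to a reference gene (BrActin-like)
and an explicit calibrator that is never defaulted, plus Tukey HSD grouping
letters at $\alpha = 0.05$ computed on untransformed relative expression by
default (a log2 option exists; the published scale is unstated). The letter
display uses the insert-and-absorb algorithm directly on the `TukeyHSD`
p-values, with a zero-residual-variance branch so degenerate inputs (all
values identical) still yield letters instead of `NaN`s.

## What the simulator emulates — and what it does not

`simulate_bsa()` generates the full experiment: F2 gametes from
heterozygous F1 parents with Poisson crossover counts under the Haldane map
(no interference), marker genetic positions proportional to physical
positions, dominant phenotype assignment at the causal locus, 50+50
phenotype-selected bulks, Poisson total depth and binomial allele depth
with a symmetric per-read miscall probability, and homozygous-opposite
parents. Defaults are the study's conditions: 294 F2, bulks of 50, depths
78.9/76.2x (parents 27.5/26.8x). Free choices, fixed once: a genome of
three 25-Mb/100-cM chromosomes plus two 1-Mb/4-cM scaffolds with 400
markers each (2,000 total, so the scaffold-versus-chromosome reporting
paths are both exercised), error rate 0.001 (Illumina scale), 5% indel
markers, and caller-like bulk genotype calls at 0.25/0.75 alt-fraction
cuts.

The simulator does **not** model mapping bias, duplicated or repetitive
regions, indel realignment artefacts, variable marker density, crossover
interference, segregation distortion, or mis-phenotyping. Passing the
simulation-based tests therefore demonstrates that the inference chain is
correct under the stated genetic model at realistic depth and population
size — not that real libraries are free of the alignment-level artefacts
the screening rules only partially absorb.

Problem sizes used in the shipped tests: the recovery study runs 100
simulated experiments at the full default design (about 0.3 s each); unit
tests use a down-scaled cross (3 sequences, 60 markers each, 80 F2) where
the full design adds nothing.

## Known limitations

* No confidence bands for delta under the null (the simulation-band
  approach of the wider QTL-seq literature) — only the fixed and
  empirical-tail thresholds of this design.
* The "average p-value ≤ 0.01" phrasing sometimes attached to such scans
  has no defined null here and is deliberately not implemented.
* Multi-allelic sites are decomposed to biallelic records at read time;
  genotypes touching a third allele become missing for each decomposed
  record rather than being re-phased.
* GO enrichment (hypergeometric) statistics and ortholog detection are out
  of scope; the package tallies, it does not test, functional annotation.
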