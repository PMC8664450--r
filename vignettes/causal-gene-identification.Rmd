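---
title: "Identifying causal essential-gene mutations from complementation-pair WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying causal essential-gene mutations from complementation-pair WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmap)
```

## The model

A chemically mutagenized (EMS) strain carries one causal recessive lesion
and a large load of strain-private background mutations. When the lesion
is lethal or sterile it is maintained over a balancer chromosome, so the
sequenced genome is heterozygous at the causal site. A single genome
therefore cannot, by itself, distinguish the causal mutation from the
background. Two independently derived alleles of the *same* gene — members
of one complementation group — change the picture: both strains must
damage the same gene, while their backgrounds are essentially disjoint.

`screenmap` formalizes this as a per-strain reduction followed by a
per-group intersection:

* **Zygosity.** A call with alternate-allele read fraction
  $f = d_{alt}/d_{tot}$ is *heterozygous* when $f \in [0.20, 0.80]$
  (inclusive at both ends; the published band is stated as "20%–80%"
  without boundary qualification, and we read a printed closed range as
  closed). Calls above the band are homozygous — impossible for a balanced
  lethal — and calls below it are low-confidence; both are removed.
* **Recurrence.** A variant with identical (chromosome, position, ref,
  alt) in more than `max_shared_strains = 3` strains of one mutant
  collection is a shared ancestral variant or a systematic calling
  artifact, not an independently induced lesion; it is removed from every
  strain. Counting is done on post-blacklist, pre-filter calls, so a
  variant homozygous in one strain still counts toward recurrence in
  others (the source describes the filter order but not the counting
  basis; we fix it this way and the audit trail makes the order
  checkable).
* **Effect.** Only protein-affecting annotations are candidates: missense,
  nonsense, start-codon loss, frameshift and in-frame indels, and splice
  sites, defined as the first two and last two bases of an intron.
  Synonymous and other noncoding variants are removed. This reproduces a
  documented escape mode: a causal lesion deep in an intron fails this
  filter and its group then has no candidate in common.
* **Mapped chromosome.** Legacy mapping places each group on one
  chromosome; candidates elsewhere are removed.

The intersection of the members' candidate gene sets yields the group
resolution: `unique` (one gene in common — the putative essential gene),
`multiple` (kept for adjudication), or `none` (flagged for reanalysis).
Singleton groups are `unresolved_singleton`: one allele cannot be resolved
this way.

## Annotation conventions

Amino-acid numbering uses the gene's **longest transcript**, measured by
CDS length with a lexicographic transcript-id tie-break so the choice is
deterministic. Splice-site calling, by contrast, considers *all*
transcripts of the gene, since any transcript's intron boundaries can be
disrupted; when the longest transcript places a variant in coding sequence
while another transcript would call it splice-site, the coding
classification wins, because allele catalogs report a single mutation type
per allele. Amino-acid changes are formatted `R62C` / `Q367*` / `M1I`;
stop-codon read-through is rendered as missense with `*` as the reference
residue. Indels that span an exon–intron boundary are conservatively
classified splice-site. Coordinates are 1-based inclusive throughout
(GFF3/VCF convention); BED blacklists are converted on read.

## Group reconciliation and deficiency corroboration

Complementation-test outcomes connect groups: groups joined by
fails-to-complement edges that also share a candidate gene are merged (two
nominally distinct groups holding lesions in the same gene). A group whose
representative fails to complement members of two groups that *complement
each other* carries lesions in two different genes and is flagged
`double_mutant`; we require the explicit complements edge between the two
partners, otherwise the evidence only supports a merge.

Deficiency (deletion) intervals carry two spans: an inner span certainly
deleted and an outer span certainly containing the deletion. A *sharp*
edge means the two coincide (the boundary is anchored only by the
outermost gene inside the deletion); a *faded* edge leaves an uncertainty
margin out to the closest gene known to lie outside. A gene partially
overlapped by the inner span counts as inside — deleting any part of an
essential gene fails to complement it. Corroboration of a group's
assignment is `consistent`, `conflict`, or `uncertain`; conflicts never
veto an assignment (historical mapping data can be wrong — the documented
conflicts were resolved in favor of the sequencing result by new
complementation tests), they set a flag for follow-up.

## The synthetic screen generator

The simulator emulates the statistical structure the analysis relies on,
at desk scale:

| parameter | default | meaning |
|---|---|---|
| `n_chromosomes` x `genes_per_chromosome` | 3 x 10 | toy genome, ~0.9 Mb per chromosome |
| `gene_length_bp` | 1200 | target CDS length; 2–4 exons, introns 50–90 bp |
| `intergenic_bp` | 80000 | mean spacer between genes |
| `n_groups` x `strains_per_group` | 20 x 2 | complementation groups / sequenced alleles |
| `background_mutations_per_strain` | 150 | strain-private EMS background |
| `ems_transition_fraction` | 0.95 | G:C→A:T share of background (EMS signature; a configurable stand-in — the mutagen and dose are documented upstream, a spectrum is not) |
| `depth_min`/`depth_mean`/`depth_max` | 21/38/65 | read-depth model |
| `het_alt_probability` | 0.5 | binomial allele sampling for heterozygotes |
| `homozygous_decoy_fraction` | 0.2 | background calls emitted homozygous |
| `recurrent_decoy_strains` | 4 | carriers per planted recurrent decoy — one more than the recurrence filter tolerates |

Depth is discrete-uniform on `[depth_min, 2*depth_mean - depth_min]`
(clipped at `depth_max`), which hits the 38x mean exactly. Causal lesions
draw their alt depth from a binomial *truncated to the heterozygous band*:
the carriers are balanced heterozygotes by construction, and the truth
table asserts they are heterozygous, so an untruncated draw would
contradict the generator's own invariant. Background calls use the
untruncated binomial, so a realistic fraction of genuinely heterozygous
background drops below the band and is removed by the zygosity filter —
the truth table records the realized zygosity, not the intent.

Genome geometry is chosen so that the *post-filter* candidate lists
resemble the real analysis — typically the causal gene plus zero to two
background genes per strain, so most pairwise intersections are unique.
Real genomes achieve this with ~100 Mb against a few hundred background
mutations; a desk-scale genome must keep the ratio of coding target to
background density in the same regime, hence the generous intergenic
spacing. What the simulator deliberately does **not** model: read-level
artifacts and mapping bias, linked balancer genetics and pedigrees,
structural variants, multi-transcript loci, UTRs, and locus-specific
mutability. Passing on synthetic data therefore validates the *logic* of
the cascade and intersection — filter correctness, bookkeeping, zygosity
arithmetic, annotation — not robustness to alignment artifacts or
incomplete annotation in real data.

The generator keeps its own anatomy bookkeeping (exploded genomic→CDS
maps, splice and intron position sets built during gene construction) and
derives the truth table — including the filter stage expected to remove
each planted decoy — from that bookkeeping alone, never by calling the
annotation module. Truth-versus-pipeline comparisons in the tests are
therefore dual-route.

```{r, eval = FALSE}
run <- run_simulated_screen(simulation_config(seed = 1))
table(run$evaluation$per_group$outcome)   # 20 groups recovered_unique
```

At these defaults, seeds 1–20 (400 groups) give full recovery, with the
occasional group resolving `multiple` instead of `unique` when both
strains' backgrounds happen to hit the same second gene — exactly the
failure mode the real analysis adjudicates with mutation severity and
prior knowledge. The severity heuristic (`adjudicate_multiple()`) is
**off by default**: the original adjudications drew on curated knowledge
of the genes, which is human judgment we do not pretend to reproduce.

## Numerical and design choices

* Heterozygous band closed at both ends; fractions below the band are
  `low_fraction`, not homozygous-reference.
* "More than three strains" means removed at ≥ 4 observations; exactly 3
  is retained. Recurrence identity is exact (chrom, pos, ref, alt); no
  fuzzy indel matching.
* Quality-score filtering beyond the positional blacklist is deliberately
  not applied; the blacklist is an input file (deriving it from historical
  resequencing data is out of scope).
* Filters only remove calls, never edit them; audit removal counts sum
  exactly to input minus output, and the per-variant removal table is
  mandatory output (it is what makes the "reanalyze the removed variants"
  workflow possible).
* Ties and degenerate inputs: longest-transcript ties break
  lexicographically; empty strains yield empty candidate sets (flagged in
  the audit), not errors; internal stop codons in a reference CDS are
  tolerated with a rendered `*` (the caller interprets).
* The Fisher overrepresentation test is one-sided (enrichment) with
  Bonferroni adjustment `min(1, p * n_terms)`; terms are flat labels, with
  no ontology-hierarchy handling.
* The expression-pattern classifier is an explicit rule-based restatement
  of what was originally visual inspection: maternal when early-embryo and
  hermaphrodite-gonad levels exceed 2x the gene's median stage level,
  plus-zygotic when a larval stage is also elevated, male-enriched when
  the male level exceeds 2x every hermaphrodite stage (taking precedence,
  with all flags co-reported). The thresholds are documented artifact
  choices; per-gene calls on real profiles are not claimed to reproduce
  the original manual classification.

## Problem sizes used in the test suite

Unit tests run on hand-built two-exon genes and a small generator
configuration (2 chromosomes x 4 genes, 4 groups, 40 background mutations
per strain). The end-to-end validation uses the default configuration
above: one full run for the decoy/audit check, twenty seeds for recovery,
and ten seeds inside the acceptance script. These sizes are the package's
standing choices for a reproducible desk-scale validation; scaling
`n_groups`, `background_mutations_per_strain` or the genome geometry up
is supported and only changes runtime.

## Known limitations

* Large structural variants and rearrangements are represented only as a
  reanalysis flag on unresolved groups, not discovered from data.
* Effect calling assumes complete, correct gene models; a wrong or missing
  model silently becomes `noncoding`.
* The deficiency fixtures used in tests are synthetic spans; historical
  deficiency breakpoints are genuinely unknown, which is precisely why
  the corroboration logic carries an `uncertain` verdict.
* The catalog fixtures transcribe printed tables, including their
  internal inconsistencies (one allele's amino-acid change differs
  between two printed tables; the transcription follows each table as
  printed).
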