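---
title: "Rule-based guild classification for methane-cycling metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based guild classification for methane-cycling metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methaneguilds)
```

This vignette is the package's own account of its methods: what the
classification rules assume, which parameters matter and why they default as
they do, what the synthetic data generator does and does not emulate, and
where the design was genuinely open.

## The inference problem

Genome-resolved metagenomics of a methane-emitting habitat ends, after
assembly, binning and annotation, with tables: one gene observation per row,
one stepwise pathway-completion record per MAG and pathway, a GTDB lineage
per MAG, and a mean read depth per scaffold. Everything this package does is
deterministic inference over those tables. Two consequences shape the design:

* **Presence is not activity.** A MAG carrying the genes for acetoclastic
  methanogenesis is a *putative* acetoclastic methanogen. No abundance,
  expression or physiology is inferred, and the rule engine never weighs
  evidence probabilistically — it fires named boolean predicates and records
  which ones fired, so every call is auditable.
* **Annotation tables are noisy and dialect-ridden.** Marker genes drop out
  of draft genomes, and annotation tools label the same enzyme differently
  between releases. The gene vocabulary is therefore an external TSV mapping
  label dialects onto unambiguous tokens, and robustness to gene dropout is a
  measured property (below), not an assumption.

## Abundance model

Mean MAG coverage is the *unweighted* arithmetic mean of per-scaffold depths.
Length weighting is available (`length_weighted = TRUE`) but off by default:
per-scaffold mean depths are already length-normalized within a scaffold, and
the unweighted mean over unique scaffolds is the straightforward reading of
"mean of the scaffold values". Relative abundance divides by the per-site
coverage total and multiplies by 100, so site profiles close to 100 exactly
and are invariant to rescaling all coverages by any positive constant —
coverage units (×) cancel. Rank aggregation sums percentages (linear, hence
equivalent to summing coverage first); MAGs unclassified at the target rank
are pooled under an explicit `unclassified_<rank>` bucket rather than
silently dropped, so mass is conserved to 1e-9 relative. Rounding to two
decimals happens only at presentation.

## The methanogen rule ledger

Candidacy requires the diagnostic marker of methanogenesis: *mcrA*, or high
completion (≥ `hydro_min`) of the 8-step hydrogenotrophic pathway together
with another gene of the *mcr* operon (*mcrBCDG*). MAGs at high completion
with no *mcr* gene at all are real biological curiosities (the CODH/ACS-
bearing archaea that use this machinery for carbon fixation) — they are
flagged `EXCLUDED_NO_MCR` and reported, never guild-classified.
*Methanoperedenaceae* run methanogenesis in reverse; they are rerouted to the
methanotroph module as ANME regardless of their gene content.

Guild rules fire in a fixed order, most specific first:

1. **Broad substrate** — *mcrA*, acetate activation, CODH/ACS >
   `codh_acs_min`, hydrogenotrophic ≥ `hydro_min`, and ≥1 methylotrophic
   substrate methyltransferase.
2. **Methylotrophic** — *mcrA*, a methyl (or methylthiol) transferase, *no*
   CODH/ACS step, hydrogenotrophic < `hydro_low_max`: only methylated
   substrates can feed methane production. When the evidence is the
   methylthiol route (*mtsA*/*mtaA*), a `methylthiol_flag` marks the call.
3. **Acetoclastic** — an *mcr* gene, acetate activation, CODH/ACS >
   `codh_acs_min`, hydrogenotrophic ≥ `hydro_min`.
4. **Strictly hydrogenotrophic** — *mcrA* (or high completion plus another
   *mcr* gene), no CODH/ACS step, no acetate activation.
5. Otherwise **unresolved**, with the partial predicate set recorded.

The order is this package's decision; no ordering is canonical in the
literature. A brute-force enumeration of the full discrete feature space
(32 mcr patterns × 9 hydrogenotrophic steps × 3 CODH/ACS steps × 4 acetate
patterns × 16 methyl patterns × 4 methylthiol patterns = 221,184 cells,
`methanogen_feature_grid()`) shows the order matters only on two overlap
families of cells — broad ⊂ acetoclastic, and methylotrophic ∩ strict —
which `guild_rule_overlaps()` emits and the test suite asserts stable.
Most-specific-first resolves both: the broad rule is strictly more demanding
than the acetoclastic rule, and a methyl-bearing, CODH/ACS-free,
low-completion MAG is better described by its methyl evidence than by the
hydrogenotrophic default.

### Threshold boundaries

Three boundary choices deserve an explicit statement, because completion
fractions sit exactly on them:

* `hydro_min = 0.75` is **inclusive** (≥). The 8-step pathway makes 6/8
  exactly 0.75; an exclusive reading would exclude the very completion level
  the threshold is defined by. Stored step counts are exact integers, so the
  boundary is decidable; fraction comparisons carry a 1e-9 guard solely for
  ratios like 6/7 that binary floating point cannot represent.
* `codh_acs_min = 0.5` is **exclusive** (>). With the 2-step CODH/ACS module
  only 2/2 qualifies — "more than half of a 2-step module" *means* complete.
* "Lacking the CODH/ACS complex" is completion exactly 0, not ≤ 0.5: one
  step present is evidence of the complex, not of its absence.

All thresholds live in `rule_thresholds()` and are configurable; the defaults
above are used everywhere in this package's own analyses.

## Methanotrophs and scaffold verification

Identification needs only the marker subunits *pmoA* and/or *mmoX*; operon
completeness is reported but never required (environmental sMMO operons
routinely lack *mmoZ*). For calls in families with no previously
characterized methanotrophs, a conservative verification applies: at least
`min_verify_gene_count = 2` distinct pMMO/sMMO gene observations on scaffolds
of at least `min_verify_scaffold_bp = 3000` bp. The genes may sit on
*different* qualifying scaffolds — the weaker reading of "multiple genes on
long scaffolds" — because co-location on one scaffold is an assembly
accident, not a biological requirement; the brute-force placement audit in
the test suite pins this decision. Failing verification flags the call
(`verified = FALSE`) but does not delete it. ANME calls are taxonomy-driven
and tallied separately from the aerobic modes throughout.

## Acetogen categories

The four categories deliberately overlap: I (Wood-Ljungdahl ≥ 6/7 with the
phosphotransacetylase + acetate kinase pair), II (CODH/ACS 2/2 with the
pair), III (Wood-Ljungdahl ≥ 6/7 *without* the pair — a curation flag), and
IV (the pair alone). I ⟹ IV and II ⟹ IV by construction, III ∩ IV = ∅; the
package reports the full set and a deterministic primary label (I > II > IV,
III standing alone) rather than forcing exclusivity the definitions do not
have.

## Ordination

Bray-Curtis dissimilarity and NMDS are delegated to vegan (`vegdist`,
`monoMDS`, global model, Kruskal stress-1 with weak-tie monotone
regression). `nmds()` adds the reproducibility layer: `n_restarts` starting
configurations (one metric-scaling start, the rest standard-normal random),
convergence tolerances tightened (`smin = 1e-9`, maximum 500 inner
iterations) so exactly embeddable inputs reach stress below 1e-6, the
minimum-stress solution kept, and coordinates centred, rotated to principal
axes and sign-fixed (largest absolute coordinate positive per axis) so the
same seed yields the same picture. Because monotone regression depends on
the dissimilarities only through their ranks, stress is invariant under
monotone transforms of the input — a property the tests exercise with
d → d². The default of 20 restarts follows the common practice of
best-of-20 NMDS runs for community tables of this size.

## Occurrence harmonization

The synonym table (`inst/extdata/gtdb_family_synonyms.tsv`) is a function
from legacy name → GTDB family, curated by hand and versioned with the
package; lookups normalize whitespace and case but never fuzzy-match, and
unmapped names return `UNRESOLVED` rather than minting families. Species and
genus names resolve through their family, making harmonization idempotent.
A study enters the denominator only if at least one of its taxa resolves to
family level or deeper; presence is liberal (any resolvable report counts)
and duplicate or synonymous reports within a study count once. The current
analysis joins the matrix as an ordinary study via
`study_report_from_calls()`, so denominators include it.

## The synthetic generator: what it emulates, and what it does not

`simulate_landfill()` plants a known guild for every MAG and emits gene,
pathway, taxonomy, coverage and study-report tables consistent with that
guild under the default thresholds. Defaults define the package's reference
conditions: 8 sites × 150 MAGs; per-site guild mixture of 33% methane/acetate
guild members against a 67% heterotrophic background (strict 5%,
acetoclastic 3%, methylotrophic 3%, methylthiol 1%, broad 2%, ANME 1%,
methanotrophs 4% across the three modes, acetogen categories 14%); MAG mean
coverage lognormal(μ = 2, σ = 1) — heavy-tailed enough for single dominant
populations of tens of percent, as real leachate communities show; scaffold
counts 5–30 per MAG with lengths uniform on 2.5–50 kbp, respecting the usual
2.5 kbp assembly inclusion floor; methanotroph accessory-trait frequencies
(nitrite reduction 27/31, nitrate 8/31, high-affinity complex IV 24/31,
low-affinity 26/31) at the rates reported for landfill leachate
methanotrophs. Each required marker gene is planted exactly once, which
makes recovery under row dropout analytically tractable:
`expected_recovery(p)` gives, per guild, the closed-form probability that
the planted label survives when every annotation row drops independently
with probability p (e.g. an acetoclastic MAG needs its single *mcrA* row and
at least one acetate-activation route: (1−p)·(1−p(1−(1−p)²))).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: correlated annotation failure (a fragmented bin
loses whole operons, not independent rows), multi-copy marker genes,
chimeric bins and contamination, taxonomically misassigned MAGs, abundance-
dependent annotation quality, and compositional correlation between sites.
Perfect noise-free recovery is a statement about the internal consistency of
generator and rule engine, not about classifier accuracy on real
assemblies.

## Problem sizes and numerical choices

The package's own analyses and checks run at: the full 221,184-cell rule
grid; 8 × 150-MAG communities for recovery and ordination; 200-MAG
communities over 20 dropout seeds at 5% noise, compared to the closed form
within 99.9% binomial intervals; 20 NMDS restarts. These sizes make every
property measurable in seconds to a few minutes on one core while keeping
per-guild counts large enough for the binomial comparison to have teeth.
Degenerate inputs are errors, not NaNs: empty coverage tables, all-zero
sites, duplicated scaffold ids, two all-zero profiles in a dissimilarity,
non-symmetric matrices and malformed lineage strings all abort with the
offending identifiers named.

## Known limitations

* Guild calls are genomic potential only; substrate affinity, H₂-dependent
  versus disproportionating methylotrophy, and syntrophic dependencies are
  out of scope by design.
* The synonym table covers the common methanogen/methanotroph lineages; it
  is a curation input, and unresolved names demand a table edit, not code.
* Pathway-completion semantics follow the annotation tool that produced the
  table; the package trusts `steps_present`/`steps_total` as given.
* NMDS stress comparability across datasets is limited by the usual caveats
  of nonmetric ordination (local minima, tie handling); the restart scheme
  controls, but cannot eliminate, the local-minimum risk.
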