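---
title: "Methods: segregation filtering, phenotype matching and matchmaking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation filtering, phenotype matching and matchmaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelmatch)
```

`mendelmatch` implements the variant-analysis core of a family-based
rare-disease workflow: pre-filtering annotated variants to the rare,
functional set; testing segregation under eight Mendelian models across
all genotyped family members; querying results across probands; matching
probands by phenotype; and a deterministic gene/variant matchmaking
registry. This vignette documents the statistical and algorithmic choices
in enough detail to reproduce or audit them.

## Data model

A variant table is a flat tibble, one row per (site, alternate allele).
Multiallelic VCF sites are split at load time and every sample genotype is
re-expressed relative to the row's alternate allele: a `0/2` call is
`HOM_REF` for the first alternate and `HET` for the second. Genotypes take
values `HOM_REF`, `HET`, `HOM_ALT`, `HEMI` and `MISSING`; male calls on X
or Y outside a (user-suppliable) pseudoautosomal interval table are mapped
to `HEMI` whenever the alternate allele is present. Population
frequencies live in `maf_<database>` columns where an empty cell means
*not observed in that database* — deliberately distinct from a frequency
of zero. Coordinates are VCF-native 1-based; coordinate-restriction
regions are half-open `[start, end)` intervals.

The flat-table choice (rather than nested structures) is what makes the
determinism guarantee cheap: an analysis result is a sorted tibble plus a
provenance header, and writing it twice produces byte-identical files.

## The rare/functional filter

`filter_rare_functional()` applies, in order:

1. **Function class.** Retained classes default to all coding classes —
   missense, nonsense, stop-loss, synonymous-within-a-splice-region,
   frameshift and in-frame indels — plus splice-site variants. Plain
   synonymous variants and `OTHER` are dropped. "Synonymous affecting
   splicing" is an input annotation (a `splice_region` flag on a
   synonymous call); the package filters on it, it is not a splice-effect
   predictor.
2. **Frequency.** A variant is *rare* iff its frequency is strictly below
   `maf_threshold` (default 0.01) in **every** configured database in
   which it was observed; absence counts as rare. The conjunctive reading
   was chosen because the rarity requirement is stated jointly over the
   population databases; the strict `<` means a variant at exactly the
   threshold is excluded.
3. **Depth.** `depth_min` (default 0 = disabled) applies to the proband's
   call; `depth_scope = "all"` extends it to every member. A missing depth
   fails an enabled depth filter — depth is evidence, and absent evidence
   should not pass an explicit quality gate.
4. **Intolerance.** With `rvis_percentile_max` set, variants in genes with
   an RVIS percentile above the ceiling are dropped; genes without an RVIS
   annotation are retained, because missing annotation is not evidence of
   tolerance.
5. **Regions.** With `regions` set, only variants inside some interval
   survive.

Lowering `maf_threshold` can only shrink the retained set — a property the
test suite checks explicitly.

## Segregation predicates

`segregate()` produces one verdict per variant: `PASS`, `PASS_POSSIBLE`
or `FAIL`, with a human-readable reason naming the offending relative
where applicable. Three conventions apply to every model:

- Members with **unknown phenotype are ignored** by all predicates.
- A `MISSING` genotype in a *required* relative (parents, or an affected
  sibling whose genotype the model constrains) downgrades the verdict to
  `PASS_POSSIBLE`, never to `PASS`: an ungenotyped parent cannot veto a
  candidate, but the claim is correspondingly weaker. This is what makes
  singletons useful — every rare heterozygote is `PASS_POSSIBLE` under
  the dominant models rather than silently passing or failing.
- **Chromosome scope**: the autosomal-dominant, recessive and imprinting
  predicates evaluate autosomal variants only; the X-linked predicates
  evaluate X variants only. Without the scoping, an X-linked de novo
  variant would satisfy the autosomal-dominant predicate verbatim, and
  each model's result file would be polluted by the others' candidates.

The predicates:

- **AD de novo** — proband `HET`; both parents `HOM_REF`; any genotyped
  affected relative carries the allele; any genotyped unaffected relative
  lacks it.
- **AD inherited** — proband `HET`; every genotyped affected member
  `HET`; every genotyped unaffected member `HOM_REF`; *and at least one
  genotyped parent carries the allele*. The last clause is this package's
  refinement: without it, a de novo trio (both parents genotyped
  `HOM_REF`) satisfies the inherited predicate too, and the de
  novo/inherited sub-verdicts of the dominant analysis would not be
  disjoint. "Inherited" is read genetically: somebody must have
  transmitted the allele, and with unaffected members required to be
  `HOM_REF`, the transmitting parent is necessarily affected.
- **AR homozygous** — proband `HOM_ALT`; genotyped parents `HET`;
  genotyped unaffected siblings not `HOM_ALT`; genotyped affected
  siblings `HOM_ALT`; no other genotyped unaffected member `HOM_ALT`.
- **AR compound heterozygous** — at least two proband-`HET` variants in
  one gene with opposite parental origin. A variant is traced to a parent
  when that parent carries it and the other genotyped parent does not.
  With both parents fully genotyped a pair is either `PASS` (opposite
  origins) or `FAIL` (same origin, untraceable origin, or a genotyped
  unaffected member carrying both members of the pair); `PASS_POSSIBLE`
  is reserved for pairs whose phase is unknowable because a parental
  genotype is missing — including the all-heterozygous-pairs report for
  singletons. Partner links are stored as a list-column and are always
  mutual.
- **XL recessive** — X only. Male proband: `HEMI`, mother a carrier,
  father not carrying. Female proband: `HOM_ALT`, both parents carriers.
  No genotyped unaffected member may hold the proband's causal genotype.
- **XL dominant** — X only; proband `HET` (female) or `HEMI` (male);
  genotyped affected members carry, genotyped unaffected members lack.
- **Imprinting (maternal/paternal)** — proband `HET` with the allele
  traced to the father (maternal imprinting: the maternal copy is
  silenced, so the paternally inherited allele is pathogenic) or to the
  mother (paternal imprinting), i.e. origin parent carries, other parent
  `HOM_REF`. Deliberately, there is **no affected-status veto on the
  carrier parent**: an unaffected carrier father is exactly what maternal
  imprinting predicts when his allele was maternally inherited.

### Predicate overlap

The eight predicates constrain genotypes, and genotypes underdetermine
mechanism: a paternally inherited heterozygote from an affected father
satisfies both the inherited-dominant and the maternal-imprinting
predicate; each half of a compound-heterozygous pair satisfies one
imprinting predicate. This is a property of the genetics, not a bug, and
the synthetic generator's truth manifest therefore records, per planted
variant, the full set of models whose predicate it satisfies. The
automated dominant analysis reports de novo and inherited sub-verdicts in
one result file with a distinguishing column.

## Cross-proband queries

Cohort recurrence deduplicates variants per (gene, proband) — incidence
is per proband — and returns genes supported by at least `k` probands.
Oligogenic overlap enumerates proband subsets (cohorts here are tens of
probands, so enumeration is exact, not heuristic) and reports the
*maximal* groups sharing at least `m` genes: a group is suppressed when a
proper superset also qualifies, which avoids reporting every sub-pair of
a qualifying trio of probands. Gene symbols are matched case-insensitively
after trimming; no alias resolution is attempted (symbol normalization is
data, not algorithm). Interaction neighbourhoods count **edges**, not
nodes — "first-order" means a direct interaction partner — and exclude the
seeds themselves; edges below the confidence threshold are removed before
traversal.

## Phenotype matching

Feature terms are a flat controlled vocabulary, normalized by case-folding
and whitespace-squishing. Proband–proband matching uses the overlap
coefficient |A∩B| / min(|A|,|B|): symmetric, in [0, 1], and equal to 1
whenever one profile contains the other — an appropriate statistic when
profiles differ widely in depth of phenotyping, since the shallower
profile sets the denominator. Thresholds are applied as `>=`, so a pair
constructed at exactly 0.8 is returned at a threshold of 0.80 and not at
0.81. No ontology ancestor-closure is applied; the vocabulary is flat in
this version, and closure (a parent-term map applied before matching) is
the natural extension point.

Differential diagnosis scores each disease by the number of features
shared with the profile (primary), breaking ties by the fraction of the
disease's features present in the profile (precision), then by disease
id; zero-intersection diseases are excluded and the top 20 retained by
default. The exact scorer is this package's own choice — any ranking
monotone in the intersection satisfies the interface; intersection-first
was chosen because profile and disease feature sets are short (a handful
of terms), where raw overlap counts are more informative than normalized
similarities, and the precision tie-break prefers diseases explained
almost entirely by the profile. The ranking is a prefix-stable list: the
top-n is always a prefix of the top-(n+1).

## Matchmaking registry

The registry is a value (a list of tibbles), and every operation returns
an updated copy — no hidden state, so identical operation sequences give
identical registries, and order-independence properties can be tested
directly. Gene submissions match all prior submissions of the same
normalized gene; each match is logged once as a pair naming both parties
(n submitters of one gene produce n(n−1)/2 logged pairs). Self-matches
(the same submitter twice) are stored but not notified.

Variant queries use the `chr:coordinate refAllele>altAllele` grammar, are
lifted to the database build when necessary (through pluggable coordinate
tables; an unmappable coordinate is an explicit error, never a silent
drop), and match on exact (chromosome, position, ref, alt). A documented
`position_only` switch relaxes matching to the coordinate alone, for the
reading under which matching is location-based; exact-allele is the
default because the query grammar carries alleles. Phenotype payloads are
attached to a match only when the query itself supplied 3–6 features —
fewer than three is a validation error, and the bound keeps shared
payloads informative without becoming a phenotype dump. Unmatched queries
are stored and replayed on every ingest, so (store, ingest) and (ingest,
query) produce the same final match log. The daily quota (default 10
accepted queries per submitter per day) is keyed by an abstract day token
supplied by the caller: the quota is a policy about days, not about
wall-clock time, and tokens make it deterministic and testable.

Candidate export for gene matchmaking takes a proband's final candidate
list in file order, drops genes already associated with a disease
phenotype, deduplicates, and caps at 10 genes.

## The synthetic generator

`generate_family()` emulates the *shape* of a family sequencing study:
a pedigree (trio, quartet with an unaffected sibling, or singleton), one
annotation table with per-sample genotype and depth columns, a matching
multi-sample VCF, and a truth manifest. Decoy variants draw a frequency
class from a mixture (30% common, uniform on [0.01, 0.5]; 40% rare,
uniform below 0.01; 30% absent from all databases — frequencies rounded
to 6 decimals, i.e. reporting precision, so tables round-trip exactly);
parental genotypes follow Hardy–Weinberg proportions at that frequency
and children receive Mendelian transmissions, which produces realistic
near-miss genotype patterns. Any decoy draw that would satisfy a model
predicate (child heterozygous with a homozygous-reference parent;
homozygous child of two carriers) is redrawn, so decoys violate every
model by construction; each decoy also gets a private gene so no spurious
compound-heterozygous pairing can arise. Planted variants are constructed
to satisfy exactly their model's predicate, and the manifest records the
full expected-model set per plant (see *Predicate overlap*). The father
is marked affected only when an inherited-dominant plant requires a
transmitting affected parent.

Phenotype profiles draw their sizes from a Poisson distribution with mean
6.8 (the average depth of phenotyping per affected individual in large
deep-phenotyping databases), truncated at one feature. Designated profile
pairs are built with an exact overlap coefficient of 0.8 — two size-5
profiles sharing four features — to pin the threshold behaviour of
`overlap_match()`.

What the generator does **not** emulate: real genome coordinates or
sequence context, linkage between variants, population structure,
genotyping error, mosaicism, and ontology structure among feature terms.
Passing the planted-recovery tests therefore demonstrates the correctness
of the predicates and plumbing on clean Mendelian data, not robustness to
call errors or to phenotype vocabulary mismatch.

## Numerical and degenerate-input choices

- No floating-point tolerances are needed anywhere: frequencies are
  compared with strict `<` against user thresholds, and overlap
  coefficients are small rationals compared with `>=`.
- Ties and ordering are always resolved deterministically: variant rows
  by (chromosome rank, position, ref, alt); compound-het partners
  lexicographically; overlap matches by descending coefficient then id;
  diagnoses by (shared, precision, id); oligogenic groups by size then
  lexicographic member list.
- Degenerate inputs: empty filter output is legal everywhere (an empty
  result file is a header-only TSV); an X-linked analysis over a variant
  set with no X data returns an empty verdict table with a warning; a
  proband with a `MISSING` genotype fails that variant outright (there is
  nothing to segregate); profiles with empty feature sets are skipped
  with a warning in overlap matching; an empty gene list, a neighbourhood
  order outside 1–3, or `k`/`m` below 2 are argument errors.
- Test and acceptance problem sizes — 100 decoys per family, 20 seeds,
  10,000 filter rows, 50-node graphs, 1,000 random profile pairs — were
  chosen so the full suite exercises every predicate path and boundary
  while completing in about a minute on a single core.

## Known limitations

- No variant calling, read-level phasing, CNV or mitochondrial models;
  annotation values are consumed, never computed.
- Compound-heterozygous phase comes only from parental genotypes; a
  de novo allele inside a candidate pair cannot be phased and the pair
  fails rather than passing optimistically.
- The flat phenotype vocabulary treats related terms as distinct; without
  ancestor closure, coarse and fine phenotyping of the same patient can
  under-match.
- Gene symbols are trusted as given (no alias table is shipped), and the
  liftover hook maps only coordinates present in its table — it is a
  correctness hook, not a genome-build service.
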