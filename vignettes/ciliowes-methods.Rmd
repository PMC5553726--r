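---
title: "Methods: tiered exome variant prioritisation for consanguineous ciliopathy families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered exome variant prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliowes)
```

## The diagnostic problem

Ciliopathies (Bardet-Biedl, Alström, McKusick-Kaufman and related
syndromes) are individually rare, genetically heterogeneous and
phenotypically overlapping, so panel sequencing frequently fails and
whole-exome sequencing (WES) is the pragmatic diagnostic route. In
consanguineous families the prior is strong and specific: the causal
allele is usually *autozygous* — homozygous by descent — and therefore
sits inside a long run of homozygosity (ROH). `ciliowes` implements the
corresponding analysis strategy as a reusable, fully offline pipeline:
annotated variants are filtered by genotype confidence, population
frequency and predicted effect; candidate genotypes are selected under
an autosomal-recessive model; in-silico pathogenicity is summarised as a
consensus over fixed predictor panels; ROH segments are mapped from the
exome genotypes themselves; and residual candidate genes are ranked by
functional similarity to a ciliary training set.

Because real patient exomes of this kind are rarely shareable, the
package ships a synthetic-cohort generator whose output has the
statistical structure the method assumes. Every stage is therefore
testable end to end without any external data.

## The filtering cascade

Three pure per-variant predicates, applied as a conjunction (so the
survivor set is independent of evaluation order):

* **Genotype confidence** — proband depth `DP >= 15` reads and genotype
  quality `GQ > 20` (strict), missing genotypes fail. The boundary
  semantics ("at least" for depth, strictly greater for quality) are
  deliberate and tested at the exact boundary values.
* **Population frequency** — a variant is excluded when *any* reported
  source (dbSNP MAF, 1000 Genomes, ESP alt-allele frequency) exceeds
  0.01; equality passes; missing values never exclude, so novel variants
  always survive. A *strict* mode used during exome-wide escalation
  requires every reported frequency to be strictly below 0.005.
* **Functional effect** — keep HIGH/MODERATE impact classes; drop
  synonymous and intronic consequences unless a splice-site term
  (donor/acceptor/region) co-occurs.

Quality is assessed in the proband only: relatives enter the analysis at
the segregation step, not the discovery step. The audit trail records
the first failing predicate per variant in the canonical order
quality → frequency → effect.

## Inheritance model and co-segregation

Consanguinity implies a homozygous-by-descent causal genotype, so
homozygous-alt candidates in the proband are primary. Compound
heterozygotes in the same gene are screened as a secondary model; phase
is resolved purely by Mendelian logic over parental carriage (one
paternal-only plus one maternal-only variant confirms *trans*; all
variants carried by one parent and confirmed absent from the other
excludes the pair as *cis*; anything else, including ungenotyped
parents, is *phase unknown*). Only a *trans*-confirmed pair counts as a
passing compound-het call.

Co-segregation of a homozygous candidate requires every available
unaffected parent to be an obligate carrier (0/1), no unaffected
relative to be homozygous-alt, and affected relatives to share the
homozygous genotype. A heterozygous *affected* relative renders the
variant inconsistent for that relative — the interpretation being that
this individual has a different cause — but the candidate is retained in
the report with its flag rather than silently dropped. Relatives of
unknown affection status constrain nothing. With no genotyped relatives
the check returns *untestable*, which does not veto a diagnosis (one of
the archetype families has no available relatives at all).
Hemizygous single-allele calls (male X) are coded as homozygous and
processed under the same rules, flagged in the output.

## Consensus pathogenicity scores

Protein-level deleteriousness is the count of positive calls over a
fixed four-tool panel — PolyPhen-2, SIFT, MutationTaster, LRT — printed
as `k/4`. Two decisions matter:

* For truncating variants (stop-gain, frameshift) PolyPhen-2 and SIFT
  cannot be run; they are recorded as *not applicable* but the
  denominator stays 4. A nonsense variant supported by MutationTaster
  and LRT therefore scores 2/4, never 2/2.
* PolyPhen-2 "possibly damaging" counts as positive. The consensus is a
  candidate screen, not a calibrated classifier, so the permissive
  reading is appropriate; the workflow logs this assumption on every
  run.

Splicing alteration is scored identically over NNSplice, NetGene2,
Human Splicing Finder and ASSEDA; a tool that was not run counts as
negative rather than shrinking the denominator, keeping the fixed `k/4`
presentation. All call vocabularies are configuration (YAML), since
annotators spell these categories inconsistently.

## Tiered search and the escalation ladder

Tier 1 restricts the cascade to a panel of known ciliary genes and
reports homozygous candidates first, compound-het calls second. Tier 2
searches exome-wide among homozygous survivors under an impact-mode
ladder:

1. `high_only` — HIGH-impact variants under the standard criteria;
2. `high_moderate` — HIGH+MODERATE impact under the *strict* criteria
   (every reported frequency < 0.005 and at least 2/4 positive protein
   predictions);
3. `moderate_only` — the same strict criteria restricted to MODERATE
   impact, available as an explicit mode.

The pipeline escalates until a passing candidate falls in a *known*
ciliary gene (family labelled `solved-known-gene`) or the ladder is
exhausted, in which case the final candidate genes go to prioritisation
(`candidate-novel-gene`) or, with no candidates at all, the family is
`unsolved`. Two design points were genuinely open and are resolved as
follows. First, the automatic ladder stops at `high_moderate`: its
strict candidate set is always a superset of `moderate_only`, so a
third rung would either repeat or lose information; `moderate_only`
remains useful interactively when HIGH-impact noise is suspected.
Second, a `high_only` hit in an unknown gene does *not* stop the
ladder: a single truncating variant in an anonymous gene is weaker
evidence than a fuller strict candidate list ranked against the
training set, and stopping there would leave the prioritiser with
nothing to discriminate. The known-gene set may be configured as a
superset of the tier-1 panel, covering genes that are established but
not "first-line" (CRB1 is the canonical example: a recognised retinal
ciliary gene that a common-ciliopathy panel may omit, then rediscovered
exome-wide by the HIGH-impact rung).

## ROH detection from exome genotypes

Exome marker maps are sparse and irregular, so the scan is windowed
rather than HMM-based: a sliding window of 50 markers tolerates at most
1 heterozygous and 5 missing calls; a marker is eligible when more than
5% of its overlapping windows satisfy both bounds; maximal eligible
runs are split at inter-marker gaps above 1,000 kb and screened for at
least 25 supporting markers, 1,000 kb of physical length and 1 marker
per 50 kb of density. All values live in `roh_config()` and are echoed
into the report header — published "optimized exome settings" for such
scans are rarely restated in full, so reproducibility here means
printing the exact configuration used. The implementation is verified
against a brute-force window-enumeration oracle on hundreds of random
instances.

Consanguinity thresholds are sometimes quoted as "ROH > 100,000 kb";
100 Mb exceeds most chromosome arms, so such figures read as unit
misprints for 1,000 kb. The consanguinity-labelling threshold is
therefore a configuration value (default 1,000 kb) and the report
prints the value actually used alongside a note on the ambiguity.

Candidate colocalization (`variant_in_roh()`) uses 1-based inclusive
boundaries internally; BED export converts to 0-based half-open.

## Prioritisation by training-set similarity

Web-service gene prioritisers are neither reproducible nor runnable
offline, so the ranking step is re-specified transparently: for each
evidence source (pathway membership, GO terms, interaction partners,
expression clusters — GMT-style text files), a candidate's similarity is
its best Jaccard index against any training gene (self-matches
excluded, empty sets score 0); candidates are ranked per source with
mid-ranked ties; and ranks are fused as the geometric mean of `rank/n`
across sources. Sources in which every candidate ties are uninformative
and excluded; if no source is informative, all candidates tie at fused
score 1 and ordering falls back to the alphabet, keeping every run
deterministic. The fused score is monotone with the final rank by
construction. Rankings are produced for the full 51-gene ciliary
training set and for any named subsets (e.g. BBS-family and MKS-family
genes), and the report highlights genes in the top 2 under every
subset. The shipped 51-gene list is an editable stand-in assembled from
well-established BBS/MKS/NPHP/ALMS/IFT genes, not an assertion of one
specific published gold-standard build.

## What the synthetic cohort does and does not emulate

`simulate_cohort()` generates six nuclear families on a miniature
genome of six 10-Mb contigs (about 30 markers/Mb). Gene symbols are
real so panel logic is exercised; all positions, sequences and feature
files are fabricated. Per family:

* Parental haplotypes are drawn per marker from a two-component
  frequency mixture (80% common, Beta-shaped over roughly 0.05–0.5; 20%
  rare, log-uniform over 1e-5–0.01), with impact classes weighted
  toward MODIFIER/LOW.
* Autozygosity is produced mechanically, not via an inbreeding
  coefficient: one ancestral haplotype segment (default 2,500 kb) is
  copied into one haplotype of *each* parent and transmitted to the
  proband from both sides, which is exactly the IBD structure the ROH
  scan must find. The causal variant rides inside this block,
  homozygous in the proband and heterozygous in each parent. Block
  markers are drawn from the common component only: ROH mapping rides
  on common polymorphisms, and rare variation inside the block is
  represented by the planted causal allele itself (this also keeps the
  strict-filter candidate counts interpretable).
* Background load is calibrated so the number of homozygous survivors
  of the standard cascade per family is close to 300 (Binomial(600,
  0.5) draw of variants constructed to survive, each then failing the
  strict rules through its frequency band or sub-threshold consensus).
  The 300 figure mirrors the scale reported for this kind of exome
  after the standard criteria.
* Depth is negative-binomial (mean 60), about 3% of genotype entries
  are degraded below the quality thresholds and about 1% set missing;
  planted variants are protected from this noise in all family members
  so that design intent, not noise, decides test outcomes.
* The two unsolved-by-panel archetypes additionally plant candidate
  sets that pass even the strict criteria (7 genes and 8 genes
  respectively), and the bundled feature matrix is engineered so the
  intended pairs (CORO2B/SLC3A1, LMO7/ZNF17) rank top-2 under the full
  training set and both subsets.

Not emulated: linkage disequilibrium, read-level sequencing error,
realistic gene structure, population demography, X-linked inheritance,
copy-number or structural variation. Passing tests on this cohort
therefore demonstrate the *logic* of the cascade, phasing, ROH scan and
prioritiser under the stated assumptions — not performance on real
exomes, where annotation errors and CNVs are prominent failure modes
(WES-based strategies are structurally blind to CNVs, a known
limitation of the approach).

Every generated genotype is checked for Mendelian consistency, and
planted variants self-validate against the cascade at generation time.
All randomness flows from a single integer seed; a fixed seed
reproduces the cohort byte-for-byte.

## Numerical and degenerate-input choices

* Ties in per-source ranks take the mean of the tied range; final ties
  break alphabetically, so output order is total and deterministic.
* A single candidate gene receives fused score `1/n = 1` and rank 1.
* Variant records are decomposed to one row per alternate allele before
  any filtering; genotypes are re-expressed against the focal alt, with
  other alternate alleles counting as non-focal. Multi-transcript
  annotations collapse to the most severe impact
  (HIGH > MODERATE > LOW > MODIFIER).
* Missing annotation is `NA` end to end and is never imputed to 0 — the
  asymmetry (missing frequency passes, missing genotype fails) is
  intentional and tested.
* Empty cohorts, header-only reports and zero-segment ROH tracks are
  all legal values, not errors.

## Problem sizes used by the shipped test-suite

The suite runs the full six-family cohort (about 2,100 variant records
per family) once and reuses it across test files; the ROH oracle
comparison uses 500 random instances of up to 200 markers; the
segregation and prioritiser recovery properties use 100 seeded
replicates each, with the segregation trios generated at reduced marker
density (the property concerns transmission logic, not marker load).
These sizes were chosen as the smallest at which the properties are
meaningful; all scale linearly if enlarged.
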