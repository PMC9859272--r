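---
title: "Methods: conservation scoring, domain coordinates, and variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation scoring, domain coordinates, and variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthovar)
```

## The problem

Families of paralogous genes that share one well-conserved domain — the
motivating case is the twenty human SOX transcription factors and their
HMG box — pose a specific variant-interpretation opportunity: a
clinically established missense variant at a domain position in one
family member is evidence about the homologous position in every other
member. Exploiting it requires three ingredients that this package
implements as separable modules: a per-codon measure of evolutionary
constraint computed from ortholog open reading frames, a shared
coordinate system that aligns the domain across paralogs, and an
integration layer that places variants from heterogeneous databases onto
those coordinates and applies explicit prioritization rules.

## Conservation model and its assumptions

All codon statistics are *reference-anchored*: every ortholog codon is
compared with the human reference codon at the same reference codon
index, not with a reconstructed ancestor. A differing codon encoding the
same amino acid increments the synonymous count *s*; a differing codon
encoding a different amino acid increments *n*. Orthologs gapped or
ambiguous at a column are excluded from that column's denominator. This
is a deliberate simplification — it conflates repeated and single
mutational events — but it is exactly the quantity the downstream rules
consume, it requires no tree, and it lets a simulator record ground
truth the statistics must reproduce *exactly* (see below).

The per-codon selection signal is

$$\mathrm{raw}_i = \frac{n_i}{N_i} - \frac{s_i}{S_i}, \qquad
  z_i = \frac{\mathrm{raw}_i - \overline{\mathrm{raw}}}{\mathrm{sd}(\mathrm{raw})}$$

where $S_i$ and $N_i$ are the reference codon's synonymous and
nonsynonymous site counts from single-nucleotide pathway counting in the
Nei–Gojobori sense: each codon position contributes the fraction of its
non-stop single-nucleotide changes that are synonymous. For example GCT
(alanine; four-fold degenerate third position, no stop neighbors) has
$S = 1$, $N = 2$. A term with zero sites (e.g. $S$ for ATG or TGG)
contributes zero, which preserves the invariant that single-codon amino
acids can show no synonymous signal. Standardization is per gene, which
makes thresholds on $z$ portable across genes with different species
counts and divergence. Production analyses often estimate dN/dS with a
maximum-likelihood codon model; that was judged out of scope here
because the pipeline consumes dN−dS only as a per-codon *ranking* signal
inside one gene, and the counting estimator preserves sign and ordering
at a fraction of the cost. Absolute dN−dS values from this estimator are
therefore not comparable with model-based estimates and are not asserted
anywhere.

Codons compared against fewer than three informative sequences are
flagged and excluded from the standardization ($z$ = NA). A gene with
zero variance in raw (e.g. fully invariant) gets all $z$ = 0 with a
warning rather than an error, because an invariant gene is a legitimate
input.

### The quantized conservation score

The score combines amino-acid conservation with substitution-pattern
evidence on a 0–2 scale in steps of 0.25:

* base **1.0** when the reference amino acid is preserved in ≥ 90% of
  compared orthologs, else 0;
* **+0.25** for each of: $s \ge 5$; $s \ge 15$; $z \le -1$; $z \le -2$;
* capped at **2.0**.

The exact published rubric behind scores of this shape is not restated
in the sources available to this package; the rubric above is this
package's design, chosen to reproduce the observed behavior of such
scores — quantized quarter steps, range 0–2, higher values with heavy
synonymous-only divergence at a conserved residue — without claiming
cell-for-cell numeric identity with any published table. The package's
tests assert the rubric's own contract (quantization, range,
monotonicity in $s$ and in $-z$), not agreement with published score
cells.

The per-gene profile places the score on a **21-codon sliding window**
(the codon plus 10 neighbors each side). Windows are *truncated* at the
termini — the first codon sums 11 terms — rather than padded or set to
NA, so every codon has a finite window value. Each gene's window track
is normalized by its maximum, so the most conserved motif of every gene
has value 1 regardless of gene length or species count; an all-zero
track normalizes to all zeros with a warning rather than dividing by
zero.

### Sequence filtering

Before any statistic, two removal rules run per gene: any sequence
containing an ambiguity character (anything outside A/C/G/T and gap,
case-insensitive) is removed; and any sequence missing more than 9
nucleotides at alignment columns occupied by more than 90% of sequences
is removed. The occupancy qualifier matters: a 12-nucleotide gap shared
by half the family is alignment structure, not missing data, and does
not trigger removal. The reference is never removed — a reference
failing either rule aborts with an error, since every downstream
statistic is anchored on it. Both thresholds (9 nt, 90%) are exposed as
arguments.

## The domain coordinate system

Domain positions are 1-based inside the domain (position 1 = the first
annotated domain residue) and strictly negative upstream (−1 = the
residue immediately before the domain). **There is no position zero**;
the mapping and its inverse are exact bijections and are property-tested
as such. A second numbering convention used in parts of the SOX
literature is offset by +2; conversion adds the offset and, for upstream
positions whose shifted value would land on or past zero, skips zero
(−1 → 2 with offset 2). The zero-skip rule for negative positions is
this package's convention — published sources do not number upstream
flank positions in the alternate scheme — and the conversion logs a
message whenever it applies.

The cross-paralog position table spans −10 to L+25 by default, covering
the flanking regions where family members diverge; both extents are
configurable. Per position it reports the set and count of distinct
residues used across paralogs and the mean ± sd of the paralogs'
conservation scores, where each paralog contributes the score at *its
own* protein position — scores are not re-computed on the cross-paralog
alignment frame. The domain itself must align gap-free across paralogs
(equal annotated length); unequal lengths are an error rather than a
silent re-alignment.

## Variant integration

A variant *site* is a residue — a (gene, protein position) pair;
distinct alternate alleles at one residue are one site, with the
multiplicity retained per source (`n_alt_*`) because the prioritization
rules need it. Sites are partitioned by their exact source combination;
the partition property (disjoint categories summing to the site total)
is property-tested. Per-site roll-ups follow the most conservative
useful convention: maximum CADD, summed allele counts, summed phenotype
profiles. Summing phenotype profiles (with the maximum recoverable from
per-record data) was an open choice; the sum was chosen because profile
counts accumulate over independent probands.

The enrichment ratio for a gene and source is
$(k/m) / (\ell/L)$ where $k$ of $m$ variants fall inside the domain,
$\ell$ is domain length and $L$ protein length. It is invariant to
duplicating every record, undefined (NA, not 0) when a gene/source has
no variants, and 1 under proportional placement — all tested.

Allele frequencies are consumed as given, never recomputed from counts.
Input is protein-coordinate TSV; genomic liftover and VCF ingestion are
out of scope, as is multi-transcript support (one canonical protein per
gene).

## Prioritization rules and thresholds

* **Cross-paralog clinical co-occurrence**: domain positions where ≥ 2
  distinct paralogs carry a ClinVar-or-literature variant; and sites
  where one gene carries ≥ 2 distinct alternate alleles.
  Literature-curated variants share the clinical channel with ClinVar
  deliberately: pre-database clinical genetics lives in papers.
* **CADD/selection filter** for in-domain phenotype-profile variants:
  CADD **strictly greater than 20** and conservation score **at least
  1**. The asymmetry (strict vs inclusive) mirrors the published
  phrasing of the thresholds verbatim and is boundary-tested. ClinVar
  paralogs at the position are attached as evidence but are *not*
  required — the curated reference table contains qualifying variants at
  positions with no ClinVar paralog.
* **Outside-domain conserved context**: sites outside the domain with
  score ≥ 1 **and** 21-codon window sum ≥ 10, observed in any of the
  clinical, phenotype-profile, or population channels. The published
  rule is qualitative ("highly conserved amino acids with additional
  amino acids around the site conserved"); the two thresholds were fixed
  once from the observation that every row of the corresponding curated
  table prints score ≥ 1 and window ≥ 10.25, and are exposed as
  arguments.
* **Somatic at clinical sites**: somatic in-domain variants restricted
  to domain positions with clinical evidence in any paralog, grouped by
  (tissue, histology) with the dominant gene per group.

Phenotype-match judgments (does the proband phenotype fit the gene?) are
surfaced as free-text evidence for human review, not automated: they are
expert curation, not a computable rule.

## The synthetic family: what it emulates and what it does not

The generator's defaults state the emulated world: 20 genes, 100
species each (the curated family averages just under 100 ortholog ORFs
per gene), 200-codon proteins with a 79-codon domain at positions
61–139, a 30% per-codon per-species substitution probability in both
regions, and region-specific nonsynonymous fractions of 5% (domain)
versus 80% (flank) — the "only the domain is conserved" regime. The
79-codon domain matches the HMG box; 200 codons is a typical SOX-family
ORF scale.

Evolution is simulated on a **star tree**: each ortholog is mutated
independently from the reference, with at most one substitution event
per codon per species, drawn uniformly from the reference codon's
single-nucleotide neighbors of the required synonymous/nonsynonymous
class (stop codons excluded throughout; when the class is empty, as for
synonymous changes to ATG, the codon is left unchanged and the truth
records the failed draw). This is not a realistic evolutionary model —
no phylogenetic correlation, no codon-usage bias, no CpG
hypermutability, no indels, no multiple hits — and that is the point:
because the statistics are reference-anchored, the generator's recorded
per-codon (s, n) equal what the counting statistics must return on the
emitted alignment, *exactly, for every seed*. A green truth-equality
test therefore establishes the counting code, not the realism of the
data. Conversely, the recovery test (domain mean above flank mean in
≥ 95 of 100 seeds, for both the score and the normalized window)
establishes that the score pipeline separates the planted regimes; it
says nothing about sensitivity on real alignments with tree structure
and rate variation, which the generator does not emulate.

Variant tables draw sites from a shared pool so that cross-database
overlap categories are populated, with geometric-tailed allele counts,
uniform CADD-like scores, small Poisson phenotype-profile counts, and
categorical tissue/histology labels. One alternate allele is planted
per site; multi-allele sites are exercised through hand-built records
and the curated tables instead.

All randomness flows from the single config seed; identical seed and
config give byte-identical FASTA and TSV output, which the pipeline
tests assert end to end.

## Numerical and degenerate-input choices

* Site counts: Nei–Gojobori fractional sites with stop-producing
  neighbors excluded from numerator and denominator; a zero-site term
  contributes zero to raw.
* Zero variance in raw dN−dS: all $z$ set to 0 with a warning.
* All-zero window track: normalized to all zeros with a warning.
* Sliding window at termini: truncation, never padding or NA.
* Score quantization: computed increments are exact multiples of 0.25;
  a final round-to-quarter guards against floating drift, and the cap
  at 2 is applied last.
* Empty variant tables are valid inputs everywhere and produce empty,
  schema-correct outputs.
* Malformed variant rows (unparseable notation, ref = alt, position
  < 1) are rejected row-wise with line-numbered logs; missing schema
  columns fail fast.

## Known limitations and one honest discrepancy

* Reference-anchored counting underestimates constraint at codons with
  repeated substitutions to the same state and cannot distinguish one
  deep change from many independent ones.
* The dN−dS z-score is a within-gene ranking; it is not calibrated
  across genes or against model-based estimators.
* The conservation-score rubric is a reconstruction of an
  under-specified published metric; printed score cells are not
  reproduced and not asserted.
* The curated in-domain clinical reference table shipped with the
  package contains **nine** positions at which one gene lists two or
  more distinct changes, while the published headline count for that
  analysis is **eight** (the published position list omits one position
  whose table row lists two alternates for one gene, and its per-gene
  attributions disagree with the table in both directions). The package
  implements the clean rule — ≥ 2 distinct alternate alleles in one
  gene at a position — and reports what it computes; the acceptance
  test asserts the published value of 8 and is accordingly expected to
  fail on the faithful transcription, by design rather than by
  adjusting the data or the rule. The companion 27-position
  multi-paralog count reproduces exactly under the analogous rule.
* CADD, allele frequencies, and phenotype annotations are consumed as
  given; the package computes none of them.
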