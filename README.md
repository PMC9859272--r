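# orthovar

Interpreting human missense variants in a paralogous gene family by
combining deep ortholog conservation with evidence transfer between
family members.

The motivating system is the SOX transcription factor family: twenty
human genes sharing one ~79-residue DNA-binding HMG box with highly
variable flanking sequence. Because the domain is shared, a clinically
annotated variant at an HMG-box position in one paralog (say SOX9)
is evidence about the same domain position in a less-studied paralog
(say SOX15). `orthovar` implements that analysis as a reusable, testable
pipeline for any family with a shared domain.

## What it computes

**Per-codon conservation from ortholog ORFs.** For each gene, a
reference-anchored codon alignment (one sequence per species, one human
reference) yields per-codon synonymous (*s*) and nonsynonymous (*n*)
substitution counts, the fraction of species preserving the human amino
acid, and a standardized per-codon dN−dS signal

    raw_i = n_i / N_i − s_i / S_i ,   z_i = (raw_i − mean(raw)) / sd(raw)

where S_i and N_i are the reference codon's synonymous and nonsynonymous
site counts from single-nucleotide pathway (Nei–Gojobori) counting,
stop-producing changes excluded. These combine into a quantized
conservation score in {0, 0.25, …, 2}: one base point for ≥90%
amino-acid conservation, plus 0.25 for each of s ≥ 5, s ≥ 15, z ≤ −1,
z ≤ −2. Scores are summed over a **21-codon sliding window** (10 codons
each side, truncated at the termini) and normalized per gene so the most
conserved motif has value 1.

**A shared, zero-free domain coordinate system.** Protein residues map
to domain positions (1 … L inside the domain, negative immediately
upstream; there is no position 0), with an alternate numbering offset by
+2 (the "53/55"-style dual labels). Cross-paralog tables report, per
domain position, the set of residues used, and the mean ± sd of each
paralog's own conservation score.

**Variant integration.** Four TSV schemas (gnomAD-style allele counts,
ClinVar-style significance, Geno2MP-style CADD + phenotype-profile
counts, COSMIC-style tissue/histology) are aggregated into one summary
per residue, with the exact source-combination partition and a domain
**enrichment ratio**: (fraction of a gene's variants inside the domain)
/ (domain length / protein length), so 1 is the random expectation.

**Prioritization rules.** (i) domain positions with clinical variants in
≥2 paralogs and sites with multiple distinct changes in one gene;
(ii) in-domain Geno2MP sites with CADD > 20 and score ≥ 1;
(iii) outside-domain sites with score ≥ 1 and 21-codon window ≥ 10 seen
in any of ClinVar/Geno2MP/gnomAD; (iv) somatic variants restricted to
clinically annotated domain positions, summarized by tissue/histology.

**Synthetic families with exact truth.** A seeded generator emulates the
stated world (20 genes, ~100 species each, a 79-codon conserved domain
with 5% nonsynonymous substitutions vs 80% in the flanks) on a star
tree, recording per-codon truth counts that the counting statistics must
reproduce exactly.

## Worked example

Headline counts recomputed from the packaged curated HMG-box tables:

```r
library(orthovar)
r <- fixture_report()
r[c("n_multi_paralog", "n_multi_change", "n_geno2mp", "n_outside")]
#> $n_multi_paralog   27   # HMG-box positions with clinical variants in >=2 paralogs
#> $n_multi_change     9   # positions with multiple distinct changes in one gene
#>                         # (published headline count is 8; the printed source
#>                         #  table contains nine qualifying positions - see the
#>                         #  methods vignette)
#> $n_geno2mp         26   # in-domain Geno2MP calls with CADD > 20, score >= 1
#> $n_outside         56   # outside-domain conserved-context calls
```

Coordinate mapping (the SOX18 HMG box starts at protein residue 85):

```r
sox18 <- domain_annotation("SOX18", "HMG", 85, 163)
to_domain_position(137, sox18)    # 53  -> the E137K variant sits at 53/55
to_alternate_numbering(53)        # 55
to_domain_position(58, domain_annotation("SOX4", "HMG", 59, 137))  # -1
```

A synthetic family recovers its planted domain:

```r
cfg <- family_sim_config(n_genes = 3, species_per_gene = 60, seed = 42)
sim <- simulate_orthologs(cfg)
prof <- conservation_profile(sim$alignments[["GENE01"]])
dom <- prof$codon_index >= 61 & prof$codon_index <= 139
mean(prof$normalized_window[dom])   #> 0.879
mean(prof$normalized_window[!dom])  #> 0.076
```

The planted domain stands out by an order of magnitude in the
normalized window profile, as it should: 95% of domain substitutions are
synonymous, so domain codons collect high scores.

## Command line

```sh
Rscript inst/cli/orthovar.R simulate --out sim --seed 1
Rscript inst/cli/orthovar.R run-all --alignments sim/alignments \
    --annotations sim/annotations.tsv --gnomad sim/variants_gnomad.tsv \
    --clinvar sim/variants_clinvar.tsv --geno2mp sim/variants_geno2mp.tsv \
    --cosmic sim/variants_cosmic.tsv --out report
Rscript inst/cli/orthovar.R fixtures --out report
```

`run-all` writes `profiles.tsv`, `paralog_table.tsv`,
`site_summaries.tsv`, `overlap_categories.tsv`, `priority_calls.tsv`,
`enrichment.tsv`, `filter_log.tsv`, `summary.json`, `manifest.json`.

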