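# liposcan

Sequence-based metagenomic screening for lipolytic enzymes (esterases,
EC 3.1.1.1, and true lipases, EC 3.1.1.3) in R.

Function-driven screening — plating metagenomic libraries on tributyrin
agar and picking halo-forming clones — recovers lipolytic enzymes at rates
of only tens of hits per gigabase of cloned DNA. `liposcan` implements the
complementary *in silico* strategy: predicted proteins from assembled
metagenomes are screened against a database of per-family profile hidden
Markov models, confirmed by Smith-Waterman similarity search against a
family-labelled reference registry, and the resulting family abundance
profiles are compared across habitats. The package is fully self-contained:
seeded generators produce family-structured protein sets with labelled
decoys and habitat-structured community tables, so the whole pipeline can
be exercised and validated without any external database or binary.

## The method

**Screening and annotation.** Proteins of 200–800 aa are scanned against a
concatenated database of family profile HMMs (one per ESTHER-style
lipolytic family, built from that family's multiple sequence alignment)
with an E-value cutoff of 1e-10. The scoring engine is a Plan7-style local
log-odds model (free entry/exit over match states, Laplace pseudocounts,
Gumbel E-value calibration on background decoys) implemented in
R/Rcpp. Each putative lipolytic protein is then searched against the
reference registry by exact Smith-Waterman alignment, and the two evidence
tiers are combined:

* profile family and similarity family agree at ≥ 60 % identity and
  ≥ 70 % query coverage → **assigned** to that family;
* best similarity hit in a miscellaneous α/β-hydrolase family, or below
  the gates, or absent, or to a *different* lipolytic family →
  **unassigned**;
* strong similarity (≥ 60 %/≥ 70 %) to a non-lipolytic family →
  **non-lipolytic**.

Families II (GDSL), VIII (β-lactamase-like) and patatin-like proteins take
a separate route: a route-profile hit must be confirmed by a secondary
functional-family profile, and family VIII calls are restricted to
350–450 aa. Assignments can be verified with a sequence similarity
network (edges at E ≤ 1e-10 and alignment score ≥ 16).

**Comparative layer.** Per-sample family or genus counts are normalized to
LPGM (Lipolytic hits Per Gigabase per Million genes):

```
LPGM = count × (1e9 / assembly_bp) × (1e6 / gene_count)
```

Habitat structure is assessed on Bray-Curtis dissimilarities of
log10(LPGM + 1) profiles with Ward ("ward.D") clustering, ANOSIM (9,999
permutations), and point-biserial indicator associations that link genera
to the habitat subsets they indicate (P ≤ 0.05, mean LPGM ≥ 0.5) in a
bipartite habitat–genus network.

## Worked example

Hit-rate arithmetic for function-based screening libraries (shipped in
`inst/extdata/library_screening.tsv`):

```r
library(liposcan)
recs  <- read_library_records(system.file("extdata",
          "library_screening.tsv", package = "liposcan"))
rates <- library_hit_rates(recs)
format_library_rates(rates)[, c("library_id", "hits_per_million_clones",
                                "gb_screened", "hits_per_gb")]
#>   library_id      hits_per_million_clones gb_screened hits_per_gb
#> 1 compost55_pFLD                      231        3.58        43.6
#> 2 compost55_pCRXL                     183        1.32        32.7
#> 3 compost76_pFLD                      132        1.69        21.9
#> 4 compost76_pCRXL                      99        0.87        16.0
library_sample_totals(rates)[, c("sample", "total_gb_screened", "total_hits")]
#>   sample    total_gb_screened total_hits
#> 1 compost55              4.89        199
#> 2 compost76               2.56         51
```

So roughly 4.89 Gb of cloned compost DNA yielded 199 confirmed lipolytic
clones (about 41 hits/Gb) for the first compost, and 2.56 Gb yielded 51
for the second.

A small synthetic screen end to end:

```r
cfg  <- generator_config(seed = 1, n_families = 3, n_members = 8,
                         n_positives_per_family = 5, n_random_decoys = 6,
                         n_twilight_decoys = 3, include_pfam_route = FALSE,
                         n_nonlipolytic = 1)
fams <- gen_families(cfg)
dbs  <- synth_hmm_dbs(fams, n_decoys = 100, decoy_length = 200, seed = 42)
ps   <- gen_protein_set(cfg, fams)
dec  <- annotate_proteins(ps$proteins, dbs$elf_db, fams$reference_set,
                          fams$registry)
verdict_counts(dec)
#>   verdict        n
#> 1 assigned      15
#> 2 no_hit         9
#> 3 unassigned     2
```

All 15 true family members are assigned (identity ≈ 0.82–0.86, coverage
1.0 to their family's references); the random decoys get no profile hit
and the twilight decoys (~22 % identity) end up `no_hit` or `unassigned`,
never `assigned`.

Habitat comparison on a synthetic 4-habitat community:

```r
comm <- gen_community(generator_config(seed = 1))
ab   <- lpgm_normalize(comm$counts, comm$metadata)
d    <- bray_curtis(lpgm_log10(abundance_matrix(ab)))
an   <- anosim_test(d, comm$metadata$habitat, n_permutations = 9999, seed = 1)
an
#> ANOSIM: R = 0.7252, p = 0.0001 (9999 permutations, 24 samples, 4 groups)
indicator_analysis(ab, n_permutations = 999, seed = 1)
#> 10 significant positive associations; the 8 planted indicator genera are
#> recovered as unique habitat indicators (r ≈ 0.93-0.97, p = 0.001)
```

`run_pipeline(liposcan_config(out_dir = "run1", seed = 1))` performs all of
the above from one config and writes decision tables, profile databases,
the dendrogram (Newick), indicator tables and GraphML networks plus a
manifest under `run1/`.

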