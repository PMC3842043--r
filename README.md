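# bhlhscan

Genome-survey toolkit for basic helix-loop-helix (bHLH) transcription
factors, for researchers cataloguing a proteome's bHLH complement the way
the *Xenopus tropicalis* surveys did: find candidate domains, classify
them into the recognised families and supergroups, test the gene set for
functional enrichment, and map interaction-network hubs — entirely
offline, on plain-text inputs, with every step reproducible from a single
seed.

## The model

A bHLH domain is matched with the degenerate consensus

```
+ + X(3-6) E + X R X(3) a N X(2) f X(2) L + X(5-22) + X(2) K X(2) d L X(2) A d X Y a X(2) L
```

(`+` = K/R, `a` = I/L/V, `f` = F/I/L, `d` = I/V/T, `X` = any residue,
`X(i-j)` a variable spacer). The 19 non-wildcard positions are the
diagnostic sites; a placement's score is its number of diagnostic-site
violations, and a sequence whose best placement has **at most 9
mismatches** is a putative bHLH protein. Hits are segmented into
basic / helix 1 / loop / helix 2 and diagnosed for E-box binding through
the invariant Glu/Arg pair (structurally Glu-9/Arg-12) plus the
basic-region K/R sites.

Downstream, domains are assigned to the 45 bHLH families (supergroups
A–F, or orphan beyond 55% divergence) by anchored-alignment distance with
column-resampling bootstrap support and neighbor-joining placement; gene
sets are tested with the exact hypergeometric tail
P(X ≥ k | N, K, n) under pooled Benjamini–Hochberg correction; and
interaction networks are confidence-filtered at 0.15 with hubs called at
degree ≥ 5.

## Worked example

Generate a small proteome whose planted domains are diverged copies of
registry representatives, scan it, and classify the hits:

```r
library(bhlhscan)
reg <- load_family_registry()
p <- generate_proteome(mismatch_schedule = rep(0, 4), n_decoys = 3,
                       seed = 42, registry = reg, divergence = 0.10,
                       out_dir = "demo")
hits <- scan_proteome(p$fasta_path)
hits[, c("sequence_id", "start", "end", "mismatches", "binding_class")]
#>   sequence_id start end mismatches binding_class
#> 1  planted_01    21  66          3  E-box-binder
#> 2  planted_02    25  77          3  E-box-binder
#> 3  planted_03    27  88          2  E-box-binder
#> 4  planted_04    20  70          2    non-binder

doms <- setNames(substring(p$sequences[hits$sequence_id],
                           hits$start, hits$end), hits$sequence_id)
classify_domains(doms, reg, bootstrap = 100, seed = 1)
#>   sequence_id  family assigned_name supergroup nearest_reference   distance support_percent
#> 1  planted_01    ASCa          ASCa          A              ASCa 0.10869565             100
#> 2  planted_02    ASCb          ASCb          A              ASCb 0.09433962             100
#> 3  planted_03    MyoD          MyoD          A              MyoD 0.09677419             100
#> 4  planted_04 E12/E47       E12/E47          A           E12/E47 0.09803922             100
```

All four domains are found at their planted coordinates (the three decoys
yield nothing), recover their donor families with 100% bootstrap support,
and sit at ~10% distance — the divergence they were generated with. The
fourth domain's basic region was hit by the mutations, so it is flagged a
non-binder, the group-D-like configuration.

The packaged survey tables work the same way:

```r
s <- summarize_counts(load_catalog_fixture())
c(s$total, s$n_families, s$n_orphans)
#> [1] 105  43   2

tab <- bhlh_pathway_fixture()
sum(bh_correct(tab$p_value) <= 0.05)
#> [1] 6
```

`run_pipeline(run_config(...))` chains scan → classify → enrich →
network into one checkpointed, hash-stamped report bundle; see
`vignettes/bhlh-survey-methods.Rmd` for the full methods account.

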