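# apohot

Discovering APOBEC-associated hotspot mutations in tumour cohorts and
classifying them as drivers or passengers.

## The problem

APOBEC cytidine deaminases mutate cytosines in single-stranded DNA,
preferring TC dinucleotide contexts, and dominate the mutational
landscape of bladder cancer.  A site's recurrence across tumours
confounds two forces — local mutability and functional selection — so
recurrent ("hotspot") mutations are a mixture of true drivers and
highly mutable passengers.  `apohot` is for cancer genomicists who want
to take a cohort SNV table and answer, reproducibly: which mutations
are hotspots, which of those are APOBEC's work, and which of *those*
actually drive the tumour.

The pipeline:

1. **Hotspot calling** — the recurrence threshold is the smallest
   integer *t* with N(count > t) / N(count = t) > 1, the head/tail
   boundary of the long-tail count distribution.
2. **APOBEC association** — per-sample 96-channel catalogues are
   refit against fixed signature profiles by multinomial EM; the
   APOBEC score is the summed fraction of the two APOBEC signatures;
   TCN→T[G/T]N hotspot carriers are tested against candidate-free
   samples (one-sided rank-sum, BH-adjusted).
3. **Structural context** — replication-strand asymmetry from RFD
   (OK-seq) tracks, and DNA hairpin folding of 25-nt windows by a
   nearest-neighbour minimum-free-energy dynamic programme, yielding a
   normalised loop stability score: 0 = the panel's most stable hairpin
   loop, 1 = not in a loop at all.
4. **Driver/passenger classification** — each mutation is a point in
   (loop stability, expression percentile rank); an iterative
   similarity classifier assigns unknowns to the closer of the known
   driver / known passenger reference sets when a Welch *t* test on the
   two distance samples is significant, then estimates FDR by
   exhaustively relabelling the 16 seeds over all C(16,9) = 11,440
   driver/passenger assignments (mean difference of distance, MDoD,
   as the statistic).
5. **Regulon analysis** — an AhR regulon is built from co-expression
   with the *AHR*/*CYP1A1* anchor pair, validated against knockdown
   differential expression, scored per sample by rank-based enrichment,
   and compared across alteration groups.

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_cohort()`, `simulate_expression()`, `simulate_knockdown()`,
`simulate_rfd()`) emulates every input with planted ground truth, so
the whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(apohot)

# a 150-sample synthetic cohort with planted hotspots (seeded)
cfg <- sim_config(n_samples = 150, mut_mean = 80,
                  planted_sites = local({
                    p <- default_planted_sites()
                    p$baseline <- p$baseline * 4   # keep carrier counts at 602-cohort levels
                    p
                  }),
                  tail_counts = c("2" = 75, "3" = 33, "4" = 5, "5" = 3),
                  n_bg_genes = 400, n_expr_genes = 600, seed = 42)
sim <- simulate_cohort(cfg)
sim$cohort
#> <cohort_table> 12816 SNVs in 150 samples (150 patients)

panel <- call_hotspots(sim$cohort)
attr(panel, "threshold")                      # head/tail recurrence threshold
#> [1] 3
exposures <- fit_signature_exposures(build_96_catalog(sim$cohort),
                                     cfg$signatures)
panel <- hotspot_association_test(panel, apobec_score(exposures))
sum(panel$apobec_associated, na.rm = TRUE)    # APOBEC-associated hotspots
#> [1] 34

# hairpin at a planted passenger site: a stable stem-loop, centre in loop
fold_mfe(panel$context25[match("PSG01", panel$gene)])
#> AAACCGGGCCTTCAAGGCCCGGAAA
#> ...((((((((...))))))))...  dG = -9.55 kcal/mol  [centre in loop]
```

The recurrence threshold 3 separates this miniature cohort's head from
its tail (the full-size default cohort yields 4); 34 of 40 TCN-motif
candidates show significantly elevated carrier APOBEC scores; the
planted passenger folds into a −9.6 kcal/mol hairpin with the mutated
cytosine exposed in the loop.  Running the whole pipeline and
classifying the unknown sites:

```r
res <- run_pipeline(pipeline_config(tempfile("demo"), sim = cfg,
                                    run_strand = FALSE, seed = 42))
table(res$result$predicted_label)
#>    driver passenger
#>        12         6
head(res$result[order(res$result$fdr),
                c("key", "predicted_label", "mdod", "perm_p", "fdr")], 3)
#>                  key predicted_label   mdod   perm_p      fdr
#> 1 chr1:110200579:C:T          driver  0.980 8.74e-05 8.74e-05
#> 2  chr1:16470118:C:T          driver  1.046 8.74e-05 8.74e-05
#> 3 chr1:112757958:C:T       passenger -0.694 8.74e-05 8.74e-05
```

Every resolved planted site recovers its generating class here
(accuracy 1.0 on this seed); positive MDoD means the point sits closer
to the driver references, and the minimal attainable permutation p is
1/11,440 ≈ 8.7e-05.

The shipped reference signature matrix is **synthetic** (profiles "2"
and "13" are APOBEC-like by construction); substitute a real catalogue
via `read_signature_reference()` for real-data work.  A published
44-hotspot bladder-cancer panel is included as a parseable fixture
(`inst/extdata/bca_apobec_hotspot_panel.tsv`).

## Documentation

The methods vignette (`vignettes/apobec-hotspot-methods.Rmd`) documents
the models, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices, and known limitations.
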