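# mirwound

Wounding rapidly remodels the small-RNA landscape of plant leaves. In
sweet potato (*Ipomoea batatas*), miR408 is repressed within 30 minutes
of mechanical wounding and releases its targets — plantacyanin-like
(*IbPCL*), 3-ketoacyl-CoA synthase 4-like (*IbKCS*) and
galacturonosyltransferase 7-like (*IbGAUT*) — as part of the wound
response. mirwound implements, as a tested and reusable R package, the
computational chain such a study runs between the sequencer and the
biology:

1. **smallrna_quant** — collapse small-RNA libraries, assign reads to a
   mature-miRNA catalog by perfect full-length match, normalize to reads
   per million (RPM = count / depth × 10⁶), and classify wound response
   from the wounded/unwounded ratio *r*: induced when *r* > 1.2,
   repressed when *r* < 0.8, unchanged in between.
2. **precursor_finder** — locate contigs containing the mature sequence
   exactly, fold a flanking window (ViennaRNA MFE by default, a weighted
   maximum base-pairing DP as the self-contained alternative), accept
   stem–loops in which the mature pairs a single opposite arm (the
   miRNA:miRNA\* duplex), and predict the star strand with the standard
   2-nt 3′ overhang.
3. **target_predictor** — score miRNA:mRNA complementarity with the
   penalty scheme *P* = 1·(mismatches) + 0.5·(G:U wobbles) + 2·(gaps);
   candidate sites need *P* ≤ 3 and no mismatch in the central region
   (miRNA positions 9–11 from the 5′ end).
4. **cleavage_mapper** — convert 5′-RLM-RACE and 3′-PPM-RACE clone
   endpoints into scission positions on the miRNA axis ("cleaved at the
   *k*th nucleotide" = the cut between the target bases pairing miRNA
   positions *k* and *k*+1), merge the chemistries, and call the modal
   cleavage site.

A seeded synthetic-data generator (**synthetic_data**) emulates every
input — two-condition libraries with planted RPM and ratios, contigs with
planted hairpins, target sites and decoys, RACE clone sets with planted
scissions — so the whole pipeline is testable without downloads. The
**pipeline** module (`run_quant`, `run_precursor`, `run_targets`,
`run_cleavage`, `run_all`, `simulate_experiment`) orchestrates the stages
from a YAML config and writes TSV reports plus an md5 manifest; a thin
CLI wrapper lives at `inst/cli/mirwound.R`.

## Worked example

```r
library(mirwound)

## 1. quantification: libraries realizing the published miR408 RPM values
ex <- mir408_example()
libs <- make_libraries(ex$catalog, ex$rpm_plan, depth = ex$depth, seed = 1)
quantify_experiment(libs$control, libs$treated, ex$catalog)
#>     mirna_id              sequence rpm_control rpm_treated  ratio regulation_class
#> 1  Ib-miR408 UGCACUGCCUCUUCCCUGGCU       290.9      197.04 0.6772        repressed
#> 2 Ib-miR408* ACGGGGACGAGGCGGAGCAUG         2.7        3.77 1.3963          induced
```

miR408 drops to 0.68 of its unwounded abundance (repressed, a 32%
decrease), while the rare star strand rises 1.4-fold — the published
behaviour, recomputed from synthetic reads.

```r
## 2. precursor: a planted hairpin with 2 stem mismatches is recovered
mir408 <- ex$catalog["Ib-miR408"]
pre <- make_precursor_contig(mir408, stem_mismatches = 2, seed = 11)
cand <- find_precursors(mir408, c(contig_1 = pre$contig))[[1]]
cand
#> hairpin_candidate: accepted, mature 151-171, arm 5p
cand$predicted_star
#> [1] "CCCGGGAAGAGGCUGUGCAUU"   # the planted star, exactly

## 3. targets: a site with one 5' and one 3' mismatch scores 2 points
tc <- make_target_contig(mir408, list(five_prime = c(gu = 0, mm = 1),
                                      three_prime = c(gu = 0, mm = 1)),
                         seed = 21)
scan_transcriptome(mir408, c(KCS_like = tc$contig))
#>   contig_id start end strand penalty gaps five_prime central three_prime   verdict
#> 1  KCS_like   100 121      +       2    0        0/1     0/0         0/1 candidate

## 4. cleavage: 30 noisy RACE clones around the canonical slicer site
sites <- scan_transcriptome(mir408, c(KCS_like = tc$contig))
aln <- attr(sites, "alignments")[[1]]
clones <- make_race_clones(aln, true_position = 10, noise_sd = 1, n = 30,
                           seed = 41)
tally_cleavage(clones, aln)
#> cleavage_profile for KCS_like: modal position 10 (30 mapped clones, 0 unmapped)
```

The penalty/region columns print in the published style: `0/1` is
"0 GU wobbles / 1 mismatch" in that region.

## Vignette

`vignettes/mirwound-methods.Rmd` documents the models, parameter
defaults (with units and rationale), numerical conventions, and known
limitations.
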