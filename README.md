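# mirfree

Genome-free discovery of microRNAs from small-RNA deep-sequencing
libraries.

`mirfree` is for researchers working on organisms **without a sequenced
genome** who still need to turn raw small-RNA reads into an annotated miRNA
catalogue. Instead of mapping to a reference, the pipeline works from the
sequences themselves:

1. **Pre-process** — collapse identical reads, drop sequences < 19 nt, with
   ambiguous bases, or with ≤ 5 reads; flag 36-nt artefact reads with
   U-rich 3' tails.
2. **Cluster** — single-linkage clustering of 5'/3' end variants at 90%
   identity / 80% coverage (coverage on the shorter sequence), most
   abundant read as representative.
3. **Annotate** — known miRNAs by per-family position-specific scoring
   matrices (log-odds with pseudocount 0.25, ±3-nt offset scan, ≥ 90%
   identity); miRNA\* by aligning full reads against mature-masked hairpins
   (`N` matches nothing); rRNA/tRNA/snRNA/piRNA-like/endosymbiont
   contaminants by exact matching at 100% identity / 95% coverage.
4. **Candidate network** — unassigned sequences with ≥ 100 reads become
   nodes; edges at 90% identity / 95% coverage; connected components plus
   fast-greedy modularity communities (`Q = Σ_i (e_ii − a_i²)`) define
   non-redundant candidates, classified conserved/specific against
   other-species small-RNA sets.
5. **Precursors** — candidates are mapped onto assembled contigs (both
   strands); contigs with two distinct non-overlapping candidates are
   folded by base-pair maximization (A-T, G-C, G-T; min loop 3) and
   miRNA:miRNA\* duplexes are called when the two candidates sit on
   opposite arms with ≥ 60% inter-arm pairing.
6. **Statistics** — Shannon diversity `H' = −Σ p_i ln p_i` per library and
   class; Pearson correlation of read counts vs qPCR abundances (> 100
   reads, Student-t significance); an efficiency-corrected expression-ratio
   randomization test (`E_t^ΔCt_t / E_r^ΔCt_r`, pair-wise fixed
   reallocation of group labels) for RNAi knockdown validation.

A ground-truthed synthetic-library generator (planted hairpin precursors,
power-law abundances, end heterogeneity with untemplated U/A additions,
artefact and contaminant classes, whole-body-like and ovary-like presets)
makes every stage testable offline.

## A worked example

Simulate two libraries, run the whole pipeline, and look at what it found:

```r
library(mirfree)

cfg <- pipeline_config(outdir = "demo_run", seed = 1)
run_pipeline(cfg)

read.delim("demo_run/network_summary.tsv")
#>                  metric      value
#> 1          n_components 60.0000000
#> 2  major_component_size 75.0000000
#> 3               Q_major  0.1135108
#> 4       n_modules_major  2.0000000
#> 5          n_candidates 61.0000000

read.delim("demo_run/correlation.tsv")
#>   library         R            p n_used
#> 1      WB 0.9993812 7.135048e-16     12
#> 2      Ov 0.9986976 1.256794e-11     10

d <- read.delim("demo_run/duplexes.tsv")
table(d$verdict)
#> duplex rejected
#>     22        2
```

Reading these numbers: the 61 non-redundant candidates come from a
similarity network of 60 connected components whose largest (75 end
variants of the dominant candidate) splits into 2 modules at modularity
0.114; read counts of the known miRNAs track the simulated qPCR abundances
(R ≈ 0.999 in both libraries after the > 100-read filter); and 22 of the 24
planted novel precursor contigs yield a called miRNA:miRNA\* duplex, with
none called on the shuffled decoy contigs.

Individual operations are plain functions, e.g.:

```r
f <- fold_hairpin(paste0(strrep("C", 22), strrep("A", 8), strrep("G", 22)))
f
#> hairpin_fold: 52 nt, 22 pairs
#> CCCCCCCCCCCCCCCCCCCCCCAAAAAAAAGGGGGGGGGGGGGGGGGGGGGG
#> ((((((((((((((((((((((........))))))))))))))))))))))
#> arms: 5' [0,22) / 3' [30,52), pairedness 1.00 / 1.00

shannon_index(c(10, 10, 10, 10))
#> Shannon H' = 1.3863 over 4 categories (max 1.3863)
```

A thin command-line front-end over the same functions ships in
`inst/scripts/mirfree.R`:

```sh
Rscript inst/scripts/mirfree.R all --outdir demo_run --seed 1
```

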