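# pyroprofile

Stage-resolved gene expression profiling from multiplexed, MID-barcoded
pyrosequencing reads — the kind of design used to chart early development
in marine invertebrates, where seven synchronized embryonic/larval cDNA
libraries (two-cell through postlarva) plus one adult tissue library are
barcoded, pooled on a single 454-class run, and read counts per
contig/scaffold stand in for expression levels.

The package is for analysts working with (or teaching about) low-depth
counting transcriptomics, where the central question is not differential
testing but *which temporal profiles are reliable at all*. It provides:

* **Preprocessing** — MID demultiplexing with an exact/near-exact 5'
  barcode match, adaptor and quality trimming, removal of reads < 50 bp,
  and per-library exact-duplicate removal (`demultiplex()`,
  `clean_reads()`, `dedup()`).
* **Profiling** — best-hit read-to-contig assignment at `E < 1e-30` from
  BLAST tabular hits or a built-in k-mer mapper, a genes x libraries count
  matrix, and per-million normalization
  `1e6 * count / (library non-redundant total)` (`resolve_best_hits()`,
  `build_count_matrix()`, `normalize_per_million()`).
* **Reliability stars** — the Poisson counting-error model
  `E[%] = 100 k / sqrt(N)` with its 16-count cutoff at the one-sigma 25%
  level; count-depth stars `tau_sigma = floor(sqrt(min_i N_i)/4)`; Dixon
  r10 outlier stars on the seven expression points at the n = 7 critical
  values 0.507/0.568/0.680 (90/95/99%); genes with 2+ total stars become
  candidates (`relative_error()`, `cutoff_count()`, `tau_sigma_stars()`,
  `dixon_q()`, `star_table()`).
* **Clustering** — zero replacement (0.0002), 3x median centering, 5x
  unit sum-of-squares row scaling, centroid-linkage trees for genes and
  stages, and Cluster 3.0 / Java TreeView CDT/GTR/ATR output
  (`cluster_expression()`, `write_treeview()`).
* **qPCR concordance** — internal-control-gene normalization (geometric
  mean), fold-change rescaling, Pearson `r` with strong (`r > 0.75`) /
  acceptable (`r > 0.6`) classification (`concordance_table()`).
* **A synthetic-data generator** — seven-stage expression archetypes
  (maternal decay, trochophore spike, postlarval rise, housekeeping,
  background), multinomial counts at the study's library depths, decorated
  reads with errors and duplicates, and qPCR panels, all with ground truth
  (`sim_config()`, `build_program()`, `sample_counts()`, `emit_reads()`,
  `simulate_qpcr()`).

## Worked example

```r
library(pyroprofile)

# simulate the eight-library study design
cfg  <- sim_config(n_genes = 300, seed = 1)
prog <- build_program(cfg)
cm   <- sample_counts(prog, seed = 101)
cm
#> count_matrix: 300 genes x 8 libraries
#> library totals: 2CELL=38923 MORU=33423 TROC=41160 19VEL=30296
#>   58VEL=22441 74VEL=14853 144PL=67916 INTE=58026

# reliability stars and candidate selection
st <- star_table(cm)
head(st[st$candidate, ], 3)
#>    gene_id total_count tau_sigma_stars q_stars     q_max q_confidence
#> 1 gene0001          96               0       3 1.0000000           99
#> 2 gene0002         233               0       3 0.9898734           99
#> 3 gene0003          61               0       3 0.9842391           99
#>   total_stars candidate
#> 1           3      TRUE
#> 2           3      TRUE
#> 3           3      TRUE
sum(st$candidate)
#> [1] 159
```

The first genes are maternal-decay transcripts: their expression collapses
after the two-cell stage, so the high point is a 99%-confidence Dixon
outlier (3 stars), while the post-collapse stages have too few counts for
any count-depth star. 295 of 300 simulated genes pass the 16-count filter
and 159 carry 2+ stars.

```r
# cluster the candidates and write TreeView-compatible files
mod <- cluster_expression(candidate_expression(st))
mod
#> cluster_model: 159 genes x 7 stages (centroid linkage, pearson)
write_treeview(mod, "candidates")   # candidates.cdt/.gtr/.atr

# validate a 5-gene panel against simulated qPCR (2 housekeeping ICGs)
hk    <- prog$genes$gene_id[prog$genes$archetype == "housekeeping"][1:2]
panel <- prog$genes$gene_id[prog$genes$archetype == "trochophore_spike"][1:5]
qp <- simulate_qpcr(prog, panel, noise_sd = 0.1, seed = 7)
ct <- concordance_table(normalize_per_million(cm), qp, icg_ids = hk)
ct
#>    gene_id         r  class
#> 1 gene0031 0.9997929 strong
#> 2 gene0032 0.9997496 strong
#> 3 gene0033 0.9998931 strong
#> 4 gene0034 0.9993662 strong
#> 5 gene0035 0.9996990 strong
```

All five trochophore-spike panels correlate above 0.999 with their qPCR
series: a single dominant stage survives counting noise, ICG normalization
and measurement noise essentially intact.

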