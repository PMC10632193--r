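# derseg

Annotation-free discovery of **differentially expressed regions (DERs)**
between two biological conditions from stranded RNA-seq.

Most differential expression pipelines count reads over annotated genes,
so transcript variation that the annotation does not describe — 5'/3'
extensions, retained introns, antisense RNAs, processing intermediates —
is invisible to them. `derseg` works directly on the per-base signal: it
computes the per-base log2 fold-change between conditions,

```
Y_i = mean_r log2(Q_i,1,r + 1) − mean_r log2(Q_i,2,r + 1),
```

where `Q` is a per-base, per-strand coverage summary (by default the
geometric mean of the 5'-end and 3'-end read counts on the +1 scale), and
segments `Y` exactly under the Gaussian mean-shift model by
functional-pruning optimal partitioning (FPOP), minimising

```
sum_j sum_{i in seg j} (Y_i − mu_j)^2 + D · lambda · sigma^2 · log(n)
```

over *all* segmentations (`D` = number of changepoints, `lambda = 2` by
default). Each segment is then tested with a two-group negative-binomial
Wald test (median-of-ratios size factors, Cox–Reid dispersion),
BH-adjusted, and DERs are called as the largest p-ordered set of segments
with fold change > 1.5 (or < 2/3) whose **post-hoc false discovery
proportion bound** — from the Simes family, `t_k = alpha·k/m` — stays at or
below 5%. DERs can be labelled against the nearest annotation (seven
classes: inside, overlapping 5'/3'/both, antisense, upstream, downstream)
and everything exports to BED/GFF3/bedGraph plus a one-click IGV session.

The package also ships a synthetic-data generator (planted DERs, NB noise,
exact-coverage BAMs), blank-design resampling, and the label-based
TPR / blank FPR evaluation metrics, so the whole pipeline is testable
without any external data.

## Worked example

Simulate a 4 kb window with one planted DER (log2-FC +2 on the forward
strand at 1101–2100), two replicates per condition, and run the fit:

```r
library(derseg)

scen <- simulation_scenario(
  genomic_window("chrS", 101, 4100),
  baseline = 20,                       # mean 5'-end count per base
  planted_ders = data.frame(start = 1101, end = 2100,
                            strand = "+", effect = 2),
  dispersion = 0.05, reps_per_condition = c(2L, 2L), seed = 31L)

ss  <- simulate_experiment(scen, "sim_bams")   # writes 4 indexed BAMs
fit <- derseg(ss, "chrS:101-4100", reference_condition = "control")
summary(fit)
```

```
Differential-region analysis over chrS:101-4100
  conditions: mutant vs control (reference)
  segments: 6 (6 tested)
  DERs: 3 (3 up, 0 down), FDP bound 0.000
  median width: DER 49, not-DER 1951
  normalization offset rho: 0.0091
  size factors: mutant_rep1=1.002, mutant_rep2=1.005, control_rep1=0.999, control_rep2=0.995
```

The planted region is recovered as up-regulated DERs; the two flanking
49 bp DERs are the half-effect plateaus that the read-length shift of the
3'-end profile creates at each planted boundary under the geometric
coverage mode (see the methods vignette):

```r
ders(fit)
```

```
GRanges object with 3 ranges and 3 metadata columns:
      seqnames    ranges strand | mean_log2fc log2FoldChange        padj
         <Rle> <IRanges>  <Rle> |   <numeric>      <numeric>   <numeric>
  [1]     chrS 1101-1149      + |    1.002193        1.32231 3.76486e-69
  [2]     chrS 1150-2100      + |    1.961307        1.98324 0.00000e+00
  [3]     chrS 2101-2149      + |    0.966532        1.31299 1.49640e-68
```

`tpr(planted_labels(scen), ders(fit))` returns `1`: the planted label is
recovered. `write_tracks(fit, "tracks")` emits the browser-ready bundle
(segmentation and DER GFF3/BED, per-condition mean log2-coverage and
per-base log2-FC bedGraphs per strand, IGV session XML), and
`write_results(fit, "results.tsv")` the per-segment table.

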