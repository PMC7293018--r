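# tssanchor

Positional analysis of transcription-factor binding around transcription
start sites, for factors that occupy CpG-island promoters *downstream* of
the TSS.

## The problem

Classical promoter TFs bind a short element upstream of the TSS. A family
of C2H2 zinc-finger factors typified by ZFX/ZNF711 behaves differently:
their ChIP-seq peaks blanket thousands of CpG-island promoters, the summit
frequency peaks near **+240 bp** (inside the 5' UTR / first exon / first
intron), with a weaker shoulder near **−240 bp**, and genes bound
downstream are the ones that lose expression when the factor is knocked
out — the signature of an activator working from inside the transcribed
region. Analysing such factors needs a positional toolkit:

* **Annotation** — strand-aware signed distance of each peak summit to the
  nearest TSS (downstream positive: on a minus-strand gene, +240 means 240
  bp 5'→3' into the gene), promoter/non-promoter and CGI/non-CGI calls,
  gene-structure classification (5' UTR, first coding exon, first intron,
  …).
* **Signal** — TSS-anchored matrices from binned coverage; tag-density and
  summit-histogram profiles with smoothed mode/shoulder detection; K-means
  clustering of row-max-normalized profiles (k-means++/Lloyd, seeded) with
  amplitude-based cluster naming and subclustering of the "combination"
  cluster; ChIP-seq vs ChIP-exo width statistics; genome-wide track
  correlation; bound-vs-unbound group signal ratios.
* **Motif null** — coverage (fraction of regions with ≥1 hit) of literal or
  IUPAC motifs, compared against width-matched regions sampled from
  CpG-island promoters at nested widths (20 nt / 200 bp / 2 kb) and against
  summit ± 10 nt windows. This is the control showing that a GC-rich motif
  like `GGCCT` is found in essentially *every* 2 kb island-promoter region,
  so only narrow-window coverage is informative.
* **Expression** — per-clone DEG calling (moderated t, BH, and the
  "adjusted p < 0.05 and fold change > 1.5" rule), exact cross-clone
  consensus sets (all clones / ≥2 clones), bound-fraction-by-cluster
  integration, and responding-promoter intersection with a re-expression
  rescue.
* **Methylation** — beta = M/(M+U) with detection-p masking, promoter
  probes from TSS−1500 through the first coding exon, and hypo/hyper
  classification at |Δβ| > 0.2.
* **Simulation** — a seeded generator for a toy genome (CpG-island
  promoters with Markov-chain island composition), positional peak
  mixtures (near modes at ±240, far modes at ±2 kb, diffuse background),
  planted motifs, negative-binomial knockout counts and methylation
  intensities, with truth manifests for every planted feature.

Everything is a `GRanges`/`DNAStringSet`-based API in the Bioconductor
idiom; readers and writers cover BED, narrowPeak, GTF (GENCODE dialect),
FASTA, bedGraph and TSV tables.

## Worked example

Simulate 2,500 peaks over 3,000 promoters under the default positional
mixture, annotate them, and cluster:

```r
library(tssanchor)

virt <- simulate_transcripts(n_genes = 3000, seed = 42)
sim  <- generate_peaks(virt$models, peak_mixture_config("seq"),
                       n_peaks = 2500, chrom_lengths = virt$chrom_lengths,
                       seed = 42)
ann  <- assign_nearest_tss(sim$peaks, virt$models)
summit_histogram(ann)
#> DensityProfile: 301 bins, primary mode 240 bp, shoulder -240 bp

tssdf   <- tss_of(virt$models)
i       <- match(ann$transcript_id, tssdf$transcript_id)
anchors <- data.frame(peak = ann$peak, chrom = ann$chrom,
                      tss = tssdf$tss[i], strand = tssdf$strand[i])
mat <- build_signal_matrix(sim$track, anchors, window = 3000, id_col = "peak")
km  <- kmeans_positional(mat, k = 4, seed = 1)
name_clusters(km)
#>   cluster label      role  mode amplitude size
#> 1       1     1 near_down   260 2156.2058  830
#> 2       2     2   near_up  -280 1283.6740  530
#> 3       3     4    far_up -2000  753.1695  583
#> 4       4     4  far_down  1980  702.9555  557
peak_width_stats(sim$peaks)$mean
#> [1] 1862.131
```

Reading: the summit histogram recovers the planted +240 downstream mode
and −240 upstream shoulder; clustering finds the strongest cluster just
downstream of the TSS (labelled "1"), an upstream cluster ("2") and the
±2 kb far clusters that make up the "combination" group ("4"); mean peak
width is ~1.8 kb in ChIP-seq mode (regenerating in `"exo"` mode drops it
to ~300 bp). `run_synthetic_demo()` chains all of this with motif-null,
consensus-expression and methylation stages and returns every headline
number in one list.

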