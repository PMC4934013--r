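# riboscope

Analysis toolkit for **ligation-free (template-switching) ribosome
profiling** of complex tissue, aimed at researchers quantifying
translational control — in the brain especially — from matched ribosome
footprint and RNA-seq libraries.

Ligation-free libraries have a characteristic raw-read structure: a short
G-rich 5′ prefix left by terminal-transferase activity, the ~30 nt
ribosome-protected footprint, and a 3′ poly(A) run added enzymatically
before reverse transcription. `riboscope` implements the full computational
path from such reads to biology:

- **Preprocessing** — fixed trimming (first 5 / last 20 bases), clipping of
  `AAAAAAAA` runs at the 3′ end, the 15-nt length filter, rRNA subtraction
  (Hamming ≤ 1 substring match), a toy exact transcriptome mapper with
  uniquely-mapped semantics, and duplicate marking.
- **QC** — power spectrum of 5′ mapping positions (the 3-nt periodicity
  check; peak at 1/3 nt⁻¹), gene-body distribution (CDS ≫ 5′UTR > 3′UTR),
  and saturation curves of detected genes / unique fragments under
  downsampling.
- **Quantification** — per-region counting, DESeq2's median-of-ratios size
  factors (re-implemented directly), translation efficiency
  TE = normalized footprint CDS counts / normalized RNA CDS counts with the
  37-count (per-sample) and 75-count (group) raw thresholds, RiboTag
  IP/homogenate enrichment scores, and the qPCR conversion
  `abundance = 2^(1−CQ)` with max-normalization.
- **Cell-type enrichment** — per-gene scores
  `E_ij = FPKM_ij / Σ_k FPKM_ik − 1/2 ∈ [−0.5, 0.5]` from a 7-cell-type
  expression reference; specific gene lists at `E > 0.2`; pairwise
  comparison scores `Es = E_ik / E_ij`.
- **Pre-ranked classic GSEA** — unweighted running statistic, gene-set
  permutation null, NES, nominal p, FDR q; TE gene sets binned in 0.75
  log2-TE-unit windows around the median; GO → cell-type assignment by the
  3-NES-unit margin rule.
- **5′UTR features** — UTR ribosomal-density flags, overlapping uAUG scan,
  isoform-abundance-weighted UTR length and GC, binned median TE, and
  Mann–Whitney U tests (exact for small samples, midrank ties).
- **Differential TE** — treated-vs-untreated TE and RNA fold changes, a
  clearly-labelled permutation + Benjamini–Hochberg substitute for the
  external GLM tool, and the flagged/TOP/ribosomal-protein Venn overlap.
- **Synthetic data** — a generator emulating the statistical structure the
  analysis assumes (periodic CDS-biased footprints, bimodal neuronal TE,
  RiboTag enrichment, TOP repression under mTOR inhibition), so every stage
  is testable offline with known ground truth.

## Worked example

```r
library(riboscope)

cfg <- sim_config(n_genes = 300, seed = 42)
sim <- simulate_annotation(cfg)
fp  <- simulate_footprints(sim, condition = "untreated", depth = 2e5,
                           emit_reads = FALSE)

periodicity_spectrum(fp$alignments, sim$models)
#> periodicity spectrum: peak at 0.3333 nt^-1 over 300 nt window
round(gene_body_distribution(fp$alignments, sim$models), 3)
#> utr5  cds utr3
#> 0.10 0.85 0.05

ribo <- count_regions(fp$alignments, sim$models, sample = "ribo_1")
rna  <- simulate_rnaseq_counts(sim, depth = 2e5)
te   <- translation_efficiency(ribo, rna, mode = "per_sample")
sum(te$passed_threshold)          # 287 of 300 genes pass the 37-count filter

E    <- enrichment_scores(sim$fpkm)
length(specific_gene_list(E, "neuron", cutoff = 0.2))   # 17 genes

keep <- te$passed_threshold
bins <- te_bins(setNames(te$log2_te[keep], te$gene[keep]), width = 0.75)
hm   <- nes_heatmap(bins, list(neuron = setNames(E[, "neuron"],
                                                 rownames(E))),
                    n_perm = 500, seed = 1)
round(hm$nes, 2)
#>        [-2.92,-2.17) [-2.17,-1.42) ... [0.08,0.83) ... [2.33,3.08)
#> neuron          1.16          1.59        -1.99            2.75
```

The peak at 1/3 nt⁻¹ is the single-codon translocation signature; the
gene-body split recovers the generator's (0.10, 0.85, 0.05) target; and the
NES row is the package's version of the bimodal-neuronal-TE heatmap:
neuron-specific genes are enriched in both the lowest and highest TE bins
(NES > 1 at both extremes) and depleted from the middle (NES ≈ −2), i.e.
neuronal genes are either very highly or very lowly translated. The
estimated log2 TE of the passing genes has Spearman correlation 0.94 with
the generator's ground truth at this depth.

## Command line

A thin CLI wraps the main file-to-file steps:

```sh
riboscope preprocess --fastq reads.fastq --annotation models.tsv \
                     --rrna-fasta rrna.fa --out-dir pre/
riboscope qc        --alignments pre/alignments.tsv --annotation models.tsv --out-dir qc/
riboscope quant     --ribo ribo_counts.tsv --rna rna_counts.tsv --mode group --out te.tsv
riboscope celltype  --fpkm fpkm.tsv --out-dir celltype/
riboscope gsea      --rnk celltype/neuron.rnk --gmt te_bins.gmt --out gsea.tsv
```

See `vignettes/riboscope-methods.Rmd` for the model assumptions, parameter
choices, and known limitations.
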