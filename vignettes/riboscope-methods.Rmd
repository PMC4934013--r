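---
title: "riboscope: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboscope: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscope)
```

# The measurement model

Ribosome profiling sequences the ~30 nt mRNA fragments protected by
translating ribosomes. Two structural signatures distinguish genuine
footprint libraries from fragmented RNA: the 5′ mapping positions advance in
3 nt steps (codon translocation), giving a power-spectrum peak at 1/3 nt⁻¹,
and reads concentrate in coding sequences, with more 5′UTR than 3′UTR
density because of upstream ORFs.

The central quantity is **translation efficiency**,

$$\mathrm{TE}_g = \frac{\text{normalized footprint CDS count}_g}
                      {\text{normalized RNA-seq CDS count}_g},$$

proportional to ribosomes per transcript. Because TE is a ratio, the TE of a
cell-type-specific gene measured in homogenized tissue is valid both for the
tissue and for the expressing cell type — which is what makes bulk profiling
of brain informative about individual cell populations when combined with a
sorted-population expression reference.

In a ligation-free (template-switching) library each raw read is

```
[G-rich prefix ~5 nt][footprint 28-31 nt][poly(A) run >= 8 nt ... to read end]
```

so preprocessing is structural, not adapter-matching: drop the first 5 and
last 20 bases, clip from the leftmost run of ≥ 8 A's to the 3′ end, and
discard anything shorter than 15 nt.

# Pipeline stages and their conventions

**Coordinates.** Transcript coordinates are 0-based half-open on the sense
strand: 5′UTR = `[0, cds_start)`, CDS = `[cds_start, cds_end)`, 3′UTR =
`[cds_end, length)`. Footprints map to transcripts, never to the genome, so
there is no strand logic anywhere.

**Poly(A) clipping.** The clip starts at the leftmost occurrence of eight
consecutive A's and removes everything downstream, with no mismatch
tolerated inside the run (fastx_clipper-like exactness). Trimming precedes
clipping. A footprint whose own 3′ end is adenosine-rich can lose those
bases into the clip; its 5′ position — the only coordinate the analysis
uses — is unaffected.

**Mapping.** The bundled mapper is deliberately a toy: exact substring
search against the transcript set (Biostrings `PDict`), with reads matching
transcripts of more than one gene discarded as multimapped ("uniquely
mapped" semantics). How a genome aligner resolves ambiguity is not modelled;
discard-on-ambiguity is this package's documented choice. Within a gene,
ties go to the lowest transcript id, then the leftmost position — this
matters for isoforms sharing a CDS, where the footprint's transcript of
origin is unidentifiable and only gene/region assignment is meaningful.

**Periodicity spectrum.** The metagene series sums 5′-end counts at offsets
0..D−1 from each CDS start, with window D = 300 nt by default (a standard
choice; transcripts shorter than D contribute their prefix). Power is scaled
as $|X_k|^2 / D^2$ so the total over all D bins equals the variance of the
mean-subtracted series (Parseval), which the tests assert at 1e-9 relative
tolerance. The peak excludes the DC bin.

**Region assignment.** Every read is assigned to exactly one region by its
5′ end (single-assignment rule), including reads overlapping a boundary.

**Normalization.** Size factors are DESeq2's median-of-ratios formula
re-implemented directly: per-gene geometric mean across samples as
reference (genes with any zero excluded), per-sample factor = median of
count/reference. One subtlety the tests encode: multiplying one of $n$
samples by $c$ moves the geometric reference by $c^{1/n}$, so the sample's
factor grows by $c^{(n-1)/n}$ while factor *ratios* between samples grow by
exactly $c$ — the ratio is the meaningful, equivariant quantity.

**TE thresholds.** Raw counts below 37 in either assay exclude a gene in
per-sample mode; group mode (TE = the mean of per-sample TEs, a documented
reading of "the TE of both samples in a group") requires ≥ 75 raw counts in
every sample of both assays. Thresholds apply to raw counts — they are
integers, and positivity of the denominators then needs no pseudocount.

**Cell-type scores.** $E_{ij} = \mathrm{FPKM}_{ij} / \sum_k
\mathrm{FPKM}_{ik} - 1/2 \in [-0.5, 0.5]$, rows summing to $1 - n/2$
exactly; genes specific to a cell type at $E > 0.2$ (strict). The pairwise
comparison score $Es = E_{ik}/E_{ij}$ is implemented exactly as defined; for
genes where both scores are negative the ratio is positive yet means
"specific to neither", so such genes carry a `both_negative` flag and are
not reinterpreted.

**GSEA.** "Classic" means the unweighted statistic (exponent 0): hits add
$1/N_{hit}$, misses subtract $1/N_{miss}$, ES is the signed maximum
deviation (ties in magnitude resolve to the positive side, within a 1e-12
tolerance so the closed-form scan and a brute-force running sum agree
bit-for-bit). Without replicate phenotype profiles the only available null
is gene-set permutation: random same-size sets from the list, 1000 draws by
default. NES divides ES by the mean same-sign null ES; FDR q is the GSEA
ratio of normalized-null to observed tail fractions, clipped at 1. TE gene
sets use half-open bins of width 0.75 log2 TE units anchored at the median,
topmost bin closed; the bin *count* is emergent from the data range rather
than imposed, which reconciles a fixed-width construction with a round
number of bins on any particular data set.

**Mann–Whitney U.** Midranks for ties; exact two-sided p by complete
enumeration of group assignments when the pooled size is ≤ 12, otherwise a
normal approximation with tie and continuity corrections. The two branches
agree within 0.02 absolute p at the boundary.

**Differential TE.** The external GLM-based tool the field uses is *not*
re-implemented; the substitute — per-gene difference of mean per-sample
log2 TE between conditions, exact (or sampled) condition-label permutation,
Benjamini–Hochberg FDR at α = 0.05, plus a ≥ 2-fold amplitude requirement —
is named in the output's `method` attribute so results cannot be mislabeled.
With fewer than two samples per condition the permutation null does not
exist; the function then warns prominently and flags on fold change alone.

# The synthetic world

The generator states one fixed world; its defaults are the conditions the
analysis assumes, and they are not adjusted to make tests pass.

| parameter | default | why |
|---|---|---|
| footprint lengths | {28: 0.2, 29: 0.3, 30: 0.3, 31: 0.2} | ~30 nt footprints; no distribution is published for this protocol |
| periodicity strength | 0.9 | strong but imperfect frame-0 preference, as real libraries show |
| gene-body split | (0.10, 0.85, 0.05) | CDS-dominated with 5′UTR > 3′UTR |
| G-rich prefix | 5 nt from {G: 0.7, C: 0.1, A: 0.1, T: 0.1} | "G-rich low-complexity" is all that is known |
| read length | 75 nt | 75-cycle sequencing kit |
| neuronal log2 TE | 0.5·N(−1.5, 0.5) + 0.5·N(+1.5, 0.5) | bimodal: neuronal genes very highly or very lowly translated |
| other cell types | means 0.5 (OPC) > 0 (newly formed) > −0.5 (myelinating); −1 (microglia) | oligodendrocyte maturation gradient; quiescent microglia translate little |
| uAUG TE shift | −0.5 log2 | uAUG-bearing genes have lower CDS TE |
| 5′UTR length slope | −1 log2 across the length range | longer UTRs, lower TE |
| TOP repression | −2 log2, on 5% of genes, treated only | coherent TE collapse of TOP genes under mTOR inhibition |
| count noise | Poisson (NB optional, dispersion 0.1) | no overdispersion value is published |

Per-read structure is conserved exactly: prefix (5) + footprint + poly(A)
fill = read length, so the poly(A) run is always ≥ 8 nt and survives the
20-base 3′ trim with ≥ 8 A's intact. Sequence constraints are enforced by
construction: flagged genes contain ≥ 1 AUG in every isoform's 5′UTR,
unflagged genes none (with a deterministic AUG-free arrangement as a
fallback), and realized 5′UTR GC stays within the configured range.

**What a green test does and does not establish.** The generator matches the
analysis' *assumptions*, so green recovery tests establish internal
consistency — the estimators invert the stated generative law at realistic
depths — not field validity. Real libraries add what the generator omits:
sequence-dependent bias (ligation-free chemistry trades ligation bias for
G-prefix/poly(A) ambiguity at read ends), nucleotide-resolution P-site
offsets, overdispersion beyond Poisson, isoform-specific TE, and genuine
genome mapping ambiguity. Conclusions about real data need the QC module's
diagnostics, not the simulator.

**RiboTag identifiability.** IP counts are homogenate counts × `enrichment`
for target-cell-type genes and × `depletion` otherwise. Under
median-of-ratios normalization only enrichment *relative to the typical
gene* is identifiable; the default `depletion = 1` anchors the majority of
genes so the configured enrichment is recovered on the absolute scale
(tested at 4× within 10%). With `depletion < 1` (closer to a real IP)
recovered scores are inflated by 1/depletion — a normalization fact, not a
bug.

**Differential-TE power world.** The power/size check uses 7 replicates per
condition and 1e7 reads per sample. Both numbers are forced by the
machinery, not by the effect: exact label permutation with 2 + 2 samples has
only 6 arrangements (minimum two-sided p = 1/3), so *no* per-gene test can
clear FDR 0.05 — with 7 + 7 there are 3432; and at 1e6 reads the 75-count
group threshold censors ~40% of 4-fold-repressed TOP genes from the
analysis universe, capping apparent power at ~0.56 even though every
surviving gene is flagged. At 1e7 reads thresholding is no longer binding
and power over *all* TOP genes is ≥ 0.9 with no false flags.

# Numerical choices and degenerate inputs

- Determinism everywhere: every generator is a pure function of
  (config, seed); rank lists break ties lexicographically by gene id;
  saturation uses one fixed permutation so nested subsamples make the curves
  monotone by construction.
- Reads of raw length ≤ 25 nt become `too_short` with an empty sequence
  rather than raising an error; empty read sets flow through as empty
  outputs; an empty rRNA reference is an error (a silently disabled filter
  would be worse).
- Genes with zero total FPKM are dropped from enrichment scores with a
  message; an all-zero matrix is an error. Zero homogenate means exclude a
  gene from RiboTag scores.
- `log2(x + 1)` is the transform for between-library count correlation (the
  transform used for the published comparison is unstated; r from external
  data is not treated as reproducible).
- Size-factor estimation errors out when no gene is nonzero in all samples.

# Known limitations

- The mapper is exact-match only by default and transcriptome-only: no
  splice junctions, no quality model, no SAM/BAM output.
- No P-site offset calibration or codon-level pause analysis; the spectrum
  is a library-level QC, not a decoding of ribosome positions.
- The differential-TE statistic is a permutation substitute; it does not
  model count overdispersion the way a GLM would, and with the paper-scale
  2 + 2 design it degrades (with a warning) to fold-change flagging.
- uORF *translation* is not inferred — an AUG in the 5′UTR plus UTR density
  is evidence, not proof, of an active uORF.
- The GC/length bin edges for the binned-median-TE maps are configurable
  inputs; no canonical edges exist.
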