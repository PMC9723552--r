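# polyprobe

Design and in-silico evaluation of gene-targeted polynucleotide FISH
probes.

Gene-targeted fluorescence in situ hybridization (direct-geneFISH)
detects a gene of interest inside individual microbial cells with
directly dye-labeled double-stranded DNA probes of a few hundred base
pairs, while a 16S rRNA oligonucleotide probe identifies the cell. Unlike
oligonucleotide probes, polynucleotide probes tolerate mismatches, so the
hybridization stringency — set mainly by the formamide (FA) concentration
of the buffer — can be tuned deliberately: stringent conditions restrict
detection to near-identical genes, relaxed conditions capture homologous
genes in related taxa. `polyprobe` provides the computational side of
this workflow for people designing such experiments (microbial
ecologists, FISH method developers):

* **Stringency calculus** (`wetmur_tm`, `max_mismatch`, `recommend_fa`,
  `stringency_envelope`): the Wetmur melting-temperature model for
  DNA:DNA duplexes,

  Tm = 81.5 + 16.6 log10([Na+]/(1 + 0.7[Na+])) + 0.41 GC − 500/N − M − 0.63 FA

  with GC content in %, duplex length N in bp, mismatch M in % and
  formamide FA in % — and the derived trade-offs: how much mismatch a
  condition tolerates, and how far FA must drop to admit a given
  mismatch load.
* **Probe-set design** (`tile_gene`, `design_primers`): tiling a target
  gene into k consecutive, non-overlapping probes with matched Tm and GC
  content (so one hybridization condition suits the whole set), plus
  amplification primer pairs per probe.
* **Specificity screening** (`align_probe`, `set_hit`, `screen_probes`):
  deterministic semi-global alignment of each probe against a gene
  database (percent identity, longest mismatch-or-gap stretch, both
  strands), the set-level hit rule (at least 4 of 5 probes at ≥ 80%
  identity), and the predicted detectability of each target at a given
  FA.
* **PUL screening** (`find_puls`, `find_suscd_tandems`,
  `homolog_links`): calling candidate polysaccharide utilization loci on
  annotated contigs (≥ 1 susC/susD-like gene plus ≥ 2 degradative
  CAZymes), flagging glucuronomannan-like loci (GH92 + sulfatase), and
  computing homolog nucleotide-identity links between loci for synteny
  plots.
* **Detection-efficiency statistics** (`detection_efficiency`,
  `compare_groups`, `quantify_experiments`): per-field-of-view gene
  detection efficiencies and relative gene abundances (mean ± sample SD
  across FOVs), with the two-stage F-test / pooled-variance t-test
  comparison.
* **Synthetic data** (`simulate_gene_family`, `simulate_contigs`,
  `simulate_fov_counts`): seed-deterministic generators for homolog
  families at controlled identity, annotated contigs with planted PUL
  cassettes, and binomial FOV count tables, so everything is testable
  without downloads.

A command-line wrapper with subcommands `design`, `stringency`,
`screen`, `pulscan`, `links`, `quant` and `simulate` is installed at
`inst/cli/polyprobe` (all logic lives in `polyprobe_cli()`).

## Worked example

Design a probe set on a simulated gene, screen it against homologs of
known identity, and pick a relaxed FA for cross-taxon detection:

```r
library(polyprobe)

fam <- simulate_gene_family(ancestor_length = 2250,
                            identity_targets = c(95, 86, 70), seed = 1)
gene <- gene_target("geneA", fam$ancestor)
ps <- tile_gene(gene, preset = "genefish2021")   # 5 probes, 442-456 bp
ps
#> probe_set geneA: 5 probes covering [3, 2237) of the gene
#>   Tm spread 2.319 C, GC spread 5.687%, objective 8.0068
#>   probe_id start  end length gc_percent tm_ref_c
#> 1  geneA_1     3  455    452   48.45133 69.68037
#> 2  geneA_2   455  898    443   48.53273 69.69127
#> 3  geneA_3   898 1348    450   52.88889 71.49485
#> 4  geneA_4  1348 1790    442   54.07240 71.95998
#> 5  geneA_5  1790 2237    447   54.13870 71.99982

sr <- screen_probes(ps, fam$homologs, hyb_conditions(fa_percent = 35))
sr$set_table[, c("target_id", "n_probe_hits", "set_hit",
                 "implied_mismatch_percent")]
#>   target_id n_probe_hits set_hit implied_mismatch_percent
#> 1   id95_r1            5    TRUE                 4.473272
#> 2   id86_r1            5    TRUE                14.227906
#> 3   id70_r1            0   FALSE                       NA

# the 86%-identity homolog carries ~14% mismatch; to also detect it,
# relax the buffer from the stringent 35% FA design point:
recommend_fa(35, 14)
#> [1] 15
```

The screen says both the 95% and 86% homologs satisfy the set-level hit
rule (all five probes ≥ 80% identity), while the 70% homolog does not;
`recommend_fa` converts the 14% mismatch of the weakest intended target
into the FA reduction that compensates its Tm penalty (14/0.63 ≈ 22%,
i.e. 12.8% FA, rounded to the 15% buffer step).

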