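---
title: "Models and methods behind polyprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprobe)
```

`polyprobe` supports the computational half of gene-targeted FISH with
double-stranded polynucleotide probes: choosing probe tilings, predicting
how hybridization stringency maps onto tolerated sequence divergence,
screening probes for cross-hybridization, locating candidate
polysaccharide utilization loci (PULs), and summarizing microscopy count
tables. This vignette explains the models and the choices made where the
design was genuinely open.

## The melting-temperature model and the stringency calculus

All thermodynamics rest on one empirical closed form for DNA:DNA
duplexes, the Wetmur relation

$$T_m = 81.5 + 16.6\,\log_{10}\!\frac{[\mathrm{Na^+}]}{1+0.7\,[\mathrm{Na^+}]}
      + 0.41\,\mathrm{GC} - \frac{500}{N} - M - 0.63\,\mathrm{FA}$$

with sodium in mol/L, GC content and mismatch $M$ in percent, duplex
length $N$ in bp and formamide FA in percent (v/v). Its virtues here are
linearity in the two quantities an experimenter actually tunes: mismatch
costs exactly 1 °C per percent and formamide 0.63 °C per percent. Three
consequences drive the package:

* `max_mismatch()` — a duplex survives hybridization when its $T_m$
  exceeds the hybridization temperature (plus an optional safety margin
  `tm_margin_c`), so the tolerated mismatch is simply
  $T_m(M=0) - (T_{hyb} + \text{margin})$, floored at zero.
* `recommend_fa()` — to *also* capture a target carrying mismatch $M$,
  the formamide reduction that exactly cancels the penalty is $M/0.63$.
  Buffers are mixed in 5% steps, so the default rounds to the nearest
  multiple of 5 (`nearest-5-down` and `none` are selectable). A 14%
  mismatch target (86% identity) from a 35% FA design point gives
  $35 - 22.2 = 12.8$, i.e. a 15% FA buffer.
* `stringency_envelope()` — a $T_m$ grid over (FA, mismatch) plus the two
  derived curves, max tolerated mismatch per FA and required FA per
  mismatch.

$T_m$ is reported unclamped — values above 100 °C or below 0 °C are
meaningless physically but keep the algebra exact; only the comparison
against $T_{hyb}$ + margin is ever interpreted.

**Defaults.** `na_molar = 0.39`, `hyb_temp_c = 46`, `tm_margin_c = 0`.
Buffer sodium and hybridization temperature are properties of the wet-lab
protocol, not of this package; the defaults are placeholders typical of
geneFISH buffers and should be set to the protocol actually used.
Mismatch percent is defined as $100 -$ percent identity of the
probe–target alignment, which ties the thermodynamics to the specificity
module's identity definition. Nearest-neighbor thermodynamics, other salt
corrections and RNA:DNA hybrids are out of scope.

## Probe tiling

`tile_gene()` splits a gene into $k$ (default 5) adjacent,
non-overlapping, gap-free probes. "Consecutive" is interpreted strictly:
probe $i+1$ starts where probe $i$ ends, with no overlaps or gaps, which
matches how such probe sets are named and synthesized. Probes within a
set should hybridize comparably under a single condition, so the
objective is

$$\text{objective} = (\max_i T_{m,i} - \min_i T_{m,i})
  + w_{GC} (\max_i GC_i - \min_i GC_i)$$

with probe $T_m$ evaluated by the Wetmur model at the design conditions
with $M = 0$, and $w_{GC} = 1$ by default (no evidence favors another
weighting; both spreads are in comparable units, °C and percentage
points).

The search enumerates breakpoint assignments (start offset plus $k$
lengths within `[min_len, max_len]`) and is **exact** whenever the
number of length combinations is at most `enum_cap` (default $10^6$) and
the total evaluation count stays within a fixed multiple of it; this
covers the default 442–456 bp preset and every instance the test suite's
brute-force oracle can check. Wider windows (e.g. the generic 300–500 bp
range) are searched on a deterministic coarse length stride with local
refinement and a 10-bp start-offset grid — a heuristic, flagged by
`exact = FALSE` in the result. When the gene is longer than
$k \cdot \texttt{max\_len}$, the covered window is chosen by the same
objective; nothing in the probe-set concept dictates which region of a
long gene to probe, so this is a documented package choice.

Ties are broken deterministically: maximal gene coverage first, then the
most equal probe lengths, then leftmost breakpoints. Preferring coverage
reflects tiling intent — among equally matched tilings, the one that
covers most of the gene gives the brightest signal — and makes results
reproducible across runs and platforms. Probes containing more than 1% N
are rejected; N counts as non-GC in GC content.

Length presets: the default window 300–500 bp is the typical
polynucleotide-probe length range; `preset = "genefish2021"` sets $k = 5$
and 442–456 bp. Probe order and coordinates are 0-based half-open
internally.

**Primers.** `design_primers()` takes the amplicon to be exactly the
probe: the forward primer is a probe prefix, the reverse the reverse
complement of a suffix, lengths 18–27 nt, GC within 40–60%, primer
$T_m$ difference ≤ 2 °C; among feasible pairs the shortest total length
wins. Primer $T_m$ uses the GC-count formula
$64.9 + 41(n_{GC} - 16.4)/\ell$ — deliberately simple and documented as
replaceable; the original probe sets were designed interactively, so
this step is re-specified rather than reproduced. When no pair meets all
constraints the pair minimizing the $T_m$ difference is returned with
`constraints_relaxed = TRUE` and a warning rather than failing, because a
slightly imbalanced primer pair is a judgment call, not an error.

## Specificity screening

The original screening workflow used BLAST inside a GUI with unstated
parameters; `polyprobe` re-specifies it as a deterministic semi-global
alignment so results are reproducible and dependency-free. BLAST-
compatible output is explicitly not promised.

`align_probe()` aligns the probe end-to-end while the target contributes
a consecutive subsequence (free end gaps on the target), the natural
geometry for a short probe hybridizing inside a longer gene. Scoring
defaults: match $+1$, mismatch $-2$, gap open $-4$, gap extend $-1$; a
gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{extend}$. Both
target strands are evaluated and the better one reported. N never
matches, including N against N. Tie-breaks are fixed (diagonal over
probe-gap over target-gap states, smallest target end index) so the
alignment trace is unique and checkable against an independent
implementation. The engine is a small C++ dynamic program; the test
suite verifies it column-for-column against a plain-R reference and its
scores against `Biostrings::pairwiseAlignment`.

Percent identity is matches over alignment columns spanning the aligned
probe (internal gaps included); a probe-length denominator is available
via `denominator = "probe"`. The longest mismatch stretch pools
substitution and gap columns into single runs — a long unbroken
mismatch run destabilizes a duplex more than the same mismatches
scattered, and is also the natural alignment-level summary of indels.

`set_hit()` applies the set-level detection rule: a probe hits at ≥ 80%
identity, a probe set hits when at least 4 of its 5 probes hit (both
configurable). The published rule states no minimum alignment coverage;
since the probe is aligned globally here, probe coverage is 1 by
construction and the configurable `min_coverage` (default 0.5) only
matters for alternative alignment backends — it is an interpretation,
kept explicit.

`screen_probes()` combines the rule with the thermodynamics: a target's
implied mismatch is $100 -$ the mean identity of its hitting probes
(`mismatch_mode = "worst"` uses the worst hitting probe instead; the
mean is the default because all probes of a set contribute signal), and
the target is predicted detectable at the given FA when that mismatch is
within `max_mismatch()` for the set's mean GC and length.

## PUL screening

Annotation is upstream input (the original workflow used Prokka):
`polyprobe` consumes per-gene labels from a TSV or GFF3, mapping
free-text products onto the controlled vocabulary `susC-like`,
`susD-like`, `GH<n>`, `PL<n>`, `sulfatase`, `other` via configurable
regexes. No HMM scanning happens here.

A candidate locus is a maximal run of PUL-relevant genes (susC/susD-like,
GH, PL, sulfatase) in which at most `max_intergenic_genes` (default 3)
non-relevant genes separate consecutive relevant ones. The membership
rule defines a PUL — at least one susC- or susD-like gene and at least
two degradative CAZymes (GH or PL families) — but not locus boundaries,
so the gap heuristic is a package choice, documented as such.
"Degradative CAZymes" is read as any GH or PL family label, with GH92
itself counting toward the two. A PUL additionally containing at least
one GH92 and at least one sulfatase is flagged glucuronomannan-like;
minimum counts of one each within the locus is the minimal reading of
the published signature. SusCD tandem pairs require immediate adjacency
on the same strand. `homolog_links()` pairs genes of two loci greedily
by (label, order along the locus) and scores each pair by global
nucleotide identity under the same alignment engine.

## Detection-efficiency statistics

Counting starts from per-field-of-view (FOV) tables; image analysis is
out of scope. The efficiency of one FOV is
$100 \cdot \text{positive}/\text{total}$; the headline statistic is the
**unweighted mean across FOVs** with its **sample SD** ($n-1$
denominator, the spreadsheet STDEV convention) — FOVs, not cells, are
the replication unit. A cell-pooled estimate is reported alongside for
reference. In RGA (relative gene abundance) mode the denominator is the
16S-probe-positive cells rather than all DAPI cells. Negative-control
rows are reported unmodified; any NC subtraction is left to an explicit
downstream decision. With a single FOV the SD is reported as `NA` rather
than 0.

Group comparisons follow the two-stage convention: a two-sample F-test
for variance equality first, then the two-tailed pooled-variance t-test;
when the F-test rejects at `alpha_variance` (default 0.05) the result
flags `equal_variance_assumed = FALSE` and the Welch test — always
computed alongside — is the one to quote. Both tests delegate to R's
`var.test()` and `t.test()`; the test suite checks them against
hand-written formulas. Significance tiers: `***` $p \le 0.001$, `**`
$p \le 0.01$, `*` $p \le 0.05$.

## Synthetic data: what it emulates, and what it does not

The generators make every module testable offline and define the
conditions under which the package's guarantees are verified.

* `simulate_gene_family()` — an i.i.d. ancestor at a target GC content,
  homologs derived by per-site substitution at rate
  $(100-\text{target})/100$, so realized identity is exact in
  expectation; substitutions always change the base and never create N.
  `clustered` mode places substitutions in geometric blocks (mean 12 bp
  by default) to create the long mismatch stretches real homolog pairs
  show; indels are off by default (identity targets then stay exact) and
  can be enabled at a low rate. There is no phylogeny, no codon
  structure, no conserved domains: a real gene family's identity varies
  along the gene, so a probe set screened against real homologs will
  show more per-probe identity spread than these fixtures do. Passing
  the recovery tests therefore demonstrates the *rule and alignment
  machinery*, not field performance.
* `simulate_contigs()` — planted five-gene glucuronomannan-like
  cassettes (susC, susD, GH92, sulfatase, GH16) at a configurable
  density on an `other`-gene background with isolated relevant
  distractors kept farther apart than the caller's gap parameter. This
  makes ground truth exact (precision/recall are meaningful), at the
  price of never testing borderline loci; the brute-force oracle test
  covers rule correctness on arbitrary label arrangements instead.
* `simulate_fov_counts()` — binomial counts with uniform FOV sizes; real
  FOV data are overdispersed (cells cluster, fields differ
  systematically), so real SDs will exceed binomial ones.

All generators are seed-deterministic: the same seed gives byte-identical
output.

## Numerical and scale choices

* Objective ties in tiling and alignment are resolved by the documented
  deterministic orders; no randomness exists outside the generators.
* Floating-point ties in the tiling objective are merged within $10^{-9}$
  before tie-breaking.
* The exhaustive-vs-heuristic switch in `tile_gene()` is a pure
  size-of-search-space criterion (`enum_cap`), never data-dependent.
* Test problem sizes: tiling optimality is cross-checked against brute
  force on genes up to 100 bp with up to 3 probes (200 instances);
  alignment against the R reference on 500 pairs up to 80 bp; set-hit
  recovery on roughly a thousand homologs of a 2250 bp ancestor across
  identity levels 70–95%; PUL calling against brute force on 100
  contigs. These sizes keep the full suite comfortably reproducible on a
  laptop while leaving each check statistically meaningful.
* GenBank input is parsed by a minimal LOCUS/FEATURES/ORIGIN reader
  (gene/CDS features, locus tags, complement spans) — sufficient for
  extracting gene targets from standard flat files, not a general
  GenBank parser. Coordinates are 0-based half-open internally; GenBank
  and GFF3 1-based closed spans are converted at the boundary.

## Known limitations

* The Wetmur relation is an empirical average: it ignores mismatch
  identity and position, sequence context and secondary structure. Its
  mismatch term is linear, so predictions degrade for heavily diverged
  duplexes.
* The FA recommendation assumes pure FA-compensation at a fixed
  hybridization temperature and inherits any error in the assumed buffer
  sodium.
* The alignment engine is quadratic per pair; screening is meant for
  probe sets against gene-scale databases (thousands of genes), not
  metagenome-scale search. No translated search, no k-mer prefilter.
* PUL calls are only as good as the upstream annotation labels; the
  caller never inspects sequence.
* Probe placement on genes longer than $k \cdot \texttt{max\_len}$ and
  the locus-gap parameter are heuristics; both are surfaced as options
  rather than hidden constants.
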