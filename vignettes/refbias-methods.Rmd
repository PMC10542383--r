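---
title: "Models and methods behind refbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind refbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refbias)
```

# Scope

`refbias` bundles the statistics needed to compare two reference assemblies
for population-genomic work and to scan modern genomes for archaic
introgression: frequency-based ABBA-BABA statistics with putative
introgression region (pIR) calling, specific-mapping-region (SMR) detection
from per-base depth, depth-scaled presence/absence genotyping of large
insertions, Weir–Cockerham Fst with empirical outlier p-values,
SV-heterozygosity windows rendered as GFA bubble graphs, alignment
p-distance, and the correlation of mapping performance with genetic
distance. A simulator generates all inputs with planted truth. This
vignette records the models, the parameter choices, and the design
decisions that were genuinely open.

# Coordinates and formats

All intervals inside the package are **1-based closed**, the convention
shared by VCF, `samtools depth`, and the Bioconductor IRanges/GRanges
containers that do the interval arithmetic here. BED input and output
convert at the boundary: the 1-based interval [100, 200] is written as the
BED line `99 200`, and a BED-like SV record with 0-based start 500,000
becomes 1-based 500,001 — and therefore belongs to the *second* 500-kb
window. An alternative would have been to keep 0-based half-open
coordinates internally; we chose the IRanges convention because every
interval operation in the package is delegated to IRanges and a single
convention end to end removes a whole class of off-by-one bugs.

VCF ingestion goes through `vcfR`; only bi-allelic SNPs are kept
(multi-allelic records and indels are dropped at read time), `./.` and
half-calls such as `0/.` become missing. The VCF writer emits a minimal
plain-text VCFv4.2 subset (GT, DP, AD) that round-trips losslessly through
the reader.

# Genotype masking and MAF classes

Cohort-scale genotype filtering uses per-genotype depth and allelic
balance: a genotype is set missing when DP < 10 or DP > 1.65 x the
sample's genome-wide mean, and a heterozygote is set missing when its
alternate-allele depth fraction exceeds 0.8 or falls below 0.25. All four
thresholds are strict inequalities, so DP = 10 and balance exactly 0.8 or
0.25 survive; masking can only remove calls, never create them. Minor
allele frequency classes use MAF < 0.01 (rare) and MAF > 0.05 (common);
when two call sets are contrasted the paired labels (`Both-rare`,
`A-rare/B-common`, `A-unique`, ...) identify the reference-dependent rare
SNPs that are the signature of reference bias.

# The ABBA-BABA model

For the topology ((P1, P2), P3, O) with per-site derived-allele
frequencies $p_1 \dots p_4$,

$$\mathrm{ABBA} = (1-p_1)\,p_2\,p_3\,(1-p_4), \qquad
  \mathrm{BABA} = p_1\,(1-p_2)\,p_3\,(1-p_4).$$

Window-level $D = (\Sigma \mathrm{ABBA} - \Sigma \mathrm{BABA}) /
(\Sigma \mathrm{ABBA} + \Sigma \mathrm{BABA})$. The modified statistic
$f_d$ shares the numerator and divides by the same expression with $p_2$
and $p_3$ both replaced by $p_D = \max(p_2, p_3)$ — the value the
numerator would take under complete replacement of the recipient by the
higher-frequency donor, so $f_d$ estimates the local replacement fraction.
The frequency-based (population) form is used throughout because P1 and P2
are population panels; single-genome taxa are simply the degenerate case
with frequencies in {0, 0.5, 1}. When $p_2 = p_3$ either choice of donor
gives the same $p_D$, so no tie-break is needed.

Polarization: the derived allele is the allele *not* carried by the
outgroup majority. A site is **good** when every taxon has at least one
called allele and the outgroup minor-allele frequency is at most 0.1
(configurable); a polymorphic outgroup cannot polarize the site reliably,
and no standard convention exists for a polymorphic outgroup, so near-fixed
outgroups are required instead.

Defaults follow the established scan design for archaic introgression:
10-kb windows, 1-kb step,
windows with fewer than 30 good sites discarded, outliers at $f_d > 0.35$
(strict), merged pIRs kept at >= 20 kb. Three conventions the method
sources leave open are fixed as follows:

* $f_d$ is reported only for windows with $D > 0$; windows with
  $D \le 0$ get $f_d = 0$ ($f_d$ has no interpretation for negative D),
  and $f_d$ is clamped to [0, 1].
* Windows are anchored at position 1 of the chromosome; the last partial
  window is retained if it clears the site minimum.
* pIR merging unions outlier windows that overlap **or abut**; the
  maximum gap bridged is configurable and defaults to 0.

# The quartet simulator

The generator is a tract-copying model, not a coalescent: simple,
analytically interpretable, and sufficient to exercise the scan with known
truth. Per site an ancestral derived-allele frequency is drawn from
Beta(0.2, 0.2) truncated to (0, 1) — the U-shaped site-frequency spectrum
typical of real panels — and each taxon drifts independently under the
Balding–Nichols model, Beta with mean $q$ and variance $F q (1-q)$. P1 and
P2 share $F = 0.1$, which makes window D exactly unbiased under the null;
the archaic taxon and the outgroup use $F = 0.5$, and the outgroup is
fixed ancestral at 95% of sites. Default panel sizes (10, 20, 1, 5
diploids for P1, P2, P3, O) mirror the design of typical archaic scans:
population panels for the two modern taxa, one high-coverage archaic
genome, a small outgroup panel.

Introgression is planted as tracts in which each P2 haplotype allele is,
with probability gamma, copied from the **sampled** P3 genotypes (their
empirical frequency), not from the latent archaic frequency. This matters:
truly introgressed haplotypes descend from a population close to the
sequenced archaic individual, and only this choice makes gamma = 1
correspond to $f_d \approx 1$. With copying from the latent frequency the
single-genome P3's sampling noise decouples the donor from the recipient
and in-tract $f_d$ plateaus near 0.6 even at full replacement.

Site density defaults to 0.01 per bp — one segregating site per 100 bp,
the scale expected when dozens of modern genomes are pooled with divergent
archaic and outgroup genomes — giving ~100 good sites per 10-kb window.

All randomness flows from the single `seed` in the config, and every
random variate is drawn in an order that does not depend on gamma. Runs at
different gamma under one seed are therefore **coupled**: the set of
copied alleles at gamma = 0.25 is a subset of the set at gamma = 0.5. This
makes the monotonicity of in-tract $f_d$ in gamma hold deterministically
per seed, not just in expectation, and makes identical configs
byte-identical on disk.

**Null calibration uses non-overlapping windows.** The validation that
window D is centred on zero without gene flow runs the scan with step =
window over a 6-Mb chromosome (600 independent windows). At the default
1-kb step each pair of neighbouring windows shares 90% of its sites; the
windows are strongly autocorrelated and the naive standard error of the
mean would be an underestimate by roughly $\sqrt{10}$, so a 3-SE bound
would have no calibrated meaning there.

What the simulator does **not** emulate: linkage disequilibrium and
recombination maps (sites are independent given the planted tracts),
coalescent genealogies, sequencing error, ancient-DNA damage, and mapping
artefacts. Passing recovery tests on these data therefore shows the
statistics are implemented correctly and behave as designed under a clean
frequency model — not that the pipeline is robust to the read-level noise
of real resequencing data.

# Depth analyses

SMR detection takes a reference-specific depth track and the genome-wide
mean depth of the **full** alignment (the specific track's own mean would
be circular; either mean is defensible, so the full-alignment mean is the
default and the caller can override).
Candidate bases are those with specific depth strictly above half the
genome-wide mean; maximal runs are merged across gaps up to `merge_gap`
(default 0), and merged regions are kept when their mean also clears the
threshold and they are at least 100 bp long. "Regions above half coverage,
merged" is ambiguous between per-base thresholding-then-merging and
region-mean thresholding; requiring both conditions reproduces either
reading at gap 0. The detector is validated against an exhaustive run-enumeration oracle.

Insertion genotyping scales a region's mean depth by the sample's
genome-wide mean: `[0.4, 0.8]` heterozygous (closed at both ends — a
band stated as "between 0.4 and 0.8" is read inclusively), above 0.8
homozygous, below 0.4 absent. At 30x coverage over a 21-kb region the
scaled depth of a heterozygote has a standard error well below 0.01, which
is why concordance with planted genotypes is effectively 1. Population
insertion allele frequency is (n_het + 2 n_hom) / (2 n).

# Heterozygosity windows and the bubble graph

SVs (>= 50 bp by construction in the simulator, matching the size floor of
long-read SV call sets) are counted per non-overlapping 500-kb window by their start
coordinate, so an SV spanning a window boundary counts exactly once and
window counts always sum to the number of input SVs; an overlap-counting
mode is provided for exploration. Windows with h >= 2 are "hete". The GFA
builder collapses maximal homozygous runs into single segments and emits
each hete window as a two-segment bubble linked to its flanking segments;
sequences are omitted in favour of `LN` length tags (renderers such as
Bandage lay the graph out from lengths alone) and the window's h travels
as an `hc:i` tag so bubbles can be shaded by heterozygosity rate.

The p-distance between two aligned sequences is mismatches over gap-free
columns. Columns containing `N` in either sequence are excluded along with
gap columns: an ambiguous base can neither support nor contradict a match,
and counting it either way would bias the estimate.

# Fst, empirical p-values, and mapping bias

Per-site Fst is the two-population Weir–Cockerham theta computed from
sample sizes, allele frequencies, and observed heterozygosity; the a/b/c
variance components are retained so windowed Fst is the ratio of summed
components (ratio of averages), never a mean of per-site ratios. Per-site
estimates may be slightly negative and are deliberately not clamped —
clamping before summation would bias windowed values upward. Monomorphic
sites are skipped. The implementation is checked to 1e-10 against an
independently coded scalar version of the textbook formulas.

The genome-wide pairwise population matrix (`fst_matrix`) averages the
same components over sites, optionally after the standard pre-filter of
random 1-in-1000 downsampling plus MAF > 0.01 (seed-deterministic). Other
toolkits build this matrix with multilocus estimators (e.g. adegenet's);
the Weir–Cockerham average is used here as a close, documented
substitute.

Empirical p-values use the add-one rank rule
$p = (1 + \#\{x_{null} \ge x\}) / (1 + N)$: p is never 0, lies in (0, 1],
is monotone non-increasing in the observed value, and is uniform under the
null up to the 1/(N+1) grid. Rank conventions vary between studies; the
add-one rule is declared explicitly here rather than inherited. The significance cutoff drawn on Fst plots is the null 95th
percentile. Differentiated regions pass when strictly more than half of
their SNVs are significant at p < 0.05; a region with no SNV fails with an
explicit flag rather than erroring, so one empty region cannot abort a
genome-wide scan.

The mapping-bias correlation takes per-population means of per-sample
differences in percent uniquely mapped reads between the two references
and correlates them with the Fst contrast of each population to the two
references' own populations. Sign conventions are fixed so that the
uniquely-mapped correlation is negative and the clipped-read correlation
positive when populations close to reference A's population map better to
reference A. The simulator plants the linear coupling at the population
level with per-sample jitter that cancels in the mean, so zero noise gives
|r| = 1 exactly and 10% noise leaves r below -0.8.

# Problem sizes and runtime

Validation runs use a 1-Mb chromosome (6 Mb for the null calibration) at
site density 0.01, two planted tracts of 80 and 100 kb, 100-kb depth
tracks, 500 insertion samples at 30x over 21 kb, 1000 Fst sites, and
10,000 draws for the uniformity check. These sizes put every Monte-Carlo
standard error well below the tolerances being asserted while keeping the
full suite under a couple of minutes on one core.

# Known limitations

* The simulator's independence across sites means window statistics have
  smaller variance than on real, LD-structured data; empirical cutoffs
  tuned here should not be transplanted to real scans.
* pIR calling has no gap tolerance by default; fragmented signal in
  low-site-density regions can split a real tract into several pIRs.
* The insertion genotyper assumes unimodal coverage; CNV-overlapping
  insertions violate the 0/0.5/1 scaling.
* `fst_matrix` is O(populations^2) over all sites; for many populations,
  downsample.
* The VCF writer emits only the GT/DP/AD subset the pipeline consumes.
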