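---
title: "Methods: simulation-backed BSR-seq mapping of a dominant locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-backed BSR-seq mapping of a dominant locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrmap)
```

# The problem and the model

bsrmap implements the computational core of map-based cloning for a
qualitative trait controlled by a single dominant nuclear locus in an F2
cross — the design used, for example, to clone the prickle locus of
eggplant. The trait model throughout is complete dominance of the donor
(P2, "B") allele: genotype AB or BB shows the dominant phenotype, AA the
recessive one, giving the familiar 3:1 F2 segregation and 1:1 in the
backcross to the recessive parent.

Four analysis stages share that model:

1. a Δ(SNP-index) bulked-segregant scan with Monte-Carlo null envelopes,
2. CAPS marker design and genotype calling by in-silico digestion,
3. recombinant-based fine mapping on marker tables, and
4. exact genotype–phenotype association on a germplasm panel.

All of them can be fed by the seeded generators in `R/synthio.R`, which is
what every test in the package does.

# The synthetic world

The generators are a stated world, not a tuning surface; their defaults
describe the experiment the pipeline targets.

**F2 crosses** (`simulate_f2`). Each individual is the union of two
independent gametes. Crossovers per gamete are Poisson with mean equal to
the map length in Morgans and are placed uniformly — the Haldane,
interference-free model. The map function is our choice (the experimental
design this emulates specifies none); it is the minimal standard model,
and for the short intervals that matter here (≈1.7 cM) interference is
negligible. The default rate of 3 cM/Mb is a mid-range plant genome
average; the fine-mapping world instead uses 1.67 cM / 1.37 Mb ≈ 1.22
cM/Mb so that two flanking markers 1.37 Mb apart recombine in the
expected ≈ 37 of 2 × 1109 meioses.

**Bulks** (`simulate_bulk_reads`). Thirty plants per phenotype class
(the standard BSR-seq bulk size) are drawn without replacement and pooled
with equal weight — pooling is done on equal RNA amounts in the lab, and
we deliberately ignore expression-level and allele-specific-expression
biases: bulks are treated as genomic allele pools. Per-SNP depth follows a
negative binomial with configurable dispersion, degenerating to fixed
depth at dispersion 0 (the published experiment reports only pool totals,
so any per-SNP depth law is a convention; dispersion 0 at depth 40 is used
in the test world). Observed alternate depth is Binomial(d, p) with p the
true bulk allele frequency. Optional "decoy" records with sub-threshold
mapping/base quality exercise the filter stage and are off by default.

**Panels** (`simulate_panel`). The default design is 190 accessions — 18
dominant-phenotype (drawn D or H with equal probability; the real D:H
split within carriers is not published) and 172 recessive-phenotype, 166
of them R and 6 discordant D. Those marginals reproduce the published
genotype-frequency figure, including the 96.51% R fraction among
prickleless accessions.

**Sequence fixtures** (`fixture_sequences`). The two published 31-bp
promoter haplotypes around the −735 bp SNP differ only at position 16,
where the dominant allele creates an SspI site (AATATT at positions
13–18). The full 391-bp genotyping amplicon is *not* published (primer
coordinates live in unavailable supplementary material), so
`build_amplicon` reconstructs one synthetically: it embeds a haplotype in
deterministic random padding with the SNP at a requested offset and
verifies that no additional SspI site is created. Offset 153 places the
cut after base 152, reproducing the published 152/239/391 band logic.
This is a labelled reconstruction, not the real amplicon: band sizes
match by construction, but the flanking sequence is synthetic.

What a green test does *not* establish: the generators contain no
alignment or variant-calling artifacts, no RNA expression bias between
alleles, no genotyping error in marker tables, and a single-locus
architecture only. Results on real data additionally depend on all of
those.

# The scan

`filter_variants` applies the published retention rule — sequencing depth
≥ 20, mapping quality ≥ 20, base quality ≥ 20, all inclusive. The depth
criterion is applied to **each pool** rather than their sum: a pool below
20 reads gives an unreliable SNP-index even when the other pool is deep
(the source analysis does not say which convention its in-house script
used; per-pool is the conservative reading). Records left with zero depth
in a pool are excluded rather than given a 0/0 index.

`null_ci` simulates the "no QTL" null: per replicate and per bulk,
n = 30 unlinked F2 genotypes are drawn with probabilities 1/4 : 1/2 : 1/4,
the bulk allele frequency is the mean dosage / 2, and reads are binomial
at depth d. This genotype-then-binomial design is the canonical QTL-seq
procedure; 10 000 replicates is the default (the original replicate count
is unreported). Bounds are the empirical 2.5/97.5 and 0.5/99.5
percentiles taken as **inverse-ECDF (type 1) quantiles**: Δ at depth d is
discrete with atoms at 1/d, so interpolated quantiles would fall between
attainable values and make strict exceedance systematically conservative.
With order-statistic bounds, the strict and closed exceedance rates
bracket the nominal level, which is exactly what the calibration tests
assert.

Each SNP is matched to the envelope via the harmonic mean of its two pool
depths (the equivalent single depth for the difference of two binomial
proportions) with nearest-neighbour lookup on the depth grid — the
source is silent on this, as on window anchoring, which we fix at
position 0 per chromosome. Windows are 400 kb / 200 kb by default,
half-open `[start, start + window)`, and empty windows are omitted.
A window is significant when its mean Δ falls **strictly** outside its
mean bound; overlapping or abutting significant windows merge.
Pool 1 is defined as the dominant-phenotype bulk, so the causal signal is
a positive Δ ≈ 2/3; the label choice (the source does not state its sign
convention) only reflects the scan, as the pool-swap test verifies.

# CAPS markers

Cut positions are 0-based between-base indices; a cut at k yields
fragments of k and L − k. Recognition sequences are IUPAC-aware; for
non-palindromic recognitions the reverse complement is scanned too, with
the bottom-strand cut mapped as `match end − cut_offset`. Fragment
lengths always sum to the amplicon length (tested for random sequences
against every bundled enzyme). One numerical subtlety: staggered-cut
palindromic enzymes (EcoRI-type) have top-strand cut coordinates that
shift by the overhang length when the same molecule is described from the
other strand; the strand-symmetry tests therefore require exact mirroring
only for centered cutters and agreement within the overhang otherwise —
gel electrophoresis cannot resolve the difference either.

`design_caps` keeps enzymes whose band multisets differ between alleles
(the DraI site present identically in both reconstructed amplicons is
correctly rejected) and ranks assays by the minimum pairwise band-size
difference, a proxy for gel resolvability. Genotype calling matches the
observed band multiset against D/R/H patterns with a tolerance of 0 bp by
default — in-silico bands are exact; gel-derived input can widen it.

`cds_protein_length` encodes the convention that a CDS includes its stop
codon, so L/3 − 1 residues are translated (618 bp → 205 aa).

# Fine mapping

`find_recombinants` flags individuals whose non-missing genotypes at the
two flanking markers differ; missing genotypes exclude the individual
from that comparison rather than being imputed.

`delimit_interval` formalizes the narrative rule used in fine-mapping
papers. Under dominance, phenotype fixes each recombinant's class at the
causal locus (recessive ⇒ A; dominant ⇒ H or B). A marker mismatching
that class in a recombinant cannot host the locus, and with error-free
single-crossover data the mismatching markers of one recombinant form a
prefix or a suffix of the marker order. The interval is therefore bounded
by the innermost prefix-mismatch marker on the left and the innermost
suffix-mismatch marker on the right (table edges when a side has none).
This extends the "maximal run of consistent markers" reading to the case
where the causal gap itself contains no marker, and it never excludes the
true position on error-free data — a property tested over 130 seeds.
Interior mismatches (double crossovers or genotyping errors) are warned
about and ignored for bound-setting. An optional `min_support` requires
≥ k independent recombinants to move a bound inward (default 1, matching
the single-recombinant bounds typical of published fine maps; progeny
testing of those single recombinants is the wet-lab analogue and can be
emulated by re-running `segregation_chi2` on offspring counts).

If every marker conflicts on both sides the locus is not in the region
and `delimit_interval` says so rather than returning a degenerate
interval.

`interval_width` is the plain difference of the marker anchor
coordinates, the convention behind printed statements like "1.37 Mb
between 86.16 and 87.53 Mb".

# Association

`carrier_table` collapses D∪H vs R, mirroring the dominant inheritance;
the 2×3 genotype table is available via `genotype_frequencies` but is not
the headline statistic. `fisher_exact` enumerates the hypergeometric
support directly in log-space; the two-sided P sums all tables with point
probability ≤ the observed one, with a 1 + 1e−7 relative guard against
floating-point ties (the convention of standard statistical software).
One-sided P takes the tail in the observed direction, which by
unimodality never exceeds the two-sided value. On the canonical
18/0/6/166 table the exact P is 1.900 × 10⁻²⁰, and one- and two-sided
agree to three significant figures, so the unpublished sidedness of the
original test does not matter. Percentages are rounded half away from
zero to 2 decimals (plain `round()` is half-even and would misreport
values like 96.515). Population-structure correction is out of scope.

# Numerical and design choices, summarized

- Haldane map (no interference); Poisson crossover counts.
- Depth law: negative binomial, `size = 1/dispersion`, fixed at
  dispersion 0.
- Per-pool depth filtering; inclusive (≥) thresholds.
- Type-1 (order-statistic) quantiles for Monte-Carlo envelopes; strict
  inequality for significance; harmonic-mean depth matching with
  nearest-neighbour grid lookup.
- Windows anchored at 0, half-open; empty windows omitted; adjacent
  significant windows merge.
- Cut coordinates 0-based between bases; fragments sorted ascending;
  band tolerance 0 by default.
- Interval bounds from innermost one-sided mismatches; ties resolved
  toward the wider interval by construction (bounds only move inward with
  explicit support).
- Single global seed fans out to per-stage seeds by a fixed integer
  derivation, so every stage is independently reproducible.

# Known limitations

- The genome-scale scan (hundreds of thousands of SNPs across 12
  chromosomes) is emulated at desk scale: one 10-Mb chromosome with 2 000
  SNPs. On such a short, fully linked chromosome, significant regions are
  wide relative to the chromosome; localization is asserted as "the 99%
  region contains the locus", not as a region-width claim.
- The reconstructed 391-bp amplicon is synthetic outside the 31-bp
  published core.
- No genotyping error model in the fine-mapping generator; `min_support`
  exists precisely because real data need it.
- RNA-specific effects (expression bias between alleles, intronic
  coverage) are not modelled; bulks behave as genomic pools.
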