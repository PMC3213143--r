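---
title: "Methods: simulating and analysing ERI-class endogenous siRNA libraries"
author: "erisift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ERI-class endogenous siRNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The worked numbers shown in the README are
produced by the code paths described here; nothing below reports a result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis model

### Reads, mapping and normalisation

Small-RNA libraries are **collapsed**: one record per distinct sequence with
its read count (`>id_xCOUNT` FASTA headers). Sequencing protocols for this
RNA class size-select 18–28 nt, so records outside that window are dropped
at read-in (and counted). U is normalised to T.

Mapping is **exact and full-length** on both genome strands: a locus is
reported where the read equals the plus strand, or its reverse complement
does (recorded as a minus-strand locus). No mismatches or gaps are allowed —
the reads are short, the simulator emits exact reads, and exact matching is
what the corresponding read-collapsing mappers for this data type do. A
sequence matching $n$ loci contributes $count/n$ fractional reads to each
locus, so totals are conserved exactly. Library size is the summed count of
mapped sequences (read copies, not distinct sequences), and abundances are
expressed as reads per million mapped reads, $\mathrm{RPM} = 10^6 \cdot
w/N$. Unmapped reads are excluded from the denominator.

### Classification

Each (read, locus) pair gets exactly one class label against the
annotation, with precedence `mirna > pirna > 26G > 22G > other`:

* **26G**: length exactly 26 nt, 5′ G, antisense overlap (≥ 1 nt) with a
  coding/pseudogene/transposon exon;
* **22G**: as 26G at exactly 22 nt;
* **mirna**: sense overlap with a miRNA feature (annotation-driven, no
  hairpin prediction);
* **pirna**: 21 nt, 5′ U, sense overlap with a piRNA locus.

Class lengths are strict because that is how the classes are defined in this
field; near-length mass is still visible in the length × 5′-nt profile
matrix, whose total is 10^6 RPM by construction. "Antisense to a feature"
means opposite strand plus ≥ 1 nt exonic overlap; intron-spanning reads are
not modelled (the generator never emits them, and gene-model exon/intron
boundaries for these loci are unreliable in practice, so exact exon
arithmetic is deliberately not load-bearing).

### Depletion calling

A feature is called as a pathway target iff its wild-type antisense RPM is
at least 10 and its mutant/wild-type ratio is at most 1/3 in every required
genotype. "Depleted by ≥ 67%" is implemented as ratio ≤ 1/3 with ties
passing, i.e. the depletion parameter defaults to exactly 2/3. Individual
26G sequences are called identically at a 1 RPM wild-type threshold. No
pseudocount is used in the call ratios — the wild-type threshold guarantees
a positive denominator — and no statistical test is performed: the method is
thresholded, by design, as is standard for this analysis.

Class-level depletion is $100\,(1 - \sum \mathrm{RPM}_{mut} / \sum
\mathrm{RPM}_{wt})$ over a class, a feature subset, or their intersection
(e.g. 22G-class reads over a published target-gene set). Negative values
(enrichment) are reported as such. Because both libraries are RPM
normalised, removing a large class from a mutant library inflates everything
else by the reciprocal of the removed mass fraction; the generator's class
mixes keep each depleted class a small enough fraction of its library that
this shift stays within a few percent, which is also how the real libraries
behave.

Sliding-window genome tracks (default 5 kb windows every 1 kb) use
$\log_2((\mathrm{mut}+p)/(\mathrm{wt}+p))$ with a declared pseudocount of
$p = 1$ RPM, because windows can be empty; windows are screening output, not
calls. A final truncated window covers any chromosome remainder.

### Duplex inference

For each 26G-class guide locus the passenger search window is the guide
extended by 14 nt on each side (54 nt for a 26-nt guide). Candidates are
reads on the opposite strand whose loci lie fully inside the window; the
passenger is the most abundant candidate by fractional locus weight, with
ties broken by |inset3 − 3| ascending, then longer read, then lexicographic
sequence. Geometry is strand-aware: `inset3` is the gap between the guide 3′
terminus and the nearest passenger terminus in duplex register (the genomic
left end for a minus-strand guide), `inset5` likewise at the 5′ end;
negative insets (protruding passengers) are recorded, not clamped.

Multi-locus guides produce one record per locus. In the consensus, each
guide sequence contributes one unit split over its loci (weight $1/n_{loci}$
per record): this keeps multi-mappers from being over-counted and makes the
median passenger:guide ratio a per-siRNA median rather than a
read-count-weighted one, matching how the ratio is summarised in this
field's analyses. Guides without a passenger enter the median with ratio 0.
The passenger fold change between genotypes is the ratio of summed passenger
RPM over each library's duplex records.

Phasing profiles express 26G 5′ ends in template (mRNA sense) coordinates,
ascending from the feature 5′ end; successive differences are the intervals,
and the reported statistic is the fraction of intervals within 23–29 nt.
Features with a single distinct 5′ position report an empty interval list
and an absent fraction rather than an error.

### Homology

Target homology uses gene sequences with 0.5 kb flanks (sense orientation,
clipped and flagged at chromosome edges). "Total nucleotide identity" is
under-specified wherever it is used informally, so the package computes
percent identity over the best local alignment with match +1, mismatch −2,
gap open −5, gap extension −2 (BLAST-like scoring without BLAST), reports
the alignment length, and applies a minimum-coverage filter (aligned length
≥ 100 nt) in the qualifying criterion. The longest perfect stretch is the
exact longest common substring, found by binary search over shared k-mer
sets (a length-k common substring exists iff the k-mer sets intersect); the
test suite verifies it against a dynamic-programming oracle. A pair
qualifies iff identity > 82 (strict), stretch ≥ 27 nt (inclusive), and the
coverage filter passes; groups are single-linkage connected components.

The background is the mean, over repeated draws, of the fraction of
randomly sampled non-target genes with a qualifying partner inside the
sample, where each sample matches the target set's combined flanked length
within ±10% (the default sample size is derived from that constraint; a
draw that cannot match emits a warning and uses the closest sample).
Proximity (same chromosome, flank-free gap strictly < 5 kb) is annotated on
every edge.

## 2. The generator and its defaults

The generator's job is to emit libraries with the statistical structure the
analysis assumes, with every read attributable to a ground-truth record.

**Genome.** Three 100-kb chromosomes of uniform random sequence, carrying
non-overlapping genes on random strands: 12 ERGO-1-class 26G target genes —
three families of three copies (the first copy is the unmutated progenitor,
the others are mutated at the configured divergence, default 0.05/nt) plus
three singletons — 6 ALG-3/4-class target genes, 6 CSR-1-class 22G genes,
30 plain background genes, 8 miRNA genes and 8 piRNA loci. Target genes use
a short gene model (2–4 exons of 300–500 nt; ~1.3 kb) and background genes a
longer one (4–6 exons of 450–650 nt; ~2.9 kb), reflecting the observation
that these siRNA targets are shorter and exon-poorer than average genes. A
configurable fraction (0.3) of family copies is placed within 5 kb of
another family member. The minimum intergenic gap is 1 kb so that the 0.5-kb
homology flanks of unrelated neighbours never share genomic sequence —
without it, flank overlap manufactures spurious "homology" between adjacent
random genes.

**Sites.** Guide sites are planned per exon as a walk with steps drawn
uniformly from 23–29 nt; 22G sites use a sparser walk. The template base
under each antisense 5′ end is planted as C (so guides read 5′ G), and as T
under sense miRNA/piRNA 5′ ends (5′ U); these anchor positions are protected
from family-copy mutation. Site layouts are drawn once per family progenitor
and inherited by every copy, so pairwise identity between progenitor and
copy is governed by the divergence parameter alone (≈ 95% at 0.05). The
phased walk restarts in each exon, so a small fraction of successive
intervals (those spanning an intron) legitimately falls outside 23–29 nt —
which is why the recovery criterion is "≥ 90% of intervals in range", not
100%.

**Abundances.** Wild-type counts allocate `library_depth` (default 2×10^5)
over classes by the per-stage mix, then over sites within a class by
log-normal weights, using largest-remainder rounding at both levels so each
wild-type library total equals the configured depth exactly. The embryo mix
is 26G(ERGO-1) 0.10, 22G(ERGO-1) 0.04, 22G(CSR-1) 0.30, miRNA 0.36, piRNA
0.20; the adult mix is 26G(ALG-3/4) 0.10, 22G(ERGO-1) 0.03, 22G(ALG-3/4)
0.22, 22G(CSR-1) 0.30, miRNA 0.23, piRNA 0.12 — stage-specific in the way
these classes are (embryonic primary 26G, post-embryonic secondary 22G,
sperm-specific ALG-3/4). The absolute mixes are the package's own choice;
they are sized so each depleted class is a minor library fraction and RPM
renormalisation shifts stay small. No published distribution exists for
per-guide 26G abundance, so log-normal is an assumption; no test depends on
its exact shape.

**Passengers.** Each guide site carries a passenger:guide ratio drawn
log-normal with median 0.05 (the reported median for this pathway) and sdlog
1.5 (so a few-hundred-guide population spans ratios ≈ 0–6, matching the
reported 0–6.4 range). Wild-type passenger counts are guide count × ratio
with stochastic rounding (floor plus Bernoulli remainder), keeping the
expectation exact at desk-scale counts; passengers are emitted on top of the
class allocation (the depth conservation statement applies to the
non-passenger classes). Passenger geometry is exact by construction —
sense-strand, 19 nt, inset 3 nt from the guide 3′ end and 4 nt from its 5′
end — with optional ±1 nt jitter on the 5′-side inset (off by default).
Abundance weights and ratios are drawn once per family site plan and shared
across copies, for the same reason as the site layouts: with independent
per-copy draws, fractional multi-mapper weighting mixes family members'
values and biases the recovered per-siRNA median ratio toward the
log-normal mean rather than its median.

**Genotypes.** Mutant counts are Poisson draws around wild-type count ×
factor, per (genotype, stage, class). Poisson thinning rather than rounding
matters: with a factor of 0.002 most per-guide expectations are ≪ 1, and
rounding would zero them collectively, biasing class-level recovery.
Default factors: 26G(ERGO-1) × 0.002 in *eri-6*/*eri-7*/*eri-1* embryos and
× 0.04 in *ergo-1*; the passenger co-depleted (× 0.002) in *eri* mutants but
stabilised (× 2) in *ergo-1*; 22G(ERGO-1) × 0.1 in *eri* mutants (embryo and
adult — the secondary class follows its primary trigger); ALG-3/4, CSR-1,
miRNA and piRNA classes at 1.0 everywhere; wild type 1.0 by definition.
*ergo-1* leaves the embryonic 22G class at 1.0, consistent with its weaker
overall siRNA loss. Default libraries: wild type, *eri-6*, *eri-7*, *eri-1*,
*ergo-1* embryos; wild type and *eri-7* adults.

**Determinism.** One root seed drives genome construction and the
per-species draws; each library's emission uses a substream derived from a
stable hash of (genotype, stage), so adding a library never perturbs the
others, and the same configuration is byte-reproducible end to end.

## 3. Numerical and coordinate conventions

* Internal coordinates are 0-based half-open everywhere; conversion to
  1-based happens only at the GFF3 and Biostrings boundaries (BED is
  already 0-based). A single convention eliminates off-by-one drift between
  modules.
* Mode statistics break ties toward the smaller value; medians are lower
  weighted medians. Both are deterministic.
* Depletion ties (ratio exactly 1/3) pass; identity 82% exactly does not
  qualify; stretch 27 nt exactly does. Zero wild-type denominators are
  explicit errors in ratio functions, never silent NaNs; the window track is
  the one place a pseudocount (1 RPM, declared) is used.
* Loci, calls and report entries are emitted in deterministic sort orders so
  reports are byte-comparable.

## 4. Problem sizes

The default conditions — 300 kb genome, seven libraries of 2×10^5 wild-type
reads, ≈ 350–600 guide loci — run the full pipeline in well under two
minutes, and the test suite (including a 100-genome mapping oracle sweep and
a double end-to-end determinism run) in a few minutes. These sizes were
chosen so that class-level recoveries sit close to their asymptotic values:
at 2×10^5 reads the 26G class carries ≈ 2×10^4 reads, so a 0.04 factor is
estimated with ≈ 3.5% relative Poisson error, comfortably inside the
recovery tolerances the tests assert.

## 5. What the synthetic data does and does not show

The generator emulates: collapsed library structure; multi-mapping through
genuine sequence duplication; strict class definitions with 5′-nucleotide
identity; phased guide layouts; exact duplex geometry; class-level
genotype effects including passenger stabilisation; duplicated families
above and below the homology thresholds.

It does **not** emulate: sequencing error or adapter contamination (reads
are exact genomic matches by design — the mapper is exact-match and would
drop erroneous reads rather than misplace them); quality scores; expression
divergence between family copies (weights are shared by plan); intronic or
intergenic siRNA production; annotation errors; partial or chimeric
duplications (copies duplicate the full gene); or base-composition bias.
Passing the recovery tests therefore demonstrates correctness of the
analysis logic under the stated statistical structure, not robustness to
artefacts real libraries may contain. On real data the exact-match policy
silently discards reads with errors, deflating the mapped total; that is the
same behaviour as the reference mappers for this protocol, but it is worth
knowing when comparing depths.

## 6. Known limitations

* Depletion calling is purely threshold-based (no dispersion modelling or
  multiple-testing control); this mirrors the method it implements, but
  borderline features near 10 RPM or ratio 1/3 flip with Poisson noise.
* The passenger search takes the single most abundant candidate; co-equal
  candidates are resolved by the declared tie-breaks, and sub-modal 5′-inset
  variants are reported in the records without interpretation.
* Percent identity depends on the stated alignment scoring; other scoring
  schemes shift identity by a point or two around the 82% boundary.
* `run_pipeline()` analyses simulated data only; applying the analysis
  stages to real libraries means calling the module functions directly on
  files read with the `smallrna_io` readers.
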