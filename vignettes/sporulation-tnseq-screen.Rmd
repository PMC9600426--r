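---
title: "Simulating and calling synthetic sporulation Tn-seq screens"
author: "SporeTnSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and calling synthetic sporulation Tn-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SporeTnSeq)
```

# The experiment being modeled

A mariner-family transposon inserts at TA dinucleotides. A saturated
insertion library is grown into sporulation, heat-killed (80 °C, 20 min —
only mature, germinable spores survive), plated, and a fixed number of
colonies from germinated spores is pooled and sequenced via MmeI-released
transposon–chromosome junction tags. Insertions in genes required for spore
formation disappear between the input library and the post-selection pool.
Running the screen in a wild-type and in a sensitized mutant background and
comparing the two post-selection (T30) profiles reveals genes that are
dispensable normally but required when the sensitized pathway is
compromised — conditional essentiality by synthetic lethality.

SporeTnSeq implements this as a generative model plus the calling
statistics, so the whole analysis chain can be exercised against a known
planted truth.

# The generative model

**Genome.** `generateGenome()` draws an i.i.d. nucleotide sequence at a
target GC content (default 0.43, *B. subtilis*-like) and packs
non-overlapping genes (default 600–1500 bp, uniform) with intergenic gaps of
at least 50 bp. Genes never span the origin, and each is guaranteed at least
one TA site (offending gene bodies — vanishingly rare at these lengths — are
resampled). The feasibility pre-check uses the *expected* gene length plus
the minimum gap against 90 % of the genome length; the placement itself
still fails loudly if the sampled lengths cannot be packed. `findTASites()`
indexes every TA by the 1-based coordinate of its T, including overlapping
occurrences (TATA gives two sites) and the wraparound site of a circular
chromosome; a site belongs to the gene whose body contains its T coordinate,
which keeps the site-to-gene assignment single-valued even for a TA
straddling a boundary.

**Fitness truth.** `fitnessModel()` gives every gene, per background, a
vegetative survival probability *w* (probability an insertion clone forms a
colony during library construction) and a sporulation survival probability
*s* (probability the clone yields a heat-resistant, germinable spore).
Neutral genes take the baseline *s*; vegetative-essential genes have
*w* = 0 everywhere; planted conditional essentials keep the baseline *s* in
the reference background and *s*/ratio in the sensitized one. Intergenic
insertions have *w* = 1 and baseline *s*. The baseline is 0.5 by default: a
typical fraction of sporulation-competent cells for *B. subtilis* in
exhaustion medium, chosen once as a realistic operating point — the screen
statistic compares two backgrounds, so it is insensitive to the exact
baseline.

**Library and selection.** `buildLibrary()` drops each transformant on a
uniformly random TA site and keeps it with probability *w* — the T0 pool.
`applySelection()` is a two-stage sampler: binomial thinning of each site's
clone count by its gene's *s* (sporulation + heat kill + germination),
followed by multinomial resampling of a fixed colony count proportional to
the thinned counts (the pooling bottleneck). Outgrowth is not modeled as
competitive: the experimental readout is colony formation, not relative
growth rate. The paper-scale experiment pooled roughly 750,000 transformants
and 750,000 colonies; the desk-scale defaults (50,000 / 50,000 clones,
2,000,000 reads per library) preserve the per-site coverage regime
(~40 reads per TA site) that the statistics operate in — this is the
package's chosen study size, stated here once and used throughout the test
suite and the acceptance script.

**Sequencing.** `simulateReads()` draws reads multinomially from clone
abundances. Each read is the 16-bp genomic tag flanking the insertion's TA,
from the left or the right junction with equal probability; right-junction
tags are reverse complemented, emulating sequencing off the transposon end.
The 16-bp default stands in for the MmeI cut offset (the enzyme cuts ~18/20
nt from its site; the exact tag length only has to be consistent between
simulator and mapper, and it is configurable). Substitution errors are
i.i.d. per base; the default error rate is 0 so that the end-to-end identity
between mapped counts and the truth table is exact. PCR amplification and
duplicates are deliberately not modeled — duplicates rescale counts within a
site and are orthogonal to the rank-based gene statistic.

# Mapping and tallying

`buildTagIndex()` enumerates both candidate tags of every TA site whose
flanks fit inside the (possibly circular) genome; tags occurring at more
than one site are quarantined as ambiguous. `mapReads()` does exact string
matching of each read's first 16 bases: hits increment their site, ambiguous
tags are counted but never assigned (conservative; fractional assignment
would manufacture signal), everything else is unmapped. The accounting
identity mapped + unmapped + ambiguous = total holds on every input and is
property-tested. At 16 bp on a random 300-kb genome, collisions are
essentially absent; at short tag lengths the pigeonhole principle makes
ambiguity the norm, which the tests exercise explicitly. Both junction
orientations collapse into a single per-site count — the profile tracks and
the gene test need site totals, not strands. A general aligner is
intentionally not used: tags are short, fixed-length and error-free by
default, and exact matching keeps the mapper a closed, testable system
(mismatch tolerance would trade auditability for a mapped-fraction gain of
1 − 0.99^16 ≈ 15 % at a 1 % error rate).

# The screen statistics

**Normalization.** Libraries differ in depth, so each is scaled before gene
tests. To keep jackpot sites (a handful of TA positions carrying a large
share of reads, common in real Tn-seq) from dominating the scale factor,
each library's total is computed after winsorizing its top 0.1 % of nonzero
sites at the corresponding quantile. Both libraries are then scaled to the
harmonic mean of the two winsorized totals, so the two scale factors average
to 1 and identical libraries map to factors (1, 1). Only the *ratio* of
factors affects the gene statistics; the harmonic target is a symmetric
convention.

**Fold reduction.** Per gene, `(total_ref + 1) / (total_test + 1)` over all
TA sites in the gene body. The pseudocount of 1 read bounds the ratio when
selection empties a gene in the test library — precisely the strongest hits
— while leaving well-covered genes essentially untouched.

**Mann–Whitney U.** The per-gene test compares the two libraries' per-site
counts within the gene, zeros included: absence of insertions *is* the
signal, and dropping empty sites would erase it. The statistic is the U of
the test sample, `U = #{x_i < y_j} + ½·#{x_i = y_j}`, and the headline
p value is one-sided ("less": the test library stochastically smaller —
underrepresentation). For genes with `n + m ≤ 14` values the p value is
exact by enumerating all `choose(n+m, m)` assignments of the observed
multiset, which handles ties without approximation; above that, a normal
approximation with tie-corrected variance and a 0.5 continuity correction is
used (at typical coverage the count ties are sparse enough that the
approximation is near-exact, which the tests check against enumeration at
the cutover). A fully tied gene has zero variance and is assigned p = 1 —
the correct "no evidence" answer, with the side effect that degrading an
already-extreme profile into a complete tie can only move p upward to 1.
Benjamini–Hochberg q values are added across genes; the raw p remains
available as a ranking axis. Output rows are sorted by decreasing fold
reduction with ties broken by increasing p and then gene id, which makes the
TSV deterministic.

These are the package's own conventions: the sample units (per-site
counts), sidedness, tie handling and normalization of the original screen
analysis are not published, and site-level rank testing is the standard
Tn-seq practice this implementation follows.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `gcContent` | 0.43 | fraction | *B. subtilis*-like base composition |
| `geneLengthRange` | 600–1500 | bp | typical bacterial ORF lengths |
| `baselineS` | 0.5 | probability | sporulation-competent fraction in exhaustion medium |
| `conditionalRatio` | 20 | fold | planted *s* defect; matches the effect size the screen targets |
| `nTransformants` / `nColoniesPooled` | 50,000 | clones | desk-scale stand-in for the ~750,000-clone experiment |
| `depth` | 2,000,000 | reads | ~40 reads per TA site on a 300-kb genome |
| `tagLength` | 16 | bp | MmeI-style junction tag |
| `errorRate` | 0 | per base | exact end-to-end identities by default |
| `winsorFraction` | 0.001 | fraction of nonzero sites | bounds jackpot influence on scaling |
| `pseudocount` | 1 | reads | finite fold reduction for emptied genes |
| `trimFraction` | 0 | fraction of gene body | no edge trimming by default; optional terminal exclusion |

All stochastic operations take one integer seed and restore the caller's RNG
state; pipeline stages derive their seeds from the run seed by fixed
offsets, so a config + seed pair reproduces every artifact byte for byte.

# What the generator does and does not emulate

It reproduces the structural features the statistics see: uniform TA-site
targeting, per-gene selection with a pooling bottleneck (which injects the
multinomial noise a fixed-size colony pool adds), junction tags from both
orientations, and configurable sequencing error. It does **not** emulate
insertion hot/cold spots or orientation effects, polar effects on operons,
PCR duplicates or amplification bias, competitive outgrowth dynamics, or
real genome composition (repeats, operons, codon structure). Passing tests
therefore demonstrate that the calling machinery is correct and well-sized
under the stated model — not that real libraries satisfy the model; on real
data, biological replication and inspection of the per-site profiles remain
essential. The single post-selection timepoint is labeled T30 throughout
(the protocol samples cultures around 24–30 h; the simulator does not
distinguish harvest from profile timepoints).

# Degenerate inputs and edge handling

Vegetative-essential genes are empty in *both* libraries; they are still
tested and come out as clean null rows (fold reduction 1, p = 1) rather
than being dropped. A library extinguished by selection raises an explicit
error, as do unknown backgrounds, disjoint TA indices, zero-read libraries
and malformed FASTA/GFF3/FASTQ/WIG records (with line or record numbers).
On linear genomes, sites whose tags would run off an end are skipped with a
warning by the simulator and contribute no tags to the index; real-data N
bases simply never form TA sites, while synthetic mode rejects non-ACGT
alphabets outright.

# Problem sizes used in the checks

The package's test suite and `scripts/acceptance.R` size their simulations
as: a 750-kb, 500-gene genome for the null-calibration check (empirical
size at α = 0.05 and KS uniformity of p values), a 300-kb, 200-gene genome
with 10 planted conditional essentials (ratio 20) for recovery — 20 seeds in
the test suite, 5 in the acceptance script — and a 50-kb genome for the
end-to-end exactness and determinism checks. These are the package's chosen
study conditions at desk scale; all other checks run on 12–30-gene toy
genomes with worked-out oracles.

# Known limitations

* Single library per condition, as in the screen design itself: no
  replicate-aware dispersion modeling (DESeq2-style shrinkage is a
  different tool for a different design).
* Exact-match mapping discards reads with any tag error; at nonzero error
  rates the mapped fraction drops as `(1 - e)^16` and hits all sites
  uniformly, leaving the rank statistics unbiased but less deep.
* The Mann–Whitney p is conservative for very short genes (few TA sites):
  with `n = m = 3` the smallest one-sided exact p is 1/20, so single-gene
  significance is impossible there by construction — such genes rely on the
  fold-reduction ranking.
* No Gumbel/HMM essentiality calling; the package calls *conditional*
  depletion between two libraries, not absolute essentiality.
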