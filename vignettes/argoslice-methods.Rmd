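---
title: "Models and methods behind argoslice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind argoslice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design choices the
package is built on, in the spirit of a methods supplement: what is being
computed, under which assumptions, and what the synthetic data can and
cannot tell you.

## The slicing kernel

Strand coordinates are 1-based from the 5′ end. In a duplex, passenger
position $p$ pairs guide position $a - p$, where the anchor
$a = L_g - o_3 + 1$ is set by the guide length $L_g$ and the guide 3′
overhang $o_3$. The two DCL3 geometries are fixed by construction:

| geometry | guide | passenger | passenger 3′ past guide 5′ | guide 3′ past passenger 5′ |
|---|---|---|---|---|
| 24/23 | 24 nt | 23 nt | 1 nt (untemplated) | 2 nt |
| 24/24 | 24 nt | 24 nt | 2 nt | 2 nt |

Argonaute cleavage severs the substrate bond between the nucleotides
paired to guide positions 10 and 11 (`slice_site_guide_positions()` keeps
the rule in one place). With anchor 23, the cut falls after passenger
position 12, giving the 12-nt 5′ fragment and an 11-nt (24/23) or 12-nt
(24/24) 3′ fragment. Target slicing uses the same rule on a
`guide_target_alignment`; by default perfect Watson–Crick pairing is
required at guide positions 9–11 only, because mismatching those three
positions abolishes cleavage while the cut position itself never depends
on base identity. Two deliberate conventions:

* **G:U wobble counts as a mismatch.** Strict Watson–Crick keeps the
  geometry unambiguous and the brute-force oracle in the test suite
  trivial to state.
* **The untemplated passenger 3′ nucleotide is never checked** for
  complementarity; it has no partner.

The open question of which fragment of an asymmetrically cut long target
is 5′ versus 3′ is resolved by bookkeeping, not biology: `slice_target()`
always reports `frag5` as the piece containing the target 5′ end, and the
test for the 54-nt substrate asserts the unordered pair of lengths
(22 and 32 nt).

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with every random draw under one seed.

**Genome and loci.** I.i.d. DNA at 36% GC (a gene-poor plant-like
composition). Loci are placed by slotting, so a request for $n$ loci
yields exactly $n$ non-overlapping intervals; each carries a mean-1 gamma
expression weight (shape 2) that scales its duplex output and,
optionally, its methylation gain.

**Precursors.** Pol IV copies the + strand over 25–40 bp. Its 5′
nucleotide follows `polIV_5p_bias` and the RDR2 5′ nucleotide (the
complement of the Pol IV 3′ base) follows `rdr2_5p_bias`, both imposed by
rejection sampling of start/length (capped at 50 tries, then accepted),
so reads always match the genome rather than overwriting bases. The RDR2
strand is the full complement plus exactly one untemplated 3′ nucleotide,
drawn uniformly because its identity is unconstrained; genomically it sits
one base outside the template and is carried by aligned reads as a
terminal mismatch, the way an aligner tolerating two mismatches would
place them.

**Dicing.** With probability `1 - p_24_24` the 24/23 duplex is taken from
the precursor end holding the Pol IV 5′ terminus (guide = Pol IV nt 1–24;
passenger = the RDR2 3′-terminal 23-mer, whose penultimate base is the
templated complement of the guide 5′ base — the penultimate-U signature
propagates automatically). Otherwise the 24/24 duplex is taken from the
other end with 2-nt 3′ overhangs at both ends; at a blunt precursor
terminus that geometry forces the partner strand two bases inboard, so
the simulated 24/24 guide spans the final 24 genomic bases and its
partner the 24 bases offset by −2 on the opposite strand. Candidate
duplexes are accepted with probability proportional to the DCL3
end-preference weight of the guide 5′ base (`dcl3_5pA_weight`,
`dcl3_5pG_weight`).

Defaults were fixed once: `polIV_5p_bias = (A .65, C .05, G .25, U .05)`
(initiation mostly with A or G), `rdr2_5p_bias = (A .35, C .15, G .15,
U .35)` (a weaker A/U tendency), DCL3 weights 1.5 (A) and 0.5 (G), and
`p_24_24 = 0.5` (the two duplex classes are comparably abundant, which is
what makes the unsliced 24:23 strand ratio 3:1). Jointly these give an
effective 5′-A frequency of ~0.8 among 24/23 guides, emulating the in
vivo bias. Note that the *pooled* 24-mer population of a
slicing-defective library is less A-biased, because it also contains
24/24 partner strands whose 5′ ends are precursor-internal; analyses that
care about the guide bias should condition on guides, as the tests do.

**Loading and maturation.** Slicing-defective AGO4 emits the guide and
the intact passenger. Wild type emits the guide and, with
`frag12_retention_prob` (default 0.4), the 12-nt passenger 5′ fragment
computed by the slicing kernel itself; the 11/12-nt 3′ fragment is
discarded by default (`keep_frag3` retains it for sensitivity analyses)
because small RNA pools show a 12-nt class but no matching 3′-fragment
class. Partial 12-mer retention keeps 12-mers a minor class relative to
24-mers, as observed; it does not affect any fraction-based statistic.
Guide turnover — 1-nt 3′ truncation and 1–2-nt untemplated uridylation,
5% each — is applied in the wild-type pool. Wild-type and
slicing-defective libraries built from the same duplex stream
(`simulate_duplexes()` + `mature_library()`) are paired at identical
genomic positions, which is what makes the co-5′ analysis meaningful.

**Targets.** Each locus yields one long (> 100 nt) transcript on the
strand opposite the guides. Every 24-nt guide with a perfectly
complementary site programs one cut of the intact transcript (no
re-slicing); both fragments ≥ 30 nt are kept. Position 10 of a 3′
fragment pairs guide position 1, so the +10 U signature equals the
guide-pool 5′-A frequency by construction. The no-slicing control places
the same number of cuts uniformly at random.

**Methylomes.** Every genomic cytosine (both strands) receives a
Poisson(`coverage_mean`) read total and a binomial methylated count.
Rates are per-context backgrounds (CG .20, CHG .08, CHH .03) plus, for
CHG/CHH inside designated loci, a gain of 0.25 scaled by genotype
retention: 1 in wild type, 0.1 in the AGO4-null, 0.5 in the
slicing-defective line (intermediate, as its phenotype is). An optional
per-locus `gain_scale` couples methylation gain to expression weight for
association analyses.

## Registry spectra and the null

The pairing registry of a + strand read and an overlapping − strand read
is `r = start(top) − start(bottom)` in 0-based coordinates — the signed
distance from the top read's 5′ nucleotide to the bottom read's 3′
nucleotide. Positive `r` means the bottom 3′ terminus passes the top 5′
terminus: +1 for canonical 24/23 products, +2 for 24/24. The sign
convention is ours; it is documented, used consistently, and the
strand-swap property (mirroring the genome shifts the swapped-size
spectrum by the length difference) is tested. Pairs are found by a
windowed non-equi join (|r| ≤ 30 by default, covering all DCL3-relevant
registries while bounding the search); each pair contributes the product
of its record counts, with a unique-record mode available. Overlap is
assessed from genomic coordinates, since reads are genome-derived.

The null library re-places every read uniformly within its locus,
preserving locus, length, strand and count. Its spectrum is flat up to
edge effects: over the ±30 window the overlap constraint permits 46
registries, so no bin should exceed roughly 1/46 ≈ 1.3× the 61-bin
uniform expectation — the calibration tests use 3× as the bound.

## The DMR caller

Fixed, non-sliding 100-nt tiles from coordinate 0, half-open; both
strands pooled (standard for plant contexts). The per-bin rate is
Σmeth/Σtotal over cytosines meeting the per-cytosine coverage filter
(≥ 4 reads), and a bin qualifies when at least 4 cytosines meet it — in
every library entering the comparison, so power is symmetric. A bin is
differential when **every** mutant replicate is at least `delta` below
**every** wild-type replicate — the strictest all-pairs reading of a
two-replicate criterion. `delta` is 0.10 in absolute rate units (10
percentage points); a `relative` switch interprets it as a fraction of
the wild-type rate instead. Differential bins on one chromosome merge by
single linkage when their end-to-start gap is ≤ 200 bp; merged DMR rates
are re-pooled from summed counts, not averaged averages. No significance
test is layered on top: the procedure is a threshold rule by design, and
at coverage 20 with ≥ 4 cytosines per bin the binomial noise (~1 point)
is an order of magnitude below the 10-point threshold, which is why the
identical-genotype null yields zero DMRs and seeded loci are recovered
with sensitivity ≥ 0.9. CHG/CG rates are reported per DMR but never used
for calling.

## Problem sizes and determinism

The default simulation scale is 200 loci × ~50 duplexes (about 10⁴
dicing events), which recovers modal registries and signatures
comfortably; the test suite runs reduced variants (30–100 loci, 10–25
duplexes) chosen so every stochastic check sits several standard errors
from its threshold, and the DMR recovery checks use a 50–100-kb genome
with 10–20 seeded loci at coverage 20. Every simulating function takes a
`seed` and restores the RNG state afterwards (`withr::with_seed`);
`run_pipeline()` derives one seed per stage from the master seed so
stages can be rerun independently, and its manifest records file
checksums so determinism is verifiable.

## Limitations

The generator makes no attempt at sequencing error, PCR duplication,
FASTQ-level simulation, loading thermodynamics, or aligner behaviour
beyond the single untemplated-base mismatch; locus weights are i.i.d.
rather than spatially structured; transcripts are one per locus. Passing
tests on this synthetic data demonstrate that the analysis code measures
what it claims under the stated generative model — not that real
libraries satisfy the model. Genome-scale counts from real data (numbers
of loci, DMRs, unique sequences) are outside what synthetic data can
reproduce and are deliberately not asserted anywhere.
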