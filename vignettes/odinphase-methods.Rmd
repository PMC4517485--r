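---
title: "Phasing-based organellar assembly and odin detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing-based organellar assembly and odin detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odinphase)
```

## The problem

Mitochondria and plastids shed DNA into the other genomes of the same
cell. These organellar-derived inserted sequences — numts (mitochondrial
DNA in the nucleus), nupts (plastid DNA in the nucleus) and mtpts
(plastid DNA in mitochondria), collectively *odins* — are close
paralogues of the organellar genome, typically a few percent diverged.
When total-DNA sequencing reads are mapped against an organellar
reference, odin reads cross-map onto their source region. Coverage there
is inflated, and every site where the inserted copy has diverged looks
heterozygous. A consensus caller that keeps the most common nucleotide
(majority count, MC) will happily bake the insertion's alleles into the
"organellar" sequence whenever the copy is present at higher effective
depth; the stricter 2/3-ratio rule fails less often but cannot
reconstruct the insertion itself, and neither can say *which* allele is
organellar.

`odinphase` treats the apparent heterozygosity as signal. Reads (or mate
pairs) covering two or more heterozygous-looking sites link their
alleles; linked sites form phased blocks with two haplotypes — one per
origin. Reconstructing both haplotype sequences and scoring each against
a *secondary reference* (a trusted organellar sequence, possibly from a
relative, possibly the mapping reference itself) identifies the
organellar haplotype and, as a by-product, assembles the insertion. The
whole procedure is iterated, feeding each consensus back as the next
mapping reference, until the sequence stops changing.

## Pipeline and models

One pass runs: duplicate marking → pileup → SNV calling → phasing →
haplotype reconstruction and classification → consensus.

**Duplicates.** Proper pairs are grouped by fragment coordinates
(reference, leftmost start, fragment length), single-end reads by
(reference, start, strand, span); the fragment with the highest total
base quality is kept. Pileups exclude flagged reads and base calls below
phred 13.

**SNV calling.** Per column the top two alleles by count enter a
three-genotype likelihood with a fixed per-read error probability
$\varepsilon$ (default 0.01): a read contributes $1-\varepsilon$ if it
matches a genotype allele, $\varepsilon$ otherwise, and $1/2$ per read
under the heterozygous genotype. With a flat prior, the call confidence
is $-10\log_{10}(1 - p_{\text{best}})$; calls are emitted at phred 10
and marked `PASS` at phred 30 (the conventional emit/call thresholds).
Indels are never called, so every consensus preserves the reference
length — masking and substitution only. A fixed $\varepsilon$ rather
than per-base qualities keeps the model in closed form and testable by
exhaustive enumeration; low-quality bases were already removed at the
pileup.

**Phasing.** For each adjacent pair of het sites, fragments observing
both count as *cis* (same-numbered alleles together) or *trans*. The
pair phase quality is a likelihood-ratio score,
$PQ = 10\,|c - t|\,\log_{10}\frac{1-\varepsilon}{\varepsilon}$, about
19.96 phred per net fragment at $\varepsilon = 0.01$, and a block
extends across a pair exactly when $PQ \ge 10$ — so one clean net
fragment links, and a tie splits. The sweep is greedy and local, which
matches the behaviour of read-backed phasers in this setting; the test
suite bounds the cost of that choice by comparing against a brute-force
search over all $2^{k-1}$ phase configurations on 200 random instances.
Haplotype 0 carries the reference-bearing allele at the block's first
site, making output deterministic; everything downstream is invariant
to swapping the labels.

**Read separation and multiallelic detection.** Each read overlapping a
block is assigned to the haplotype it matches at *all* covered sites.
Reads matching different haplotypes at different sites — or carrying a
third allele — are *chimeric* and are never reassigned: a chimeric read
may itself derive from another insertion copy. A site is flagged
multiallelic when a third allele reaches 10% of its depth; a block is
flagged when any site is, or when chimeric reads reach 10% of its
informative reads (with at least 10 informative reads). The read-level
trigger matters in practice: insertion families that arose by
duplication-then-divergence (copy of a copy) contribute three
haplotypes while producing almost no three-allele columns, because two
independent substitutions rarely strike the same position — but their
reads are reliably chimeric against any two-haplotype split.

**Classification.** Each haplotype sequence is the primary-reference
backbone over the block interval with that haplotype's alleles
substituted; positions with no haplotype-specific read coverage are
masked to N. Sequences are scored against the secondary reference by
semi-global alignment (query end gaps penalized, reference end gaps
free) with match +1, mismatch −1, gap opening −2 and −1 per gapped
base; N scores 0 against anything, so masking neither helps nor hurts.
The alignment itself is `Biostrings::pairwiseAlignment`; an independent
dynamic-programming oracle checks it in the tests. The higher-scoring
haplotype is organellar; ties fall back to supporting read depth and
are flagged for review. When the secondary is coordinate-compatible the
search is windowed around the block (padded by twice the query length),
otherwise the whole secondary is scanned.

**Consensus.** The phased consensus substitutes the organellar
haplotype inside every classified block, applies homozygous-alternative
calls at all other positions, keeps the reference base elsewhere, and
masks depth-below-1 positions to N. MC and 2/3 baselines are provided
for comparison: MC keeps the most common nucleotide (ties go to the
reference base), 2/3 replaces the reference only when an alternative
reaches two thirds of the depth; both mask zero coverage.

## Iteration, stalls, and allele separation

`run_iterations()` repeats the pass with each consensus as the next
primary reference. Convergence means zero non-N differences between
consecutive consensi (positions masked in either sequence are not
counted, so masking changes alone never count as sequence changes) with
no unresolved multiallelic blocks. The iteration cap defaults to 40;
the published analyses of this approach ran to 31 iterations on a
heavily numt-laden felid dataset.

A region with more than two haplotypes breaks the diploid model: the
consensus either freezes with flagged blocks outstanding, or —
instructively — enters a period-2 oscillation in which a handful of
sites toggle between the organellar and an insertion allele on
alternate iterations. Both are treated as a *stall*: the consensus
equals the one from one or two iterations back while multiallelic
blocks persist. After three stalled iterations (`stall_patience`) the
loop switches, irreversibly, to allele-separation mode. A period-2
cycle with *no* flagged blocks left (classification itself alternating
at a few sites as the reference alternates) is a limit cycle with
nothing to rescue; the loop arbitrates the differing sites by the
secondary reference — the origin-by-score rule at single-site
granularity — and declares convergence.

In that mode each flagged block is rescued: the block's hap0, hap1 and
chimeric read sets are each re-called and re-phased on their own.
Re-phasing the chimeric set as a candidate pool of its own is essential
— in a three-haplotype region one entire true haplotype (often one of
the insertion copies, sometimes the organelle) lands in the chimeric
bucket, and discarding it would lose a sequence the method exists to
reconstruct. Sub-blocks found inside a set are classified against the
secondary reference individually, so the organellar side is chosen per
sub-block rather than by a global pairing of labels. Candidate
sequences over the block interval are scored against the secondary
reference; the best becomes the organellar sequence, the others are
reported as insertion haplotypes. Finally, because linkage inside a
flagged block is unreliable by definition, sites where the
coordinate-compatible secondary reference carries one of the two called
alleles take that allele — the same origin-by-alignment-score rule at
single-site granularity. The known residual risk is a site where the
secondary happens to carry the insertion's allele; a divergent
secondary can also, conversely, leave a tie that the phased candidate
then decides.

## The internal mapper and mapping stringency

The package ships a mapping *contract* rather than an aligner: any
function from reads and a reference to alignments can drive the loop.
The built-in implementation places each simulated read at its known
homologous organellar coordinate and keeps it only if its mismatch
fraction against the current reference is at most
`mapper_max_mismatch_frac` (default 0.04). This reproduces, exactly and
deterministically, the stringency dynamics that an aligner's
mismatch-tolerance settings produce: insertion reads map against a
contaminated or converging reference and drop out as the consensus
approaches the organellar truth, flattening the coverage over the
source region across iterations.

Stringency is a real dial, not a nuisance parameter. Under the strict
default, reads from a copy a few percent diverged are lost wherever
their substitutions cluster within a read length, which erases the
heterozygous signal locally; single-pass analyses therefore use a
relaxed cap (0.08 here; ancient-DNA analyses 0.10), mirroring the
field's practice of maximally relaxed mapping for single-pass insertion
hunting and for ancient DNA, while the strict cap is what makes the
iterative loop's coverage normalization work.

## The simulator

`simulate_truth()` / `simulate_reads()` generate the study conditions:
an organellar genome (default 16–20 kb, GC 0.4, i.i.d. bases), inserted
copies from configurable source intervals with per-site substitution
divergence (indels deliberately excluded — the pipeline excludes them,
so simulating them would only test a mapper), configurable copy number,
per-copy relative depth, and optional nesting (a copy diverged from
another copy). Reads are uniform 90 bp single-end or paired-end
(insert ~300 bp with 10% jitter), with i.i.d. sequencing errors
(default 0.2%) and per-base qualities jittered around phred 37; the
ancient-DNA model draws fragment lengths from a truncated log-normal
(mode ≈ 45 bp, range 30–80 bp) and elevates C→T at 5′-terminal
positions (rate halving per position into the read). Insert and quality
jitter are not cosmetic: with fixed inserts and flat qualities,
chance duplicate-key collisions in a region at 3× effective depth
systematically discard true fragments at 50× on a 16 kb genome.

Every read's origin and truth placement are recorded, so tests can
score any stage against ground truth. What the simulator does *not*
emulate: alignment ambiguity and soft-clipping at insertion breakpoints,
indel divergence, site-dependent error profiles, real aDNA fragmentation
chemistry beyond terminal deamination, and host-genome context. Passing
tests therefore demonstrate the method's logic under its own model of
cross-mapping, not end-to-end performance with a particular aligner on
a particular instrument.

## Test scenarios and problem sizes

The acceptance suite runs, at fixed seeds, the study conditions the
package targets; the same scenarios are recomputed from scratch by
`scripts/acceptance.R` at a caller-supplied seed:

- **Biallelic numt recovery.** 20 kb organelle, one 2 kb insertion at
  3% divergence and 2× relative depth, 2×90 bp pairs at 50×: the phased
  consensus must match truth at every divergent site, MC must miscall
  at least one, and the emitted odin regions (merged within one insert
  length, in the spirit of bedtools merge — blocks span their het
  sites, so SNV-free stretches split one insertion into several blocks)
  must cover ≥90% of the true interval.
- **Stall and rescue.** 16 kb organelle with a nested pair of copies
  over the same 2 kb source (2% from the organelle; the second copy a
  further-diverged version of the first, ~5% total), relative depths
  0.8 and 1.0, 90 bp single-end at 50×, starting from a reference 0.3%
  diverged. Copy depths were chosen so the chimeric-read fraction sits
  well above the 10% detection threshold while organellar fragments
  still dominate every adjacent-site junction. The loop must stall,
  switch modes, converge with no unresolved blocks, and match truth at
  the multiallelic sites.
- **Coverage normalization.** Same geometry with a single 8%-divergent
  copy at 2× depth, starting from a reference carrying the insertion's
  allele at 30% of its divergent sites — a coverage-based prior
  assembly contaminated by the insertion, which is precisely the input
  situation the iterative mode is for. The region/background depth
  ratio (raw mapped coverage, 100 bp windows) must be non-increasing
  across iterations within an estimator tolerance of 0.02 and end
  within 1.25× of background.
- **Ancient DNA.** A 200 bp gene-sized region with a 4%-divergent
  insertion at equal depth, 35–50 bp deaminated fragments (30% terminal
  C→T) at 60×, relaxed mapping: both the gene and the pseudogene
  haplotype must be reconstructed within one mismatch of their truths
  in a single pass.

Sizes were chosen as the smallest realistic organellar scales (a
mammalian mitogenome is ~16.5 kb) at which every mechanism — duplicate
collisions, junction statistics, stringency dropout — operates as it
would on real data.

## Numerical and degenerate-input choices

Quality scores are computed in log space throughout (no underflow up to
arbitrary depth). MC ties keep the reference base. Score ties in
classification fall back to read counts and set a `tie` flag. A block
haplotype with no read support is fully masked and classified against
by default. Columns whose reference base is N (masked in a previous
iteration) are called against an arbitrary null allele, so masked
stretches can be repaired by later iterations. Empty pileups yield
empty call sets; a fully masked haplotype is an error for the aligner
("unalignable block"). All randomness flows from explicit integer
seeds (kept below 2³¹), and identical inputs with identical seeds give
byte-identical outputs.

## Known limitations

The greedy sweep can mis-join at a junction where two insertion
haplotypes jointly outvote the organelle in trans; the result is a
mosaic pair of haplotypes of which classification keeps the better,
occasionally leaving single-site errors outside flagged blocks (the
rescue only runs where the multiallelic signature is detected). Control
regions and other repeat/heteroplasmy-rich stretches violate the
two-haplotype assumption in ways no amount of phasing fixes — their
reconstruction should be treated with suspicion, and uneven coverage
there is expected. Polyploid phasing proper, indel-bearing insertions,
and locating insertions in the host genome are out of scope.
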