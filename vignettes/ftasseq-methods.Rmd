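---
title: "Modelling terminator-assisted semi-targeted RNA-seq: simulator and caller methods"
author: "ftasseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling terminator-assisted semi-targeted RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftasseq)
```

## The chemistry being modelled

FTAS-seq (fusion sequencing via terminator-assisted synthesis) is a
semi-targeted library preparation for discovering 3' fusion partners of a
known 5' gene. Total RNA is reverse transcribed; a single primer specific
to the anchor gene's first exon (here TMPRSS2, whose promoter is
androgen-regulated and whose fusions with ETS-family genes such as *ERG*
dominate prostate cancer) is then extended along the cDNA in a mix of
dNTPs and oligonucleotide-tethered dideoxynucleotides (OTDDNs): chain
terminators for C and U channels that carry a universal adapter on the
nucleobase. Each extension therefore stops at a random pyrimidine, leaving
an adapter at the 3' end of the nascent strand. A nested indexing PCR with
an inner anchor-specific primer (hybridising closer to any breakpoint)
adds full-length flow-cell adapters, and short products are removed by
size selection. Every on-target read pair then starts at the nested
primer (R1) and ends at the dideoxy-terminated base (R2), so the unknown
3' partner is read agnostically, and the termination coordinate acts as a
molecular identifier for duplicate collapse — the chemistry has no UMI,
but the random termination plays the same role.

The package implements this system twice over: a generative simulator of
the library chemistry, and an anchored fusion caller for the reads it (or
a real instrument) produces. A deterministic toy reference ties the two
together for validation.

## The toy reference

`makeToyReference()` builds a two-chromosome reference. `chrA` carries a
five-exon TMPRSS2-like anchor gene — its exon 1 embeds the real outer
extension primer upstream of the real nested primer — followed 250 nt
downstream by a six-exon coding ERG-like gene, mimicking the
intra-chromosomal deletion geometry of the TMPRSS2–ERG fusion. `chrB`
carries interchromosomal partner analogues (a seven-exon SIM2-like gene
whose intron 6 serves as an inverted-segment donor, coding PPP3CA-like and
minus-strand AMACR-like genes with CDS phases arranged so that T3-P2 and
T5-A2 junctions preserve the reading frame) and a non-coding GAPDH-like
housekeeping gene. Exon/intron sizes (36–300 nt exons, 70–120 nt introns)
are small but within the realistic range; all filler sequence is drawn
i.i.d. from a seeded RNG, and the generator verifies that the nested
primer occurs exactly once in the genome so that anchoring is
well-defined. Output (FASTA, GTF, manifest TSV) is byte-identical for a
fixed seed.

## Simulator model, stage by stage

**Sampling and reverse transcription** (`degradeAndReverseTranscribe`).
Molecules are drawn multinomially from the configured pool. Degradation is
modelled as independent per-phosphodiester-bond breaks at
`degradationRate` (unit: probability per bond); each fragment is reverse
transcribed from a uniform internal position (random priming, fraction
`randomPrimingFraction = 0.5`) or from its 3' end (oligo-dT), giving a
cDNA span. The cell-line presets use `degradationRate = 0` — intact
cultured-cell RNA — while the knob exists to emulate degraded clinical
material. Only spans covering the complete outer-primer site can serve as
extension templates; this, not an explicit filter, is what makes the
library semi-targeted.

**Terminator-assisted extension** (`extendWithTerminators`). Incorporation
competition is concentration-proportional with equal efficiency for dNTP
and OTDDN, so the per-incorporation termination probability in each
pyrimidine channel is `terminator / (terminator + dNTP)`. With the default
mix (1 µM dATP/dGTP, 0.9 µM dTTP/dCTP, 0.1 µM each OTDDN) that is 0.1 per
incorporated C or T; the walk down a template is then a per-position
Bernoulli process, and the number of pyrimidines incorporated before
termination is geometric when the two channel probabilities are equal. The
simulator samples the termination index by inverse CDF over the exact
per-position probabilities, which reduces to the geometric draw in the
equal-probability case but remains exact for asymmetric mixes. Termination
is allowed on the very first base after the primer (the chemistry offers
no reason to forbid it). Fifteen extension cycles are modelled as fifteen
independent nascent strands per template — a single primer cannot amplify
exponentially.

**Nested PCR and size selection** (`nestedPcrSizeSelect`). Molecules
lacking the nested-primer site are dropped; survivors are re-anchored to
begin at the nested primer's 5' base. Amplification over `pcrCycles = 20`
cycles at `pcrEfficiency = 0.9` per cycle is a Galton–Watson branching
process recorded as a per-molecule `duplicateCount`; the published 3–7
reamplification cycles are folded into this count. The two-step bead
cleanup is abstracted to a hard insert-size window (50–700 nt); annealing
temperatures, enzyme amounts and bead ratios have no sequence-level
consequence and are not modelled.

**Sequencing** (`sequencePairs`). R1 reads the insert from the nested
primer into the OTDDN adapter and i7-side context when the insert is
short; R2 reads the reverse complement from the termination base into the
reverse complement of the i5 adapter. Substitution errors are i.i.d. at
`substitutionRate = 0.001` (a typical per-base rate for the instrument
class); qualities are constant Q30 except error positions, which carry
Q11. Indel errors are off by default but exposed (`indelRate`). Sequencing
depth is normalised to `depth` pairs per replicate by multinomial
resampling of the duplicate counts — the depth-limited draw from an
amplified library that a sequencer performs — so every emitted pair still
maps to exactly one truth molecule. Two technical replicates with derived
sub-seeds are simulated by default.

**What the simulator does not emulate.** Optical/flow-cell duplicates,
PhiX spike-in, position-dependent quality decay, polymerase sequence bias,
template switching, and genuine expression noise beyond multinomial
sampling. Passing tests on simulated data therefore demonstrate that the
caller inverts *this* generative model — primer anchoring, random
pyrimidine termination, PCR duplication, substitution noise — not that it
is robust to every artefact of real instruments.

## Sample presets

The fusion-positive preset (`samplePreset("nci-h660", ...)`) contains the
five fusion isoforms reported in the NCI-H660 prostate cancer cell line —
`T1-E4`, `T2-E4`, `T1-EIIIa` (partial ERG-like intron 3 followed by exon
4), `T2-E5` and `T1-E5` — each at relative abundance 1 against the
housekeeping transcript at 1000, matching the ~1000-fold excess of
housekeeping over fusion transcript measured in that line by RT-qPCR. The
wild-type anchor transcript is present at abundance 5, comparable to the
summed fusion abundance, since the cell line retains non-rearranged
alleles and stromal contamination behaves likewise. The fusion-negative
preset (`"lncap"`) has the same composition minus the fusions.

## The anchored caller

`callFusions()` runs trimming, mapping, deduplication, clustering and
replicate concordance. Design choices that matter:

* **Trimming** (`trimPairs`) reproduces the stated rule set: right-side
  adapter k-mer trimming (k = 23 shortening to 11 at the read end, one
  mismatch allowed), right-side quality trimming below Q15,
  pair-equalising trim when one mate is adapter-trimmed (the
  adapter-implied insert length applies to both mates), and discard below
  50 nt or above one ambiguous base. It is a reimplementation of the
  parameter semantics, not of any specific trimming tool.
* **Anchor check**: R1 must begin with the nested primer within one
  mismatch; everything else is off-target (and in practice the
  housekeeping transcript contributes zero reads at all, because it lacks
  the primer sites — enrichment is physical, not computational).
* **Split mapping** (`splitMapPair`): R1 is compared to the expected
  wild-type anchor transcript; reads without a divergence point and with
  at most `max(2, 2%)` mismatches are wild type. Divergent reads seed
  their remainder (k = 15 exact k-mers, stride 4) against an index over
  both genome strands *and* the canonical spliced transcripts — so a
  partner segment crossing one of the partner's own splice junctions still
  chains as a single locus. Partner tails shorter than k are rescued by an
  exact search of the terminal `minOverhang` bases. The junction is placed
  at the split maximising matched bases over the whole read (match +1,
  mismatch −1, no gaps within segments); ties go to the annotated exon
  boundary, then leftmost. The chimeric interpretation must strictly beat
  the best single-locus alignment, both segments must reach 10 nt and both
  overhangs 10 nt — applied as acceptance filters *after* the
  unconstrained search, so short-overhang junction reads are rejected
  rather than re-split at a wrong position. Partner loci inside the anchor
  gene itself (intron readthrough) are classified wild type, not chimeric.
  Equal-scoring distinct partner loci set an ambiguity flag and the read
  is excluded from evidence counts.
* **Long inserts**: when the insert exceeds the read length (no adapter
  read-through), the junction may only be visible in R2; such pairs are
  re-anchored by seeding the reverse complement of R2 onto the anchor
  transcript. Pairs where neither read spans the junction cannot support a
  base-precise call and are not counted.
* **Deduplication** (`deduplicateAlignments`): fragments are identical
  when junction, retained-strand and termination coordinate agree —
  because every molecule starts at the same primer, the termination base
  is the only molecular identifier this chemistry provides.
* **Clustering** (`clusterCalls`): junction distance is measured in
  *transcript* coordinates where both breakpoints are exonic — a one-base
  shift across an intron is one transcript base, not one intron length —
  and genomically otherwise, with a 3 nt merge window. Additionally,
  junctions related by a coordinated shift of up to `minOverhang` bases
  whose flanking reference bases are homologous up to one mismatch are
  merged: inside such a micro-homology tract the split position is not
  determined by the read, and a single sequencing error can make a
  shifted split score best, producing deterministic satellite junctions
  in every replicate if treated as distinct. Each cluster is reported at
  its modal junction (most supporting reads, then most fragments, then
  leftmost).
* **Confidence tiers** are this package's own evidence thresholds, stated
  in the report header: *high* needs ≥ 5 unique fragments from ≥ 2
  distinct terminations, *medium* ≥ 2 fragments, everything else *low*.
  They deliberately depend only on transparent counts.
* **Replicate concordance**: a call must appear (same gene pair, junction
  within the merge window) in both technical replicates; per-replicate
  fragment counts are reported. A union mode with a flag exists for
  single-replicate designs.

## Isoform naming and reading frames

Names follow `<5'code><5'unit>-<3'code><3'unit>`: configurable short gene
codes (T = TMPRSS2, E = ERG, ...; unknown genes are an error, never a
guess), arabic exon numbers for exonic breakpoints, and the Roman numeral
of the containing intron for intronic breakpoints, e.g. `T1-E4`,
`T1-EIIIa`, `T5-SVI`. When several intronic breakpoints share an intron
they get lowercase letters in order of increasing distance from the
preceding exon — a convention of this package, since no published rule
defines the lettering. Inverted intron segments render the plain Roman
numeral with the inversion recorded in the call record. Exon numbering
follows each gene's canonical (first-listed) transcript.

Reading frames: a fusion is *in frame* when both breakpoints lie within
or at the boundaries of annotated CDS and the codon phase 5' of the
junction equals the phase 3' of it (a breakpoint exactly at the CDS end
counts as at the boundary); *out of frame* when both sides are coding but
phases differ; *unclear* when the 5' side contributes no CDS (the anchor's
exon 1 is 5' UTR, so all T1 fusions are unclear), the 3' breakpoint is
intronic, inverted or in a non-coding gene, or alternative annotated 3'
transcripts disagree on the phase.

## Problem sizes and numerical checks

The validation suite simulates 2 replicates × 10^5 pairs from 10^5
sampled molecules for the fusion-positive condition (about a minute of
calling on one core) and verifies that exactly the five preset isoforms
are called with replicate support; the fusion-negative condition is run
once at 10^5 pairs and across twenty seeds at 10^4 pairs — a breadth/depth
trade that keeps the whole suite in a few minutes — and must yield zero
calls. Termination chemistry is checked over ≥ 10^5 incorporation events
(frequency 0.100 ± 0.005) with a chi-square goodness-of-fit test against
the geometric law at α = 0.01; the chi-square form is used because the
distribution is discrete with heavy ties, which invalidates the classical
KS null. The split mapper is compared to an exhaustive-alignment oracle
(every split position × exact substring search over all references) on
200 random zero-error instances. Monotonicity properties — calls never
increase with `minOverhang`, mean insert length strictly decreases with
the terminator:dNTP ratio — are tested at three settings each.

## Known limitations

The caller assumes every informative read is anchored; it cannot discover
fusions whose 5' partner is not the configured anchor gene. Junctions
landing within long perfect repeats are reported at the
annotation-preferred representative, and partners outside any annotated
gene are dropped rather than reported as intergenic. The
confidence tiers are heuristics over counts, not calibrated
probabilities. The simulator's error model is substitution-dominated and
position-independent; adapter-dimer and chimera artefacts of PCR are not
generated, so the caller's robustness to them is untested here.
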