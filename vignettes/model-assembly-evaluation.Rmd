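---
title: "Simulation-based evaluation of transcriptome assemblies with a positional gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based evaluation of transcriptome assemblies with a positional gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maeval)
```

## The evaluation problem

A de novo transcriptome assembler receives reads and returns contigs; with
no reference there is no direct way to tell a good assembly from a bad one.
Length-based summaries are actively misleading for transcriptomes: merging
reads of two homologous isoforms into one contig *raises* N50 and mean
contig length while producing a chimera. `maeval` evaluates assemblers on
simulated reads whose exact origin is known, so that the optimal assembly —
and the identity of every misplaced read — is known too.

The framework has three parts: a library/sequencing simulator that tags
every read with its origin, the Model Assembly built from those tags, and a
set of comparison metrics applied uniformly to the Model Assembly and to
any external assembly of the same reads.

## The Model Assembly

All coordinates in the package are 0-based, half-open and
transcript-relative; GTF input (1-based inclusive) is converted at the
boundary. For a read set $R_t$ on transcript $t$ with spans
$[s_i, e_i)$, the Model Assembly (MA) merges two reads iff they share the
origin transcript and their spans overlap by at least one base
($s_i < e_j$ and $s_j < e_i$). MA contigs are the connected components of
this overlap relation; each contig's span is the union of its member
spans, and its sequence is the reference substring over that span.

Two choices deserve comment:

* **Reference-derived sequence.** The MA is positional: it never consults
  read sequences, so its contig sequence is taken from the reference
  transcript rather than from a read consensus. This makes the MA's
  specificity exactly 100% by construction, which the test suite uses as a
  self-consistency check.
* **Strictly-positive overlap.** Adjacent reads ($s_j = e_i$) are *not*
  merged. The implementation is a single sorted sweep per transcript; the
  test suite checks it against a brute-force connected-components oracle
  on random instances.

Before any comparison, assemblies are filtered identically: contigs shorter
than 100 bp and singletons (exactly one placed read) are discarded. The
length boundary is *keep length ≥ 100*; the boundary and the singleton rule
are both configurable, and the singleton filter degrades to length-only
with a warning when an assembler does not expose read placements.

## The library simulator

`library_config()` collects the stages and their defaults:

| stage | parameter(s) | default | meaning |
|---|---|---|---|
| expression | `zipf_exponent` k | 1.0 | rank-abundance power law $p(r) \propto r^{-k}$ |
|  | `zipf_tail_cutoff` x0 | off | optional damping $e^{-(r/x_0)^2}$ |
|  | `n_molecules` | 1e5 | multinomial trials (2e8 at full scale) |
|  | `n_cells` | 20000 | metadata only |
| reverse transcription | `tss_sd` | 25 bp | half-normal 5' start jitter |
|  | `polyA_shape`, `polyA_scale` | 0 | poly-A tail model disabled |
| fragmentation | `fragmentation_lambda` | 900 bp | mean fragment length |
| size selection | `cutoff_min`, `cutoff_max` | 500, 800 bp | closed interval |
| subsampling | `subsample_n` | none | uniform without replacement |

Rationale for the non-obvious ones:

* **"Modified Zipf's law."** Heavy-tailed rank-abundance is the empirical
  norm for transcriptomes, but the exact modification is a modelling
  choice. We implement a power law with an optional Gaussian rank cutoff,
  $p(r) \propto r^{-k} e^{-(r/x_0)^2}$, defaulting to the pure one-parameter
  power law $k = 1$. Ranks are a seeded random permutation of the
  transcripts; integer counts come from a single multinomial, so `n_cells`
  carries no per-cell mechanics.
* **Reverse transcription** is modelled as 5' start jitter only:
  `start = clamp(round(|N(0, tss_sd)|), 0, L-1)`, `end = L`. This encodes
  the 5'→3' representation bias of RT libraries while the poly-A
  parameters are zero. An optional `random_primers` mode adds uniform
  internal truncation and is off by default, since the default parameter
  set pins down only the start-site variation.
* **Fragmentation** is a Poisson process: a molecule of length $\ell$
  receives $\mathrm{Pois}(\ell/\lambda)$ breakpoints uniform over the
  $\ell - 1$ internal cut sites, giving mean fragment length $\lambda$ and
  an exact partition of the molecule (coincident breakpoints are
  deduplicated, a negligible correction at these lengths). This is the
  simplest concrete "mechanical breakage" model with the right mean.
* **Size selection** keeps the closed interval $[500, 800]$ — the natural
  reading of a "500–800 bp" cutoff.

## The sequencer

454-style pyrosequencing flows nucleotides in the fixed order T, A, C, G
(one cycle = 4 flows; the default 100 flow cycles = 400 flows). A flow
reads the *whole* homopolymer run of the flowed base and produces a light
signal; base-calling errors are therefore homopolymer length errors, not
substitutions. `sequence_fragment()` implements this directly on the run
decomposition of the template:

* a run of true length $n \ge 1$ draws signal
  $N(n,\ \sigma_0 + \sigma_1\sqrt{n})$, called as the signal rounded
  half-away-from-zero and floored at 0 (a call of 0 deletes the run; the
  rounding rule is fixed and exposed for tests);
* a zero-mer flow (flowed base absent at the current template position)
  yields a spurious signal ≥ 0.5 with probability `p_insert_zero`,
  inserting one base of the flowed nucleotide. One-base insertions are the
  dominant observed spurious-flow mode, so the inserted length is fixed at
  1;
* sequencing stops at the earlier of flow exhaustion and template
  consumption; trailing flows after the template is consumed do not
  insert.

Defaults are $\sigma_0 = 0.03$, $\sigma_1 = 0.09$,
`p_insert_zero` = 0.005 — small scales chosen so that error rates are
realistic for the platform (fractions of a percent per base, concentrated
in long homopolymers). Mean read length is *emergent*: it is the
homopolymer-dependent flow capacity of 400 flows, roughly 260–270 bp on
random 50%-GC sequence and lower on homopolymer-rich templates; the test
suite checks the simulated mean against a brute-force zero-noise flow
counter rather than asserting a fixed number. Read orientation is
Bernoulli(1/2); a reverse read consumes the fragment from its 3' end, and
the origin span records the error-free template interval actually
consumed. Origins travel in the FASTA headers under the grammar
`readNNN|transcript|gene|start|end|strand`, which round-trips losslessly.

## Containment, ambiguity, chimeras

**Containment.** A sequence is *contained* in a set if a single local
alignment passes `evalue_max` (1e-9) and covers at least `coverage_min`
(80%) of the length of the sequence selected by `coverage_denominator`.
Specificity is the contained fraction of assembly contigs against the
reference set; sensitivity swaps the roles. The coverage denominator is
genuinely ambiguous in the field's usage — "the hit covered at least 80% of
the length" can attach to either sequence. We default to the *contained*
sequence (the query), which is the self-consistent choice: under the
reference-side reading, an assembly of short but perfectly correct contigs
would score near-zero specificity against full-length transcripts. The
literal reference-side mode is available as
`coverage_denominator = "reference_sequence"`.

**The builtin aligner** is a seed-and-extend local aligner: exact 11-mer
seeding into a global subject index, per-diagonal maximal-scoring ungapped
extension (match +1, mismatch −2, Kadane's algorithm), and banded chaining
of colinear segments across nearby diagonals with affine gap costs (open 5,
extend 2) — sufficient for the homopolymer indels the sequencer produces.
E-values use the ungapped Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with $\lambda$ solved from the scoring scheme
($\lambda \approx 1.33$ for +1/−2 at uniform composition) and
$K = 0.621$; both are documented in `containment_params()` and
overridable. E-value constants are backend-specific conventions, so the
contract with the external backend (any 12-column tabular output, e.g.
NCBI blastn) is *identical containment verdicts*, not identical e-values;
the test suite enforces exactly that.

**Ambiguity** counts, for each read aligned back to the contigs, how many
distinct contigs it hits above the e-value threshold (any-hit counting by
default, matching the multiple-hits criterion; a best-hit-only mode is a
flag). **Chimera statistics** need no alignment at all: each placed read's
origin is known, each contig's majority origin transcript is determined
(ties broken lexicographically and reported), misplaced reads are members
whose origin differs, and a contig is chimeric iff any member is
misplaced. Judging misplacement at the *transcript* level is deliberate —
isoforms of one gene are distinct origins, which is why the report is
split by the alternative-splicing status of the majority gene; a
gene-level misplaced fraction is carried as a secondary column. Class
means are unweighted over contigs.

## The synthetic transcriptome generator

`generate_synthetic_transcriptome()` emulates the features of an annotated
transcriptome that this framework actually exercises: multiple genes, a
configurable fraction with ≥ 2 isoforms, and — crucially — isoforms that
share *full exon sequences* (extra isoforms skip one internal exon), so
that provenance-based chimera detection faces the same confusion a real
assembler faces on alternatively spliced genes. Exons are uniform-random
sequence at a configurable GC content, 100–400 bp by default, 2–8 exons
per gene; generation is deterministic per seed.

What it does **not** emulate: real exon/intron length distributions,
sequence homology between genes (paralogs), repeats and low-complexity
tracts, biased base composition along transcripts, UTR structure. Passing
tests therefore demonstrate the framework's internal correctness —
oracle-equivalent merging, calibrated distributions, indel-only error
model, self-consistent Model Assembly — not performance claims about any
real transcriptome: on real data, repeats and paralogy make both
containment and ambiguity strictly harder.

## Numerical choices and degenerate inputs

* Flow-signal rounding is half-away-from-zero (for the relevant
  non-negative signals, `floor(x + 0.5)`), fixed and unit-tested.
* N50 ties: when the descending cumulative sum reaches exactly half the
  total, the length that closed the half is reported.
* The ≥ 1 kbp contig rows are threshold-inclusive; the 200/400/800/1000 bp
  cumulative counts are strict "longer than". Both conventions are kept as
  is because each matches its standard report row.
* Majority ties in chimera statistics break lexicographically, with a
  message.
* Degenerate inputs: 1 bp transcripts reverse-transcribe to themselves;
  molecules shorter than 2 bp cannot fragment; empty assemblies and empty
  reference sets are errors rather than NaN-producing edge cases;
  ambiguity codes in input FASTA are rejected by default with an optional
  seeded random resolution.
* All stage seeds are small fixed offsets from the one run seed, recorded
  in the run manifest together with parameters and per-stage counts.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes on one core while every
statistical check retains power: transcriptomes of 5–30 genes (up to 1000
for rank-abundance fits), libraries of 10^4–10^5 molecules, 200–2000
sequenced reads, 10^4 draws for distributional checks, 200 random
instances for the merge oracle and 1000 for the metric oracle. The
simulator itself has no scale-dependent switches: full-scale runs (10^8
molecules, 8×10^5 reads) use the same code paths.

## Known limitations

* PCR amplification bias, duplicates, adapter sequence and inter-molecule
  PCR chimeras are not simulated; observed chimera rates on real libraries
  include processes this framework deliberately excludes.
* No quality strings or SFF flowgrams are emitted; the pipeline is
  FASTA-based.
* The builtin aligner reports the best chained segment per
  (query, subject, diagonal-cluster); it does not enumerate suboptimal
  HSPs, and containment uses a single best hit with no multi-hit
  stitching.
* Read placements for external assemblies are consumed from ACE or a
  two-column TSV; formats that hide read tracing cannot be chimera-scored
  (the ambiguity and containment sections still apply).
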