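---
title: "readtrim: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{readtrim: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readtrim)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. The README shows usage; here we explain
the model behind each operator, the numerical conventions, what the
synthetic-data generator does and does not emulate, and the design
choices that were genuinely open.

## The data model

A read is an identifier, a base string over `A,C,G,T,N`, and one
integer PHRED score per base (`q`, with error probability
`10^(-q/10)`); scores are stored in FASTQ as ASCII `code = q + offset`
with offset 33 (Phred33) or 64 (Phred64). Two invariants hold
everywhere: bases and scores have equal length, and every surviving
read produced by any operator is a *contiguous* substring of its input
with scores trimmed in lockstep — trimming never edits bases, never
reorders, never lengthens. Coordinates are 0-based half-open
`[start, end)` throughout, which keeps compositions of crops closed
under the convention and makes the trim-log arithmetic
(`kept = end - start`) exact.

Bases are not case-normalized; no quality operator inspects bases, and
adapter matching is case-insensitive. `N` never counts as a match.

## Encoding detection

An incorrect PHRED offset silently invalidates every quality decision,
so the offset is detected before processing: up to 10,000 quality lines
are scanned, and with `m`/`M` the minimum/maximum ASCII code seen,
`m < 64` forces Phred33 and `m >= 64 && M > 74` forces Phred64. Codes
confined to `64..74` are consistent with both interpretations (very
high Phred33 qualities vs very low Phred64 ones); guessing here would
recreate exactly the hard-to-diagnose failure the detector exists to
prevent, so the ambiguous case is an *error* instructing the user to
pass `-phred33`/`-phred64`. The 10,000-record sample bounds startup
cost while being far more than enough signal on real libraries, where
quality codes span a wide range within the first handful of records.

## Quality trimmers

**SLIDINGWINDOW `w:q`.** Windows of width `w` are scanned 5' to 3'; at
the first window whose *mean* quality falls below `q` the read is cut
before the window, then any remaining trailing bases below `q` are
stripped (without this cleanup a low-quality tail shorter than the
window could survive the cut). A read shorter than `w` is treated as a
single window. The mean comparison is done in integer arithmetic
(`sum(q) < q*w`), so no floating-point drift can flip a boundary case;
a window exactly at the threshold passes. `4:20` is the customary
default: short enough to react within a few bases of a quality cliff,
with `q = 20` (1% error) the conventional floor.

**MAXINFO `T:s`.** Instead of a hard cutoff, the read is cut at the
prefix length `L*` maximizing

```
score(L) = ln(1 / (1 + exp(T - 1 - L)))           # length/mappability
         + (1 - s) * ln(L)                        # coverage (L >= 1)
         + s * sum_{i<L} ln(1 - 10^(-q_i / 10))   # correctness
```

The logistic first term rises steeply until the target length `T`
(the shortest length the downstream application maps confidently) and
saturates beyond it; the coverage term rewards extra bases with
diminishing returns; the correctness term is the log-probability that
the kept prefix is error-free, so each base contributes a penalty that
grows as its quality drops. The strictness `s` in (0,1) interpolates
between maximizing usable length (`s → 0`, where the increasing length
and coverage terms keep any equal-quality read whole) and aggressive
error avoidance (`s → 1`). A score of 0 is treated as 1 to keep the
logarithm finite, `L = 0` scores `-Inf` (only an empty input read is
"dropped"), and ties break toward the longer prefix. The exhaustive
argmax over all `L` *is* the definition; the compiled implementation
enumerates it directly, and the test suite checks it against an
independent vectorized enumeration. The logistic term is computed as
`-log1p(exp(x))` with the branch `x > 35 → -x`, which is exact to
double precision and cannot overflow for any sane `T`.

**LEADING/TRAILING, HEADCROP/TAILCROP/CROP, AVGQUAL, MINLEN/BASECOUNT**
are the simple operators: quality end-stripping, fixed-length cropping
(the way to remove UMIs or custom barcodes before alignment), a
whole-read mean-quality filter for globally bad reads (useful when
sequencing cycles failed systemically — it never trims, only drops),
and a length floor. BASECOUNT is schema-identical to MINLEN: its role
is enforcing a *post-trimming* minimum length so that fragments too
short to align uniquely are removed at the end of the pipeline. Every
threshold in the package fails strictly (`< q` / `< n`): one uniform
boundary rule, so a mean exactly at the threshold or a read exactly at
the minimum length survives. All of these are idempotent where
idempotence makes sense (filters), and crop pairs commute when neither
drops.

## Adapter clipping

Alignment windows are scored with `+log10(4) ≈ 0.602` per match and
`-q/10` per mismatch, `q` being the read base's quality. The match
bonus is the information content of one confirmed base, the mismatch
penalty the base-call log-error scale, so scores read as decimal-digit
confidence: the conventional simple threshold 10 (~10^10 odds) needs
about 17 consecutive matches, the palindrome threshold 30 about 50.
Candidates must first pass a seed test — at most `seedMismatches`
mismatches within the first `min(16, overlap)` columns — which makes
the scan cheap and suppresses chance hits.

*Simple mode* slides each adapter across the read, 5' to 3', including
partial overlaps hanging off the 3' end; overlaps too short for even a
perfect match to reach the threshold are skipped (and
`minAdapterLength`, default 8, floors how short an overlap is
entertained at all). The read is truncated before the earliest
qualifying offset; a hit at offset 0 means the read is pure adapter and
is dropped.

*Palindrome mode* exploits pair structure: if the fragment is shorter
than the read length, the mates read through into adapter, and the
forward read aligns against the reverse complement of the reverse read
over the entire fragment. Each mate is conceptually extended 5' with
its ligated adapter prefix (the `/1` and `/2` records of the adapter
FASTA), so for the true fragment length the aligned overlap covers
*both* adapter prefixes plus the fragment — roughly
`L + |prefix1| + |prefix2|` matching columns — which is why the method
detects read-through reliably even for very short fragments while a
34-base overlap requirement alone would not. Every fragment length `L`
below the read length is tested; the best qualifying score wins, ties
to the shorter fragment (deterministic and directly checkable by
exhaustive scan). Both mates are trimmed to `L`; the reverse mate then
carries no information not already in the forward mate, so it is
dropped unless `keepBothReads`. Extension columns carry quality 40, and
mismatch penalties use the smaller of the two column qualities so that
a low-confidence call on either mate is not over-penalized.

The adapter geometry follows standard Illumina chemistry: the sequence
appearing at the 3' end of read 1 is the reverse complement of the
`/2` prefix, and vice versa. `load_adapters()` pairs `/1`–`/2` records
sharing a stem for palindrome mode and uses everything else (including
orphaned `/1`/`/2` records, with a warning) in simple mode.

## The engine and its concurrency contract

Reads are streamed in batches (default 5,000 pairs, bounding memory at
roughly batch × read length per worker) and batches may be processed by
forked workers (`threads`). Every step is a pure function of its read
pair — no step carries state across reads — and results are written
strictly in ordinal order, so the contract is simple and testable: for
fixed inputs and steps, all outputs are byte-identical for every worker
count. The suite verifies 1 vs 2 and 1 vs 4 workers on the full
pipeline, including the summary file.

Pair bookkeeping: after the step list, each pair has exactly one of
four fates — both mates survive (written to `_1P`/`_2P`), forward only
(`_1U`), reverse only (`_2U`), or dropped. The fates partition the
input by construction, and the summary renderer refuses to render an
inconsistent partition. Single-end mode is the same engine with the
reverse stream absent and fates {surviving, dropped}.

GZIP output is written as a multi-member stream: every
`block_records = 10000` records are serialized and compressed as one
complete RFC 1952 member, resetting the compression dictionary at the
block boundary so members are independent. Standard decompressors
concatenate members, which gives the byte-identity guarantee without
any custom framing, at a small size cost per reset; the block size
keeps that overhead well under 0.1% on the suite's data while leaving
enough blocks for parallel compression to matter. Members are produced
by zlib itself (via the compiled layer) rather than R's `memCompress`,
which emits zlib-wrapped (RFC 1950) streams that are not valid `.gz`
members. BZIP2 is supported for reading and serial writing only; the
parallel path is GZIP-specific.

Pre-run validation is deliberately front-loaded: step tokens are parsed
and adapter FASTAs loaded before any read is touched, and the optional
pairing validator streams both files' names (first whitespace token,
trailing `/1`/`/2` stripped) and reports the first divergent ordinal or
a length mismatch before the engine writes anything.

## The synthetic-data generator

`simulate_pairs()` emulates a NovaSeq-like 2×100 bp library: insert
lengths `round(N(60, 10))` floored at 20, so nearly every pair reads
through into adapter; per-cycle mean quality decaying linearly Q38 → Q20
with per-base jitter (sd 3, clamped to [2, 41]); substitution errors
placed with probability proportional to each base's `10^(-q/10)`,
scaled so the mean rate is 0.1% — errors therefore concentrate where
quality is low, as on a real instrument. Read 1 continues past the
fragment into its read-through adapter (a fixed synthetic 34-mer, not
any vendor's sequence) and then random bases; read 2 mirrors this on
the reverse complement strand. The truth table records each pair's
insert length and adapter start offset, which is what lets the suite
score fragment-length recovery and residual adapter exactly, without
external data. The same seed and configuration reproduce byte-identical
files; the error injector consumes a fixed number of random draws per
read so that configurations differing only in error rate share
fragments and qualities under the same seed.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: indels and adapter-dimer artifacts,
platform-specific error motifs (e.g. G-quadruplex or poly-G tails on
two-channel chemistry), quality-score binning, optical duplicates, and
non-normal insert distributions. The validation shows the algorithms
implement their definitions and recover planted truth; calibration of
thresholds for a particular real library remains the user's decision.

## Problem sizes and test design

The suite validates the window and maxinfo trimmers against independent
brute-force oracles (exhaustive window scan; exhaustive prefix-score
enumeration) on 10,000 simulated reads plus 300 randomized
length/parameter combinations; worker invariance and adapter recovery
run on 10,000 pairs; conservation runs across 50 randomized
configurations of 20–120 pairs each. These sizes keep the whole suite
around half a minute while exercising every code path at realistic
read lengths; all quantities are recomputed from scratch by
`scripts/acceptance.R` under a caller-supplied seed.

## Known limitations

* Interleaved FASTQ, FASTA input and SAM/BAM are out of scope, as are
  Solexa (+64 with negative scores) and other historical encodings.
* Re-encoding steps (TOPHRED33/64) and maximum-length filters are not
  provided; outputs keep the input encoding.
* Palindrome mode assumes both mates have equal nominal read length at
  the clip step (the usual case when ILLUMINACLIP runs first); it
  still operates, conservatively, on unequal lengths.
* Forked parallelism (`parallel::mclapply`) degrades gracefully to
  serial execution where fork is unavailable; results are identical by
  contract either way.
* The whole-file convenience readers hold one file in memory; the
  engine itself streams in batches and is the right entry point for
  large inputs.
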