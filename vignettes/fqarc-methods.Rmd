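---
title: "Methods: adaptive context-model compression of FASTQ streams"
author: "fqarc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive context-model compression of FASTQ streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqarc)
```

## The problem

FASTQ files store sequencing reads as 4-line records: an identifier line, the
base calls, a `+` separator, and per-base quality scores. The three kinds of
line have completely different statistics — identifiers are highly templated
text, bases come from a 4–5 symbol alphabet with genomic repeat structure, and
qualities are drawn from 6–40 ASCII levels with strong serial correlation — so
a general-purpose compressor leaves a lot on the table. `fqarc` splits records
into the three homogeneous sub-streams, buffers each into fixed-size blocks,
and compresses every block with a codec matched to its stream, all sharing one
binary arithmetic coder. Blocks land in a nested container archive whose index
maps line ranges to blocks, so a record range can be decoded without touching
the rest of the archive, and each compressed block can be handed to an object
sink (a file, a directory of objects, or a remote store honouring the same
`put`/`finalize` contract) as soon as it is ready, overlapping transmission
with the compression of later blocks.

## Adaptive modelling and the arithmetic coder

All codecs are *adaptive*: symbol probabilities are estimated from the data
already coded, never from a prior scan, so compression is single-pass and the
decoder can rebuild the identical model state from its own output. An order-k
context model keeps counts of which symbol followed each k-symbol context;
predictions are add-one-smoothed relative frequencies over the block's
declared alphabet, so no coded symbol ever has probability zero. When a
context's count total reaches 256 its counts are halved — recent data then
dominates, bounding both memory and the model's inertia.

Several models of different orders run side by side and their predictions are
combined by a convex mix whose weights adapt multiplicatively: after each
symbol, every model's weight is scaled by the probability it assigned to the
symbol actually seen, renormalised, and floored at 0.01 so a model that was
wrong for a while can recover. The mixed distribution is quantised onto a
2^14 integer grid with a floor of one count per symbol; the rounding residue
is given to the largest entry. The floor is the "interpolation" step: it
guarantees decodability of symbols the models currently consider impossible.
The grid leaves two bits of headroom below the coder's 16-bit frequency
ceiling.

The coder itself is a classic binary arithmetic coder: 32-bit low/high
registers, carry propagation by pending-bit counting, and a flush that emits
the disambiguating bits of the final interval plus a two-byte tail guard so
the decoder's 32-bit preload never starves. Encoder and decoder perform the
same floating-point operations in the same order, which makes every payload
bit-reproducible across runs and worker counts.

## Stream codecs

**Bases.** Read lines are joined with `'\n'` terminators (the terminator
doubles as the length signal for variable-length reads) and transformed with
the Burrows–Wheeler transform, which sorts rotations so that symbols followed
by similar contexts become adjacent runs. A mix of an order-0 and an order-1
model (initial weights 0.5/0.5) then codes the transformed bytes. The suffix
array is built by prefix doubling with counting sort (O(n log n)); blocks are
transformed in segments of at most 4 MiB to bound the transform's working
memory, with one primary index stored per segment. The full byte alphabet is
used — `N` and IUPAC codes need no escape path.

**Qualities.** No transform. The prediction mix combines order-1, order-2,
order-4 and order-6 context models with a matching model that looks up the
most recent earlier occurrence of the current 6-symbol context and proposes
its successor with mass 0.9. Order-k contexts reset at read boundaries (the
`'\n'` symbol), keeping block decoding independent of alignment; the matching
model searches the whole block history, since consecutive reads often share
quality trajectories. Orders 4 and 6 live in hashed tables of 2^18 buckets
with verification tags; a colliding context is seen as empty, so the mix
falls back on the lower orders until the bucket is re-claimed. (Larger
tables adapt slightly better on huge blocks; 2^18 keeps a codec instance
around 50 MB, which matters when several workers run at once.)

**Identifiers.** Lines are tokenised at punctuation and space; records with
the same delimiter signature form a template group, and each field column of
a group is classified: digit columns whose successive deltas form a small
set are delta-coded value-wise; equal-width digit columns are delta-coded
digit by digit (the string `3458644` becomes `3,1,1,3,-2,-2,0`); columns
dominated by runs of identical values are run-length-limited coded (runs
capped at 255); free-running digit columns of varying precision become
self-delimiting varints (7 payload bits per byte, continuation bit — codes
concatenate without separators); everything else is carried as plain text.
The assembled streams are then entropy-coded with the order-0/1 byte codec.

**The `+` line.** Line 3 carries no modelled information, but losslessness
demands it be preserved: an auxiliary stream stores a per-record "bare `+`"
flag plus an exception list of literal payloads. On the common case (all
bare) it costs a few bytes per block.

Blocks carry the uncompressed byte count and a CRC-32 of the reconstructed
bytes; decompression verifies both, so payload corruption or truncation is
reported with the offending block's stream and record range rather than
producing silently wrong output.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `records_per_block` | 100,000 | records per block container; larger blocks compress better, smaller blocks give finer random access |
| `grid_bits` | 14 | coder probability resolution (2^14 grid) |
| rescale cap | 256 | context count total that triggers halving |
| weight floor | 0.01 | minimum mixing weight per model |
| `hash_bits` | 18 | buckets (log2) of the hashed order-4/6 tables |
| match mass | 0.9 | probability on the matching model's proposal |
| run cap | 255 | maximum run per run-length pair |
| `workers` | 1 | parallel block compressors; archives are invariant to this |

The weight-update exponent is 1 (plain probability scaling): with the floor
at 0.01 it converged as fast as steeper exponents on Markov test streams
while keeping the arithmetic identical on both coder sides. The archive
index stores `hash_bits`, so archives decode correctly whatever the writer
used.

## The synthetic-data generator

`generate_fastq()` emulates the heterogeneity the codec has to face:
read lengths fixed or ranged, bases from an order-k Markov chain whose
transition sharpness interpolates between i.i.d. uniform (alpha = 1) and
near-deterministic repeats, quality strings over alphabets of 6–39 symbols
(the range observed across Illumina 1.8+ binned and Sanger-scale real
datasets) with optional order-2 structure, and identifiers with a constant
run/instrument/flowcell template, an incrementing record counter and
free-running tile/x/y coordinates — one column for each metadata scheme.
Generation is driven by a self-contained xorshift PRNG, so a spec (including
its seed) maps to identical bytes on any platform.

What it does *not* emulate: real base composition (GC skew, genomic
repeats at biological scales), quality trajectories that drift along the
read, instrument-specific quality binning, or adapter content. Passing the
battery therefore demonstrates correctness (byte-exact losslessness, random
access, determinism) and the expected *ordering* of codec performance
(higher-order models beat order-0 on structured data, smaller quality
alphabets compress better); measured ratios on real datasets will differ.

## Numerical and degenerate-input choices

- Quantisation gives every symbol at least one grid count and pushes the
  rounding residue onto the largest entry; encoder and decoder recompute it
  identically, so cross-side drift cannot occur.
- Empty blocks (zero records) are legal everywhere and produce empty
  payloads; the empty *file* yields a valid archive with zero block
  containers.
- The BWT rejects empty input (callers skip empty blocks) and appends an
  implicit sentinel smaller than every byte, so ties in rotation order
  cannot arise.
- Line endings: LF and CRLF are accepted and recorded once per file;
  presence of a final newline is recorded too. Mixed dialects within one
  file are rejected at parse time rather than silently normalised.
- Random access requires the start line to sit on a record boundary; the
  error names the nearest boundary instead of guessing which record was
  meant.
- `summary_stats()` uses the sample (n−1) standard deviation — the only
  convention that reproduces the dispersion printed for the published
  per-dataset ratio table this package's statistics are checked against.

## Design choices where the design was open

- **Restoring line 3.** Dropping `+`-line payloads is common practice but
  lossy; the auxiliary flag-plus-exceptions stream keeps the tool honest at
  negligible cost.
- **Coder realisation.** "Bit arithmetic coding" is realised as a
  multi-symbol binary arithmetic coder over integer frequency tables; the
  precision (32-bit registers, 16-bit totals) and renormalisation strategy
  are this package's choices, stated here because no reference fixes them.
- **Payload framing.** A raw arithmetic-coded stream cannot detect a
  stripped trailing byte by itself, so the generic coder surface frames
  payloads with a 4-byte length; block payloads rely on the container's
  size + CRC-32 instead.
- **Match scope.** The matching model matches across reads within a block
  (within-read-only matching was consistently weaker on order-2 fixtures);
  order-k contexts still reset per read to keep predictions
  alignment-independent.
- **BWT granularity.** The transform runs over the concatenated block (in
  4 MiB segments), not per read: per-read transforms forgo cross-read
  redundancy, which is most of what the transform buys on genomic data.

## Problem sizes used by the test-suite

The bundled suite exercises 20+ generated corpora crossing read lengths
{50, 100, 150}, quality alphabets {6, 7, 38, 39} and all newline dialects at
200–2,000 records each, plus one corpus of 100,000 records; the coder
optimality check codes 10^6 i.i.d. symbols against a matched static model,
and transform correctness is checked against naive rotation-sort and
LF-mapping oracles on 1,000 random strings. These sizes were chosen as the
smallest that exercise multi-block archives, hashed-table contexts and
segment-spanning transforms.

## Known limitations

- Blocks are decoded whole: extracting one record still decodes its entire
  block container (that is the random-access granularity).
- The archive format is this package's own; it is documented and versioned
  but not interchange-compatible with other FASTQ compressors.
- Compression of the base stream assumes unaligned, unordered reads; no
  reference-based or reorder-based gains are attempted (by design).
- Multi-file archives are limited to one FASTQ stream per archive; arbitrary
  byte streams can be carried via the generic codec but without
  line-addressed access.
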