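---
title: "Storing digital data on sequence-defined oligomers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing digital data on sequence-defined oligomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostore)
```

## The storage channel

A sequence-defined oligomer is a synthetic chain with an exact length and an
exact, chosen order of building blocks. If an alphabet provides $B$
mass-distinguishable side-chain functionalities, a chain of length $L$ can
take $B^L$ states (`sequence_space_size()`), so short chains over a rich
alphabet store data compactly: 20 blocks already give $2.56\times10^{10}$
distinct octamers.

`oligostore` implements the full write–read channel around that idea:

1. **Write** (`encode_bits()`): a bit string becomes a small collection of
   short, index-tagged monomer sequences.
2. **Physical layer** (`fragment_ladders()`, `simulate_spectrum()`): each
   sequence maps to a precursor mass and to the two complementary
   fragment-mass ladders produced by controlled backbone urethane cleavage in
   a tandem-MS collision cell; the simulator emulates the resulting MALDI-type
   MS/MS peak lists.
3. **Read** (`read_sequence()`): a de novo reconstruction of the monomer
   sequence from a peak list, walking both ladders.
4. **Decode** (`decode_manifest()`): the recovered, unordered collection is
   reassembled into the exact original bit string.

## Mass model

For a sequence $b_1\dots b_L$ with unit masses $u(b_i)$, an $\alpha$-end
(linker) mass $\alpha$, an $\omega$-end (thiolactone stop) mass $\omega$, an
adduct mass $a$ (sodium by default, positive-mode MALDI convention) and charge
$z$ (default 1):

$$\text{precursor } m/z = \frac{\alpha + \textstyle\sum_i u(b_i) + \omega + a}{z}$$

Cleavage at the backbone urethane bond before position $i{+}1$ yields a
start-containing (prefix) fragment and a stop-containing (suffix) fragment:

$$p_i = \alpha + \sum_{k\le i} u(b_k) + \delta_L + a,
\qquad
s_j = \sum_{k> L-j} u(b_k) + \omega + \delta_R + a,$$

where $\delta_L,\delta_R$ are the constant mass offsets the cleavage leaves on
each side. Successive prefix differences reproduce the unit masses in order
($p_{i+1}-p_i = u(b_{i+1})$), suffix differences in reverse, and every
complementary pair satisfies
$p_i + s_{L-i} = z\cdot\text{precursor} + \delta_L + \delta_R + a$,
a constant the tests assert to $10^{-9}$ Da. Composition alone fixes the
precursor mass; only the ladders are order-sensitive, which is exactly why
they allow sequencing.

All masses are monoisotopic. The true end-group and cleavage offsets of a
given chemistry are calibration facts of that chemistry, so the model is plain
configuration (`mass_model()`, a flat `key: value` file); every numerical
example in the package uses the documented toy model below.

### The toy model and why its constants look odd

`toy_mass_model()` uses $\alpha=47$, $\omega=75$, $\delta_L=1.3$,
$\delta_R=0.9$ Da with a sodium adduct, and `toy_alphabet(15)` places unit
masses on a regular 5 Da lattice (100, 105, …, 170 Da, labels `A`–`O`, plus a
non-coding spacer `*` at 175 Da). The end-group constants are chosen so that
prefix peaks, suffix peaks and the precursor each sit on a *different*
off-lattice residue class modulo 5 Da (offsets 1.289, 3.889 and 4.989 after
sodium). Consequences:

* a peak from one series can never fall within a realistic tolerance of a
  target computed for the other series, and
* the heaviest single unit (175 Da) is lighter than two copies of the lightest
  (200 Da), so one ladder step can never be confused with two.

Together these make clean-channel reads provably exact rather than merely
usually-correct, which is what the channel-level test properties rely on.
Real chemistries approximate this through chemically distinct end groups; the
toy model simply makes the separation explicit.

## The fragment layout

`encode_bits()` performs **one global radix conversion** of the whole bit
string: the bits, read MSB-first, form one big integer written in base $B$
with exactly $D = \min\{d : B^d \ge 2^n\}$ digits (leading zero digits
preserved). The arithmetic is exact at any length (limb-based big-integer
conversion, `bits_to_digits()` / `digits_to_bits()`); a per-block recoding
mode is deliberately not offered, because block-local conversion wastes
capacity and complicates the length bookkeeping.

The digit stream is then cut into chunks of a **constant payload size**
$q = C - w_{\max}$, where $C$ is the fragment capacity and $w_{\max}$ the
digit width of the largest chunk index. Each chunk is prefixed with its
0-based index; the final chunk is right-padded to $q$ with the non-coding
spacer. Two index policies exist:

* **fixed width** – every index zero-padded to the same width; decoding is
  trivially stateless, and an unpadded (trimmed) final fragment is allowed;
* **minimal width** – small indices use fewer digits, so early fragments are
  shorter than capacity. Here the fragment *length* reveals the index width
  (all fragments have length $w_i + q$), so decoding stays stateless — but
  only because padding is mandatory. With a trimmed final fragment a
  width-1-index fragment whose first payload digit aliases the last index
  could be confused with the short final fragment, and for roughly one input
  in $B$ two self-consistent reassemblies would exist. `encoding_config()`
  therefore rejects `pad = FALSE` together with minimal-width indices.

### The length record

The decoder must know the exact bit count $n$ (to restore leading zeros and
to trim the spacer). Two policies:

* `"dedicated"` (default): $n$ is written in base $B$ as its own fragment,
  marked by a leading spacer flag so it can never be mistaken for a data
  fragment.
* `"residual"`: the payload width $D$ is already visible in a decoded
  collection, and only bit lengths inside a window of at most
  $\lceil\log_2 B\rceil \le B-1$ values are compatible with a given $D$
  (`bit_length_window()`). A **single flag** recording $n - n_{\min}(D)$
  therefore pins $n$ exactly — the length record is one monomer.

Decoding dereplicates exact duplicates, parses the indices, verifies that
they form a contiguous range $0..K{-}1$ (naming any gaps), glues payloads in
index order, trims the trailing spacer run, recovers $n$, and converts back.
Order and duplication of the input never matter, and a payload whose value
needs more than $n$ bits is rejected as corrupt.

### The reference configuration

`reference_config()` is the calibrated layout used by the demonstrations and
the `roundtrip` driver: 15 coding blocks (`A`–`O`), capacity 6, minimal-width
**radix-11** indices, spacer padding, residual length record. For a 33 × 33
bit matrix (1089 bits, $D = 279$ digits, $q = 4$, $K = 70$) it produces:

```{r census}
m <- encode_bits(bit_matrix_to_bits(random_matrix(33, 33, seed = 1)),
                 reference_config())
census(m)
```

11 pentamers (indices 0–10, one index digit), 59 hexamers (indices 11–69),
and the single-flag length monomer: 71 oligomers for any 1089-bit payload, a
collection that fits a 72-position automated synthesis block in one batch.
The index radix is an explicit calibration knob: radix 11 is what places the
one-digit/two-digit boundary so that this census comes out, and nothing else
in the system depends on it. The census is a function of the payload *length*
only, never of its content.

## Reading sequences de novo

`read_sequence()` needs the alphabet, the mass model and the chain length
$L$ (known per sample for sequence-defined material). Steps:

1. **Filter** (`filter_peaks()`): keep peaks with signal-to-noise above
   `snr_min` (default 5). If the input carries no noise estimate, the median
   peak intensity is the noise floor — a deliberately crude, overridable
   estimator, recorded on the output so filtering is idempotent.
2. **Anchors** (`anchor_search()`): the smallest fragment of each series
   ($p_1$ and $s_1$) identifies the first and last block. Near-isobaric
   blocks produce multi-label anchors; ambiguity is propagated, never
   resolved by intensity heuristics.
3. **Walk both ladders** (`ladder_walk()`): from the series base, test
   $m + u(b)$ for every block $b$ against the peak list within the tolerance
   (0.02 Da absolute by default; a ppm mode exists). A unique hit assigns the
   block and advances the *theoretical* mass — observed jitter is never
   accumulated, so a jitter of up to half the tolerance can never push a walk
   off course. No hit halts the walk with a gap; multiple hits halt it with
   recorded candidates. Cost: $O(L \cdot B \cdot \log P)$; the per-read
   lookup count is exposed in the diagnostics and grows exactly linearly
   in $L$.
4. **Merge**: positions claimed by both walks must agree exactly (label
   equality, not mass re-derivation); positions claimed by one walk are
   accepted. Every position is witnessed by up to two independent peaks
   ($p_k$ and $s_{L-k+1}$), so deleting any single ladder peak never changes
   a read — including the smallest fragment, whose loss just removes one
   anchor while the opposite walk still covers the whole chain. If exactly
   one position stays open, candidate labels are inferred from the precursor
   mass (complementary-mass inference), but the read is reported
   `ambiguous`, not silently completed.
5. **Verify**: the full theoretical ladders of the read sequence are matched
   back to the spectrum to annotate per-position evidence (`left`, `right`,
   `both`), to list unexplained peaks, and to enforce two acceptance rules:
   the reconstructed precursor must match the observed one within tolerance,
   and (under `require_both_anchors`, the default) each series must have
   contributed at least one matched peak. The both-anchors rule is enforced
   at the level of the whole series rather than literally on $p_1$/$s_1$:
   demanding the smallest fragments themselves would make every
   smallest-peak dropout unreadable even though the information is fully
   present.

Failure modes are explicit: `failed` with a reason (`conflict` at a named
position, `anchor_missing` with the side, `precursor_mismatch`) or
`ambiguous` with per-position candidate sets. Ties between two peaks inside
one tolerance window go to the nearer peak.

The reader requires the alphabet's smallest unit-mass gap to exceed twice the
tolerance and warns when it does not; with the default 0.02 Da tolerance the
constructor of `toy_alphabet()` guarantees a gap above 0.04 Da even under
mass jitter.

## The simulator and what it does not show

`simulate_spectrum()` emits the surviving ladder peaks plus the precursor,
each perturbed uniformly within ±`jitter`, adds `n_noise_peaks` uniform
random noise peaks across the spectrum span, and is byte-deterministic under
a seed (the caller's RNG stream is left untouched). Intensities are
schematic — constant for signal, configurable for noise — because the reader
uses intensity only through signal-to-noise; by default noise sits below the
S/N threshold so that clean-channel guarantees stay testable, and an
above-threshold range exercises ambiguity reporting instead.

The simulator deliberately omits isotope envelopes, multiple charging,
in-source fragmentation, intensity physics and mixture spectra. Passing the
test suite therefore demonstrates the *algorithmic* correctness of the codec
and reader under the stated peak-level error modes (dropout, jitter,
sub-threshold noise), not robustness to every artefact of real MALDI data.
Real spectra are ingested through the same `peak_list()` surface (MGF or
two-column CSV), one spectrum per oligomer; pooled-mixture deconvolution is
out of scope.

## Problem sizes and numerical choices

* Radix conversion is exact big-integer arithmetic; everything else is plain
  double-precision sums of configuration masses, compared only against a
  user-visible tolerance (default 0.02 Da, absolute).
* The test suite exercises: exhaustive decode∘encode identity for all bit
  strings up to 12 bits over bases 2, 3 and 15, plus randomized payloads to
  10⁴ bits; 10³ clean-channel reads (L 3–8, 15 + 1 blocks); every
  single-peak deletion on octamers; equal-composition hexamer pairs;
  manifest permutation/duplication invariance; and full 33 × 33
  encode–simulate–read–decode round trips. The whole suite runs in well
  under a minute on one CPU.
* Degenerate inputs are first-class: empty manifests, empty sequences
  (allowed only behind an explicit flag), one-block chains, all-zero bit
  strings and payloads of a single bit all have defined behaviour and tests.

## Known limitations

* Average-mass mode is not offered; read-out assumes monoisotopic peaks.
* The text codec's position prefixes are single decimal symbols as printed;
  more than 9 words requires the explicit multi-digit option, which assumes
  words do not begin with digit characters.
* `sequence_space_size()` refuses results beyond $2^{53}$ rather than
  returning an approximation.
* Per-series adducts and negative-ion mode are not modelled; the charge
  parameter exists mainly to keep ESI-style data usable.
* The dedicated length record may exceed the fragment capacity for extremely
  long payloads; the residual policy never does.
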