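# oligostore

Digital data storage on sequence-defined oligomers: write bits into short
synthetic chains, read them back from tandem mass spectra.

## The problem

Sequence-defined oligomers — macromolecules with an exact chain length and an
exact, chosen order of side-chain building blocks — can carry digital
information the way DNA does, but over a much richer chemical alphabet: with
*B* mass-distinguishable blocks, a chain of length *L* takes *B^L* states
(20 blocks give 8&nbsp;000 trimers and 2.56&nbsp;×&nbsp;10¹⁰ octamers).
Writing is solid-phase synthesis; reading is tandem mass spectrometry, where
controlled cleavage of the backbone urethane bonds produces two complementary
fragment-mass ladders whose successive mass differences spell the sequence
left-to-right and right-to-left.

`oligostore` is for chemists and method developers working on molecular data
storage who need the *informatics* half of that pipeline:

* **Binary codec** — `encode_bits()` converts any bit string (plain 0/1
  text, raw files, PBM bitmaps) with one exact big-integer radix conversion
  into an unordered collection of short, index-tagged oligomer sequences with
  a length record and non-coding spacer padding; `decode_manifest()` inverts
  it from any permutation, with duplicates, naming any missing fragment.
* **Text codec** — `encode_text()` / `decode_text()` write a sentence as one
  position-prefixed oligomer per word.
* **Mass model** — `oligomer_mass()` and `fragment_ladders()` map sequences
  to precursor masses and theoretical prefix/suffix ladders
  (`p_i = α + Σu + δ_L + adduct`, `s_j = Σu + ω + δ_R + adduct`); end-group
  and cleavage-offset masses are configuration, editable as flat text files.
* **De novo reader** — `read_sequence()` reconstructs a monomer sequence from
  an MS/MS peak list (MGF or CSV) by signal-to-noise filtering (S/N > 5),
  anchor search, and a tolerance-bounded walk of both ladders (0.02 Da
  default), merging the two directions with per-position evidence. One
  missing peak anywhere — anchors included — never changes a read.
* **Simulator** — `simulate_spectrum()` generates seeded synthetic spectra
  with controllable peak dropout, m/z jitter and noise, so the whole
  write→read→decode channel is testable without instrument time
  (`roundtrip()`).

A command line ships at `system.file("cli", "oligostore", package =
"oligostore")` with subcommands `encode`, `decode`, `text-encode`,
`text-decode`, `simulate`, `read`, `roundtrip` and `census`.

## Worked example

Read a trimer `CAB` back from a simulated spectrum (toy 15-letter alphabet
`A`–`O`, unit masses 100–170 Da; documented toy mass model):

```r
library(oligostore)
ab <- toy_alphabet(15)
mm <- toy_mass_model()

fragment_ladders("CAB", mm, ab)
#> <fragment_ladder> CAB  precursor m/z 459.9892
#>   prefix: 181.2892 281.2892 386.2892
#>   suffix: 203.8892 303.8892 413.8892
```

The prefix differences 281.289 − 181.289 = 100 (= `A`) and
386.289 − 281.289 = 105 (= `B`) spell the chain after the `C` anchor; the
suffix ladder spells it backwards. Simulate a jittered, noisy spectrum and
read it de novo:

```r
pl <- simulate_spectrum("CAB", ab, mm,
                        sim_config(jitter = 0.005, n_noise_peaks = 8, seed = 4))
read_sequence(pl, ab, mm, L = 3)
#> <read_result> status: unique
#>   sequence: CAB
#>   evidence: both both both
```

`evidence: both` means every position is witnessed by a peak in each ladder.
Now the full channel on a machine-readable payload — a 33 × 33 bit matrix
(1089 pixels), encoded, simulated one spectrum per oligomer, read, and
decoded:

```r
rt <- roundtrip(random_matrix(33, 33, seed = 11),
                sim = sim_config(jitter = 0.005, seed = 11))
rt
#> <roundtrip_report>
#>   payload:        1089 bits (33 x 33 matrix)
#>   fragments:      71  census 1:1 5:11 6:59
#>   unique reads:   71 / 71
#>   bit-exact:      TRUE
```

Under the shipped reference configuration (capacity 6, minimal-width
radix-11 indices, single-flag residual length record) any 1089-bit payload
becomes exactly 71 oligomers — 1 monomer, 11 pentamers, 59 hexamers — a
collection sized for one batch of a 72-position automated synthesizer. The
census depends only on the payload length, never its content.

See the methods vignette (`vignettes/oligostore-methods.Rmd`) for the mass
model, the fragment-layout design and its decoding-ambiguity constraints,
the reader's acceptance rules, and known limitations.

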