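---
title: "Models and conventions behind fluopeer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind fluopeer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluopeer)
```

This vignette is the package's own account of the models it implements: the
reporter logic, the site/pegRNA geometry, the deterministic editing
simulators, the quantification estimators, and the numerical and design
choices made where the underlying procedure left them open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The reporter model

A fluorescent prime-editing reporter couples editing of a plasmid to a
visible signal. A 45–100 nt genomic window is cloned between a constitutive
GFP cassette and a Cherry cassette, connected by P2A linkers so one promoter
drives the whole frame. Pre-edit, the insert must block Cherry: either the
genomic variant itself is a nonsense or frameshift allele, or a disruption
is added. Post-edit, the insert must read through: length a multiple of 3
and no in-frame stop. `verify_reporter()` simulates exactly this logic:

* `gfp_expressed` is always true (GFP is 5′ of the insert).
* `cherry_expressed` is true iff the insert length is `0 mod 3` **and**
  translation of GFP–P2A–insert–P2A–Cherry in one continuous frame reaches
  the end without a stop codon.

Ribosome skipping at P2A is deliberately *not* modelled: the design rules
depend only on frame and stop logic, and a frameshifted Cherry is scored
dark even if translation happens to continue. The GFP and Cherry segment
constants shipped by `reporter_segments()` are short **synthetic** stop-free
stand-in ORFs — for frame/stop simulation any stop-free in-frame sequence is
equivalent — and the P2A is the standard 66-nt P2A. All segments are
user-replaceable; fixed cloning-scar bases at the insert junctions are
regarded as absorbed into the flanking segments, so the insert alone defines
the frame.

## Coordinates and site geometry

All user-facing coordinates are 1-based, inclusive, on the top strand. The
*PAM strand* is the strand carrying protospacer and PAM; positions along it
("o coords") map to top coords by `L - y + 1` on the minus strand. With
spacer length `SL` (default 20) and PAM 5′-most base at o-coord `g`:

* protospacer: `[g - SL, g - 1]`;
* nick: `nick_offset` nt 5′ of the PAM, i.e. the base 5′ of the nicked bond
  is `g - nick_offset - 1`. The default `nick_offset = 3` is the canonical
  SpCas9-nickase geometry (between protospacer positions 17/18) and is
  configurable per editor profile.

`find_spacer_sites()` scans for PAM matches whose 5′-most base lies within a
window of offsets relative to the edited base, *measured on the PAM strand*
(default −10..+4). The window anchors the PAM, not the nick or spacer —
the simplest reading of "a region around the target site searched for PAMs"
— and is fully configurable if an alternative anchoring is wanted. For
multi-base edits the anchor is the 5′-most edited base on the scanned
strand, which keeps the scan exactly strand-symmetric (a property test
asserts this). Prime-editing candidates additionally require
`nick_to_edit ≥ 0`: the RT must be able to write the edit, so the edit must
sit at or downstream of the first flap base. For base-editor profiles the
scan window is irrelevant; the PAM offset range is derived from the
base-editing window instead (protospacer position `p` pins the PAM at
offset `SL - p + 1`).

Overlapping patterns (an NGG is always also an NGN) are deduplicated by
site; per-pattern counts in `scan_variant_table()` count each pattern
separately while the `total` column deduplicates.

## pegRNA design

`design_pegrnas()` enumerates one candidate per (PBS length, RTT length)
pair under `design_constraints()`:

* **PBS**: reverse complement of the PAM-strand bases immediately 5′ of the
  nick; length 9–15 nt with at least 5 G/C. These bounds are the published
  design rule this package exists to operationalise.
* **RTT**: reverse complement of the 3′ flap, the post-edit PAM-strand
  sequence starting at the nick; length 10–20 nt, long enough that the flap
  spans the entire alt allele **plus at least one downstream homologous
  base** (for deletions, the first base past the junction).

Candidates are ordered by a documented deterministic heuristic — PBS length
closest to 12, then RTT length closest to the mid-range — which is a
tie-break, *not* an efficiency prediction; no published scoring formula
exists for flexible-PAM editors, so all candidates are returned. Spacer
on-target scoring is left as a user-side filter. An RTT beginning with `C`
is flagged (`rtt_starts_with_c`) but never filtered, following common
pegRNA guidance. epegRNAs append a named 3′ structured motif; the shipped
motif constant is a **placeholder** that must be replaced with a real
stabilising motif sequence before synthesis.

PE3/PE3b nicking guides (`design_nicking_guides()`) are scanned on the
opposite strand of the *post-edit* sequence within ±100 bp of the pegRNA
nick (a span covering typical PE3 offsets). A guide is PE3b when its
spacer/PAM footprint overlaps the edited bases and its spacer occurs
nowhere in the pre-edit sequence — the operational meaning of "binds only
after successful editing".

## The prime-editing simulator

`simulate_prime_edit()` is a design verifier, not an efficiency or
off-target model. It requires an exact, unique protospacer+PAM match
(ambiguity is an error — on a short reporter insert a duplicated site is a
design bug), an exact reverse-complement PBS match 5′ of the nick, and then
resolves the flap against the displaced strand. Flap resolution must choose
how many displaced bases `r` the flap replaces; the rule is:

1. admit every `r` whose displaced segment ends with at least
   `min_homology` (default 1) nt of terminal homology to the flap 3′ end;
2. prefer maximal terminal homology;
3. break ties by minimal edit distance between flap and displaced segment;
4. then by smallest length shift `|r - f|`, then smallest `r`.

Terminal homology comes first because designed flaps always end in several
homologous bases, whereas edit distance alone is flat for large deletions;
distance then disambiguates repeats with coincidentally long homology. The
rule is deterministic but can still be ambiguous in adversarial repeats, so
`design_reporter_insert()` *verifies every candidate through the simulator*
and rejects any whose resolution does not reproduce the intended post-edit
sequence exactly. The round-trip property — simulated editing equals plain
string splicing (`apply_edit()`) for every returned design — is asserted
over 500 seeded random targets in the acceptance tests.

## Reporter insert design

`design_reporter_insert()` selects a window of about `length_pref` nt
(default 60, comfortably inside 45–100 while keeping oligos short) covering
the pegRNA footprint (protospacer, PAM, PBS and RTT spans) with a 5-nt
margin, centred on the protospacer. It then searches a small candidate grid
— window shifts of 0/±3/±6, frame offsets 0–2 (5′ trim), 3′ trims 0–2 — for
the first combination in that fixed preference order satisfying all
invariants (post in frame and stop-free; pre blocked; length bounds;
footprint covered; simulator round trip).

If the genomic edit is itself frameshifting (`Δ mod 3 ≠ 0`) or removes a
stop in the reporter frame, the window is cloned unmodified
(`native_frameshift` / `native_stop`). Otherwise a disruption is added
inside the RTT-rewritten span so the same pegRNA removes it: by default a
1-nt insertion (a frameshift), placed downstream of the PAM — so the
pre-edit reporter is still recognised by the editor — and as far from the
nick as possible *minus a 4-nt homology margin*. The margin is the
package's own refinement of "farthest from the nick": leaving only one
homologous base past the disruption makes flap re-annealing ambiguous in
random sequence, while four bases make the correct resolution essentially
unique. Four alternative inserted bases (T/A/G/C) are tried in order when
repeats defeat the first choice. An in-frame `TAA` insertion
(`disruption_kind = "added_stop"`) is available as the alternative
disruption style.

When no candidate satisfies every invariant — for example a stop codon in
every reading frame of every admissible window — the function signals an
`fp_design_failure` condition whose `report` enumerates the violated
constraint per candidate. Around 20 % of uniform-random 200-nt targets fail
by construction (stop codons are dense in random sequence); real genomic
windows inside coding exons fail far less often. Design failures are an
honest answer, not an error path to be retried.

The base-editing mode (`design_base_edit_reporter()`) scans all six reading
frames (two orientations × three offsets) of a window around a single-base
substitution and picks a frame in which the pre-edit sequence carries a stop
codon covering the edited base and the post-edit insert is in frame and
stop-free; the insert is then cloned in that orientation and frame. When no
frame qualifies, the failure report lists all six verdicts.

## Cloning simulation

`emit_insert_oligos()` produces the annealed duplex for the SalI/Acc65I
acceptor: top `TCGACC + insert + G`, bottom `GTACC + revcomp(insert) + GG`;
the annealing identity (`bottom` minus its 4-nt 5′ overhang equals the
reverse complement of `top` minus its 4-nt 5′ overhang) and regeneration of
both recognition sites under `simulate_digest_ligate()` are asserted for
every emitted pair. pegRNA Golden Gate duplexes (`emit_pegrna_oligos()`)
use acceptor-supplied vector overhangs and segment-derived inter-duplex
overhangs so that `simulate_golden_gate()` chains them back into exactly
spacer+scaffold+extension; duplicate junction overhangs in an acceptor
definition are an error. The scaffold constant is the standard SpCas9
sgRNA scaffold and is user-replaceable.

## Quantification

* `facs_ratio_score()` implements the efficiency score: mean Cherry over
  mean GFP across GFP⁺ events, invariant under common channel gain. Gates
  are fixed thresholds or a per-channel 99.9th-percentile quantile of a
  negative-control table (`gate_config()`); the quantile default reflects
  standard negative-control gating practice.
* `classify_amplicon_reads()` collapses reads to alleles, drops alleles
  below `min_freq` (default 0 — the external analyzer this mirrors exposes
  the same knob without a published default), and classifies within the
  window of R bases either side of the nick (R = 30 or 70, i.e. 60 or
  140 bp of flank): exact window match to the edited amplicon → intended;
  to the unedited amplicon → unedited; a global alignment to the unedited
  amplicon (match 2, mismatch −4, gap open 10, gap extend 1; configurable)
  with an in-window gap → indel; anything else → other. A read carrying the
  intended edit *and* an extra in-window indel counts as indel — the
  conservative tie-break. Percentages are intended/denominator and
  indel/denominator over above-threshold reads.
* `rank_and_correlate()` ranks conditions (average ranks on ties) and
  reports Spearman's ρ and Pearson's r via `stats::cor`.

## Synthetic data and what passing tests show

The fixture generators are first-class, seeded and byte-deterministic:

* `gen_random_target()` draws i.i.d. bases at a requested GC fraction and a
  valid random edit (substitution, or 1–6 bp insertion/deletion) at least
  40 nt from either end.
* `gen_facs_events()` plants three log-normal populations (untransfected,
  transfected-unedited, transfected-edited) with configurable log-means and
  σ (default 0.25, giving clean separation) and records exact planted
  counts plus analytic midpoint gates in a truth object.
* `gen_amplicon_reads()` apportions reads deterministically to
  edited/indel/other/unedited classes (so planted fractions are exact, not
  binomial), plants 1–3 bp indels at the nick, and optionally applies a
  uniform per-base substitution error.

These fixtures exercise the estimators' logic, not real-data pathology:
i.i.d. bases lack repeats, homopolymers and GC structure of real loci;
log-normal channels lack spectral spillover, autofluorescence tails and
doublets; the error model lacks quality-dependent and indel sequencing
errors. Passing recovery tests therefore demonstrates correctness of the
computations, not robustness to messy instruments. Problem sizes used by the
test suite — 500 seeded targets for the round-trip property, 200 sequences
for scanner/oracle equivalence, reads at n = 1000, events at n = 10⁴ — were
chosen as the smallest sizes at which the properties are meaningfully
exercised.

## Known limitations

* No efficiency prediction: candidates are constraint-filtered and ordered
  by a documented tie-break only.
* Exact-match site recognition; no off-target or mismatch-tolerant binding.
* No MMR/PE4/PE5 outcome modelling and no indel by-product simulation; the
  simulators verify intended outcomes.
* FCS binary flow-cytometry files are out of scope (CSV event tables only),
  as are paired-end merging, adapter trimming and quality modelling.
* The `fluopeer fixtures` CLI listed alongside the other subcommands is
  served by the exported `gen_*` functions rather than a shell wrapper.
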