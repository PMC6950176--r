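---
title: "Detecting Pol III dumbbell-shaped miRNA cassettes in retroviral LTRs"
author: "dumbbellscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Pol III dumbbell-shaped miRNA cassettes in retroviral LTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dumbbellscan)
```

## The biological problem

Several retroviruses — foamy viruses in particular, following the precedent
of bovine leukemia virus — encode microRNAs not from spliced Pol II
transcripts but from compact RNA polymerase III transcription units embedded
in the non-coding U3 region of the long terminal repeat (LTR). In foamy
viruses the primary transcript is a "dumbbell": two stem-loops of roughly
25–35 bp each, side by side on a short basal helix, about 111–128 nt from
first to last paired base. Each stem-loop is processed into mature ~22-nt
miRNAs. The transcription unit is delimited by Pol III signals: an upstream
TATA box and/or gene-internal A/B boxes (the type-2 promoter arrangement of
tRNA genes) and a run of ≥ 4 T residues on the sense strand, at which Pol III
terminates.

`dumbbellscan` finds such cassettes in proviral genomes or pre-extracted
LTR/U3 sequences. A candidate must satisfy three independent filters:

1. **Stability** — the window folds at or below −30 kcal/mol;
2. **Topology** — the trimmed structure has exactly two hairpin loops
   (one in single-hairpin mode), each arm carrying at least 8 bp of stem,
   with at least half of the trimmed span paired;
3. **Context** — a Pol III terminator overlapping the 25 nt downstream of
   the trimmed 3′ end, plus a promoter: a TATA box 15–40 nt upstream of the
   trimmed 5′ end, or a functional internal box combination (see below).

## The folding engine

Windows are folded with a self-contained Zuker-style dynamic program over a
simplified nearest-neighbour model at 37 °C: stacking energies for the 36
ordered combinations of the six allowed pairs (AU, UA, GC, CG, GU, UG),
hairpin/bulge/internal-loop penalties by size with logarithmic extrapolation
for large loops, an affine multiloop term (3.4 + 0.4 per branch + 0.0 per
unpaired base), hairpin loops of at least 3 nt, interior/bulge loops capped
at 30 unpaired nt, no dangles, no coaxial stacking, and free exterior bases.
`N` never pairs. Watson–Crick stacks lie in [−3.4, −0.9] kcal/mol, GU stacks
are weaker.

These parameter values are implementation constants, *not* a reproduction of
a published parameter set. What the package guarantees — and what its tests
certify — is internal consistency: the loop-decomposition evaluator
`eval_db_energy()` defines the energy of a structure, the DP minimises it,
and an exhaustive enumeration oracle (`brute_force_fold()`, ≤ 24 nt)
recomputes the minimum independently. Two hundred seeded random sequences
per run are checked for exact agreement. On random 130-mers at 40% GC the
model tracks `RNAfold` within a few kcal/mol, which is sufficient for a
threshold classifier; exact published energies are *not* asserted anywhere.
Where fidelity to the Turner parameter set matters, the `vienna` backend
delegates folding to `RNAfold`, and the test suite checks that the two
backends agree on dumbbell/non-dumbbell classification of fixtures (never on
energies).

The DP is banded to the widest scan window and computed once per region;
because the pair matrices depend only on the inner subsequence, each sliding
window re-uses them and only the exterior recursion is window-specific. This
makes the 100–140 nt sweep over kilobase regions linear in region length in
practice. Co-optimal structures are resolved by a deterministic traceback
(pair-first, smallest partner index, smallest interior offsets); the
enumeration oracle breaks ties by the lexicographically smallest dot-bracket.
The two rules can pick different co-optimal structures, so cross-engine
assertions compare energies, which are unique.

## Topology classification

`classify_dumbbell()` works on the *trimmed* structure — everything outside
the first and last paired base is ignored — so calls are invariant to window
padding, and the reported "span" (trimmed extent) is an outcome of the data
rather than an input. Arms are the two top-level stem-loop subtrees under
the shared multiloop (or exterior loop); an arm's stem size aggregates all
base pairs on the path to its hairpin, because real pre-miRNA stems are
interrupted by bulges and internal loops. The basal helix is the set of
pairs enclosing both arms and is optional by default (`min_basal_helix_bp =
0`): the published precursor model shows a short closing stem but never
quantifies it. The paired-fraction floor (0.5) guards against windows where
two tiny hairpins float in unstructured sequence, which the energy cutoff
alone does not exclude because MFE scales with length.

## Element association

Motif matching is windowed IUPAC comparison with a mismatch budget
(`TATAWAW`/0 for TATA, `TRGCNNARYNNG`/1 for the A box, `GTTCRANNC`/1 for the
B box — the canonical core-promoter and tRNA-gene consensi); `N` in a
sequence matches only the consensus symbol `N`. Terminators are maximal runs
of ≥ 4 T. All tolerances and distance windows are configurable
(`scan_config()`, or the flat key=value config file used by the CLI), since
the exact settings behind the published genome survey are not recorded.

Two association rules deserve explanation:

* **Terminator overlap.** A qualifying T-run must *overlap* the interval
  from the trimmed 3′ end to 25 nt downstream, not necessarily start inside
  it. The MFE trim occasionally absorbs one or two downstream bases into a
  closing pair, and background T's can extend a run leftwards; requiring
  the run to begin strictly after the trimmed end would drop genuine
  cassettes on such boundary effects.
* **Box pairing.** By default (`box_promoter_rule = "pair"`) internal boxes
  count as a promoter only as an A-box + B-box or B-box + B-box
  combination. A gene-internal type-2 Pol III promoter is functionally a
  *pair* of elements, and with a 1-mismatch budget on a 12-nt degenerate
  consensus a lone "A box" arises by chance in roughly a quarter of 130-nt
  windows — a single internal box is therefore nearly vacuous as evidence.
  On the synthetic benchmark the pair rule cuts false cassettes about
  six-fold at identical sensitivity. `box_promoter_rule = "single"` restores
  the permissive behaviour.

A TATA box 15–40 nt upstream always suffices on its own, which matches the
observation that most genomes in the published survey carry cassettes with
no internal boxes at all. Overlapping window calls are reduced to discrete
cassettes by greedy best-MFE selection (ties: leftmost, then narrowest) on
trimmed spans; within a genome, cassettes with byte-identical sequence are
reported once by default, because the 5′ and 3′ LTRs of a provirus are
copies.

## The synthetic benchmark

`make_dataset()` generates the study conditions every statistical claim in
the package is tested under: 50 genomes of 1500 nt i.i.d. background at 40%
GC (LTR-like composition), each carrying up to two planted cassettes (two
Bernoulli slots) and, with probability 0.3, one structural decoy — a strong
single hairpin or a weak 6-bp-arm dumbbell. A planted cassette is a designed
dumbbell of two perfect-complement GC-rich stems (25 bp arms, 8 nt A-only
loops, 4 bp basal helix, 2 nt spacer: a 126-nt span, inside the reported
111–128 nt envelope; the generator verifies the arithmetic), a TATA
realization 25 nt upstream, optional A/B-box realizations written into the
5′ stem strands so pairing is preserved, and a T5 terminator 5 nt
downstream. At generation time every planted dumbbell is folded with the
builtin model and must show exactly two hairpins at ≤ −30 kcal/mol; stems
are redrawn GC-richer on the rare failure. The truth table records designed
coordinates, the folded MFE, and the *effective* box status obtained by
running the scanner's own matcher on the designed sequence (chance hits
included), so box assertions compare like with like.

What the generator does **not** emulate: phylogenetic sequence structure,
mutational erosion of stems, overlapping reading frames, composition skew
along the LTR, or degenerate/partial promoter elements. Passing the
benchmark therefore demonstrates that the pipeline is correct and
well-calibrated on idealised signals over realistic background — not that
its sensitivity transfers unchanged to real proviral sequence, where motif
tolerances may need loosening (every threshold is exposed for exactly that
reason).

Problem sizes were chosen to keep a full verification cycle comfortable on
one core: 200 oracle sequences of 10–24 nt, 50 benchmark genomes of 1.5 kb,
and ≤ 24 nt enumeration inputs; the complete suite folds roughly 10^5
windows.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 output is
  1-based inclusive; BED input is 0-based half-open. One conversion each at
  the boundary, covered by round-trip tests.
* U→T and case normalization happen at read time; `N` is preserved, never
  pairs, and never satisfies a non-`N` consensus symbol.
* The interior-loop cap (30 nt) is part of the energy model, enforced
  identically by the DP and by the structure evaluator, so the oracle
  equivalence is exact rather than approximate.
* Scanning defaults to the provirus sense strand, where these cassettes are
  described; minus-strand and both-strand scans map coordinates back to the
  reference and are covered by mirror-image tests.
* Candidate windows are never clipped at annotated region boundaries
  (annotation restricts where scanning *starts*, not how far a structure may
  extend), since at least one published cassette extends beyond its U3
  region into R.
* The default generator arm length is 25 bp. The 25–35 bp arm range quoted
  for real precursors is compatible with spans well above 128 nt only if
  loops/spacers shrink; 25 bp arms with the default loop and spacer sizes
  are the unique round-number choice that lands the designed span (126 nt)
  inside the reported 111–128 nt envelope, which the generator asserts at
  build time.

## Mature arms and seed identity

Without a Drosha/Dicer processing model, candidate mature arms are
fixed-length (22 nt) slices anchored at the duplex termini of each stem-loop
— hairpin1-5p/3p, hairpin2-5p/3p — which covers the experimentally described
high-abundance species on the 5′ side of each stem-loop. Seed identity is
exact equality of positions 2–8 (7-mer; a 2–7 6-mer option exists), the
grouping that defines miRNA families. Matching against a host catalog is a
plain exact-seed join, certified against a brute-force pairwise count.
Reproducing the published virus-to-host pairing table requires the
experimentally determined mature viral sequences and a miRBase snapshot,
neither of which this package ships; users supply both as FASTA.

## Genome-survey calibration

Scanning the 38 published proviral accessions requires downloading them
(`dumbbellscan fetch --accessions inst/extdata/fv_accessions.txt --out
scratch/fv_genomes.fasta`); the package performs no network access from
library code or tests. The shipped defaults are the calibration starting
point; the corresponding test compares per-genome cassette counts against
`inst/extdata/fv_reference_counts.tsv` when the genomes are present locally.
Because the survey's exact folding program and motif tolerances are
unrecorded, count-level agreement may require adjusting mismatch budgets or
`mfe_max` via the config file — the run manifest serialises every resolved
parameter so such sweeps are reproducible.

## Known limitations

* The builtin energy model is deliberately simplified; absolute MFE values
  are not comparable to Turner-parameter folders. Only threshold
  classifications should be interpreted.
* No pseudoknots, no suboptimal structures, no partition function.
* Single-hairpin mode exists (the bovine-leukemia-virus-style cassette) but
  its thresholds are not calibrated against any reference set.
* Degenerate promoters: the default TATA consensus admits no mismatches;
  highly diverged LTRs may need `tata_max_mismatch = 1` in the config file.

## A worked example

```{r example}
set.seed(1)
bg <- random_background(800, gc_fraction = 0.4, rng_seed = 7)
planted <- plant_cassette(bg, position = 300,
                          plant_spec(with_abox = TRUE, with_bbox = TRUE,
                                     rng_seed = 8))
rec <- seq_record("demo", planted$seq)
gs <- scan_genome(rec)
gs
cs <- gs$cassettes[[1]]
cs
dumbbell_span(cs$dumbbell)
extract_arms(rec$seq, cs$dumbbell, cassette_id = cs$id)[, c("arm_id", "seed")]
```
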