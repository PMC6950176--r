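# dumbbellscan

Detection of RNA polymerase III "dumbbell-shaped" miRNA cassettes in
retroviral long terminal repeats (LTRs).

Foamy viruses (and, in single-hairpin form, bovine leukemia virus) encode
microRNAs from compact Pol III transcription units in the non-coding U3
region of the LTR. The primary transcript is a ~111–128 nt double stem-loop
("dumbbell"): two arms of ~25–35 bp on a short basal helix, flanked by Pol
III signals — an upstream TATA box and/or gene-internal A/B boxes, and a
downstream run of ≥ 4 T at which Pol III terminates. `dumbbellscan` finds
such cassettes in proviral genomes or pre-extracted LTR/U3 sequences, for
virologists and small-RNA bioinformaticians annotating retroviral miRNA
loci.

A window of sequence is reported as a cassette when it passes three
independent filters:

1. **Stability** — minimum free energy `ΔG ≤ −30 kcal/mol`, computed by a
   self-contained Zuker-style dynamic program over a nearest-neighbour
   energy model (or by ViennaRNA's `RNAfold` with `--backend vienna`);
2. **Topology** — the trimmed structure has exactly two hairpin loops, each
   arm with ≥ 8 bp of (bulge-aggregated) stem, ≥ 50 % of the trimmed span
   paired; basal helix optional;
3. **Pol III context** — a T-run (≥ 4 T) overlapping the 25 nt downstream
   of the trimmed 3′ end, and a promoter: TATA (`TATAWAW`) 15–40 nt
   upstream, or an internal A-box + B-box / B-box + B-box combination.

Every threshold is a `scan_config()` field and a CLI flag. The folding
engine is certified against an exhaustive-enumeration oracle under the
identical energy model; mature 5p/3p arm candidates and their 7-mer seeds
(positions 2–8) can be matched against a host miRNA catalog; a synthetic
LTR generator with planted cassettes and ground truth makes the whole
pipeline testable offline.

## A worked example

```r
library(dumbbellscan)
bg      <- random_background(800, gc_fraction = 0.4, rng_seed = 7)
planted <- plant_cassette(bg, position = 300,
                          plant_spec(with_abox = TRUE, with_bbox = TRUE,
                                     rng_seed = 8))
rec <- seq_record("demo", planted$seq)
(gs <- scan_genome(rec))
#> demo    1 cassette(s)   1 with A/B boxes
gs$cassettes[[1]]
#> cassette demo_cassette_295 [275,436) mfe=-109.90 span=136 nt TATA A/B-box
extract_arms(rec$seq, gs$cassettes[[1]]$dumbbell,
             cassette_id = "demo")[, c("arm_id", "seed")]
#>         arm_id    seed
#> 1   demo-h1-5p CUAGCGC
#> 2   demo-h1-3p GCGGGUG
#> 3   demo-h2-5p CGUUCGA
#> 4   demo-h2-3p GGUCGUA
```

The summary line counts discrete cassettes and the subset carrying a
functional internal box combination. The cassette line shows the annotated
interval (0-based half-open, TATA start through terminator end), the window
MFE in kcal/mol, and the trimmed dumbbell span in nt. The four arms are the
22-nt candidate mature miRNAs (5p/3p of each stem-loop) with their seeds.

From a shell:

```sh
dumbbellscan scan --fasta genomes.fasta --out cassettes.gff3 \
    --summary summary.tsv            # GFF3 + TSV + JSON run manifest
dumbbellscan simulate --n 50 --seed 17 --out bench/
dumbbellscan fold GGGGAAAACCCC
dumbbellscan seedmatch --arms arms.fa --catalog mature.fa
dumbbellscan fetch --accessions inst/extdata/fv_accessions.txt \
    --out scratch/fv_genomes.fasta   # network; calibration runs only
```

Exit codes: 0 success (including zero hits), 1 I/O or format error,
2 configuration error.

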