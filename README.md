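# goldenpool

Design toolkit for synthesizing multi-kilobase genes from array-synthesized
oligonucleotide pools by Golden Gate assembly.

Array synthesis delivers thousands of distinct ≤250-nt oligos in one cheap
pool, but a gene has to be *designed* onto that substrate: the coding
sequence must be purged of the assembly enzymes' recognition sites, split
into fragments whose 4-nt junction overhangs reassemble in one pot with
high ligation fidelity, flanked with index primers so one target's
fragments can be PCR-retrieved from the pool, and — after cloning —
verified cheaply by pooled barcoded amplicon sequencing. `goldenpool`
implements that whole design loop in R, plus the in-silico checks
(digest–ligate simulation, read simulation, consensus calling) that let
every design be validated before any DNA is ordered.

It is aimed at synthetic biologists and sequence-design tool builders;
everything runs on a laptop with no external services.

## The model at the core

Junction overhangs are scored against an all-by-all 256×256 ligation count
matrix `C` (counts of ligation events between every pair of 4-mers,
measured experimentally or generated synthetically). After symmetrizing
`C'[a,b] = (C[a,b] + C[rc(b),rc(a)])/2`, the predicted fidelity of a
junction with overhang `o` inside an overhang set `S` is

    f(o | S) = (C'[o, rc(o)] + C'[rc(o), o]) / Σ_{p ∈ P} (C'[o, p] + C'[rc(o), p]),

where `P = S ∪ rc(S)` is the reaction pool, and the set fidelity is the
product `F(S) = Π_{o ∈ S} f(o | S)` — the probability that every junction
ligates its intended partner. `F` is non-increasing as overhangs are
added, which the fragmenter exploits: junctions drawn from a precomputed
high-fidelity set (a *hingeset*, built by a genetic algorithm, always
containing the standard part termini `AATG`/`GCTT`) can only do as well or
better than the constraining set itself.

Sequence design is protein-preserving throughout: restriction-site
removal, k-mer uniquification (no repeat ≥ 12 nt), hairpin avoidance
(stems ≥ 20 nt within 250 bp), minimum windowed GC content (60-bp windows,
GC objective weighted 4× over codon usage), and iterative purging of
predicted splice donor/acceptor motifs all operate by synonymous codon
swaps only.

## Worked example

Design a 918-nt coding sequence (923 nt once the standard `AATG…GCTT`
part termini are added) into pool oligos, then prove the design
reassembles:

```r
library(goldenpool)

m     <- synthetic_ligation_matrix(correct_count = 1000, mismatch_rate = 0.02, seed = 101)
hinge <- bundled_hingesets()[[2]]          # precomputed size-20 set
hinge
#> hingeset: 20 overhangs, predicted fidelity 1.0000 (seed 120)
#>    AACT AATG ACAA ACTC AGAC ATAG ATCC ATTA CCGT CTGA GCAC GCCG GCTT GGCA GGTG TACG TCCT TGGG TTCA TTTG

cds  <- random_cds(918, gc = 0.5, seed = 42)
part <- prepare_cds_part(domesticate(cds, design_constraints(), flat_codon_table(), seed = 1))
plan <- fragment_sequence(part, hinge, m)
plan
#> fragment_plan target: 5 fragments (183-192 nt), predicted fidelity 1.0000
#>   overhangs: AATG GTGC CCGT CACC GGAT GCTT

idx    <- generate_primer_candidates(2, seed = 7)
oligos <- layout_oligos(plan, enzyme = "BbsI", index_pair = idx$sequence)
oligos[, c("fragment_index", "length", "left_ov", "right_ov")]
#>   fragment_index length left_ov right_ov
#> 1              1    240    AATG     GTGC
#> 2              2    244    GTGC     CCGT
#> 3              3    235    CCGT     CACC
#> 4              4    239    CACC     GGAT
#> 5              5    241    GGAT     GCTT

res <- digest_ligate(oligos$full_sequence, "BbsI")
res$products[1] == part
#> [1] TRUE
```

The 923-nt target needs 5 oligos; each carries the fragment payload plus
exactly 52 nt of overhead (two 18-nt index primers and two BbsI
recognition+spacer flanks), staying under the 250-nt synthesis budget.
The digest–ligate simulator confirms a unique full-length product whose
sequence equals the designed part. Targets beyond ~2 kb route through
`plan_two_step()` (oligos → ~1,050-bp BsmBI-flanked blocks → final part);
`run_pipeline()` drives everything from a FASTA plus a YAML config, and
`simulate_reads()` / `demultiplex()` / `consensus_and_classify()` /
`summarize_run()` cover the downstream clone-verification stage.

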