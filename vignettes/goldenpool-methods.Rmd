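---
title: "Designing oligo-pool gene synthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing oligo-pool gene synthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldenpool)
```

This vignette is the package's own account of the models, parameters and
design choices behind each stage of the pipeline. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Ligation fidelity of overhang sets

Golden Gate assembly orders fragments by the complementarity of 4-nt
5' overhangs. Overhangs also ligate mismatched partners at measurable
rates, so a design's junctions must be chosen as a *set*: what matters is
not an overhang's intrinsic quality but how little it cross-talks with
everything else in the same reaction.

The substrate is a 256×256 count matrix `C` over all 4-mers, `C[a, b]`
being observed ligation events between `a` and `b` (both read 5'→3' on
their own strands). Because one physical junction appears in the raw data
in two orientations, the matrix is first symmetrized,
`C'[a,b] = (C[a,b] + C[rc(b), rc(a)])/2`; the operation is idempotent and
scoring is refused on unsymmetrized matrices rather than silently
accepting orientation artifacts. Per-junction fidelity is the two-strand
on-target fraction restricted to the reaction pool `P = S ∪ rc(S)`:

$$ f(o \mid S) \;=\; \frac{C'[o,\mathrm{rc}(o)] + C'[\mathrm{rc}(o),o]}
{\sum_{p \in P} \big(C'[o,p] + C'[\mathrm{rc}(o),p]\big)} $$

and set fidelity is the product over members. The data source prints no
closed-form equation for this statistic, so the formula is this package's
committed convention (it matches the companion methodology of the
published count data): it is recorded in output metadata, and two
properties motivate it — it equals 1 exactly when no in-pool mismatch
mass exists, and it is monotone non-increasing as members are added,
which both the optimizer and the fragmenter rely on. Palindromic 4-mers
are excluded outright (they ligate copies of their own junction), as are
reverse-complement pairs within a set. Fidelity is invariant under
replacing any member by its reverse complement, so a set is really a set
of rc-pairs.

## Hingeset optimization

High-fidelity sets of a requested size are built once and reused
("hingesets"). The search is a small genetic algorithm over member sets:
tournament selection (k = 3), uniform set-crossover (child drawn from the
parents' union, fixed members forced, topped up randomly), mutation
replacing one non-fixed member with a random admissible 4-mer, elitism 2,
population 50, at most 500 generations with a 50-generation stagnation
stop. Every set contains `AATG` and `GCTT`, the standard coding-sequence
part termini used for cloning. The run is reproducible from its seed, and
at sizes 2–6 over a 16-overhang toy alphabet the suite checks the GA
against exhaustive enumeration. A library of sets (sizes 10–60) optimized
against the package's synthetic matrix ships in `inst/extdata`; it is
labelled synthetic and should be regenerated against a measured matrix
for production work.

## Fragmentation

A target enters fragmentation with its terminal overhangs as its first
and last 4 nt (`prepare_cds_part()` yields `A + cds + GCTT`, completing
the `AATG` start-codon overhang). The fragment count is the smallest `n`
with `(L + 4(n−1))/n ≤ max_payload`; the default payload budget of 198 nt
is the 250-nt synthesis budget minus 52 nt of overhead (two 18-nt index
primers and two 6-nt BbsI sites with 2-nt spacers). Ideal junctions are
equidistant (`round(i·L/n)`); candidates are positions within `radius`
(default 30 bp) whose 4-mer belongs to the constraining hingeset in
either orientation and collides with nothing already taken.

Junction assignment is exact branch-and-bound. Two admissible prunes keep
it fast: a partial set's fidelity bounds any completion (monotonicity),
and on fidelity ties a lower bound on the remaining offset sum bounds the
tie-break key. Ties are broken by total distance from the ideal
positions, then by the deterministic candidate order (|offset|, then
position); an additional lexicographic key was considered and dropped
because it defeats the offset prune — determinism is preserved without
it. If no assignment exists at the minimal `n`, `n` is incremented a few
times before the search reports the failing window and suggests a larger
radius or hingeset. Because plan overhangs are a subset of the hingeset
plus its fixed termini, monotonicity guarantees every plan's predicted
fidelity is at least the constraining set's — the suite asserts this on
every plan it builds.

## Sequence design

All design operations are protein-preserving by construction: the only
move is a synonymous codon swap. The engine is a per-codon local search
over a lexicographic energy — (hard-violation count, windowed GC deficit)
— with candidate swaps enumerated in the codons overlapping the first
violation, ties broken toward higher codon-usage frequency, and seeded
random kicks to escape local minima; it errors naming the stuck window
rather than returning a violating sequence.

Hard constraints and defaults:

* forbidden motifs on both strands — BsaI `GGTCTC`, BsmBI `CGTCTC`, BbsI
  `GAAGAC` (the assembly hierarchy's sites);
* no duplicated k-mer of length 12 (repeats at and above this length
  promote mispriming and misassembly);
* no inverted repeat with stem ≥ 20 nt whose arms lie within a 250-bp
  window — a deliberately thermodynamics-free hairpin definition matching
  the constraint's plain semantics;
* optionally, GC ≥ `gc_min` in every 60-bp sliding window.

GC enforcement first re-optimizes codon usage (`match_usage` uses
largest-remainder quotas per amino acid, so the output's synonym
distribution tracks the table as closely as integer counts allow), then
greedily raises deficient windows, scoring each swap as
`gc_boost × (GC bases gained) + log2(f_new/f_old)` with `gc_boost = 4` so
the GC term dominates codon usage, and finally re-repairs any
hard-constraint violations the GC pass introduced. Feasibility is checked
up front: if some window cannot reach `gc_min` even with all GC-maximal
synonyms, the operation errors naming it. Windows may fall short of the
floor by at most a documented tolerance of 0.02, which keeps the
interleaved hard-constraint repair feasible. One upstream tool treats
windowed GC as a boosted soft objective; this package deliberately makes
it a hard constraint with that small tolerance, because downstream stages
(fragmentation, synthesis QC) assume the floor holds.

## Splice-site purging

Cryptic splice junctions can truncate a transgene's mRNA in plant nuclei.
The predictor interface is pluggable — any
`function(seq) -> data.frame(position, kind, score)` can stand in, so an
external neural model can be dropped in — and the default is a log-odds
position-weight model of the canonical donor (`MAG|GTAAGT`) and acceptor
(polypyrimidine tract + `YAG|`) motifs, with the call threshold at 0.7 of
each motif's maximum score. The threshold is a repo choice (the external
model this emulates publishes no comparable cutoff); PWM predictions are
not expected to match any neural predictor's counts numerically, and the
tests only assert internal consistency (exhaustive-rescan equality,
planted-consensus detection). `deintronize()` runs up to four rounds of
scan → synonymous purge → re-domestication, retries under extra seeds
while residuals remain, and returns the best run (fewest residual sites,
then fewest edits); residual predictions are reported, never fatal.

## Oligo layout and the digest–ligate simulator

Each fragment becomes
`fwd_index(18) + site + spacer + payload + rc(spacer + site) + rc(rev_index)(18)`.
With BbsI (2-nt spacer) the overhead is exactly 52 nt; the published
description of "~50 bp of index and cut sequences" is realized as 52 and
the spacer is configurable. Default spacer bases (`TT`, with fallbacks)
are rejected automatically if they form a recognition site with adjacent
bases — the layout is accepted only if an in-silico digest returns
exactly the designed payload with its designed overhangs.

The simulator cuts every recognition site on both strands at the
enzyme's offset, discards pieces still carrying a site (they are re-cut
in the real one-pot reaction), and chains sticky ends wherever one
fragment's right overhang equals the next one's left overhang (top-strand
representation makes complementarity an equality test). It reports
ambiguous overhangs (reused by several fragment ends), palindromic
overhangs, dead ends, and circular products; a clean design yields
exactly one linear product equal to the prepared part. Cloning into a
receiving vector is modeled by adding a linear vector molecule whose
ends expose `GCTT…AATG`, closing the circle.

## Two-step hierarchy

Targets above the routing threshold (default 2,000 bp) are planned in two
steps: the prepared part is split into `round(L / 1050)` blocks (nearest
integer; a ~9.5-kb part gives nine ~1,050-bp blocks) at hingeset
junctions using the same exact search at block scale, each block is
flanked with BsmBI sites that re-expose its junction overhangs, and each
flanked block gets its own BbsI oligo-level plan. The same hingeset
constrains both levels by default; the two levels are separate reactions,
so their overhang namespaces are independent, and the suite checks that
no 4-mer collides within a level. Flank pads (`AA`/`AG`) were chosen so
each flanked block's termini are themselves admissible overhangs. One
contract subtlety: blocks tile exactly `A + cds + GCTT` with terminal
`AATG`/`GCTT` overhangs, and the BsaI adapters that make the final part
reusable downstream are carried as plan metadata (`bsai_flanks`) rather
than inside the tiled sequence — placing them inside would contradict the
terminal-overhang invariant that step-two assembly relies on.
`simulate_two_step()` replays both assembly steps and asserts the final
product equals the prepared part.

## Primers and barcodes

Index primers are rejection-sampled 18-mers: exactly 9 G/C bases,
homopolymers ≤ 4, no assembly-enzyme site on either strand, and
nearest-neighbor Tm within 60 ± 1.5 °C. The Tm model uses the unified
duplex parameters with terminal initiation terms and the entropic
monovalent-salt correction `0.368 (N−1) ln[Na+]`; default conditions
(500 nM per strand, 200 mM monovalent-equivalent salt) approximate a PCR
mix and center exactly-50%-GC 18-mers near the 60 °C setpoint, which is
what makes the GC and Tm constraints jointly satisfiable. The
implementation is checked against values frozen from an independent
published NN implementation under identical conditions (0.5 °C band).

Cross-hybridization between primers is scored in-package (the external
scorer used historically publishes energies this package does not try to
match): longest complementary run between the pair, plus the
complementary run anchored at each 3' terminus — so 3'-terminal
complementarity, where polymerase extension starts, is effectively
counted twice. The hard dimer threshold (default 24 on this scale) was
calibrated so perfect rc-pairs (score 54 for 18-mers) and long 3'
anchors fail it while ≥95% of random pairs pass; `select_index_set()`
greedily removes the worst aggregate offender until the requested count
remains. Barcodes for amplicon multiplexing use greedy max–min selection
on Levenshtein distance (seeded with the globally farthest pair), with a
hard floor of 8 edits at size 96 — large enough that demultiplexing at
≤3 edits per terminal window can never cross-assign.

## Amplicon validation

The validation stage is a desk-scale reimplementation of a long-read
consensus workflow; verdict-level correctness on simulations with known
ground truth is the contract, not numerical parity with production
tools. Reads are `fwd_barcode + template + rc(rev_barcode)` with
independent per-base substitution/insertion/deletion errors (defaults
2%/0.5%/0.5%, nanopore-like) on a random strand. Demultiplexing requires
both terminal windows to match one barcode pair within 3 edits (either
orientation) and refuses barcode sets whose minimum distance does not
exceed twice that budget. A length filter (±20% of the expected amplicon)
stands in for a quality filter; consensus is reference-anchored
per-position plurality (deletions by plurality, insertions when a
majority of reads agree on the inserted string), which is appropriate
because every amplicon has a known expected sequence — de novo assembly
is deliberately out of scope. Clones classify as `unassigned` (< 5 usable
reads), `misassembled` (reference coverage < 0.98, or a junction's
flanking 20-mer absent/out of order under fuzzy matching with ≤4 edits —
fuzziness tolerates residual point errors without masking a dropped
fragment), `error_free` (consensus equals reference) or
`correct_with_errors` (variant list attached).

## Synthetic data: what it does and does not show

The generators make every test self-contained: stop-free CDSs of chosen
length and GC (site-free by construction, GC within ±2%), ligation
matrices with Watson–Crick mass `correct_count` and off-target mass
`mismatch_rate × correct_count` per row concentrated on partners at
Hamming distance 1 from the true partner (the qualitative structure of
measured ligation error), and the barcoded noisy reads above. Defaults —
1,000 counts per WC cell, 2% mismatch rate, 50% GC test sequences, 2%
read error at depth 20 — are the package's fixed study conditions.

Passing tests on these fixtures demonstrates algorithmic correctness:
round trips, oracle equalities, monotonicities, confusion-matrix
recovery. They do not demonstrate that predicted fidelities match any
measured matrix (synthetic mismatch structure is idealized; real
matrices have condition-dependent, longer-range mismatch mass), that the
PWM finds the sites a neural predictor would find, or that real nanopore
error (homopolymer-biased, quality-correlated) behaves like the i.i.d.
model. Those claims require the measured inputs the package can load but
does not ship.

## Numerical choices and degenerate inputs

Seeds are mandatory on every stochastic operation and child seeds are
derived per stream, so pipeline reruns are byte-identical. Fidelity
comparisons use an absolute 1e-12 tolerance; the GC window tolerance is
0.02; empty overhang sets score fidelity 1 by convention; an overhang row
with zero ligation signal is an error, not a zero. Degenerate inputs are
contracts, not crashes: empty read sets yield an `unassigned` verdict,
an empty plan list yields an empty pool table, a target shorter than one
payload yields a single-fragment plan with only the terminal overhangs.

Problem sizes in the shipped suite (toy alphabets of 16 overhangs,
hundreds-of-nt to 10-kb targets, 24-clone plates at depth 20, 5,000
barcode candidates) were chosen so the full suite runs in minutes on one
core while still crossing every scale threshold the algorithms care
about (multi-fragment plans, two-step routing, 18-fragment assemblies,
96-barcode selection).

## Known limitations

Ligation-condition dependence (time, temperature, enzyme) is not
modeled — one matrix is active per run and its provenance is recorded as
a label. The GA optimizes fidelity alone (no overhang-GC balancing). The
fragmenter does not orthogonalize overhangs across different targets
pooled into one reaction beyond hingeset membership. The splice default
is a motif model, not a trained predictor. The amplicon simulator's
error model is i.i.d. per base. Three-level assembly hierarchies are out
of scope.
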