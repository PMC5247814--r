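---
title: "Direct-repeat response element discovery in gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct-repeat response element discovery in gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarescan)
```

## The problem

Retinoic acid (RA) signalling is kept in balance by feedback loops: RA
activates its own degrading enzymes (the CYP26 cytochromes), whose genes in
several chordates sit in a tandem genomic cluster. The molecular basis of
that feedback is direct binding of RAR/RXR heterodimers to retinoic acid
response elements (RAREs) — direct repeats (DRs) of the hexameric half-site
(A/G)G(G/T)TCA — in the neighbourhood of the target genes. Deciding whether
a cluster is under such direct control requires three computational steps:
finding every candidate DR element in a survey region, asking which
candidates are conserved across related species in both sequence and
relative cluster position, and summarising the validated elements as a
degenerate signature. `rarescan` implements this workflow as composable,
deterministic stages, plus a synthetic benchmark generator that makes every
stage testable against a known ground truth.

## The motif grammar and matching semantics

A DR pattern is two hexameric half-sites around a spacer. Half-sites and
fixed spacers are IUPAC strings expanded into per-position
allowed-nucleotide sets; a variable spacer `N{a,b}` matches any `a`–`b`
bases. The default scan pattern is the canonical grammar
`RGKTCA (N)0–9 RGKTCA`; the degenerate signature of in-vitro validated
amphioxus DR5 elements (`RGKTSA NNNRV RGKWCA`) ships as a named built-in
but is deliberately **not** the default scan input, because it was derived
*from* validated hits rather than used to find them.

Matching is exact set membership — no position-weight-matrix scores and no
mismatch budget. That choice reproduces the enumerative "all possible
combinations of the consensus" semantics: the candidate set is a well
defined, threshold-free function of the pattern. Three deliberate
conventions:

* **Exhaustive overlap policy.** All matches are reported, including
  nested ones and pairs sharing a half-site at different spacings.
  Downstream stages filter; the scanner never does.
* **Genomic `N` policy.** An `N` in the assembly satisfies only a fully
  degenerate position (the wildcard spacer), never a constrained one —
  conservative against phantom elements in gappy assemblies.
* **Case policy.** Matching is case-insensitive by default
  (`masked_policy = "match"`); `"skip"` makes soft-masked lowercase
  residues fail every position, for users who want repeat-masked scans.

Minus-strand elements are found by matching the reverse-complemented
pattern on the plus strand; coordinates are always 0-based half-open on
the plus strand, with the element fields read 5′→3′ on the matching
strand. Scans restricted to a window use the interval from `up` bp
upstream of the first gene's start codon to `down` bp downstream of the
last gene's stop codon (defaults 20 kb / 20 kb, the published survey
region).

## Cluster-relative annotation

Distances in the source literature are quoted "upstream of gene X, d bp
from the start codon", so annotation is anchored on codons rather than
transcript models. Each hit gets:

* a **compartment** — intragenic if it overlaps any base of a gene body
  (codon-to-codon span when only codons are given; UTR-extended spans can
  be supplied instead), otherwise the flanking/intergenic interval holding
  its midpoint;
* the **nearest downstream gene** along the cluster axis and the distance
  to its start codon, counted as the bases strictly between the element's
  proximal edge and the first ATG base (an element abutting the ATG is at
  0 bp). The literature never defines its edge convention; ours is fixed,
  documented in output headers, and reproduces the published worked
  distance (a hit at [900, 917) with the ATG at 5000 is 4083 bp away);
* the **orientation** relative to the cluster axis (`+` if the hit strand
  equals the axis strand);
* a **normalized intra-compartment position** in [0, 1] along the axis,
  the quantity the conservation stage compares across species.

All of this is reflection-symmetric: reverse-complementing every input and
flipping gene strands yields mirrored annotations, which the test suite
asserts end to end.

## The conservation filter

"Conserved" is operationalised as: same DR class; same element sequence at
a configurable stringency (`exact-element` by default — the one element
printed for all three amphioxus species is letter-identical —
`half-sites-and-spacer-length` and `class-only` for sensitivity analyses);
same compartment by ortholog rank; same orientation; and normalized
positions within a tolerance, default 0.25 of the compartment length. The
original report states the position criterion only qualitatively; the
tolerance is therefore a parameter, and the default is recorded in output
metadata. Orientation agreement is likewise configurable because the
published criterion text does not mention it even though orientations are
reported.

Groups are assembled greedily: species in alphabetical order (making the
result invariant to input order), seeds sorted along the cluster axis, and
for each remaining species the unused candidate with the smallest
normalized-position discrepancy. A group is emitted only if *every*
pairwise check passes, not just a spanning chain, and each hit joins at
most one group. At realistic densities (tens of candidates per species) an
optimal assignment would change nothing; the greedy order is deterministic
and documented.

## Consensus and information content

The validated elements are fixed-structure (6 + spacer + 6) and therefore
already aligned within a DR class, so an EM-based motif discovery step
would add nothing: the package counts nucleotides per column, includes a
letter in position `j`'s set iff its frequency exceeds θ, and serialises
the sets to IUPAC. θ = 0 (the default) gives union semantics — the printed
degenerate consensus of a validated set includes every observed variant —
and guarantees closure (every training site matches its own consensus) and
monotonicity (raising θ never widens a set). Sites of different spacer
lengths are never mixed into one count matrix; the pipeline builds one
model per DR class. Information content per column is
`2 + Σ p log2 p` bits with optional pseudocount smoothing
(default 0: with a dozen sites, honest small-sample values matter more
than smoothed logos).

## The synthetic benchmark

`generate_cluster_set()` emulates the comparative setting: three species
whose clusters span 85, 56, and 79 kb (the published spans from the first
gene's start codon to the third gene's stop codon), three tandem
plus-strand genes, and an i.i.d. background at GC 0.41 (amphioxus-like).
Gene bodies occupy 10 % of the span each and the two intergenic gaps
35 % each — a deliberately simple layout chosen so that the flagship
element, planted at its published absolute distances upstream of the
second gene (6405 / 6740 / 4083 bp), lands at normalized positions whose
spread (~0.20) sits inside the default tolerance, i.e. the real element
passes the position criterion under the default geometry. The other 15
conserved elements share normalized compartment positions exactly; 5
decoys per species are placed uniformly (rejection-sampled against
overlaps). All planted sequences are drawn from the canonical grammar,
kept pairwise unique, and rejection-sampled so that each contains exactly
one canonical match when scanned in isolation — this keeps the truth table
a sound oracle for any seed.

With `clean_background = TRUE`, accidental background matches (about two
are expected per ~130 kb sequence at this GC; the analytic expectation is
attached to the output) are destroyed by resampling their non-planted
bases until none remain. The generator is byte-deterministic per seed, and
every random draw flows from the single spec seed.

What the benchmark does **not** emulate: real substitution processes
(elements in real genomes diverge; here conserved elements are
letter-identical, matching the exact-element default), indels and
rearrangements (compartment ranks are fixed), k-mer background structure
(the background is i.i.d.), and assembly artefacts. Passing the benchmark
therefore demonstrates the correctness of the machinery — enumeration,
bookkeeping, criteria logic — not the biological sensitivity of the
criteria on diverged genomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and in BED output; the
  human-readable headers state the convention.
* Spacer bounds parse up to 9 by default (the canonical grammar) and are
  hard-capped at 15 to bound scan cost.
* Identical `(start, end, strand, pattern)` duplicates are removed; a
  match and its reverse-complement at the same locus remain distinct hits
  only when the strands differ.
* Ragged consensus input, empty pattern lists, out-of-bounds windows,
  non-nucleotide residues, and single-species conservation runs all fail
  fast with instructive errors rather than producing silent partial
  output.
* A θ high enough to empty a position set is an error, not an empty
  consensus.

## Problem sizes used in the tests

The shipped test suite runs the scanner–oracle comparison on 200 random
5 kb sequences at GC 0.3–0.5, strand symmetry on 100 sequences, consensus
properties on 1000 random site sets, and the full pipeline on both the
default benchmark (85/56/79 kb spans) and a reduced 30/24/27 kb version
used for the faster integration tests; these sizes give well-populated hit
sets while keeping a full run to a couple of minutes on one core.

## Known limitations

* No approximate matching: a single substitution in a half-site hides an
  element, by design; sensitivity analyses belong at the criteria level
  (`half-sites-and-spacer-length`, `class-only`), not in the scanner.
* Conservation requires user-supplied ortholog ranks (the `cluster_rank`
  column); the package does not infer synteny.
* The consensus stage presumes pre-aligned fixed-structure sites; it is
  not a general motif-discovery tool.
* The candidate counts of a real survey depend on how overlapping
  candidates were collapsed, which the source does not specify; `rarescan`
  reports the exhaustive both-strand set and flags that interpretation in
  its output metadata.
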