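---
title: "Methods: structure-based Cassandra detection, promoter mimicry, and rDNA linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based Cassandra detection, promoter mimicry, and rDNA linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system being modelled

Cassandra elements are nonautonomous LTR retrotransposons in miniature
(TRIMs): two near-identical long terminal repeats of roughly 30–500 bp
flank a short internal region with no coding capacity, bounded by a primer
binding site (PBS) and a polypurine tract (PPT). What sets Cassandra apart
from other TRIMs is a region inside each LTR derived from the host's 5S
rRNA gene — about 70 bp covering the RNA-polymerase-III internal control
region with its three promoter boxes (A-Box, intermediate element IE,
C-Box) plus short genic flanks. Because the element borrows the 5S
promoter for its own transcription, mutations that become fixed in the
genic 5S C-Box (as in the Anthemideae, where the canonical `AGGATGGGTG`
reads `GGCTTGGGTG`) are tracked by the resident Cassandra population,
which carries its own shifted mirror motif (`GGCCTGGGTG`) — promoter
mimicry. A related question is whether the 5S gene sits inside the 35S
rDNA monomer (linked arrangement, L) or in its own tandem array
(separated, S), which low-coverage read assemblies expose as one versus
two graph components.

This package implements that entire analytic chain over synthetic genomes
with planted ground truth, so every stage is measurable without any
external download.

## Detection

`find_ltr_pairs()` is a seed-and-extend direct-repeat search. Exact words
of `seed_word` = 12 bp found at two positions whose distance is compatible
with the TRIM geometry (LTR 30–500 bp, internal region 30–2000 bp) are
chained along their diagonal into repeat segments; segment ends are
refined by ungapped x-drop extension (match +1, mismatch −2, drop 10,
backtracking to the best-scoring point); the two refined copies are then
scored by global alignment and kept when all length bounds hold and the
identity is at least `min_ltr_identity` = 70 % (inclusive). PBS, PPT, TSD
and TG…CA are evidence columns, not filters, matching a relaxed screen;
`require_tsd`/`require_tg_ca` turn them into filters.

**Overlap resolution.** Candidates are accepted greedily by LTR-pair
*alignment score* (ties by identity, then leftmost), and a candidate
overlapping an accepted element span by ≥ 20 bp is dropped. An
identity-first rule with a longer-element tie-break was tried and rejected:
when several elements in one genome share the identical ~70 bp 5S core —
the defining Cassandra situation — the spurious cross-element core
pairings tie the true full-LTR pairs at 100 % identity and, being longer,
would win, collapsing precision and recall. Score ordering expresses that
a 270 bp perfect repeat is far stronger evidence than a 70 bp one.

**Boundary accuracy.** At zero divergence the reported intervals equal the
planted ones except when the flanking sequences happen to match at a
boundary (probability 1/4 per column), which legitimately extends the
repeat — an ambiguity shared by every de novo LTR boundary caller. The
evaluation therefore uses ≥ 50 % reciprocal overlap for matching
detections to truth; one unit test demonstrates exact recovery on a
fixture whose flanks are constructed to mismatch at all four boundaries.

**PPT scan direction.** The PPT window search walks 5'-ward from the 3'
LTR start (the tract abuts the LTR it primes) and reports the first
window with ≥ `ppt_min_purines` = 8 purines of `ppt_window` = 10 nt,
within 20 nt.

## Promoter annotation and classification

The 120 bp 5S gene layout places a 15 nt A-Box at [49, 64), the 6 nt IE at
[68, 74) and the 10 nt C-Box at [79, 89) (0-based, half-open). The IE
offset was chosen so that the inter-box gaps are exactly 4 and 5 nt — the
lengths of the polymorphic MotIE and MotC spacers, which this package
anchors immediately upstream of the IE and C-Box respectively. A- and
IE-box strings are configurable layout parameters with documented
defaults; only the three C-Box strings are treated as fixed references.

`classify_cbox()` assigns a 10-mer to the nearest reference by Hamming
distance with a cutoff of 2 mismatches: the references are mutually 1–3
apart, so 2 keeps the classes separable while tolerating one private
substitution; exact ties are `ambiguous`, anything farther is `other`.
`scan_boxes()` searches in promoter order (A-Box, then IE downstream of
it, then C-Box downstream of the IE) to avoid spurious C-Box hits upstream
of the internal control region. Note the IE is only 6 nt: at 2 allowed
mismatches it can chance-match in random sequence, which is why an IE hit
without an A-Box is weak evidence (the tests assert exhaustive-scan
consistency rather than absence).

`locate_similarity_region()` is a local alignment of the LTR against the
genic 5S sequence (match +1, mismatch −2, gap open −2, extend −2),
accepted at score ≥ 40 and aligned length ≥ 40 bp — permissive enough for
species-specific core extents, strict enough that a Cassandra-like TRIM
LTR never passes. `classify_element()` labels a candidate *cassandra* when
either LTR yields a region (the 5' one is primary), else
*cassandra_like_trim* when `TATAAA` starts within 48 ± 5 nt of the 5' LTR
terminus, else *other_trim*.

## Identity and clustering

Percent identity is defined as matched columns over columns where at least
one sequence has a residue, terminal-overhang columns excluded and
internal gap columns counted; `N` never matches. The source analyses used
an unnamed alignment viewer's definition, so identity values reproduced on
real data may differ by a few points; the definition here is explicit and
the scoring configurable (defaults mirror the original search scoring:
match +1, mismatch −2, gap 2/2).

Families are single-linkage connected components at the inclusive 70 %
threshold. Single linkage is deliberate: indel-bearing variants depress
mean pairwise identity but remain chained to the family through their
non-indel regions. Variants are found by aligning each member to the
family's longest member and collecting internal gap events ≥ 10 bp. Events
are matched with tolerances (positions within 20 bp, lengths within 10 bp)
rather than by exact 10 bp binning: alignment ambiguity shifts the
placement of one and the same planted deletion by a few bases between
copies, and exact bins split such copies across bin boundaries. Family
statistics report medians (mean-of-middle for even counts) and *mean*
pairwise identities over all member pairs; whether the original tables
used all-pairs or a multiple alignment is unknown, so this choice is
flagged as configurable.

## Dotplots

`window_matches()` marks every window-start pair `(i, j)` whose k-mers
differ at ≤ n positions (defaults k = 12, n = 3), computed per diagonal
with running mismatch sums and verified against a brute-force oracle.
Shading is the longest common substring divided by the shorter sequence
length — the original figure legend names the statistic but not the
normalisation, so it is documented here and configurable. Reverse-strand
matching is off by default (LTR sets are compared in fixed orientation).

## rDNA linkage

Reads are decomposed into k-mers (k = 31, `min_count` = 2 to suppress
singleton noise; safe for error-free synthetic reads, exposed for real
data); nodes overlap-chain into unitigs; unitigs are colored by exact
k-mer hits to the 18S/5.8S/26S marker blocks and the 5S gene; the
neighborhood within 25 unitig-graph hops of any colored node is extracted
("distance 5 to 25" in the original viewer is interpreted as hop count and
parameterised); and the arrangement is called L when one weak component
carries both a 35S color and the 5S color, S when the colored components
are disjoint by type, ambiguous when a color is missing or the signal
splits across more than two components. Cyclicity (a directed cycle in
the component; a perfect tandem monomer compresses to a single self-loop
unitig whose k-mer count equals the monomer length) is reported but not
required for an L call — arrangement can be concluded from imperfect
assemblies. This in-house unitig graph replaces a two-round assembler
pipeline whose only role here is to expose monomer topology.

## The synthetic world

Generator defaults state the modelled system: a 120 bp 5S gene with a
100–500 bp (default 300 bp) spacer; LTR 270 bp and internal region 82 bp
(the observed Asteraceae medians); a 70 bp core centered mid-LTR
(`core_offset_fraction` = 0.5, inside the observed 25–75 % positional
band); PBS `TGGTATCAGAGC` (a methionine-tRNA complement standard for
plant LTR elements; only "methionine PBS" is stated by the source);
PPT = a 10 nt purine run (the source names the PPT but no rule); TSD 4–6
bp; indel lengths uniform 1–30 bp (the variant-defining range); 35S
subunits as seeded-random marker blocks of 1.8 kb / 160 bp / 3.4 kb —
real rRNA sequence is unnecessary for coloring and would require
downloads. `make_cassandra_family()` models amplification: copies of one
master element with independent per-site substitutions and an optional
shared LTR deletion (the variant mechanism). A `protect_cbox` switch
keeps divergence out of the planted C-Boxes, implementing deterministically
the "substitutions outside C-Boxes" condition used by the mimicry
recovery analysis.

What a green suite does **not** establish: real genomes have nested and
truncated elements, sequencing errors, N runs and heterogeneous copy ages;
the detector is single-strand (callers run both strands); recall figures
apply to substitution divergence — large indels between two LTR copies
break seed diagonals and shorten the refined repeat; and the 100 % linkage
accuracy holds for error-free reads at ≥ 10×.

## Oracles and test scoping

Alignment, dotplot and LCS operations are checked against independent
brute-force implementations. The detector's oracle has two honest layers:
a literally exhaustive enumeration over every (start, LTR length, gap)
triple at reduced bounds on ≤ 400 bp inputs, and a per-diagonal
sliding-window scan at full TRIM bounds on 2–3 kb inputs (any admissible
≥ 70 %-identity pair implies a ≥ 70 % 30-mer window on an admissible
diagonal). Equivalence is asserted as: every detection implies oracle
signal; oracle silence implies no detection; and planted repeats are found
by both. A marginal pair at exactly the threshold with no exact 12-mer run
is detectable by the oracle but invisible in principle to any
seed-and-extend search — a scoping shared with the genome-scale tools this
detector replaces. Some test and acceptance runs use reduced rDNA marker
blocks (600/100/1200 bp) purely for runtime; coverage, copy numbers and
every threshold are unchanged.

## Known limitations

Identity values on real data depend on the (unknown) original alignment
definition by a few points; no nested-element resolution, ORF screening or
RNA secondary-structure analysis; the k-mer graph performs no error
correction and is not a general assembler; dotplot rendering is left to
downstream code — all results are plain coordinate tables.
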