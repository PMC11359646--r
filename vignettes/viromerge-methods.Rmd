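---
title: "Methods: curation, classification and segment association in viromerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, classification and segment association in viromerge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromerge)
```

# The problem

RNA virome discovery from a fermentation metatranscriptome starts where the
assembler stops. The assembled contigs are redundant (the same virus
assembled several times), fragmented (one genome split into pieces that
share short terminal overlaps), occasionally chimeric (two molecules fused
by mis-assembly), and of unknown taxonomic standing. `viromerge`
implements the post-assembly stages for the three-time-point (7 h, 20 h,
68 h) cocoa-fermentation study design: contig curation, known/novel
classification against a reference virome, ORF discovery under alternate
genetic codes, association of multi-segmented narnavirus segments, and
abundance/diversity dynamics. Every stage is exercised end to end on
seeded synthetic data carrying planted ground truth, so the package needs
no downloads to validate itself.

# Curation

`curate()` applies, in order:

1. **Length filter** (`min_len = 500` nt, inclusive). The sources disagree
   between "minimum size threshold of 500" and "longer than 500 nt"; we
   default to the inclusive reading, with `strict_gt = TRUE` available.
2. **Redundancy clustering** (`cluster_redundant()`), a CD-HIT-style greedy
   pass at 95% identity and 95% coverage of the shorter sequence. We do not
   reproduce CD-HIT's exact word-filter semantics; instead contigs are
   visited longest first (ties by id) and join the first representative
   they match, which is deterministic and directly checkable against an
   all-pairs single-linkage oracle. The two procedures agree whenever
   clusters are separated, i.e. within-cluster identity is above and
   between-cluster identity below the threshold — the regime the tests
   construct and the one in which a 95% threshold is meaningful at all.
3. **Terminal-overlap merging** (`merge_by_overlap()`), driven by the
   end-alignment rule: an ungapped suffix/prefix overlap of at least 20 nt
   is accepted with at most 2 mismatches, none adjacent. We read "within
   20 nucleotides" as a bound on the overlap window with the mismatch
   budget applying to the whole overlap; `per_window = TRUE` offers the
   sliding-sub-window reading. Merging is iterative (longest accepted
   overlap first), takes the left contig's bases at mismatch positions,
   checks the reverse-complement orientation by default (library
   strandedness is not guaranteed), and flags containments instead of
   merging them.
4. **Re-clustering** of the merged set.
5. **Chimera removal** (`detect_chimera()`). A contig is chimeric when two
   local reference hits from different families cover disjoint regions
   (each ≥ 20% of the contig, gap/overlap ≤ 50 nt) and no ORF ≥ 300 nt
   reads through the junction. The rescue ORF must extend at least half
   the rescue length on *both* sides of the junction: by chance a
   truncated reading frame runs a mean of ~21 codons past a junction
   before hitting a stop, so a bare "spans the junction" test would
   rescue real chimeras roughly a fifth of the time. These thresholds
   (20%, 50 nt, 300 nt) operationalize what was a manual inspection step;
   all are exposed in the `curate()` config.

The audit trail assigns every input contig exactly one terminal action
(`length_dropped`, `clustered_away`, `merged_into`, `chimera_dropped`,
`kept`), which the tests check for conservation and against generator
truth.

# Alignment conventions

Pairwise alignment is delegated to `Biostrings::pairwiseAlignment`:
ends-free ("overlap") mode for identity/coverage, local mode for the
split hits that betray chimeras. Nucleotide scoring is match +2 /
mismatch −3, affine gaps −5 to open (first position included) and −2 to
extend; proteins use BLOSUM62 with −11/−1. Identity is computed over
aligned columns; coverage is reported both as query coverage (consumed by
classification, matching translated-search convention) and
shorter-sequence coverage (consumed by clustering, matching CD-HIT
convention), because published identity/coverage thresholds rarely state
the denominator. The ends-free score is pinned against exhaustive
enumeration of all alignments on small inputs.

The terminal-overlap scanner computes, for every overlap length k at
once, the number of suffix/prefix matches via FFT cross-correlation of
per-base indicator vectors, then verifies the few candidate lengths
within the mismatch budget position by position. This keeps all-pairs
merging O(L log L) per pair while remaining exactly equivalent to the
naive scan (a property the tests enforce on hundreds of random pairs).

# Classification

`best_hits()` is an exhaustive desk-scale stand-in for a translated
similarity search: every contig against every reference at the nucleotide
level, every six-frame peptide (stop-free stretch ≥ 20 aa) against every
reference protein. Minimal-evidence filters (nucleotide: identity ≥ 60%
over ≥ 100 nt; protein: BLOSUM62 score ≥ 60, identity ≥ 30% over ≥ 30 aa)
separate genuine homology from the best-scoring random alignment.

`assign_status()` encodes two published thresholds that overlap: known
viruses match at > 85% identity and > 95% coverage; new species fall
below 90% identity or coverage (the sources say "identity and coverage
below 90%" without fixing AND/OR; we default to OR with
`novel_rule = "and"` available). Identities between 85 and 90% satisfy
both sentences at once, so they are reported as `known_like` rather than
silently binned either way; `known` therefore requires identity at or
above the novelty bound. Contigs with no support at either level are
`unclassified`.

# ORFs under alternate genetic codes

Mitoviruses replicate in mitochondria and several narnavirus relatives
infect hosts using mold/protozoan mitochondrial translation, so ORF
calling supports NCBI tables 1 and 4 (TGA = Trp). `find_orfs()` reports
maximal start-to-stop ORFs: the ORF opens at the first ATG after the
previous in-frame stop and its nucleotide length includes the stop codon
while the protein excludes it (2055 nt ↔ 684 aa). Only stop-terminated
ORFs are reported; a consequence, pinned in the tests, is that a
TGA-terminated code-1 ORF has no code-4 counterpart when no TAA/TAG
exists downstream in frame. Defaults — `min_len_nt = 150`, start codons
`{ATG}` with `{ATG, GTG, TTG}` behind a flag — follow common ORF-finder
practice; the sources do not state theirs.

# Segment association

Multi-segmented narnaviruses carry an RdRp on RNA1 and hypothetical
proteins on RNA2/RNA3 with no conserved domains, so association relies on
three custom profile HMMs plus molecular signatures:

* `build_profile_hmm()` is a classical match/insert/delete profile
  (Durbin-style): columns under 50% gaps become match states, emissions
  and transitions are pseudocount-1 estimates from the training rows, the
  background is the alignment's residue composition, and inserts emit the
  background (zero log-odds). There is no E-value calibration — scores
  are raw Viterbi bits against the background null, with a default
  acceptance threshold of 10 bits chosen as a margin comfortably above
  the scores of random length-matched sequences (strongly negative) and
  far below true-positive scores (hundreds of bits); `assign_segment()`
  exposes it.
* `hmm_score()` is a global-to-the-model Viterbi in bits. The
  delete-state recursion is solved per sequence position with a prefix-sum
  plus cumulative-maximum identity, so the dynamic program is fully
  vectorized over match states. It is pinned against exhaustive path
  enumeration on toy models.
* `merge_split_segments()` joins same-class candidates sharing an exact
  terminal pairing of ≥ 18 nt (`exact_terminal_overlap()`, forward
  orientation — continuity of read coverage across such junctions
  supports a same-strand overlap; a reverse-complement check can be
  composed by the caller), then re-runs `longest_orf()`;
  `junction_coverage()` certifies continuity by exact read placement.
* `find_terminal_hairpin()` replaces thermodynamic folding with an
  exhaustive stem-loop scan of the 3'-terminal 50 nt (stem ≥ 3 bp, loop
  3–8 nt, score = Watson-Crick pairs + 0.5 per GU; ties prefer longer
  stems, then 3'-most placement). The call records the full geometry so
  any external folder can re-check it. `terminal_conservation()` aligns
  3' ends gaplessly, anchored at the terminus.

# Synthetic data: what it emulates and what it does not

The generator plants exactly the structures the pipeline detects:
multi-family reference viromes with one long ORF each (~60% of the
genome, capped upstream by an in-frame stop so the planted coordinates
are the recoverable ones); substitution-only mutants at exact Hamming
identity; codon-aware mutants that diverge nucleotides while conserving
protein; fragment pairs with exact planted mismatch structure in their
overlap; cross-family chimeras (breakpoint in the middle half,
rejection-sampled so no ORF legitimately rescues the junction);
tri-segmented genomes (RNA1 2510 nt, RNA2 2163 nt with a 2055-nt ORF,
RNA3 540 nt, matching the scale of the segmented narnavirus the package
was built around) sharing an 18-nt 3' motif and a planted stem-loop, with
RNA2 optionally split into fragments sharing an exact 18-nt terminus; and
error-free multinomial reads under declining / peaked-at-20 h / rising
abundance trajectories (defaults 70/15/15%, the mix dominated by decline
that fermentation time courses show).

The 3' block uses a restricted alphabet (A/C filler and motif, G/C stem)
chosen so the planted hairpin is provably the unique maximal stem-loop in
the window — real terminal structure lives in unconstrained sequence and
real folding is thermodynamic, so passing hairpin tests certifies the
search, not RNA structure prediction. Reads are error-free and
forward-stranded, mutations are substitution-only (the curation rules are
stated in mismatch counts, not edit distances), and no host background is
simulated. Passing on this data therefore demonstrates that each rule is
implemented as stated and recovers what it is defined to recover; it does
not demonstrate robustness to sequencing error, indels, strand ambiguity
or host contamination.

# Quantification and dynamics

`assign_reads()` replaces a k-mer/EM quantifier with exact-substring
assignment on either strand, splitting multi-mapping reads equally —
adequate and fully auditable for error-free synthetic reads. `tpm()` is
the standard length-normalized rate scaled to 10^6 (all-zero columns stay
zero). `alpha_diversity()` reports richness (detected contigs above a
TPM threshold, default > 0) and Shannon entropy in nats via `vegan`. The
fractional "richness" values printed in time-course virome studies cannot
arise from a count, which is why both indices are always reported side by
side rather than guessing which was meant. `family_dynamics()` sums TPM
per family and labels trajectories from the signs of successive
differences (`declining`, `peaked`, `rising`, plus `dipped`/`flat` for
completeness). `ranksum_test()` computes Mann-Whitney U with midranks
and, for both sample sizes ≤ 10, an exact two-sided p by full enumeration
of group assignments — valid under ties, unlike the classical tables —
falling back to the tie-corrected normal approximation with continuity
correction.

# Problem sizes and numerical choices

The validation suite runs at desk scale by design: references of
0.7–2 kb, 50-contig curation suites, 84-row training alignments, 60
assignment trials, 10,000 reads per time point. These sizes make every
oracle (alignment enumeration, naive overlap scans, ORF enumeration, HMM
path enumeration, single-linkage clustering) computable exactly while
keeping each planted effect far larger than its sampling noise.
Probability groups in HMMs are validated to 1e-9; TPM columns to 1e-3 of
10^6; truth-fraction recovery is asserted within 3 binomial standard
deviations. Deterministic tie-breaks are fixed throughout (longest, then
lexicographic id; forward orientation before reverse-complement; M over I
over D in Viterbi tracebacks) so every run of a seeded pipeline is
byte-reproducible.

# Interfaces

The package is function-first: `read_fasta()`/`write_fasta()`,
`write_fastq()` (fixed quality, as synthetic reads are error-free),
plain-text profile-HMM serialization with a round-trip guarantee, and TSV
truth tables cover the exchange formats. `scripts/acceptance.R` re-runs
the headline computations from scratch and writes them as JSON; a
shell-level CLI would add nothing over these two entry points for an
analysis package of this shape, so none is shipped.

# Known limitations

* Greedy clustering can split a chain of pairwise-similar contigs where
  single-linkage would not; agreement holds only for separated clusters.
* Chimera detection requires both parents (or close relatives) in the
  reference set; novel-virus chimeras with one unknown parent pass.
* Multi-mapping reads are split equally, never re-apportioned; abundance
  estimates for contigs sharing long exact repeats are approximate.
* Profile HMM scores are uncalibrated bits; comparing scores across
  models of very different lengths requires care, which is why
  assignment competes the three segment models on the same ORF rather
  than thresholding each in isolation.
* The hairpin score counts pairs; it will prefer a longer weak stem over
  a shorter strong one where a thermodynamic model might not.
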