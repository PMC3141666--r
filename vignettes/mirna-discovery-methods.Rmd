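---
title: "Methods: hairpin-based miRNA discovery from small-RNA tags"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hairpin-based miRNA discovery from small-RNA tags}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemloop)
```

# The problem and the pipeline

Plant microRNAs are 19-24 nt regulators excised by DCL1 from stem-loop
precursors (pre-miRNAs) in which the mature miRNA pairs its star strand
with characteristic 2-nt 3' overhangs. Given adapter-trimmed small-RNA
libraries and a genome, `stemloop` reconstructs candidate precursors and
decides which sequenced tags are genuine miRNAs:

1. **Collapse and filter** (`collapse_reads()`, `filter_tags()`): reads
   are grouped into unique tags with per-library counts; tags with a
   pooled count of two or fewer, or outside the 19-24 nt window, are
   discarded. The published protocol does not say whether the count rule
   was applied per library or pooled; we default to pooled and expose
   `per_library = TRUE` as the alternative.
2. **Exact mapping** (`build_index()`, `map_and_filter()`): tags are
   matched to both genome strands with no mismatches; tags matching more
   than five loci (both strands pooled) are dropped as likely repeats.
3. **Star location** (`extract_flanks()`, `locate_star()`): 200 bp of
   genomic sequence is taken on each side of a hit, and the reverse
   complement of the tag (rc-tag) is aligned into the window (excluding
   the tag's own interval) with Smith-Waterman. The candidate precursor
   is the region between the tag and rc-tag alignments.
4. **Fold and validate** (`fold_hairpin()`, `evaluate_duplex()`): the
   precursor is folded and accepted only if (i) mature and star lie
   entirely on opposite arms of the terminal loop, (ii) at most four
   mature positions are unpaired to the star (G:U wobbles count as
   paired), and (iii) the duplex shows at most one asymmetric bulge of at
   most two bases.
5. **Annotation** (`classify_mirnas()`, `assign_names()`,
   `group_isomirs()`), **target scoring** (`scan_targets()`) and
   **expression analysis** (`design_primers()`, `relative_expression()`,
   `expression_report()`) operate downstream of discovery.

# Tunable parameters

`pipeline_config()` concentrates every constant. Defaults follow the
published soybean analysis where that analysis states a value:

| parameter | default | unit | provenance |
|---|---|---|---|
| `min_total_count` | 3 | reads | counts <= 2 discarded |
| `length_window` | 19-24 | nt | trimmed read lengths |
| `flank_length` | 200 | nt | flank extraction |
| `max_genome_hits` | 5 | loci | repeat filter |
| `max_duplex_mismatches` | 4 | positions | criterion ii |
| `max_asym_bulges` / `max_bulge_size` | 1 / 2 | bulges / nt | criterion iii |
| `target_score_cutoff` | 3.0 | points | target reporting |
| `mismatch_weight` / `gu_weight` | 1.0 / 0.5 | points | target scoring |
| `alpha` | 0.05 | — | expression tests |

Three parameters are artifact choices the source text does not specify.
The Smith-Waterman scores (`+1/-1/-2`) are conventional small-RNA
settings; G:U wobble is deliberately *not* rewarded during the rc-tag
alignment (the alignment is a sequence-identity search; wobble handling
belongs to the duplex evaluation). The star-score floor
(`min_star_score_frac = 0.6` of the perfect rc-tag score) prevents
spurious star calls in random flanks; without a floor nearly every
window yields some local alignment.

The bulge rule as printed ("frequency of asymmetric bulges ... less than
one and the size should be less than two bases") reads literally as
"no bulges", which would reject canonical plant precursors, including
structures in the source's own locus table. We therefore implement the
Meyers-style reading (at most one asymmetric bulge of at most two
bases) and leave both limits configurable; `max_asym_bulges = 0` gives
the strict reading.

# The folding model

`fold_hairpin()` maximises the summed pair weight (G-C = 3, A-U = 2,
G-U = 1) over all non-crossing structures with a minimum hairpin loop of
3 nt, by Nussinov-style dynamic programming. The score is a
stem-stability proxy; it is **not** a free energy and is not comparable
to thermodynamic kcal/mol values, which are out of numeric scope here.
Two numerical choices matter:

* **Traceback determinism.** When several structures attain the optimum,
  the traceback pairs each position with the *largest* admissible
  partner. The outermost choice reconstructs long stems; the opposite
  (smallest-partner) convention can pair a stem base into an A-rich
  terminal loop at equal score, which mislabels duplex mismatches.
* **Criterion evaluation on the trimmed precursor.** Criteria are
  evaluated on the tag-to-rc-tag interval, exactly the sequence the
  discovery step reports, with the mature and star intervals taken from
  the mapping and the alignment rather than re-estimated from the fold.

Mismatches in criterion ii are "mature positions whose fold partner is
not inside the located star interval"; unpaired positions count as
mismatches, wobble pairs do not. Asymmetric bulges are scored by walking
consecutive star-paired mature positions and comparing the unpaired run
lengths on the two strands.

# The synthetic-data generator

`generate_genome_and_truth()` emulates the study conditions the
pipeline was built for: a small multi-chromosome genome (default two
chromosomes of 50 kb), 20 planted hairpin loci, eight libraries named
DSRC/DSRT/DTRC/DTRT/RSLC/RSLT/RRLC/RRLT (two genotypes x control/treated
for a drought-root and a rust-leaf panel), isomiR end-variation,
background degradation tags, and per-library fold changes.

Each planted hairpin is built as a continuous stem `LEFT | loop | RIGHT`
with `RIGHT = revcomp(LEFT)` before star-side mutations. The mature arm
reads `extension | mature | spacer` with the spacer loop-proximal, so the
mature is fully paired; the biological star strand is the duplex strand
whose 3' end pairs two positions 5' of the mature's own 5' end — the
canonical 2-nt 3' overhang geometry. Mismatches (default 0-2 per duplex)
and asymmetric bulges (default at most one of 1 nt) are introduced only
on the star arm, away from the duplex ends. Every candidate hairpin is
verified through the package's own discovery chain (star location at the
default floor, fold, criteria) before insertion and re-drawn otherwise,
so the planted truth is criteria-compliant by construction.

Choices a user should know:

* **Mismatch default 0-2, not 0-4.** Criterion ii tolerates four
  mismatches, but with four substitutions a 19-nt rc-tag alignment scores
  `19 - 2*4 = 11 < 0.6 * 19`, below the star floor: such a hairpin would
  be planted yet undiscoverable. The default range keeps constructive
  validity; the field accepts values up to 4 for users who want
  borderline cases.
* **Strand ambiguity of perfect duplexes.** With zero mismatches the
  rc-mature region equals `revcomp(mature)` exactly, so the tag maps to
  both strands of its own locus and discovery reports the same physical
  hairpin twice, once per strand. Exact mapping cannot resolve the
  transcribed strand there; tests treat the mirrored record as the same
  locus, not a false discovery.
* **Background tags** are uniform random 19-24-mers rejected if they (or
  their reverse complements) occur in the genome, so their truth label is
  known-negative; they exercise the unmapped-tag path.
* **Counts.** With `dispersion = 0` (default) emitted counts equal the
  rounded expected counts (base abundance x fold change, split between
  the mature, its isomiR variants at `isomir_shift_prob`, and the star at
  `star_fraction`), so tests are deterministic; a negative-binomial mode
  is available. Per-library totals are arbitrary because the source
  reports none.
* The simulator does **not** model adapter ligation, sequencing error,
  quality scores, or RNA degradation beyond random background tags, and
  each library is one abundance vector (the source itself pools its 125-
  and 150-minute stress samples). Passing the recovery tests therefore
  shows the chain is correct on clean, criteria-compliant hairpins — not
  that it is robust to sequencing artefacts.

# Target scoring

`scan_targets()` slides an ungapped window of the miRNA length along
each transcript and pairs the miRNA antiparallel to it; the score is
`1.0 x mismatches + 0.5 x G:U wobbles`. Reporting uses `<= 3.0`
although the source text says "less than 3.0": printed target tables
include sites scoring exactly 3.0 under the stated weights, so the
strict reading would contradict the source's own tables (`strict = TRUE`
restores it). Gapped sites, seed-position weighting and accessibility
energetics are not modelled; the published tool chain does not specify
them.

# Expression analysis

`design_primers()` reproduces stem-loop RT-qPCR primer construction: the
forward primer is the mature as DNA, the RT primer is a fixed 44-nt
backbone plus the reverse complement of the mature's 3'-terminal six
bases, and the universal reverse primer is a substring of the backbone.

`relative_expression()` normalises each replicate's target Ct by the
arithmetic mean Ct of the reference genes (equivalent to the geometric
mean on the linear scale), forms the delta-delta-Ct between conditions
and reports `RQ = 2^-ddCt`. The source cites three reference miRNAs but
not a combination rule; the mean-of-Ct is the conventional choice.
Replicates are treated as unpaired biological triplicates: the Welch
two-sided t-test compares the replicate delta-Ct sets, with significance
at `p < alpha` and no multiple-testing correction (the source applies
none). At three replicates per group the Welch test is conservative —
its measured type-I error is near 0.03 at a nominal 0.05 — which the
null-simulation test band accounts for. `expression_report()` arranges
the four pairwise comparisons of a two-genotype/two-condition panel and
attaches the `*`/`a`/`b`/`1` significance codes of the source design.

# Degenerate inputs and edge rules

* Windows truncated at chromosome ends are flagged and processed.
* Overlapping self-matches of a tag each count as a distinct locus in
  the five-hit rule.
* Candidates from one locus (both arms sequenced, isomiR variants) are
  merged into one record keyed by the most abundant tag; ties break
  lexicographically.
* `filter_tags()` is idempotent; collapsing conserves read totals; both
  are tested as invariants.
* isomiR grouping requires members to share a positional core on the
  precursor; members that do not occur in the precursor are dropped with
  a warning, and an empty intersection is an error rather than a guess.

# Problem sizes used by the test-suite

The packaged tests run the alignment oracle on 100 random pairs of
4-8 nt sequences against an exhaustive substring-pair Needleman-Wunsch,
the folding oracle on 200 random 4-12 nt sequences against explicit
enumeration of all non-crossing structures, the end-to-end recovery on
the default synthetic genome (seed 7, 20 hairpins, two 50-kb
chromosomes), and the null calibration of the Welch test on 1000
simulated Ct tables. These sizes keep the whole suite under a minute on
one CPU while exercising every code path; they are the package's chosen
verification scale, not a statement about real-genome performance.

# Known limitations

* Folding ignores thermodynamics, coaxial stacking and suboptimal
  ensembles; structures with equally weighted alternatives depend on the
  documented traceback convention.
* Exact mapping only: a tag with a single SNP against the reference is
  lost, as in the original protocol.
* Classification relies on sequence identity/containment against
  supplied catalogs; it does not model paralog families beyond the
  two-substitution family rule, and catalog ids are taken at face value.
* The qPCR module assumes perfect amplification efficiency.
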