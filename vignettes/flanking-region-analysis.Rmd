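---
title: "Dissecting the regions flanking a conserved core domain"
author: "flankscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the regions flanking a conserved core domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankscan)
```

## The problem

Homeodomain–leucine zipper (HD-Zip) subfamily I transcription factors pair
a DNA-binding homeodomain (HD) with a dimerization leucine zipper (HALZ).
The HD-Zip block is so conserved across the family that DNA-binding
specificity contributes little functional diversity; whatever distinguishes
family members must largely reside in the poorly characterized
amino-terminal region (NTR) before the HD and carboxy-terminal region (CTR)
after the HALZ. `flankscan` packages the in-silico workflow for dissecting
those flanks: split every protein into NTR / core / CTR from profile-HMM
domain hits, scan the flanks for degenerate post-translational-modification
consensus sites with a built-in control, profile positional residue
composition, quantify alignment conservation, and annotate externally
discovered motifs by placement, group specificity, activation-motif
character and overlap with phosphorylation/NLS predictions.

Nothing in the package is specific to HD-Zip proteins beyond the defaults:
any family with one well-defined core domain and variable flanks fits.

## Region partitioning

For each protein the core block is `[HD.start, max(HD.end, HALZ.end)]`. The
two profile-HMM models abut or overlap in this family, so the union is
treated as a single core; the NTR is `[1, HD.start - 1]` and the CTR is
`[core.end + 1, L]`, either possibly empty. The three intervals tile the
sequence exactly — `partition_family()` enforces
`ntr_length + core_length + ctr_length == length` — and all coordinates in
files and outputs are 1-based inclusive. A missing HALZ hit is an error by
default; with `require_halz = FALSE` the core falls back to the HD hit alone
(with a warning), which is the right behaviour for truncated entries.
Multiple HD hits keep the best-scoring one. No trimming is applied around
hits: hit boundaries are taken at face value.

## Consensus scanning and the canonical/control ratio

Degenerate patterns use PROSITE-style syntax: elements joined by `-`, with
`x` for any residue, `[...]` for an allowed set and `{...}` for its
complement within the 20 standard amino acids. The sumoylation consensus
ΨKXE/D — Ψ a large hydrophobic residue (F, V, I, M or L), X anything, then
Glu or Asp — is written:

```{r pattern}
canonical <- compile_pattern("[FVIML]-K-x-[ED]")
control   <- compile_pattern("[FVIML]-K-x-{ED}")
canonical
```

`scan_sequence()` tests every start offset and reports all overlapping
matches; ambiguity codes (B, Z, U, X) never satisfy a constrained position,
while `x` accepts anything. The rudimentary significance device is the
*control pattern*: identical except that the last position must **not** be
acidic. The occurrence-count ratio canonical/control then measures
overrepresentation of true consensus sites relative to near-miss K-centred
tetrapeptides with the same hydrophobic context. The ratio is
occurrence-based, not protein-based: a family in which the canonical motif
appears 143 times against 82 control matches has ratio 1.74 regardless of
how the matches distribute over proteins. A protein is tallied once in
`n_proteins_with_hit` no matter how many sites it carries. A zero control
count yields `NA` (with a warning), never infinity.

`enrichment_summary()` also returns per-position residue-identity
distributions of the canonical matches — in practice the identity of the
hydrophobic first position (V/I/L/M/F) and the E:D split of the acidic
last position — with display percentages rounded to whole percent.

## Positional composition profiles

`decile_histogram()` pools a focal residue's frequency over `k`
relative-position bins (default 10). Position `i` of a region of length `L`
maps to bin `ceiling(i * k / L)`. This mapping was chosen over
`floor((i-1) * k / L) + 1` so that the *last residue of every region falls
in the last bin*, no matter how short the region — the terminal decile is
exactly the set of last `ceiling(L/10)` residues, which is where this
family concentrates its tryptophans. For `L >= k` the two mappings differ
negligibly. Frequencies are pooled (residue-weighted) across regions;
per-protein averaging is available via `per_protein = TRUE`. Non-standard
residues are tallied but excluded from denominators by default, to avoid
inventing frequencies for ambiguity codes. An advisory per-bin binomial
p-value against the pooled background is computed but no claim rests on it.

## Conservation, PFMs and information content

`column_profile()` reports per-column residue frequencies with the *total
number of sequences* as denominator and the gap fraction tallied
separately, so the two sum to one. Information content is
`log2(20) − H(column)` in bits, computed from the non-gap residue
distribution; it is bounded by `[0, log2 20 ≈ 4.32]`, with all-gap columns
defined as 0 and flagged. `key_residue_report()` turns a label→column map
(e.g. `Q50 → column 60`) into whole-percent conservation figures; because
the core block of this family is essentially gap-free the default
denominator counts gaps against conservation, and `denominator = "nongap"`
is available since either reading of a published percentage is plausible.
`region_logo()` exports the PFM (columns sum to 1 over non-gap residues)
and per-column IC for logo rendering; the small-sample correction
`19 / (2 ln 2 · n)` is off by default — at family sizes near 200 it is
negligible — and available for small synthetic sets, with IC floored at 0.

## Motif architecture

Externally discovered motif occurrences (a TSV, or the minimal MEME
plain-text adapter) are placed by `localize_occurrences()`: each occurrence
is assigned to the region containing its midpoint, and occurrences whose
ends fall in different regions are flagged rather than split — discovery
tools happily report sites straddling the HALZ/CTR border. Within the CTR,
the relative midpoint divides occurrences into a *proximal* zone (adjacent
to the HALZ, Ser/acidic motifs, phosphorylation candidates) and a *distal*
zone (the activation-motif end). The family literature divides the CTR only
"roughly"; we adopt an explicit, reproducible surrogate — a boundary
fraction `b = 0.5` of the CTR length, configurable — and report it with the
results.

`group_specificity()` computes, per motif and phylogenetic group, the
fraction of group members carrying the motif and the distribution of the
motif's occurrences across groups. A motif present in at least 50% of
exactly one group and under 10% of every other is flagged
*group-characteristic*; both thresholds are explicit parameters because the
underlying judgement in the literature is qualitative.

`aha_features()` quantifies resemblance to AHA activation motifs (Aromatic,
large Hydrophobic, Acidic context) of the heat-stress-factor type:
per-position aromatic (W/F/Y) and large-hydrophobic (W/F/Y/L/I/V/M)
frequencies, the pooled D/E fraction, and terminal-window tryptophan
statistics, including the atypical basic-residue-adjacent-to-terminal-Trp
configuration. `overlay_sites()` filters phosphorylation and NLS
predictions at score cutoffs 0.9 and 0.6 respectively (the conventional
thresholds for these predictors' reports) and counts retained sites inside
motif occurrences and regions; overlap counts are monotone non-increasing
in the cutoff.

## The synthetic family generator

Real family sets require assembling third-party supplementary data, so the
package ships a generator whose defaults encode the study conditions the
analysis assumes:

* 178 proteins in six groups (I subdivided a/b/c) plus a moss-like
  outgroup set and unassigned members (group VI ≈ 6%);
* a 103-residue synthetic HD+HALZ core consensus with per-column
  consensus-identity targets 0.74, 0.94, 0.93, 0.54/0.46 (I with V as the
  alternative), 1.00, 0.99, 1.00 at homeodomain positions 2, 3, 5, 47, 50,
  51, 55 and 0.85 elsewhere. *Identity is exactly the probability of the
  consensus residue*: non-consensus draws exclude it, so configured values
  are recoverable expectations;
* NTR lengths uniform on [19, 91] and CTR lengths uniform on [62, 127] —
  the observed spans in this family; uniform is the simplest distribution
  consistent with a reported range, and the length model is pluggable;
* group-specific distal CTR motifs, Trp/Phe-rich with acidic context,
  placed in the final 15% of the CTR (the distal motif covers the last
  residues of the protein); a Ser/acidic proximal motif shared by several
  groups; an NTR motif confined to one group; and no distinctive CTR motif
  for group VI;
* sumoylation-consensus sites planted at 0.6 per CTR and 0.05 per NTR,
  with Ψ drawn as V/I/L/M/F = .62/.19/.11/.06/.02 and E:D = .84:.16. The
  CTR rate was set so that planted sites plus the closed-form background
  expectation under the generator's composition reproduce the observed
  family-wide density of roughly 143 sites per 178 CTRs — an observed
  total, not a planted count;
* a 3-fold tryptophan enrichment in the terminal decile of the CTR
  (reported in this family only as a "visible" enrichment; 3× is clearly
  visible above the ~1% background without being cartoonish);
* Swiss-Prot-style average background residue frequencies elsewhere.

Planted sites match `[FVIML]-K-x-[ED]` exactly, never overlap planted
motifs or each other (rejection sampling), and every planted coordinate is
emitted in ground-truth tables that satisfy the package's own I/O schemas.
One seeded generator drives all randomness; `simulate_family(config, seed)`
is byte-identical across runs and the seed is recorded in every output
header.

```{r simulate}
sim <- simulate_family(simulation_config(), seed = 1)
sim
parts <- partition_family(sim$proteins, sim$domains)
ctr <- region_sequences(sim$proteins, parts, "ctr")
enrichment_summary(ctr, "[FVIML]-K-x-[ED]", "[FVIML]-K-x-{ED}")
```

### What the generator does and does not emulate

It reproduces the family's *structure*: a conserved core with specified
column identities, variable-length flanks, group-confined motifs, planted
consensus sites, terminal aromatic enrichment. It does **not** emulate the
real flanks' *composition*: flank residues are drawn from average protein
composition, whereas real CTRs of this family are serine-rich, acidic and
comparatively lysine-poor. Two visible consequences: the control pattern
(which needs only a K with a hydrophobic neighbour) matches far more often
in synthetic flanks than in the real family, so the synthetic
canonical/control ratio sits near 0.5–0.6 rather than well above 1; and
synthetic NTRs carry more background canonical matches than the handful
seen in the real family. Passing recovery tests on synthetic data therefore
demonstrates that the *measurements* are correct (planted signal is
recovered at the configured rates; background matches the closed-form
expectation), not that synthetic families are compositionally
indistinguishable from real ones. The generator also performs no
evolutionary simulation: no indels along a tree, no substitution-matrix
correlation between group members beyond the planted structure.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive at every interface; empty regions have
  `NA` bounds and length 0.
* Overlapping pattern matches are all counted (no collapsing rule exists
  for raw "times found" tallies; the sumoylation 4-mer cannot self-overlap
  anyway, since its K and E/D constraints conflict at every shared offset).
* Ratios with a zero denominator are `NA` with a warning.
* Display percentages are rounded to whole percent; ratios to two decimals;
  underlying objects keep full precision.
* Midpoints at region borders round up (`ceiling`), a fixed tie-break.
* Sequences shorter than a pattern yield an empty occurrence list, not an
  error; all-empty region sets are an error.
* The scanner is a compiled-once perl lookahead regex; its correctness is
  checked in the test suite against an independent window-by-window
  set-membership oracle on tens of thousands of random sequences.

## Problem sizes used in the test suite

Property-style tests run the scanner oracle on 10,000 random sequences of
length 4–50, and all parameter-recovery checks (planted-site recovery
within 3σ of the analytic background, conservation within binomial 3σ,
group-specificity flagging, terminal-decile enrichment within 30% of the
configured factor) use simulated families of 200 proteins — large enough
that binomial bands are tight relative to the planted effects, small
enough to keep the full suite around two minutes.

## Known limitations

* The proximal/distal CTR split is a surrogate for a visual judgement; no
  single boundary fraction can reproduce a figure drawn by eye.
* The MEME adapter targets the classic plain-text "sites sorted by
  position p-value" block only; the TSV schema is the canonical interface.
* `aha_features()` reports per-position frequencies only for equal-length
  inputs (motif occurrence sets); ragged inputs get pooled statistics.
* Conservation percentages depend on the denominator convention when
  alignments contain gaps; both modes are provided and reported.
* No statistical test is attached to motif–group association or to the
  canonical/control ratio beyond the advisory binomial bin p-values; the
  ratio is a descriptive overrepresentation index.
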