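# flankscan

Motif architecture of the regions flanking a conserved core domain, built
around HD-Zip subfamily I transcription factors.

## The problem

HD-Zip I proteins bind DNA through a homeodomain (HD) and dimerize through
an associated leucine zipper (HALZ). The HD-Zip block is nearly invariant
across the family — the key DNA-contacting homeodomain residues are
conserved at 74–100% — so functional diversity must come mostly from the
flanking regions: the amino-terminal region (NTR) before the HD and the
carboxy-terminal region (CTR) after the HALZ. `flankscan` implements the
computational workflow for dissecting those flanks:

* **Region partitioning** — split each protein into NTR, core
  `[HD.start, max(HD.end, HALZ.end)]`, and CTR from profile-HMM hit tables;
  the three regions tile the sequence exactly.
* **Degenerate consensus scanning** — compile PROSITE-style patterns
  (`x` any, `[..]` allowed, `{..}` excluded) and scan regions with a
  built-in control. The flagship application is the sumoylation consensus
  ΨKXE/D (`[FVIML]-K-x-[ED]`), whose overrepresentation is measured by the
  occurrence ratio against the near-miss control `[FVIML]-K-x-{ED}`:

  ratio = n(ΨKX[ED]) / n(ΨKX{ED})

  together with per-position residue-identity distributions (V/I/L/M/F at
  the hydrophobic position, E vs D at the acidic one).
* **Positional composition** — decile histograms of a focal residue
  (position `i` of a length-`L` region maps to bin `ceil(i·k/L)`), e.g.
  the terminal-decile tryptophan enrichment of the family's CTRs.
* **Conservation** — alignment column frequencies, whole-percent
  key-residue reports, and PFM + information content
  (`IC = log2 20 − H`, in bits) for sequence logos.
* **Motif architecture** — map externally discovered motif occurrences onto
  regions, proximal/distal CTR zones, motif × group specificity, AHA
  activation-motif features (aromatic core, acidic context, terminal Trp),
  and overlap with phosphorylation (cutoff 0.9) / NLS (cutoff 0.6)
  prediction reports.
* **Synthetic families** — a seeded generator producing families with a
  conserved core, group-specific planted motifs, planted consensus sites
  and terminal Trp enrichment, with full ground-truth tables, so the whole
  pipeline is testable without external downloads.

## Worked example

```r
library(flankscan)

# scan one sequence for the sumoylation consensus
scan_sequence("MVKAEIKLDW", "[FVIML]-K-x-[ED]")
#>   start end matched_seq
#> 1     2   5        VKAE
#> 2     6   9        IKLD

# a synthetic family under the generator's default study conditions
sim   <- simulate_family(simulation_config(), seed = 1)
parts <- partition_family(sim$proteins, sim$domains)
ctr   <- region_sequences(sim$proteins, parts, "ctr")

enrichment_summary(ctr, "[FVIML]-K-x-[ED]", "[FVIML]-K-x-{ED}")
#> <enrichment_result> [FVIML]-K-x-[ED] vs [FVIML]-K-x-{ED}
#>   canonical: 133 occurrence(s) in 98 of 178 proteins
#>   control:   240 occurrence(s) in 130 proteins
#>   canonical/control ratio: 0.55

decile_histogram(ctr, "W")
#> <frequency_profile> residue W, 10 bins, 178 regions (pooled)
#>   bin1   bin2   bin3   bin4   bin5   bin6   bin7   bin8   bin9  bin10
#> 0.0097 0.0091 0.0069 0.0075 0.0165 0.0099 0.0099 0.0120 0.0300 0.1359
```

The 133 canonical occurrences are the ~107 planted sumoylation sites plus
background matches consistent with the closed-form rate
(`analytic_background_rate()`); the control count is high because synthetic
flanks use average protein composition, which is richer in lysine and
hydrophobics than this family's real acidic, Ser-rich CTRs (see the
methods vignette). The tryptophan histogram shows the planted terminal
signature: the last decile is the clear maximum, at ~13% versus a ~1%
background.

Conservation of the key homeodomain residues on the simulated core:

```r
core <- region_sequences(sim$proteins, parts, "core")
key_residue_report(core,
  c(K2 = 2, K3 = 3, R5 = 5, IV47 = 47, Q50 = 50, N51 = 51, R55 = 55),
  c(K2 = "K", K3 = "K", R5 = "R", IV47 = "IV", Q50 = "Q", N51 = "N", R55 = "R"))
#>   label column residue count percent
#> 1    K2      2       K   133      75
#> 2    K3      3       K   166      93
#> ...
#> 6   Q50     50       Q   178     100
```

The full pipeline (partition → scans → composition → conservation →
architecture, plus a reproducibility manifest) runs from one config:

```r
run_pipeline(list(seed = 1, simulate = list()), "out/")
```

or from the shell via the thin wrapper `inst/scripts/flankscan
{simulate|all} --config run.yaml --out-dir out/`.

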