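---
title: "Mapping phage gene essentiality with Cas12a CRISPRi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phage gene essentiality with Cas12a CRISPRi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemap)
```

## The measurement model

An arrayed CRISPRi essentiality screen infects lawns of a host strain,
each expressing a catalytically dead Cas12a and one gene-targeting
crRNA, with a dilution series of the phage. The dCas12a/crRNA complex
binds its protospacer and blocks transcription elongation without
cutting. If the silenced gene (or anything downstream of the roadblock
on the same transcript — see polarity below) is required for the lytic
cycle, plaque formation collapses. The quantitative readout per gene is
the efficiency of plating,

$$\mathrm{EOP} = \frac{\text{titer on the targeting lawn}}
                     {\text{titer on the nontargeting-control lawn}},$$

and the working definition of an essential-gene phenotype is a plating
defect of at least three orders of magnitude, EOP $\le 10^{-3}$.

The package assumes: (i) knockdown is strong enough that a required
gene's silencing is visible as a plating defect (roadblock efficacy is
*not* modeled — see limitations); (ii) plaque counts in a spot are
Poisson; (iii) annotations are correct simple CDS spans (compound/joined
locations are rejected on input).

## Guide design rules and their parameters

`design_config()` collects the designer's tunables:

| parameter | default | units | why |
|---|---|---|---|
| `pam_motif` | `TTTV` | IUPAC | the Cas12a PAM; V = A/C/G |
| `spacer_length` | 28 | nt | crRNA spacer length for Cas12a |
| `window_lo`, `window_hi` | 0.20, 0.33 | fraction of CDS length | PAM start must fall 20–33% into the CDS: far enough from the annotated ATG that an alternative start site is still silenced, early enough that the roadblock precedes most of the ORF |
| `strand_policy` | coding strand only | — | the spacer is defined on the coding strand of the target gene |
| `fallback` | `none` | — | strict window; `extend_downstream` widens to [0.20, 1] only before declaring a gene untargetable |

Three choices here were genuinely open and are worth recording:

* **Window membership** is evaluated at the *PAM start* offset, as a
  fraction of CDS length, inclusive at both bounds. "20% to 33% of the
  way through the CDS" does not pin down whether the PAM, the spacer, or
  the spacer midpoint must sit in the window; PAM-start is the simplest
  consistent reading and is what the tests encode. Benchmarks against a
  published design can legitimately disagree at window-boundary genes.
* **Tie-break**: among in-window PAMs the smallest CDS offset wins —
  deterministic, and matches the "earliest usable site after the 20%
  mark" intent.
* **The spacer may overhang the stop codon** (it must exist in the
  genome, not in the CDS): nothing in the design rationale requires the
  spacer to be intragenic, and short genes would otherwise lose their
  only in-window sites.

`N` bases are accepted in genome sequences but match no PAM base and
invalidate any spacer containing them; other ambiguity codes are
rejected on input rather than silently interpreted. Genes shorter than
the spacer are untargetable ("gene too short"). Only the coding strand
is scanned for knockdown guides; counterselection guides for barcode
engineering (below) scan both strands, because cutting needs a target
but no orientation.

## Titers, censoring, and classification

`titer_from_spots()` reads a 10-fold spot-titration series (2 µL spots
by default) and uses the least-diluted spot whose plaque count lies in
the countable range [3, 30] — the standard small-spot counting window;
it is configurable. Degenerate series are handled explicitly: all spots
lawn-cleared is an error ("dilute further"); all spots zero yields a
censored detection-limit bound of one plaque at the least dilute spot,
propagated as an EOP upper bound and rendered `<x`; positive counts that
all fall outside the countable window fall back to the least-diluted
positive spot, flagged in the result (the specification of the countable
rule leaves this case open, and discarding the series entirely would
lose real information).

`analyze_spot_table()` estimates the control titer **once**, as the mean
of the per-replicate control titrations, and divides each target
replicate's titer by that pooled value. This is deliberate: the control
stock's titer is a single physical quantity, and pairing each target
spot with a single noisy control spot makes the EOP a ratio of two small
Poisson counts, which is biased upward by roughly the reciprocal of the
control count (~+12% at counts near 10, measured by simulation). With
the pooled control the simulate→analyze loop recovers true EOPs of
$1, 10^{-2}, 10^{-4}, 10^{-6}$ within three standard errors at 100
replicates — the property the acceptance suite checks.

`aggregate_and_classify()` reports the arithmetic mean and sample
standard deviation (n−1) over uncensored replicates. Censored bounds are
never averaged with uncensored values: all-censored replicates propagate
as a bound (and force an `E` call when the bound is below threshold);
mixed series use the uncensored values and warn if a censored bound
contradicts them. Calls: `E` at mean ≤ 10⁻³, `NE` at ≥ 10⁻², and
`intermediate` between — the band acknowledges partial plating defects
(an endolysin produced in large excess, for example, can tolerate
substantial knockdown). The shipped benchmark tables' printed calls are
**taken as given, not re-derived**: they contain entries that a pure
threshold cannot reproduce (the same mean EOP labeled differently for
different genes), so the published calls evidently include judgment;
`tally_calls()` counts whatever the table says.

## Roadblock polarity

Because the roadblock is a DNA-bound complex, it silences every gene
downstream on the same transcript. `interpret_calls()` therefore treats
an essential readout as *informative* only when no gene strictly
downstream in its transcriptional unit is also called essential;
essential readouts upstream of another essential gene are *potentially
polar*, and nonessential readouts upstream of an essential gene are
*readthrough anomalies* — the roadblock demonstrably let transcription
through, which is worth flagging rather than resolving. Genes without an
E/NE call never act as blockers; genes in no unit are *unplaced*.

Two further choices:

* **Trans-complementation**: when a downstream gene (e.g., a late-gene
  antiterminator) is supplied from a plasmid, that gene is removed from
  the unit for the rerun evaluation — its own knockdown phenotype is
  masked, so it can neither receive a status nor block upstream genes.
  Combining the base interpretation with the rerun interpretation (union
  of informative sets) reproduces the published four-gene informative
  set {N, P, Q, J} for the lambda lytic transcripts, as the test suite
  verifies.
* **Genes served by several transcripts** get the most conservative
  combination of their per-unit statuses (informative only if
  informative in every containing unit): a roadblock on shared DNA
  blocks all transcripts through it.

The shipped lambda transcript fixture encodes only the three lytic
transcriptional units the polarity argument needs (the leftward early
unit headed by *N*; the rightward early unit from *cro* through *Q*; the
late transcript from *orf-64* through the tail-fiber genes); lysogenic
transcripts are omitted. No P1 transcript fixture is shipped: the
45-unit P1 transcript map exists in the literature but is not printed in
the benchmark source, so P1 polarity accounting is left to the user's
own unit table.

## Barcoding and counterselection

`design_construct()` copies two homology arms (default 100 nt — long
enough for efficient lambda-Red-style recombination, short enough for a
synthesized fragment) exactly from the genome around the insertion
point (the locus midpoint for a gene target), and draws a random 20-nt
barcode between two fixed primer-binding flanks. Barcode composition
filters — GC in [0.25, 0.75], no homopolymer of 5, pairwise Hamming
distance ≥ 3 within a set — are standard Barseq hygiene and
configurable. The default flank sequences are **placeholders**: real
designs supply their own primer-binding sequences, and the package
treats flanks as opaque configurable strings throughout.

`design_counterselection_guide()` searches both strands near the
junction for a PAM whose spacer spans the insertion point, then verifies
by exhaustive scan that the protospacer+PAM occurs in the wild-type
genome but not in the in-silico recombinant — the property that makes
nuclease-active counterselection enrich recombinants. When no spanning
guide exists the error lists the nearest PAM positions.

`count_barcodes()` anchors the left flank with at most one mismatch
(configurable), extracts the following 20-mer, and requires the right
flank immediately after within the same budget. Barcode matching is
exact after anchoring — no error correction on the 20-mer, so indels or
barcode-internal errors land in the unassigned tally, which is reported
alongside the counts (assigned + unassigned = total, always).

## What the simulators do and do not emulate

`generate_genome()` builds ATG-initiated, stop-terminated ORFs on random
strands with short intergenic gaps; planted genes carry a `TTTG` whose
start sits ~25% into the CDS, guaranteeing a designable site, and the
PAM-free schedule (T-free internal codons) guarantees the opposite.
`simulate_spot_counts()` draws Poisson counts down a decade dilution
series, marking counts above 100 per spot as uncountable confluent
lysis. `simulate_barcode_reads()` emits flank-barcode-flank amplicons
with known mixture proportions.

Defaults describe a small but realistic screen: 20 genes of 300–900 nt,
a control titer of 5×10⁹ PFU/mL (a typical high-titer lysate), 2-µL
spots over dilutions 10⁰–10⁻⁸, three replicates. The test and
acceptance runs use 20–100 gene genomes, 100 replicates for recovery
checks, and 10,000 reads for mixture recovery — sizes chosen so each
Monte-Carlo check has discriminating power at its 3-standard-error
tolerance.

The simulators deliberately omit: plate-to-plate overdispersion
(counting noise is pure Poisson), variable roadblock efficacy and
readthrough (every knockdown is perfect), CRISPRi escape mutants,
polarity itself (simulated EOPs are assigned per gene, not propagated
along transcripts), PCR chimeras and sequencing error beyond the flank
mismatch budget, and genome features like overlapping genes or
origin-wrapping CDSs. Passing the recovery tests therefore shows the
*analysis* is calibrated for the stated noise model — not that a real
screen is free of the biological confounders above; the polarity module
exists precisely because the largest such confounder must be handled at
interpretation time.

## Known limitations

* The published reference genome records used by the original lambda/P1
  benchmarks are not redistributed with the package; the
  roster-reproduction check in the acceptance suite documents the
  expected counts and runs whenever the two GenBank records are placed
  under `inst/extdata/`. Window-boundary convention differences (above)
  are the expected source of any residual per-gene disagreement, and the
  designer's report carries per-gene diagnostics for exactly that
  comparison.
* The lambda benchmark table tallies 36 E / 31 NE / 6 NT over its 73
  rows; the accompanying text summarises the same screen as 35/32. The
  fixture transcribes the table verbatim and the package reports what it
  tallies, without editorializing.
* Circular genome storage is supported but origin-wrapping features are
  rejected rather than handled.
* Essentiality calls are a threshold on mean EOP; no hypothesis test is
  performed, matching screen-scale practice where replicate counts are
  small.
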