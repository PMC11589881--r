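---
title: "Classifying C-terminal transmembrane helices and their tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying C-terminal transmembrane helices and their tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctails)
library(dplyr)
```

## The biological problem

When a transmembrane helix (TM) finishes its synthesis it still sits inside
the ribosome exit tunnel, out of reach of the membrane-insertion machinery.
The translocon can only insert a TM once roughly 45 further residues have
been synthesised C-terminally of it. A TM close to the C-terminus — a
**cTM** — followed by fewer than ~45 residues therefore cannot insert
cotranslationally and must insert after translation ends.

Posttranslational insertion is handled by Oxa1-family insertases (YidC in
bacteria; EMC, GET and TMCO in the eukaryotic ER). These machines have no
protein-conducting pore, only a membrane-thinning hydrophilic groove, and
struggle to translocate long or hydrophilic polypeptides. Which flank of
the cTM must cross the membrane depends on the topology: with a cytosolic
C-terminus (**C_cyt**) the *penultimate loop* translocates and the C-tail
stays in the cytosol; with an extracytosolic C-terminus (**C_ext**) it is
the *C-tail itself* that must cross. This package provides the full desk
side of that analysis: topology consensus building, tail scoring and
classification, group statistics, stop-loss (nonstop) variant analysis and
quantification of insertion assays.

## Hydrophilicity scoring

All scoring rests on the biological hydrophobicity scale: an apparent free
energy of translocon-mediated membrane insertion, ΔG^app in kcal/mol, per
residue placed at the membrane centre. Negative values (L, I, F, V, M, C)
favour insertion; positive values mark polar and charged residues. The
scale ships as a TSV (`inst/extdata/biological_hydrophobicity_scale.tsv`)
rather than being hard-coded; tests assert orderings and signs, never
absolute constants.

The *hydrophilicity* of a loop or tail is the plain sum of mid-membrane
values over its residues (`tail_hydrophilicity()`), so it grows with both
length and polarity — a 4-residue NNNN extension adds
`r tail_hydrophilicity("NNNN")` kcal/mol while GSGS adds only
`r tail_hydrophilicity("GSGS")`.

For scoring *candidate TM windows* (`segment_dg()`) a positional profile
matters: polar residues cost less near the membrane interfaces than at the
centre. We model this as a per-residue Gaussian attenuation of the
mid-membrane value across the window (width `pos_sigma`, on the scaled
membrane-normal coordinate, shipped in the same TSV; default 0.5 for all
residues). This is a deliberately simple parametric stand-in for the full
published position-specific coefficient set; disabling it
(`positional = FALSE`) falls back to the plain sum. Because every
conclusion the package draws from TM windows is a *minimum over windows*
(below) or an ordering, the qualitative behaviour does not depend on the
profile's exact shape.

Predictor TM boundaries are fuzzy, so a per-TM ΔG^app is assigned by
`min_dg_near_center()`: the minimum of `segment_dg()` over all windows of
length 19–23 whose centre lies within ±5 residues (configurable to 6, the
two readings of "five to six residues") of the annotated TM centre. The TM
centre is the floor midpoint of the annotated segment — a deterministic
choice where "core residues" have no numeric definition. Windows that would
cross a sequence end are skipped; if no allowed window fits at all, the
largest window that fits is scored and flagged `truncated` rather than
silently dropped.

Selenocysteine (`U`) is substituted by cysteine as an explicit, logged
preprocessing step in `read_fasta()`; any other non-standard letter (X, B,
Z) is rejected with an error naming the letter, so scoring is always
deterministic.

## Topology consensus

Per-protein topologies come from up to three predictors (CCTOP-style,
TMAlphaFold-style, PolyPhobius-style), supplied as per-residue strings
(`read_topology_string()`, TOPCONS dialect `i`/`o`/`M` with a leading `S`
run for signal peptides) or as segment tables (`read_segment_table()`).
Two predictions *agree* when TM counts match and, pairing TMs by rank
order, every centre pair differs by at most half the 14-residue window
(|Δ| ≤ 7). We read "within a 14-residue window" as a window centred on one
prediction; the laxer |Δ| ≤ 14 reading is available by setting
`center_window = 28`. Pairing by rank order is sufficient because counts
are already equal — no assignment problem arises.

`merge_topologies()` applies the priority rules: all three agreeing gives
quality `"high"` with CCTOP coordinates; otherwise a CCTOP–TMAlphaFold
agreement wins, then TMAlphaFold–PolyPhobius; with no agreement or missing
data, PolyPhobius is preferred over CCTOP over TMAlphaFold and the result
is `"low"` quality. Since only the three-way case is named high and the
fallback low, two-way agreements default to `"low"` with an opt-in
`"medium"` label. The coordinate donor in an agreeing pair is the
higher-priority member; the output is always one input verbatim — no
averaging. TMAlphaFold predictions passing fewer than 5 of its 10 structure
tests are discarded before merging. Missing predictors are represented as
outputs with an absent topology, never as errors.

## C-tail classification

`tail_profile()` derives, per protein: the C-tail (all residues after the
last TM's end coordinate, taken verbatim from the consensus annotation),
its orientation (`C_cyt` if the C-terminal side is cytosolic — the
N-terminal side flipped once per TM), its summed hydrophilicity, and the
insertion route by the 45-residue rule: `tail_len < 45` ⇒
`posttranslational` (strict inequality; the boundary tail of exactly 45
residues counts as cotranslational-capable). The penultimate loop and
N-tail are scored the same way; signal-peptide residues are excluded from
the N-tail statistics while indices are preserved.

Cohort assembly (`filter_proteome()`) applies, in order: length bounds
(18–10,000 residues), a ≥3-TM requirement (restricting to
translocon-inserted multispanning proteins), and a user-supplied organelle
exclusion list (mitochondrial/peroxisomal proteins follow different
insertion pathways; the curated lists are external data, so exclusion is
list-driven, never inferred). Each filter's removal count is logged.

Group differences (C_cyt vs C_ext tails among posttranslational proteins)
are tested with a two-sided Mann–Whitney U test implemented in
`mann_whitney_two_sided()`: midrank U, exact null when `min(n) ≤ 8` with no
ties, tie-corrected normal approximation otherwise. No continuity
correction is applied, so identical samples give p = 1 exactly; the switch
threshold is configurable. No multiple-testing correction is applied —
comparisons are reported per panel.

## Nonstop variants

A stop-loss variant replaces the stop codon by a sense codon so translation
continues to the next in-frame stop. `apply_nonstop()` takes an explicit
CDS (including stop codon and 3′ UTR) plus a `c.{pos}{ref}>{alt}` variant,
verifies that the variant really hits the stop codon and that the reference
base matches, and translates the extension (standard genetic code only).
Protein-level notation `p.Ter{N}{Aaa}` is also accepted — Ter at codon N
means N − 1 encoded residues — and suffices when the extension peptide is
supplied directly, with no transcript-database lookup anywhere.

`classify_effect()` rebuilds the tail (new tail = wild-type tail +
extension; hydrophilicity is additive), re-applies the 45-residue rule and,
for C_ext proteins only, raises a misinsertion flag when the extended tail
still requires posttranslational insertion but its hydrophilicity exceeds
the insertase capacity threshold. That threshold is a band, ΔG^app ≈ 5–6
kcal/mol; a boolean flag needs one number, so the default is the midpoint
5.5 and the flag's value at both band edges is always reported alongside.

## Insertion quantification

The cysteine-accessibility assay probes which side of the membrane a
single engineered Cys occupies: AMS (membrane-impermeable) blocks
PEGylation only of extracytosolic Cys, NEM (membrane-permeable) blocks
everything accessible in whole cells, and an untreated sample gives maximal
PEGylation. `percent_insertion()` computes

$$\%insertion = 100 \cdot \frac{1 - \%PEG_{AMS}/\%PEG_{untreated}}
                              {1 - \%PEG_{NEM}/\%PEG_{untreated}}$$

The statistic is a ratio, hence invariant to common rescaling of the three
lanes and monotone decreasing in the AMS lane. `peg_untreated = 0` and
`peg_nem ≥ peg_untreated` are rejected as errors (the denominator controls
for inaccessible cysteines and is meaningless otherwise). Band noise can
push the raw value slightly outside [0, 100]; we clamp *and* flag, keeping
the raw value, rather than truncating silently.

Densitometry calibration (`calibrate_densitometry()`) fits a line through
the origin to a geometric dilution series — the stated purpose of the curve
is accuracy of band quantification, and within the linear range of
detection a through-origin line is the simplest faithful form. Saturation
of the brightest band is detected against a leave-top-out fit: a capped top
point drags a through-origin fit toward itself, so its residual must be
judged against the line defined by the unsaturated dilutions (flagged when
it exceeds twice their residual RMS). Replicates aggregate as mean ± SEM,
with a warning below three replicates.

## Synthetic data and what it does (not) show

`make_proteome()` generates cohorts with known ground truth. Defaults are
chosen to emulate the structure of a real posttranslational cohort: TM
counts 3–10; half the proteins C_ext; C_ext tails short (negative binomial,
mean 8 residues) with mild hydrophilicity targets (mean 3 ± 1.5 kcal/mol,
below the 5–6 capacity band), C_cyt tails longer (mean 25) and markedly
hydrophilic (mean 15 ± 5). Tail composition is steered to the drawn ΔG^app
target by greedy residue swaps against the shipped scale (guaranteed,
fast convergence; tolerance ±0.5 kcal/mol; unreachable targets are
resampled with a logged count). TMs are drawn from hydrophobic residues
only, loops uniformly over the 20 residues.

`make_predictor_outputs()` perturbs a true topology per predictor (centre
jitter, TM drop/add, missing output) to exercise every consensus branch;
`make_cds()` reverse-translates with uniform codon usage (codon bias is
irrelevant to every consuming stage) and emits the single-base variant
recreating a chosen extension — only extensions whose first residue is one
substitution away from a stop codon are constructible, exactly as for
natural single-nucleotide nonstop variants; `make_gels()` inverts the
%insertion formula and adds mean-corrected multiplicative lognormal noise
per band. Every generator is a deterministic function of its spec and seed.

The generators make no attempt at realistic amino-acid composition beyond
the ΔG targets, nor at homology structure, predictor-specific error modes,
or the length–hydrophilicity correlation of real tails. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline machinery* is
correct (labels recovered exactly at zero perturbation, effects detected at
the generated effect size), not that any particular biological cohort will
show a given effect size or p-value; reproducing published cohort sizes
would additionally require the original proteome downloads and
predictor-version parity, which is out of scope by design.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 500 synthetic
proteins for label recovery, 1000 simulated cohorts of 50 + 50 for power
and 1000 of 5 + 5 for test level, 1000 random CDS/variant pairs against an
independent translator, 1000 random 60-mers for the window-scan oracle, and
500 replicate gels for estimator bias — sizes at which the binomial noise
of the checked fractions is well below the asserted margins while the whole
suite runs in minutes on a laptop. Ties in the Mann–Whitney test switch to
the corrected normal approximation regardless of sample size; degenerate
window scans are flagged, not guessed; and all thresholds (45-residue rule,
14-residue agreement window, 5–6 kcal/mol band, 19–23 window lengths, ±5
scan slack) are exposed as parameters with the defaults documented above.
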