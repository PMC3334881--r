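---
title: "Detecting 3' 2'-O-methylation of small RNAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3' 2'-O-methylation of small RNAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAmethyl)
```

## The biological question

*C. elegans* carries several classes of ~20-30 nt regulatory RNAs that are
distinguished by length, 5' nucleotide, biogenesis, and Argonaute partner:
piRNAs (21 nt, 5' U, PIWI-bound), secondary 22G siRNAs (22 nt, 5'
triphosphorylated G, RdRP products antisense to their source transcripts),
primary 26G siRNAs (26 nt, 5' G, Dicer products; an ERGO-1-associated
embryonic class and an ALG-3/4-associated spermatogenic class), and
miRNAs. A HEN1-family methyltransferase deposits a 2'-O-methyl group on
the 3'-terminal ribose of some of these classes. Which classes are
methylated can be read out chemically: periodate oxidation followed by
beta-elimination removes the 3' nucleoside of any RNA with a free
2',3'-diol and leaves an end that cannot be ligated to a sequencing
adapter, whereas a 2'-O-methylated 3' end is untouched. Sequencing a
beta-eliminated library next to an untreated one therefore enriches
methylated species and depletes unmethylated ones.

This package implements that comparison end to end — read classification,
reads-per-million (RPM) normalization, log2 enrichment ratios and status
calls, 3' trimming/tailing decomposition, guide-target complementarity
rules for siRNA target recognition, and 2^-ddCt quantification — together
with a synthetic-data generator that emulates the structure of such
libraries so every stage is testable without any download.

## The synthetic generator: what it emulates

`build_reference()` assembles a single random contig carrying typed,
non-overlapping loci: piRNA loci, coding loci, 26G source loci of both
classes, annotated mature miRNAs, an "X-cluster"-like locus whose
transcript contains `n_motif_copies` (default 7) embedded copies of one
26-nt motif, and a trigger locus whose antisense 26G read is a designed
guide partially complementary to that motif. The guide/motif pair is
constructed position by position: Watson-Crick pairs at guide positions
1-10 and 14-19, mismatches at 11-13, and two G:U wobbles among otherwise
mismatched 3' positions — 18 of 26 positions paired, a complementarity
fraction of 0.692, just above the 0.69 scanning threshold. The builder
verifies that the motif occurs in the genome exactly `n_motif_copies`
times and that scanning the X-cluster transcript with the guide recovers
exactly the embedded placements; random spacers are redrawn otherwise,
because a random window occasionally ties the designed complementarity
and would silently displace a true site.

`simulate_library()` draws collapsed read species per class. Defaults
(editable through `library_config()`):

| class            | length | 5' nt | orientation | methylated | tail rate | trim rate |
|------------------|--------|-------|-------------|-----------|-----------|-----------|
| piRNA_21U        | 21     | U     | sense       | 1.0       | 0.05      | 0.02      |
| miRNA            | mature | —     | sense       | 0.0       | 0.05      | 0.02      |
| siRNA_22G        | 22     | G     | antisense   | 0.0       | 0.15      | 0.10      |
| siRNA_26G_ERGO1  | 26     | G     | antisense   | 1.0       | 0.30      | 0.15      |
| siRNA_26G_ALG34  | 26     | G     | antisense   | 0.0       | 0.30      | 0.15      |

Copy counts are negative-binomial (dispersion 2, class-specific means
chosen so a default library holds roughly 2x10^5 copies across ~190
species — large enough for stable class ratios, small enough to simulate
in seconds). Tailing and trimming are drawn **per copy** (a species can
split into plain/trimmed/tailed sub-species), so observed tailed-copy
fractions are exactly binomial in the configured rate — that is what
makes the rate-recovery tests well-posed. Tail lengths default to 1-3 nt
with probabilities 0.6/0.3/0.1; the first tail base is drawn to differ
from the genomic continuation at the source placement, so simulated tails
are untemplated by construction. A size-selection window of 18-28 nt
(mirroring gel size selection) is applied to the output.

Methylation probabilities default to 1 for piRNAs and ERGO-1 class 26G
siRNAs and 0 elsewhere; the tailing defaults are high for siRNA classes
and low for miRNAs/piRNAs, following the qualitative pattern seen in real
libraries.

What the generator deliberately does **not** emulate: sequencing errors,
adapter remnants, quality scores, expression structure beyond a single
dispersion parameter, genome repeat structure beyond the designed motif,
and cross-mapping between loci. Tests passing on these simulations
therefore demonstrate correctness of the analysis logic under the stated
generative model, not robustness to artefacts of real sequencing data.

## Beta-elimination as copy dropout

`apply_beta_elimination()` models the treatment at the ligation step:
each copy survives a Bernoulli draw with probability `p_meth`
(methylated, default 1.0) or `p_unmeth` (unmethylated, default 0.1), and
species with no surviving copies leave the library. Shortened
unligatable molecules are never emitted as reads, because the chemistry
removes them from the sequencable pool rather than shortening the
observed sequence. `p_unmeth` is a free parameter, not a measured value:
published libraries show strong depletion rather than complete
elimination of unmethylated species (a prominent unmethylated 22G siRNA
retains roughly 20% of its normalized reads after treatment), so 0.1 is
of the right order; the model requires `p_unmeth <= p_meth` because
methylation protects.

## Mapping and classification

Reads are placed by **exact** matching on both strands; the published
pipelines this emulates used an exact-match short-read mapper whose
mismatch settings are not stated, and exact matching is also what makes
untemplated-tail detection well-defined. `map_read()` reports all
placements achieving the maximal genome-templated 5' prefix length `k >=
min_prefix`; the 3' remainder is the untemplated tail. Because `k` is
maximal, a tail can never begin with a base templated at its placement.
`min_prefix` defaults to 15 nt: short enough to keep trimmed-and-tailed
18-mers placeable, long enough that a 15-mer almost never matches a
50-kb reference by chance.

Classification applies rules in priority order: exact coordinate match to
an annotated mature miRNA; then 21-nt 5'U reads sense to a piRNA locus;
then 26-nt 5'G reads antisense to a 26G source locus (ERGO-1 before
ALG-3/4); then 22-nt 5'G reads antisense to any transcript locus;
otherwise `other`, or `unmapped` without a placement. Lengths are
evaluated on the templated prefix, so 3'-tailed reads keep their class;
3'-**trimmed** reads no longer satisfy the exact class lengths and fall
to `other`. That is a deliberate property of a strict
length-and-locus classifier, and it is why the truth-recovery test (>=
99% of copies assigned their simulated class) is run with trimming
disabled. The class labels partition the library, and multimapping reads
are tallied once (first placement in deterministic contig/start/strand
order) for library-level counts, once per feature for per-feature counts.

## Normalization, enrichment, and status calls

RPM uses each library's **total mapped copies** as denominator ("reads
per million total reads" is ambiguous between raw and mapped totals;
mapped is the documented choice here and the totals are recorded so
either can be reproduced). Per-feature enrichment is
`log2((rpm_treated + e) / (rpm_untreated + e))` with `e = 0` for features
observed in both libraries and `e = 1` RPM (flagged) for features at zero
in exactly one; features absent from both are reported missing.
Per-class ratios divide summed RPM over all reads of the class, using all
genome-mapping copies as denominator. Status calls use a threshold of 0
by default — strict sign, with ties called `unchanged` — matching the
convention of shading everything below ratio 0 as depleted.
`percent_depletion(u, t) = 100 (1 - t/u)` reproduces the worked example:
1270 RPM untreated and 257 RPM treated give 79.8%, i.e. "~80% depletion".
`ddct_fold_change()` implements 2^-ddCt exactly;
`ddct_summary()` adds a dispersion range `[2^-(ddCt+SD), 2^-(ddCt-SD)]`
across replicates (the variance convention is a package choice).

## 3' trimming and tailing

`resolve_3prime()` anchors each call to the feature with the largest
overlap and expresses trimming relative to the annotated mature length
there: the miRNA annotation when present, otherwise the canonical class
length (21/22/26 nt) of the locus; `NA` when neither applies. The tailed
proportion of a class is tailed copies over all placed copies — the
tailed-plus-untailed denominator — and the trimmed proportion is reported
separately rather than guessing any combined "trimming and tailing"
quantity. Tail composition (fraction of tailed copies by first tail
nucleotide) is reported descriptively only.

One interaction worth knowing: with the default 18-28 nt size window, a
26-nt species carrying a 3-nt tail is 29 nt and is removed by size
selection, so the **observed** tailing rate of 26-mers sits below the
generative rate — exactly as gel size selection would bias a real
library. The rate-recovery analysis therefore caps simulated tails at 2
nt; the decomposition itself reproduces the simulator's truth exactly.

## Guide-target rules

Pairing states are per guide position (1 = 5' nt): `W` (Watson-Crick),
`G` (G:U wobble), `M` (mismatch), `D` (guide bulge), `I` (target bulge).
G:U counts toward the complementarity fraction `(#WC + #GU) / L` but is
tracked separately — the 0.692 figure for the designed guide is only
reached with wobbles counted as paired, and scanning emits the wobble
count so a WC-only accounting can be derived. With one bulge allowed,
the placement maximizing paired positions is chosen, ties broken toward
the guide-3'-most bulge; a target bulge is recorded **at** the adjacent
guide position (one position of the state vector is spent on the `I`
marker, so a perfect-with-insertion site reads 21 W + 1 I over a 22-nt
guide). At most one bulge per site is supported.

`predict_silencing()` distils the sensor mutagenesis into an ordered rule
table: any defect within positions 1-5 is nonfunctional; a full mismatch
block at 12-14 is nonfunctional; a full mismatch block at 9-11 is
partial; a single target bulge within 13-15 is partial; a single
mismatch or guide bulge at 13 as the only defect is functional;
mismatches confined to 20-22 are functional; otherwise the
complementarity threshold (default 0.69, from the designed trans-acting
sites) decides. Mapping fluorescence categories onto three levels is an
abstraction: "only a very modest increase" (single target deletion at 13)
is mapped to functional while a single target insertion is mapped to
partial — a documented judgment call at the boundary between "modest"
and "partial".

`scan_transcript()` slides every window (ungapped by default), keeps
windows at or above the complementarity threshold, and reduces
overlapping candidates to local maxima (highest complementarity, ties to
the leftmost window). On transcripts of a few kb this is exhaustive
enumeration, and the tests compare it against an independent per-window
recount.

A note on symmetry: swapping guide and target roles preserves the state
multiset, but reverse-complementing both strands does **not** preserve
G:U wobbles (a G:U duplex complements to A:C); only the Watson-Crick
pair count is invariant under that operation, and the tests assert
exactly that.

## Determinism and numerical choices

Every generator is a pure function of (configuration, seed);
`run_pipeline()` fans one base seed out per stage and records seeds,
configuration, record counts, and file digests in a JSON manifest, so a
rerun with the same configuration is byte-identical. Tie-breaks are
deterministic everywhere (placements ordered by contig/start/strand,
leftmost window on scan ties, 3'-most bulge on alignment ties). Problem
sizes used by the shipped analyses — ~2x10^5 copies per library, 20
replicates for the enrichment pattern, a 50-kb reference and 1,000 reads
for the mapper oracle, ~10^4 copies per class for rate recovery — were
chosen to keep every stage in seconds-to-a-minute on one CPU while
leaving binomial noise well inside the tested tolerances.

## Known limitations

Exact matching cannot place reads carrying internal sequencing errors or
SNVs; trimmed reads are not recovered by the strict classifier; at most
one bulge per guide-target site; no thermodynamic scoring; the
beta-elimination model has a single survival parameter per methylation
state rather than species-specific ligation efficiencies; and none of
the wet-lab observables (fluorescence, brood sizes, blots) are modelled.

```{r example, eval = FALSE}
# a complete run
run_pipeline(default_config(seed = 42), outdir = "run42")
summarize_run("run42")$class_ratios
```
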