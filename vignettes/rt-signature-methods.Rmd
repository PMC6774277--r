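---
title: "RT-signature profiling and modification calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-signature profiling and modification calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsig)
```

## The measurement model

Reverse transcriptases stumble on RNA residues whose Watson–Crick face is
chemically blocked. For 1-methyladenosine (m¹A), three event classes are
observable after alignment of the cDNA reads:

* **arrest** — synthesis aborts when the enzyme reaches the modified
  residue, so the truncated read's 5′-most aligned base is the position 3′
  of the site. In a pileup this is a coverage drop from position *i+1*
  (reached first, since the enzyme reads 3′→5′) to position *i*.
* **misincorporation** — a wrong dNTP is built in opposite the modified
  base, seen as a reference mismatch at the site.
* **jumps** — the enzyme skips one or two template nucleotides, seen as
  alignment deletions of length 1 at the site (*direct*), length 1 at the
  −1 neighbour (*delayed*), or length 2 covering the site and its −1
  neighbour (*double*).

`compute_profile()` turns a pileup into one record per covered reference
position holding the strand-split base counts, coverage, the 3′-neighbour
reference base (*prebase* — the base the enzyme encounters immediately
before the site, a known modulator of signature strength), and five rates.

### Rate definitions and their denominators

Coverage `cov` counts aligned bases only; deletion placeholders are
excluded. This convention is forced by the identity `cov = A+G+T+C+N+
a+g+t+c+n`, which the package checks on every row it reads or writes.

The jump denominator is the *spanning-read* count
`span = cov + direct + double`: reads deleted at the position still span
it physically, while delayed-jump reads already contribute an aligned base
to `cov`. Across curated example rows with nonzero jump rates, this is the
unique simple denominator under which the implied deletion counts are
integers that reproduce the published rates at all five printed decimals;
that integer-consistency argument is encoded as a test rather than left as
prose.

Arrest is `clamp(1 − span(i)/span(i+1), 0, 1)`, i.e. the fraction of reads
that reached *i+1* but produced no base or deletion at *i*. Using `span`
rather than raw `cov` on both sides keeps jump reads from inflating
arrest. When *i+1* is absent or empty the rate is 0 — with no information
about what the enzyme did next, claiming arrest would be arbitrary. A
`--arrest-simple` mode (`arrest_mode = "simple"`) computes the plain
coverage ratio for comparison. On some published rows adjacent to strong
sites, no simple coverage-ratio formula reproduces the printed arrest
value from printed quantities alone (the exact upstream read subset is not
recoverable); we document our formula, show it reproduces the reference
row at the m¹A site exactly, and deliberately do not tune it cell by cell.

Rows with `cov` below `min_cov` (default 1) are suppressed; rates at zero
coverage are undefined, so zero-coverage positions never produce a row.

## Overhang trimming

The supported library-preparation protocol C-tails the cDNA 3′ end;
residual tail bases can survive adapter trimming and then align as
terminal mismatches, mimicking modification signatures. The trimmer
reconstructs per-read linkage purely from the pileup (slot order is
preserved across consecutive columns; `^` inserts a slot, `$` removes it)
and then deletes terminal bases while they mismatch the reference, up to
`max_iterations` (default 10) per terminus.

Design choices worth spelling out:

* **Iteration, not a single comparison.** Tails longer than one base would
  survive a single-base rule; iterating while the new terminal base still
  mismatches removes the whole tail, and the cap bounds the damage.
* **Both ends by default.** Paired-end mates map in both orientations, so
  the cDNA 3′ terminus can be either alignment end. Only mismatching bases
  are ever removed, which bounds collateral damage; `ends = "left"/"right"`
  is available for protocol-aware use.
* **Known collateral damage.** A genuine modification mismatch sitting
  exactly at a read terminus is indistinguishable from an overhang base
  and is removed (at most `max_iterations` bases). This is documented
  behaviour, not a bug to fix: the information to separate the two cases
  does not exist at the pileup level.

Trimming is idempotent, never touches non-terminal events, and in
simulations where every injected tail base mismatches the reference it
removes exactly the injected bases.

## Filtering

`threshold_filter()` splits the positions of one base of interest into
"likely modified" (coverage, mismatch and arrest all at or above their
thresholds) and "likely unmodified". `demeth_change_filter()` compares an
untreated reference against a treated sample (AlkB demethylation or the
alkaline Dimroth rearrangement erase the m¹A signature): a position passes
when the absolute mismatch drop `m_ref − m_trt` and the relative drop
`(m_ref − m_trt)/m_ref` and coverage all reach their thresholds (defaults
0.3, 0.5 and 250).

Directionality is deliberate: demethylation *lowers* the mismatch rate, so
negative changes never pass. The coverage requirement applies to **both**
samples by default — a rate estimated from an under-covered sample is
untrustworthy on either side of the comparison — with
`cov_scope = "either"` as the configurable alternative. Positions whose
reference mismatch is zero have an undefined relative change and are
skipped and counted in the attached skip report rather than erroring.
The output rows are taken from the treated sample, matching the use case
of reporting the post-treatment state of each surviving candidate. Both
filters are deterministic, order-independent, and monotone in every
threshold (property-tested on random profiles).

## The random-forest caller

Each profile row yields 15 features, all computable from the row alone:
the five rates; forward and reverse match fractions; the fractions of
reads showing G, T and C relative to coverage (for the adenosine rows the
caller targets, these are the misincorporation spectrum); `log10(cov+1)`;
and the prebase one-hot encoded over A/C/G/T, with `-`/other as all
zeros. We use four indicator columns rather than five because the fifth
category is the complement of the others; the schema is versioned and
stored with every trained model, and prediction refuses schema mismatches.

Class imbalance is handled by randomly downsampling the majority class to
a strict 1:1 ratio *before* cross-validation (seeded, without
replacement). Downsampling is the simplest scheme that removes the
majority-class bias of random forests — a bias that produces false
negatives for the modified class without necessarily showing up in
headline scores. Performance is estimated by stratified 5-fold
cross-validation repeated 10 times (defaults; both adjustable): within a
repeat the out-of-fold probabilities are pooled into a single AUROC, and
the report carries the per-repeat values with mean and standard deviation.
The final forest (500 trees by default) is refit on the full balanced set.
The decision threshold for binary calls is fixed at 0.5; AUROC itself is
threshold-free. With fewer minority instances than folds, training stops
with an explicit error — modifications that rare cannot support this
learning scheme.

When known sites are supplied, negatives are restricted to rows whose
reference base equals the modal reference base of the positives, so the
classifier compares like with like instead of learning to separate base
identities.

## The simulator

`simulate_pileup()` generates the data-generating process the profiler
assumes, so every estimator can be validated against known truth:

* reads start at the reference 3′ end and extend 5′-ward; at each modified
  site, surviving reads arrest with `p_arrest` (truncating the read at
  pos+1), skip one or two template bases with `p_jump1`/`p_jump2`, or
  align a base that mismatches with `p_mismatch` (drawn from a
  configurable distribution over the three non-reference bases);
* reads are split into forward/reverse strand populations
  (`strand_fraction`);
* with probability `overhang_prob`, a C-tail remnant of geometric length
  (mean 2, capped at 5 by default) is appended past the 5′-most aligned
  position — `C` on forward alignments, `G` (its complement) on reverse
  ones;
* the emitted pileup uses the full marker syntax (`^`, `$`, `-N` plus
  deleted sequence, `*`/`#` placeholders) and round-trips losslessly
  through the parser;
* background bases are error-free by default (`error_rate = 0`), because
  the profiler's baseline assumption is clean alignment; a uniform error
  rate is available to stress that assumption.

The truth table records realized per-site event counts next to the
generative probabilities, and the arrest/jump estimators recover those
realized fractions *exactly* (an accounting identity, tested as such),
while mismatch recovery is tested within three binomial standard errors.

What the simulator does **not** emulate — and hence what green tests do
not certify about real data: sequencing and alignment errors around
homopolymers, position-correlated modification clusters (dense tRNA
modification can blur neighbouring signatures), variable read starts from
RNA fragmentation, reference ambiguity between near-identical tRNA genes,
and PCR duplicates. Single-base resolution of all deletion placement is
also idealized; real aligners shift deletions within repeats.

Problem sizes in the shipped test-suite simulations (depths of 2 000–10 000
reads over 40–76-nt references, 20 planted sites, 100 random profile pairs
for monotonicity, 200+200 training instances for the separable-caller
check) were chosen as the smallest sizes at which the binomial tolerances
above are sharp enough to catch real estimator bugs.

## Numerical and I/O conventions

* Positions are 1-based throughout, following pileup convention.
* Rates are serialized with five decimal places; counts as integers. A
  profile write/read round trip is exact at that precision.
* The pileup parser trusts the tokenized events over the depth column
  (warning on disagreement), consumes `^`'s mapping-quality character
  blindly (it can be any printable character, including `$` or `^`), and
  treats base qualities as opaque — no quality filtering anywhere.
* Deletion placeholders are written strand-aware (`*` forward, `#`
  reverse, the samtools `--reverse-del` convention) so strand survives a
  round trip; plain `*` input parses as forward.
* Seeds are mandatory for every stochastic operation; there is no
  wall-clock seeding. Derived seeds stay below 2³¹.
* Ties in the AUROC rank computation get midranks (Mann–Whitney
  convention), verified against an independent ROC implementation.

## Known limitations

The package is splice-unaware by design (its domain is short, contiguous
references such as tRNAs), starts at pileup level (adapter/UMI trimming
and alignment are upstream concerns), models no insertion-rate statistic,
and its two-sample filter is purely threshold-based — a deliberate match
to established practice rather than a statistical test with error control.
Dense modification clusters and low-coverage sites degrade signature
quality in ways no amount of downstream modelling fully repairs; the
coverage thresholds exist precisely to keep such positions out of the
candidate lists.
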