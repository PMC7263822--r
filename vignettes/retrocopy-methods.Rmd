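---
title: "Models and methods behind retrofossil"
author: "retrofossil authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrofossil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrofossil)
```

`retrofossil` packages the computational machinery needed to study
retrocopies of the APOBEC3 (A3) cytidine deaminase family: a neutral
ORF-decay simulator with a retention test, annotation of candidate
retrocopy loci, an exact-match expression counter, and a labelled
synthetic-data generator. This vignette explains the models, the
parameters that matter, the numerical conventions, and what the package's
tests do and do not demonstrate about real data.

## The neutral ORF-decay model

A retrocopy is born as a faithful cDNA copy of its parent mRNA and —
absent selection — accumulates mutations freely. The simulator asks: if an
ORF of length $L_0$ evolves neutrally for $T$ years, what is the
probability that it is still *intact*? Intact means (i) the sequence still
has its original length, (ii) it begins with ATG, and (iii) no complete
codon strictly before the final codon is a stop (TAA/TAG/TGA). For
sequences whose length is not a multiple of three, the trailing partial
codon is the final codon — it can never hold a stop, so every complete
codon is checked. Requiring the start codon is a deliberate reading of
"still open": a destroyed ATG counts as loss; it can be disabled with
`require_start_codon = FALSE` in `simulation_config()`.

Three event types act per site per generation: substitutions at rate
$\mu_s$, 1-bp insertions at $\mu_i$, and 1-bp deletions at $\mu_d$.
Substitution sites are uniform and the replacement base is uniform over
the three alternatives (a Jukes–Cantor-like model — the simplest model
consistent with a single scalar rate; no CpG/context effects, no
codon-usage awareness). Indels are fixed at 1 bp: the cited rates are
scalar per-site rates with no length distribution, and 1 bp is the minimal
frameshifting unit, which also makes the length-change criterion sharp.

Rather than sweeping every generation (which would be $\sim 10^5\times$
slower at no accuracy gain), the engine draws per-event-type Poisson
counts for each census interval $\Delta$ (default 50,000 years) with mean
$\mu \cdot L \cdot \Delta / g$, where $L$ is the *current* sequence length
and $g$ the generation time in years, then applies the events in random
order at uniform positions. Intactness is re-evaluated on the current
sequence at every census — there is no latching, so a back-mutation can in
principle restore an ORF (this is vanishingly rare but keeps the model
honest). A sequence that reaches length zero is counted not-intact from
then on. For substitution-only evolution over one interval the model has a
closed form: the intact probability is
$\sum_k \mathrm{Pois}(k; m)(1-f)^k = e^{-mf}$ with $m$ the expected
substitution count and $f$ the fraction of single substitutions that break
the ORF; the test suite verifies the engine against this form with $f$
computed by exhaustive enumeration of all $3L$ single substitutions.

The replicate engine is compiled (Rcpp) and draws from R's global RNG, so
a `seed` in `simulation_config()` makes trajectories bit-reproducible.
Replicates consume the RNG stream sequentially; the engine is
single-threaded, which keeps determinism trivial. 10,000 replicates of a
1,150 bp ORF over 50 My run in well under a minute on one core.

### Parameter presets

`mutation_preset()` bundles the three published per-species parameter
sets (rates per site per generation, generation time in years):

| preset | $\mu_s$ | $\mu_i$ | $\mu_d$ | $g$ |
|---|---|---|---|---|
| `human-like` | 1.16e-8 | 2e-10 | 5.5e-10 | 25 |
| `mouse-like` | 5.4e-9 | 1.55e-10 | 1.55e-10 | 0.3 |
| `nwm-like` | 8.1e-9 | 1.55e-10 | 1.55e-10 | 1 |

The `nwm-like` (New World monkey) set pairs the night-monkey substitution
rate with the mouse indel rates and a 1-year generation time. Indel rates
have not been measured for NWMs, so the mouse values stand in; the 1-year
generation time is the short end of the 1–9-year maturation range reported
for these species and therefore the *fastest*-decay (most conservative for
retention claims) choice. Both are overridable in `mutation_params()` or a
YAML/JSON config (`read_sim_config()`; see
`inst/extdata/nwm_sim_config.yaml`).

### The retention test

`retention_test(age, orf, params)` reports the simulated neutral
probability that an ORF of this length is intact at the given age, and
flags an observed *intact* retrocopy as a "candidate selected" when that
probability is below a threshold (default the 5th percentile). Under the
`nwm-like` preset, fewer than 5% of 1,150 bp ORFs remain intact past
roughly 4–5 My and essentially none past 20 My, so any intact retrocopy
dated to 20 My or more is flagged. `retention_percentiles()` reports the
first census at which the intact fraction falls to each requested
percentile; crossings are census times, so their resolution is
$\Delta$.

## Annotation of candidate loci

Coordinates are 1-based inclusive everywhere (the R/Bioconductor and GFF3
convention); minus-strand hits are stored with ascending genomic
coordinates and a strand flag, and parent-mRNA coordinates always ascend.

**Merging and clustering.** Candidate hits (12-column tabular files, or
the built-in `find_hits()` exact 15-mer seed-and-extend matcher, which is
adequate for synthetic genomes and deliberately not a sensitive homology
search) are first chained into contiguous loci: same contig and strand,
genomic gap at most `max_gap` (50 bp), collinear mRNA coordinates. A
second, coarser pass (`cluster_gap`, 5 kb) unites collinear loci into one
candidate region — the seed islands of a diverged retrocopy, or the exon
hits of the parental gene across its introns. 50 bp separates alignment
noise from biology; 200 bp (`min_intron`) is the smallest excess gap
treated as an intron.

**Intronless classification.** For every parent exon–exon junction
covered by a region (with at least 8 bp of aligned mRNA on each side — the
margin stops a chance 1–2 bp extension past a junction from counting as
coverage), the genomic alignment either bridges the junction contiguously
or shows an intron-scale excess gap. Any intron-scale junction classifies
the region as the parental gene (`FALSE`); bridging at least one junction
with none classifies it intronless (`TRUE`); a region covering no junction
is indeterminate (`NA`) — single-exon evidence cannot distinguish a
retrocopy from a parental fragment.

**Truncation.** `truncation_5p` is simply the first parent-mRNA position
covered minus one; short retrocopies made by target-primed reverse
transcription show the characteristic 3′ bias this measures.

**Mapping inactivating mutations.** `map_inactivating_mutations()` aligns
retrocopy nucleotides to the parent protein (terminal stop included as
`*`) with a three-state Gotoh dynamic programme whose match state may
consume 3 nt (a codon), 4 nt (frameshift insertion) or 2 nt (frameshift
deletion), the latter two at a frameshift penalty (default 15).
Substitution scores are BLOSUM62 at codon granularity; gaps are affine at
codon granularity (first codon `gap_open + 3*gap_extend` = 14, further
codons 3). The alignment is local on both axes — one best block — so
5′-truncated copies, unalignable UTR overhangs and mid-codon truncation
remainders cost nothing and generate no artifact events. Reported events
are premature stops (an aligned codon translating to `*` before the
parent's terminal stop) and ±1-nt frameshifts, in 1-based parent codon
coordinates. Ties resolve deterministically (match > frameshift > gap,
then leftmost). Alignments scoring below `min_score` (default 100, far
above the ~40 expected for the best chance block of unrelated sequence at
this scale and far below the thousands scored by genuine copies) are
reported `"unalignable"` — which is also how complex cases such as nested
retrocopy insertions surface, rather than being resolved.

Two identifiability limits are worth knowing. A lone 1-bp indel is
localisable only to within one codon: when the shifted reading of the
neighbouring codon scores equally, the optimal placement is ambiguous, and
the tests assert frameshift positions to ±1 codon (stop positions and
event counts are exact). And a stop codon immediately abutting a
frameshift can be absorbed into the shift.

**Motifs and synteny.** `detect_deaminase_motifs()` scans for the
zinc-coordinating H-x-E … C-x-x-C arrangement of each A3 deaminase domain;
the spacer window (default 20–40 residues between the end of H-x-E and the
start of C-x-x-C) brackets the ~25–30-residue spacer of real A3 domains.
Unpaired C-x-x-C motifs are reported as partial hits. `synteny_support()`
compares flank-gene name lists (conventionally within 1 Mbp either side)
between two species: shared names on both sides, one side, or none.

## Expression counting

The published filter — keep a read only if it matches a queried sequence
at 100% identity over its entire length and maps uniquely to one of them —
fully determines the result, so the filter alone is implemented:
`assign_read()` returns the unique reference containing the read as an
exact substring (forward or reverse complement; strandedness of public
datasets is rarely knowable, so both strands count by default and the
behaviour is toggleable), `"multi"` when two or more match, `"none"`
otherwise; reads containing N never match; paired mates are independent
reads. Counts conserve: assigned + multi + none = total, per dataset.
`build_matrix()` averages counts within (species, tissue) and presents
log10(count + 1), with tissue columns grouped germline → brain → blood →
other, matching how such data are usually displayed.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with every label recorded:

* **Parent**: a 384-residue A3G-like protein (the length of the
  full-length A3G ORF), starting with M, carrying two planted HxE…CxxC
  motifs (N-terminal domain near residue 65, C-terminal near 255,
  28-residue spacers), resampled until the motif scan reports exactly the
  planted domains; reverse-translated with uniform synonymous codons,
  given short UTRs, split into 4 coding exons with 300–3000 bp introns,
  and embedded in background sequence.
* **Retrocopies**: each copy is the parent mRNA, full-length with
  probability `p_full` (default 0.6) or else 5′-truncated by a geometric
  draw (mean 300 bp) — a minimal model of the observed 3′ bias; ages
  default to uniform over 0–25 My, the span of the NWM radiation over
  which these retrocopies were continually born. Copies evolve for their
  age with a pure-R event loop deliberately independent of the compiled
  replicate engine (the cross-module consistency test compares the two
  implementations). `orf_constrained` copies reject any ORF-breaking
  event (indels in the CDS; substitutions creating a premature stop or
  destroying the ATG) — rejection sampling is the simplest mechanism that
  *guarantees* the retained-ORF phenotype; it is not a fitness model.
  Constrained copies are forced full-length so the phenotype is well
  defined.
* **Reads**: error-free, uniform positions, forward strand, recorded
  per-copy truth counts.
* **Background**: i.i.d. uniform nucleotides with 6 kb flanks. No repeat
  structure, no TSDs/poly-A, no sequencing error — adequate for
  exact-match and alignment testing at desk scale, and the reason passing
  tests bound algorithmic correctness rather than performance on real
  genomes (repeats create multi-mapping and spurious seeds that this
  background cannot produce).

## Problem sizes and numerical choices

The shipped tests run the decay acceptance simulation at full scale
(10,000 replicates, 1,150 bp, 50 ky censuses to 40 My — this takes
seconds) and the cohort tests at 150–400 copies; Monte-Carlo assertions
use 3-standard-error tolerances throughout. The generator-versus-engine
consistency check runs at 2 My of divergence, where the intact fraction
(~0.2) gives the comparison statistical power; at 20 My both routes are
pinned near zero and the comparison would be vacuous, so that regime is
exercised instead by the retention-flagging test (200 copies at 20 My:
all constrained copies intact and flagged, ≥90% of neutral copies
broken). Oracle-agreement tests (longest ORF, motif scan, read
assignment, percentile scan) run ≥1,000 randomised instances each against
brute-force reference implementations.

## Known limitations

* The mutation model ignores context effects (CpG hypermutability),
  codon-usage bias and indels longer than 1 bp; rate heterogeneity along
  the sequence is not modelled.
* "Same length" is checked at census resolution: a deletion and an
  insertion within one census interval that restore the length with an
  intervening frame disruption are undetectable by construction.
* `find_hits()` is an exact-seed matcher for synthetic genomes, not a
  replacement for a sensitive genome-scale search.
* Frameshift events are localised to ±1 codon (see above); nested
  retrocopy insertions are flagged unalignable, not resolved.
* Divergence dating, phylogenetics (tree building), and selection tests
  on real alignments (dN/dS, RELAX-style analyses) are out of scope.
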