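---
title: "Detecting and validating chromosome-end extension from optical maps and long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating chromosome-end extension from optical maps and long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloforge)
```

## The problem

Human chromosome ends are the worst-assembled parts of the reference genome:
subtelomeres are mosaics of segmental duplications shared between the tips of
different chromosomes, and individual genomes carry heritable structural
polymorphism there — terminal sequence missing relative to the reference,
or *extensions*: extra distal sequence, often a duplicated copy of another
chromosome's tip, occasionally a tandem amplification of the chromosome's own
terminal unit.

Optical genome mapping observes none of the base-level sequence. A nicking
enzyme marks its recognition sites ("labels") along DNA molecules hundreds of
kilobases long; the observable is an ordered list of label positions with
sizing error. That is enough to anchor an assembled contig to a reference
chromosome end, to measure how much of the contig extends past the reference
(or vice versa), and — because label-interval patterns are distinctive — to
ask where else in the genome an extension's label pattern occurs, i.e. which
terminus donated it. Long reads then validate candidate extensions at the
sequence level and resolve structures optical maps cannot, such as tandem
repeats of a unit comparable to the label spacing.

`teloforge` implements this entire analysis as a tested pipeline, together
with a synthetic-data generator that plants all of the structures with known
ground truth. Every claim the pipeline makes on synthetic data can therefore
be scored exactly.

## Label maps and the alignment model

A label map is an ordered set of label positions plus molecule length
(coordinates 0-based internally; the CMAP-dialect files on disk are 1-based).
In-silico digestion records every occurrence of the nicking motif *and of its
reverse complement* on forward coordinates; labels closer than 450 bp are
merged to their centroid, mirroring the pre-alignment merging of imaging
systems that cannot resolve them.

Two label maps are aligned by dynamic programming over monotone label
pairings. A matched interval pair of lengths $q$ and $r$ scores

$$ s(q, r) = m - \frac{(q - r)^2}{2\sigma^2}, \qquad
   \sigma^2 = \mathrm{sd}^2 + (\mathrm{sr}\cdot r)^2 $$

a Gaussian sizing-error log-likelihood against a match bonus $m$ (default 3).
Skipped interior labels are penalised per label ($m/2$ each by default), the
DP looks back at most 12 labels on either side, and in *endoutlier* mode the
unmatched terminal run of the query is free — the mode used throughout,
because a contig whose tip extends past the reference is exactly the signal
of interest. The relative sizing error defaults to `sr = 0.01`; the fixed
term defaults to 1 kb rather than zero because a zero fixed SD would make
short intervals infinitely precise.

Two implementation points deserve emphasis:

* **Exactness.** An alignment must report at least `min_labels` (default 3)
  matched labels to exclude degenerate one-pair hits. The naive DP is *not*
  exact under that constraint — a cell preferring a short high-scoring path
  hides a longer path the constraint requires — so the DP is layered by
  matched-pair count up to `min_labels`. For queries of up to 32 labels this
  layered DP is used together with full multi-match candidate enumeration,
  and it is verified against a brute-force enumeration oracle (all monotone
  pairings, both orientations) on hundreds of random instances. Whole-contig
  queries use the single-layer recursion and report the best path per
  orientation; their optima have far more pairs than `min_labels`, making the
  layering irrelevant there.
* **Spurious-hit control.** Production optical-map aligners suppress chance
  hits with a p-value model that is out of scope here. The emulation instead
  gates candidate alignments on *per-interval score quality*: a genuine match
  reproduces interval sizes to within the sizing noise (per-interval score
  close to $m$), while chance collinearity of a handful of labels leaves
  residuals at the label-spacing scale. Anchoring requires quality
  $\ge 0.95\,m$ per interval, origin classification $\ge 0.97\,m$; both are
  exposed as parameters. With the default noise model a true match loses
  only ~0.05 of $m$ per interval, so these gates sit far from the true-match
  distribution while rejecting the chance hits we observed in simulation.

## Calling chromosome-end status

The length threshold separating real structural difference from ordinary
label spacing is `mean + k * SD` of the adjacent-label distance distribution
(population SD, gap-spanning pairs excluded), with `k = 3`. On human-scale
nicking maps (mean 8.2 kb, SD 8.3 kb) this gives 33.1 kb; on a simulated
genome it is recomputed from that genome's own maps.

Per terminus, contigs aligned into the terminal window are ranked by
*distality first* (most distal matched reference label), then score, then
aligned span: a weaker alignment reaching closer to the tip anchors the
terminus. From the anchor we take the contig tail (distal of the last matched
label, including the unlabeled tail, since contigs carry length past their
last label) and the reference tail (distal of the last matched reference
label, minus N-gap bases for the missing direction). The reported values are
the *net* lengths

```
extension = max(0, contig_tail - ref_tail)
missing   = max(0, (ref_tail - N_bp) - contig_tail)
```

rather than the raw tails: the two tails past the last shared label represent
the same flank seen from both sides, and netting them makes the reference
called against itself yield exactly zero in both directions — a property the
test suite asserts for every terminus. Each net length is compared to the
threshold independently, so a rearranged terminus can be both extended and
missing.

Extensions are classified by realigning the extension's label subsequence
genome-wide with multiple matches: if an alignment covers at least half of
the extension labels (and passes the quality gate), the extension is
**category 1** and all qualifying origins are recorded with arm, span and
orientation; otherwise **category 2**. Extensions with fewer than
`min_labels` labels cannot be classified and default to category 2 with a
flag.

Trio inheritance compares the child's anchored terminal label sequence with
each parent's: the difference is the number of unmatched labels, on either
side, within the distal 10-label window (window size exposed; the criterion
is "no more than one label difference"). A parent within tolerance is the
parent of origin; both parents within tolerance are reported as `both`,
which is counted as consistent with either truth assignment. The same
windowed difference drives diploid-terminus detection: contigs anchored to
one terminus that differ by more than the tolerance are distinct alleles —
the heterozygous-extension situation in which a child carries an extended
allele from one parent and a reference-type allele from the other.

## Long-read validation and tandem structure

For a category-1 extension the predicted chromosome end is the chimera
`origin segment + N-gap + reference terminal segment`, all in terminus-distal
orientation (position 0 is the predicted tip; q-arm segments are
reverse-complemented into this frame). The default gap is the extension
length minus the origin's matched span, floored at zero.

Validation is deliberately alignment-free: exact shared k-mers (k = 16,
exposed) between read and prediction form a dotplot; greedy per-diagonal
chaining (gap ≤ 500 bp, diagonal drift ≤ 100 bp, segments ≥ 1 kb) formalises
how one reads such a plot by eye. The verdict is the fraction of the origin
part covered by chained segments (confirmed at ≥ 0.5 by default); an
internal uncovered run above 5 kb flanked by coverage is reported as an
internal deletion — the extension is real but more complicated than a simple
duplication. At long-read error rates up to ~10%, exact 16-mers still occur
every few bases along a true match, so chains survive with small gaps;
substitution-only read error is the generator default (an indel fraction is
available) and keeps diagonals exact.

Terminal tandem expansions defeat the chimera construction (the extension's
origin is the terminus itself), so they are read from a self-dotplot of the
read's terminal window: forward off-diagonal chains that are
*terminus-anchored* (reaching the window end — interspersed duplication
copies inside the window stop short and are ignored) have offsets at
multiples of the repeat unit. The unit is the approximate greatest common
divisor of the offsets (5% tolerance) and the copy count is
`1 + max(offset)/unit`, rounded. On a simulated allele carrying four copies
of its own terminal 11 kb unit, the estimator returns 4 copies of 11 000 bp
from an error-free read and from a 1%-error read alike.

## Duplication families and dating

The subtelomeric duplication analysis starts from a pair table (BED-like,
one record per unordered pair of homologous intervals). The *base-pair copy
number* of a position is the number of table entries overlapping it (both
sides of every pair count); the profile is kept run-length encoded and is
tested against per-base counting. Maximal runs with copy number ≥ 22 are
high-copy regions, ordered by length; for each region, every pair with a
side containing the whole region contributes both its intervals as family
members (copies merely overlapping the region are excluded), deduplicated.
Note the arithmetic this implies: a family of $n$ copies contributes depth
$n-1$ at each copy — the ≥ 22 depth at a real family core comes from the
unrelated partial duplication entries stacked on subtelomeres, not from the
family itself. The generator models this with a background of
partial-overlap pairs around the designated core locus, none of which spans
the core (so membership is unaffected).

Members intersecting the first or last 1 Mb of their chromosome are
subtelomeric; families with none are dropped. Enrichment of members in
subtelomeres is a one-sided exact binomial test with null probability
`subtel_bp / genome_bp` (an interpretation — the source analysis names no
test; a permutation alternative would condition on member lengths).
Pairwise divergence between copies is the percentage of mismatching aligned
columns with indel columns ignored entirely, computed from a global
alignment (match/mismatch/gap = 1/−1/−2, via `Biostrings::pairwiseAlignment`),
with a minimum-aligned-length filter. The molecular clock converts
divergence to age at 0.3% divergence between copies per Myr (3% per 10 Myr),
so 3% dates to 10 Myr and 0.79% to ≈ 2.6 Myr — within the human lineage.
The `≥ 22` threshold, the 1 Mb window and the clock rate are all parameters.

## The synthetic genome

The generator's defaults are the study conditions the rest of the package is
tested under:

* five chromosomes of 5 Mb, i.i.d. uniform A/C/G/T background — composition
  carries no signal for label- or duplication-based analyses;
* nicking motif `GCTCTTC` (Nt.BspQI-like 7-mer): ~1 label per 10 kb on random
  sequence, the spacing regime of human nicking maps;
* two duplication families, units 9 kb and 8 kb, 16 members each (the human
  copy count of both known subtelomeric families): fifteen subtelomeric
  copies — all oriented towards their chromosome end, as real subtelomeric
  duplications are — plus one interstitial ancestral copy, with per-copy
  divergence 0.5% (inside the 0.02–0.8% range observed between human
  subtelomeric copies);
* contig noise seeded from production aligner error parameters: fixed sizing
  SD 200 bp, relative 1%, false positives 0.6/100 kb, miss rate 6%,
  resolution 1450 bp. Interval errors are Gaussian, misses Bernoulli, false
  labels Poisson — the upstream description fixes only the parameters, not
  the generative model, so this model is a declared stand-in;
* long reads with substitution errors at 10% by default; terminal-anchored
  reads are generated on request so each terminus of interest is spanned,
  reported with the chromosome tip at the read end.

p-arm events reuse the q-arm code path by mirroring the chromosome into
terminus-distal orientation and back — one code path, consistent with the
"same orientation towards the chromosome end" convention of subtelomeric
biology. One master seed drives everything; per-stage seeds are derived
deterministically from the stage name, and reruns are byte-identical.

What the generator does *not* emulate: telomere repeat arrays, heterochromatin,
realistic karyotypes and chromosome-length variation, base-composition bias,
read-quality scores, and assembly itself (contigs are whole chromosomes with
map-level noise, not assemblies of molecules). Passing tests therefore
demonstrate the *logic* of detection, classification, inheritance and dating
under controlled noise — not performance on real BioNano or nanopore data,
whose error structure is richer.

## Numerical choices and degenerate inputs

* Centroid label merging rounds half up; merged centroids are provably more
  than the merge distance apart, so merging is idempotent.
* Population (not sample) SD for inter-label statistics; at genome scale the
  difference is negligible but it must be fixed for reproducibility.
* Anchoring ties break by score, then aligned span, then contig id;
  alignment-score ties effectively break towards fewer skips via the
  penalties.
* At least two usable adjacent-label pairs are required for inter-label
  statistics (the SD of one pair is degenerate).
* An empty genome yields an empty contig list; a terminus with no anchoring
  candidate is `excluded`, not an error; a dotplot of sequences shorter than
  k is empty; k-mers containing N never match.
* Event length 0 and tandem copy count 1 are identity transforms.
* The enrichment null probability is clamped to 1 (relevant only for toy
  genomes smaller than twice the subtelomere window).

## Scale of the shipped checks

The test suite runs the full pipeline on a three-chromosome, 800 kb-per-
chromosome noise-free trio (shared across test files), a two-chromosome noisy
determinism check, and one five-chromosome 5 Mb noise-free trio for the
planted-extension recovery; the aligner oracle runs 200 random instances of
up to 7 labels; the copy-number oracle 100 random pair sets. These sizes were
chosen so the whole suite completes in a few minutes while the 5 Mb run
exercises the same label densities (~500 labels per chromosome) as
human-scale maps.

## Running the pipeline

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 17)       # default simulated trio scenario
bundle <- run_end_to_end(cfg, outdir = "out")
bundle$scoring$status_accuracy          # terminus-status recovery vs truth
bundle$trio_consistency                 # inheritance recovery
writeLines(bundle$report)               # per-terminus paralogy report
```

A thin command-line wrapper (`inst/scripts/teloforge.R`) drives the same
function from a shell, with the simulation configurable through a YAML file
(`write_sim_config()` / `read_sim_config()`).

## Known limitations

* The interval-score form follows a one-sentence description of the
  production likelihood; absolute scores are not comparable to RefAlign's,
  and all downstream logic depends only on ranking.
* The quality gates stand in for a proper alignment p-value; on real data a
  calibrated significance model would be preferable.
* Contig-level simulation bypasses assembly, so assembly artefacts (chimeric
  joins, collapsed repeats) — a real source of false extension calls — are
  not represented.
* Real-data headline counts from the source study (numbers of extended
  termini, category-1 fractions, heritability percentages) require the
  original public datasets and are out of scope; the synthetic recoveries
  test the same machinery under known truth instead.
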