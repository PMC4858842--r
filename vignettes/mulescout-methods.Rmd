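---
title: "Methods: MULE discovery, dating and epigenomic profiling"
author: "mulescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MULE discovery, dating and epigenomic profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulescout)
```

## Scope

`mulescout` implements a complete desk-scale pipeline for the study of
non-autonomous Mutator-like transposable elements (MULEs) in plant
genomes: element discovery from terminal-inverted-repeat (TIR) evidence,
classification of genic elements and MULE-derived putative genes,
identification of parental (donor) loci, presence/absence dating across a
species phylogeny, divergence-based amplification dating, Ka/Ks
selection screens, and region-level epigenomic statistics (bisulfite
methylation, 24-nt siRNA occupancy, TE content, TIR similarity,
Marey-map recombination rates, expression-bias tests).  A seeded
synthetic-genome generator plants ground-truthed elements on the
phylogeny so that every stage can be verified end to end without any
external data.

## Element model and calling rules

A complete non-autonomous MULE is modelled as two TIR copies of one
family in opposite orientations, separated by an internal sequence, with
a 7–11 bp target-site duplication (TSD) immediately outside both TIRs.
The caller accepts a candidate pair only when

* both TIR hits belong to the same family,
* their orientations are opposite,
* their inner-edge distance is below 20 kb, and
* a valid TSD exists within a ±10 bp swing of the putative TIR ends.

TSD validity depends on length: a 7-bp duplication must be perfect, an
8-bp one may carry one mismatch or indel, and 9–11-bp duplications up to
two.  "Mismatches/indels" are scored as unit-cost Levenshtein edit
distance, the most literal reading of a mixed mismatch/indel allowance.
Among valid candidates the search keeps the one with the fewest edits,
then the longest duplication, then the smallest total offset; residual
ties resolve on the left, then right, offset.  This makes `find_tsd()`
a deterministic function of the sequence, which the test suite verifies
against an exhaustive scorer over every length × offset combination.

Pairing is a greedy deterministic left-to-right sweep: each unpaired hit
takes the nearest following valid partner, and a hit joins at most one
element.  The underlying conflict-resolution rule is a package choice —
nothing in the element model dictates one — and determinism was the
deciding property; the rule is stated here so downstream users know that
a different sweep order could pair borderline cases differently.
Elements overlapping a transposase protein hit at E < 1e-9 are flagged
autonomous and excluded from all downstream gene-centric analyses.

An element is *genic* when it overlaps at least 30% of the length of an
annotated transcript whose CDS is ≥150 bp with an intact ATG start, a
clean stop, and no internal stop codon.  The 30% denominator is the
transcript length (the sum of exonic length; the annotation model used
throughout carries single-segment CDSs).  The same ORF rules define
MULE-derived putative genes.

Candidate TIR families are screened the same way a de novo repeat
library would be: fewer than 20 genome-wide copies, ≥30% of the
consensus masked by known non-MULE repeats, or fewer than 5
TSD-validated elements all reject the family.

For synthetic genomes the TIR hits come from an internal two-tier scan
(exact full-length matching plus k-mer-seeded alignment verification at
≥80% identity over ≥80% of the consensus).  Real-data runs are expected
to import RepeatMasker `.out` or BLAST/PSL tables through
`read_intervals()`/`read_hit_table()`; E-value-based rules apply only to
imported tables, and PSL input (which carries no E-values) falls back to
identity/coverage proxies.

## Coordinates and formats

All internal containers are Bioconductor-native: `GRanges`/`IRanges`
with 1-based closed coordinates, `DNAString` sequence, `phylo` trees.
Conversion happens only at I/O boundaries (BED's 0-based half-open
starts, RepeatMasker's `C` orientation) and is involutive — writing and
re-reading any supported fixture reproduces it field for field.  This
choice trades the arithmetic convenience of half-open intervals for
direct access to the interval algebra (`findOverlaps`, `reduce`) the
rest of the stack is built on.

## Cross-species presence and Dollo dating

Presence of an element in another genome requires both an identity
criterion — the element's best hit covers ≥30% of its length — and a
synteny criterion: either the best hit lies on the element's home
chromosome with at least one of four flank probes (1 bp–1 kb and 1–2 kb,
up- and downstream) hitting within 4 kb of it, or at least two flank
probes hit within 4 kb.  Distances are measured between closest edges.

Origins are assigned by Dollo (single-gain, multi-loss) parsimony: the
element arose on the branch above the most recent common ancestor of all
carrier taxa; absences inside that clade are recorded as losses.  A
consequence worth stating explicitly: when presence is undercalled
(detection failures or genuine losses), the MRCA of the surviving
carrier set is necessarily a descendant of the true origin, so the
inferred origin can only be *younger* than or equal to the truth, never
older.  The test suite asserts exactly this one-sided guarantee.

The default 11-taxon tree covers the cultivated rices, their wild Asian
relatives, the African, American and Australian AA-genome species, the
BB-genome *O. punctata*, basal *O. brachyantha* and the outgroup
*Leersia perrieri*, with node ages (0.8, 2.5, 6.8 and 26 MY at the
Asian, AA, AA+BB and root nodes) matching the divergence windows that
define the evolutionary age groups: species-specific, Asian (<~0.8 MY),
AA (~2.5–6.8 MY), AB (~6.8–26 MY).  Age groups are assigned by clade
containment, so any branch inside the Asian clade maps to "Asian", etc.

## Divergence dating and selection

Amplification times come from the divergence of each element to its
closest same-family paralog: T = k/(2r), with k the Kimura
two-parameter distance

k = ½·ln(1/(1 − 2P − Q)) + ¼·ln(1/(1 − 2Q))

and r = 1.3 × 10⁻⁸ substitutions/site/year, the rice-calibrated neutral
rate (configurable).  The factor 2 reflects divergence accumulating
along both lineages since duplication.  K2P replaces a
maximum-likelihood baseml fit; the closed form is exact under the model
the generator simulates, and `ape::dist.dna(model = "K80")` serves as an
independent cross-check in the tests.  Saturated pairs (a non-positive
log argument) are reported as undefined rather than clamped.

Ka/Ks uses Nei–Gojobori (1986) counting: synonymous/nonsynonymous site
counts averaged over the pair, substitution pathways averaged for
multi-difference codons with stop-codon intermediates excluded,
Jukes–Cantor correction of both proportions, and a two-sided normal
test on Ka − Ks with binomial variances.  Mutations that would create a
stop codon are excluded from the site opportunity counts, matching the
fact that `codon_align_trim()` removes stop-bearing codon columns (and
gap-bearing ones, which restores frame across short indels) before
counting; pairs trimmed below 30 codons are untestable.  Significance is
controlled with Benjamini–Hochberg FDR — chosen over Storey's q-value
because it has no tuning parameter — and calls are made only at
q ≤ 0.05.  One degenerate corner: a single synonymous difference on a
single codon saturates the Jukes–Cantor correction (one difference over
a third of a site trio), so Ks is undefined there; on any realistic
alignment length the estimate is finite.

## Methylation, sRNA and recombination statistics

A region's methylation level in a context (CG/CHG/CHH) pools counts
over cytosines covered by ≥3 reads: Σ methylated / Σ total.  Regions
where fewer than 50% of the context's cytosines are mapped are
undefined, and a region with no cytosine of the context at all is
flagged distinctly.  The pooled (read-weighted) estimator is the
standard choice for bisulfite region summaries; a site-binary mode
(site methylated if ≥1 methylated read) is exposed because the
per-region percentage is sometimes computed that way.  Raising the
coverage floor can only shrink the mapped set, so the count of defined
regions is non-increasing in the threshold — asserted as a property
test at ≥3/≥5/≥7 reads.

Meta-profiles bin each element into 500-bp flanks (fixed 50-bp
windows), 10 proportional bins per TIR and 20 across the internal
region; these bin counts are a presentation choice with no analytic
consequence.  Bins receive the mean of defined per-element levels, and
bins with fewer than 10 contributing elements are flagged.

TIR similarity is identical aligned bases divided by the left TIR
length after a global alignment (match +1, mismatch −1, gap open −2,
extend −0.5) of the two copies co-oriented (the right TIR is
reverse-complemented first).  TE content of an internal region is the
merged union length of non-MULE repeat hits over the internal length.
sRNA occupancy filters to 24-nt species and, by default, to species
mapping to a single genomic location; both summed read abundance and
distinct species counts are reported because "number of small RNAs" is
ambiguous between the two.

Recombination rates come from a Marey map: markers with multiple
genomic placements are dropped, then anomalous markers are removed one
at a time against an isotonic preliminary fit until no residual exceeds
3 robust SDs (MAD).  One-at-a-time removal matters: a gross outlier
distorts the monotone fit for its whole neighbourhood, and batch
removal would discard genuine markers with it.  The robust scale is
floored just above float precision so that perfectly collinear maps are
left untouched.  The local rate is the analytic derivative of a local
quadratic (tricube-weighted, span 0.2 of markers — LOESS with degree 2)
evaluated at the query midpoint, clamped at zero; evaluations outside
the marker range are flagged as extrapolation.  On an exactly linear
map the local quadratic reproduces the slope to machine precision,
which anchors the 1%-recovery test.

Expression: FPKM = count / ((exonic kb) · (library size in millions));
a gene inherits an FPKM value only from regions overlapping ≥50% of its
length, taking the maximum across qualifying regions (a conservative,
order-independent rule for a case the upstream tooling leaves
unspecified), and FPKM > 0 defines "expressed".  Tissue bias is a
two-sided Fisher exact test on expressed/unexpressed × set membership.

## The synthetic-genome generator

`simulate_genomes()` builds one ancestral chromosome carrying GC-rich
donor genes (intact ATG…stop ORFs) in a GC-poorer background, assigns
each planted element to a tree branch, and emits one genome per taxon
in which the element appears at its orthologous site in exactly the
descendant taxa.  Insertion duplicates the 7–11 bp target site verbatim
on both sides; downstream coordinates shift accordingly, and the truth
table records every TIR/TSD/internal interval per carrying taxon.
Defaults emulate the study conditions the pipeline is meant for: 2 Mb
per taxon on the 11-taxon tree, 50 clean elements per terminal taxon,
TIR consensi of 150–250 bp, internal regions of 0.8–2.5 kb, 40% capture
rate, ~10% autonomous and nested-TE fractions, r = 1.3 × 10⁻⁸ per site
per year with a transition:transversion event ratio of 2 when branch
mutation is enabled.

Two generator details are deliberate design decisions rather than
conveniences.  First, insertion sites are redrawn when flanking-base
coincidences would create a longer perfect duplication outscoring the
planted TSD under the documented tie-break: roughly 40% of uniform
random sites have such a coincidence (a one-base extension matches with
probability ~1/4 per side), and at those sites *no* caller could
recover the planted TSD as "the" TSD because the ground truth itself is
ambiguous.  Clean planted truth means unambiguous planted truth.
Second, elements that can co-occur in one genome are kept ≥5 kb apart
(with a 200-bp global guard between any two sites) so flank probes and
pairing are not confounded; non-co-occurring elements may sit closer.

`evolve_sequence()` applies a Poisson number of K2P substitution events
at uniform positions, allowing multiple hits, so the K2P-corrected
distance to the ancestor is an unbiased estimate of r·T.
`simulate_methylome()` draws per-site Poisson depth and binomial
methylated counts at region-specific target levels, with contexts read
from the actual sequence on both strands.  `simulate_srna_and_expression()`
produces 24-nt (plus a minority of 21/22-nt) species with configurable
multi-mapping fractions, and Poisson per-tissue expression counts.

What the generator does **not** emulate: read-level sequencing error,
indel-rich or recombining evolution, nested coordinate shifts from
TE-in-TE insertions into already-planted elements, selection, or
realistic repeat landscapes.  Passing tests therefore demonstrate that
the algorithms implement their rules correctly and recover planted
signal under the stated noise models — not that real genomes satisfy
those models.

## Problem sizes used by the checks

The element-calling check runs the full default scale (11 × 2 Mb, 550
planted elements).  Dating uses 50-kb alignments, 10–15 replicate pairs
per planted age (0.5/2/6 MY).  The neutrality check runs 100–200
500-codon pairs at 10% per-site mutation — long enough that the
Jensen-type upward bias of a ratio with a noisy denominator stays well
inside the ±0.1 band.  The direction-of-effect study plants 110
elements per age group on a 6-Mb chromosome with 250 genes, capture
donors confined to the high-recombination half of the chromosome, and
planted levels 0.35/0.50/0.65 (internal, by age), 0.45/0.30/0.15 (TIR
CHH, by age), sRNA abundances 50/30/12, and pollen expression
probabilities ~0.7 vs ~0.3.  These magnitudes are chosen as plausible
for rice-scale data; the qualitative directions, not the magnitudes,
are what the assertions test.

## Interface

The exported functions and this vignette are the interface; a typical
run chains `plant_config() |> simulate_genomes()` (or `read_intervals()`
/`read_hit_table()` on real tables) into `call_mules()`,
`call_mule_derived_genes()`, `assign_origin_branch()`,
`amplification_time()`, `ng86_kaks()` and the region statistics, as the
README's worked example shows.
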