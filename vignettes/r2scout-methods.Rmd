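---
title: "r2scout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{r2scout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

R2 retrotransposons are non-LTR mobile elements that insert
site-specifically into the multicopy 28S ribosomal RNA genes of animals by
target-primed reverse transcription (TPRT): the single element-encoded
protein nicks the first DNA strand at a conserved 28S position (the
canonical nick site) and primes reverse transcription of the element RNA
from the nick. Curating these elements from genome assemblies means
answering, for every candidate locus: does it sit at the 28S target site
(and at what offset from the canonical nick)? is it full-length or
5'-truncated (the typical TPRT degradation mode)? what is the N-terminal
domain architecture of its protein (which zinc fingers, how many Myb
domains)? are the reverse-transcriptase (RT) motifs intact? and which of
the two deep R2 lineages -- A (typically three N-terminal zinc fingers) or
D (typically one) -- does its RT descend from?

`r2scout` implements that curation pipeline end to end, together with a
synthetic-data generator that produces rDNA arrays with embedded elements
and known ground truth, so that every stage has a closed testing loop that
never requires downloading genomes.

# The synthetic-data generator defines the test conditions

`make_reference_rdna()` lays out one rDNA unit (18S-like, ITS-like,
28S-like segments; defaults 1800 + 700 + 3800 nt) and annotates the
canonical nick position inside the 28S-like segment (default 1900). The
nick position is configuration, not a constant: the biological coordinate
depends on which 28S reference is used, so the generator and the junction
analysis share whatever position the reference declares.

`element_spec()` + `make_element()` build elements from editable motif
templates (`inst/extdata/motif_templates.tsv`): zinc fingers assembled from
the grammar below, a Myb helix-turn-helix consensus, RT motifs 0-7, an
RLE endonuclease block and a thumb-zinc-knuckle, joined by random linkers
to a requested ORF length (default 1100 aa, comfortably above the 900-aa
filter). The templates are synthetic consensi designed to satisfy the
package's own detectors -- self-consistency by construction, since no
curated consensus sequences are bundled; users with curated profiles can
replace the file. Three design
choices matter:

* Linkers never contain C or H, so the zinc-finger grammar cannot fire
  inside them; all C/H containing segments are intentional.
* RT inter-motif linkers are not free random sequence: they descend from
  the lineage-A or lineage-D synthetic reference RT (lightly diverged, 0.2
  substitutions/site by default, again C/H-free). This is what gives the
  PSSM lineage placement a recoverable signal, mirroring the fact that
  real lineages share linker ancestry, not just motif ancestry.
* The ORF is bracketed by in-frame stops and does not begin with
  methionine, reflecting the non-canonical translation of R2 ORFs; ORF
  extraction therefore looks for maximal stop-free stretches, not
  ATG-initiated frames.

`build_genome_and_truth()` plants site-specific elements at
`nick_pos + insertion_offset` of distinct tandem units (at most one per
unit), Myb-less (Utopia-like) elements at a separate U2-like repeat locus,
and non-site-specific homologs in random sequence with variable flanks.
5'-truncated copies lose their first `truncate5_nt` nucleotides and
receive a random junk spacer upstream, emulating the interrupted-TPRT
truncations seen in real arrays. One generator subtlety: the junk spacer's
terminal base is drawn to differ from the element base it replaces.
Without this, the ground-truth start coordinate would be ill-defined under
local alignment (a coincidentally matching junk base genuinely belongs to
the optimal alignment), and "exact boundary" would not be a meaningful
target. A misassembly mode splits one element across two contigs with
chimeric junctions to exercise the read-rescue path.

`simulate_reads()` samples reads uniformly over positions and strands with
independent per-base substitution and indel errors (each capped at 0.3).
`evolve_on_tree()` evolves proteins along a tree under the model below.

What the generator does **not** emulate: rDNA unit heterogeneity and copy
number variation, promoter structure, nested or fragmented older element
copies, compositional bias, sequencing error profiles with
context-dependent indels (homopolymer-biased errors are only partially
represented through uniform indels), and alignment-relevant features such
as profile-specific gap structure. Passing the synthetic round trips shows
the machinery is self-consistent and exact where exactness is claimed; it
does not show field performance on diverged real genomes.

# Discovery

`scan_genome()` is a two-stage seeded search: exact k-mer seeds (default
word size 7 in nucleotide mode, chosen to match sensitive BLASTN-style
searching; 3 in translated mode over all six frames) are chained when
co-linear on nearby diagonals (drift <= 30 nt, subject gap <= 300 nt,
backwards jumps break a chain), and each chain is screened by a cheap
ungapped diagonal extension (best contiguous run, Kadane's algorithm)
before any gapped alignment is spent on it. Surviving chains are extended
by affine-gap Smith-Waterman (`local_align()`, Gotoh algorithm in C++)
of the query against the spanned segment. Default nucleotide scoring is
+2/-3 with gap cost `5 + 2k` for a gap of length k, BLAST-like conventions;
protein mode uses BLOSUM62 half-bits with `11 + 1k` gaps. `N` scores as a
mismatch against everything (including itself) and the ambiguous residue
X scores -4 everywhere, so ambiguity can neither seed nor extend a hit.
`merge_loci()` merges hits on one contig and strand separated by at most
`max_gap` (default 100 nt) into loci; merging is idempotent.

`rescue_from_reads()` recovers full-length elements when the assembly is
truncated or chimeric: reads hitting the query seed a pool, remaining
reads are recruited by shared k-mers (k = 13, >= 3 shared), mutually
overlapping reads form clusters, and each cluster is collapsed by
iterative majority-vote polishing against a growing draft. Two numerical
choices were made after inspecting failure modes on synthetic data: the
draft is extended at both ends with the longest read overhang each round
(a pileup can only polish positions the draft already has), and votes are
resolved by plurality with ties keeping the draft, because alignment
ambiguity around indels in short tandem repeats splits the "correct" vote
across equivalent edits and a strict majority rule then never fires. This
stage is a deliberately simplified consensus/polish procedure; its
accuracy claims are made on synthetic reads only.

# Target-site analysis

`classify_junctions()` aligns the `window` (default 200 nt) upstream and
downstream flanks of a candidate against the 28S reference; a flank
matches at identity >= 0.80 over >= 50 aligned nt (tolerant of diverged
28S while excluding random matches), and the junction coordinate is the
28S position abutting the element, extrapolated across at most 5
unaligned nt. Completeness follows R2 biology: both flanks = full-length,
only the 3' flank = 5'-truncated, otherwise no rDNA flanks (a 3'-only
truncation is not separately typed; it falls into the last class).
`nick_offset()` is measured on the rDNA forward strand regardless of
element strand, negative = upstream of the canonical nick.
`classify_element()` applies the class rules: Myb present with rDNA
flanks = site-specific R2; Myb without rDNA flanks = non-site-specific R2
homolog; no Myb = Utopia-like (no attempt is made to locate a U2 snRNA
gene; the U2 association is context, not a computed criterion); no usable
ORF = unclassified.

# Domain grammar and architecture

ORFs shorter than 900 aa are filtered out (the boundary is inclusive:
900 is kept, 899 is not). Zinc fingers are detected by the motif grammar

```
C x(s) C x(8-14) H x(3-5) [H|C],   s in {1, 2, 3}
```

with the spacing windows taken from canonical C2H2 finger geometry. The
final coordinating residue gives the pair type (CCHH, or CCHC -- the ZnF2
signature); the first-pair spacing gives the variant CxC / CxxC / CxxxC;
and a literal C,P,C,C first-pair region raises `cpcc_flag`. CPCC is
grammatically ambiguous (it parses as CxC with a C-containing spacer or as
CxxC); the annotator prefers the CxxC parse in that case, treating CPCC as
a sequence variant of CxxC, which is also how the generator labels it.
Other overlaps resolve greedily left-to-right, shortest spacing first.

Myb, RLE and knuckle domains and RT motifs 0-7 are found by sliding
single-sequence log-odds profiles (half-bits; detection threshold 0.55 of
each profile's maximum score, high enough that 100 random shuffles of a
generated protein yield zero hits in >= 95 cases, low enough to tolerate
roughly 0.3 substitutions/site of motif divergence). The RT is "intact"
only when all eight motifs appear in increasing coordinate order.

`classify_architecture()` numbers only fingers N-terminal to the first
Myb, starting at the finger nearest the Myb (ZnF1) and increasing toward
the N terminus: 3 fingers = A, 1 = D (D+Myb2 with a duplicated Myb), 4 =
4ZnF (kept distinct rather than forced into A-D), no Myb = no-Myb. With
exactly two fingers the more N-terminal finger's pair type disambiguates:
CCHC means ZnF2 is retained (label B), CCHH means ZnF3 (label C). This is
a design decision -- the B/C labels are historically phylogenetic, and
sequence evidence is all this module has -- and the output says so.
`cofold_znf32_plausible` is a linker-length heuristic (ZnF3-ZnF2 linker <=
10 aa) standing in for structure prediction of the interdependently folded
ZnF3:2 pair; it is never presented as a structural result.
`trim_n_terminus()` keeps 10 residues N-terminal of the most N-terminal
finger, the trim used before tree building.

# PSSM lineage placement

`build_pssm()` drops columns with more than 50% gaps, then per column

```
freq  = (counts + pseudocount * background) / (n + pseudocount)
score = 2 * log2(freq / background)        # half-bits, rounded to 0.5
```

with pseudocount 1 and uniform background 1/20 by default.
`score_against_pssm()` aligns a query to the profile with affine gaps
(11 + 1k half-bits). `lineage_placement()` follows the profile-database
direction: the candidate family forms the PSSM and the two lineage
reference RTs are the queries; the call is the larger score unless the
margin is within 2 half-bits (ambiguous). Scores are raw half-bit
alignment scores without E-value calibration -- they are used for relative
comparison and 2-D visualisation, not significance testing. The shipped
references are synthetic stand-ins built from the package's own motif
templates with lineage-specific linkers (files named `*_synthetic`);
substituting curated reference RTs is a one-argument change.

# Evolutionary model, site rates, phylogenetics

All likelihood machinery uses the 20-state equal-rates (Poisson-style)
amino-acid model with branch lengths in expected substitutions per site:

```
P_same(t) = 1/20 + (19/20) exp(-20 t / 19)
```

The choice is deliberate: the closed form gives the test suite exact
oracles for the simulator, the pruning likelihood and the two-leaf case,
which an empirical matrix (LG-style) would not; the machinery is
model-pluggable in principle via the substitution-score data file. Site
rates (`site_rates()`) use K = 4 equal-probability discrete-gamma
categories (category rate = the gamma mean within each quantile bin), the
shape fitted by golden-section search on log(alpha) over [0.05, 20], and
per-column posterior-mean rates binned into equal-frequency sextiles
(bin 1 = most conserved, ties broken by column index) for the
conservation track over RT motifs 0-7.

`align_progressive()` builds a guide tree by NJ on shared-3-mer distances
and merges profiles postorder with affine-gap profile-profile alignment
(frequency-weighted BLOSUM62 column scores); gaps are only inserted, never
residues changed. `trim_alignment()` drops columns whose gap fraction
exceeds 0.9 -- a gap-fraction rule standing in for more elaborate
alignment-trimming heuristics, recorded per column. `distance_matrix()`
offers p, Poisson (`-ln(1-p)`) and Kimura-protein
(`-ln(1 - p - 0.2 p^2)`) corrections.

`neighbor_joining()` is canonical NJ with deterministic tie-breaking
(lowest taxon-index pair), negative branch lengths clamped to zero with
the deficit moved to the sister edge, bootstrap by column resampling
(default B = 1000) with supports as the percentage of replicates
containing each internal bipartition, and outgroup rooting on the pendant
edge. NJ replaces maximum-likelihood tree search by design: it is exact on
additive matrices (an oracle-testable property), fast enough for
bootstrap-heavy use, and the downstream claims tested here are
topological; the method is recorded in the tree metadata. Supports below
80 are the conventional display threshold (`low_support_nodes()`).
`rf_distance()` prunes to the shared leaf set (>= 4 leaves) and counts the
symmetric bipartition difference.

# Pipeline and report

`run_pipeline()` chains discovery, junction classification, ORF/domain
annotation, element classification, per-element RT lineage placement and
the bootstrapped NJ tree of trimmed ORFs, deterministically for a fixed
config and seed (all stage seeds derive from the one top-level seed), and
writes TSV, GFF3 (1-based inclusive, converted by a single audited
function from the 0-based half-open internal coordinates), FASTA, newick
and a JSON manifest with input checksums. `summarize_run()` produces the
per-genome census by class/completeness/architecture, the list of genomes
where lineage A and D calls co-occur, and -- when a host tree is given --
the Robinson-Foulds discordance between a one-representative-per-genome
element tree and the host tree.

# Problem sizes and verification

The shipped verification (test suite and `scripts/acceptance.R`) runs at
the following sizes, chosen to exercise every claim at desk scale:
discovery on a ~137 kb genome with 10 rDNA units and 20 planted elements
(12 full-length, 8 truncated); a 50-template architecture panel covering
all seven labels and all four first-pair variants; nick offsets -11, 0,
+5 (plus a -50..+50 range check); lineage placement on 40 six-taxon
families evolved 0.5 substitutions/site from the two references; NJ
consistency on all 15 labelled five-taxon topologies with random additive
matrices; pruning-vs-enumeration agreement to 1e-10 log-units on five-leaf
trees; rate recovery on 12 taxa with 300-500 sites across shape values
0.3-3; and read rescue from 30 long reads at 8% combined error. Example
outputs in the README come from these same runs.

# Known limitations

* Detection profiles are single-sequence consensi; on real, diverged
  proteins they are weaker than curated HMMs, and the thresholds were set
  against the package's own generator.
* The equal-rates substitution model underfits real amino-acid exchange
  preferences; fitted alpha values on real alignments will absorb model
  misfit.
* NJ topology quality degrades with strong rate heterogeneity across
  lineages where ML methods would not; supports are bootstrap percentages
  under the same distance model, not posterior probabilities.
* The rescue consensus assumes a single dominant haplotype per cluster;
  mixed element subfamilies sharing >= 13-mers can collapse.
* B/C architecture labels from sequence evidence alone are a convention;
  elements with two fingers and unusual pair types may be mislabelled
  relative to a phylogenetic definition.
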