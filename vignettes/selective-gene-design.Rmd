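---
title: "Selective gene design for engineered microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective gene design for engineered microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selectigene)
```

## The problem

Genetic information introduced into a microbiome does not stay where it is
put: horizontal gene transfer exposes a construct to every member of the
community. `selectigene` designs the expression-determining elements of a
heterologous gene so that expression is favored in a declared set of
*wanted* hosts and disfavored in the *unwanted* hosts, even after the
construct (or a fragment of it) migrates. Three orthogonal layers are
engineered: the coding region (translation efficiency), the promoter
(transcription initiation), and restriction-site presence (cell entry and
persistence).

## Codon-usage models

Three per-codon weighting schemes are supported, each normalized so that the
best codon of a host has weight 1:

* **CAI** — within each synonymous family, a codon's weight is its count in
  a highly expressed reference gene set divided by the family maximum (the
  relative synonymous codon usage ratio). The reference set is the top
  tertile of genes by measured expression; without expression data genes
  are ranked by CAI against genes annotated as ribosomal proteins (or the
  whole proteome when none is annotated). Codons never observed in the
  reference set receive a pseudo-weight of 0.5 (configurable): a zero would
  be undefined under the geometric mean, and 0.5 is the standard remedy.
* **tAI** — the raw weight of codon *i* is
  $\sum_j (1 - s_{ij})\, \mathrm{tGCN}_{ij}$ over its recognizing
  anticodons, where tGCN is the tRNA gene copy number (a proxy for tRNA
  abundance) and $s_{ij}$ discounts wobble pairing. The default pairing and
  $s$ values follow the dos Reis convention (G:U 0.41, I:C 0.28, I:A
  0.9999, U:G 0.68, lysidine-read ATA 0.89); the table ships as
  `inst/extdata/wobble_s_values.tsv` and both the table and the pairing are
  overridable. Codons with no recognizing tRNA receive the geometric mean
  of the nonzero weights; normalization takes the maximum over nonzero raw
  weights.
* **TDR** — the typical decoding rate of a codon is the inverse of its mean
  normalized ribosome-footprint density; weights are rates over the maximum
  rate, with missing codons filled by the median rate. Only codon-level
  density tables are consumed; read alignment is out of scope.

A gene's score is the geometric mean of its codon weights (terminal stop and
ambiguous codons excluded). Per host we summarize the proteome by the mean
$\mu$ and the **sample** standard deviation $\sigma$ of gene scores — the
sample estimator is the conservative choice for the small proteomes typical
of metagenome bins, and a zero $\sigma$ (a degenerate proteome) is an error
rather than a silent division.

## Differential ORF optimization

For a candidate recoding $X'$ the per-host normalized distance is
$d_h(X') = (\mathrm{CUB}_h(X') - \mu_h)/\sigma_h$, and the objective is

$$f(X') = \alpha \cdot \mathrm{mean}_{a \in A}\, d_a(X') -
          \mathrm{mean}_{b \in B}\, d_b(X'),$$

with $A$ the wanted and $B$ the unwanted hosts. $\alpha$ defaults to 1
(symmetric weighting of the two goals); it is exposed because the
appropriate trade-off is application-specific.

Two optimizers are provided:

* **Proteome-relative hill climb.** A neighborhood move recodes *all*
  codons of one amino acid to one synonymous codon; the best strictly
  improving move is accepted until a local maximum or the iteration cap.
  Because the objective depends only on codon counts, each candidate is one
  dot product against the stacked log-weight matrix. Amino acids are
  visited alphabetically, codons lexicographically, and score ties break
  toward the lexicographically smaller sequence, so runs are deterministic
  without any RNG. On genes small enough to enumerate, the certified local
  maxima of the exhaustive synonymous landscape coincide with the
  optimizer's fixed points (this is asserted in the test suite).
* **Individual amino acid method.** Each family is solved independently by
  a per-codon score: the ratio score
  $R_i = \sum_{a} w_i/\max(w) - \sum_b w_i/\max(w)$, or a difference score
  $D_i$. The printed form of the difference score mixes signs in a way that
  rewards *low* wanted-host weights; we treat that as a typographical
  artifact and default to the corrected direction
  ($\sum_a w_i/\max(w) + \sum_b (1 - w_i/\max(w))$), while keeping the
  printed variant available behind `d_formula = "printed"` so both
  behaviors are testable. $\max(w)$ is taken within the host's own
  synonymous family, which makes the contributions comparable across hosts;
  a global maximum would let a single host's scale dominate.

Designs are evaluated by the optimization index: per host
$(\mathrm{CUB}_h(X') - \mathrm{CUB}_h(X))/\sigma_h$, averaged over wanted
hosts minus the average over unwanted hosts. It is exactly antisymmetric
under swapping the two sets, which the tests assert bit-for-bit.

## Promoter design

Promoters are the up-to-200 bp immediately 5′ of an ORF on its own strand;
intergenic sequence is everything on the strand belonging to neither an ORF
nor a promoter. Promoters shorter than 200 bp are truncated at the contig
edge or an upstream feature rather than discarded (minimum 30 bp), which
keeps small genomes and fragmented bins usable; promoters overlapping an
upstream ORF are truncated, a choice the logs flag.

Motif discovery is contrastive: for each wanted host, motifs enriched in
the promoters of its most highly expressed genes against its intergenic
background ("enhancing" motifs); for each unwanted host, motifs enriched in
intergenic sequence against those promoters ("anti-motifs", read as
transcription-suppressing). Two backends satisfy the same contract (motif
length 6–20, significance 0.05): an external backend that shells out to
STREME/MAST and parses MEME motif text, and an internal backend used
throughout the tests — Fisher-exact enriched k-mer seeding followed by EM
refinement of a position probability matrix against a 0-order background
estimated from the control set. Seeds that are shifted or
reverse-complemented variants of one another (overlap ≥ 4 with at most one
mismatch) are collapsed to one representative, mirroring how dedicated
discovery tools suppress duplicate elicitations; without this the candidate
set floods with shifted copies of the same signal and the percentile filter
below degenerates.

Motif similarity is the Spearman correlation between the two probability
matrices flattened column-major; across unequal lengths the shorter matrix
slides ungapped along the longer and the maximum over offsets and the
reverse-complement orientation is taken (recognition is double-stranded).
Per host, a similarity threshold $D_h$ is the 95th percentile (linear
interpolation, the type-7 convention) of similarities between the host's
motifs and 100 random PSSMs — columns drawn symmetric-Dirichlet(1), lengths
uniform on 6–20, seeded. The candidate set is the union of wanted hosts'
enhancing motifs; each candidate scores
$\alpha \sum_a \delta_a + (1-\alpha) \sum_b \delta_b$ where $\delta_h$
indicates similarity ≥ $D_h$ to some motif of host $h$'s own set, and the
final set keeps candidates strictly above the 75th percentile of scores.
Matching an unwanted host's *anti*-motifs is rewarded, per their
suppressing interpretation; whether the indicator should instead penalize
similarity to unwanted-host enhancing motifs is left as configured behavior
for a future extension. With few hosts the score distribution is coarse and
the strict inequality can empty the final set; the function warns rather
than silently relaxing the filter.

Candidate promoters (top quartile of wanted hosts' promoters by expression)
are ranked by E-value: per motif the best log-odds hit on either strand,
its exact p-value by enumeration of the score distribution (convolution for
motifs longer than 10 columns), a correction for the number of scanned
windows, the product-of-p-values combination
$\rho \sum_{j<k} (-\ln\rho)^j / j!$, and multiplication by the number of
candidates. Top promoters are tailored by correcting motif–promoter
mismatches: one variant per single mismatch plus one fully corrected
variant, the original always retained.

## Restriction-site editing

Sites are classified by recognizing role (wanted-only, unwanted-only,
shared). Recognition acts on double-stranded DNA, so both the coding strand
and its reverse complement are scanned, with palindromic sites deduplicated
by interval. The policy is: insert unwanted-only sites by synonymous
changes, and remove every wanted-recognized occurrence — including shared
sites, sacrificing some unwanted-host cutting, because any wanted-host
recognition endangers the construct in the hosts that should keep it.

Potential insertions are found by a per-pattern, per-reading-frame
compatibility table: the constraints a site places on each overlapping
codon depend only on the offset modulo 3, so feasibility per offset is a
table lookup. Conflict-free insertions are realized first; conflicted ones
in ascending conflict-degree order, choosing within a group by newly
covered unwanted hosts, then coverage weighted 1/(1 + existing sites of the
host) (favoring hosts with few sites), then lexicographic site and smallest
offset. A realization is rejected if it would destroy an existing
unwanted-recognized occurrence or create a wanted-recognized site with no
synonymous escape that keeps the insertion intact.

Removal searches synonymous variants of the overlapping codons
exhaustively, by increasing number of changed codons, preferring the
variant that least perturbs the wanted-host mean CAI (protecting the
translation design already applied); occurrences forced by the protein
sequence and site ambiguity are reported as irremovable. Because removal
edits can open fresh insertion windows, the insert/remove pair is iterated
to a fixed point (bounded rounds), which is what makes the editor
idempotent; insertions destroyed along the way lose their protected status
so they cannot veto later escapes.

## The synthetic-data generator

`make_microbiome()` emulates the study conditions end-to-end: wanted and
unwanted hosts draw codons from role-level preference vectors whose
separation scales with `bias_strength` (a shared Dirichlet baseline blended
with role-specific skew; 0 makes the groups statistically
indistinguishable), hosts jitter around their role vector, and every host
gets one contig of genes with 200-bp promoters and intergenic spacers, a
log-normal expression table, a tGCN table and TDR densities consistent with
its preferences, an enzyme repertoire drawn Poisson(4.6) from a shared
pool, and a 16S sequence mutated from a common ancestor. The defaults — 3
wanted + 3 unwanted hosts, 50 genes of 200 codons, bias 0.8, mean 4.6
sites/host — are the community sizes and signal strengths the package's
validation targets; the enzyme pool defaults to 120 distinct sites so that
repertoire overlap stays low across 10–50-host samples, mirroring the
diversity of the restriction-enzyme database (thousands of sites across
thousands of organisms). A planted IUPAC motif can be embedded in the
top-tertile promoters of wanted hosts to give the promoter pipeline a known
ground truth.

What the generator does **not** emulate: phylogenetic covariance between
hosts, operonic gene structure, strand mixtures (fixture genes are all
forward-strand), GC-content gradients, sequencing noise, and incomplete
bins. Passing tests therefore demonstrate correctness of the algorithms
under controlled signal, not performance on real metagenomes.

## Numerical choices and problem sizes

Percentiles use linear interpolation throughout so the strict inequality in
the final-set filter is reproducible. Score ties in the hill climb break
lexicographically; promoter E-value ties break by promoter id. Log-odds
matrices are smoothed with $\varepsilon = 10^{-4}$ before logs. The test
suite runs the protocol replications at pool sizes of 50 hosts with 8 genes
× 60 codons, microbiome sizes 10–50 with 10 replicates, and the motif
pipeline at 3 + 1 hosts with 40 genes — sizes chosen so the full suite
completes in minutes while every statistical property under test retains
power; the generator's scientific defaults above are used wherever the
property being tested depends on them.

## Known limitations

* The internal discovery backend is a deliberately simple EM refiner; it
  recovers strongly planted motifs but is not a substitute for STREME's
  sensitivity on subtle real signals (the external backend exists for
  that).
* Anti-motif sets on unstructured backgrounds are usually empty, so with
  very few hosts the aggregated motif scores can tie and empty the final
  set (a warning is emitted).
* The site editor's fixed-point iteration is bounded; pathological
  repertoires that cycle insertion against removal stop after the bound
  with a warning.
* Joint promoter+ORF co-optimization, mRNA folding, ramp effects,
  methyltransferase protection and digestion-end chemistry are out of
  scope.

## A short example

```{r example, eval = FALSE}
mb <- make_microbiome(fixture_spec(seed = 1))
goi <- make_goi(100, seed = 2)
report <- design(mb, goi, scheme = "CAI", method = "hill")
report$opt_index$index
report$site_summary
```
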