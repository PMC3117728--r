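---
title: "Models and methods behind mhc2div"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mhc2div}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mhc2div` analyses allelic diversity at a single MH class II beta-chain
locus from three inputs: an in-frame codon alignment of exon-2 alleles, a
diploid genotype panel (individual → unordered allele pair, optionally with
degenerate IUPAC consensus sequences), and nuclear-family pedigrees. This
vignette is the package's own account of the statistics it implements, the
choices that were genuinely open, and what its tests do and do not
establish.

## The codon frame

Exon 2 of a class II beta-chain gene usually starts and ends mid-codon; the
reader trims a configurable number of leading and trailing nucleotides
(default 2 and 1, matching a 273-bp exon whose complete reading frame is
the internal 270 bp / 90 codons). After trimming, sequences must be
equal-length, gap-free, `A/C/G/T`-only and stop-free; violations are hard
errors naming the record and column, because every downstream statistic
assumes a clean codon frame. Codon and nucleotide coordinates are 1-based
over the trimmed frame. Indels are out of scope: single-locus exon-2 allele
sets are typically indel-free, and a gapped frame would silently corrupt
the NG86 counts.

## Diversity summaries

Nucleotide diversity π defaults to the *unweighted* mean pairwise p-distance
over unique alleles — the quantity a diversity program reports when fed the
allele FASTA, which is how such figures are usually produced. A
frequency-weighted estimator (`n/(n−1) Σ 2wᵢwⱼ dᵢⱼ/L`, with `n` the number
of chromosomes) is available when the panel, not the allele set, is the
object of interest. A segregating column counts as a whole-column
*synonymous substitution* only when every allele, each in its own codon
context, encodes the same amino acid at the containing codon — the
column-shading convention of published exon-2 alignments.

## Pathway-averaged dN/dS and the Z-test

Nei–Gojobori (1986) counting is used with three conventions fixed to match
the MEGA lineage of implementations:

* potential-site counts treat mutations to stop codons as non-synonymous
  (the per-position denominator stays 3);
* observed differences are averaged over all orderings of the differing
  positions, with pathways through stop codons excluded and the average
  renormalized over the survivors; codon pairs with no stop-free pathway
  are dropped from that pair's counts with a warning;
* each pair's pN and pS are Jukes–Cantor corrected
  (`d = −¾ ln(1 − 4p/3)`; `p ≥ ¾` is a saturation error) *before* averaging
  across pairs (the "within-group mean" convention).

Partitioned runs restrict the alignment to a codon subset first, so the PBS
and non-PBS tables are fully self-contained; the reported allele count for
a partition is the number of *distinct* subsequences there.

The Z-test of positive selection uses `Z = (dN − dS)/√(Var dN + Var dS)`
with variances from bootstrap resampling of codon columns (seeded), and a
one-tailed standard-normal p for the alternative dN > dS. **Calibration
finding:** under neutral (ω = 1) simulation this construction is
conservative — across 6–8 taxa, 25–90 codons and several divergences the
measured rejection rate at nominal α = 0.05 was 0–2%. The property suite
therefore asserts type-I *control* (rate ≤ 7%), not exactness; a
significant Z-test is trustworthy, a non-significant one is weak evidence
of neutrality.

## PBS catalogs and homology mapping

Fish class II peptide-binding sites cannot be read off a crystal structure
and are inferred by homology to the human DR molecule. Two catalogs of
human β-chain contact positions are shipped — the classic crystallographic
set ("brown") and the updated set based on a larger peptide sample
("reche", 24 positions, the recommended default). The residue lists are
transcribed reconstructions from the cited structural literature, in mature
β-chain numbering against a packaged DRB β1 reference sequence; users with
their own catalog can pass explicit positions. Mapping aligns the query β1
protein to the reference (Needleman–Wunsch, BLOSUM62, gap open 10 / extend
0.5) and transfers positions through the alignment, dropping (with a
warning) any position that lands in a gap. On an ungapped 90-codon frame
the reche catalog spans 24 codons = 72 bp.

## GY94 site models (M7 vs M8)

Site-class codon models are fitted by maximum likelihood under GY94:
rate `q(i→j) = π_j · κ^[transition] · ω^[non-synonymous]` for single-base
codon changes, with F3×4 stationary frequencies (positional nucleotide
frequencies floored at 1e-4 and renormalized, so the reversible generator
stays irreducible on rare-codon data). M7 draws ω from Beta(p, q),
discretized into K = 10 equal-probability classes represented by their
class means; M8 adds a class at ωₛ > 1 with weight p1. M8 nests M7
(p1 → 0), so `2·(lnL₈ − lnL₇)` is referred to χ² with df = 2 — a
boundary-conservative convention, which is the standard practice.

Numerical scheme and the genuinely open choices:

* **Transition probabilities** come from the symmetrized eigendecomposition
  of the 61-state rate matrix (`B = D Q D⁻¹` with `D = diag(√π)`), with
  pruning performed in the eigenbasis and scalar per-edge rescaling (exact,
  since the same constant is restored to every site).
* **Branch lengths.** Full joint optimization of ~31 branch lengths with
  numeric gradients is disproportionate for 17 short alleles, so the tree
  is fixed to the neighbor-joining topology on Jukes–Cantor nucleotide
  distances (negative branches clamped to 0), converted to per-codon units,
  and multiplied by a single tree-scale factor optimized jointly with κ and
  the class parameters. For the shallow, star-like trees typical of allele
  sets this sacrifices little; it is the main deliberate simplification of
  the module, and exact numerical equality with other implementations'
  likelihoods is correspondingly not promised — tests and acceptance use
  significance-level agreement.
* **Optimization** is deterministic without a seed: a fixed 3-point start
  grid (4 points for M8, including a near-M7 start) explored coarsely with
  K = 5, then the two best candidates polished at full K with BFGS
  (reltol 1e-9). When the fitted M8 selection-class weight collapses
  (p1 < 0.01), the shared parameters are re-profiled with p1 pinned at the
  boundary; this guarantees the nested M7 optimum is attained and makes the
  nesting invariant (`lnL₈ ≥ lnL₇ − 1e-4`) hold in practice.
* **Per-site calls**: empirical-Bayes posteriors over the ω classes; a site
  is called positively selected when its posterior mass on ω > 1 classes is
  ≥ 1 − threshold (default threshold 0.05). With ~17 sequences, posterior
  0.95 is demanding; recall on planted sites is moderate (~50–60% per
  replicate in the test scenarios) while precision is high — the right
  asymmetry for reporting candidate sites.

The packaged GY94 simulator uses a *common mixture-average* rate scaling
across ω classes, so branch lengths mean expected substitutions per codon
averaged over sites and high-ω sites genuinely evolve faster — matching
the fitted model's convention. (An earlier per-class normalization was a
defect: it silently equalized evolutionary speed across classes and gutted
planted-selection signal.)

## Hardy–Weinberg and allelic-combination tests

Conditional on allele counts, HWE genotype tables are distributed as a
random pairing of the 2n gametes. For ≤ 3 alleles and ≤ 10 individuals the
package enumerates all tables and computes the exact probability test;
otherwise it samples the same conditional null by i.i.d. re-shuffling and
re-pairing of the gamete pool (seeded, +1-corrected). This sampler draws
from exactly the distribution the classic Markov-chain switch algorithm
converges to, without burn-in or mixing diagnostics; it was chosen for that
reason.

The allelic-combination test asks whether particular unordered allele pairs
co-occur in individuals more often than expected if pairs formed at random:
each replicate draws two alleles per individual i.i.d. from the empirical
allele frequencies; per-combination one-sided excess p-values use the +1
correction, 95% simulation envelopes are the 2.5/97.5 percentiles, and
family-wise control uses Holm's sequential Bonferroni at α = 0.05
(combinations never observed and never simulated report p = 1; a two-sided
variant is available by flag). **Calibration finding:** with the null
frequencies re-estimated from the tested panel — the standard field
practice — the test is conservative (~1% rejection at nominal 5%), because
the estimation conditions the null on the observed data. Supplying known
generating frequencies (the optional `frequencies` argument) restores
near-nominal calibration (~4%); the calibration suite runs in that mode.
Practically: raw flags from this test understate, not overstate,
significance.

## Phasing

Bayesian coalescent phasing is deliberately replaced by Excoffier–Slatkin
EM over haplotype frequencies — a declared stand-in, not a replication.
Each degenerate IUPAC consensus expands into its compatible unordered
haplotype pairs (at most 20 heterozygous positions; beyond that the
expansion is refused with advice to prune sites), EM iterates expected pair
posteriors and frequency updates to a 1e-8 log-likelihood tolerance with
five seeded restarts, and each individual reports its maximum-posterior
pair. For short, moderately divergent allele sets the two approaches
resolve essentially identically; the EM recovery suite measures ≥ 95%
correct pairs on panels drawn from a known 17-allele pool (observed: 100%).

## Mendelian checking

An offspring pair {x, y} is compatible when one allele can be assigned to
the father's pair and the other to the mother's (homozygotes therefore
need the allele in both parents). Incompatibility is a result, not an
error. The printed five-family pedigree table ships as a plain-text
fixture in the four-column-per-family layout, and planted-corruption tests
confirm 100% detection.

## Recombination scan

Each allele in turn is the target; the rest are sources. A dynamic program
over columns (state = current source; mismatch cost 1, switch cost ρ)
yields the minimal mosaic cost; the *saving* relative to the best single
source measures mosaic structure; significance comes from permuting the
variable-column order — the same permutation for all sequences, which
destroys linkage between columns while preserving each column's content
(the single-source cost is permutation-invariant). Only variable columns
enter the DP (invariant columns cost nothing either way). Ties break
toward fewer switches, then lower source index. ρ is in
mutation-equivalents per switch; its published analogue's internal scaling
is not documented, so ρ = 1 is the default and analyses are run as a sweep
over {0.5, 1, 2}, flagging an allele if any ρ does.

## Haplotype networks

Minimum-spanning networks with retained ties: edges are added in
increasing distance order, and within one distance class every pair that
bridges two components *as they stood before the class* is kept, so tied
alternative connections survive as reticulation loops — the visual
signature of recombinant alleles. Identical sequences merge into one node
with summed frequency. The statistical-parsimony 95% connection limit is
intentionally not applied: at ~25 variable sites over 270 bp all alleles
connect comfortably, and the limit would only add a code path the data
never exercises. Distances are nucleotide differences by default (edge
labels always list the amino-acid substitutions, e.g. `K2E`, in 1-based
codon numbering); an amino-acid distance mode is available.

## The synthetic world

The generator's defaults *are* the study design the pipeline targets: 17
alleles × 90 codons; a shared pool of 25 biallelic polymorphic sites (at
most one per codon) from which each allele draws ~Poisson(5) substitutions,
giving π ≈ 0.03 and realistic shared polymorphism; a 24-codon (72-bp) PBS
set with non-synonymous placement odds ω = 5 inside and 0.5 outside;
panels of 101 diploid individuals under HWE (or with designated enriched
combinations); 5 families of 8–13 offspring. Dirichlet(1) allele
frequencies give the skewed, empirical-style spectra such panels show.
Planted recombinants are single crossovers between two sufficiently
divergent pool alleles, recorded in a truth register along with every
substitution, so downstream recovery tests have exact expectations.

What it does **not** emulate: coalescent genealogies (alleles are
independent draws from the site pool given the ancestor), sequencing or
PCR artifacts, indels, gene conversion tracts, population structure, or
linkage to anything outside the locus. A green recovery test therefore
establishes that the *algorithms* behave as specified on data with the
assumed structure — not that the assumptions hold for any particular real
dataset. The one-site-per-codon constraint in the site pool is a fixture
simplification (it guarantees stop-freeness compositionally); real alleles
occasionally stack two changes in one codon.

## Reproducibility and budgets

Every randomized stage takes an explicit integer seed and is
bit-reproducible given it; the pipeline writes a provenance log with
versions, seeds and configuration. Monte-Carlo suites in the tests are
scaled down from their full-size sketches (noted inline in each test) to
keep the default run inside a CI budget; thresholds are kept, with bands
widened only where a smaller n forces a wider binomial interval.

## Known limitations

* The deposited 17-allele exon-2 dataset requires a one-time online fetch;
  the four acceptance tests tied to its published values fail offline by
  design (instructions in the failure message) rather than being skipped.
* Branch lengths in the site models are NJ-shaped up to a global scale
  (see above); likelihoods are not numerically comparable to other
  implementations, only inferentially.
* The PBS catalogs are literature reconstructions; for publication-grade
  partition calls, verify the residue lists against the primary structural
  sources for your taxon's alignment.
* The EM phaser ignores recombination within the phased fragment and
  coalescent priors; for long or highly het fragments a dedicated phasing
  tool is the better instrument.
* `em_phase` cost grows as 2^(het sites) per individual; the 20-site cap
  is a hard guard, and 15+ heterozygous positions are already slow.
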