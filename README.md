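# mhc2div

Single-locus MH class II exon-2 allelic diversity analysis for R.

Teleost fishes carry their major histocompatibility (MH) class I and II
genes unlinked, and several lineages — salmonids, seahorses — have a single
MH class II beta-chain locus (MHIIβ). Exon 2 of this gene encodes the β1
domain whose peptide-binding region (PBR) contacts antigens; balancing
selection typically keeps it hypervariable. Characterizing that variation
from a panel of sequenced individuals is a standard study design:
single-locus verification through Mendelian segregation in families,
polymorphism and heterozygosity summaries, dN/dS-based tests of positive
selection partitioned by peptide-binding sites, codon site-model tests,
Hardy–Weinberg and mate-choice-motivated allele-combination tests,
recombination detection, and haplotype networks.

`mhc2div` implements that entire pipeline as composable R functions plus a
seed-deterministic synthetic-data generator, so every stage is testable with
no external downloads. It is aimed at molecular ecologists working on MH /
MHC diversity in non-model vertebrates.

## What it computes

* **Polymorphism** — nucleotide diversity
  π (unweighted over unique alleles, or frequency-weighted
  `n/(n−1) · Σᵢ<ⱼ 2wᵢwⱼdᵢⱼ/L`), segregating sites, variable amino-acid
  sites, whole-column synonymous substitutions, observed heterozygosity.
* **Pathway-averaged dN/dS** (Nei–Gojobori 1986 counting with Jukes–Cantor
  correction `d = −¾ ln(1 − 4p/3)`): per-pair pN and pS corrected then
  averaged over pairs; mutations to stop codons count as non-synonymous,
  pathways through stops are excluded and renormalized. Partitioned by PBS /
  non-PBS codons, with both the Brown et al. (1993) and Reche & Reinherz
  (2003) human β-chain PBS catalogs mapped by pairwise homology.
  A codon-bootstrap Z-test (`Z = (dN−dS)/√(Var dN + Var dS)`, one-tailed)
  tests for positive selection.
* **Codon site models** — GY94 with F3×4 frequencies on an NJ tree: M7
  (ω ~ Beta(p,q), K equal-probability classes) versus M8 (beta plus a class
  at ωₛ > 1), df = 2 likelihood-ratio test, empirical-Bayes per-site
  posteriors of positive selection.
* **Population tests** — conditional exact Hardy–Weinberg test (complete
  enumeration for small problems, gamete-re-pairing Monte Carlo otherwise);
  a permutation test of allelic co-occurrence against i.i.d. draws from
  empirical allele frequencies, with 95% simulation envelopes, +1-corrected
  one-sided p-values and sequential Bonferroni (Holm) correction;
  Excoffier–Slatkin EM phasing of degenerate IUPAC genotypes; Mendelian
  compatibility checking in nuclear families.
* **Recombination** — minimal-cost mosaic scan: each allele is explained
  from the others with per-column mismatch cost 1 and switch penalty ρ; the
  saving of the best mosaic over the best single source is referred to a
  column-permutation null.
* **Networks** — minimum-spanning haplotype networks with retained ties
  (loops), edges labeled with amino-acid substitutions, and recombinant-
  pruned rebuilds.

## Worked example

A synthetic study at the canonical design scale (17 alleles × 90 codons, a
24-codon / 72-bp PBS partition, 101 diploid individuals, 5 families, two
planted recombinant alleles):

```r
library(mhc2div)
cfg  <- sim_config(seed = 13, n_recombinants = 2)
pool  <- gen_allele_pool(cfg)
panel <- gen_panel(pool$alignment, cfg)
fams  <- gen_families(pool$alignment, cfg)

diversity_summary(pool$alignment, panel$genotypes)
#> pi = 0.0326 | S = 25 segregating sites | 21 variable aa sites | 4 synonymous
#> observed heterozygosity = 90/101 = 0.891

mean_dn_ds(pool$alignment, partition_label = "Exon 2")
#> NG86/JC [Exon 2] 90 codons, 17 alleles: dN = 0.037, dS = 0.023, dN/dS = 1.56
mean_dn_ds(pool$alignment, cfg$pbs_codons, "Exon 2, PBS")
#> NG86/JC [Exon 2, PBS] 24 codons, 17 alleles: dN = 0.104, dS = 0.018, dN/dS = 5.66
mean_dn_ds(pool$alignment, setdiff(1:90, cfg$pbs_codons), "Exon 2, non-PBS")
#> NG86/JC [Exon 2, non-PBS] 66 codons, 14 alleles: dN = 0.014, dS = 0.026, dN/dS = 0.55

z_test_positive_selection(pool$alignment, cfg$pbs_codons, reps = 1000, seed = 1)
#> PBS Z-test: Z = 3.32, one-tailed p = 0.000

hwe_exact_test(panel$genotypes, mc_steps = 5000, seed = 1)
#> HWE exact test: p = 0.16

recomb_pvalues(pool$alignment, rho = 1, reps = 1000, seed = 1)
#> recombination scan (rho = 1, 1000 permutations): 17 alleles, 25 variable columns
#> alleles at p < 0.05: A16, A17        # exactly the two planted recombinants

build_network(collapse_alleles(panel$genotypes, pool$alignment), pool$alignment)
#> haplotype network: 17 nodes, 34 edges, 18 loop(s) [nucleotide distances]

mendel_check_all(fams$families)$total_compatible
#> 41 of 41 offspring compatible
```

Reading the numbers: non-synonymous divergence concentrates in the PBS
partition (dN 0.104 vs 0.014 outside it; dN/dS 5.66 vs 0.55) exactly as the
generator planted (ω = 5 inside, 0.5 outside), the Z-test rejects
neutrality for the PBS codons, the panel is consistent with Hardy–Weinberg,
the mosaic scan recovers both planted recombinants and nothing else, and the
pedigrees segregate cleanly — the full single-locus verification loop.

The same pipeline runs end-to-end on files via `run_all(run_config(...))`
or the CLI wrapper (`inst/scripts/mhc2div`), with subcommands `simulate`,
`diversity`, `dnds`, `sitemodels`, `hwe`, `combos`, `mendel`, `recomb`,
`network`, `all`.

## Documentation

The methods vignette (`vignettes/mhc2div-methods.Rmd`) describes the models,
their assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical choices,
and known limitations.
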