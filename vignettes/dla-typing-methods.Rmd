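---
title: "Methods: DLA class II typing, phasing and association in dlatyper"
output: html_document
vignette: >
  %\VignetteIndexEntry{Methods: DLA class II typing, phasing and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlatyper)
```

# Scope and data model

`dlatyper` analyses sequence-based typing data for the three classical
canine MHC (DLA) class II loci, DRB1, DQA1 and DQB1. Each locus is a
fixed-size amplicon (290, 312 and 372 bp by default), so alleles at a
locus are modelled as equal-length A/C/G/T strings with no indels; the
reference universe is an `AlleleLibrary`. The observable per dog and
locus is a single reconciled diploid consensus string in which
heterozygous positions carry the IUPAC symbol of the two underlying
bases. How forward and reverse chromatogram reads were merged into that
consensus is upstream of this package: base-calling, trace processing
and primer handling are out of scope.

# Genotype calling

A pair of alleles $(a_1, a_2)$ *explains* a consensus $s$ when, at
every position $i$, the IUPAC union of $a_1[i]$ and $a_2[i]$ equals
$s[i]$; in particular every unambiguous position forces
$a_1[i] = a_2[i] = s[i]$. `callGenotype` proceeds by case:

* **No ambiguity codes.** An exact library match is a homozygote.
  No match is a novel allele, reported with the closest known alleles
  by Hamming distance — "closest" is not quantified in typing protocols,
  and minimum Hamming distance is the natural choice for equal-length
  amplicons; ties are all reported, never broken — and the 0-based
  mismatching positions (0-based indices match the TSV interchange
  format, which is shared with non-R tooling).
* **Ambiguity codes present.** All unordered known-allele pairs are
  enumerated. Exactly one explaining pair is a heterozygote; two or
  more are reported as `ambiguous` with the full, lexicographically
  sorted candidate list. Ambiguity is surfaced, not resolved: downstream
  stages treat such dogs as untyped, because forcing a choice would
  silently bias haplotype and association counts.
* **No explaining pair.** If exactly one known allele is *compatible*
  (its base lies in the consensus base set everywhere), the partner
  allele is forced base by base and returned as a hypothesised novel
  complement — this is how a previously undescribed allele is detected
  in a heterozygous dog. Otherwise the call is `novel` without a
  reconstruction. A position carrying a three- or four-base symbol
  (other than `N`) can never arise from a diploid union and therefore
  always routes here.

`N` is accepted as a sequencing-failure wildcard compatible with any
base; `strictN = TRUE` rejects it instead. Because `N` can make several
homozygote matches possible, a consensus containing `N` may also come
back `ambiguous` with identical-pair candidates.

Calling is validated two ways: a round-trip property (render the union
of any library pair, call it, recover the pair or an ambiguity set
containing it) and an independent brute-force oracle that re-derives
the IUPAC union from the published Biostrings code map and enumerates
all pairs; the two agree over a thousand randomised libraries per test
run (up to 8 alleles of up to 12 bp — small enough to enumerate, large
enough to hit collisions).

# Haplotype inference

Three-locus phasing follows Clark's parsimony algorithm. A dog
heterozygous at $h$ loci has $2^{h-1}$ unordered phase decompositions
($1$ for $h \le 1$). Iteration 0 resolves every dog with a unique
decomposition — fully homozygous dogs and single-locus heterozygotes,
whose phase is certain without any reference set — and seeds the known
set $H$ with their haplotypes. Each subsequent sweep, in sorted
`dog_id` order for determinism, applies two rules to every unresolved
dog:

1. **both-known**: if exactly one decomposition has both haplotypes in
   $H$, assign it;
2. **one-known extension**: otherwise, if no decomposition has both in
   $H$ and exactly one has a single haplotype in $H$, assign it and add
   the complement to $H$.

Anchors-first ordering and preferring both-known assignments minimise
the number of invented haplotypes. If several decompositions survive
the applicable rule the dog stays unresolved that sweep; since $H$ only
grows, a dog can resolve later, and resolution is monotone (re-running
with the final $H$ reproduces the assignments — a tested property).
Dogs never resolved, and dogs with an ambiguous, novel or missing call
at any locus, are reported `unidentified` and contribute two copies to
an "Unidentified" count row, so copy totals are always conserved at
twice the cohort size. The sweep cap (`maxIter = 10`) is generous; the
fixpoint arrives in at most three sweeps on every cohort exercised in
the tests. Non-convergence is a legitimate outcome (an unidentified
remainder), not an error.

Statistical phasing (EM, MCMC, reference panels) is deliberately out of
scope: with three tightly linked loci and homozygote anchors, parsimony
phasing is the field's procedure, and its failure mode — an explicit
Unidentified class — is more honest for small cohorts than
frequency-weighted guessing.

# Association statistics

All contrasts are 2×2 tables: $a$/$b$ affected units carrying/not
carrying the feature, $c$/$d$ likewise for controls. The unit is the
allele copy (each fully typed dog contributes two per locus), the
haplotype copy, or the dog (for the three-locus homozygosity test).
Dogs not fully typed at a locus are excluded from that locus's
denominators.

The convention, chosen once and verified against an independent
statistics oracle before the module was built, is:

* $\mathrm{OR} = ad/bc$; when any cell is zero, $0.5$ is added to every
  cell first (Haldane–Anscombe), and the result is flagged `corrected`.
* Woolf logit CI: $\exp(\ln \mathrm{OR} \pm z \cdot \mathrm{SE})$,
  $\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$ on the possibly
  corrected cells. The default critical value is $z = 1.96$, the
  conventional two-decimal reporting value — which is what the
  reference tables this package validates against actually used (the
  exact quantile `qnorm(0.975)` changes one printed bound from 278.23
  to 278.21); pass `zCrit = qnorm(0.975)` for the exact value.
* Two-sided Wald test: $p = 2(1 - \Phi(|\ln \mathrm{OR}|/\mathrm{SE}))$.

Pearson's χ² and Fisher's exact test do *not* reproduce the reference
tables' P-values; the Wald/Woolf convention reproduces all 59 rows from
their printed counts at printed precision (one printed CI bound is
internally inconsistent between two identical-count rows — 0.06 vs
0.07 — and the fixture carries an erratum flag for it). No
multiple-testing adjustment is applied in this module, matching the
reporting convention of candidate-locus DLA studies; the GWAS stage, by
contrast, is Bonferroni-corrected.

# GWAS stage

`qcFilter` keeps SNPs with call rate ≥ 0.90 and pooled minor allele
frequency ≥ 0.05 (boundary kept; the standard reading of the usual QC
sentence, which is often garbled in print). `allelicTest` is the 1-df
allelic Pearson χ² on the 2×2 allele-count table without continuity
correction — the computation behind a basic association scan — with
missing genotypes excluded pairwise and degenerate margins returning
χ² = 0, p = 1. Bonferroni correction multiplies raw P by the number of
SNPs tested (capped at 1). The genomic inflation factor is
$\lambda = \mathrm{median}(\chi^2)/0.4549364$, reported descriptively
and never used to rescale P-values.

**Small-sample behaviour of λ.** With 15 cases and 16 controls (62
allele copies), the allelic χ² is strongly discrete, and the exact
median of its null distribution sits above the asymptotic χ²₁ median:
enumeration gives λ between 0.93 and 1.21 depending on MAF, about 1.15
integrated over MAF ~ U(0.05, 0.5), converging to ~0.99 by 200 samples
per arm. A median-based λ computed on a simulated cohort of this size
therefore hovers near 1.1–1.15 even with no stratification whatsoever.
The acceptance suite asserts the asymptotic bracket [0.9, 1.1] and this
expectation fails by construction at these sample sizes; the package
reports the honestly computed value rather than masking the
discreteness.

# Synthetic data

The generator emulates the study design the analysis assumes: a
reference library of 6 random alleles per locus (pairwise Hamming
distance ≥ 2, so one sequencing error cannot turn one allele into
another), a pool of six three-locus haplotypes with frequencies
(0.10, 0.30, 0.22, 0.18, 0.12, 0.08), the first being the risk
haplotype, diploid Hardy–Weinberg sampling, and a multiplicative
disease model: odds of disease $= 0.05 \times 4^{\text{risk copies}}$
by default. Dogs are rejection-sampled to exactly 34 affected and 66
controls, mirroring case-control ascertainment. The SNP panel is
independent of the DLA track: 1,000 unlinked markers, MAF uniform on
(0.05, 0.5), genotypes Binomial(2, MAF), over 15 cases and 16 controls.

Two modelling notes. First, with a logistic link the allele-copy odds
ratio induced in the population is not exactly the per-copy parameter;
`trueAllelicOR` computes it exactly by enumerating the three genotype
classes (≈ 3.81 for riskOR 4 at frequency 0.10 and baseline odds 0.05),
and the CI-coverage tests target that estimand. The baseline odds of
0.05 keeps the disease uncommon, so the two copies of a case dog are
nearly independent and the copy-level table is the natural summary.
Second, the error process (optional, off by default) substitutes a
random different IUPAC symbol per position — no indels, consistent with
the equal-length allele model.

What the simulator does **not** emulate: linkage disequilibrium between
the SNP panel and the DLA haplotypes, population structure or
relatedness, allele-frequency spectra of real arrays (uniform MAF is a
convenience), recurrent mutation, or chromatogram-level noise. Passing
tests therefore demonstrate the correctness of the algorithms under the
stated statistical model, not robustness to structured real-world
artefacts.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU: 50
simulated null GWAS cohorts of 1,000 SNPs for the λ/Bonferroni
properties, 500 replicate cohorts of 100 dogs for CI coverage, 1,000
randomised libraries for the calling oracle, and 200 seeds for OR
recovery brackets. All randomness flows through explicit integer seeds;
generators are pure functions of (config, seed), and the pipeline's
outputs are byte-identical across re-runs (a tested property).

Tie-breaking is everywhere deterministic and conservative: ambiguous
calls list all candidates sorted lexicographically; Hamming ties list
all closest alleles; phase ambiguity leaves the dog unresolved; PED
minor-allele ties resolve alphabetically. Zero cells in 2×2 tables are
the only place a continuity device is used, and it is flagged in the
output.

# Known limitations

* The Wald/Woolf machinery is asymptotic; for very sparse tables the
  corrected CI is wide but its coverage is approximate (the 500-replicate
  coverage check targets the default study geometry, not arbitrary
  designs).
* Equal-length, indel-free alleles are an amplicon-specific assumption.
* The phasing procedure inherits Clark's order-of-information caveat in
  principle; determinism is guaranteed by sorted iteration, but cohorts
  without anchors simply stay unresolved.
* λ on two-digit sample sizes is biased upward by discreteness (see
  above) and should be read qualitatively there.
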