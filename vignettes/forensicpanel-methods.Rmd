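---
title: "Statistical methods behind forensicpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind forensicpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forensicpanel)
```

`forensicpanel` implements the statistical pipeline used to characterise a
mixed forensic NGS marker panel — autosomal, X- and Y-chromosomal STRs,
identity and ancestry SNPs, and mitochondrial control-region sequences — in
population samples. This vignette explains the models and formulas, the
conventions chosen where the field's tools disagree, what the synthetic-data
generator does and does not emulate, and the known limitations.

## Data model

Genotype tables hold string allele labels throughout, because STR
microvariants (`"14.2"`) and sequence-named alleles must survive round
trips; labels that parse as numbers sort numerically, everything else
lexicographically. Ploidy is class- and sex-dependent: autosomal genotypes
are unordered pairs, X genotypes are pairs in females and single alleles in
males, Y genotypes are single haplotype tokens in males and absent in
females. Multi-copy Y loci (e.g. DYS385a/b) call combinations like
`"13-14"`; these are treated as *single* haplotype-alleles everywhere, so a
frequency table never splits them. Y null alleles (label `"null"`) are
non-amplifications, not alleles, and are excluded from gene-count
denominators. Missing calls (`"."`) are dropped pairwise per computation,
never imputed.

## Per-locus forensic parameters

With allele frequencies \(p_i\), power sums \(S_r = \sum_i p_i^r\), and
\(n\) observed gene copies:

* observed heterozygosity \(H_{obs}\); plain expected heterozygosity
  \(H_e = 1 - S_2\); Nei's gene diversity \(GD = \frac{n}{n-1} H_e\);
* \(PIC = 1 - S_2 - S_2^2 + S_4\);
* match probability \(PM = \sum_g f_g^2\) over **observed** genotype-class
  frequencies (the convention of the STRAF/PowerStats family; the
  HWE-expected form is available via `pm = "expected"`) and
  \(PD = 1 - PM\);
* exclusion probability \(PE = H_{obs}^2 (1 - 2 H_{obs} Hom^2)\) with
  \(Hom = 1 - H_{obs}\), and typical paternity index
  \(TPI = 1/(2\,Hom)\), reported as `Inf` when every genotype is
  heterozygous so that combined products stay computable;
* haplotype diversity \(HD = \frac{n}{n-1}(1 - \sum p_i^2)\), also used as
  the Y-locus gene diversity (Nei and Tajima's unbiased form).

Panel-level statistics multiply: \(CMP = \prod PM_i\), \(CPD = 1 - CMP\),
\(CPE = 1 - \prod (1 - PE_i)\). `combined_stats()` also returns the CMP
curve in the given locus order and in descending-PD order; the latter is
pointwise below the former, which is how "how many SNPs are enough"
figures are produced.

Two conventions deserve emphasis. First, `GD` carries the \(n/(n-1)\)
correction while the X-chromosomal module works with the uncorrected
\(H_e\): the published 27-locus X-STR reference table shipped with the
package demonstrates this choice (its PDM column equals its He column
exactly, and PDM is \(1 - S_2\) by definition). Second, PM is
observed-genotype based by default because that is what the upstream tools
compute; on HWE data the two versions converge.

## X-chromosomal efficiency parameters

For X markers the discrimination and exclusion parameters are polynomials
in the power sums:

* \(PD_{male} = H_e = 1 - S_2\) (hemizygous males are discriminated by a
  single allele);
* \(PD_{female} = 1 - 2 S_2^2 + S_4\);
* \(MEC_{trio} = PIC\): in a father–mother–daughter trio the paternal
  allele of the daughter is identified, so the trio mean exclusion chance
  equals the polymorphism information content (Kishida/Desmarais result);
* \(MEC_{duo} = 1 - 2 S_2 + S_3 = \sum_i p_i (1 - p_i)^2\): a
  father–daughter duo without the mother;
* \(MEC_{def} = 1 - 2 S_2 - 2 S_2^2 + S_3 + 3 S_2 S_3 + 2 S_4 - 3 S_5\):
  deficiency cases, where the alleged father is unavailable and a diploid
  relative is typed in his place, so the paternal allele cannot always be
  resolved against the tested genotype. This is the exact
  (Krüger-type) trio exclusion probability obtained by enumerating
  mother × child × tested-woman genotypes; the package validates it
  against the shipped reference table by solving the formula for \(S_5\)
  row-by-row and checking that the value lands inside the algebraic window
  \([S_4^2/S_3,\; S_4^{5/4}]\) that any true frequency spectrum must
  satisfy. The formula slot is pluggable (`mec_df_formula`) so alternative
  deficiency conventions can be compared.

The deficiency formula involves \(S_5\), which is *not* recoverable from a
published table reporting only \((He, MEC_d, PDF)\); this is why the
validation goes through the \(S_5\) window rather than a direct
recomputation. One printed cell of the reference table (DXS7423 in the
Yugu sample) has a trio MEC that disagrees with its PIC by 0.0074 even
though the identity \(MEC_t = PIC\) is mathematical; the recovered power
sums confirm the PIC value, so the package documents that cell as a
printing defect and asserts the identity on the other 53 rows (worst
remaining deviation 0.0002, consistent with 4-decimal rounding).

Combined values use \(1 - \prod(1 - x_i)\) (`x_combined()`), which is
permutation invariant and reported at full floating precision because the
interesting part is the complement (e.g. a combined trio MEC of
\(1 - 1.2\times 10^{-14}\)).

```{r}
ref <- xstr_reference_table()
x_combined(ref$MEC_t[ref$Population == "Yugu"])
```

## Equilibrium tests

`hwe_exact()` is the exact conditional test: given the allele counts, the
genotype array follows the Levene/Haldane distribution
\(P(f) \propto 2^{h} / \prod_{i \le j} f_{ij}!\) (h = heterozygote count),
and the p-value is the mass of arrays no more probable than the observed
one — the "probability" test, Genepop's default. Biallelic loci are always
fully enumerated (arrays are indexed by the heterozygote count);
multiallelic loci are enumerated when a cheap bound shows the recursion is
small, and otherwise sampled by Monte-Carlo pairing of shuffled gene copies
(C++ core, default `mc_reps = 1e5`, add-one estimator). The add-one
estimator makes Monte-Carlo p-values valid but never smaller than
`1/(mc_reps + 1)`.

Exact tests on discrete support are conservative; how conservative depends
on the richness of the support. Biallelic loci at realistic sample sizes
reject a true null at roughly 0.032–0.042 when the nominal level is 0.05,
while STR-like multiallelic loci (the validity study in the test suite
uses six Dirichlet(2) alleles, 150 diploids, 10\^4 Monte-Carlo draws per
locus) are close to nominal. That is a property of exact tests, not an
implementation artefact, and it is why the validity study is run on
multiallelic loci.

`ld_permutation()` tests pairwise linkage disequilibrium with the G
(likelihood-ratio) statistic of the two-locus *genotype* contingency
table — the genotypic test appropriate for unphased data — against a null
built by permuting one locus across samples. `bonferroni()` returns
`alpha/m` exactly plus the display form population reports print (two
significant digits, truncated to at most five decimals); pairwise
corrections use unordered pair counts `choose(L, 2)`.

## Kinship likelihood ratios

A pairwise relationship is an IBD triple \((k_0, k_1, k_2)\) with
\(k_1^2 \ge 4 k_0 k_2\): full siblings (0.25, 0.5, 0.25), half siblings
(0.5, 0.5, 0), parent–child (0, 1, 0), unrelated (1, 0, 0). The LR against
unrelatedness at one locus is

\[
LR = k_0 + k_1 \frac{P(g_2 \mid g_1, 1\,\text{IBD})}{P(g_2)}
         + k_2 \frac{[g_2 = g_1]}{P(g_2)},
\]

where the 1-IBD transition copies a uniformly chosen allele of \(g_1\) and
draws the other from the population. The test suite brute-forces the
normalisation \(\sum_{g_2} (k_0 P_0 + k_1 P_1 + k_2 P_2) = 1\) over 2- and
4-allele loci and checks \(E[LR] = 1\) under unrelatedness.

`run_lr_study()` reproduces the standard panel-assessment design: simulate
1,000 pairs under the true relationship by gene dropping, score each with
the product LR over loci, and report exceedance at a decision threshold of
\(10^4\). Gene dropping is done at the gamete level with explicit
recombination (an optional linkage map gives the recombination fraction
\(\theta\) between adjacent loci), and the realised per-locus IBD state is
recorded so LR behaviour can be validated against true relatedness. Two
divergences from nature are deliberate and mirror forensic practice: the
LR always assumes locus independence (even when the simulation used
linkage), and there is no mutation model, so true parent–child pairs can
never be excluded. Both matter for real casework and are flagged in the
function documentation.

On the synthetic study panel (54 STR-like loci with Dirichlet(1)
ten-allele spectra, plus 133 biallelic SNPs), full siblings exceed
\(LR > 10^4\) essentially always, half siblings less than half the time
with STRs alone, and adding the SNP set strictly raises half-sib
exceedance — the qualitative pattern such panel studies report. The exact
published exceedance values depend on the study populations' allele
frequencies, which are not republished here, so they are validated as a
pattern, not as numbers.

## Mitochondrial diversity, neutrality, and demography

All sequence statistics use complete deletion (columns containing `-` or
`N` anywhere are dropped first), DnaSP's default, so \(S\), \(k\) and
\(\pi = k / L_{\mathrm{eff}}\) are mutually consistent and \(k\) is exactly
the mean of the mismatch distribution.

Tajima's D is \((k - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}\) with the standard
constants; significance uses Tajima's beta approximation (two-sided). At
\(n = 3\) the variance constants vanish identically (k is determined by S)
and D is reported as 0 with class "undefined" rather than NaN. Fu & Li's
outgroup-free \(D^*\) and \(F^*\) use total mutations \(\eta\) (multi-state
columns count states minus one) and singletons \(\eta_s\) with the
corrected variance constants; because the published critical-value tables
are not reproduced here, significance classes come from simulating the
constant-size coalescent at Watterson's \(\hat\theta_W\)
(`signif_reps` replicates; the class bands `<0.01`, `<0.02`, `<0.05`, `ns`
match the reporting style of the field's software).

The mismatch module fits the sudden-expansion model. In mutational time
(pairwise mutation rate 1), a population at scaled size \(\theta_0\) that
grew instantaneously to \(\theta_1\) at time \(\tau\) ago has expected
pairwise-difference distribution

\[
F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
      \sum_{i=0}^{j} \frac{e^{-\tau}\tau^i}{i!}
      \left[\hat F_{j-i}(\theta_0) - \hat F_{j-i}(\theta_1)\right],
\qquad \hat F_j(\theta) = \frac{\theta^j}{(1+\theta)^{j+1}},
\]

the Rogers–Harpending form (derived from memorylessness of the equilibrium
geometric at the expansion boundary; the vignette's test suite checks it
collapses to the right equilibria at \(\tau = 0\) and \(\tau \to \infty\)).
All three parameters are estimated by least squares on the observed
mismatch frequencies — a moment-seeded grid around the observed mean
followed by Nelder–Mead on a transformed scale that enforces
\(0 \le \theta_0 \le \theta_1\), \(\tau > 0\). Goodness of fit is the sum
of squared deviations (SSD) and Harpending's raggedness
\(r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2\) with the explicit boundary
convention \(x_{d+1} = 0\) (secondary sources are ambiguous here, so the
convention is part of the contract). P-values are parametric-bootstrap:
`B` datasets are simulated under the fitted model with the package's own
coalescent generator, each is refitted, and \(p = \#\{stat_b \ge
stat_{obs}\}/B\) — the procedure popularised by Arlequin.

## The synthetic-data generator

Every generator is a pure function of its arguments and a seed (the
session RNG is saved and restored). It emulates:

* Dirichlet(\(\alpha\)) allele-frequency spectra (\(\alpha = 1\) gives
  realistically uneven STR spectra; \(\alpha \to \infty\) equifrequent);
* Hardy–Weinberg genotypes with sex-correct ploidy at X/Y loci;
* Balding–Nichols population structure: descendant frequencies are
  Beta\((p\frac{1-F}{F}, (1-p)\frac{1-F}{F})\) draws with variance
  \(F\,p(1-p)\);
* relative pairs by gamete-level gene dropping over optionally linked
  loci, with realised IBD bookkeeping;
* haploid sequence samples from a Kingman coalescent, constant-size
  (\(E[k] = \theta\), \(E[S] = \theta a_1\)) or sudden-expansion with the
  same \((\theta_0, \theta_1, \tau)\) parameterisation the mismatch fitter
  estimates, with infinite-sites mutations written as a binary
  substitution alignment.

It does **not** emulate: stepwise STR mutation, mutation in pedigree
transmissions, recombination within mtDNA, sequencing error, allelic
dropout, or population admixture. Passing tests therefore demonstrate
internal correctness and statistical validity of the estimators on clean
HWE/coalescent data — not robustness to the artefacts of real casework
data.

Default study sizes used in the tests (chosen to match the scale of the
source analyses while keeping a laptop run comfortable): 1,000 simulated
pairs per kinship study; 1,000 loci for the HWE validity study (150
diploids each, 10\^4 Monte-Carlo draws); 500 datasets for LD p-value
uniformity; 500 constant-size replicates (n = 30, θ = 5) for the Tajima
null mean; 50 replicates × B = 100 bootstraps for mismatch model
consistency; 200 biallelic loci (200 gene copies per population) for
Balding–Nichols FST recovery.

## Population comparison

`pairwise_fst()` treats haplogroup (or allele) categories as alleles of
one haploid locus. The default estimator is the Hudson form
\(1 - H_S/H_B\) with unbiased within-population diversity; under
Balding–Nichols divergence its expectation ratio equals the divergence
parameter exactly, with no number-of-demes correction. The classical
pooled-frequency \(G_{ST}\) is available as `method = "nei_gst"` but for
two demes it reads roughly half the simulated parameter, which is why it
is not the default; the estimator name travels with the result so
alternates can be compared. Negative estimates are floored at zero in the
report and kept raw alongside. Multi-locus input combines by ratio of
sums. `zscore_matrix()` standardises each category across populations
(n−1 sd; constant columns map to zero), the normalisation behind
haplogroup heat maps. Rosenberg's informativeness for assignment

\[
I_n = \sum_{\text{alleles}} \Big(-\bar p \ln \bar p
      + \frac{1}{K}\sum_{\text{pops}} p \ln p\Big)
\]

uses the unweighted across-population mean and natural-log units; it is 0
for identical populations and bounded by \(\ln K\).

## Known limitations

* The exact HWE enumeration falls back to Monte-Carlo based on a
  conservative bound on the recursion size, so some enumerable
  multi-allelic tables are sampled instead (the two paths agree within
  Monte-Carlo error; the suite asserts it).
* Mismatch-model bootstrap p-values inherit the usual caveat of parametric
  bootstraps at estimated parameters: calibration is approximate, which is
  exactly what the model-consistency study in the test suite quantifies.
* The kinship engine is pairwise-IBD only: no mutation, silent alleles,
  theta correction, or pedigrees beyond two individuals.
* mtDNA haplogroup calling, ancestry clustering, tree building and skyline
  reconstruction are out of scope; the package starts from called
  genotypes, haplogroup frequencies and aligned sequences.
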