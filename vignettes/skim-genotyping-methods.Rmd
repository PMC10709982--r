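---
title: "Skim-sequencing genotyping, imputation and genomic prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skim-sequencing genotyping, imputation and genomic prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimpute)
```

# The problem

Genotyping-by-sequencing from very low ("skim") whole-genome coverage —
0.05–2 bases sequenced per reference base — cannot observe both alleles at
most heterozygous sites, and at sub-1x coverage it does not observe most
sites at all. Skim pipelines therefore lean on a phased reference panel of
haplotypes: the sparse read evidence anchors the sample onto panel
haplotypes, and the panel fills in the rest. For genomic prediction in
livestock the end product is not the genotypes themselves but the genomic
estimated breeding value (GEBV), a linear combination of genotype dosages at
a fixed prediction SNP set with previously estimated SNP effects. skimpute
implements this pipeline end to end at desk scale: simulation of the study
system, genotype calling from long-read pileups, reference-panel
construction, two imputation engines, SNP-BLUP prediction, and the
evaluation metrics used to compare genotyping sources.

Long-read (nanopore-style) data shape two design choices. First, base
errors are several percent, so calls must weigh base qualities rather than
trust individual bases. Second, a single read of a couple of kilobases can
span several SNP, so reads carry phase information that genotype-likelihood
pipelines discard; the read-aware engine is built around exactly this
signal.

# Genotype calling

## Q-score likelihoods

For a biallelic site with alleles $A_1, A_2$ and a pileup of $M$ reads with
observed bases $b_i$ and phred-derived error probabilities $e_i$, the
likelihood of genotype $G = \{A_1, A_2\}$ is

$$ GL(G) = \prod_{i=1}^{M} \left( \tfrac12 \Pr(b_i \mid A_1) +
   \tfrac12 \Pr(b_i \mid A_2) \right), \qquad
   \Pr(b \mid A) = \begin{cases} 1 - e & b = A \\ e/3 & b \ne A,\end{cases} $$

the classical per-read mixture over the two allele copies. Bases matching
neither allele contribute $e/3$ under both alleles, so third-allele noise
penalizes every genotype equally. An empty pileup yields the uninformative
triple $(1,1,1)$. Likelihoods are kept on the linear scale internally and
phred-scaled (PL, normalized to minimum 0) only in VCF output, which avoids
underflow surprises while keeping the formula literal in code. Input phred
values are capped at Q40 so $e = 0$ never occurs.

## CpG methylation masking

Methylated cytosines elevate the miscall rate of nanopore basecallers, and
crucially the reported base qualities do not reflect the elevation — the
artefact is invisible to the likelihood model. Methylation affects the
strand carrying the cytosine, so the caller genotypes potential methylation
sites from the non-methylated strand only: at the C of a forward-strand CpG
only reverse-strand observations are kept, and symmetrically for the
reverse-strand C (the G on the forward strand). A fully masked column
proceeds with depth 0. The mask is applied before likelihoods in the
Q-score path and, by default, to the read evidence of the read-aware
imputation engine as well, since the artefact corrupts that evidence
identically.

## Minimum allele count (MAC) calling

The MAC caller is the hard-call alternative: within coverage bins, an
allele is accepted when seen in at least `mac` reads; both alleles passing
gives a heterozygote, one a homozygote, none a missing call. The default
bin table — depths 1–4 require 1, 5–9 require 2, and ≥10 require
$\lceil 0.15\,d \rceil$ — grows the threshold roughly with the noise floor
($e \approx 3\%$ per base, so at depth $d$ about $0.03 d$ reads support a
wrong base, and $0.15 d$ sits five-fold above that); the table is a
configurable `mac_rule()` and is recorded with the calls. Bases matching
neither allele count toward the bin depth but toward neither allele.

# Imputation

Both engines are built on the Li–Stephens haplotype-copying model: a gamete
is an imperfect mosaic of the $H$ panel haplotypes; between adjacent panel
sites at distance $d$ bp the copied haplotype switches with probability
$p = 1 - \exp(-\rho \, s \, d)$ (recombination intensity $\rho$ per bp,
dimensionless scale $s$), landing uniformly so each haplotype's transition
row is $(1-p)\delta + p/H$; a copied haplotype emits the opposite allele
with mismatch probability $\varepsilon$. The forward–backward passes are
rescaled at every site and are exact; both kernels are verified against
exhaustive path enumeration in the test suite (tolerance $10^{-9}$).

**Defaults and units.** $\rho = 10^{-6}$/bp matches the per-bp mosaic
switch rate of the default sample simulation (the model is then exactly the
generative process up to emission noise); $s = 1$;
$\varepsilon = 10^{-3}$ absorbs panel-copying error independently of base
error, which enters through the genotype likelihoods or per-base read
evidence instead.

## Diploid genotype-likelihood engine

The GL engine consumes the Q-score likelihood triples (uninformative at
uncovered sites) and runs the forward–backward over ordered haplotype pairs
($H^2$ states; transitions factorize per gamete, so an update is $O(H^2)$,
not $O(H^4)$). The emission of state $(j,k)$ is the site's GL of the allele
pair implied by the two copied haplotypes, each smoothed by $\varepsilon$.
It returns per-site genotype posteriors and dosages for every panel site,
including sites with no data. Memory is held at $O(H^2 \sqrt{L})$ by
checkpointing the forward pass and recomputing it blockwise during the
backward pass. This is the engine family that treats sites as independent
observations once likelihoods are formed — the mechanism shared by
likelihood-based imputation tools.

## Read-aware engine

The read-aware engine models what the GL engine throws away: all
observations on one read came from the same parental gamete. Each read
carries a latent label in $\{1, 2\}$, and the sampler is a two-block Gibbs
on the pair (gamete copying paths, read labels):

1. **Paths given labels.** For each gamete, the reads currently labelled to
   it define per-site evidence products, and a concrete reference-copying
   path is drawn exactly by forward-filtering backward-sampling.
2. **Labels given paths.** Given the two sampled paths the reads are
   conditionally independent, so each read's label is resampled from its
   exact conditional likelihood under the two paths.

Two extra moves fix the mixing problems this state space is known for: a
collapsed Metropolis *breakpoint move* proposes flipping the labels of all
reads starting beyond a random site and accepts on the marginal
(forward-likelihood) ratio with paths integrated out — without it, phase
blocks that share no read can settle into opposite labelings and
single-read updates cannot cross between the symmetric modes; and a global
label swap (accepted with probability ½ by symmetry) keeps the gamete
identities exchangeable. After burn-in, each sweep contributes a genotype
posterior as the convolution of the two gametes' *marginal*
forward–backward allele posteriors (Rao-Blackwellized over paths; gametes
independent given labels), and sweeps are averaged. The labels returned to
the caller are finalized as the per-read argmax under the last sampled
paths; the label trace keeps the raw posterior samples. Defaults: 60
sweeps, 20 burn-in, single chain, labels initialized uniformly at random
from the seed. With no reads the output reduces to the panel-frequency
prior (dosage $2p$ per site up to $\varepsilon$-smoothing).

## Reference panels

Panels are filtered with strict minor-allele-frequency cutoffs
(`MAF > 0.1/0.2/0.3` on the panel's own haplotypes), always retaining the
prediction SNP set so the predicted loci can never be filtered away; the
smallest panel is the prediction set alone (the HD-array analogue). The
filtered-panel invariants — prediction set always a subset, retained count
non-increasing in the cutoff, idempotence — are enforced by tests.

# Prediction and evaluation

GEBVs are the raw SNP-BLUP product $\hat a = M \hat g$ with $M$ the
$n \times m$ dosage matrix at the prediction sites and $\hat g$ the fixed
effect vector; no centering or scaling, matching the standard formulation.
Imputed genotypes enter as posterior-mean dosages; hard-call sources enter
as integer dosages; missing dosages are imputed to the column mean by
default. Evaluation metrics: Pearson correlation with Fisher-z 95%
intervals; prediction bias as the OLS slope of reference on test GEBVs
minus 1; imputation accuracy as matching hard calls over all evaluated
cells (missing counts as a mismatch, the denominator being the full
prediction-site count); duplicate-run concordance over sites non-missing in
both runs (the stats-tool convention — the source description leaves
missing-site handling open); quartile-transition counts with rank ties
broken by sample order and earlier quartiles taking the remainder; and
coverage-outlier dropping at one sample standard deviation from the
per-coverage mean. The outlier rule is two-sided by default
(`|c - mean| > sd`) with a one-sided (`low`) switch: in practice the
low-coverage tail is what fails, but realized coverage can also overshoot a
nominal subsampling target, and dropping both tails is the conservative
reading of "more than one standard deviation from the mean".

The grid runner sweeps coverage × panel × method over independent
simulation replicates, with deterministic per-stage seeds derived from the
base seed, and scores every cell against the truth-genotype GEBVs. On
synthetic data the natural reference is the truth itself; there is no
analogue of a separate reference genotyping technology, so correlations are
truth-correlations.

# The synthetic-data generator

The generator defines the study conditions and stands in for data that
cannot ship with a package: a large cattle cohort's haplotype panel and
nanopore runs.

* **Sites.** 2,000 biallelic SNP uniformly placed on a 2 Mb chromosome
  (one per kb, the density of a whole-genome panel scaled to desk size);
  25% form the prediction set (500 sites); 10% are CpG-flagged, alternating
  forward/reverse strand, with ref allele C (forward) or G (reverse). CpG
  density per SNP set is a free choice — the methylation literature gives
  no canonical value for "fraction of SNP at CpG context" at panel scale.
* **Allele frequencies.** Beta(0.5, 0.5), truncated to MAF ≥ 1/H. The
  U-shape yields many rare variants, so the MAF-filter sweep meaningfully
  shrinks the panel (as a real sequence panel does) instead of being a
  no-op.
* **Panel.** 200 haplotypes copied as recombinant mosaics of 32 founders
  (switch rate 5×10⁻⁶/bp, i.e. LD decaying on a ~200 kb scale). A founder
  mosaic reproduces LD decay with minimal machinery; a coalescent backend
  could replace it without touching downstream code.
* **Samples.** 20 diploids, each haplotype a mosaic of panel rows at
  1×10⁻⁶ switches/bp (~2 switches per chromosome) — samples are
  near-panel, as for a within-population reference.
* **Reads.** Uniformly placed, geometric-like lengths with mean 1,792 bp;
  drawn until total bases first reach the target coverage, so realized
  coverage is within one read length of nominal and per-site depth is
  Poisson. Each read samples one gamete fairly (origin recorded for test
  oracles) and a uniform strand. Base error e = 10^(-1.5) ≈ 3.2% (phred
  Q15, inside the 2.7–7% nanopore range); at CpG sites on the
  methylation-prone strand the error is inflated 10-fold while recorded
  qualities still encode e. The 10× factor is a free parameter chosen to
  make the artefact unambiguous, not an estimate of basecaller behaviour.
* **Effects.** Gaussian N(0, 1) at all prediction sites by default
  (`prop_causal = 1`), the infinitesimal regime SNP-BLUP assumes.

**What passing tests do and do not show.** The generator reproduces the
statistical skeleton the methods rely on — LD decay, rare-variant-heavy
spectra, Poisson depth, quality-blind CpG miscalls, reads spanning multiple
SNP — but not indels or structural variants, homopolymer error modes,
multi-allelic sites, mapping error, breed structure in the panel, or
per-base quality variation. Accuracy numbers from this scenario
characterize the engines under the model's own assumptions; they are not
forecasts for any real cohort.

# Numerical choices and degenerate inputs

Forward/backward vectors are renormalized at every informative site; sites
with uniform emissions preserve total mass exactly and skip the rescan.
Likelihood products use linear scale guarded by the Q40 cap. Hard calls
from posteriors take the argmax with ties to the heterozygote (a tie means
the data cannot distinguish, and the heterozygote is the middle ground);
the same rule applies to dosage rounding. Empty pileup columns, fully
masked columns, zero-read samples and monomorphic panels are all defined
inputs with the limits stated above. Depths outside the MAC bin table are
an error rather than a silent default.

# Problem sizes used by tests and the acceptance script

Unit tests run on miniatures (tens of haplotypes, 100–400 sites) where
brute-force oracles are exact and fast; HMM kernels are compared against
exhaustive path enumeration at H = 3, L = 3–4. The end-to-end sweeps use
the default scenario above with five replicates: the coverage sweep
{0.05, 0.1, 0.5, 2}× with the read-aware engine (plus five duplicate
samples for concordance), and the 0.1× engine/panel contrast. These sizes
were chosen so a full run is a few minutes of single-core compute while
keeping per-cell Monte Carlo error well below the effect sizes being
checked.

# Known limitations

* Single linear chromosome; no genetic map (uniform recombination).
* The Gibbs conditional's leave-one-out correction is per-site, not a full
  chain recomputation; with very long reads over very sparse panels the
  residual self-influence grows.
* The diploid engine's $H^2$ state space is exact but limits panels to a
  few hundred haplotypes; larger panels need subsampling before the call.
* The genotype posterior of the read-aware engine assumes gamete
  independence given labels; no joint diploid re-estimation is performed.
* Engines are deliberately simplified mechanisms for contrast experiments,
  not re-implementations of any production imputation tool.
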