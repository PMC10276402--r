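---
title: "Models and methods behind slamburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slamburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcription of most genes is bursty: short episodes of activity separated
by silent intervals. Conventional single-cell RNA-seq constrains the
*dimensionless* shape of bursting — burst size $b$ (transcripts per burst)
and burst rate $a$ (bursts per transcript lifetime) — but cannot attach a
timescale, because the steady-state count distribution is invariant to
rescaling time. Metabolic labelling (a 4sU pulse of duration $t$ followed by
chemical conversion that reads incorporated sites as T>C mismatches) breaks
this degeneracy: the fraction of labelled reads per cell carries the decay
rate $\delta$, and therefore burst frequency $\kappa = a\delta$ and lifetime
$\gamma = 1/\delta$ in real minutes.

`slamburst` implements joint Bayesian inference of
$\theta = (\mu, a, \gamma)$ per gene — with $\mu$ the mean expression level,
$b = \mu/a$, $\kappa = a/\gamma$, $\delta = 1/\gamma$ derived per posterior
draw — from per-cell UMI counts, per-cell capture efficiencies and per-read
T>C conversion counts, plus an exact stochastic simulator that generates
this data shape from first principles.

## Observation model

Under the instantaneous-burst limit of the telegraph model
($\delta \ll k_{off}$, $k_{on} \ll k_{off}$), the latent transcript count
$m$ is negative binomial, $P(m) = \mathrm{NB}(m \mid a,\, b/(1+b))$.
Observed UMI counts follow a Poisson approximation of binomial capture,
$P(l \mid m, \alpha) = \mathrm{Pois}(l \mid m\alpha)$, with the cell's
capture efficiency $\alpha$ supplied by the user (it is estimated upstream
from spike-ins and consumed here as data). The approximation deliberately
allows $l > m$, which keeps the sampler mobile in regions where the
truncation bound would otherwise forbid an observation. Latent sums are
truncated at the finite state projection bound $M$, the 0.9999 quantile of
$P(m)$, leaving at most $10^{-4}$ of the mass outside.

A pulse of scaled duration $\tau = t\delta$ splits $m$ into surviving
transcripts $s$ (binomial thinning with survival $e^{-\tau}$; marginally
again negative binomial with thinned odds — an exact identity the test
suite verifies at $10^{-10}$) and new transcripts $n$, whose marginal uses
an approximate non-equilibrium solution involving a terminating Gauss
hypergeometric factor ${}_2F_1(-n, -a, 1-a-n; (1+b)/(e^\tau + b))$. Because
$-n$ is a non-positive integer the series terminates after $n+1$ terms and
is evaluated directly in compiled code with magnitude rescaling.

The per-read conversion count mixes a background Poisson rate
$u\lambda_s$ and a labelled rate $u(\lambda_n + \lambda_s)$ over the
gene-specific uracil-content distribution $P(u)$, weighted by the
new-transcript fraction $n/m$. Since that mixture is linear in $n/m$, the
conversion kernel for every $m$ reduces to
$w_m A + (1 - w_m) B$ with $w_m = E[n/m \mid m]$ and $A, B$ two
$\theta$-independent mixture vectors — the central performance decision:
per proposal only the weights $w_m$ are rebuilt, then mixed per cell
through the posterior $P(m \mid l, \alpha)$.

Five likelihoods support the ablation study: `loglik_L1` (UMI counts only;
provably flat in $\gamma$), `loglik_L2` (cell-specific conversions),
`loglik_model2` = L1+L2 (the full model), `loglik_L3` (cell-pooled
conversions; depends on $\theta$ only through $\tau$, hence flat in
$(\mu, a)$) and `loglik_model3` = L1+L3. The multinomial coefficient is
omitted everywhere: it is constant in $\theta$ and cancels in the
Metropolis ratio, so no posterior changes; absolute likelihood values are
shifted by that constant.

## Unstable parameter space and the model switch

The hypergeometric approximation for $P(n)$ oscillates when $a$ and/or $b$
grow large or $\tau$ becomes small, eventually producing negative values.
`slamburst` treats negativity or non-finiteness anywhere on the projection
support as a per-evaluation *instability flag*, never an exception: the
likelihood value becomes $-\infty$, the proposal is rejected, and the
rejection is recorded. If, within a rolling window of $w$ steps (never
looking before step $w/2 + 1$), at least $w/20$ steps saw such a rejection,
the chain restarts from a fresh initialisation under model 3, whose pooled
conversion likelihood never evaluates the approximation.

One situation the in-chain rule cannot reach: a gene so deep in unstable
space that *no* initialisation draw ever has positive model-2 density. The
restart rule would never fire because the chain never starts. Our design
choice: when more than 90% of a failed initialisation's draws were
rejected for instability, the gene falls straight through to model 3 with
`switch_step = 0`; any other initialisation failure is reported as an
error for that gene. This is the only point where the package extends the
published procedure, and it only triggers where model 2 is unusable anyway.

## The sampler

A Metropolis-adjusted Langevin algorithm inside a Gibbs sweep updates
$(\mu, a, \gamma)$ in that fixed order, each sub-step conditioning on the
freshest values of the others. The proposal for coordinate $k$ is
$\mathcal{N}(\theta_k + S_k \nabla_k, \sqrt{2 S_k})$ — the printed form,
with $\sqrt{2S_k}$ as the normal's scale parameter, is followed verbatim;
deviating from the textbook step-size convention affects efficiency only,
not correctness. Gradients are secant estimates from the last accepted
move, reset to zero on rejection. Scales adapt as
$S_k \leftarrow \exp(\log S_k + \eta (A - 0.574))$ with
$\eta \leftarrow 0.999\,\eta$, initialised at
$S = \theta^{(1)}/100$, $\nabla = 0$, $\eta = 0.1$; rejections from outside
the uniform prior box ($\mu, a \sim U(0, 10^5)$, $\gamma \sim U(1, 10^5)$)
or from instability adapt with $A = 0$, the natural acceptance probability
of an impossible proposal.

Initialisation is semi-random: $\mu$ at the moment estimate
$\hat\mu = \overline{l_c/\alpha_c}$, $a$ log-uniform on $[1, 10]$, and
$\gamma \sim \mathcal{N}(\hat\gamma, \hat\gamma/5)$ with
$\hat\gamma = -t / \log(\mathrm{clamp}(1 - (\lambda - \lambda_s)/\lambda_n,
0.1, 0.9))$, where $\lambda$ is the gene's overall conversion rate computed
as total converted Ts over total genomic Ts across reads. Draws repeat
until the posterior density is positive (bounded at 1000 tries).

Chains run 5000 steps when $\hat\mu < 1000$ (posterior = last 2500 steps,
thinned by 2, 1250 samples; instability window $w = 500$) and 1500 steps
otherwise (window 1000, 500 samples, $w = 100$). Point estimates are
posterior means; confidence is $CV = \mathrm{sd}/\mathrm{mean}$, both on
the thinned tail samples, with derived parameters transformed per draw
before summarising. `select_genes` keeps genes whose worst CV over
$(\mu, a, b, \kappa, \delta)$ is at most 0.45; $\gamma$ is excluded from
the gate as a monotone transform of $\delta$.

### Numerical choices

* Probabilities are floored at $10^{-300}$ before logging; clip events are
  counted (`clip_count()`).
* Extreme $\tau$ is safe by construction ($e^{-\tau}$ underflow and
  $e^{\tau}$ overflow both collapse to correct limits), but proposals whose
  projection bound would exceed 50x the bound at initialisation are
  rejected as numerically out of support: the latent grid, and with it the
  $O(M^2)$ kernel build, would otherwise grow without bound chasing
  proposals the likelihood is about to reject.
* The normalising convolution of the new/surviving split is computed by
  direct $O(M^2)$ summation in C++ rather than FFT, avoiding roundoff sign
  flips in the far tail; the resulting weights are clamped to $[0, 1]$.
* At $m = 0$ the mixture weight $n/m$ is $0/0$; the conversion pmf is
  defined as the background-only mixture, consistent with a cell that has
  no transcripts to label (the term carries essentially no posterior weight
  whenever reads exist).

## The simulator as a stated world

`simulate_gene_dataset` is a first-class module, not a fixture: Gillespie's
exact algorithm over six reactions and two transcript pools (pre-pulse
`RNA0`, in-pulse `RNA1`), burn-in $t_0 = 2\times10^5$ min from
$(0, 0, 0, 1)$, then a pulse of $t_1 = 1000$ min with synthesis redirected
to the new pool. Sequencing noise: $\alpha \sim \mathrm{Beta}(1, 9)$,
UMIs binomially captured per pool, reads per UMI zero-truncated Poisson
($\nu = 5$), uracils per read Poisson ($\hat u = 60$), conversions binomial
at $\lambda_s = 0.01$ (background) or $\lambda_s + \lambda_n$ with
$\lambda_n = 0.075$ (labelled). These defaults are the published simulation
conditions and are not revisited; cell numbers are the only quantity the
tests scale down (to 500–1000 cells) to fit a desk-scale compute budget,
and the acceptance report records the `n` used. Bursting parameters map to
rate constants with $k_{off} = 1$ per minute, $\beta = b\,k_{off}$,
$\kappa = k_{on}$.

What the generator emulates: the full generative chain the likelihood
assumes, plus two deliberate mismatches the model tolerates by design —
capture is truly binomial (the model uses the Poisson approximation) and
bursts have finite duration ($k_{off} = 1$, the model assumes the
instantaneous limit). What it does not emulate: alignment artifacts,
barcode collisions, doublets, ambient RNA, position-dependent read T
content (reads have no genomic coordinates; $u \sim \mathrm{Pois}(\hat u)$
stands in), or UMI-consensus collapsing (reads of one UMI are independent).
A green recovery test therefore establishes correctness of the inference
machinery under the model's own assumptions plus those two mismatches — it
does not certify performance on data with artifacts the generator omits.

At moderate cell numbers the recovery targets carry real sampling
variability: with $a = 0.5$ the latent count distribution is heavy-tailed,
and the dataset's own realised burst size (the quantity the likelihood can
see) fluctuates around the generating value from seed to seed. The
acceptance criterion is therefore stated, and tested, as agreement within
three *posterior* standard deviations rather than a fixed percentage.

One mismatch deserves explicit mention because it tilts, not just widens,
the recovery. The generator's reads are clustered — the several reads of a
UMI all inherit its transcript's pool, and every read in a cell shares one
realisation of the new/surviving split — while the multinomial conversion
likelihood treats reads as independent draws given $(l, \alpha)$. The
resulting extra within-cell dispersion of conversion fractions is absorbed
by the fit as slightly burstier, faster-turnover kinetics: on 1000-cell
datasets $\delta$ lands a few-to-15 percent high and $a$ correspondingly
low, with $b$ high. A self-consistency experiment (data drawn from the
likelihood's own generative assumptions, reads independent) recovers all
parameters without tilt, which localises the effect entirely to the
generator/model discrepancy rather than the sampler or the kernels.

## Open questions resolved

* Whether the pure-L2 ablation conditions on observed $l$: we follow the
  likelihood as printed (it conditions on $l$ per cell); "without the UMI
  counts" refers to omitting the L1 factor.
* The tolerance of the convolution $\approx P(m)$ normalisation is not
  stated; we assert 5% relative error over the distribution bulk and treat
  the tails qualitatively.
* The model-3 restart re-initialises $\theta^{(1)}$ afresh (reuse is not
  stated); the instability monitor is disabled under model 3.
* Sub-step order is $(\mu, a, \gamma)$, matching the printed tuple; the
  source names no order.

## Limitations

Single-pulse, single-dataset chains only (no joint chains across pulse
durations); no cell-cycle stratification or allele-specific inference; no
raw-read processing — capture efficiencies, $\lambda_n$ and per-read
conversion tables are inputs. Genes whose data are incompatible with the
projection bound at every initialisation draw are skipped with a logged
reason rather than forced.
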