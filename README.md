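# dyadlearn

Simulation and analysis of joint learning in hierarchical dyads.

Many organisational tasks split decision-making across two levels: a
higher-level **strategy agent** (H-agent) frames the problem — here, by
choosing which information to disclose — while a lower-level **operational
agent** (L-agent) executes within that frame.  Because the H-agent only
sees coarse feedback about the L-agent's performance, and the L-agent can
only learn inside the frame it is given, the two agents can either
bootstrap each other into competence or trap each other in a
self-reinforcing deadlock.  `dyadlearn` simulates this interaction and
ships the analysis toolkit needed to characterise its outcome
distribution: learning curves, switch rates, median-split clustering,
convergence classification, and Hartigan's dip test of unimodality.

It is aimed at researchers in computational cognitive modelling and
organisational learning who want to reproduce, probe or extend this class
of hybrid reinforcement-learning/supervised-learning models.

## The model

Each epoch, the environment presents inputs **x** = (x1, x2, x3), integers
drawn uniformly from [0, 100], with hidden value

    y = w · x,  w a fixed random permutation of {0.9, 0.5, 0.1}.

The H-agent first picks an information filter **f** — an indicator vector
disclosing exactly two of the three components (the optimal filter hides
the 0.1-weight component).  The L-agent then estimates five inputs in a
row with a simple perceptron,

    o = Σ_j v_j · x_j · f_j,

updating its weights after every trial by the delta rule

    v_j ← v_j + λ · (y − o) · f_j · x_j ,

with initial weights from U[0, 1].  After the fifth trial the H-agent
receives the epoch's average percent error %E and reinforces the chosen
filter's attraction,

    a_k ← a_k + max{0, 100 − %E},

choosing the next filter by the softmax rule p_i ∝ exp(γ·a_i/100) (the
sensitivity γ is calibrated per unit of reward *fraction*, the scale of
the epoch's bonus-winning probability; see the methods vignette).  A run
is 20 epochs — 20 filter choices, 100 estimations.  The two free
parameters are γ (canonical best fit 0.55) and λ (1.3e-5); both are
estimated by grid search minimising the sum of normalised mean square
deviations between simulated and target 20-epoch curves of estimation
error and disclosed-information rate.

## Worked example

```r
library(dyadlearn)
cohort <- run_cohort(n_dyads = 2000, gamma = 0.55, lambda = 1.3e-5,
                     seed = 7, keep_trials = FALSE)
cohort
#> <hl_cohort> baseline: 2000 dyads x 20 epochs (gamma=0.55, lambda=1.3e-05, seed=7)
#>   mean error epoch 1: 29.89; epoch 20: 12.52

set.seed(7)
analyze_cohort(cohort, n_boot = 500)
#> <hl_analysis> 2000 dyads, window = last 5 epochs
#>   median long-run error: 12.97
#>   dip D = 0.0317, Monte Carlo p = 0 (n_boot = 500)
#>   learning dyads converged to optimal filter: 76.1%
#>   deadlocked dyads settled on a suboptimal filter: 63.2%
#>   non-converging deadlocked choice shares (last 5): 20/43/37%
#>   switch rate (last 5): learning 0.08, deadlocked 0.20
```

Reading the output: the cohort's mean error falls from ~30 to ~12.5 — a
classical learning curve — but the *distribution* of long-run error is
bimodal (the dip test rejects unimodality, p < 0.002): roughly half the
dyads (the "learning" group, below the median) lock onto the optimal
filter and approach the attainable floor of 2.5, while "deadlocked" dyads
either settle on a suboptimal filter or keep wandering, switching filters
four times more often in the final epochs.  All dyads are identically
parameterised — the split is produced entirely by early chance experiences
feeding back on themselves.

Ablations isolate each agent's contribution:

```r
fixed <- run_ablation_fixed_filter("optimal", lambda = 1.3e-5,
                                   n_dyads = 2000, seed = 8)
median(last_epochs_error(fixed))   # ~4.0: L-agent alone learns fine
frozen <- run_ablation_frozen_L("correct", gamma = 0.55,
                                n_dyads = 2000, seed = 9)
dip_test(last_epochs_error(frozen))  # multimodal again: H-agent alone
                                     # cannot reliably find the optimum
```

A command-line front end wraps the same functions:

```sh
exec/dyadlearn simulate --n-dyads 2000 --gamma 0.55 --lambda 1.3e-5 \
    --seed 7 --out runs/baseline
exec/dyadlearn analyze --in runs/baseline --seed 1 --out runs/baseline
exec/dyadlearn reproduce --scale desk --seed 1 --out runs/report
```

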