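# ssdopt

Surrogate-assisted sample size determination for clinical trials with
several design parameters, several objectives, and operating
characteristics that must be estimated by simulation.

## The problem this package addresses

When a trial's power or type I error has no analytic formula — multilevel
structures, multiple correlated endpoints, misspecified working models —
each candidate design must be assessed by simulating the whole trial and
its analysis hundreds of times. With several design parameters (sample
sizes, cluster counts, allocation ratio, nominal test level) and several
conflicting objectives to minimise, a grid or greedy search over
Monte Carlo estimates is computationally hopeless.

`ssdopt` solves the constrained multi-objective problem

$$\min_{x \in X}\; f_i(x),\ i = 1,\dots,B
  \qquad \text{s.t. } g_j(x) = \mathrm{OC}_j(x) - \tau_j \le 0$$

with efficient global optimisation (EGO): each simulation-estimated
operating characteristic gets a Gaussian-process surrogate with fixed
heteroscedastic Monte Carlo noise ($\omega^2 = \hat p(1-\hat p)/N$ per
observation), and the next design to evaluate maximises the expected
hypervolume improvement penalised by the probability of being deemed
feasible after evaluation,

$$EI(x) = \bigl[H(A \cup \{f(x)\}) - H(A)\bigr]\,
  \prod_j \Phi(-m_{j,+}/s_{j,+}),$$

where a design is deemed feasible when the upper $p$-quantile
$m + \Phi^{-1}(p)s$ of each constraint's predictive distribution is
non-positive. The result is a Pareto *approximation set* of trial
designs — the menu of available trade-offs — scored by dominated
hypervolume (computed exactly in 2 and 3 objectives).

It is aimed at trial statisticians who can write a short R function that
simulates one trial and returns a 0/1 reject indicator; everything else —
quasi-random initial designs, surrogate fitting, acquisition search,
budget accounting, checkpoint/resume, logging — is provided. Two built-in
problems serve as templates and test beds: an analytically tractable
cluster randomised trial (with closed-form power and an exhaustive true
Pareto set) and a two-endpoint trial with partially nested therapists,
crossed doctors, and likelihood-ratio analysis of deliberately
misspecified univariate mixed models.

## A worked example

Find the trade-off between total participants ($2n$) and total clusters
($2k$) for a cluster randomised trial (within-cluster variance 0.95,
between-cluster variance 0.05, standardised effect 0.3, one-sided
$\alpha = 0.025$) subject to type II error at most 0.1, with 20 initial
designs plus 30 iterations at $N = 100$ simulated trials per evaluation:

```r
library(ssdopt)

params  <- cluster_params()                    # sigma_W^2 = .95, sigma_B^2 = .05, delta = .3
problem <- cluster_problem(params)             # objectives (2n, 2k), beta <= 0.1
sim     <- cluster_simulator(params)

run <- run_ego(problem, sim,
               ego_control(iterations = 30, init_size = 20,
                           n_per_eval = 100, seed = 42))
run
#> <ego_run> cluster_rct: 49 designs evaluated (30 iterations + initial design)
#>   simulator draws: 5000; approximation set size: 10
#>   dominated hypervolume: 78388
```

So 5000 simulated trials (the exact budget: $(20 + 30) \times 100$)
bought a 10-design approximation set. `tidy(run)` returns it as a tibble;
the cheapest designs by total sample size:

```r
dplyr::arrange(tidy(run), total_n)
#>       k     n total_n total_k estimate_type2  q_type2
#>      59   280     560     118           0.07 -0.00270
#>      57   288     576     114           0.09 -0.00800
#>      52   301     602     104           0.07 -0.00464
#>      49   322     644      98           0.09 -0.0113
#>      47   351     702      94           0.09 -0.0202
#>      39   353     706      78           0.09 -0.00253
#>   ...
```

`estimate_type2` is the pooled Monte Carlo estimate at each design and
`q_type2` the upper 90% feasibility quantile under the final surrogate
(non-positive means deemed feasible: e.g. 560 participants in 118
clusters, or 706 participants if only 78 clusters are available). Because
this example has closed-form power, the returned designs can be checked
against `cluster_power_analytic()` — in this run all ten have true type
II error below the nominal 0.1 — and against the exhaustive optimum:

```r
truth <- cluster_true_pareto(params)
dominated_hypervolume(as.matrix(truth[, c("total_n", "total_k")]),
                      problem$ref_point)
#> [1] 88288
```

i.e. the 50-evaluation run captured 78388/88288 ≈ 89% of the attainable
hypervolume. `autoplot(run)` draws the evaluated designs and the
approximation front; `ego_diagnostics(run)` reports standardised
prediction errors of the surrogate; `run_fixed_design()` is the
space-filling comparator; `resume_ego(run, k)` continues a run (also from
a checkpoint file, bit-reproducibly).

The two-endpoint multilevel problem is available as
`pace_problem()` + `multilevel_simulator()`, with the same interface, three
objectives (participants, therapists, doctors) and two constraints
(power, familywise type I error).

## Command line

A thin wrapper over the same functions lives at `inst/cli/ssd-opt`:

```sh
ssd-opt run       --config cfg.yaml
ssd-opt resume    --checkpoint out/checkpoint.json --iterations 20
ssd-opt fixed     --config cfg.yaml --points 50
ssd-opt report    --checkpoint out/checkpoint.json
ssd-opt benchmark --config cfg.yaml --repeats 20 --sizes 50,200
```

Configs are YAML or JSON naming a built-in problem (or an R file defining
`problem` and `simulator`), with all parameters overridable; unknown keys
are rejected. Outputs are CSV (evaluation log, approximation set) and
JSON (diagnostics, checkpoint). Exit codes: 0 success, 1 user error,
2 internal error.

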