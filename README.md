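# leukopred

Dose-driven probabilistic forecasting of peripheral blood leukocyte counts
during 6-mercaptopurine (6-MP) maintenance therapy for paediatric acute
lymphoblastic leukaemia.

During maintenance therapy the daily oral 6-MP dose is titrated to hold the
leukocyte count in a narrow band (≈1.5–3.0 × 10⁹/L).  The marrow reacts to
dose changes with a delay of weeks, while infections and assay noise add
large short-term fluctuations — a hard setting for dosage decisions.  This
package implements Bayesian nonlinear state-space models that forecast the
leukocyte count from the dosing history, plus the evaluation machinery
needed to judge such forecasts, for biostatisticians and PK/PD modellers
working on chemotherapy dose individualisation.

## Models

**TCM** (two-compartment model) couples a kinetic-pharmacodynamic drug
effect *M* (1/day) to the log leukocyte count *L*:

    dM/dt = k_me ( e_tgn d(t) / (d(t) + h) − M )
    dL    = ( k_pl_max ρ^γ / (ρ^γ + e^{γL}) − M − k_L ) dt + σ_L dB_t
    l_k   = L_k + ε_k,   ε_k ~ N(0, σ_leuk²)

with `d(t)` the BSA-normalised dose given in the last 24 h.  The drug
equation is solved exactly per sub-step; the leukopoiesis SDE is
discretised by Euler–Maruyama at Δt = 0.25 day.

**TCM-CRP** adds a latent infection level *V* — an Ornstein–Uhlenbeck
process observed through log(CRP + 1) — that inflates the leukopoiesis
volatility, `σ_L(V) = σ_L⁰ exp(β_crp V)`: a stochastic-volatility model
that *downweights* counts measured during infections instead of chasing
them.

**JM**, the comparator, is an 8-compartment ODE model (3-compartment 6-MP
pharmacokinetics feeding a 5-compartment leukopoiesis maturation chain,
steady-state initialised, dose impulses via solver events).  **NM**, the
baseline, is i.i.d. `N(μ, σ²)` on the linear scale.

Inference: extended-Kalman-filter marginal likelihood (compiled core,
reference R kernels), MAP estimation over log free parameters with vague
N(0, 10) priors by Nelder–Mead, joint cross-patient estimation of the
infection hyperparameters `(σ_ou, θ_ou, β_crp)`, and rolling-origin
cross-validation with RMSE/MAE and central-interval coverage CP₅₀/CP₉₀ on
the linear scale.  A synthetic-patient simulator generates cohorts with the
clinical structure the models target (weekly visits, stepwise dose
intensification with pauses, infection episodes, growth in BSA), so the
whole pipeline is testable without patient data.

## Worked example

```r
library(leukopred)

## a synthetic patient: ~500 days of daily dosing, weekly counts and CRP
sim <- simulatePatient(simulationScenario(seed = 42))
sim$record
#> PatientRecord 'sim42'
#>   span: 498 days | 499 dose days | 72 visits (66 leukocyte, 65 CRP) | 17 BSA points

## MAP fit of the state-space model
fit <- mapFit(sim$record, tcmParameters())
fit
#> MapFit [tcm]: logPosterior=22.9024 converged=TRUE (408 evaluations)
#> TcmParameters
#>   free : eTgn=0.2802 h=11.97 kPlMax=0.8802 kL=0.4286 sigmaL=0.08041
#>   fixed: gamma=1 kMe=0.1 rho=5 sigmaLeuk=0.057 tDur=1 dt=0.25

## four-week forecast from day 150 under the administered doses
pred <- predictHorizon(sim$record, fittedParameters(fit),
                       tFrom = 150, horizon = 28)
cbind(time = pred@times, predicted = round(pointPrediction(pred), 2),
      round(predictionIntervals(pred, 90), 2))
#>        time predicted   lo   hi
#> [1,] 152.75      1.80 1.42 2.29
#> [2,] 162.75      1.79 1.40 2.30
#> [3,] 168.50      1.79 1.40 2.29
#> [4,] 175.25      1.79 1.40 2.29

## rolling-origin cross-validation (2-week horizon)
runTsc(sim$record, tcmParameters(), horizon = 14)
#> TscReport: patient 'sim42', model tcm, horizon 14 days
#>   32 rounds (0 failed), 58 held-out observations
#>   RMSE=0.400 MAE=0.290 CP50=0.328 CP90=0.672
```

The fitted free parameters sit near the simulator's generating values; the
forecast holds the patient just below 2 × 10⁹/L — inside the therapeutic
band — with 90% intervals of roughly ±25%, and the cross-validated MAE of
0.29 × 10⁹/L is about half of what the naive mean baseline achieves on the
same record.  (CP values below nominal under *estimated* parameters are
expected for MAP fits, which ignore parameter uncertainty.)

Command-line wrappers live in `inst/scripts/`:
`simulate-cohort.R` writes a synthetic cohort as per-patient CSVs;
`crossvalidate.R --model tcm|tcmcrp|jm|nm --horizon 14 --data DIR --out report.json`
cross-validates a cohort directory (for `tcmcrp` the infection
hyperparameters are first estimated jointly across patients).

Patient files use a documented CSV schema (`patient_id, time, dose,
leukocyte, crp, bsa`; empty cells = not recorded, one file per patient);
`readPatientCsv()`/`readCohort()` validate on read, and external column
names can be remapped via `dialect`.

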