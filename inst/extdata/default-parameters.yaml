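# Default model parameters.
#
# `fixed` values are constants of the model variant (not estimated); the
# `free_init` values are the Nelder-Mead starting points of the per-patient
# MAP fits.  All rates are per day, doses in mg/m^2, cell counts in
# 1e9 cells/L, measurement SDs on the natural-log scale.  Every value here
# can be overridden via the constructor arguments or a user-supplied copy of
# this file.
tcm:
  free_init:
    eTgn: 0.3      # maximal drug-effect rate (1/day)
    h: 15.0        # half-saturation dose (mg/m^2)
    kPlMax: 1.0    # maximal proliferation rate (1/day)
    kL: 0.5        # leukocyte elimination rate (1/day)
    sigmaL: 0.1    # leukopoiesis SD (1/sqrt(day))
  fixed:
    gamma: 1.0     # feedback exponent
    kMe: 0.1       # drug-effect elimination rate (1/day); ~10 day TGN time scale
    rho: 5.0       # feedback scale; untreated steady state = rho when kPlMax = 2 kL
    sigmaLeuk: 0.057   # log-scale leukocyte measurement SD (literature value)
    tDur: 1.0      # dose-input window (days)
    dt: 0.25       # state discretisation step (days)
tcmcrp:
  fixed:
    thetaOu: 0.3   # OU mean-reversion rate (1/day); ~3 day infection memory
    sigmaOu: 0.8   # OU diffusion SD; stationary SD ~ 1.0 on log(CRP+1)
    betaCrp: 0.3   # volatility coupling
    sigmaCrp: 0.1  # log(CRP+1) measurement SD (~10% CV at CRP >= 3.5 mg/L)
jm:
  free_init:
    kCm: 1.0       # maximal plasma->TGN metabolism rate
    kTr: 0.8       # maturation transit rate (1/day)
    kPlMax: 1.6    # maximal stem-cell proliferation rate (1/day)
    kL: 0.5        # leukocyte elimination rate (1/day)
    gamma: 1.0     # feedback exponent
    eMax: 0.2      # maximal drug effect on stem-cell production (1/day)
    sigmaLeuk: 0.3 # log-scale observation SD
  fixed:
    kAb: 4.8       # gut absorption rate (1/day); 6-MP absorbed within hours
    kEl: 5.0       # plasma elimination rate (1/day); plasma half-life ~ hours
    k: 1.0         # Michaelis constant of the metabolism term
    vCm: 0.5       # TGN production scaling
    kMe: 0.1       # TGN elimination rate (1/day)
    rho: 5.0       # feedback scale (1e9 cells/L)
    eC50: 10.0     # TGN level of half-maximal drug effect
    rtol: 1.0e-6   # ODE solver relative tolerance
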