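# Synthetic allometric-equation registry (demonstration coefficients,
# not literature values). Forms: power_D = a*D^b; power_D2H = a*(D^2*H)^b;
# loglinear_DH = exp(a + b*lnD + c*lnH); linear_BA = a + b*BA;
# linear = intercept + sum(coef_<P> * P). D in cm, H in m, BA in m^2,
# NB = branch count; output AGB in kg dry mass.
equations:
  - taxon_id: T001
    form: loglinear_DH
    coefficients: {a: -2.2, b: 2.3, c: 0.45}
    source: synthetic endemic broadleaf example
  - taxon_id: T004
    form: power_D2H
    coefficients: {a: 0.04, b: 0.92}
    source: synthetic plantation conifer example
  - taxon_id: T005
    form: power_D
    coefficients: {a: 0.13, b: 2.35}
    source: synthetic invasive broadleaf example
  - taxon_id: T010
    form: linear_BA
    coefficients: {a: 1.5, b: 5200}
    source: synthetic basal-area example
  - taxon_id: T011
    form: linear
    predictors: [D, NB]
    coefficients: {intercept: 0.5, coef_D: 1.8, coef_NB: 0.6}
    source: synthetic multi-stem shrub example
  - taxon_id: generic.broadleaf
    form: power_D
    coefficients: {a: 0.12, b: 2.4}
    source: synthetic generic broadleaf power law
  - taxon_id: generic.conifer
    form: power_D2H
    coefficients: {a: 0.035, b: 0.95}
    source: synthetic generic conifer D2H power law
  - taxon_id: generic
    form: power_D
    coefficients: {a: 0.10, b: 2.4}
    source: synthetic generic fallback
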