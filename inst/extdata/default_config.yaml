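'n': 167.0
seed: ~
grade_weights:
  '0': 0.338
  I: 0.021
  II: 0.255
  III: 0.386
params:
  e_prime:
    meanlog:
    - 2.251291798606495
    - 1.945910149055313
    - 1.90210752639692
    - 1.757857917552374
    sdlog:
    - 0.161960606625144
    - 0.145380177289038
    - 0.145380177289038
    - 0.228865955012556
  E_over_e_prime:
    meanlog:
    - 2.23001440015921
    - 2.054123733695546
    - 2.302585092994046
    - 2.873564639579783
    sdlog:
    - 0.271872623580162
    - 0.140285304249259
    - 0.140285304249259
    - 0.250147301654878
  E_over_A:
    meanlog:
    - 0.182321556793955
    - -0.356674943938732
    - -0.22314355131421
    - 0.0
    sdlog:
    - 0.249427242240076
    - 0.264403531584463
    - 0.264403531584463
    - 0.458894451862509
  DT:
    meanlog:
    - 5.198497031265826
    - 5.43372200355424
    - 5.337538079701318
    - 5.241747015059643
    sdlog:
    - 0.200487678584426
    - 0.159962929774522
    - 0.159962929774522
    - 0.282101215572957
  LAVI:
    meanlog:
    - 3.165475048141086
    - 2.809402695362498
    - 3.044522437723423
    - 3.230804395733474
    sdlog:
    - 0.478691441550918
    - 0.306502174907063
    - 0.306502174907063
    - 0.380226441238806
  EF:
    meanlog:
    - 4.127134385045092
    - 4.204692619390966
    - 4.110873864173311
    - 4.0943445622221
    sdlog:
    - 0.165416562111833
    - 0.249427242240076
    - 0.249427242240076
    - 0.32753110936867
copula_rho: 0.3
copula:
  e_prime:
  - 1.0
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  E_over_e_prime:
  - 0.3
  - 1.0
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  E_over_A:
  - 0.3
  - 0.3
  - 1.0
  - 0.3
  - 0.3
  - 0.3
  DT:
  - 0.3
  - 0.3
  - 0.3
  - 1.0
  - 0.3
  - 0.3
  LAVI:
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 1.0
  - 0.3
  EF:
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 0.3
  - 1.0
missingness:
  E: 0.02
  A: 0.19
  e_prime: 0.11
  DT: 0.27
  LAVI: 0.16
quality_loading: 0.359
comorbidity:
  htn:
  - 0.38
  - 1.0
  - 0.595
  - 0.732
  dm:
  - 0.24
  - 1.0
  - 0.243
  - 0.571
  ihd:
  - 0.1
  - 1.0
  - 0.135
  - 0.411
female:
- 0.46
- 0.667
- 0.351
- 0.643
age:
  meanlog:
  - 4.007333185232471
  - 4.454347296253507
  - 4.0943445622221
  - 4.276666119016055
  sdlog:
  - 0.379
  - 0.234
  - 0.234
  - 0.149
outcome:
  coef:
    E: -0.105360515657826
    E_over_A: 1.68824909285839
    e_prime: 0.746687947487975
    E_over_e_prime: 0.451075619360217
    DT: 0.0
    LAVI: 0.0
  intercept: -5.069
  target_mortality: 0.24
icu_stay:
  meanlog: 0.993251773010283
  sdlog: 0.55
severity:
  apache2:
    meanlog: 3.218875824868201
    sdlog: 0.439
  sofa_adm:
    meanlog: 2.079441541679836
    sdlog: 0.449
  sofa_72h:
    meanlog: 1.791759469228055
    sdlog: 0.6
vasopressor: 0.678
mech_vent: 0.368
ivf:
  meanlog: 7.003065458786462
  sdlog: 1.03
tapse:
  meanlog: 2.995732273553991
  sdlog: 0.224
s_prime:
  meanlog: 2.079441541679836
  sdlog: 0.281
max_reject_iter: 1000.0
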