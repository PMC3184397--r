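# Reduced erythrocyte redox network: H2O2 / superoxide detoxification coupled
# to the glutathione cycle and the oxidative pentose phosphate pathway.
# Concentrations in micromolar, time in seconds, fluxes in uM/s.
#
# The glutathione-reductase vmax and the constant G6P supply flux were fixed
# by scripts/calibrate.R so that the healthy-control G6PD variant reaches a
# pre-perturbation steady state with GSH/GSSG close to 700 and G6P close to
# its stated initial value.  All other constants are documented conventional
# choices (see the methods vignette).
name: reduced_rbc_redox
species:
- {name: h2o2,     initial: 0.1,    clamped: no}   # intracellular H2O2
- {name: o2minus,  initial: 0.1,    clamped: no}
- {name: gsh,      initial: 3199.0, clamped: no}
- {name: gssg,     initial: 5.0,    clamped: no}
- {name: nadph,    initial: 60.0,   clamped: no}
- {name: nadp,     initial: 2.0,    clamped: no}
- {name: g6p,      initial: 40.0,   clamped: no}
- {name: gl6p,     initial: 0.3,    clamped: no}
- {name: h2o2_ext, initial: 0.0,    clamped: yes}  # extracellular H2O2
- {name: atp,      initial: 1600.0, clamped: yes}
- {name: bpg23,    initial: 5000.0, clamped: yes}  # 2,3-bisphosphoglycerate
- {name: glc,      initial: 5000.0, clamped: yes}  # glucose (not rate-limiting)
reactions:
- name: h2o2_influx
  law: diffusion
  stoich: {h2o2: 1}
  params: {k: 1.0, source: h2o2_ext, target: h2o2}
- name: o2minus_generation
  law: constant_flux
  stoich: {o2minus: 1}
  params: {v: 2.0}
- name: SOD
  law: mass_action
  stoich: {o2minus: -2, h2o2: 1}
  substrates: [o2minus]
  params: {k: 10.0}
- name: CAT
  law: mass_action
  stoich: {h2o2: -2}
  substrates: [h2o2]
  params: {k: 3.0}
- name: GSHpx
  law: michaelis_2s
  stoich: {h2o2: -1, gsh: -2, gssg: 1}
  substrates: [h2o2, gsh]
  params: {vmax: 2.0, km_a: 1.0, km_b: 100.0}
- name: GR
  law: michaelis_2s
  stoich: {gssg: -1, nadph: -1, gsh: 2, nadp: 1}
  substrates: [gssg, nadph]
  params: {vmax: 4.0198042, km_a: 65.0, km_b: 20.0}
- name: G6PD
  law: g6pd_eq1          # patient-specific kinetics supplied per subject
  stoich: {g6p: -1, nadp: -1, gl6p: 1, nadph: 1}
  params: {}
- name: ppp_second_step  # lumped 6PGL hydrolysis + 6PGD, second NADPH yield
  law: saturating_mass_action
  stoich: {gl6p: -1, nadp: -1, nadph: 1}
  substrates: [gl6p]
  params: {k: 1.0, km: 0.05, saturating: nadp}
- name: g6p_supply       # hexokinase/glucose input, held constant
  law: constant_flux
  stoich: {g6p: 1}
  params: {v: 2.6530002}
- name: g6p_drain        # glycolytic consumption of G6P
  law: mass_action
  stoich: {g6p: -1}
  substrates: [g6p]
  params: {k: 0.06}
- name: nadph_drain      # basal non-glutathione NADPH consumption
  law: mass_action
  stoich: {nadph: -1, nadp: 1}
  substrates: [nadph]
  params: {k: 0.005}
moieties:
  glutathione: {gsh: 1, gssg: 2}
  nicotinamide: {nadp: 1, nadph: 1}
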