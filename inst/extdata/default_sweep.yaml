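# Reference sweep conditions: full diameter x viscosity grid, 5000 particles
# per cell, 500 s end time, standard stratum-corneum patch geometry.
diameters_nm: [1.0, 5.0, 10.0, 15.0]
viscosities_mPas: [10.0, 20.0, 50.0]
n_particles: 5000
t_end_s: 500.0
temperature_K: 298.0
rho_p_kg_m3: 2200.0
rho_f_kg_m3: 1000.0
seed: 1
cap_length_m: 1.0e-6
h_fit_m: 1.0e-6
scheme: overdamped
geometry:
  L1_m: 0.02
  L2_m: 0.02
  a_m: 2.0e-5
  b_m: 2.0e-5
  d1_m: 5.0e-8
  d2_m: 5.0e-8
  h_k_m: 1.0e-5
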