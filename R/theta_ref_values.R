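# Frozen reference parameter values.  Produced once by the feature
# calibration in inst/scripts/derive_theta_ref.R (Nelder-Mead on log10
# parameters against the qualitative kinetic feature set, with the nuclear
# buffering strength pinned at B_n = 20, the nuclear-dominant regime); frozen
# here and used as the generator truth for all packaged synthetic data.
# Units: 1/min for rates; amounts as fractions of total cellular ERK.
.theta_ref_values <- list(
  a_M = 1.487, d_M = 0.6094,
  k_fb = 0.5472, k_rec = 0.04421,
  a_E1 = 6.881, a_E2 = 6.881,
  d_c1 = 2.437, d_c2 = 2.437, d_n1 = 2.437, d_n2 = 0.5467,
  k_in = 0.9371, k_pass = 0.4619, k_out = 0.6649,
  k_on_c = 1, k_off_c = 5, k_cat_c = 5, k_sdp_c = 5,
  Sc_tot = 0.05,
  k_on_n = 0.7607, k_off_n = 0.2315, k_cat_n = 0.1103, k_sdp_n = 0.000141,
  Sn_tot = 1.797,
  phi_n = 0.2, k_rel = 10,
  fb_mode = 0, fb_K = 0.05, fb_h = 2,
  M2_const = 0.25, S_basal = 0.02
)
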