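data_EX_FLAGGED
_audit_creation_method 'cifaudit example (synthetic)'
_diffrn_radiation_wavelength 1.54184
_diffrn_reflns_theta_max 58.90
_refine_ls_R_factor_gt 0.1210
_refine_ls_wR_factor_ref 0.3305
_refine_ls_goodness_of_fit_ref 2.41
_refine_ls_shift/su_max <0.01
_refine_diff_density_max 1.310
_refine_diff_density_min -0.980
loop_
 _atom_site_label
 _atom_site_type_symbol
 _atom_site_occupancy
 _atom_site_disorder_group
C1 C 1 .
H1 H 1 .
O1 O 0.55 .
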