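data_EX_CLEAN
_audit_creation_method 'cifaudit example (synthetic)'
_diffrn_radiation_wavelength 0.71073
_diffrn_reflns_theta_max 27.50
_refine_ls_R_factor_gt 0.0391
_refine_ls_wR_factor_ref 0.1022
_refine_ls_goodness_of_fit_ref 1.037
_refine_ls_shift/su_max 0.001
_refine_diff_density_max 0.402
_refine_diff_density_min -0.315
_refine_ls_number_parameters 217
_refine_ls_number_restraints 0
_refine_ls_number_constraints 0
loop_
 _atom_site_label
 _atom_site_type_symbol
 _atom_site_occupancy
 _atom_site_disorder_group
C1 C 1 .
H1 H 1 .
N1 N 1 .
O1 O 1 .
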