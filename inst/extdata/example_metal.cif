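data_EX_METAL
_audit_creation_method 'cifaudit example (synthetic)'
_diffrn_radiation_wavelength 0.71073
_diffrn_reflns_theta_max 26.02
_refine_ls_R_factor_gt 0.0482
_refine_ls_wR_factor_ref 0.1251
_refine_ls_goodness_of_fit_ref 1.051
_refine_ls_shift/su_max 0.002
_refine_diff_density_max 1.92
_refine_diff_density_min -1.45
_refine_special_details 'SQUEEZE used to treat disordered solvent.'
loop_
 _atom_site_label
 _atom_site_type_symbol
 _atom_site_occupancy
 _atom_site_disorder_group
C1 C 1 .
H1 H 1 .
N1 N 1 .
Pt1 Pt 1 .
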