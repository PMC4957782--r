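# Default morphometric profile for the rat renal arterial tree.
#
# Smooth approximations digitized from published micro-CT morphometry
# (daughter diameter vs parent diameter: cubic mean, linear SD; vessel length
# vs diameter: linear mean and SD) and from inter-arteriole spacing
# measurements in optically cleared tissue (exponential rate). Coefficients
# are in increasing polynomial order; diameters and lengths in micrometers.
name: default
ddp_mean_coeffs: [1.2, 0.78, 1.0e-05, -2.0e-08]
ddp_sd_coeffs: [0.15, 0.005]
vlvd_mean_coeffs: [60.0, 6.0]
vlvd_sd_coeffs: [15.0, 0.8]
aa_spacing_rate: 0.0333333
aa_diam_mean: 19.25
aa_diam_sd: 1.81
valid_diameter_range: [20.0, 530.0]
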