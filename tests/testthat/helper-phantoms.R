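# Shared phantom configurations. The "exact" phantom removes the PSF and
# the PET/CT grid mismatch so the TNR recovery is an identity and engine
# properties can be asserted to numerical precision; the "standard"
# phantoms keep the clinical-style blur and voxel-size mismatch.

exact_phantom <- function(tnr_field = list(type = "gradient",
                                           t_lo = 1.64, t_hi = 3.90),
                          ...) {
  phantom_spec(psf_fwhm_mm = 0, pet_factor = c(1, 1, 1),
               tnr_field = tnr_field, ...)
}

standard_phantom <- function(tnr_field = list(type = "gradient",
                                              t_lo = 1.64, t_hi = 3.90),
                             ...) {
  phantom_spec(tnr_field = tnr_field, ...)
}

heterogeneous_field_suite <- function() {
  list(gradient = list(type = "gradient", t_lo = 1.64, t_hi = 3.90),
       bimodal = list(type = "bimodal", t1 = 1.2, t2 = 3.5),
       gaussian = list(type = "gaussian", t_peak = 4.0, sigma_mm = 6))
}
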