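# Shared fixtures: parameter sets and simulated series built in code.

ref_params <- function(t_half = 120, tau2 = -2, lam = 60, lam_max = lam) {
  kinetic_params(
    vo2_rest = 300, vo2_ss = 1000, vo2_rec = 400,
    tau1 = 30, tau2 = tau2, t_half = t_half,
    lam = lam, lam_max = lam_max
  )
}

# One patient's binned series evaluated on the model curve (optionally with
# Gaussian noise); already aligned since lam == lam_max.
make_series <- function(p, family, bin_width = 10, follow_up = 600,
                        noise_sd = 0, id = "S1", stage = 2L) {
  total <- p$lam_max + 360 + follow_up
  t <- seq(bin_width / 2, total, by = bin_width)
  vo2 <- vo2_curve(t, p, family)
  if (noise_sd > 0) vo2 <- vo2 + stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(
    patient_id = id, stage = stage, lam = p$lam, lam_max = p$lam_max,
    time = t, vo2 = vo2, bin_width = bin_width
  )
}

# Central finite-difference gradient of the curve in the six parameters.
numeric_gradient <- function(t, p, family, h_rel = 1e-6) {
  nm <- c("vo2_rest", "vo2_ss", "vo2_rec", "tau1", "tau2", "t_half")
  out <- matrix(NA_real_, length(t), 6, dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    h <- h_rel * max(1, abs(p[[nm[j]]]))
    up <- p
    dn <- p
    up[[nm[j]]] <- p[[nm[j]]] + h
    dn[[nm[j]]] <- p[[nm[j]]] - h
    out[, j] <- (vo2_curve(t, up, family) - vo2_curve(t, dn, family)) / (2 * h)
  }
  out
}

# A small three-stage cohort spec used where full study size is unnecessary.
small_spec <- function(seed, n = c(`2` = 4, `3` = 4, `4` = 4), ...) {
  cohort_spec(n_per_stage = n, seed = seed, ...)
}
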