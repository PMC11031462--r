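# Shared fixtures: the clinical example eye, random optical systems for the
# matrix oracle, and small seeded cohorts.

# Liou-Brennan-type cornea with AQD 3.00 mm (the worked clinical example;
# its spectacle correction is refracted at a 14 mm vertex distance).
clinical_eye <- function() eye_biometry(7.77, 6.40, 0.50, 3.00, 3.70)

clinical_cfg <- function(scenario) scenario_config(scenario, vault = 0.4, vd = 14)

# random alternating surface/gap chain with consistent media, starting in air
random_system <- function(n_surfaces = 3) {
  n_cur <- 1
  els <- list()
  for (i in seq_len(n_surfaces)) {
    n_next <- runif(1, 1.2, 1.6)
    r <- sample(c(-1, 1), 1) * runif(1, 5, 60)
    els <- c(els, list(elem_surface(n_cur, n_next, radius = r)))
    n_cur <- n_next
    if (i < n_surfaces) els <- c(els, list(elem_gap(runif(1, 0.1, 4), n_cur)))
  }
  els
}

random_cohort <- function(n, seed) sample_cohort(cohort_spec(n, seed = seed))

eye_from_row <- function(row) {
  eye_biometry(row$rc_a, row$rc_p, row$cct, row$aqd, row$lt)
}

design_row <- function(tbl, power) tbl[abs(tbl$power_dpt - power) < 1e-9, ]

default_biometry_corr_for_test <- function() {
  nm <- c("rc_a", "rc_p", "cct", "aqd", "lt")
  corr <- diag(5)
  dimnames(corr) <- list(nm, nm)
  corr["rc_a", "rc_p"] <- corr["rc_p", "rc_a"] <- 0.9
  corr["aqd", "lt"] <- corr["lt", "aqd"] <- -0.3
  corr
}

# element chain of a thick lens, rebuilt here so matrix-oracle tests do not
# depend on package internals
lens_elements_for_test <- function(lens) {
  list(elem_surface(lens$n_before, lens$n_lens, radius = lens$r_front),
       elem_gap(lens$thickness, lens$n_lens),
       elem_surface(lens$n_lens, lens$n_after, radius = lens$r_back))
}
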