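# Shared fixtures and independent oracles for the test suite.

# A small two-class panel for fast unit tests.
tiny_panel <- function() {
  lipid_panel(
    c("TAG 48:0", "TAG 50:1", "TAG 50:2", "SM C16:0", "SM C24:1"),
    c(TAG = "TAG-IS", SM = "SM-IS")
  )
}

# A panel of n null species within one class (fast to parse and simulate).
null_panel <- function(n) {
  lipid_panel(paste0("C", seq_len(n)), c(CARNITINE = "carnitine-IS"))
}

tiny_config <- function(...) {
  simulation_config(panel = tiny_panel(), ...)
}

noiseless_config <- function(...) {
  args <- list(noise_cv = 0, tech_cv = 0, baseline_log_sd = 0, matrix_drift = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(tiny_config, args)
}

# Brute-force two-sided exact binomial p at null proportion 0.5:
# sum the point probabilities of all outcomes no more likely than the
# observed one (the standard two-sided construction).
oracle_binom_p <- function(k, n) {
  pmf <- vapply(0:n, function(j) choose(n, j) * 0.5^n, numeric(1))
  obs <- pmf[k + 1]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# Independent Student-t reference for species_stats(): stats::t.test on the
# per-animal values, species by species.
oracle_t_p <- function(norm, var_equal = TRUE) {
  vapply(split(norm, norm$species), function(d) {
    stats::t.test(d$value[d$group == "treated"],
                  d$value[d$group == "control"],
                  var.equal = var_equal)$p.value
  }, numeric(1))
}

# Approximate analytic power of the pooled two-sample t-test for a spiked
# fold change under the generator's noise model (lognormal biological and
# technical factors, ratio to a noisy standard, nrep technical injections
# averaged per animal).
analytic_spike_power <- function(fc, noise_cv, tech_cv, n_per_group, n_tech_reps,
                                 alpha = 0.05) {
  st2 <- log(1 + tech_cv^2)
  cv_ratio2 <- exp(2 * st2) - 1          # species/standard tech noise ratio
  cv_animal2 <- (1 + noise_cv^2) * (1 + cv_ratio2 / n_tech_reps) - 1
  sd_c <- sqrt(cv_animal2)               # control mean normalized to 1
  sd_t <- fc * sqrt(cv_animal2)
  ncp <- (fc - 1) / sqrt(sd_c^2 / n_per_group + sd_t^2 / n_per_group)
  df <- 2 * n_per_group - 2
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

# Run preprocessing + species statistics on a raw table.
quick_stats <- function(raw, panel, scale = "raw") {
  norm <- average_duplicates(normalize_to_standard(raw, panel))
  if (scale == "class_fraction") norm <- class_fraction_normalize(norm, panel)
  species_stats(norm, scale)
}
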