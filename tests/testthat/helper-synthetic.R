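# shared fixtures built in code

noise_off <- function(seed = 1L) {
  noise_model(elisa_cv = 0, intensity_cv = 0, background_level = 0,
              background_cv = 0, interference_fraction = 0, seed = seed)
}

noisefree_study <- function(route = "IV", n_animals = 2, ...) {
  generate_study(study_design(n_animals = n_animals, route = route, ...),
                 pk_parameters(), noise_off())
}

quiet_nca <- function(study, config = analysis_config()) {
  suppressWarnings(nca_study(study$profiles, study$concentrations, study$dose,
                             config = config, quiet = TRUE))
}

# independent two-sided t tail via the incomplete beta function
p_from_t <- function(t, df) stats::pbeta(df / (df + t^2), df / 2, 0.5)

# brute-force paired t oracle (explicit difference formula)
oracle_paired <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = p_from_t(t, n - 1))
}

# brute-force Welch oracle (closed-form Welch-Satterthwaite)
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = p_from_t(t, df))
}

# exhaustive BH step-up oracle: try every cutoff, keep the largest valid one
oracle_bh_reject <- function(p, fdr) {
  m <- length(p)
  ps <- sort(p)
  valid <- which(ps <= seq_len(m) / m * fdr)
  if (length(valid) == 0) return(rep(FALSE, m))
  p <= ps[max(valid)]
}
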