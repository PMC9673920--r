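#' Default glycoform clearance multipliers
#'
#' Maps each registered glycoform to a multiplicative factor on the reference
#' clearance, following the qualitative ordering observed for IgG1 Fc
#' glycoforms: oligomannose cleared fastest (1.20), monoantennary moderately
#' fast (1.08), monogalactosylated slightly slow (0.92), fully galactosylated
#' and sialylated slow (0.85); everything else clears at the reference rate.
#'
#' @param registry A `glyco_registry`.
#' @return Named numeric vector of multipliers.
#' @export
default_cl_multipliers <- function(registry = default_registry()) {
  m <- rep(1, nrow(registry))
  m[registry$n_galactose == 1L] <- 0.92
  m[registry$n_galactose == 2L] <- 0.85
  m[registry$n_sialic > 0L] <- 0.85
  m[registry$n_antennae == 1L] <- 1.08
  m[registry$oligomannose] <- 1.20
  setNames(m, registry$name)
}

#' One-compartment PK parameters of the synthetic study
#'
#' The generator uses one-compartment disposition with glycoform-specific
#' first-order elimination \eqn{k_g = CL_{ref} \cdot m_g / V} and, for SC
#' dosing, first-order absorption with galactose-dependent bioavailability
#' \deqn{F_g = \min(1,\ f_{base} \cdot (1 + \beta \cdot n_{gal}(g)/2)),}
#' the simplest mechanism that shifts the serum profile toward galactosylated
#' glycoforms around Tmax after SC injection.
#'
#' Defaults are calibrated to minipig single-dose magnitudes: V = 50 mL/kg and
#' CL_ref = 0.9 mL/day/kg give an initial IV concentration of 10 \eqn{\mu}g/mL
#' at a 0.5 mg/kg dose; ka = 6/day puts the SC Tmax near 24 h; f_base = 0.5
#' gives an SC Cmax near 5 \eqn{\mu}g/mL; beta = 0.46 shifts SC serum
#' galactosylation by about 3.5 percentage points at Tmax for a typical
#' CHO-like formulation.
#'
#' @param volume_ml_per_kg Distribution volume V (mL/kg).
#' @param cl_ref_ml_day_kg Reference-glycoform clearance (mL/day/kg).
#' @param cl_multipliers Named positive multipliers per glycoform.
#' @param ka_per_day SC absorption rate constant (1/day).
#' @param f_base Baseline bioavailability in (0, 1].
#' @param absorption_gal_bias Dimensionless galactose absorption bias
#'   \eqn{\beta \ge 0}.
#' @return List of class `pk_parameters`.
#' @export
pk_parameters <- function(volume_ml_per_kg = 50,
                          cl_ref_ml_day_kg = 0.9,
                          cl_multipliers = default_cl_multipliers(),
                          ka_per_day = 6,
                          f_base = 0.5,
                          absorption_gal_bias = 0.46) {
  stopifnot(volume_ml_per_kg > 0, cl_ref_ml_day_kg > 0,
            all(cl_multipliers > 0), ka_per_day > 0,
            f_base > 0, f_base <= 1, absorption_gal_bias >= 0)
  structure(list(volume_ml_per_kg = volume_ml_per_kg,
                 cl_ref_ml_day_kg = cl_ref_ml_day_kg,
                 cl_multipliers = cl_multipliers,
                 ka_per_day = ka_per_day,
                 f_base = f_base,
                 absorption_gal_bias = absorption_gal_bias),
            class = "pk_parameters")
}

#' Observation noise model
#'
#' Defaults emulate the assay precision seen in serum PK studies of this
#' design: a 10% proportional ELISA error on the total concentration, and a 5%
#' proportional error per glycoform signal, which reproduces the
#' percentage-point scale of scatter that replicate serum glycosylation
#' profiles show at n = 5 (galactosylation SD a few tenths of a point to about
#' one point).
#'
#' @param elisa_cv Proportional CV of the total-concentration observation
#'   (multiplicative log-normal, mean-preserving).
#' @param intensity_cv Proportional CV of each glycoform's LC-MS signal.
#' @param background_level Mean LC-MS background intensity (arbitrary units).
#' @param background_cv Proportional CV of the per-analyte background draw
#'   around `background_level`.
#' @param interference_fraction Fraction of the background leaking into the
#'   analyte signals (default 0.3) — the interference that
#'   [correct_background()] removes.
#' @param seed Random seed used by [generate_study()].
#' @return List of class `noise_model`.
#' @export
noise_model <- function(elisa_cv = 0.1, intensity_cv = 0.05,
                        background_level = 100, background_cv = 0.25,
                        interference_fraction = 0.3, seed = 1L) {
  stopifnot(elisa_cv >= 0, intensity_cv >= 0, background_level >= 0,
            background_cv >= 0,
            interference_fraction >= 0, interference_fraction < 1)
  structure(list(elisa_cv = elisa_cv, intensity_cv = intensity_cv,
                 background_level = background_level,
                 background_cv = background_cv,
                 interference_fraction = interference_fraction,
                 seed = seed),
            class = "noise_model")
}

#' Default sampling schedules
#'
#' IV: 0.08, 1, 7, 24, 48, 72, 96, 168 h; SC: 2, 7, 24, 48, 72, 96, 168,
#' 240 h.
#'
#' @param route `"IV"` or `"SC"`.
#' @return Numeric vector of sampling times (h).
#' @export
default_schedule <- function(route = c("IV", "SC")) {
  route <- match.arg(route)
  if (route == "IV") c(0.08, 1, 7, 24, 48, 72, 96, 168)
  else c(2, 7, 24, 48, 72, 96, 168, 240)
}

#' Typical CHO-type formulation profile
#'
#' G0F 60%, G1F 25%, and G2F, Man5 and G0F-N at 5% each — the composition of
#' a typical CHO-produced IgG1 dominated by agalactosylated and
#' monogalactosylated fucosylated diantennary glycans.
#'
#' @return Tibble with columns `glycoform`, `fraction`.
#' @export
default_formulation_profile <- function() {
  tibble::tibble(glycoform = c("G0F", "G1F", "G2F", "Man5", "G0F-N"),
                 fraction = c(0.60, 0.25, 0.05, 0.05, 0.05))
}

#' Synthetic study design
#'
#' @param n_animals Animals per group (default 5; at least 2).
#' @param route `"SC"` (default) or `"IV"`.
#' @param schedule_h Sampling times (h); defaults to [default_schedule()].
#' @param nominal_dose_mg_per_kg Single dose (default 0.5 mg/kg).
#' @param formulation_profile Glycoform composition of the injected material.
#' @param group Group label; default derived from the route.
#' @return List of class `study_design`.
#' @export
study_design <- function(n_animals = 5, route = c("SC", "IV"),
                         schedule_h = NULL,
                         nominal_dose_mg_per_kg = 0.5,
                         formulation_profile = default_formulation_profile(),
                         group = NULL) {
  route <- match.arg(route)
  if (n_animals < 2) stop("need at least 2 animals for statistics", call. = FALSE)
  if (is.null(schedule_h)) schedule_h <- default_schedule(route)
  if (length(schedule_h) == 0) stop("sampling schedule is empty", call. = FALSE)
  stopifnot(all(schedule_h >= 0), !is.unsorted(schedule_h, strictly = TRUE),
            nominal_dose_mg_per_kg > 0)
  fp <- tibble::as_tibble(formulation_profile)[c("glycoform", "fraction")]
  fp$fraction <- fp$fraction / sum(fp$fraction)
  if (is.null(group)) group <- paste0("SYN-", route)
  structure(list(n_animals = as.integer(n_animals), route = route,
                 schedule_h = schedule_h,
                 nominal_dose_mg_per_kg = nominal_dose_mg_per_kg,
                 formulation_profile = fp, group = group),
            class = "study_design")
}

glycoform_k_per_day <- function(params, glycoform) {
  m <- params$cl_multipliers[glycoform]
  if (anyNA(m)) {
    stop("no clearance multiplier for glycoform(s): ",
         paste(glycoform[is.na(m)], collapse = ", "), call. = FALSE)
  }
  unname(params$cl_ref_ml_day_kg * m / params$volume_ml_per_kg)
}

#' Bioavailability of a glycoform after SC dosing
#'
#' @param params A [pk_parameters()].
#' @param glycoform Glycoform name(s).
#' @param registry Registry resolving `n_galactose`.
#' @return Bioavailability fraction(s) in (0, 1].
#' @export
sc_bioavailability <- function(params, glycoform, registry = default_registry()) {
  att <- registry_lookup(registry, glycoform)
  pmin(1, params$f_base *
         (1 + params$absorption_gal_bias * att$n_galactose / 2))
}

#' True glycoform concentration after an IV bolus
#'
#' One-compartment disposition: \eqn{C_g(t) = (dose_g / V) e^{-k_g t}} with
#' \eqn{k_g = CL_{ref} m_g / V} (1/day; `t` is supplied in hours).
#'
#' @param params A [pk_parameters()].
#' @param dose_g_ug_kg Glycoform dose (\eqn{\mu}g/kg).
#' @param glycoform Glycoform name.
#' @param t_h Time(s) after dosing, hours.
#' @return Concentration(s) in \eqn{\mu}g/mL.
#' @export
true_conc_iv <- function(params, dose_g_ug_kg, glycoform, t_h) {
  stopifnot(all(t_h >= 0))
  k <- glycoform_k_per_day(params, glycoform)
  dose_g_ug_kg / params$volume_ml_per_kg * exp(-k * t_h / 24)
}

#' True glycoform concentration after SC dosing
#'
#' First-order absorption into a one-compartment model:
#' \deqn{C_g(t) = \frac{F_g \, dose_g \, k_a}{V (k_a - k_g)}
#'   \left(e^{-k_g t} - e^{-k_a t}\right),}
#' with galactose-dependent bioavailability \eqn{F_g} (see
#' [sc_bioavailability()]). The analytic area under the curve is
#' \eqn{AUC_\infty = F_g \, dose_g / CL_g}, which serves as the exact oracle
#' for NCA recovery tests.
#'
#' @inheritParams true_conc_iv
#' @param registry Registry resolving the glycoform's galactosylation.
#' @return Concentration(s) in \eqn{\mu}g/mL.
#' @export
true_conc_sc <- function(params, dose_g_ug_kg, glycoform, t_h,
                         registry = default_registry()) {
  stopifnot(all(t_h >= 0))
  k <- glycoform_k_per_day(params, glycoform)
  ka <- params$ka_per_day
  if (abs(ka - k) < 1e-12) {
    stop("ka equals the elimination rate of ", glycoform,
         " (flip-flop degeneracy); change ka or the multiplier", call. = FALSE)
  }
  f <- sc_bioavailability(params, glycoform, registry)
  t_d <- t_h / 24
  f * dose_g_ug_kg * ka / (params$volume_ml_per_kg * (ka - k)) *
    (exp(-k * t_d) - exp(-ka * t_d))
}

# mean-preserving multiplicative log-normal factor with a given CV
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Observe a total concentration by ELISA
#'
#' Applies mean-preserving multiplicative log-normal error with CV
#' `noise$elisa_cv` and flags observations below the LLOQ.
#'
#' @param true_total True concentration(s), \eqn{\mu}g/mL.
#' @param noise A [noise_model()].
#' @param lloq_ng_ml Lower limit of quantitation (ng/mL).
#' @return Tibble with columns `conc_ug_ml`, `bloq`.
#' @export
observe_elisa <- function(true_total, noise, lloq_ng_ml = 7) {
  stopifnot(all(true_total >= 0))
  obs <- true_total * lognormal_factor(length(true_total), noise$elisa_cv)
  tibble::tibble(conc_ug_ml = obs, bloq = obs < lloq_ng_ml / 1000)
}

# fixed LC-MS response factor (signal units per ug/mL); arbitrary because
# profiles are compositional and only signal ratios matter
lcms_response_factor <- 1000

#' Observe glycoform LC-MS intensities with background interference
#'
#' Generates per-glycoform signals
#' \deqn{intensity_g = \max(0,\ s\, C_g (1 + \epsilon_g)) +
#'   interference\_fraction \cdot B_g,}
#' where `s` is a fixed response factor, \eqn{\epsilon_g} is mean-zero normal
#' noise with CV `intensity_cv`, and \eqn{B_g} is the background reported for
#' that analyte window (log-normal around `background_level`). The reported
#' background is returned alongside so that [correct_background()] can remove
#' the planted interference.
#'
#' @param true_conc Named vector of true glycoform concentrations
#'   (\eqn{\mu}g/mL).
#' @param noise A [noise_model()].
#' @return Tibble with columns `glycoform`, `intensity`, `background`.
#' @export
observe_lcms_intensities <- function(true_conc, noise) {
  stopifnot(all(true_conc >= 0), !is.null(names(true_conc)))
  n <- length(true_conc)
  bg <- noise$background_level * lognormal_factor(n, noise$background_cv)
  eps <- rnorm(n, 0, noise$intensity_cv)
  signal <- pmax(0, lcms_response_factor * as.numeric(true_conc) * (1 + eps))
  tibble::tibble(glycoform = names(true_conc),
                 intensity = signal + noise$interference_fraction * bg,
                 background = bg)
}

#' Generate a complete synthetic single-dose study
#'
#' Simulates, per animal and sampling time, the true glycoform concentrations
#' (one-compartment IV bolus or first-order SC absorption with
#' galactose-biased bioavailability), the observed ELISA total (log-normal
#' error, LLOQ censoring) and the observed LC-MS intensities (proportional
#' noise plus background interference). Intensities are background-corrected
#' with the noise model's interference fraction and total-area normalized into
#' profiles; profiles are emitted only for samples whose observed total is
#' quantifiable and at or above `profile_loq_ug_ml`. Spiked-standard
#' replicates (formulation at 10 \eqn{\mu}g/mL in blank serum) are measured
#' with the same LC-MS noise; their mean profile provides the dose-adjustment
#' standard.
#'
#' The output is fully reproducible from `noise$seed`, and the truth element
#' retains the noiseless concentrations and the true per-glycoform clearance
#' and bioavailability for recovery tests.
#'
#' @param design A [study_design()].
#' @param params A [pk_parameters()].
#' @param noise A [noise_model()].
#' @param registry A `glyco_registry`.
#' @param n_standards Number of spiked-standard replicates (default 3).
#' @param lloq_ng_ml ELISA LLOQ (ng/mL).
#' @param profile_loq_ug_ml Lowest observed total at which a profile is
#'   reported (\eqn{\mu}g/mL).
#' @return List with elements `profiles`, `concentrations`, `dose`
#'   (a [dose_spec()] whose standard profile is the mean observed standard),
#'   `standards` (long tibble of observed standard replicates), `truth`
#'   (tibble `animal_id`, `glycoform`, `true_cl_ml_day_kg`, `true_f`,
#'   `cl_multiplier`) and `true_concentrations`.
#' @export
generate_study <- function(design, params, noise = noise_model(),
                           registry = default_registry(), n_standards = 3,
                           lloq_ng_ml = 7, profile_loq_ug_ml = 1.0) {
  stopifnot(inherits(design, "study_design"), inherits(params, "pk_parameters"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  glyco <- design$formulation_profile$glycoform
  f_form <- setNames(design$formulation_profile$fraction, glyco)
  registry_lookup(registry, glyco)
  dose_ug_kg <- design$nominal_dose_mg_per_kg * 1000
  dose_g <- dose_ug_kg * f_form
  animals <- sprintf("A%02d", seq_len(design$n_animals))

  true_g <- function(t_h) {
    vapply(glyco, function(g) {
      if (design$route == "IV") true_conc_iv(params, dose_g[[g]], g, t_h)
      else true_conc_sc(params, dose_g[[g]], g, t_h, registry)
    }, numeric(length(t_h)))
  }
  ct_true <- true_g(design$schedule_h)            # times x glycoforms
  if (length(design$schedule_h) == 1) ct_true <- matrix(ct_true, nrow = 1,
                                                        dimnames = list(NULL, glyco))

  profiles <- list(); concs <- list(); true_rows <- list()
  for (a in animals) {
    total_true <- rowSums(ct_true)
    obs <- observe_elisa(total_true, noise, lloq_ng_ml)
    concs[[a]] <- tibble::tibble(animal_id = a, group = design$group,
                                 time_h = design$schedule_h,
                                 conc_ug_ml = obs$conc_ug_ml, bloq = obs$bloq)
    for (i in seq_along(design$schedule_h)) {
      t <- design$schedule_h[i]
      true_rows[[paste(a, t)]] <- tibble::tibble(
        animal_id = a, time_h = t, glycoform = glyco,
        conc_ug_ml = unname(ct_true[i, ]), total_ug_ml = total_true[i])
      if (obs$bloq[i] || obs$conc_ug_ml[i] < profile_loq_ug_ml) next
      sig <- observe_lcms_intensities(setNames(ct_true[i, ], glyco), noise)
      corrected <- correct_background(sig$intensity, sig$background,
                                      noise$interference_fraction)
      if (sum(corrected) <= 0) next
      fr <- normalize_profile(setNames(corrected, sig$glycoform))
      profiles[[paste(a, t)]] <- tibble::tibble(
        sample_id = paste(design$group, a, t, sep = "_"),
        animal_id = a, group = design$group, route = design$route,
        time_h = t, glycoform = names(fr), fraction = as.numeric(fr))
    }
  }

  std_conc <- 10  # ug/mL spike of the formulation in blank serum
  std <- lapply(seq_len(n_standards), function(r) {
    sig <- observe_lcms_intensities(std_conc * f_form, noise)
    corrected <- correct_background(sig$intensity, sig$background,
                                    noise$interference_fraction)
    fr <- normalize_profile(setNames(corrected, sig$glycoform))
    tibble::tibble(sample_id = paste0(design$group, "_std", r),
                   glycoform = names(fr), fraction = as.numeric(fr))
  })
  standards <- dplyr::bind_rows(std)
  std_mean <- tapply(standards$fraction, standards$glycoform, mean)[glyco]
  dose <- dose_spec(design$group, design$nominal_dose_mg_per_kg, design$route,
                    tibble::tibble(glycoform = glyco,
                                   fraction = as.numeric(std_mean) / sum(std_mean)))

  true_cl <- params$cl_ref_ml_day_kg * params$cl_multipliers[glyco]
  true_f <- if (design$route == "IV") rep(1, length(glyco)) else
    sc_bioavailability(params, glyco, registry)
  truth <- tidyr::expand_grid(animal_id = animals, glycoform = glyco)
  truth$true_cl_ml_day_kg <- as.numeric(true_cl[truth$glycoform])
  truth$true_f <- rep(as.numeric(true_f), times = design$n_animals)
  truth$cl_multiplier <- as.numeric(params$cl_multipliers[truth$glycoform])

  list(profiles = dplyr::bind_rows(profiles),
       concentrations = dplyr::bind_rows(concs),
       dose = dose,
       standards = standards,
       truth = truth,
       true_concentrations = dplyr::bind_rows(true_rows))
}
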