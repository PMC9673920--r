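test_that("IV kinetics follow the one-compartment closed form", {
  par <- pk_parameters()  # V = 50 mL/kg, CL_ref = 0.9 mL/day/kg
  expect_equal(true_conc_iv(par, 500, "G0F", 0), 10)
  t_half_h <- 24 * par$volume_ml_per_kg * log(2) / par$cl_ref_ml_day_kg
  expect_equal(true_conc_iv(par, 500, "G0F", t_half_h), 5, tolerance = 1e-12)
  # a multiplier scales the elimination rate exactly
  par2 <- pk_parameters(cl_multipliers = c(X = 1.2, G0F = 1))
  k_ratio <- log(true_conc_iv(par2, 500, "X", 0) / true_conc_iv(par2, 500, "X", 240)) /
    log(true_conc_iv(par2, 500, "G0F", 0) / true_conc_iv(par2, 500, "G0F", 240))
  expect_equal(k_ratio, 1.2, tolerance = 1e-12)
  expect_error(true_conc_iv(par, 500, "NOPE", 0), "NOPE")
})

test_that("SC kinetics start at zero and integrate to the closed-form AUC", {
  par <- pk_parameters()
  expect_equal(true_conc_sc(par, 500, "G1F", 0), 0)

  # with no galactose bias, bioavailability is identical across glycoforms
  par0 <- pk_parameters(absorption_gal_bias = 0)
  f <- sc_bioavailability(par0, c("G0F", "G1F", "G2F", "Man5"))
  expect_true(all(f == par0$f_base))

  # quadrature oracle vs analytic AUCinf = F * dose / CL (units: ug*h/mL)
  for (g in c("G0F", "G2F", "Man5")) {
    num <- stats::integrate(function(t) true_conc_sc(par, 500, g, t),
                            0, Inf, rel.tol = 1e-10)$value
    f_g <- sc_bioavailability(par, g)
    cl_g <- par$cl_ref_ml_day_kg * par$cl_multipliers[[g]]
    expect_equal(num, 24 * f_g * 500 / cl_g, tolerance = 1e-3)
  }

  # flip-flop degeneracy is rejected, not silently computed
  par_ff <- pk_parameters(ka_per_day = 6,
                          cl_multipliers = c(X = 6 * 50 / 0.9))
  expect_error(true_conc_sc(par_ff, 500, "X", 24, registry = glyco_registry(
    tibble::tibble(name = "X", n_antennae = 2, n_galactose = 0, n_sialic = 0,
                   core_fucose = TRUE, oligomannose = FALSE))),
    "flip-flop")
})

test_that("ELISA observation error is mean-preserving with the requested CV", {
  noise0 <- noise_model(elisa_cv = 0)
  expect_equal(observe_elisa(c(5, 0.004), noise0)$conc_ug_ml, c(5, 0.004))
  expect_equal(observe_elisa(c(5, 0.004), noise0)$bloq, c(FALSE, TRUE))

  set.seed(99)
  draws <- observe_elisa(rep(10, 10000), noise_model(elisa_cv = 0.1))$conc_ug_ml
  expect_gt(sd(draws) / mean(draws), 0.09)
  expect_lt(sd(draws) / mean(draws), 0.11)
  expect_equal(mean(draws), 10, tolerance = 0.01)
})

test_that("LC-MS observation plants exactly the interference the correction removes", {
  # deterministic case: proportionality and pure interference
  set.seed(1)
  noise0 <- noise_model(intensity_cv = 0, background_level = 0,
                        interference_fraction = 0)
  sig <- observe_lcms_intensities(c(G0F = 2, G1F = 1), noise0)
  expect_equal(sig$intensity / sig$intensity[2], c(2, 1))

  noise_bg <- noise_model(intensity_cv = 0, background_level = 200,
                          background_cv = 0, interference_fraction = 0.3)
  pure <- observe_lcms_intensities(c(G0F = 0), noise_bg)
  expect_equal(pure$intensity, 60)
  expect_equal(pure$background, 200)

  # simulation oracle: corrected, normalized profiles are unbiased
  truef <- c(G0F = 0.6, G1F = 0.25, G2F = 0.05, Man5 = 0.05, `G0F-N` = 0.05)
  noise <- noise_model(seed = NULL)
  recovered <- replicate(1000, {
    s <- observe_lcms_intensities(truef * 10, noise)
    normalize_profile(setNames(
      correct_background(s$intensity, s$background, 0.3), s$glycoform))
  })
  bias <- rowMeans(recovered) - truef
  expect_lt(max(abs(bias)), 0.005)
})

test_that("generated studies are reproducible and internally consistent", {
  des <- study_design(route = "IV", n_animals = 2)
  par <- pk_parameters()
  s1 <- generate_study(des, par, noise_model(seed = 42))
  s2 <- generate_study(des, par, noise_model(seed = 42))
  expect_identical(s1, s2)
  s3 <- generate_study(des, par, noise_model(seed = 43))
  expect_false(identical(s3$concentrations$conc_ug_ml, s1$concentrations$conc_ug_ml))
  expect_identical(s3$true_concentrations, s1$true_concentrations)

  # glycoform concentrations sum exactly to the true total at every point
  tc <- s1$true_concentrations
  sums <- tapply(tc$conc_ug_ml, paste(tc$animal_id, tc$time_h), sum)
  totals <- tapply(tc$total_ug_ml, paste(tc$animal_id, tc$time_h), unique)
  expect_equal(as.numeric(sums), as.numeric(totals), tolerance = 1e-15)

  expect_error(study_design(n_animals = 1), "at least 2")
  expect_error(study_design(route = "IV", schedule_h = numeric(0)), "empty")
})

test_that("with noise off, observed profiles equal true concentration fractions", {
  st <- noisefree_study("SC")
  tc <- st$true_concentrations
  for (i in seq_len(nrow(st$profiles))) {
    row <- st$profiles[i, ]
    sub <- tc[tc$animal_id == row$animal_id & tc$time_h == row$time_h, ]
    truef <- unname(sub$conc_ug_ml[sub$glycoform == row$glycoform] /
                      sub$total_ug_ml[1])
    expect_equal(row$fraction, truef, tolerance = 1e-12)
  }
})

test_that("noise-free IV pipeline recovers every planted clearance to < 0.5%", {
  st <- noisefree_study("IV")
  res <- quiet_nca(st)
  truth <- unique(st$truth[c("glycoform", "true_cl_ml_day_kg")])
  res_g <- res[res$glycoform != "Total", ]
  got <- tapply(res_g$clearance_ml_day_kg, res_g$glycoform, mean)
  want <- setNames(truth$true_cl_ml_day_kg, truth$glycoform)[names(got)]
  expect_true(all(abs(got / want - 1) < 0.005))
})

test_that("galactose absorption bias enriches SC serum galactosylation at Tmax", {
  st <- noisefree_study("SC")
  prof24 <- st$profiles[st$profiles$time_h == 24 &
                          st$profiles$animal_id == "A01", ]
  gal_serum <- compute_traits(setNames(prof24$fraction, prof24$glycoform))$galactosylation
  des <- study_design(route = "SC")
  gal_form <- compute_traits(setNames(des$formulation_profile$fraction,
                                      des$formulation_profile$glycoform))$galactosylation
  expect_gt(gal_serum, gal_form)
})
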