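make_profiles <- function(times, fracs, animal = "A1", group = "G", route = "IV") {
  dplyr::bind_rows(lapply(times, function(t) {
    tibble::tibble(sample_id = paste(animal, t), animal_id = animal,
                   group = group, route = route, time_h = t,
                   glycoform = names(fracs), fraction = as.numeric(fracs))
  }))
}

make_conc <- function(times, conc, animal = "A1", group = "G") {
  tibble::tibble(animal_id = animal, group = group, time_h = times,
                 conc_ug_ml = conc, bloq = FALSE)
}

test_that("splitting concentrations conserves the total and honours the window", {
  prof <- make_profiles(c(24, 264), c(G0F = 0.6, G1F = 0.4))
  conc <- make_conc(c(24, 264), c(5, 2))
  out <- split_concentrations(prof, conc)
  expect_equal(out$time_h, c(24, 24))  # 264 h beyond the 240 h window
  expect_equal(out$conc_ug_ml[out$glycoform == "G0F"], 3)
  expect_equal(out$conc_ug_ml[out$glycoform == "G1F"], 2)
  expect_equal(sum(out$conc_ug_ml), 5, tolerance = 1e-15)

  # BLOQ totals are dropped
  conc2 <- make_conc(c(24, 48), c(5, 0.004))
  conc2$bloq <- c(FALSE, TRUE)
  prof2 <- make_profiles(c(24, 48), c(G0F = 0.6, G1F = 0.4))
  out2 <- split_concentrations(prof2, conc2)
  expect_equal(unique(out2$time_h), 24)

  # an animal with no joinable points is an error, not silence
  conc3 <- dplyr::bind_rows(conc, make_conc(24, 5, animal = "A2"))
  expect_error(split_concentrations(prof, conc3), "A2")
})

test_that("terminal slope is exact on exponential data and picks the full window", {
  lz <- estimate_lambda_z(c(48, 72, 96), c(4, 2, 1))
  expect_equal(lz$lambda_z_per_h, log(2) / 24, tolerance = 1e-12)
  expect_equal(lz$half_life_h, 24, tolerance = 1e-12)
  expect_equal(lz$r2adj, 1, tolerance = 1e-12)

  times <- default_schedule("IV")
  k <- log(2) / 24
  lz2 <- estimate_lambda_z(times, 10 * exp(-k * times))
  expect_equal(lz2$lambda_z_per_h, k, tolerance = 1e-10)
  expect_equal(lz2$n_points, length(times))  # ties resolved to more points

  # too few usable points -> not estimable
  expect_equal(estimate_lambda_z(c(1, 2), c(2, 1))$n_points, 0L)
  # non-positive concentrations are excluded before fitting
  lz3 <- estimate_lambda_z(c(24, 48, 72, 96), c(8, 4, 2, 0))
  expect_equal(lz3$lambda_z_per_h, log(2) / 24, tolerance = 1e-12)
})

test_that("terminal slope is nearly unbiased on identifiable noisy decays", {
  set.seed(23)
  times <- default_schedule("IV")
  k <- log(2) / 24
  est <- replicate(1000, {
    conc <- 10 * exp(-k * times) * exp(rnorm(length(times), 0, 0.05))
    estimate_lambda_z(times, conc)$lambda_z_per_h
  })
  expect_lt(abs(stats::median(est, na.rm = TRUE) / k - 1), 0.02)
})

test_that("trapezoidal AUC matches hand calculation and converges under refinement", {
  times <- c(0, 24, 48, 72)
  conc <- c(10, 5, 2.5, 1.25)
  a <- auc_trapezoid(times, conc, lambda_z_per_h = log(2) / 24)
  expect_equal(a$auc_last_ug_h_ml, 315)
  expect_equal(a$auc_inf_ug_h_ml, 315 + 1.25 * 24 / log(2), tolerance = 1e-12)
  expect_equal(a$extrap_percent,
               100 * (1.25 * 24 / log(2)) / a$auc_inf_ug_h_ml, tolerance = 1e-12)

  expect_equal(auc_trapezoid(c(0, 10), c(3, 3))$auc_last_ug_h_ml, 30)

  # Richardson-style check: halving the grid converges to the quadrature value
  f <- function(t) 10 * exp(-0.01 * t)
  exact <- stats::integrate(f, 0, 100)$value
  errs <- sapply(c(10, 5, 2.5), function(h) {
    t <- seq(0, 100, by = h)
    abs(auc_trapezoid(t, f(t))$auc_last_ug_h_ml - exact)
  })
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[3] / errs[2], 0.25, tolerance = 0.05)  # O(h^2)

  # log-down rule integrates exponential decline exactly
  t <- c(0, 24, 48)
  a2 <- auc_trapezoid(t, f(t), rule = "lin-up-log-down")
  expect_equal(a2$auc_last_ug_h_ml, stats::integrate(f, 0, 48)$value,
               tolerance = 1e-10)
})

test_that("NCA clearance matches the closed-form oracle and is linear in dose", {
  # monoexponential single-glycoform study: AUCinf = D / (V k)
  par <- pk_parameters(cl_multipliers = c(G0F = 1))
  times <- default_schedule("IV")
  conc <- make_conc(times, true_conc_iv(par, 500, "G0F", times))
  prof <- make_profiles(times, c(G0F = 1))
  ds <- dose_spec("G", 0.5, "IV", tibble::tibble(glycoform = "G0F", fraction = 1))
  res <- suppressWarnings(nca_study(prof, conc, ds, quiet = TRUE))
  cl <- res$clearance_ml_day_kg[res$glycoform == "G0F"]
  expect_lt(abs(cl / 0.9 - 1), 0.03)

  # halving the standard fraction halves the glycoform dose and the clearance
  prof2 <- make_profiles(times, c(G0F = 0.5, G1F = 0.5))
  conc2 <- make_conc(times, 2 * true_conc_iv(par, 500, "G0F", times))
  ds2 <- dose_spec("G", 0.5, "IV",
                   tibble::tibble(glycoform = c("G0F", "G1F"), fraction = c(0.5, 0.5)))
  res2 <- suppressWarnings(nca_study(prof2, conc2, ds2, quiet = TRUE))
  # same G0F series (0.5 x 2C = C) but half the glycoform dose -> half the CL
  expect_equal(res2$clearance_ml_day_kg[res2$glycoform == "G0F"], cl / 2,
               tolerance = 1e-9)
  expect_equal(res2$dose_ug_kg[res2$glycoform == "G0F"], 250)

  # clearance invariant under uniform rescaling of dose and concentrations
  conc3 <- conc; conc3$conc_ug_ml <- conc3$conc_ug_ml * 3
  ds3 <- dose_spec("G", 1.5, "IV", tibble::tibble(glycoform = "G0F", fraction = 1))
  res3 <- suppressWarnings(nca_study(prof, conc3, ds3, quiet = TRUE))
  expect_equal(res3$clearance_ml_day_kg[res3$glycoform == "G0F"], cl,
               tolerance = 1e-12)

  # glycoform absent from the standard profile is an error
  expect_error(suppressWarnings(nca_study(prof2, conc2, ds, quiet = TRUE)),
               "missing from the spiked-standard")
})

test_that("AUCs are exactly additive across glycoforms with the linear rule", {
  st <- noisefree_study("IV", n_animals = 2)
  res <- quiet_nca(st)
  for (a in unique(res$animal_id)) {
    sub <- res[res$animal_id == a, ]
    expect_equal(sum(sub$auc_last_ug_h_ml[sub$glycoform != "Total"]),
                 sub$auc_last_ug_h_ml[sub$glycoform == "Total"],
                 tolerance = 1e-12)
  }
})

test_that("noise-free recovery preserves the planted clearance rank order", {
  st <- noisefree_study("IV")
  res <- quiet_nca(st)
  one <- res[res$animal_id == "A01" & res$glycoform != "Total", ]
  ord <- one$glycoform[order(one$clearance_ml_day_kg, decreasing = TRUE)]
  expect_equal(ord, c("Man5", "G0F-N", "G0F", "G1F", "G2F"))
})

test_that("reference normalization yields exact ratios and excludes broken animals", {
  st <- noisefree_study("IV", n_animals = 3)
  res <- quiet_nca(st)
  norm <- normalize_to_reference(res, "G0F")
  ref <- norm[norm$glycoform == "G0F", ]
  expect_true(all(ref$ratio == 1))
  mult <- default_cl_multipliers()
  for (g in unique(norm$glycoform)) {
    expect_equal(norm$ratio[norm$glycoform == g], rep(mult[[g]], 3),
                 tolerance = 1e-5)
  }

  # arithmetic on reported group means: Man5 1.04 vs G0F 0.88
  expect_equal(1.04 / 0.88, 1.1818, tolerance = 1e-4)

  broken <- res
  broken$clearance_ml_day_kg[broken$animal_id == "A01" &
                               broken$glycoform == "G0F"] <- NA
  expect_warning(norm2 <- normalize_to_reference(broken, "G0F"), "A01")
  expect_false("A01" %in% norm2$animal_id)

  summ <- summarize_normalized(norm)
  expect_equal(summ$sd[summ$glycoform == "G0F"], 0)
  expect_equal(summ$n, rep(3L, nrow(summ)))
})
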