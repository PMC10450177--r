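test_that("standard curve recovers a perfect line and inverts it", {
  conc <- seq(0, 100, by = 20)
  sc <- fit_standard_curve(conc, 0.01 * conc)
  expect_equal(sc$slope, 0.01)
  expect_equal(sc$intercept, 0)
  expect_equal(sc$r_squared, 1)
  expect_equal(invert_curve(sc, predict(sc, 50)), 50)
  expect_equal(invert_curve(sc, 0.01 * 37.5), 37.5)
  expect_error(fit_standard_curve(c(0, 50), c(0, 1)), "3 calibration")
  expect_error(fit_standard_curve(c(5, 5, 5), c(1, 1, 1)), "vary")
})

test_that("noisy calibration recovers the true slope within 3 SE", {
  set.seed(101)
  conc <- rep(seq(0, 100, by = 12.5), each = 2)
  abs_true <- 0.012 * conc + 0.05
  sc <- fit_standard_curve(conc, abs_true * (1 + rnorm(length(conc), 0, 0.05)))
  slope_se <- summary(sc$lm)$coefficients["conc", "Std. Error"]
  expect_lt(abs(sc$slope - 0.012), 3 * slope_se)
})

test_that("initial velocity is the in-window regression slope", {
  t <- seq(0, 150, by = 10)
  # linear rise 0 -> 10 uM over the first 100 s, then continue linearly
  y <- 0.1 * t
  v <- initial_velocity(t, y, window = c(0, 100))
  expect_equal(v$v0, 0.1)
  expect_equal(initial_velocity(t, y, window = c(0, 100),
                                enzyme_conc = 0.01)$per_enzyme, 10)
  expect_equal(initial_velocity(t, rep(3, length(t)))$v0, 0)
  # default window drops pre-quench points
  y2 <- y; y2[t < 30] <- 99
  expect_equal(initial_velocity(t, y2)$v0, 0.1)
  expect_error(initial_velocity(c(10, 160), c(0, 1)), "fewer than 2")
  expect_error(initial_velocity(c(10, 10, 40), c(0, 1, 2)), "increasing")
})

test_that("Michaelis-Menten fit recovers noiseless truth exactly", {
  S <- c(11, 22, 44, 88, 175, 350, 700, 1400, 2000)
  v <- 1 * S / (100 + S)
  fit <- fit_michaelis_menten(S, v, enzyme_conc = 0.01)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["Vmax"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["Km"]), 100, tolerance = 1e-8)
  expect_equal(fit$kcat, 100, tolerance = 1e-7)
  # half-saturation identity of the fitted curve
  expect_equal(predict(fit, unname(coef(fit)["Km"])),
               unname(coef(fit)["Vmax"]) / 2)
  # fitted curve is strictly increasing in substrate
  grid <- predict(fit, seq(0, 2000, length.out = 200))
  expect_true(all(diff(grid) > 0))
})

test_that("binding fit recovers noiseless truth, both model forms", {
  P <- c(0, 5, 10, 25, 50, 100, 250, 500, 1000, 2500)
  dr <- 0.1 * P / (25 + P)
  fit <- fit_binding(P, dr)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["Kd"]), 25, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["Bmax"]), 0.1, tolerance = 1e-8)
  expect_equal(predict(fit, 25), 0.05, tolerance = 1e-8)

  # quadratic (ligand-depletion) form, generated from its own equation
  pr <- 10
  drq <- 0.1 * (P + pr + 25 - sqrt((P + pr + 25)^2 - 4 * P * pr)) / (2 * pr)
  fitq <- fit_binding(P, drq, probe_conc = pr, quadratic = TRUE)
  expect_true(fitq$converged)
  expect_equal(unname(coef(fitq)["Kd"]), 25, tolerance = 1e-6)
  expect_true(all(diff(predict(fitq, seq(0, 2500, length.out = 100))) > 0))
})

test_that("failed fits are flagged, not raised", {
  # constant response has no saturable signal: Km unidentifiable
  S <- c(11, 50, 200, 800, 2000)
  fit <- fit_michaelis_menten(S, rep(0, 5))
  expect_false(fit$converged)
  expect_error(predict(fit, 100), "converge")
  expect_error(fit_michaelis_menten(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_binding(c(1, 2, 3, 4), c(1, 2, 3, 4)), "5 distinct")
})

test_that("recovery is unbiased over repeated noisy simulations", {
  S <- c(11, 22, 44, 88, 175, 350, 700, 1400, 2000)
  P <- c(2, 5, 10, 25, 50, 100, 250, 500, 1000, 2500)
  rel_err <- matrix(NA_real_, 200, 3,
                    dimnames = list(NULL, c("Vmax", "Km", "Kd")))
  for (i in 1:200) {
    mm <- assay_truth("michaelis_menten", list(Vmax = 0.32, Km = 150),
                      noise_sd = 0.05, seed = 5000 + i)
    obs <- simulate_assay(mm, S, replicates = 3)
    fit <- fit_michaelis_menten(obs$x, obs$y)
    bd <- assay_truth("single_site_binding", list(Kd = 25, Bmax = 0.1),
                      noise_sd = 0.05, seed = 7000 + i)
    obs_b <- simulate_assay(bd, P, replicates = 2)
    fit_b <- fit_binding(obs_b$x, obs_b$y)
    if (fit$converged) {
      rel_err[i, "Vmax"] <- abs(coef(fit)["Vmax"] - 0.32) / 0.32
      rel_err[i, "Km"] <- abs(coef(fit)["Km"] - 150) / 150
    }
    if (fit_b$converged) {
      rel_err[i, "Kd"] <- abs(coef(fit_b)["Kd"] - 25) / 25
    }
  }
  med <- apply(rel_err, 2, median, na.rm = TRUE)
  expect_lt(med["Vmax"], 0.05)
  expect_lt(med["Km"], 0.05)
  expect_lt(med["Kd"], 0.05)
  expect_gt(mean(!is.na(rel_err[, "Km"])), 0.95)
})

test_that("kcat computed two independent ways agrees within fit error", {
  set.seed(55)
  S <- c(11, 22, 44, 88, 175, 350, 700, 1400, 2000)
  tr <- assay_truth("michaelis_menten", list(Vmax = 0.32, Km = 150),
                    noise_sd = 0.05, seed = 55)
  obs <- simulate_assay(tr, S, replicates = 3)
  fit <- fit_michaelis_menten(obs$x, obs$y, enzyme_conc = 0.01)
  # route 2: per-enzyme velocity at saturating substrate, scaled to Vmax
  v_sat <- mean(obs$y[obs$x == 2000])
  kcat2 <- (v_sat * (coef(fit)["Km"] + 2000) / 2000) / 0.01
  expect_equal(fit$kcat, unname(kcat2),
               tolerance = 5 * fit$kcat_se / fit$kcat)
})

test_that("simulate and residuals methods are coherent", {
  S <- c(11, 22, 44, 88, 175, 350, 700, 1400, 2000)
  tr <- assay_truth("michaelis_menten", list(Vmax = 1, Km = 100),
                    noise_sd = 0.03, seed = 9)
  obs <- simulate_assay(tr, S, replicates = 2)
  fit <- fit_michaelis_menten(obs$x, obs$y)
  expect_equal(residuals(fit), obs$y - predict(fit, obs$x))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(length(obs$x), 3L))
  ci <- confint(fit)
  expect_true(ci["Km", "lower"] < coef(fit)["Km"] &&
                coef(fit)["Km"] < ci["Km", "upper"])
})
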