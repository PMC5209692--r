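model <- default_model()

test_that("observed series validates its records", {
  obs <- observed_series(c(1, 2), c(0.1, 0.2), "venous_plasma")
  expect_s3_class(obs, "pbpk_obs")
  expect_equal(obs$error, c(1, 1))
  expect_error(observed_series(numeric(0), numeric(0)), "empty")
  expect_error(observed_series(-1, 0.1), "nonnegative")
  expect_error(observed_series(1, 0.1, error = 0), "positive")
  expect_error(observed_series(1, 0.1, variable = "liver"), "variable")
})

test_that("weighted residuals follow (Mod - Obs)/error and are antisymmetric", {
  expect_equal(weighted_residuals(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(weighted_residuals(2, 1), 1)
  expect_equal(weighted_residuals(c(2, 1), c(1, 2), error = c(2, 2)),
               c(0.5, -0.5))
  mod <- c(1.4, 2.2); obs <- c(1.0, 2.5)
  expect_equal(weighted_residuals(mod, obs), -weighted_residuals(obs, mod))
  # SSR of the residual vector (1, -2, 3) is 14
  expect_equal(sum(weighted_residuals(c(1, -2, 3), c(0, 0, 0))^2), 14)
  expect_error(weighted_residuals(1:3, 1:2), "equal length")
})

test_that("residuals use the observation error column when present", {
  obs <- observed_series(c(1, 2), c(2, 4), "venous_plasma", error = c(2, 4))
  expect_equal(weighted_residuals(c(4, 8), obs), c(1, 1))
})

test_that("noiseless single-stage fit recovers the generating parameters", {
  truth <- c(k_a = 0.8, kp_re = 52.6)
  m_true <- set_fitted(model, truth)
  times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 48)
  sim <- simulate_pbpk(m_true, t_end = 48, dt = 0.01)
  obs <- observed_series(times,
                         approx(sim$time, sim$conc[, "venous_plasma"],
                                xout = times)$y,
                         "venous_plasma")
  fit <- fit_pbpk(model, obs, free = c(k_a = 1.2, kp_re = 30))
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates), unname(truth), tolerance = 1e-3)
  expect_lt(fit$ssr, 1e-8)
  expect_equal(length(fit$residuals), nrow(obs))
  expect_true(all(fit$se >= 0))
})

test_that("standard errors and p-values follow the Jacobian-based t-test", {
  # 5 observations, 2 parameters: df = 3; a t-ratio of 0.122 must give the
  # near-unity two-sided p typical of weakly identified parameters
  expect_equal(2 * pt(-abs(0.01193 / 0.09783), df = 3), 0.9103, tolerance = 1e-3)
  truth <- c(k_a = 0.8)
  m_true <- set_fitted(model, truth)
  times <- c(0.5, 1, 2, 4, 8)
  sim <- simulate_pbpk(m_true, t_end = 8, dt = 0.01)
  vals <- approx(sim$time, sim$conc[, "venous_plasma"], xout = times)$y
  set.seed(11)
  obs <- observed_series(times, vals * exp(rnorm(5, 0, 0.05)), "venous_plasma")
  fit <- fit_pbpk(model, obs, free = c(k_a = 1))
  expect_equal(fit$df, 4)
  tval <- fit$estimates[["k_a"]] / fit$se[["k_a"]]
  expect_equal(unname(fit$p_values[["k_a"]]), 2 * pt(-abs(tval), 4))
})

test_that("fit preconditions and error paths are enforced", {
  obs <- observed_series(1, 0.01, "venous_plasma")
  expect_error(fit_pbpk(model, obs, free = numeric(0)), "free parameter")
  expect_error(fit_pbpk(model, obs[0, ], free = c(k_a = 1)), "nonempty")
  expect_error(fit_pbpk(model, obs, free = c(nope = 1)), "unknown fitted")
})

test_that("two-stage protocol wires plasma then heart estimation", {
  truth <- c(k_a = 0.8, kp_re = 52.6, q_pf = 0.012, p = 0.78)
  spec <- fixture_spec(cv = 0, seed = 5, truth = truth)
  plasma <- make_plasma_series(spec, model)
  heart <- make_heart_series(spec, model, anchor = FALSE)
  fit <- two_stage_fit(model, plasma, heart)
  # noiseless inputs: near-perfect fit at both stages
  expect_lt(fit$stage1$ssr, 1e-6)
  expect_lt(fit$stage2$ssr, 1e-6)
  expect_named(fit$estimates, c("k_a", "kp_re", "q_pf", "p"))
  expect_equal(fit$estimates[c("k_a", "kp_re")], truth[c("k_a", "kp_re")],
               tolerance = 0.01)
  # plasma-only input cannot run stage 2
  expect_error(two_stage_fit(model, plasma, heart_obs = NULL), "heart")
  expect_error(two_stage_fit(model, plasma, plasma), "total_heart")
})

test_that("observation CSV round-trips including ng/mL conversion", {
  path <- withr::local_tempfile(fileext = ".csv")
  obs <- observed_series(c(0.5, 3.5), c(0.02, 0.11435), "total_heart")
  write_obs_csv(obs, path, comment = "synthetic check fixture")
  back <- read_obs_csv(path)
  expect_equal(back$value, obs$value)
  expect_equal(back$variable, obs$variable)
  # ng/mL input converts to internal mg/L
  writeLines(c("time_h,value,unit,variable",
               "3.5,114.35,ng/mL,total_heart"), path)
  expect_equal(read_obs_csv(path)$value, 0.11435)
})
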