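model <- default_model()

test_that("the zero state is an equilibrium and single-tissue terms evaluate", {
  p <- pack_parms(model)
  y0 <- initial_state(model, 0)
  d0 <- unlist(pbpk_rhs(0, y0, p)[[1]])
  expect_equal(d0, setNames(numeric(length(y0)), names(y0)), ignore_attr = TRUE)

  # muscle uptake with arterial plasma at 1 mg/L and empty muscle: Q_mu * 1
  y <- y0
  y[["arterial"]] <- p[["v_art"]] * 1
  d <- unlist(pbpk_rhs(0, y, p)[[1]])
  expect_equal(d[["muscle"]], p[["q_mu"]] * 1)
  expect_equal(d[["adipose"]], p[["q_ad"]] * 1)
  expect_equal(d[["epicardium"]], p[["q_mural"]] * 1)
})

test_that("depot transfer and total mass derivative balance", {
  p <- pack_parms(model)
  set.seed(4)
  y <- initial_state(model, 22)
  y[2:18] <- runif(17, 0, 0.5)
  d <- unlist(pbpk_rhs(0, y, p)[[1]])
  expect_equal(d[["depot"]], -p[["k_a"]] * y[["depot"]])
  expect_equal(sum(d), 0, tolerance = 1e-12)   # conservation incl. elim bins
  expect_error(pbpk_rhs(1.5, replace(y, 3, NaN), p), "t = 1.5")
})

test_that("pericardial flux convention and antisymmetry", {
  expect_equal(pericardial_flux(1, 0, 0.78, 0.05), 0.78)
  expect_equal(pericardial_flux(0.3, 0.3 / 0.05, 0.78, 0.05), 0)
  expect_equal(pericardial_flux(2, 7, 0, 0.05), 0)
  # amount leaving the epicardium equals the amount entering the fluid
  p <- pack_parms(model)
  y <- initial_state(model, 0)
  y[["epicardium"]] <- 0.01
  y[["pericardial_fluid"]] <- 0.002
  d <- unlist(pbpk_rhs(0, y, p)[[1]])
  j <- pericardial_flux(y[["epicardium"]] / p[["v_epi"]],
                        y[["pericardial_fluid"]] / p[["v_pf"]],
                        p[["p_diff"]], p[["fu_pf"]])
  # isolate the flux terms: subtract the perfusion/elimination parts
  cv_epi <- y[["epicardium"]] / p[["v_epi"]] / p[["kp_epi"]]
  cv_pf <- y[["pericardial_fluid"]] / p[["v_pf"]] / p[["kp_pf"]]
  expect_equal(d[["epicardium"]],
               -p[["q_mural"]] * cv_epi - p[["cl_card"]] / 3 * cv_epi - j)
  expect_equal(d[["pericardial_fluid"]], -p[["q_pf"]] * cv_pf + j)
})

test_that("concentrations include venous plasma and weighted total heart", {
  # identity: amount = volume gives 1 mg/L
  y <- initial_state(model, 0)
  p <- pack_parms(model)
  y[["epicardium"]] <- p[["v_epi"]]
  y[["midmyocardium"]] <- p[["v_mid"]]
  y[["endocardium"]] <- p[["v_endo"]]
  cc <- compartment_concentrations(y, model)
  expect_equal(unname(cc[["total_heart"]]), 1)

  # the layer-weighted mean reproduces the transmural ratio arithmetic:
  # layers at 2.89/7.13/13.41 (relative to venous blood) with fractions
  # 0.1/0.3/0.6 average to 10.474
  y2 <- initial_state(model, 0)
  y2[["epicardium"]] <- 2.89 * p[["v_epi"]]
  y2[["midmyocardium"]] <- 7.13 * p[["v_mid"]]
  y2[["endocardium"]] <- 13.41 * p[["v_endo"]]
  cc2 <- compartment_concentrations(y2, model)
  expect_equal(unname(cc2[["total_heart"]]), 10.474)

  # blood-to-plasma bridging: venous blood = BP * venous plasma
  y3 <- initial_state(model, 0)
  y3[["venous"]] <- p[["v_ven"]] * 1.0   # 1 mg/L plasma
  cc3 <- compartment_concentrations(y3, model)
  expect_equal(unname(cc3[["venous_plasma"]]), 1.0)
  expect_equal(unname(cc3[["venous"]]), 1.04)
})

test_that("compiled and R right-hand sides produce the same trajectory", {
  sim_c <- simulate_pbpk(model, t_end = 6, dt = 0.02)
  sim_r <- simulate_pbpk(model, t_end = 6, dt = 0.02, engine = "r")
  # identical equations; difference is LSODA step-control noise at rtol 1e-8
  expect_lt(max(abs(sim_c$conc - sim_r$conc)), 1e-6)
})

test_that("integrated trajectory matches an independent RK4 oracle on 0-2 h", {
  p <- pack_parms(model)
  y0 <- initial_state(model, 22)
  rk <- rk4_trajectory(pbpk_rhs, y0, p, t_end = 2, dt = 5e-4)
  sim <- simulate_pbpk(model, t_end = 2, dt = 0.05)
  idx <- round(sim$time / 5e-4) + 1L   # 0.05 h grid sits on the RK4 grid
  expect_false(anyNA(idx))
  a_rk <- rk$y[idx, colnames(sim$amounts)]
  scale <- max(abs(a_rk))
  expect_lt(max(abs(sim$amounts - a_rk)) / scale, 1e-5)
})

test_that("with q_pf = p = 0 the system reduces to the sixteen-compartment oracle", {
  m0 <- set_fitted(model, c(q_pf = 0, p = 0))
  m0$heart$q_pf <- 0   # set_fitted validates; make the zero explicit
  m0$heart$p <- 0
  sim <- simulate_pbpk(m0, t_end = 12, dt = 0.05)
  # pericardial fluid never fills
  expect_equal(max(abs(sim$amounts[, "pericardial_fluid"])), 0)
  # and the remaining compartments match the independently coded system
  pp <- sixteen_parms(m0)
  y0 <- setNames(numeric(17), c("depot", "arterial", "venous", "lung",
                                "adipose", "bone", "brain", "kidney",
                                "spleen", "gut", "liver", "muscle", "skin",
                                "rest", "epicardium", "midmyocardium",
                                "endocardium"))
  y0[["depot"]] <- m0$drug$f_abs * 22
  out <- deSolve::ode(y0, seq(0, 12, by = 0.05), rhs_sixteen, pp,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  for (nm in names(y0)) {
    expect_equal(unname(sim$amounts[, nm]), unname(out[, nm]),
                 tolerance = 1e-6)
  }
})

test_that("steady infusion drives tissue:plasma ratios to Kp", {
  m <- default_model()
  m$drug$k_a <- 1e-9   # no oral input; infusion only
  sim <- simulate_pbpk(m, dose_mg = 0, t_end = 3000, dt = 1,
                       infusion_mg_h = 0.1)
  last <- nrow(sim$conc)
  cp_art <- sim$conc[last, "arterial"] / m$drug$bp
  for (nm in c("adipose", "bone", "brain", "muscle", "skin", "spleen",
               "rest")) {
    expect_equal(unname(sim$conc[last, nm] / cp_art), m$drug$kp[[nm]],
                 tolerance = 1e-3)
  }
  # heart layers eliminate and exchange with the pericardial fluid, so they
  # sit near (not exactly at) their layer Kp
  expect_equal(unname(sim$conc[last, "epicardium"] / cp_art),
               m$heart$kp_epi, tolerance = 0.05)
})

test_that("nonnegativity is preserved from nonnegative starts", {
  sim <- simulate_pbpk(model, t_end = 48, dt = 0.01)
  expect_gte(min(sim$amounts), -1e-12)
  expect_gte(min(sim$conc), -1e-12)
  # depot is monotonically nonincreasing
  expect_lte(max(diff(sim$amounts[, "depot"])), 0)
})
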