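#' Observed concentration-time series
#'
#' Builds the observation table the fitting workflow consumes. Each record is
#' a time \[h\], a value \[mg/L\], the observed variable (`venous_plasma` or
#' `total_heart`) and an error weight used in the weighted residuals
#' (default 1, i.e. unweighted).
#'
#' @param time_h observation times \[h\], nonnegative.
#' @param value observed concentrations \[mg/L\].
#' @param variable observed variable id(s).
#' @param error positive weighting factor(s).
#' @return data.frame of class `pbpk_obs`.
#' @export
observed_series <- function(time_h, value,
                            variable = "venous_plasma", error = 1) {
  n <- length(time_h)
  if (n == 0) stop("empty observation series", call. = FALSE)
  if (length(value) != n) stop("`time_h` and `value` lengths differ", call. = FALSE)
  variable <- rep_len(variable, n)
  error <- rep_len(error, n)
  if (any(time_h < 0)) stop("observation times must be nonnegative", call. = FALSE)
  if (any(error <= 0)) stop("error weights must be positive", call. = FALSE)
  ok <- c("venous_plasma", "total_heart")
  if (!all(variable %in% ok)) {
    stop("`variable` must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  structure(data.frame(time_h = time_h, value = value, variable = variable,
                       error = error, stringsAsFactors = FALSE),
            class = c("pbpk_obs", "data.frame"))
}

#' Weighted residuals between model and observations
#'
#' `res_i = (Mod_i - Obs_i) / error_i`; with the default unit error this is
#' the plain model-minus-observation difference. Antisymmetric under swapping
#' model and observation.
#'
#' @param model_values model predictions at the observation times.
#' @param observed observed values (same length), or a `pbpk_obs` whose
#'   `value`/`error` columns are used.
#' @param error weighting factor(s), ignored when `observed` is a `pbpk_obs`.
#' @return residual vector.
#' @export
weighted_residuals <- function(model_values, observed, error = 1) {
  if (inherits(observed, "pbpk_obs") || is.data.frame(observed)) {
    error <- observed$error
    observed <- observed$value
  }
  if (length(model_values) != length(observed)) {
    stop("model and observed vectors must have equal length", call. = FALSE)
  }
  (model_values - observed) / error
}

# Model predictions at the observation times: dense simulation then linear
# interpolation per observed variable. Times outside the simulated span error.
predict_at_obs <- function(model, obs, dt = 0.01, engine = "compiled",
                           rtol = 1e-8, atol = 1e-10) {
  t_end <- max(obs$time_h)
  if (t_end <= 0) stop("observations need at least one positive time", call. = FALSE)
  sim <- simulate_pbpk(model, t_end = t_end, dt = dt, engine = engine,
                       rtol = rtol, atol = atol)
  pred <- numeric(nrow(obs))
  for (v in unique(obs$variable)) {
    idx <- obs$variable == v
    if (any(obs$time_h[idx] > max(sim$time))) {
      stop("observation time outside the simulated range", call. = FALSE)
    }
    pred[idx] <- stats::approx(sim$time, sim$conc[, v],
                               xout = obs$time_h[idx], rule = 1)$y
  }
  pred
}

#' Least-squares parameter estimation for the PBPK model
#'
#' Minimizes the sum of squared weighted residuals over a named subset of the
#' four estimable parameters (`k_a`, `kp_re`, `q_pf`, `p`) with the
#' Levenberg-Marquardt algorithm (`minpack.lm::nls.lm`). Positivity is
#' enforced by optimizing on the log scale (a smooth transform of the default
#' (0, Inf) box). Standard errors come from the Jacobian-based covariance
#' `SSR/(n-p) * (J'J)^-1` evaluated at the estimate in natural units;
#' p-values are two-sided t-tests of the estimate against zero with `n - p`
#' degrees of freedom.
#'
#' @param model a `pbpk_model` carrying the fixed parameters.
#' @param observed a `pbpk_obs` (see [observed_series()]).
#' @param free named numeric vector of starting values for the parameters to
#'   estimate; names among `k_a`, `kp_re`, `q_pf`, `p`.
#' @param dt simulation output step used for interpolation \[h\].
#' @param engine ODE engine, see [simulate_pbpk()].
#' @param rtol,atol integrator tolerances during fitting.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return object of class `pbpk_fit`: estimates, standard errors, p-values,
#'   residuals, SSR, convergence flag, iteration count, degrees of freedom.
#'   Non-convergence is flagged, not thrown; a (numerically) singular Jacobian
#'   sets `singular = TRUE` and inflates the affected standard errors to `Inf`.
#' @export
fit_pbpk <- function(model, observed, free, dt = 0.01,
                     engine = "compiled", rtol = 1e-8, atol = 1e-10,
                     max_iter = 100) {
  if (!nrow(observed)) stop("observations must be nonempty", call. = FALSE)
  if (length(free) == 0) stop("at least one free parameter is required", call. = FALSE)
  if (is.null(names(free)) || any(!nzchar(names(free)))) {
    stop("`free` must be a named vector of starting values", call. = FALSE)
  }
  if (any(free <= 0)) stop("starting values must be positive", call. = FALSE)
  par_names <- names(free)
  allowed <- c("k_a", "kp_re", "q_pf", "p")
  if (length(setdiff(par_names, allowed))) {
    stop("unknown fitted parameter(s): ",
         paste(setdiff(par_names, allowed), collapse = ", "), call. = FALSE)
  }

  # invalid parameter regions (e.g. q_pf at or above the mural flow) and
  # integrator failures act as a soft barrier so LM backs off instead of dying
  resid_fn <- function(theta) {
    res <- try({
      m <- set_fitted(model, stats::setNames(exp(theta), par_names))
      pred <- predict_at_obs(m, observed, dt = dt, engine = engine,
                             rtol = rtol, atol = atol)
      weighted_residuals(pred, observed)
    }, silent = TRUE)
    if (inherits(res, "try-error") || any(!is.finite(res))) {
      return(rep(1e6 * (1 + sum(theta^2)), nrow(observed)))
    }
    res
  }

  lm_fit <- minpack.lm::nls.lm(par = log(free), fn = resid_fn,
                               control = minpack.lm::nls.lm.control(
                                 maxiter = max_iter))
  estimates <- stats::setNames(exp(lm_fit$par), par_names)
  residuals <- lm_fit$fvec
  ssr <- sum(residuals^2)
  n <- length(residuals)
  p <- length(estimates)
  df <- n - p
  converged <- lm_fit$info %in% 1:4

  # covariance in natural units from a central-difference Jacobian
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- 1e-4 * estimates[j]
    up <- dn <- estimates
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, .Machine$double.xmin)
    r_up <- resid_fn(log(up))
    r_dn <- resid_fn(log(dn))
    J[, j] <- (r_up - r_dn) / (up[j] - dn[j])
  }
  jtj <- crossprod(J)
  se <- rep(NA_real_, p)
  singular <- FALSE
  s2 <- if (df > 0) ssr / df else NA_real_
  cov_try <- try(solve(jtj) * s2, silent = TRUE)
  if (inherits(cov_try, "try-error") || anyNA(cov_try)) {
    singular <- TRUE
    sv <- svd(jtj)
    pos <- sv$d > max(sv$d) * 1e-12
    if (any(pos)) {
      pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      se <- sqrt(pmax(diag(pinv) * s2, 0))
      se[!pos] <- Inf
    } else {
      se <- rep(Inf, p)
    }
    warning("Jacobian is singular or near-singular; standard errors inflated",
            call. = FALSE)
  } else {
    se <- sqrt(pmax(diag(cov_try), 0))
  }
  names(se) <- par_names
  tval <- estimates / se
  pval <- if (df > 0) 2 * stats::pt(-abs(tval), df) else rep(NA_real_, p)
  names(pval) <- par_names

  structure(
    list(parameters = par_names, estimates = estimates, se = se,
         p_values = pval, residuals = residuals, ssr = ssr,
         converged = converged, iterations = lm_fit$niter,
         message = lm_fit$message, df = df, singular = singular,
         model = set_fitted(model, estimates)),
    class = "pbpk_fit"
  )
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat("PBPK least-squares fit",
      if (!x$converged) "(NOT converged)" else "", "\n")
  for (i in seq_along(x$parameters)) {
    cat(sprintf("  %-6s = %12.5f  (SE %.5f, p = %.3g)\n",
                x$parameters[i], x$estimates[i], x$se[i], x$p_values[i]))
  }
  cat(sprintf("  SSR %.6g on %d residuals (df %d), %d iterations\n",
              x$ssr, length(x$residuals), x$df, x$iterations))
  invisible(x)
}

#' Two-stage fitting protocol
#'
#' Reproduces the staged estimation workflow of the reference analysis:
#' stage 1 estimates the absorption rate `k_a` and the rest-of-body partition
#' coefficient `kp_re` against the plasma series while the pericardial
#' parameters are held at their start values (`q_pf` 0.01, `p` 0.40 L/h);
#' stage 2 fixes the stage-1 estimates and estimates the pericardial flow
#' `q_pf` and the diffusion clearance `p` against the heart-tissue series,
#' starting from the same held values.
#'
#' @param model a `pbpk_model`.
#' @param plasma_obs `pbpk_obs` with variable `venous_plasma`.
#' @param heart_obs `pbpk_obs` with variable `total_heart`.
#' @param stage1_start starting values for stage 1.
#' @param stage2_start starting (and stage-1 held) values for `q_pf` and `p`.
#' @param ... passed on to [fit_pbpk()] (engine, tolerances, `dt`).
#' @return list of class `pbpk_two_stage` with elements `stage1` and `stage2`
#'   (`pbpk_fit` objects) and `estimates`, the combined four-parameter vector.
#' @export
two_stage_fit <- function(model, plasma_obs, heart_obs,
                          stage1_start = c(k_a = 1, kp_re = 30),
                          stage2_start = c(q_pf = 0.01, p = 0.40), ...) {
  if (missing(heart_obs) || is.null(heart_obs) || !nrow(heart_obs)) {
    stop("stage 2 requires a nonempty heart-tissue series", call. = FALSE)
  }
  if (!nrow(plasma_obs)) stop("stage 1 requires a nonempty plasma series",
                              call. = FALSE)
  if (!any(plasma_obs$variable == "venous_plasma")) {
    stop("`plasma_obs` must contain the `venous_plasma` variable", call. = FALSE)
  }
  if (!any(heart_obs$variable == "total_heart")) {
    stop("`heart_obs` must contain the `total_heart` variable", call. = FALSE)
  }
  m1 <- set_fitted(model, stage2_start)
  stage1 <- fit_pbpk(m1, plasma_obs, free = stage1_start, ...)
  m2 <- set_fitted(model, stage1$estimates)
  stage2 <- fit_pbpk(m2, heart_obs, free = stage2_start, ...)
  structure(
    list(stage1 = stage1, stage2 = stage2,
         estimates = c(stage1$estimates, stage2$estimates)),
    class = "pbpk_two_stage"
  )
}

#' @export
print.pbpk_two_stage <- function(x, ...) {
  cat("Two-stage PBPK fit\n-- stage 1 (plasma) --\n")
  print(x$stage1)
  cat("-- stage 2 (heart tissue) --\n")
  print(x$stage2)
  invisible(x)
}

#' Read an observed series from CSV
#'
#' Expected columns: `time_h`, `value`, `variable`, and optionally `unit`
#' (`mg/L` or `ng/mL`; ng/mL values are converted to the internal mg/L) and
#' `error`. Lines starting with `#` are treated as comments.
#'
#' @param path CSV file path.
#' @return a `pbpk_obs`.
#' @export
read_obs_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_h", "value", "variable")
  if (!all(need %in% names(df))) {
    stop("observation CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  value <- df$value
  if ("unit" %in% names(df)) {
    ngml <- df$unit %in% c("ng/mL", "ng/ml")
    value[ngml] <- ng_ml_to_mg_l(value[ngml])
    bad <- !df$unit %in% c("ng/mL", "ng/ml", "mg/L", "mg/l")
    if (any(bad)) stop("unsupported unit(s): ",
                       paste(unique(df$unit[bad]), collapse = ", "),
                       call. = FALSE)
  }
  observed_series(df$time_h, value, df$variable,
                  if ("error" %in% names(df)) df$error else 1)
}

#' Write an observed series to CSV
#'
#' Columns `time_h, value, unit, variable, error` with values in mg/L; the
#' optional header comment documents the provenance of synthetic fixtures.
#'
#' @param obs a `pbpk_obs`.
#' @param path output path.
#' @param comment optional character vector written as `# ` comment lines.
#' @return `path`, invisibly.
#' @export
write_obs_csv <- function(obs, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  df <- data.frame(time_h = sprintf("%.6g", obs$time_h),
                   value = sprintf("%.10g", obs$value),
                   unit = "mg/L",
                   variable = obs$variable,
                   error = sprintf("%.6g", obs$error))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
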