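#' Default amitriptyline whole-body PBPK model
#'
#' Assembles the complete reference parameterization: a 70 kg reference human,
#' the four-compartment heart anatomy, and the amitriptyline drug block
#' (physicochemical constants, partition coefficients, hepatic Michaelis-Menten
#' enzyme kinetics, cardiac CYP clearances, renal clearance) together with the
#' fitted parameter values of the reference analysis (k_a = 0.80075 1/h,
#' Kp_rest = 52.6095, Q_pf = 0.01193 L/h, P = 0.7823 L/h), a 22 mg oral dose
#' and the integration settings.
#'
#' @param body_weight body weight \[kg\].
#' @return object of class `pbpk_model`.
#' @examples
#' m <- default_model()
#' clearance_set(m)$clu_int_heart  # 0.316 L/h
#' @export
default_model <- function(body_weight = 70) {
  physiology <- build_reference_human(body_weight)
  heart <- heart_anatomy()
  drug <- list(
    name = "amitriptyline",
    mw = 277.4,          # g/mol, free base
    f_abs = 0.5,
    k_a = 0.80075,       # 1/h, fitted
    fu_p = 0.05,
    fu_pf = 0.05,
    fu_h = 0.014,
    fu_mic = 1,
    isef_heart = 1,
    bp = 1.04,
    log_p = 4.62,        # informational; Kp prediction is upstream of this model
    cl_renal = 0.504,    # L/h
    kp = c(adipose = 4.27, bone = 4.28, brain = 2.78, gut = 11.97,
           kidney = 6.52, liver = 20.16, lung = 2.09, muscle = 10.04,
           skin = 5.73, spleen = 11.24, rest = 52.60950),
    enzymes = default_hepatic_enzymes()
  )
  dose <- list(amount_mg = 22)
  run <- list(t_end = 48, dt = 0.01, rtol = 1e-8, atol = 1e-10)
  model <- structure(
    list(physiology = physiology, heart = heart, drug = drug,
         dose = dose, run = run),
    class = "pbpk_model"
  )
  validate_model(model)
  model
}

#' Hepatic CYP kinetics for amitriptyline
#'
#' Recombinant-enzyme Vmax \[pmol/min/pmol CYP\], Km \[uM\] and ISEF per
#' isoform, with healthy-volunteer hepatic abundances \[pmol/mg microsomal
#' protein\]. The abundances are standard population values consistent with
#' the simulator toolchain the kinetic data come from; all are overridable
#' through the config.
#'
#' @return data.frame with columns isoform, vmax_pmol, km_um, isef,
#'   liver_abundance.
#' @export
default_hepatic_enzymes <- function() {
  data.frame(
    isoform = c("CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "CYP3A4",
                "CYP2C8", "CYP2B6"),
    vmax_pmol = c(1.79, 3.97, 4.22, 1.49, 3.37, 0.70, 0.25),
    km_um = c(63.5, 50.5, 8.52, 7.12, 213.8, 9.74, 56.7),
    isef = c(11.1, 5.73, 3.07, 0.74, 3.92, 3.7, 3.7),
    liver_abundance = c(52, 73, 14, 8, 137, 24, 17),
    stringsAsFactors = FALSE
  )
}

#' Validate a PBPK model object
#'
#' Checks structural completeness and physical constraints: positive volumes,
#' flows and partition coefficients; unbound fractions in (0, 1]; the
#' pericardial flow strictly below the total heart blood flow; nonnegative
#' enzyme kinetics.
#'
#' @param model a `pbpk_model`.
#' @return the model, invisibly; otherwise an error naming the violated
#'   constraint.
#' @export
validate_model <- function(model) {
  if (!inherits(model, "pbpk_model")) stop("not a `pbpk_model`", call. = FALSE)
  d <- model$drug
  for (f in c("fu_p", "fu_pf", "fu_h", "fu_mic")) {
    if (!is.numeric(d[[f]]) || d[[f]] <= 0 || d[[f]] > 1) {
      stop(sprintf("`%s` must lie in (0, 1]", f), call. = FALSE)
    }
  }
  if (d$f_abs <= 0 || d$f_abs > 1) stop("`f_abs` must lie in (0, 1]", call. = FALSE)
  if (d$k_a <= 0) stop("`k_a` must be positive", call. = FALSE)
  if (d$bp <= 0) stop("`bp` must be positive", call. = FALSE)
  if (d$mw <= 0) stop("`mw` must be positive", call. = FALSE)
  if (d$cl_renal < 0) stop("`cl_renal` must be nonnegative", call. = FALSE)
  kp_tissues <- c("adipose", "bone", "brain", "gut", "kidney", "liver",
                  "lung", "muscle", "skin", "spleen", "rest")
  if (!all(kp_tissues %in% names(d$kp))) {
    stop("drug Kp vector must name: ", paste(kp_tissues, collapse = ", "),
         call. = FALSE)
  }
  if (any(d$kp[kp_tissues] <= 0)) stop("all Kp values must be positive", call. = FALSE)
  enz <- d$enzymes
  need <- c("isoform", "vmax_pmol", "km_um", "isef", "liver_abundance")
  if (!is.data.frame(enz) || !all(need %in% names(enz))) {
    stop("`drug$enzymes` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(enz$vmax_pmol < 0) || any(enz$km_um <= 0) || any(enz$isef <= 0)) {
    stop("enzyme kinetics: Vmax >= 0, Km > 0, ISEF > 0 required", call. = FALSE)
  }
  q_he <- model$physiology$flows[["heart"]]
  if (model$heart$q_pf >= q_he) {
    stop("`q_pf` must be below the total heart blood flow", call. = FALSE)
  }
  if (model$run$t_end <= 0 || model$run$dt <= 0) {
    stop("`t_end` and `dt` must be positive", call. = FALSE)
  }
  invisible(model)
}

#' Load a model configuration from YAML
#'
#' Reads a YAML file whose blocks mirror the model structure
#' (`physiology:`, `heart:`, `drug:`, `dose:`, `run:`) and merges it over the
#' embedded amitriptyline defaults; an empty file therefore yields the full
#' default model. Every overridden key is reported via `message()` and
#' recorded in the `"overrides"` attribute so parameter provenance
#' (default vs user override) stays visible. Unknown keys are an error.
#'
#' Scalar drug keys (`mw`, `f_abs`, `k_a`, `fu_p`, `fu_pf`, `fu_h`, `fu_mic`,
#' `bp`, `log_p`, `cl_renal`), the `kp:` map, the `enzymes:` list of
#' `{isoform, vmax_pmol, km_um, isef, liver_abundance}` records, heart keys
#' (`q_pf`, `p`, `v_pf`, `kp_epi`, `kp_mid`, `kp_endo`, `kp_pf`,
#' `layer_fractions`, `cyp_abundance`, `cl_per_pmol`, `mg_protein_per_heart`),
#' `physiology: body_weight/cardiac_output_ml_s/mppgl/fractional_volumes/`
#' `fractional_flows`, `dose: amount_mg` and `run: t_end/dt/rtol/atol` are
#' supported.
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @param quiet suppress the override log.
#' @return validated `pbpk_model` with an `"overrides"` attribute.
#' @export
load_model_config <- function(path = NULL, quiet = FALSE) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  }
  known_blocks <- c("physiology", "heart", "drug", "dose", "run")
  unknown <- setdiff(names(cfg), known_blocks)
  if (length(unknown)) {
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  phys_cfg <- cfg$physiology %||% list()
  allowed_phys <- c("body_weight", "cardiac_output_ml_s", "mppgl",
                    "fractional_volumes", "fractional_flows",
                    "fractional_plasma", "fractional_erythrocytes")
  check_keys(phys_cfg, allowed_phys, "physiology")
  fv <- default_fractional_volumes()
  ff <- default_fractional_flows()
  fv[names(phys_cfg$fractional_volumes)] <- unlist(phys_cfg$fractional_volumes)
  ff[names(phys_cfg$fractional_flows)] <- unlist(phys_cfg$fractional_flows)
  physiology <- build_reference_human(
    body_weight = phys_cfg$body_weight %||% 70,
    fractional_volumes = fv, fractional_flows = ff,
    cardiac_output_ml_s = phys_cfg$cardiac_output_ml_s %||% 108.33,
    mppgl = phys_cfg$mppgl %||% 45,
    fractional_plasma = phys_cfg$fractional_plasma %||% 0.0424,
    fractional_erythrocytes = phys_cfg$fractional_erythrocytes %||% 0.0347
  )

  heart_cfg <- cfg$heart %||% list()
  allowed_heart <- c("layer_fractions", "v_pf", "q_pf", "p", "kp_epi",
                     "kp_mid", "kp_endo", "kp_pf", "cyp_abundance",
                     "cl_per_pmol", "mg_protein_per_heart")
  check_keys(heart_cfg, allowed_heart, "heart")
  heart_def <- heart_anatomy()
  heart_args <- heart_def[allowed_heart]
  for (k in names(heart_cfg)) {
    v <- heart_cfg[[k]]
    if (k %in% c("layer_fractions", "cyp_abundance", "cl_per_pmol")) {
      v0 <- heart_args[[k]]
      v0[names(v)] <- unlist(v)
      v <- v0
    }
    heart_args[[k]] <- v
  }
  heart <- do.call(heart_anatomy, heart_args)

  model <- default_model(body_weight = physiology$body_weight)
  model$physiology <- physiology
  model$heart <- heart

  drug_cfg <- cfg$drug %||% list()
  allowed_drug <- c("name", "mw", "f_abs", "k_a", "fu_p", "fu_pf", "fu_h",
                    "fu_mic", "isef_heart", "bp", "log_p", "cl_renal",
                    "kp", "enzymes")
  check_keys(drug_cfg, allowed_drug, "drug")
  for (k in setdiff(names(drug_cfg), c("kp", "enzymes"))) {
    model$drug[[k]] <- drug_cfg[[k]]
  }
  if (!is.null(drug_cfg$kp)) {
    kp <- model$drug$kp
    bad <- setdiff(names(drug_cfg$kp), names(kp))
    if (length(bad)) stop("unknown Kp tissue(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    kp[names(drug_cfg$kp)] <- unlist(drug_cfg$kp)
    model$drug$kp <- kp
  }
  if (!is.null(drug_cfg$enzymes)) {
    model$drug$enzymes <- do.call(rbind, lapply(drug_cfg$enzymes, function(e) {
      need <- c("isoform", "vmax_pmol", "km_um", "isef")
      if (!all(need %in% names(e))) {
        stop("each enzyme record needs: ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      data.frame(isoform = e$isoform, vmax_pmol = e$vmax_pmol,
                 km_um = e$km_um, isef = e$isef,
                 liver_abundance = e$liver_abundance %||% NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }

  dose_cfg <- cfg$dose %||% list()
  check_keys(dose_cfg, "amount_mg", "dose")
  if (!is.null(dose_cfg$amount_mg)) model$dose$amount_mg <- dose_cfg$amount_mg
  run_cfg <- cfg$run %||% list()
  check_keys(run_cfg, c("t_end", "dt", "rtol", "atol"), "run")
  for (k in names(run_cfg)) model$run[[k]] <- run_cfg[[k]]

  validate_model(model)
  overrides <- flatten_keys(cfg)
  if (!quiet && length(overrides)) {
    message("config overrides applied: ", paste(overrides, collapse = ", "))
  }
  attr(model, "overrides") <- overrides
  model
}

#' Write a model configuration to YAML
#'
#' Serializes the tunable blocks of a model so that
#' `load_model_config(dump_model_config(m, f))` reproduces `m`.
#'
#' @param model a `pbpk_model`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_model_config <- function(model, path) {
  stopifnot(inherits(model, "pbpk_model"))
  enz <- model$drug$enzymes
  cfg <- list(
    physiology = list(
      body_weight = model$physiology$body_weight,
      cardiac_output_ml_s = model$physiology$flows[["cardiac_output"]] / 3.6,
      mppgl = model$physiology$mppgl,
      fractional_volumes = as.list(model$physiology$fractional_volumes),
      fractional_flows = as.list(model$physiology$fractional_flows),
      fractional_plasma = model$physiology$fractional_plasma,
      fractional_erythrocytes = model$physiology$fractional_erythrocytes
    ),
    heart = list(
      layer_fractions = as.list(model$heart$layer_fractions),
      v_pf = model$heart$v_pf, q_pf = model$heart$q_pf, p = model$heart$p,
      kp_epi = model$heart$kp_epi, kp_mid = model$heart$kp_mid,
      kp_endo = model$heart$kp_endo, kp_pf = model$heart$kp_pf,
      cyp_abundance = as.list(model$heart$cyp_abundance),
      cl_per_pmol = as.list(model$heart$cl_per_pmol),
      mg_protein_per_heart = model$heart$mg_protein_per_heart
    ),
    drug = c(
      model$drug[c("name", "mw", "f_abs", "k_a", "fu_p", "fu_pf", "fu_h",
                   "fu_mic", "isef_heart", "bp", "log_p", "cl_renal")],
      list(kp = as.list(model$drug$kp),
           enzymes = lapply(seq_len(nrow(enz)), function(i) as.list(enz[i, ])))
    ),
    dose = model$dose,
    run = model$run
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Update fitted disposition parameters
#'
#' Applies values for any of the four estimable parameters to a model:
#' `k_a` (first-order absorption rate, 1/h), `kp_re` (rest-of-body partition
#' coefficient), `q_pf` (pericardial blood flow, L/h) and `p`
#' (pericardial-epicardial diffusion clearance, L/h).
#'
#' @param model a `pbpk_model`.
#' @param pars named numeric vector with names among `k_a`, `kp_re`, `q_pf`, `p`.
#' @return the updated, revalidated model.
#' @export
set_fitted <- function(model, pars) {
  stopifnot(inherits(model, "pbpk_model"))
  allowed <- c("k_a", "kp_re", "q_pf", "p")
  bad <- setdiff(names(pars), allowed)
  if (length(bad)) {
    stop("unknown fitted parameter(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  if ("k_a" %in% names(pars)) model$drug$k_a <- unname(pars[["k_a"]])
  if ("kp_re" %in% names(pars)) model$drug$kp[["rest"]] <- unname(pars[["kp_re"]])
  if ("q_pf" %in% names(pars)) model$heart$q_pf <- unname(pars[["q_pf"]])
  if ("p" %in% names(pars)) model$heart$p <- unname(pars[["p"]])
  validate_model(model)
  model
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat("Whole-body PBPK model with four-compartment heart sub-model\n")
  cat(sprintf("  drug: %s (MW %.1f g/mol, BP %.2f, fu_p %.3f)\n",
              x$drug$name, x$drug$mw, x$drug$bp, x$drug$fu_p))
  cat(sprintf("  subject: %.0f kg, cardiac output %.1f L/h\n",
              x$physiology$body_weight,
              x$physiology$flows[["cardiac_output"]]))
  cat(sprintf("  fitted set: k_a %.5f 1/h, Kp_re %.4f, Q_pf %.5f L/h, P %.5f L/h\n",
              x$drug$k_a, x$drug$kp[["rest"]], x$heart$q_pf, x$heart$p))
  cat(sprintf("  dose: %.1f mg oral (F_abs %.2f); run: 0-%g h, dt %g h\n",
              x$dose$amount_mg, x$drug$f_abs, x$run$t_end, x$run$dt))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(block, allowed, name) {
  bad <- setdiff(names(block), allowed)
  if (length(bad)) {
    stop(sprintf("unknown key(s) in `%s`: %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

flatten_keys <- function(cfg, prefix = "") {
  out <- character(0)
  for (k in names(cfg)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    v <- cfg[[k]]
    if (is.list(v) && !is.null(names(v))) {
      out <- c(out, flatten_keys(v, full))
    } else {
      out <- c(out, full)
    }
  }
  out
}
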