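# State layout shared by the R and compiled right-hand sides. Amounts in mg.
# depot: unabsorbed bioavailable dose in the gut lumen; elim_*: cumulative
# eliminated-mass bins kept so total mass is conserved and testable.
state_names <- function() {
  c("depot", "arterial", "venous", "lung", "adipose", "bone", "brain",
    "kidney", "spleen", "gut", "liver", "muscle", "skin", "rest",
    "epicardium", "midmyocardium", "endocardium", "pericardial_fluid",
    "elim_hepatic", "elim_renal", "elim_cardiac")
}

# Number of hepatic enzyme slots in the packed parameter vector (the compiled
# RHS reads fixed offsets; unused slots carry Vmax 0 / Km 1).
MAX_ENZ <- 12L

#' Pack a model into the flat ODE parameter vector
#'
#' Produces the named numeric vector consumed by both the R and the compiled
#' right-hand side. Drug transport follows the plasma-carriage convention:
#' the circulating vehicle is plasma, so every physiological blood flow
#' enters the equations as its plasma fraction `(1 - hct) * Q_blood`, the
#' venous and arterial pools are the plasma portions of the venous and
#' arterial blood volumes, and tissue partitioning is plasma-referenced
#' (emergent concentration `C_T / Kp_T`). The fitted pericardial parameters
#' `q_pf` and `p` are constants of this convention and are not rescaled; the
#' mural heart flow is `q_mural = (1 - hct) * q_heart - q_pf`.
#'
#' @param model a `pbpk_model`.
#' @param infusion_mg_h optional constant infusion rate into venous blood
#'   \[mg/h\] (used for steady-state checks; 0 for oral dosing).
#' @return named numeric vector.
#' @export
pack_parms <- function(model, infusion_mg_h = 0) {
  validate_model(model)
  phys <- model$physiology
  V <- phys$volumes
  fp <- 1 - phys$hematocrit          # plasma fraction of blood (flow & volume)
  Q <- phys$flows * fp               # plasma flows [L/h]
  layers <- heart_layer_volumes(V[["heart"]], model$heart$layer_fractions)
  q_mural <- heart_flow_split(Q[["heart"]], model$heart$q_pf)
  cl <- clearance_set(model)
  kp <- model$drug$kp

  n_enz <- length(cl$hepatic_vmax)
  if (n_enz > MAX_ENZ) stop("at most ", MAX_ENZ, " hepatic enzymes supported",
                            call. = FALSE)
  vmax <- rep(0, MAX_ENZ); km <- rep(1, MAX_ENZ)
  vmax[seq_len(n_enz)] <- cl$hepatic_vmax
  km[seq_len(n_enz)] <- cl$hepatic_km

  p <- c(
    v_art = V[["arterial"]] * fp, v_ven = V[["venous"]] * fp,
    v_lu = V[["lung"]],
    v_ad = V[["adipose"]], v_bo = V[["bone"]], v_br = V[["brain"]],
    v_ki = V[["kidney"]], v_sp = V[["spleen"]], v_gu = V[["gut"]],
    v_li = V[["liver"]], v_mu = V[["muscle"]], v_sk = V[["skin"]],
    v_re = V[["rest"]],
    v_epi = layers[["epicardium"]], v_mid = layers[["midmyocardium"]],
    v_endo = layers[["endocardium"]], v_pf = model$heart$v_pf,
    q_co = Q[["cardiac_output"]], q_ad = Q[["adipose"]], q_bo = Q[["bone"]],
    q_br = Q[["brain"]], q_ki = Q[["kidney"]], q_sp = Q[["spleen"]],
    q_gu = Q[["gut"]], q_ha = Q[["hepatic_artery"]],
    q_li = Q[["liver_venous"]], q_mu = Q[["muscle"]], q_sk = Q[["skin"]],
    q_re = Q[["rest"]], q_mural = q_mural, q_pf = model$heart$q_pf,
    kp_lu = kp[["lung"]], kp_ad = kp[["adipose"]], kp_bo = kp[["bone"]],
    kp_br = kp[["brain"]], kp_ki = kp[["kidney"]], kp_sp = kp[["spleen"]],
    kp_gu = kp[["gut"]], kp_li = kp[["liver"]], kp_mu = kp[["muscle"]],
    kp_sk = kp[["skin"]], kp_re = kp[["rest"]],
    kp_epi = model$heart$kp_epi, kp_mid = model$heart$kp_mid,
    kp_endo = model$heart$kp_endo, kp_pf = model$heart$kp_pf,
    fu_pf = model$drug$fu_pf, fu_h = model$drug$fu_h,
    k_a = model$drug$k_a, p_diff = model$heart$p,
    cl_renal = model$drug$cl_renal, cl_card = cl$clm_ht,
    infusion = infusion_mg_h, n_enz = n_enz
  )
  names(vmax) <- paste0("vmax_", seq_len(MAX_ENZ))
  names(km) <- paste0("km_", seq_len(MAX_ENZ))
  c(p, vmax, km)
}

#' Initial state for an oral dose
#'
#' The absorption depot holds the bioavailable dose `F_abs * dose` at t = 0;
#' every tissue compartment and elimination bin starts at zero.
#'
#' @param model a `pbpk_model`.
#' @param dose_mg oral dose \[mg\].
#' @return named state vector \[mg\].
#' @export
initial_state <- function(model, dose_mg = model$dose$amount_mg) {
  if (dose_mg < 0) stop("`dose_mg` must be nonnegative", call. = FALSE)
  y <- stats::setNames(numeric(length(state_names())), state_names())
  y[["depot"]] <- model$drug$f_abs * dose_mg
  y
}

#' Net passive flux between epicardium and pericardial fluid
#'
#' The permeability-limited exchange grouped into the single clearance P:
#' `J = P * (C_epi - fu_pf * C_pf)` \[mg/h\], positive into the pericardial
#' fluid. Outward transfer is driven by the total epicardial tissue
#' concentration, the return path by the unbound pericardial concentration;
#' the flux is antisymmetric between the two compartments.
#'
#' @param c_epi epicardial tissue concentration \[mg/L\].
#' @param c_pf pericardial fluid concentration \[mg/L\].
#' @param p diffusion clearance \[L/h\].
#' @param fu_pf unbound fraction in pericardial fluid.
#' @return net flux \[mg/h\].
#' @export
pericardial_flux <- function(c_epi, c_pf, p, fu_pf) {
  if (any(p < 0)) stop("`p` must be nonnegative", call. = FALSE)
  p * (c_epi - fu_pf * c_pf)
}

#' Right-hand side of the PBPK ODE system (reference R implementation)
#'
#' Perfusion-limited well-stirred equations for the seventeen compartments in
#' the plasma-carriage convention (see [pack_parms()]): the lung sits in
#' series between the venous and arterial plasma pools at the full cardiac
#' plasma flow; the depot empties first-order into the gut tissue (portal
#' absorption); the liver is fed by the hepatic artery plus the gut and
#' spleen outflows, with Michaelis-Menten elimination driven by the unbound
#' liver concentration `fu_h * C_li`; renal elimination is
#' `CL_renal * C_ki / Kp_ki` (plasma-equivalent kidney concentration); the
#' heart wall is perfused serially (epicardium -> midmyocardium ->
#' endocardium) at the mural flow, each layer eliminating one third of the
#' total cardiac metabolic clearance on its plasma-equivalent concentration;
#' the pericardial fluid is perfused directly from arterial plasma at `q_pf`
#' and exchanges passively with the epicardium via [pericardial_flux()].
#'
#' Interface follows `deSolve`: returns `list(dy)`.
#'
#' @param t time \[h\] (unused; the system is autonomous).
#' @param state named amounts vector \[mg\], see `initial_state()`.
#' @param parms packed parameter vector from [pack_parms()].
#' @return list with the derivative vector \[mg/h\].
#' @export
pbpk_rhs <- function(t, state, parms) {
  if (any(!is.finite(state))) {
    stop(sprintf("non-finite state at t = %.6g h", t), call. = FALSE)
  }
  p <- parms
  # circulating plasma concentrations [mg/L]
  c_art <- state[["arterial"]] / p[["v_art"]]
  c_ven <- state[["venous"]] / p[["v_ven"]]
  # equilibrium plasma concentration emerging from each tissue
  cv <- function(amount, v, kp) amount / v / kp
  cv_lu <- cv(state[["lung"]], p[["v_lu"]], p[["kp_lu"]])
  cv_ad <- cv(state[["adipose"]], p[["v_ad"]], p[["kp_ad"]])
  cv_bo <- cv(state[["bone"]], p[["v_bo"]], p[["kp_bo"]])
  cv_br <- cv(state[["brain"]], p[["v_br"]], p[["kp_br"]])
  cv_ki <- cv(state[["kidney"]], p[["v_ki"]], p[["kp_ki"]])
  cv_sp <- cv(state[["spleen"]], p[["v_sp"]], p[["kp_sp"]])
  cv_gu <- cv(state[["gut"]], p[["v_gu"]], p[["kp_gu"]])
  cv_li <- cv(state[["liver"]], p[["v_li"]], p[["kp_li"]])
  cv_mu <- cv(state[["muscle"]], p[["v_mu"]], p[["kp_mu"]])
  cv_sk <- cv(state[["skin"]], p[["v_sk"]], p[["kp_sk"]])
  cv_re <- cv(state[["rest"]], p[["v_re"]], p[["kp_re"]])
  cv_epi <- cv(state[["epicardium"]], p[["v_epi"]], p[["kp_epi"]])
  cv_mid <- cv(state[["midmyocardium"]], p[["v_mid"]], p[["kp_mid"]])
  cv_endo <- cv(state[["endocardium"]], p[["v_endo"]], p[["kp_endo"]])
  cv_pf <- cv(state[["pericardial_fluid"]], p[["v_pf"]], p[["kp_pf"]])

  absorbed <- p[["k_a"]] * state[["depot"]]

  # hepatic Michaelis-Menten elimination on the unbound liver concentration
  c_li <- state[["liver"]] / p[["v_li"]]
  cu_li <- p[["fu_h"]] * c_li
  n_enz <- as.integer(p[["n_enz"]])
  r_hep <- 0
  for (i in seq_len(n_enz)) {
    r_hep <- r_hep +
      p[[paste0("vmax_", i)]] * cu_li / (p[[paste0("km_", i)]] + cu_li)
  }
  r_ren <- p[["cl_renal"]] * state[["kidney"]] / p[["v_ki"]] / p[["kp_ki"]]

  # cardiac elimination: one third of CLm_HT per mural layer
  cl3 <- p[["cl_card"]] / 3
  e_epi <- cl3 * cv_epi
  e_mid <- cl3 * cv_mid
  e_endo <- cl3 * cv_endo
  j_pf <- pericardial_flux(state[["epicardium"]] / p[["v_epi"]],
                           state[["pericardial_fluid"]] / p[["v_pf"]],
                           p[["p_diff"]], p[["fu_pf"]])

  q_out_art <- p[["q_ad"]] + p[["q_bo"]] + p[["q_br"]] + p[["q_ki"]] +
    p[["q_sp"]] + p[["q_gu"]] + p[["q_ha"]] + p[["q_mu"]] + p[["q_sk"]] +
    p[["q_re"]] + p[["q_mural"]] + p[["q_pf"]]

  dy <- c(
    depot = -absorbed,
    arterial = p[["q_co"]] * cv_lu - q_out_art * c_art,
    venous = p[["q_ad"]] * cv_ad + p[["q_bo"]] * cv_bo + p[["q_br"]] * cv_br +
      p[["q_ki"]] * cv_ki + p[["q_li"]] * cv_li + p[["q_mu"]] * cv_mu +
      p[["q_sk"]] * cv_sk + p[["q_re"]] * cv_re + p[["q_mural"]] * cv_endo +
      p[["q_pf"]] * cv_pf - p[["q_co"]] * c_ven + p[["infusion"]],
    lung = p[["q_co"]] * (c_ven - cv_lu),
    adipose = p[["q_ad"]] * (c_art - cv_ad),
    bone = p[["q_bo"]] * (c_art - cv_bo),
    brain = p[["q_br"]] * (c_art - cv_br),
    kidney = p[["q_ki"]] * (c_art - cv_ki) - r_ren,
    spleen = p[["q_sp"]] * (c_art - cv_sp),
    gut = p[["q_gu"]] * (c_art - cv_gu) + absorbed,
    liver = p[["q_ha"]] * c_art + p[["q_sp"]] * cv_sp + p[["q_gu"]] * cv_gu -
      p[["q_li"]] * cv_li - r_hep,
    muscle = p[["q_mu"]] * (c_art - cv_mu),
    skin = p[["q_sk"]] * (c_art - cv_sk),
    rest = p[["q_re"]] * (c_art - cv_re),
    epicardium = p[["q_mural"]] * (c_art - cv_epi) - j_pf - e_epi,
    midmyocardium = p[["q_mural"]] * (cv_epi - cv_mid) - e_mid,
    endocardium = p[["q_mural"]] * (cv_mid - cv_endo) - e_endo,
    pericardial_fluid = p[["q_pf"]] * (c_art - cv_pf) + j_pf,
    elim_hepatic = r_hep,
    elim_renal = r_ren,
    elim_cardiac = e_epi + e_mid + e_endo
  )
  list(dy)
}

#' Per-compartment concentrations from amounts
#'
#' Divides compartment amounts by their volumes and derives the reported
#' series. The circulating pools are plasma, so `venous_plasma` and
#' `arterial` plasma concentrations are amount/volume directly; the
#' blood-referenced `venous` and `arterial` columns multiply the plasma
#' concentration by BP (equivalently, plasma = blood / BP). `total_heart` is
#' the layer-volume-weighted mean of the three mural layers (the pericardial
#' fluid is excluded from "total heart").
#'
#' @param amounts matrix (rows = times) or vector of amounts \[mg\] named by
#'   compartment, as produced by the integrator.
#' @param model the `pbpk_model` the amounts come from.
#' @return matrix (or named vector) of concentrations \[mg/L\]: blood
#'   concentrations for `venous`/`arterial`, tissue concentrations elsewhere,
#'   plus `venous_plasma` and `total_heart`.
#' @export
compartment_concentrations <- function(amounts, model) {
  vec_in <- is.null(dim(amounts))
  if (vec_in) amounts <- matrix(amounts, nrow = 1,
                                dimnames = list(NULL, names(amounts)))
  p <- pack_parms(model)
  vols <- c(arterial = p[["v_art"]], venous = p[["v_ven"]], lung = p[["v_lu"]],
            adipose = p[["v_ad"]], bone = p[["v_bo"]], brain = p[["v_br"]],
            kidney = p[["v_ki"]], spleen = p[["v_sp"]], gut = p[["v_gu"]],
            liver = p[["v_li"]], muscle = p[["v_mu"]], skin = p[["v_sk"]],
            rest = p[["v_re"]], epicardium = p[["v_epi"]],
            midmyocardium = p[["v_mid"]], endocardium = p[["v_endo"]],
            pericardial_fluid = p[["v_pf"]])
  if (any(vols <= 0)) stop("all compartment volumes must be positive", call. = FALSE)
  conc <- sweep(amounts[, names(vols), drop = FALSE], 2, vols, "/")
  bp <- model$drug$bp
  v_he <- p[["v_epi"]] + p[["v_mid"]] + p[["v_endo"]]
  total_heart <- (amounts[, "epicardium"] + amounts[, "midmyocardium"] +
                    amounts[, "endocardium"]) / v_he
  out <- cbind(conc,
               venous_plasma = conc[, "venous"],
               total_heart = total_heart)
  out[, "venous"] <- out[, "venous"] * bp      # blood-referenced
  out[, "arterial"] <- out[, "arterial"] * bp
  if (vec_in) out[1, ] else out
}
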