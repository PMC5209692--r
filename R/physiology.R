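#' Reference-human whole-body physiology
#'
#' Builds the body-weight-scaled physiological parameter set used by the
#' whole-body PBPK model: absolute tissue volumes \[L\], absolute tissue blood
#' flows \[L/h\], cardiac output and the liver microsomal-protein scalar
#' (MPPGL). Volumes scale linearly with body weight; flows are fixed fractions
#' of cardiac output. The hepatic arterial flow is computed by difference so
#' that the liver venous outflow equals the sum of hepatic artery, gut and
#' spleen inflows.
#'
#' @param body_weight body weight \[kg\]; the reference human is 70 kg.
#' @param fractional_volumes named vector of tissue volumes \[L/kg body
#'   weight\]. Names: adipose, bone, brain, gut, heart, kidney, liver, lung,
#'   muscle, skin, spleen, venous, arterial, rest.
#' @param fractional_flows named vector of tissue blood flows as fractions of
#'   cardiac output. `liver_venous` is the flow leaving the liver (hepatic
#'   vein); the hepatic artery receives `liver_venous - gut - spleen`.
#' @param cardiac_output_ml_s cardiac output \[mL/s\]; converted once to L/h.
#' @param mppgl mg microsomal protein per g liver \[mg/g\].
#' @param fractional_plasma,fractional_erythrocytes plasma and erythrocyte
#'   volumes \[L/kg\]; their sum is the blood volume (venous + arterial), and
#'   the implied hematocrit sets the plasma fraction of every blood flow used
#'   by the transport equations.
#'
#' @return An object of class `pbpk_physiology`: a list with `body_weight`,
#'   `volumes` \[L\], `flows` \[L/h\] (blood flows, including `hepatic_artery`
#'   and `cardiac_output`), `hematocrit`, `mppgl`, and the input fractions.
#' @examples
#' phys <- build_reference_human(70)
#' phys$volumes[["heart"]]        # 0.329 L
#' phys$flows[["cardiac_output"]] # 389.988 L/h
#' @export
build_reference_human <- function(body_weight = 70,
                                  fractional_volumes = default_fractional_volumes(),
                                  fractional_flows = default_fractional_flows(),
                                  cardiac_output_ml_s = 108.33,
                                  mppgl = 45,
                                  fractional_plasma = 0.0424,
                                  fractional_erythrocytes = 0.0347) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0) {
    stop("`body_weight` must be a single positive number [kg]", call. = FALSE)
  }
  vol_names <- names(default_fractional_volumes())
  flow_names <- names(default_fractional_flows())
  missing_v <- setdiff(vol_names, names(fractional_volumes))
  missing_f <- setdiff(flow_names, names(fractional_flows))
  if (length(missing_v)) {
    stop("missing fractional volumes: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing_f)) {
    stop("missing fractional flows: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  fractional_volumes <- fractional_volumes[vol_names]
  fractional_flows <- fractional_flows[flow_names]
  if (any(!is.finite(fractional_volumes)) || any(fractional_volumes <= 0)) {
    stop("all fractional volumes must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(fractional_flows)) || any(fractional_flows <= 0)) {
    stop("all fractional flows must be strictly positive", call. = FALSE)
  }
  if (cardiac_output_ml_s <= 0) stop("cardiac output must be positive", call. = FALSE)
  if (mppgl <= 0) stop("`mppgl` must be positive", call. = FALSE)

  # venous-return flow fractions must account for the whole cardiac output
  venous_return <- c("adipose", "bone", "brain", "heart", "kidney",
                     "liver_venous", "muscle", "skin", "rest")
  ret_sum <- sum(fractional_flows[venous_return])
  if (abs(ret_sum - 1) > 1e-6) {
    stop(sprintf("venous-return flow fractions sum to %.8f, expected 1", ret_sum),
         call. = FALSE)
  }
  f_ha <- fractional_flows[["liver_venous"]] - fractional_flows[["gut"]] -
    fractional_flows[["spleen"]]
  if (f_ha < 0) {
    stop("hepatic arterial fraction (liver_venous - gut - spleen) is negative",
         call. = FALSE)
  }

  if (fractional_plasma <= 0 || fractional_erythrocytes < 0) {
    stop("plasma fraction must be positive, erythrocyte fraction nonnegative",
         call. = FALSE)
  }
  co_l_h <- cardiac_output_ml_s * 3600 / 1000
  volumes <- fractional_volumes * body_weight
  flows <- c(fractional_flows * co_l_h,
             hepatic_artery = unname(f_ha) * co_l_h,
             cardiac_output = co_l_h)
  structure(
    list(body_weight = body_weight,
         volumes = volumes,
         flows = flows,
         hematocrit = fractional_erythrocytes /
           (fractional_plasma + fractional_erythrocytes),
         mppgl = mppgl,
         fractional_volumes = fractional_volumes,
         fractional_flows = fractional_flows,
         fractional_plasma = fractional_plasma,
         fractional_erythrocytes = fractional_erythrocytes),
    class = "pbpk_physiology"
  )
}

#' @rdname build_reference_human
#' @export
default_fractional_volumes <- function() {
  c(adipose = 0.213, bone = 0.085629, brain = 0.02, gut = 0.0171,
    heart = 0.0047, kidney = 0.0044, liver = 0.021, lung = 0.0076,
    muscle = 0.4, skin = 0.0371, spleen = 0.0026, venous = 0.0514,
    arterial = 0.0257, rest = 0.109771)
}

#' @rdname build_reference_human
#' @export
default_fractional_flows <- function() {
  c(adipose = 0.05, bone = 0.05, brain = 0.12, gut = 0.146462, heart = 0.04,
    kidney = 0.19, liver_venous = 0.215385, muscle = 0.17, skin = 0.05,
    spleen = 0.017231, rest = 0.114615)
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat("PBPK reference-human physiology\n")
  cat(sprintf("  body weight:     %.1f kg\n", x$body_weight))
  cat(sprintf("  cardiac output:  %.3f L/h\n", x$flows[["cardiac_output"]]))
  cat(sprintf("  MPPGL:           %.1f mg/g liver\n", x$mppgl))
  cat(sprintf("  tissues:         %d volumes, %d flows\n",
              length(x$volumes), length(x$flows)))
  invisible(x)
}

#' Heart anatomy and heart-specific drug disposition parameters
#'
#' Assembles the four-compartment heart sub-model parameterization: the
#' epicardium/midmyocardium/endocardium volume fractions of total heart tissue,
#' the pericardial-fluid volume (a fixed anatomical quantity, additional to the
#' heart tissue volume and invariant to body weight), the pericardial blood
#' flow `q_pf`, the grouped pericardial-epicardial diffusion clearance `p`,
#' layer partition coefficients, and cardiac CYP450 content used for metabolic
#' clearance scaling.
#'
#' `mg_protein_per_heart` is the total cardiac microsomal protein used to scale
#' per-mg intrinsic clearances to the whole organ. Its default (11732 mg) is a
#' calibration chosen so that the amitriptyline reference inputs reproduce a
#' total cardiac intrinsic clearance of 0.316 L/h; it is not a measured value
#' and can be overridden.
#'
#' @param layer_fractions fractions of total heart tissue volume for the
#'   epicardium, midmyocardium and endocardium; must sum to 1.
#' @param v_pf pericardial fluid volume \[L\].
#' @param q_pf blood flow through the pericardial fluid \[L/h\].
#' @param p grouped passive diffusion clearance between epicardium and
#'   pericardial fluid \[L/h\].
#' @param kp_epi,kp_mid,kp_endo,kp_pf tissue:plasma partition coefficients for
#'   the three mural layers and the pericardial fluid.
#' @param cyp_abundance named vector \[pmol/mg microsomal protein\] of cardiac
#'   CYP isoform abundances.
#' @param cl_per_pmol named vector \[uL/min/pmol\] of per-pmol intrinsic
#'   clearances for the same isoforms.
#' @param mg_protein_per_heart cardiac microsomal protein \[mg\] (calibrated
#'   default, see Details).
#' @return list of class `pbpk_heart_anatomy`.
#' @export
heart_anatomy <- function(layer_fractions = c(epicardium = 0.1,
                                              midmyocardium = 0.3,
                                              endocardium = 0.6),
                          v_pf = 0.03,
                          q_pf = 0.01193,
                          p = 0.78230,
                          kp_epi = 3.0, kp_mid = 7.4, kp_endo = 14.0,
                          kp_pf = 2.6,
                          cyp_abundance = c(CYP2C8 = 0.2, CYP2C9 = 5.5,
                                            CYP2J2 = 0.17),
                          cl_per_pmol = c(CYP2C8 = 0.072, CYP2C9 = 0.079,
                                          CYP2J2 = 0.000),
                          mg_protein_per_heart = 11732) {
  ln <- c("epicardium", "midmyocardium", "endocardium")
  if (!all(ln %in% names(layer_fractions))) {
    stop("`layer_fractions` needs names epicardium, midmyocardium, endocardium",
         call. = FALSE)
  }
  layer_fractions <- layer_fractions[ln]
  if (any(layer_fractions <= 0) || any(layer_fractions >= 1)) {
    stop("each heart layer fraction must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    stop("heart layer fractions must sum to 1", call. = FALSE)
  }
  if (v_pf <= 0) stop("pericardial fluid volume must be positive", call. = FALSE)
  if (q_pf < 0) stop("`q_pf` must be nonnegative", call. = FALSE)
  if (p < 0) stop("`p` must be nonnegative", call. = FALSE)
  kps <- c(kp_epi, kp_mid, kp_endo, kp_pf)
  if (any(kps <= 0)) stop("heart Kp values must be positive", call. = FALSE)
  if (!identical(names(cyp_abundance), names(cl_per_pmol))) {
    stop("`cyp_abundance` and `cl_per_pmol` must cover the same isoforms",
         call. = FALSE)
  }
  if (any(cyp_abundance < 0) || any(cl_per_pmol < 0)) {
    stop("cardiac CYP abundances and clearances must be nonnegative",
         call. = FALSE)
  }
  if (mg_protein_per_heart <= 0) {
    stop("`mg_protein_per_heart` must be positive", call. = FALSE)
  }
  structure(
    list(layer_fractions = layer_fractions, v_pf = v_pf, q_pf = q_pf, p = p,
         kp_epi = kp_epi, kp_mid = kp_mid, kp_endo = kp_endo, kp_pf = kp_pf,
         cyp_abundance = cyp_abundance, cl_per_pmol = cl_per_pmol,
         mg_protein_per_heart = mg_protein_per_heart),
    class = "pbpk_heart_anatomy"
  )
}

#' Heart-layer partition coefficients from a fixed ratio
#'
#' Constructs the epicardium:midmyocardium:endocardium Kp triple from a base
#' epicardial Kp and the transmural ratio (default 1:2.5:5, after postmortem
#' transmural distribution data).
#'
#' @param kp_epi epicardial tissue:plasma partition coefficient.
#' @param ratio length-3 ratio epicardium:midmyocardium:endocardium.
#' @return named vector of the three layer Kps.
#' @export
kp_layers_from_ratio <- function(kp_epi, ratio = c(1, 2.5, 5)) {
  if (kp_epi <= 0) stop("`kp_epi` must be positive", call. = FALSE)
  if (length(ratio) != 3L || any(ratio <= 0)) {
    stop("`ratio` must be three positive numbers", call. = FALSE)
  }
  stats::setNames(kp_epi * ratio / ratio[1],
                  c("kp_epi", "kp_mid", "kp_endo"))
}

#' Absolute heart-layer volumes
#'
#' Splits total heart tissue volume into epicardial, midmyocardial and
#' endocardial compartment volumes. The pericardial fluid volume is a separate
#' fixed anatomical constant and is not derived from the heart tissue volume.
#'
#' @param v_he total heart tissue volume \[L\].
#' @param layer_fractions layer fractions summing to 1 (see [heart_anatomy()]).
#' @return named vector (epicardium, midmyocardium, endocardium) \[L\].
#' @examples
#' heart_layer_volumes(0.329) # 0.0329 0.0987 0.1974
#' @export
heart_layer_volumes <- function(v_he,
                                layer_fractions = c(epicardium = 0.1,
                                                    midmyocardium = 0.3,
                                                    endocardium = 0.6)) {
  if (!is.numeric(v_he) || length(v_he) != 1L || v_he <= 0) {
    stop("`v_he` must be a single positive volume [L]", call. = FALSE)
  }
  if (abs(sum(layer_fractions) - 1) > 1e-9) {
    stop("heart layer fractions must sum to 1", call. = FALSE)
  }
  stats::setNames(v_he * as.numeric(layer_fractions),
                  c("epicardium", "midmyocardium", "endocardium"))
}

#' Serial mural flow after pericardial subtraction
#'
#' The pericardial flow is taken out of the total heart blood flow so the sum
#' of all tissue flows still equals cardiac output; the remainder perfuses the
#' mural layers in series (epicardium -> midmyocardium -> endocardium).
#'
#' @param q_he total heart blood flow \[L/h\].
#' @param q_pf pericardial fluid blood flow \[L/h\]; must be below `q_he`.
#' @return mural (serial) blood flow \[L/h\].
#' @export
heart_flow_split <- function(q_he, q_pf) {
  if (q_he <= 0) stop("`q_he` must be positive", call. = FALSE)
  if (q_pf < 0 || q_pf >= q_he) {
    stop("`q_pf` must satisfy 0 <= q_pf < q_he", call. = FALSE)
  }
  q_he - q_pf
}
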