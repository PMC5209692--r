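#' Scale in vitro enzyme velocity to a whole-liver Vmax
#'
#' In vitro-in vivo extrapolation of a recombinant-enzyme maximal velocity
#' \[pmol/min/pmol CYP\] to a whole-organ maximal metabolic rate \[mg/h\]:
#'
#' `Vmax = Vmax_pmol * abundance * MPPGL * liver_mass_g * ISEF * 60 * MW * 1e-9`
#'
#' where abundance is the hepatic CYP content \[pmol/mg microsomal protein\],
#' MPPGL the microsomal protein per gram of liver \[mg/g\], ISEF the
#' inter-system extrapolation factor, and MW the compound molecular weight
#' \[g/mol\]. Liver mass is taken as volume at density 1 g/mL, so
#' `liver_mass_g = 1000 * v_li`.
#'
#' @param vmax_pmol maximal velocity \[pmol/min/pmol CYP\].
#' @param liver_abundance hepatic isoform abundance \[pmol/mg\].
#' @param mppgl mg microsomal protein per g liver.
#' @param v_li liver volume \[L\].
#' @param isef inter-system extrapolation factor.
#' @param mw molecular weight \[g/mol\].
#' @return whole-liver Vmax \[mg/h\].
#' @examples
#' scale_hepatic_vmax(3.37, 137, 45, 1.47, 3.92, 277.4) # ~1992.5 mg/h
#' @export
scale_hepatic_vmax <- function(vmax_pmol, liver_abundance, mppgl, v_li, isef, mw) {
  if (vmax_pmol < 0) stop("`vmax_pmol` must be nonnegative", call. = FALSE)
  if (any(c(liver_abundance, mppgl, v_li, isef, mw) <= 0)) {
    stop("abundance, MPPGL, liver volume, ISEF and MW must be positive",
         call. = FALSE)
  }
  vmax_pmol * liver_abundance * mppgl * (v_li * 1000) * isef * 60 * mw * 1e-9
}

#' Michaelis constant in mass-concentration units
#'
#' Converts a Km reported in uM to the mg/L scale used by the ODE system.
#'
#' @param km_um Michaelis constant \[uM\].
#' @param mw molecular weight \[g/mol\].
#' @return Km \[mg/L\].
#' @export
km_to_mass_units <- function(km_um, mw) {
  if (any(km_um <= 0)) stop("`km_um` must be positive", call. = FALSE)
  if (mw <= 0) stop("`mw` must be positive", call. = FALSE)
  km_um * mw / 1000
}

#' Per-isoform cardiac unbound intrinsic clearance
#'
#' Scales a per-pmol intrinsic clearance to the whole heart:
#' the per-mg clearance is `cl_per_pmol * abundance` \[uL/min/mg\], the
#' per-heart clearance is that times the total cardiac microsomal protein,
#' converted to L/h (`* 60 * 1e-6`), and the unbound intrinsic clearance
#' applies the ISEF correction and divides by the microsomal unbound fraction.
#'
#' @param cl_per_pmol intrinsic clearance per pmol CYP \[uL/min/pmol\].
#' @param abundance cardiac isoform abundance \[pmol/mg microsomal protein\].
#' @param mg_protein_per_heart total cardiac microsomal protein \[mg\]
#'   (calibrated default in [heart_anatomy()]).
#' @param isef inter-system extrapolation factor.
#' @param fu_mic unbound fraction in the microsomal incubation.
#' @return unbound intrinsic clearance for the isoform \[L/h\].
#' @examples
#' cardiac_intrinsic_clearance(0.079, 5.5, 11732) # CYP2C9 contribution
#' @export
cardiac_intrinsic_clearance <- function(cl_per_pmol, abundance,
                                        mg_protein_per_heart,
                                        isef = 1, fu_mic = 1) {
  if (any(c(cl_per_pmol, abundance, mg_protein_per_heart) < 0)) {
    stop("clearance inputs must be nonnegative", call. = FALSE)
  }
  if (fu_mic <= 0) stop("`fu_mic` must be positive", call. = FALSE)
  if (isef < 0) stop("`isef` must be nonnegative", call. = FALSE)
  cl_per_mg <- cl_per_pmol * abundance          # uL/min/mg
  cl_heart <- cl_per_mg * mg_protein_per_heart * 60 * 1e-6  # L/h
  cl_heart * isef / fu_mic
}

#' Total cardiac metabolic clearance
#'
#' Sums per-isoform unbound intrinsic clearances into the total cardiac
#' unbound intrinsic clearance and applies the well-stirred flow correction to
#' obtain the total heart metabolic clearance:
#'
#' `CLm_HT = Q_he * (fu_p/BP) * CLu_int / (Q_he + (fu_p/BP) * CLu_int)`
#'
#' `CLm_HT` is bounded above by the heart blood flow for any finite intrinsic
#' clearance (flow-limited asymptote).
#'
#' @param clu_int_isoforms vector of per-isoform unbound intrinsic clearances
#'   \[L/h\]; an empty vector yields zero clearances.
#' @param q_he total heart blood flow \[L/h\].
#' @param fu_p unbound fraction in plasma.
#' @param bp blood:plasma concentration ratio.
#' @return list with `clu_int` and `clm_ht` \[L/h\].
#' @examples
#' clu <- cardiac_intrinsic_clearance(c(0.072, 0.079, 0), c(0.2, 5.5, 0.17), 11732)
#' total_cardiac_clearance(clu, q_he = 15.59952, fu_p = 0.05, bp = 1.04)
#' @export
total_cardiac_clearance <- function(clu_int_isoforms, q_he, fu_p, bp) {
  if (q_he <= 0) stop("`q_he` must be positive", call. = FALSE)
  if (fu_p <= 0 || fu_p > 1) stop("`fu_p` must lie in (0, 1]", call. = FALSE)
  if (bp <= 0) stop("`bp` must be positive", call. = FALSE)
  if (length(clu_int_isoforms) && any(clu_int_isoforms < 0)) {
    stop("isoform clearances must be nonnegative", call. = FALSE)
  }
  clu_int <- sum(clu_int_isoforms)
  x <- fu_p * clu_int / bp
  clm_ht <- q_he * x / (q_he + x)
  list(clu_int = clu_int, clm_ht = clm_ht)
}

#' Whole-organ clearance set for a model
#'
#' Computes every scaled clearance the ODE system needs from a model
#' parameterization: per-isoform hepatic Vmax \[mg/h\] and Km \[mg/L\], the
#' cardiac unbound intrinsic clearance and well-stirred total cardiac
#' metabolic clearance \[L/h\], and the fixed renal clearance.
#'
#' @param model a `pbpk_model`, see [default_model()].
#' @return list of class `pbpk_clearance_set` with elements `hepatic_vmax`,
#'   `hepatic_km` (named by isoform), `clu_int_isoforms`, `clu_int_heart`,
#'   `clm_ht`, `cl_renal`, `fu_mic`, `fu_h`.
#' @export
clearance_set <- function(model) {
  stopifnot(inherits(model, "pbpk_model"))
  enz <- model$drug$enzymes
  missing_ab <- enz$isoform[is.na(enz$liver_abundance)]
  if (length(missing_ab)) {
    stop("missing liver abundance for isoform(s): ",
         paste(missing_ab, collapse = ", "), call. = FALSE)
  }
  v_li <- model$physiology$volumes[["liver"]]
  vmax <- vapply(seq_len(nrow(enz)), function(i) {
    scale_hepatic_vmax(enz$vmax_pmol[i], enz$liver_abundance[i],
                       model$physiology$mppgl, v_li, enz$isef[i],
                       model$drug$mw)
  }, numeric(1))
  km <- km_to_mass_units(enz$km_um, model$drug$mw)
  names(vmax) <- names(km) <- enz$isoform

  ha <- model$heart
  clu_iso <- cardiac_intrinsic_clearance(ha$cl_per_pmol, ha$cyp_abundance,
                                         ha$mg_protein_per_heart,
                                         isef = model$drug$isef_heart,
                                         fu_mic = model$drug$fu_mic)
  q_he <- model$physiology$flows[["heart"]]
  tot <- total_cardiac_clearance(clu_iso, q_he, model$drug$fu_p, model$drug$bp)

  structure(
    list(hepatic_vmax = vmax, hepatic_km = km,
         clu_int_isoforms = clu_iso,
         clu_int_heart = tot$clu_int, clm_ht = tot$clm_ht,
         cl_renal = model$drug$cl_renal,
         fu_mic = model$drug$fu_mic, fu_h = model$drug$fu_h),
    class = "pbpk_clearance_set"
  )
}

#' @export
print.pbpk_clearance_set <- function(x, ...) {
  cat("PBPK clearance set\n")
  cat("  hepatic Vmax [mg/h]:\n")
  for (i in seq_along(x$hepatic_vmax)) {
    cat(sprintf("    %-7s Vmax %9.2f  Km %7.3f mg/L\n",
                names(x$hepatic_vmax)[i], x$hepatic_vmax[i], x$hepatic_km[i]))
  }
  cat(sprintf("  cardiac CLu_int: %.4f L/h (well-stirred CLm_HT: %.6f L/h)\n",
              x$clu_int_heart, x$clm_ht))
  cat(sprintf("  renal clearance: %.3f L/h\n", x$cl_renal))
  invisible(x)
}
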