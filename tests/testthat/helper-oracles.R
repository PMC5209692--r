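# Independent numerical oracles used by the tests. These deliberately avoid
# the package's own integration path.

# fixed-step classical Runge-Kutta trajectory for a deSolve-style rhs
rk4_trajectory <- function(rhs, y0, parms, t_end, dt) {
  n_steps <- round(t_end / dt)
  out <- matrix(NA_real_, n_steps + 1, length(y0),
                dimnames = list(NULL, names(y0)))
  out[1, ] <- y0
  y <- y0
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- unlist(rhs(t, y, parms)[[1]])
    k2 <- unlist(rhs(t + dt / 2, y + dt / 2 * k1, parms)[[1]])
    k3 <- unlist(rhs(t + dt / 2, y + dt / 2 * k2, parms)[[1]])
    k4 <- unlist(rhs(t + dt, y + dt * k3, parms)[[1]])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    out[i + 1, ] <- y
  }
  list(time = seq(0, by = dt, length.out = n_steps + 1), y = out)
}

# Hand-coded sixteen-compartment system (no pericardial fluid), written
# independently of pbpk_rhs() as the reduction oracle for q_pf = p = 0.
# Same plasma-carriage conventions; indexes by explicit compartment name.
rhs_sixteen <- function(t, y, pp) {
  cav <- function(nm) y[[nm]] / pp$V[[nm]]
  cout <- function(nm) y[[nm]] / pp$V[[nm]] / pp$Kp[[nm]]
  art <- cav("arterial"); ven <- cav("venous")
  absorbed <- pp$k_a * y[["depot"]]
  cu <- pp$fu_h * cav("liver")
  hep <- sum(pp$vmax * cu / (pp$km + cu))
  ren <- pp$cl_renal * cav("kidney") / pp$Kp[["kidney"]]
  cl3 <- pp$cl_card / 3
  d <- c(
    depot = -absorbed,
    arterial = pp$Q[["co"]] * cout("lung") - pp$Q[["co"]] * art,
    venous = sum(vapply(c("adipose", "bone", "brain", "kidney", "muscle",
                          "skin", "rest"),
                        function(nm) pp$Q[[nm]] * cout(nm), numeric(1))) +
      pp$Q[["liver"]] * cout("liver") + pp$Q[["heart"]] * cout("endocardium") -
      pp$Q[["co"]] * ven,
    lung = pp$Q[["co"]] * (ven - cout("lung")),
    adipose = pp$Q[["adipose"]] * (art - cout("adipose")),
    bone = pp$Q[["bone"]] * (art - cout("bone")),
    brain = pp$Q[["brain"]] * (art - cout("brain")),
    kidney = pp$Q[["kidney"]] * (art - cout("kidney")) - ren,
    spleen = pp$Q[["spleen"]] * (art - cout("spleen")),
    gut = pp$Q[["gut"]] * (art - cout("gut")) + absorbed,
    liver = pp$Q[["ha"]] * art + pp$Q[["spleen"]] * cout("spleen") +
      pp$Q[["gut"]] * cout("gut") - pp$Q[["liver"]] * cout("liver") - hep,
    muscle = pp$Q[["muscle"]] * (art - cout("muscle")),
    skin = pp$Q[["skin"]] * (art - cout("skin")),
    rest = pp$Q[["rest"]] * (art - cout("rest")),
    epicardium = pp$Q[["heart"]] * (art - cout("epicardium")) -
      cl3 * cout("epicardium"),
    midmyocardium = pp$Q[["heart"]] * (cout("epicardium") -
      cout("midmyocardium")) - cl3 * cout("midmyocardium"),
    endocardium = pp$Q[["heart"]] * (cout("midmyocardium") -
      cout("endocardium")) - cl3 * cout("endocardium")
  )
  list(d)
}

# parameter bundle for rhs_sixteen assembled from a pbpk_model by independent
# arithmetic (plasma fraction applied directly to Table-style inputs)
sixteen_parms <- function(model) {
  ph <- model$physiology
  fp <- 1 - ph$hematocrit
  lay <- model$heart$layer_fractions
  V <- c(arterial = ph$volumes[["arterial"]] * fp,
         venous = ph$volumes[["venous"]] * fp,
         lung = ph$volumes[["lung"]], adipose = ph$volumes[["adipose"]],
         bone = ph$volumes[["bone"]], brain = ph$volumes[["brain"]],
         kidney = ph$volumes[["kidney"]], spleen = ph$volumes[["spleen"]],
         gut = ph$volumes[["gut"]], liver = ph$volumes[["liver"]],
         muscle = ph$volumes[["muscle"]], skin = ph$volumes[["skin"]],
         rest = ph$volumes[["rest"]],
         epicardium = ph$volumes[["heart"]] * lay[["epicardium"]],
         midmyocardium = ph$volumes[["heart"]] * lay[["midmyocardium"]],
         endocardium = ph$volumes[["heart"]] * lay[["endocardium"]])
  Q <- c(co = ph$flows[["cardiac_output"]],
         adipose = ph$flows[["adipose"]], bone = ph$flows[["bone"]],
         brain = ph$flows[["brain"]], kidney = ph$flows[["kidney"]],
         spleen = ph$flows[["spleen"]], gut = ph$flows[["gut"]],
         ha = ph$flows[["hepatic_artery"]], liver = ph$flows[["liver_venous"]],
         muscle = ph$flows[["muscle"]], skin = ph$flows[["skin"]],
         rest = ph$flows[["rest"]], heart = ph$flows[["heart"]]) * fp
  Kp <- c(lung = model$drug$kp[["lung"]], adipose = model$drug$kp[["adipose"]],
          bone = model$drug$kp[["bone"]], brain = model$drug$kp[["brain"]],
          kidney = model$drug$kp[["kidney"]], spleen = model$drug$kp[["spleen"]],
          gut = model$drug$kp[["gut"]], liver = model$drug$kp[["liver"]],
          muscle = model$drug$kp[["muscle"]], skin = model$drug$kp[["skin"]],
          rest = model$drug$kp[["rest"]],
          epicardium = model$heart$kp_epi,
          midmyocardium = model$heart$kp_mid,
          endocardium = model$heart$kp_endo)
  cl <- clearance_set(model)
  list(V = V, Q = Q, Kp = Kp, k_a = model$drug$k_a, fu_h = model$drug$fu_h,
       vmax = unname(cl$hepatic_vmax), km = unname(cl$hepatic_km),
       cl_renal = model$drug$cl_renal, cl_card = cl$clm_ht)
}
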