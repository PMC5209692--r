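test_that("reference human scales volumes and flows from body weight", {
  phys <- build_reference_human(70)
  expect_equal(phys$volumes[["heart"]], 0.329)
  expect_equal(phys$flows[["cardiac_output"]], 389.988)
  expect_equal(phys$flows[["heart"]], 389.988 * 0.04)
  expect_equal(phys$volumes[["liver"]], 1.47)
  # hepatic artery by difference: liver venous - gut - spleen
  expect_equal(phys$flows[["hepatic_artery"]],
               (0.215385 - 0.146462 - 0.017231) * 389.988)
  expect_equal(phys$hematocrit, 0.0347 / (0.0424 + 0.0347))
})

test_that("volumes scale linearly with body weight", {
  p1 <- build_reference_human(50)
  p2 <- build_reference_human(100)
  expect_equal(p2$volumes / p1$volumes, rep(2, length(p1$volumes)),
               ignore_attr = TRUE)
  # flows are weight-independent (fixed cardiac output)
  expect_equal(p1$flows, p2$flows)
})

test_that("venous-return flows sum to cardiac output", {
  phys <- build_reference_human(70)
  back <- sum(phys$flows[c("adipose", "bone", "brain", "heart", "kidney",
                           "liver_venous", "muscle", "skin", "rest")])
  expect_equal(back, phys$flows[["cardiac_output"]], tolerance = 1e-12)
  # and stays exact after splitting the heart flow for any valid q_pf
  for (q_pf in c(0, 0.01193, 1, 5)) {
    mural <- heart_flow_split(phys$flows[["heart"]], q_pf)
    expect_equal(mural + q_pf, phys$flows[["heart"]], tolerance = 1e-12)
  }
})

test_that("invalid physiology inputs are rejected", {
  expect_error(build_reference_human(0), "positive")
  expect_error(build_reference_human(-70), "positive")
  bad_flows <- default_fractional_flows()
  bad_flows[["muscle"]] <- 0.3
  expect_error(build_reference_human(70, fractional_flows = bad_flows),
               "sum to")
  # hepatic arterial fraction must be nonnegative (venous-return sum kept at 1)
  bad <- default_fractional_flows()
  bad[["rest"]] <- bad[["rest"]] + bad[["liver_venous"]] - 0.10
  bad[["liver_venous"]] <- 0.10
  expect_error(build_reference_human(70, fractional_flows = bad), "negative")
})

test_that("heart layer volumes follow the 10/30/60 split", {
  expect_equal(heart_layer_volumes(0.329),
               c(epicardium = 0.0329, midmyocardium = 0.0987,
                 endocardium = 0.1974))
  expect_equal(unname(heart_layer_volumes(1.0)), c(0.1, 0.3, 0.6))
  expect_error(heart_layer_volumes(0.329, c(epicardium = 0.2,
                                            midmyocardium = 0.3,
                                            endocardium = 0.6)),
               "sum to 1")
  expect_error(heart_layer_volumes(0), "positive")
})

test_that("mural flow is the heart flow minus the pericardial flow", {
  expect_equal(heart_flow_split(15.59952, 0.01193), 15.58759)
  expect_equal(heart_flow_split(15.5995, 0), 15.5995)
  expect_error(heart_flow_split(10, 11), "q_pf")
  expect_error(heart_flow_split(10, 10), "q_pf")
})

test_that("layer Kp ratio constructor reproduces the 1:2.5:5 pattern", {
  kp <- kp_layers_from_ratio(3)
  expect_equal(unname(kp), c(3, 7.5, 15))
  expect_equal(unname(kp_layers_from_ratio(2, c(2, 5, 10))), c(2, 5, 10))
  expect_error(kp_layers_from_ratio(0), "positive")
})

test_that("heart anatomy validates its invariants", {
  ha <- heart_anatomy()
  expect_equal(sum(ha$layer_fractions), 1)
  expect_error(heart_anatomy(layer_fractions = c(epicardium = 0.5,
                                                 midmyocardium = 0.5,
                                                 endocardium = 0.5)),
               "sum to 1")
  expect_error(heart_anatomy(kp_epi = -1), "positive")
  # pericardial volume is an anatomical constant, not scaled by body weight
  expect_equal(heart_anatomy()$v_pf,
               heart_anatomy()$v_pf * 1)
  m50 <- default_model(body_weight = 50)
  m90 <- default_model(body_weight = 90)
  expect_equal(m50$heart$v_pf, m90$heart$v_pf)
})
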