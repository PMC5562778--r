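test_that("the toy clearance model has the closed-form coefficient", {
  # one-compartment linear clearance: AUC = D/CL, d log AUC / d log CL = -1
  auc <- function(p) p$dose / p$cl
  pars <- list(dose = 1, cl = 2)
  # forward difference at +5% is -1/(1+delta); central kills the O(delta) term
  expect_equal(finite_sc(auc, pars, "cl", delta = 0.05), -1 / 1.05,
               tolerance = 1e-12)
  expect_equal(finite_sc(auc, pars, "cl", delta = 0.05, side = "central"),
               -1, tolerance = 0.01)
  expect_equal(finite_sc(auc, pars, "dose"), 1, tolerance = 1e-9)
})

test_that("the normalized coefficient is invariant to parameter units", {
  in_uM <- function(p) p$vmax * 500 / (p$km_uM + 500)
  in_mM <- function(p) p$vmax * 500 / (p$km_mM * 1000 + 500)
  sc_uM <- finite_sc(in_uM, list(vmax = 1, km_uM = 49), "km_uM")
  sc_mM <- finite_sc(in_mM, list(vmax = 1, km_mM = 0.049), "km_mM")
  expect_equal(sc_uM, sc_mM, tolerance = 1e-12)
})

test_that("finite_sc rejects undefined configurations", {
  expect_error(finite_sc(function(p) p$a, list(a = 0), "a"), "non-zero")
  expect_error(finite_sc(function(p) 0, list(a = 1), "a"), "zero or non-finite")
  expect_error(finite_sc(function(p) p$a, list(a = 1), "b"), "non-zero")
})

test_that("downstream parameters cannot influence upstream formation", {
  m <- pbk_model("chinese")
  sc <- sensitivity_coefficient(m, "km.HES", "HE", 0.01)
  expect_lt(abs(sc), 1e-6)
})

test_that("1'-hydroxylation kinetics dominate 1'-hydroxyestragole formation", {
  m <- pbk_model("chinese")
  sc <- sensitivity_coefficient(m, "vmax.HE", "HE", 0.01)
  expect_gt(sc, 0.1)
})

test_that("competing pathway Vmax values pull the shared product oppositely", {
  m <- pbk_model("chinese")
  expect_gt(sensitivity_coefficient(m, "vmax.HES", "HES", 0.01), 0)
  expect_lt(sensitivity_coefficient(m, "vmax.OE", "HES", 0.01), 0)
  expect_lt(sensitivity_coefficient(m, "vmax.HEG", "HES", 0.01), 0)
})

test_that("coefficients are robust to the perturbation size", {
  m <- pbk_model("chinese")
  for (par in c("vmax.HE", "km.HE", "vmax.OE", "body_weight")) {
    # the underlying derivative is stable: central differences at 5% and
    # 1% agree closely ...
    sc5c <- sensitivity_coefficient(m, par, "HES", 0.01, delta = 0.05,
                                    side = "central")
    sc1c <- sensitivity_coefficient(m, par, "HES", 0.01, delta = 0.01,
                                    side = "central")
    expect_lt(abs(sc5c - sc1c), 0.02)
    # ... while the default one-sided +5% perturbation carries an O(delta)
    # bias of up to ~0.04 on the most curved kinetic parameters
    sc5f <- sensitivity_coefficient(m, par, "HES", 0.01, delta = 0.05)
    expect_lt(abs(sc5f - sc5c), 0.06)
  }
})

test_that("the sweep filters at the reporting threshold", {
  m <- pbk_model("chinese")
  pars <- c("vmax.HE", "km.HE", "vmax.OE", "km.OE", "vmax.HES", "km.HES",
            "vmax.HEG", "partition.estragole.fat")
  rep <- sensitivity_sweep(m, doses = 0.01, outputs = c("HE", "HES"),
                           parameters = pars)
  expect_equal(nrow(rep$all), length(pars) * 2)
  expect_true(all(abs(rep$influential$sc) >= 0.1))
  # sulfation, 1'-hydroxylation and the competing oxidation all matter for
  # the ultimate carcinogen at the dietary dose
  inf_hes <- rep$influential$parameter[rep$influential$output == "HES"]
  expect_true(all(c("vmax.HES", "vmax.HE", "vmax.OE") %in% inf_hes))
  # an unreachable threshold empties the filtered table
  rep_inf <- sensitivity_sweep(m, doses = 0.01, outputs = "HE",
                               parameters = "vmax.HE", threshold = Inf)
  expect_equal(nrow(rep_inf$influential), 0)
  expect_equal(nrow(rep_inf$all), 1)
})

test_that("parameter paths address every scalar and round-trip", {
  m <- pbk_model("chinese")
  for (p in pbk_parameter_names(m)) {
    v <- pbk_get_parameter(m, p)
    expect_true(is.finite(v))
    m2 <- pbk_set_parameter(m, p, v * 2)
    expect_equal(pbk_get_parameter(m2, p), v * 2)
  }
  expect_error(pbk_get_parameter(m, "km.XX"), "unknown parameter")
  expect_error(pbk_get_parameter(m, "nothing"), "unknown parameter")
  expect_equal(pbk_get_parameter(m, "yield.S9"), 143)
  expect_equal(pbk_get_parameter(m, "partition.hydroxyestragole.liver"), 1.6)
})
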