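test_that("volumes and flows derive from the physiology tables", {
  ch <- derive_flows_volumes(pbk_model("chinese"))
  expect_equal(ch$volumes_L[["liver"]], 0.023 * 60)      # 1.38 L
  expect_equal(ch$liver_mass_g, 1380)
  ca <- derive_flows_volumes(pbk_model("caucasian"))
  expect_equal(ca$volumes_L[["liver"]], 0.026 * 70)      # 1.82 L
  expect_equal(ca$cardiac_output_L_per_h, 15 * 70^0.74)
  expect_equal(ca$flows_L_per_h[["liver"]], 0.227 * 15 * 70^0.74)
  # total blood-side flow is the sum of tissue flows, conserving mass even
  # though the printed Chinese fractions sum to 100.15%
  expect_equal(ch$total_flow_L_per_h, sum(ch$flows_L_per_h))
  expect_equal(sum(reference_physiology("chinese")$flow_fraction_pct), 100.15)
  # a zero fraction maps to a zero volume (raw physiology, not validated)
  ph <- reference_physiology("chinese")
  ph$tissue_fraction_pct[["fat"]] <- 0
  expect_equal(derive_flows_volumes(ph)$volumes_L[["fat"]], 0)
})

test_that("model validation rejects broken specifications", {
  expect_error(pbk_model("martian"), "population")
  kin <- reference_kinetics("chinese")
  expect_error(
    pbk_model(physiology = reference_physiology("chinese"),
              partitions = reference_partitions(),
              kinetics = kin[kin$pathway != "HES", ]),
    "exactly the pathways"
  )
  ph <- reference_physiology("chinese")
  ph$flow_fraction_pct[["fat"]] <- 20
  expect_error(
    pbk_model(physiology = ph, partitions = reference_partitions(),
              kinetics = kin),
    "flow fractions"
  )
  bad_part <- reference_partitions()
  bad_part$estragole[["fat"]] <- -1
  expect_error(
    pbk_model(physiology = reference_physiology("chinese"),
              partitions = bad_part, kinetics = kin),
    "positive"
  )
})

test_that("derivatives vanish for a closed system at rest", {
  kin <- reference_kinetics("chinese")
  kin$vmax_invitro <- 0
  still <- pbk_model(
    physiology = reference_physiology("chinese"),
    partitions = reference_partitions(), kinetics = kin, ka_per_h = 0
  )
  d <- pbk_derivatives(c(AGI_E = 5), still)
  expect_equal(unname(d), rep(0, length(d)))
})

test_that("absorption moves dose from the gut into the liver at rate Ka", {
  m <- pbk_model("chinese")
  d <- pbk_derivatives(c(AGI_E = 3), m)
  expect_equal(d[["AGI_E"]], -1.0 * 3)
  expect_equal(d[["AL_E"]], +1.0 * 3)
  expect_equal(sum(abs(d[setdiff(names(d), c("AGI_E", "AL_E"))])), 0)
})

test_that("transport terms cancel algebraically at random states", {
  m <- pbk_model("caucasian")
  set.seed(31)
  for (i in 1:10) {
    st <- setNames(10^runif(16, -4, 1),
                   c("AGI_E", "AL_E", "AF_E", "AR_E", "AS_E", "AB_E",
                     "AL_HE", "AB_HE", "AM_AP", "AM_EE", "AM_HE", "AM_HA",
                     "AM_M5", "AM_HEG", "AM_OE", "AM_HES"))
    d <- pbk_derivatives(st, m)
    # estragole: compartments + its five metabolite fluxes balance uptake
    est <- d[["AL_E"]] + d[["AF_E"]] + d[["AR_E"]] + d[["AS_E"]] + d[["AB_E"]] +
      d[["AM_AP"]] + d[["AM_EE"]] + d[["AM_HE"]] + d[["AM_HA"]] + d[["AM_M5"]]
    expect_equal(est, m$ka_per_h * st[["AGI_E"]], tolerance = 1e-10)
    # 1'-hydroxyestragole branch: pools + products balance its formation
    he <- d[["AL_HE"]] + d[["AB_HE"]] + d[["AM_HEG"]] + d[["AM_OE"]] +
      d[["AM_HES"]]
    expect_equal(he, d[["AM_HE"]], tolerance = 1e-10)
  }
  expect_error(pbk_derivatives(c(AL_E = -1), m), "non-negative")
  expect_error(pbk_derivatives(c(BOGUS = 1), m), "unknown state")
})

test_that("a zero dose yields an identically zero trajectory", {
  sim <- simulate_pbk(pbk_model("chinese"), 0, dt_h = 1)
  expect_true(all(sim$states == 0))
  expect_equal(sim$summary$percent_of_dose, rep(0, 8))
  expect_equal(mass_balance_error(sim), 0)
})

test_that("mass is conserved and states stay non-negative", {
  for (pop in c("chinese", "caucasian")) {
    for (dose in c(0.01, 150)) {
      sim <- cached_sim(pop, dose)
      expect_lt(mass_balance_error(sim), 1e-6)
      expect_true(all(sim$states > -1e-9))
    }
  }
})

test_that("percent-of-dose summaries are dose-linear at low dose", {
  lo <- simulate_pbk(pbk_model("chinese"), 0.001, dt_h = 0.5)
  hi <- cached_sim("chinese", 0.01)
  expect_equal(lo$summary$percent_of_dose, hi$summary$percent_of_dose,
               tolerance = 0.01)
})

test_that("the low-dose conjugate split follows the scaled efficiencies", {
  tab <- scaled_pathways(pbk_model("chinese"))
  eff <- setNames(tab$efficiency_scaled, tab$pathway)
  sim <- simulate_pbk(pbk_model("chinese"), 1e-3, dt_h = 0.5)
  formed <- vapply(c("HEG", "OE", "HES"), function(p) cumulative_amount(sim, p),
                   numeric(1))
  expect_equal(formed / sum(formed),
               eff[c("HEG", "OE", "HES")] / sum(eff[c("HEG", "OE", "HES")]),
               tolerance = 5e-3)
})

test_that("halving solver tolerances leaves the summaries unchanged", {
  base <- cached_sim("chinese", 5)
  tight <- simulate_pbk(pbk_model("chinese"), 5, dt_h = 0.5,
                        rtol = 5e-9, atol = 5e-13)
  expect_equal(tight$summary$percent_of_dose, base$summary$percent_of_dose,
               tolerance = 1e-3)
})

test_that("populations differ only by parameterization, not code path", {
  ca <- pbk_model("caucasian")
  swapped <- pbk_model("chinese")
  for (p in pbk_parameter_names(swapped)) {
    swapped <- pbk_set_parameter(swapped, p, pbk_get_parameter(ca, p))
  }
  s_ca <- simulate_pbk(ca, 0.01, dt_h = 1)
  s_sw <- simulate_pbk(swapped, 0.01, dt_h = 1)
  expect_identical(s_ca$states, s_sw$states)
})

test_that("summary accessors do their arithmetic and reject unknowns", {
  sim <- cached_sim("chinese", 0.01)
  s <- sim$summary
  i <- match("HE", s$pathway)
  expect_equal(percent_of_dose(sim, "HE"),
               s$cumulative_umol[i] / sim$dose_umol * 100)
  expect_equal(amount_per_g_liver(sim, "HE"),
               s$cumulative_umol[i] * 1000 / 1380)
  expect_error(percent_of_dose(sim, "XYZ"), "not tracked")
  # reported formation of the main detoxification product at dietary dose
  expect_equal(amount_per_g_liver(sim, "OE"), 1.2, tolerance = 0.1)
})

test_that("simulation rejects invalid doses", {
  expect_error(simulate_pbk(pbk_model("chinese"), -1), "non-negative")
  expect_error(simulate_pbk(pbk_model("chinese"), c(1, 2)), "single")
})
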