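test_that("HUSr follows the 2xC3 + 2xC4 + C5 stoichiometry", {
  # propionate 10, n-butyrate 5, n-valerate 2 mM out of total 100
  p <- make_profile(total = 100, ac = 83, pr = 10, nbu = 5, ibu = 1,
                    nva = 2, iva = 0, formate = 0)
  hb <- hydrogen_balance(p, pct_tolerance = 1.5)
  expect_equal(hb$husr, 2 * 10 + 2 * 5 + 2)

  # all-acetate profile carries no [2H] into SCFA
  p0 <- make_profile(total = 50, ac = 100, pr = 0, nbu = 0, ibu = 0,
                     nva = 0, iva = 0)
  expect_warning(hb0 <- hydrogen_balance(p0), "HUSr is zero")
  expect_equal(hb0$husr, 0)
  expect_true(is.na(hb0$formate_to_scfa_h))

  # branched inclusion adds exactly 2*iso_butyrate + iso_valerate
  p2 <- make_profile(total = 100, ac = 80, pr = 10, nbu = 4, ibu = 2,
                     nva = 3, iva = 1)
  base <- hydrogen_balance(p2)$husr
  with_iso <- hydrogen_balance(p2, include_branched = TRUE)$husr
  expect_equal(with_iso - base, 2 * 2 + 1)
  expect_gte(with_iso, base)

  # HUFr is the formate concentration, scale examples from reported doses
  pf <- make_profile(formate = 12)
  expect_equal(hydrogen_balance(pf)$hufr, 12)
  expect_equal(hydrogen_balance(make_profile(formate = 4.2))$hufr, 4.2)
})

test_that("ACL and non-carboxyl carbon follow the chain-length convention", {
  # pure acetate: every molecule has 2 carbons, 1 non-carboxyl
  p_ac <- make_profile(total = 100, ac = 100, pr = 0, nbu = 0, ibu = 0,
                       nva = 0, iva = 0)
  hb <- suppressWarnings(hydrogen_balance(p_ac))
  expect_equal(hb$acl, 2)
  expect_equal(hb$non_carboxyl_carbon, 100)

  # pure formate: ACL 1, so no non-carboxyl carbon at all
  p_fo <- make_profile(total = 0, formate = 10, ac = 100, pr = 0, nbu = 0,
                       ibu = 0, nva = 0, iva = 0)
  hb_fo <- suppressWarnings(hydrogen_balance(p_fo))
  expect_equal(hb_fo$acl, 1)
  expect_equal(hb_fo$non_carboxyl_carbon, 0)

  # empty straight-chain pool is undefined
  p_bad <- make_profile(total = 0, formate = 0, ac = 100, pr = 0, nbu = 0,
                        ibu = 0, nva = 0, iva = 0)
  expect_error(hydrogen_balance(p_bad), "undefined")

  # hand oracle on the reported hay low-dose group means
  p_hay_low <- reference_profile("hay", "low")
  hb_low <- hydrogen_balance(p_hay_low, pct_tolerance = 1)
  expect_equal(hb_low$acl,
               (0 + 2 * 91 * .62 + 3 * 91 * .18 + 4 * 91 * .11 +
                  5 * 91 * .0376) /
                 (0 + 91 * (.62 + .18 + .11 + .0376)),
               tolerance = 1e-12)
  expect_equal(hb_low$non_carboxyl_carbon,
               oracle_non_carboxyl(91, 0, 62, 18, 11, 3.76),
               tolerance = 1e-12)
  expect_equal(round(hb_low$non_carboxyl_carbon), 140)
})

test_that("non-carboxyl carbon scales with total SCFA at fixed composition", {
  p1 <- make_profile(total = 80)
  p3 <- make_profile(total = 240)
  hb1 <- hydrogen_balance(p1)
  hb3 <- hydrogen_balance(p3)
  expect_equal(hb3$acl, hb1$acl)
  expect_equal(hb3$non_carboxyl_carbon, 3 * hb1$non_carboxyl_carbon)
  # dilution leaves the HUFr/HUSr ratio unchanged
  pd <- make_profile(total = 40, formate = 2)
  pu <- make_profile(total = 80, formate = 4)
  expect_equal(hydrogen_balance(pd)$formate_to_scfa_h,
               hydrogen_balance(pu)$formate_to_scfa_h)
})

test_that("percent conversion and closure checks behave", {
  p <- make_profile(total = 88)
  conc <- scfa_mM(p)
  expect_equal(conc$acetate_mM, 88 * 0.62)
  acid_sum <- conc$acetate_mM + conc$propionate_mM + conc$n_butyrate_mM +
    conc$iso_butyrate_mM + conc$n_valerate_mM + conc$iso_valerate_mM
  expect_equal(acid_sum, 88, tolerance = 0.005)

  expect_error(hydrogen_balance(make_profile(ac = 40)), "sum to 100")
  # published whole-percent rounding can miss 100 by ~0.6; tolerance opens it
  p_hh <- reference_profile("hay", "high")
  expect_error(hydrogen_balance(p_hh), "sum to 100")
  expect_silent(hydrogen_balance(p_hh, pct_tolerance = 1))
})

test_that("A:P ratio matches reported values and errors on zero propionate", {
  p <- make_profile(ac = 62, pr = 18)
  expect_equal(round(acetate_propionate_ratio(p)$a_p, 2), 3.44)
  expect_equal(acetate_propionate_ratio(make_profile(ac = 18, pr = 18,
                                                     ibu = 45.53))$a_p, 1)
  expect_error(acetate_propionate_ratio(
    make_profile(ac = 80, pr = 0, ibu = 19.53)), "propionate")
})

test_that("percent decrease and diet fold ratios are plain arithmetic", {
  expect_equal(percent_decrease_vs_control(15, 24), 37.5)
  expect_equal(percent_decrease_vs_control(24, 24), 0)
  expect_equal(round(percent_decrease_vs_control(17, 27), 2), 37.04)
  expect_error(percent_decrease_vs_control(1, 0), "zero")
  expect_equal(round(diet_fold_ratio(1.43, 0.83), 2), 1.72)
  expect_equal(round(diet_fold_ratio(0.97, 0.33), 2), 2.94)
  expect_equal(diet_fold_ratio(2, 2), 1)
  expect_error(diet_fold_ratio(1, 0), "zero")
})

test_that("H2 per CH4-decrease exposes both the plain ratio and the /4 form", {
  em <- tibble::tibble(
    animal_id = "a1", period = c("control", "mid", "mid"),
    gas = c("CH4", "CH4", "H2"), mol_day = c(8.85, 6.89, 2.81)
  )
  rs <- h2_per_ch4_decrease(em)
  expect_equal(rs$mol_h2_per_mol_ch4_decrease, 2.81 / (8.85 - 6.89))
  expect_equal(rs$h_fraction_recovered,
               rs$mol_h2_per_mol_ch4_decrease / 4)
  expect_equal(round(rs$mol_h2_per_mol_ch4_decrease, 2), 1.43)

  # no H2 expelled -> ratio 0; ratio 4 <-> fraction 1
  em$mol_day[3] <- 0
  expect_equal(h2_per_ch4_decrease(em)$mol_h2_per_mol_ch4_decrease, 0)
  em$mol_day[3] <- 4 * (8.85 - 6.89)
  expect_equal(h2_per_ch4_decrease(em)$h_fraction_recovered, 1)

  # CH4 increase leaves the ratio undefined, flagged with a warning
  em_up <- tibble::tibble(
    animal_id = "a1", period = c("control", "mid", "mid"),
    gas = c("CH4", "CH4", "H2"), mol_day = c(6, 7, 1)
  )
  expect_warning(out <- h2_per_ch4_decrease(em_up), "no CH4 decrease")
  expect_true(is.na(out$mol_h2_per_mol_ch4_decrease))
})

test_that("HUSr change vs control is a percent contrast within animal", {
  hb <- tibble::tibble(
    animal_id = rep(c("a1", "a2"), each = 2),
    period = rep(c("control", "mid"), 2),
    husr = c(32, 40, 30, 60)
  )
  out <- husr_change_vs_control(hb)
  expect_equal(out$husr_change_pct[out$period == "mid"], c(25, 100))
  expect_true(all(is.na(out$husr_change_pct[out$period == "control"])))
  # doubling all C3/C4/C5 doubles HUSr, i.e. +100%
  p <- make_profile(total = 100, ac = 79, pr = 10, nbu = 5, ibu = 1,
                    nva = 2, iva = 3)
  p2 <- make_profile(total = 200, ac = 79, pr = 10, nbu = 5, ibu = 1,
                     nva = 2, iva = 3)
  expect_equal(hydrogen_balance(p2)$husr, 2 * hydrogen_balance(p)$husr)
})
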