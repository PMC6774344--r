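test_that("Donnan concentrations match the closed form for the standard case", {
  bath <- nacl_bath(1)
  cc <- donnan_concentrations(fixed_charge_field(2, -1L), bath)
  expect_equal(unname(cc[["gel_cation"]]), 2.4142, tolerance = 1e-4)
  expect_equal(unname(cc[["gel_anion"]]), 0.4142, tolerance = 1e-4)
  # no fixed charge: gel equals bath
  cc0 <- donnan_concentrations(fixed_charge_field(0, -1L), bath)
  expect_equal(unname(cc0), c(1, 1))
  # c_f = 3, c_sol = 2: root of {c+ = c- + 3, c+ c- = 4} is (4, 1)
  cc2 <- donnan_concentrations(fixed_charge_field(3, -1L), nacl_bath(2))
  expect_equal(unname(cc2), c(4, 1), tolerance = 1e-12)
  expect_error(
    donnan_concentrations(fixed_charge_field(2, -1L),
                          bath_composition(list(ion_species("Ca", 2L, 1e-7),
                                                ion_species("SO4", -2L, 1e-7)),
                                           c(1, 1))),
    "monovalent")
})

test_that("Donnan potential matches the printed value and both ion forms", {
  bath <- nacl_bath(1)
  eq <- donnan_equilibrium(fixed_charge_field(2, -1L), bath)
  expect_equal(1e3 * eq$potential_jump, -22.252, tolerance = 1e-4)
  expect_lt(eq$potential_jump, 0) # anionic gel sits at negative potential
  # equal concentrations: zero jump
  expect_equal(donnan_potential(c(gel_cation = 1, gel_anion = 1), bath), 0)
  # concentration ratio 1/2 at 293 K: (RT/F) log(1/2)
  cc <- donnan_concentrations(fixed_charge_field(3, -1L), nacl_bath(2))
  expect_equal(1e3 * donnan_potential(cc, nacl_bath(2)), -17.50,
               tolerance = 1e-3)
  expect_error(donnan_potential(c(gel_cation = -1, gel_anion = 1), bath),
               "positive")
})

test_that("Donnan product, electroneutrality and limit hold across c_f", {
  bath <- nacl_bath(1)
  cfs <- c(0, 1e-4, 0.03, 0.5, 2, 7, 40)
  prev_mag <- -Inf
  for (cf in cfs) {
    cc <- donnan_concentrations(fixed_charge_field(cf, -1L), bath)
    # ideal Donnan product c+ c- = c_sol^2
    expect_equal(cc[["gel_cation"]] * cc[["gel_anion"]], 1,
                 tolerance = 1e-10)
    # gel electroneutrality c+ - c- = c_f
    expect_lt(abs(cc[["gel_cation"]] - cc[["gel_anion"]] - cf),
              1e-12 * max(1, cf))
    expect_true(all(cc > 0))
    phi <- donnan_potential(cc, bath)
    # |potential| grows monotonically with |c_f| and vanishes at c_f = 0
    if (cf == 0) expect_equal(phi, 0)
    expect_gt(abs(phi) + 1e-15, prev_mag)
    prev_mag <- abs(phi)
    # the two species forms of the potential agree
    vt <- thermal_voltage(physical_constants())
    expect_lt(abs(vt * log(1 / cc[["gel_cation"]]) +
                  vt * log(1 / cc[["gel_anion"]])), 1e-12)
  }
})

test_that("closed form agrees with a brute-force 1D root search", {
  bath4 <- nacl_bath(4)
  for (cf in c(0.3, 2, 11)) {
    cc <- donnan_concentrations(fixed_charge_field(cf, -1L), bath4)
    # solve (c- + cf) c- = c_sol^2 for c- in (0, c_sol] numerically
    root <- stats::uniroot(function(cm) (cm + cf) * cm - 16,
                           c(1e-12, 4), tol = 1e-14)$root
    expect_equal(cc[["gel_anion"]], root, tolerance = 1e-8)
    expect_equal(cc[["gel_cation"]], root + cf, tolerance = 1e-8)
  }
})

test_that("cationic gels give the mirrored equilibrium", {
  bath <- nacl_bath(1)
  cc <- donnan_concentrations(fixed_charge_field(2, 1L), bath)
  expect_equal(cc[["gel_anion"]], sqrt(2) + 1, tolerance = 1e-12)
  expect_equal(cc[["gel_cation"]], sqrt(2) - 1, tolerance = 1e-12)
  expect_gt(donnan_potential(cc, bath), 0)
})
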