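test_that("condition validation accepts exactly the documented closed ranges", {
  expect_length(validate_conditions(buffer_conditions(20, 7.0, 100)), 0)
  # boundaries are inclusive (ionic equivalence must be positive)
  expect_length(validate_conditions(buffer_conditions(0, 0, 500)), 0)
  expect_length(validate_conditions(buffer_conditions(40, 14, 0.001)), 0)
  expect_length(validate_conditions(buffer_conditions(20, 14.0, 500)), 0)
  # one violation per offending field, naming value and range
  v <- validate_conditions(buffer_conditions(41, 7.0, 100))
  expect_length(v, 1L)
  expect_match(v, "temperature")
  expect_match(v, "0-40")
  expect_length(validate_conditions(buffer_conditions(-0.5, 7, 100)), 1L)
  expect_match(validate_conditions(buffer_conditions(20, 14.5, 100)), "ph")
  expect_match(validate_conditions(buffer_conditions(20, 7, 501)), "ionic_equivalence")
  expect_length(validate_conditions(buffer_conditions(20, 7, 0)), 1L)
  expect_length(validate_conditions(buffer_conditions(50, -1, 600)), 3L)
})

test_that("van't Hoff correction matches the closed form and its identities", {
  expect_identical(vant_hoff_adjust(10, NULL, 25, 20), 10)
  expect_identical(vant_hoff_adjust(10, NA, 25, 20), 10)
  expect_equal(vant_hoff_adjust(10, -33.6, 25, 25), 10)
  # hand evaluation of log_k - dH/(ln10 R) (1/T2 - 1/T1), frozen beforehand
  expect_equal(vant_hoff_adjust(10, -33.6, 25, 20), 10.100400258853714,
               tolerance = 1e-12)
  # exothermic binding weakens as temperature rises
  lks <- vapply(seq(0, 40, by = 5), function(t)
    vant_hoff_adjust(8, -30, 20, t), numeric(1))
  expect_true(all(diff(lks) < 0))
  lks_endo <- vapply(seq(0, 40, by = 5), function(t)
    vant_hoff_adjust(8, 20, 20, t), numeric(1))
  expect_true(all(diff(lks_endo) > 0))
  expect_error(vant_hoff_adjust(Inf, -10, 20, 25), "finite")
})

test_that("the Debye-Hueckel activity term has the documented shape", {
  expect_identical(debye_huckel_term(0, 20), 0)
  # frozen independent evaluation of A(T)(sqrt(I)/(1+sqrt(I)) - I/4)
  expect_equal(debye_huckel_term(100, 20), 0.10914621661835920,
               tolerance = 1e-12)
  expect_equal(debye_huckel_term(150, 20), 0.12254347012442782,
               tolerance = 1e-12)
  # strictly increasing up to the ~485 mM turnover of the -I/4 term
  ie <- seq(0.5, 480, by = 0.5)
  f <- vapply(ie, debye_huckel_term, numeric(1), temperature = 20)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0))
  # slope is about 0.51 near room temperature: f at tiny I ~ A sqrt(I)
  expect_equal(debye_huckel_term(1e-3, 25) / sqrt(1e-6), 0.51,
               tolerance = 0.01)
  expect_error(debye_huckel_term(-1, 20), "non-negative")
})

test_that("ionic-strength transfer weakens association at higher Ie", {
  expect_identical(ionic_strength_adjust(10.86, 16, 100, 100, 20), 10.86)
  expect_identical(ionic_strength_adjust(10.86, 0, 100, 300, 20), 10.86)
  # frozen hand evaluation for Ca2+ + EGTA4- (dz2 = 16), 100 -> 150 mM
  expect_equal(ionic_strength_adjust(10.86, 16, 100, 150, 20),
               10.645643943902902, tolerance = 1e-12)
  expect_lt(ionic_strength_adjust(10.86, 16, 100, 200, 20), 10.86)
  expect_gt(ionic_strength_adjust(10.86, 16, 100, 50, 20), 10.86)
})

test_that("proton competition reproduces the alpha polynomial", {
  set <- parse_constant_set(toy_set_json())
  lig <- set$ligands$EG
  # frozen arbitrary-precision evaluation for pK 9.4/8.8/2.7/2.0 at pH 7
  expect_equal(proton_competition(lig, 7.0), 6.2104414659110043e-5,
               tolerance = 1e-12)
  # no protonation steps: alpha is exactly 1 at any pH
  nop <- parse_constant_set('{
    "source": "custom", "metals": [{"id": "Ca", "charge": 2}],
    "ligands": [{"id": "L", "charge": -2, "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100, "protonation": [],
      "complexes": [{"metal": "Ca", "protons": 0, "log_k": 6}]}]
  }')$ligands$L
  for (ph in c(0, 4, 7, 14)) expect_identical(proton_competition(nop, ph), 1)
  # high-pH limit and monotonicity
  expect_equal(proton_competition(lig, 14), 1, tolerance = 1e-4)
  a <- vapply(seq(0, 14, by = 0.25), function(p) proton_competition(lig, p),
              numeric(1))
  expect_true(all(diff(a) >= 0))
  expect_true(all(a > 0 & a <= 1))
})

test_that("apparent constants compose alpha and the corrected betas", {
  cond <- cond_ref()
  # degenerate reduction: no protonation, no MHL, reference conditions
  nop <- parse_constant_set('{
    "source": "custom", "metals": [{"id": "Ca", "charge": 2}],
    "ligands": [{"id": "L", "charge": -2, "ref_temperature_c": 20,
      "ref_ionic_equivalence_mm": 100, "protonation": [],
      "complexes": [{"metal": "Ca", "protons": 0, "log_k": 6}]}]
  }')
  expect_equal(apparent_constant(nop$ligands$L, nop$metals$Ca, cond), 1e6,
               tolerance = 1e-12)
  # stored constants pass through unchanged at reference conditions (no dH):
  # K_app is then exactly alpha * 10^logk, the composition frozen beforehand
  set <- parse_constant_set(toy_set_json())
  expect_equal(apparent_constant(set$ligands$EG, set$metals$Ca, cond),
               4499067.1258467671, tolerance = 1e-10)
  # nondecreasing in pH without MHL species
  ks <- vapply(seq(4, 9, by = 0.25), function(p)
    apparent_constant(set$ligands$EG, set$metals$Ca,
                      buffer_conditions(20, p, 100)), numeric(1))
  expect_true(all(diff(ks) > 0))
  # a missing pair is an error naming both ids
  err <- expect_error(apparent_constant(set$ligands$EG,
                                        list(id = "Zn", charge = 2), cond))
  expect_match(conditionMessage(err), "Zn")
  expect_match(conditionMessage(err), "EG")
})

test_that("temperature and ionic corrections commute within the stated bound", {
  grid <- expand.grid(dh = c(-60, -20, 20, 60), t = c(0, 20, 40),
                      ie = c(10, 150, 400))
  for (r in seq_len(nrow(grid))) {
    a <- ionic_strength_adjust(
      vant_hoff_adjust(10, grid$dh[r], 20, grid$t[r]),
      16, 100, grid$ie[r], grid$t[r])
    b <- vant_hoff_adjust(
      ionic_strength_adjust(10, 16, 100, grid$ie[r], grid$t[r]),
      grid$dh[r], 20, grid$t[r])
    expect_lt(abs(a - b), 1e-6)
  }
})

test_that("build_table covers the selection and matches pairwise calls", {
  set <- load_builtin("NIST")
  cond <- cond_ref()
  tab <- build_table(set, c("Ca", "Mg"), c("EGTA", "ATP"), cond)
  expect_identical(dim(tab$kapp), c(2L, 2L))
  expect_equal(sum(!is.na(tab$kapp)), 4L)
  tab2 <- build_table(set, c("Ca", "Mg"), c("EGTA", "ATP"), cond)
  expect_identical(tab, tab2)
  for (m in c("Ca", "Mg")) for (l in c("EGTA", "ATP"))
    expect_identical(tab$kapp[m, l],
                     apparent_constant(set$ligands[[l]], set$metals[[m]], cond))
  expect_error(build_table(set, "Ca", "EGTA", buffer_conditions(45, 7, 100)),
               "invalid buffer conditions")
  expect_error(build_table(set, "Pb", "EGTA", cond), "Pb")
  df <- as.data.frame(tab)
  expect_identical(nrow(df), 4L)
  expect_true(all(c("metal", "ligand", "log_K_app", "alpha") %in% names(df)))
})
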