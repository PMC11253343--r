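test_that("purity correction scales the nominal concentration", {
  expect_identical(apply_purity(chelator_entry("EGTA", 1, "mM")), 1e-3)
  expect_equal(apply_purity(chelator_entry("EGTA", 1, "mM", purity = 95)), 9.5e-4)
  expect_identical(apply_purity(chelator_entry("EGTA", 0, "M", purity = 80)), 0)
  expect_error(chelator_entry("EGTA", 1, "mM", purity = 0), "purity")
  expect_error(chelator_entry("EGTA", 1, "mM", purity = 101), "purity")
})

test_that("pX transform handles powers of ten and the domain edge", {
  expect_identical(p_transform(1e-6), 6)
  expect_equal(p_transform(10^-5.5), 5.5)
  expect_identical(p_transform(0), NA_real_)
  expect_identical(p_transform(-1), NA_real_)
  expect_equal(p_transform(c(1e-3, 0, 1e-9)), c(3, NA, 9))
})

test_that("the 1:1 closed form matches its frozen high-precision root", {
  expect_identical(closed_form_1_1(1e-3, 1e-3, 0), 1e-3)
  expect_identical(closed_form_1_1(1e-3, 0, 1e6), 1e-3)
  expect_identical(closed_form_1_1(0, 1e-3, 1e6), 0)
  # frozen 50-digit evaluation of the stable quadratic
  expect_equal(closed_form_1_1(1e-3, 1e-3, 1e6), 3.1126729201736938e-5,
               tolerance = 1e-15)
  root50 <- closed_form_1_1(1e-3, 1e-3, 1e6, arithmetic_context("decimal", 50))
  # frozen against an mpmath evaluation with the same binary-double inputs
  expect_identical(chelation:::.dec_format(attr(root50, "decimal"), 30),
                   "3.11267292017369387159653669722e-5")
  # excess-metal branch (negative b) is stable: free ~ M_T - L_T + L_free
  expect_equal(closed_form_1_1(2e-3, 1e-3, 1e9), 1e-3 + 1e-9,
               tolerance = 1e-8)
})

test_that("degenerate mixtures reduce exactly", {
  cond <- cond_ref()
  # zero chelators: free equals total for every metal
  mix <- mixture_spec(metals = list(metal_entry("Ca", 1, "mM"),
                                    metal_entry("Mg", 2, "mM")),
                      conditions = cond)
  res <- speciate(mix, load_builtin())
  expect_identical(res$metals$free, res$metals$total)
  expect_identical(res$convergence$iterations, 0L)
  # zero metals: ligand free equals its effective (purity-scaled) total
  mix2 <- mixture_spec(chelators = list(chelator_entry("EGTA", 1, "mM", purity = 90)),
                       conditions = cond)
  res2 <- speciate(mix2, load_builtin())
  expect_equal(res2$ligands$free_unbound, 9e-4, tolerance = 1e-15)
  # zero-concentration species stay in the result
  mix3 <- toy_mixture(c(Ca = 1e-3, Mg = 0), c(X = 1e-3))
  res3 <- solve_free_from_total(mix3, toy_table(
    matrix(c(1e6, 1e4), 2, 1, dimnames = list(c("Ca", "Mg"), "X"))))
  expect_identical(res3$metals$free[res3$metals$metal == "Mg"], 0)
})

test_that("1:1 systems match the closed-form oracle to 1e-10 relative", {
  cond <- cond_ref()
  cases <- expand.grid(mt = c(1e-5, 1e-3), lt = c(1e-5, 1e-3, 2e-3),
                       k = c(1e2, 1e6, 1e10))
  for (r in seq_len(nrow(cases))) {
    mix <- toy_mixture(c(Ca = cases$mt[r]), c(X = cases$lt[r]))
    tab <- toy_table(matrix(cases$k[r], 1, 1, dimnames = list("Ca", "X")))
    res <- solve_free_from_total(mix, tab)
    cf <- closed_form_1_1(cases$mt[r], cases$lt[r], cases$k[r])
    expect_lt(abs(res$metals$free - cf) / cf, 1e-10)
    # conservation
    expect_lt(abs(res$metals$free + sum(res$bound) - cases$mt[r]) / cases$mt[r],
              1e-12)
  }
})

test_that("multi-metal systems match the independent brute-force oracle", {
  cond <- cond_ref()
  for (seed in 1:12) {
    set <- make_synthetic_constant_set(2, 2, seed = seed)
    tab <- build_table(set, conditions = cond)
    mix <- make_random_mixture(set, cond, seed = seed + 100)
    res <- solve_free_from_total(mix, tab)
    oracle <- brute_force_speciation_oracle(mix, tab)
    expect_lt(max(abs(res$metals$free - oracle) / oracle), 1e-8)
  }
})

test_that("free-known mode inverts total-known mode", {
  cond <- cond_ref()
  set <- load_builtin()
  tab <- build_table(set, c("Ca", "Mg"), c("EGTA", "ATP"), cond)
  # hand-composable 1:1 case: free Ca 1e-6 with K 1e6 and 1 mM ligand
  mix1 <- toy_mixture(c(Ca = 1e-6), c(X = 1e-3), modes = "free")
  tab1 <- toy_table(matrix(1e6, 1, 1, dimnames = list("Ca", "X")))
  res1 <- solve_total_from_free(mix1, tab1)
  expect_equal(res1$metals$total, 5.01e-4, tolerance = 1e-12)
  expect_equal(res1$ligands$free_unbound, 5e-4, tolerance = 1e-12)
  # zero chelators: total equals free
  mix0 <- mixture_spec(metals = list(metal_entry("Ca", 1, "uM", mode = "free")),
                       conditions = cond)
  res0 <- speciate(mix0, set)
  expect_identical(res0$metals$total, res0$metals$free)
  # round trip on a realistic buffer: free -> total -> free
  mixf <- mixture_spec(
    chelators = list(chelator_entry("EGTA", 1, "mM"), chelator_entry("ATP", 2, "mM")),
    metals = list(metal_entry("Ca", 1, "uM", mode = "free"),
                  metal_entry("Mg", 6, "mM")),
    conditions = cond)
  resf <- solve_total_from_free(mixf, tab)
  mixt <- mixture_spec(
    mixf$chelators,
    list(metal_entry("Ca", resf$metals$total[1]),
         metal_entry("Mg", 6, "mM")),
    cond)
  rest <- solve_free_from_total(mixt, tab)
  expect_lt(abs(rest$metals$free[1] - 1e-6) / 1e-6, 1e-8)
  # and the inverse direction: total -> free -> total
  rest2 <- solve_total_from_free(mixture_spec(
    mixf$chelators,
    list(metal_entry("Ca", rest$metals$free[1], mode = "free"),
         metal_entry("Mg", 6, "mM")),
    cond), tab)
  expect_lt(abs(rest2$metals$total[1] - resf$metals$total[1]) /
              resf$metals$total[1], 1e-8)
  # mode preconditions
  expect_error(solve_total_from_free(mixt, tab), "free")
  expect_error(solve_free_from_total(mixf, tab), "total")
})

test_that("solver refuses a table built for other conditions", {
  set <- load_builtin()
  tab <- build_table(set, "Ca", "EGTA", buffer_conditions(25, 7, 100))
  mix <- mixture_spec(list(chelator_entry("EGTA", 1, "mM")),
                      list(metal_entry("Ca", 0.5, "mM")),
                      cond_ref())
  expect_error(solve_free_from_total(mix, tab), "do not match")
})

test_that("free metal responds monotonically to totals", {
  cond <- cond_ref()
  set <- load_builtin()
  tab <- build_table(set, c("Ca", "Mg"), c("EGTA", "ATP"), cond)
  chel <- list(chelator_entry("EGTA", 1, "mM"), chelator_entry("ATP", 2, "mM"))
  frees <- vapply(seq(0.1e-3, 1.5e-3, length.out = 12), function(ca) {
    mix <- mixture_spec(chel, list(metal_entry("Ca", ca), metal_entry("Mg", 6e-3)),
                        cond)
    solve_free_from_total(mix, tab)$metals$free[1]
  }, numeric(1))
  expect_true(all(diff(frees) > 0))
  frees2 <- vapply(seq(0.2e-3, 3e-3, length.out = 12), function(eg) {
    mix <- mixture_spec(list(chelator_entry("EGTA", eg), chelator_entry("ATP", 2e-3)),
                        list(metal_entry("Ca", 1e-3), metal_entry("Mg", 6e-3)), cond)
    solve_free_from_total(mix, tab)$metals$free[1]
  }, numeric(1))
  expect_true(all(diff(frees2) < 0))
})

test_that("native-float and high-precision solves agree on well-conditioned buffers", {
  cond <- cond_ref()
  set <- load_builtin()
  tab <- build_table(set, c("Ca", "Mg"), c("EGTA", "ATP"), cond)
  mix <- mixture_spec(
    list(chelator_entry("EGTA", 1, "mM"), chelator_entry("ATP", 2, "mM")),
    list(metal_entry("Ca", 1, "mM"), metal_entry("Mg", 6, "mM")), cond)
  dres <- solve_free_from_total(mix, tab)
  res50 <- solve_free_from_total(mix, tab, arithmetic_context("decimal", 50))
  expect_lt(max(abs(res50$metals$free - dres$metals$free) / dres$metals$free),
            1e-6)
  # determinism: same inputs, same digits, bit-identical results
  res50b <- solve_free_from_total(mix, tab, arithmetic_context("decimal", 50))
  expect_identical(res50$metals, res50b$metals)
  # precision ladder on the closed form: 15 vs 30 digits within 1e-9
  r15 <- closed_form_1_1(1e-3, 1e-3, 1e6, arithmetic_context("decimal", 15))
  r30 <- closed_form_1_1(1e-3, 1e-3, 1e6, arithmetic_context("decimal", 30))
  expect_lt(abs(r15 - r30) / r30, 1e-9)
})
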