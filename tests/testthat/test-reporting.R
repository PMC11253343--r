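test_that("unit conversion is exact power-of-ten scaling", {
  expect_identical(convert_unit(1, "M"), 1)
  expect_identical(convert_unit(1, "mM"), 1e-3)
  expect_identical(convert_unit(250, "nM"), 2.5e-7)
  expect_identical(convert_unit(3, "uM"), 3e-6)
  expect_identical(convert_unit(3, "μM"), 3e-6)  # Greek mu alias
  # chaining with the inverse drifts by at most one ulp
  x <- 0.1234567
  expect_lte(abs(convert_unit(x, "nM") * 1e9 - x), .Machine$double.eps * x)
  expect_identical(convert_unit(convert_unit(2.5, "mM"), "M"), 2.5e-3)
  err <- expect_error(convert_unit(1, "pM"))
  for (u in c("M", "mM", "uM", "nM"))
    expect_match(conditionMessage(err), u, fixed = TRUE)
})

test_that("ionic equivalence follows Ie = 0.5 sum Ci |zi| and is linear", {
  expect_identical(ionic_equivalence(c(150, 150), c(1, -1)), 150)
  expect_identical(ionic_equivalence(c(100, 50), c(1, -2)), 100)
  a_c <- c(10, 20); a_z <- c(2, -1)
  b_c <- c(5); b_z <- c(-3)
  expect_identical(ionic_equivalence(c(a_c, b_c), c(a_z, b_z)),
                   ionic_equivalence(a_c, a_z) + ionic_equivalence(b_c, b_z))
  expect_error(ionic_equivalence(numeric(0), numeric(0)), "at least one")
  expect_error(ionic_equivalence(-5, 1), ">= 0")
  expect_error(ionic_equivalence(10, 0), "nonzero")
})

make_result <- function(ca_mm = 1) {
  mix <- mixture_spec(
    chelators = list(chelator_entry("EGTA", 1, "mM", purity = 97),
                     chelator_entry("ATP", 2, "mM")),
    metals = list(metal_entry("Ca", ca_mm, "mM"), metal_entry("Mg", 6, "mM")),
    conditions = cond_ref())
  speciate(mix, load_builtin())
}

test_that("sessions append in order without touching earlier records", {
  s0 <- new_session()
  expect_length(s0, 0L)
  r1 <- make_result(0.5)
  r2 <- make_result(1)
  r3 <- make_result(2)
  s1 <- append_result(s0, r1)
  expect_length(s1, 1L)
  expect_length(s0, 0L)  # sessions are values, not references
  s3 <- append_result(append_result(s1, r2), r3)
  expect_length(s3, 3L)
  got <- vapply(s3$records, function(rec) rec$result$metals$total[1], numeric(1))
  expect_identical(got, c(5e-4, 1e-3, 2e-3))
  expect_identical(s3$records[[1]]$result$metals, r1$metals)
})

test_that("workbook export has one sheet per calculation plus a summary", {
  sess <- append_result(append_result(new_session(), make_result(0.5)),
                        make_result(1))
  p <- withr::local_tempfile(fileext = ".xlsx")
  export_session(sess, p)
  sheets <- read_workbook(p)
  expect_identical(names(sheets), c("summary", "calc_1", "calc_2"))
  expect_identical(nrow(sheets$summary), 4L)  # 2 calcs x 2 metals
  expect_error(export_session(new_session(), p), "empty")
})

test_that("report configuration controls which quantities are exported", {
  res <- make_result()
  sess <- append_result(new_session(), res,
                        report_config(px = FALSE, kapp = FALSE))
  p <- withr::local_tempfile(fileext = ".xlsx")
  export_session(sess, p)
  calc <- read_workbook(p)$calc_1
  expect_false("pX" %in% calc$quantity)
  expect_false("log10_K_app" %in% calc$quantity)
  expect_true("free" %in% calc$quantity)
  # selected entities filter rows
  sess2 <- append_result(new_session(), res, report_config(metals = "Ca"))
  p2 <- withr::local_tempfile(fileext = ".xlsx")
  export_session(sess2, p2)
  calc2 <- read_workbook(p2)$calc_1
  expect_false("Mg" %in% calc2$entity)
  expect_true("Ca" %in% calc2$entity)
})

test_that("every exported value re-reads exactly as written", {
  res <- make_result()
  sess <- append_result(new_session(), res)
  p <- withr::local_tempfile(fileext = ".xlsx")
  export_session(sess, p, digits = 12)
  calc <- read_workbook(p)$calc_1
  free_row <- calc[calc$entity == "Ca" & calc$quantity == "free", ]
  expect_identical(free_row$value, sprintf("%.12g", res$metals$free[1]))
  px_row <- calc[calc$entity == "Ca" & calc$quantity == "pX", ]
  expect_identical(px_row$value, sprintf("%.12g", res$metals$px[1]))
  # identical sessions export identical bytes
  p2 <- withr::local_tempfile(fileext = ".xlsx")
  export_session(append_result(new_session(), res), p2, digits = 12)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("CSV export mirrors the workbook sheets", {
  sess <- append_result(new_session(), make_result())
  prefix <- withr::local_tempfile()
  export_session(sess, prefix, format = "csv")
  expect_true(file.exists(paste0(prefix, "_summary.csv")))
  calc <- utils::read.csv(paste0(prefix, "_calc_1.csv"),
                          colClasses = "character")
  expect_true(all(c("entity", "quantity", "value", "unit") %in% names(calc)))
  expect_true("free" %in% calc$quantity)
})

test_that("the JSON echo is machine-readable and faithful", {
  res <- make_result()
  doc <- jsonlite::fromJSON(speciation_json(res))
  expect_identical(doc$source, "NIST")
  expect_equal(doc$metals$free, res$metals$free, tolerance = 1e-15)
  expect_equal(doc$conditions$ph, 7)
  expect_identical(doc$convergence$method, res$convergence$method)
})
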