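test_that("signed errors are prediction minus reference, matched by complex", {
  refs <- data.frame(complex_id = c("a", "b"), delta_e_kcal = c(-380, -250))
  preds <- data.frame(functional = rep("F1", 2), complex_id = c("a", "b"),
                      delta_e_kcal = c(-380, -250))
  expect_equal(signed_errors(preds, refs)$signed_error, c(0, 0))
  offs <- c(1.5, -2.25)
  preds$delta_e_kcal <- refs$delta_e_kcal + offs
  expect_equal(signed_errors(preds, refs)$signed_error, offs)
  preds$complex_id <- c("a", "zz")
  expect_error(signed_errors(preds, refs), "zz")
})

test_that("published per-complex errors return the published statistics", {
  fx <- load_paper_fixtures()
  preds <- paper_predictions(fx)
  refs <- paper_references()
  err <- signed_errors(preds[preds$functional == "BB1K" &
                               preds$complex_id %in% complex_groups()$A, ],
                       refs)
  expect_equal(sort(err$signed_error), sort(c(-0.47, 0.21, -0.26, 1.76)),
               tolerance = 1e-9)
  expect_equal(mue(err$signed_error), 0.67, tolerance = 0.01)
  # the largest group-A error for BB1K sits on the hexaaqua complex
  expect_equal(signed_errors(preds[preds$functional == "BB1K" &
                                     preds$complex_id == "Fe(H2O)6", ],
                             refs)$signed_error, 1.76, tolerance = 1e-9)
})

test_that("MSE/MUE/MaxE behave as mean, absolute mean and argmax", {
  e <- c(-0.47, 0.21, -0.26, 1.76)
  expect_equal(mse(e), mean(e))
  expect_equal(mue(e), mean(abs(e)))
  mx <- maxe(e, c("w", "x", "y", "z"))
  expect_equal(mx$value, 1.76)
  expect_identical(mx$complex_id, "z")
  expect_equal(unlist(maxe(c(0, 0))[1]), c(value = 0))
  expect_equal(mse(c(0, 0)), 0)
  # maxe ties break by canonical complex order
  tie <- maxe(c(-2, 2), c("Fe(H2O)4", "Fe(H2O)"))
  expect_identical(tie$complex_id, "Fe(H2O)")
  expect_error(mue(numeric(0)), "no error records")
  # invariants: mue >= |mse| (equality iff single-signed), maxe >= mue
  set.seed(7)
  for (i in 1:20) {
    x <- stats::rnorm(6)
    expect_gte(mue(x), abs(mse(x)))
    expect_gte(maxe(x)$value, mue(x))
  }
  one_sign <- abs(stats::rnorm(5))
  expect_equal(mue(one_sign), abs(mse(one_sign)))
})

test_that("accuracy groups follow the volt thresholds, boundaries inclusive", {
  th <- group_thresholds()
  expect_equal(qty_value(th$group1_max), 2.3061, tolerance = 1e-4)
  expect_equal(qty_value(th$group2_max), 4.6121, tolerance = 1e-4)
  expect_identical(classify_group(1.72, th), "I")
  expect_identical(classify_group(3.03, th), "II")
  expect_identical(classify_group(0, th), "I")
  expect_identical(classify_group(qty_value(th$group1_max), th), "I")
  expect_identical(classify_group(5.5, th), "III")
  expect_error(classify_group(-0.1, th), "negative")
  # monotone non-decreasing in MUE
  grid <- classify_group(seq(0, 8, by = 0.05), th)
  expect_true(all(diff(match(grid, c("I", "II", "III"))) >= 0))
  strict <- group_thresholds(strict_paper = TRUE)
  expect_identical(qty_value(strict$group1_max), 2.31)
  expect_identical(qty_value(strict$group2_max), 4.62)
})

test_that("ranking sorts by MUE with MaxE and name tie-breaks", {
  s <- data.frame(functional = c("b", "a", "c"),
                  mue = c(1, 2, 1), maxe = c(3, 5, 2))
  r <- rank_functionals(s)
  expect_identical(r$functional, c("c", "b", "a"))
  expect_identical(r$rank, 1:3)
  expect_true(all(diff(r$mue) >= 0))
  s2 <- data.frame(functional = c("b", "a"), mue = c(1, 1), maxe = c(2, 2))
  expect_identical(rank_functionals(s2)$functional, c("a", "b"))
  expect_identical(rank_functionals(s[1, ])$rank, 1L)
  # output is a permutation of the input
  expect_setequal(r$functional, s$functional)
})

test_that("the fitted benchmark object carries errors, summary and methods", {
  ds <- gen_benchmark_dataset(
    n_complexes = 12,
    functionals = data.frame(functional = c("f1", "f2", "f3"),
                             bias = c(2, 0, -3), sd = c(0, 0, 0)),
    seed = 11)
  fit <- dft_benchmark(ds$predictions, ds$references)
  s <- summary(fit)
  expect_s3_class(fit, "dft_benchmark")
  # noiseless constant offsets: MSE = bias, MUE = |bias| exactly
  expect_equal(s$mse[s$functional == "f1"], 2)
  expect_equal(s$mue[s$functional == "f1"], 2)
  expect_equal(s$mue[s$functional == "f2"], 0)
  expect_equal(s$mue[s$functional == "f3"], 3)
  expect_identical(s$functional[s$rank == 1], "f2")
  expect_identical(s$group, c("I", "I", "II"))
  expect_equal(coef(fit), c(f2 = 0, f1 = 2, f3 = -3))
  expect_output(print(fit), "3 functionals over 12 complexes")
})

test_that("report tables render ranked 2-dp groupwise layouts", {
  fit <- benchmark_from_fixtures(complete_only = FALSE)
  ta <- report_tables(fit, "A")
  expect_identical(ta$rank, 1:10)
  expect_identical(ta$functional[1:3], c("BB1K", "mPWB1K", "mPW1N"))
  expect_equal(ta$mue[ta$functional == "mPW1N"], 2.23)
  expect_equal(ta[ta$functional == "BB1K", "Fe(H2O)6"], 1.76)
  expect_true(all(c("Fe(H2O)", "Fe(H2O)2", "Fe(H2O)4", "Fe(H2O)6") %in%
                    names(ta)))
  # a 3-functional synthetic set renders 3 ranked rows
  ds <- gen_benchmark_dataset(
    n_complexes = 4,
    functionals = data.frame(functional = c("x", "y", "z"),
                             bias = c(1, -2, 0.5), sd = 0.2),
    seed = 3)
  small <- dft_benchmark(ds$predictions, ds$references)
  to <- report_tables(small, "overall")
  expect_identical(to$rank, 1:3)
  expect_error(report_tables(small, "C"), "no complexes")
})
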