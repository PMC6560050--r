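test_that("component series follow the planted convergence forms", {
  m <- convergence_model(hf_cbs = -100, corr_cbs = 0, hf_amp = 1,
                         corr_amp = 0, hf_form = "exponential", hf_rate = 1)
  ser <- gen_component_series(m, 2:4)
  expect_equal(ser$e_hf[1], -99.864665, tolerance = 1e-6)
  expect_equal(ser$e_hf, -100 + exp(-(2:4)), tolerance = 1e-12)
  expect_identical(ser$basis_label,
                   c("aug-cc-pVDZ", "aug-cc-pVTZ", "aug-cc-pVQZ"))
  expect_error(gen_component_series(m, c(1, 2)), "2..6")
  expect_error(convergence_model(-1, -1, hf_rate = -1), "> 0")
})

test_that("scheme-matched extrapolation inverts any noiseless model", {
  h <- function(x) quantity(x, "hartree")
  cases <- list(
    list(form = "exponential", rate = 1.4, corr_p = 3, scheme = "scheme2"),
    list(form = "exponential", rate = 0.8, corr_p = 3, scheme = "scheme2"),
    list(form = "power", rate = 4.93, corr_p = 2.13, scheme = "scheme1")
  )
  for (cs in cases) {
    m <- convergence_model(hf_cbs = -123.4, corr_cbs = -2.1,
                           hf_amp = 0.07, corr_amp = 0.2,
                           hf_form = cs$form, hf_rate = cs$rate,
                           corr_exponent = cs$corr_p)
    ser <- gen_component_series(m, 2:4)
    ce <- function(i) component_energy(h(ser$e_hf[i]), h(ser$e_corr[i]))
    res <- if (cs$scheme == "scheme2") {
      scheme2_cbs(ce(1), ce(2), ce(3))
    } else {
      scheme1_cbs(ce(1), ce(2))
    }
    expect_equal(qty_value(res$cbs_hf), -123.4, tolerance = 1e-10)
    expect_equal(qty_value(res$cbs_corr), -2.1, tolerance = 1e-10)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  m <- convergence_model(-100, -2, noise_sd = 1e-4)
  expect_identical(gen_component_series(m, 2:4, seed = 9),
                   gen_component_series(m, 2:4, seed = 9))
  expect_false(identical(gen_component_series(m, 2:4, seed = 9),
                         gen_component_series(m, 2:4, seed = 10)))
  expect_identical(gen_benchmark_dataset(seed = 5),
                   gen_benchmark_dataset(seed = 5))
  t1 <- gen_species_energies("x", -380, noise_sd = 1e-4, seed = 2)
  t2 <- gen_species_energies("x", -380, noise_sd = 1e-4, seed = 2)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(gen_benchmark_dataset(seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("planted reduction energies survive the full pipeline", {
  for (de in c(-380, 0, -602.854)) {
    tab <- gen_species_energies("Fe(H2O)6", de)
    expect_equal(build_reference_table(tab)$delta_e_kcal, de,
                 tolerance = 1e-8)
  }
  # quantity input in other units is honoured
  tab <- gen_species_energies("x", quantity(-380 / 627.509474, "hartree"))
  expect_equal(build_reference_table(tab)$delta_e_kcal, -380,
               tolerance = 1e-8)
})

test_that("record noise propagates into the recovered energy within the propagation bound", {
  # per-record sd 1e-4 hartree; linear propagation through the scheme-II
  # weights gives a per-seed sd of ~0.33 kcal/mol, so individual errors stay
  # within ~4 sigma and the 100-seed mean well inside 0.2 kcal/mol
  errs <- vapply(1:100, function(s) {
    tab <- gen_species_energies("x", -380, noise_sd = 1e-4, seed = s)
    build_reference_table(tab)$delta_e_kcal - (-380)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.2)
  expect_lt(max(abs(errs)), 1.4)
})

test_that("benchmark datasets plant exact bias structure", {
  ds <- gen_benchmark_dataset(
    n_complexes = 12,
    functionals = data.frame(functional = "f", bias = 2, sd = 0), seed = 1)
  s <- summary(dft_benchmark(ds$predictions, ds$references))
  expect_equal(s$mse, 2)
  expect_equal(s$mue, 2)
  one <- gen_benchmark_dataset(
    n_complexes = 1,
    functionals = data.frame(functional = "f", bias = 0, sd = 1), seed = 4)
  s1 <- summary(dft_benchmark(one$predictions, one$references))
  expect_equal(s1$maxe, s1$mue)
  expect_equal(s1$maxe, abs(s1$mse))
  expect_error(gen_benchmark_dataset(n_complexes = 0), ">= 1")
  # references stay inside the requested regime
  expect_true(all(ds$references$delta_e_kcal >= -600 &
                    ds$references$delta_e_kcal <= -240))
})

test_that("across seeds, unbiased predictions average to zero signed error", {
  ms <- vapply(1:200, function(s) {
    ds <- gen_benchmark_dataset(
      n_complexes = 12,
      functionals = data.frame(functional = "f", bias = 0, sd = 1),
      seed = s)
    summary(dft_benchmark(ds$predictions, ds$references))$mse
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.25)
})
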