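test_that("prevalence, intensity and abundance follow the standard definitions", {
  s <- summarize_infection(c(3, 16), n_examined = 2)
  expect_equal(s$prevalence, 1.0)
  expect_equal(s$mean_intensity, 9.5)
  expect_equal(s$mean_abundance, 9.5)

  s2 <- summarize_infection(c(1, 1, 1), n_examined = 10)
  expect_equal(s2$prevalence, 0.3)
  expect_equal(s2$mean_intensity, 1.0)
  expect_equal(s2$mean_abundance, 0.3)

  s3 <- summarize_infection(integer(0), n_examined = 24)
  expect_equal(s3$prevalence, 0)
  expect_true(is.na(s3$mean_intensity))
  expect_equal(s3$mean_abundance, 0)
})

test_that("abundance = prevalence x intensity and errors are raised", {
  s <- summarize_infection(c(2, 3), n_examined = 6)
  expect_equal(s$mean_abundance, s$prevalence * s$mean_intensity)
  expect_lte(s$mean_abundance, s$mean_intensity)
  expect_error(summarize_infection(c(1), n_examined = 0), "positive")
  expect_error(summarize_infection(c(0, 2), n_examined = 5), "at least one")
  expect_error(summarize_infection(c(1, 1, 1), n_examined = 2), "more infected")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(11 / 8, 1), 1.4)
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(0.05, 1), 0.1)
})

test_that("pooling weights prevalence by hosts examined", {
  a <- summarize_infection(c(1, 2), n_examined = 4)   # prevalence 0.5
  b <- summarize_infection(integer(0), n_examined = 6) # prevalence 0
  pooled <- pool_surveys(a, b)
  expect_equal(pooled$n_examined, 10L)
  expect_equal(pooled$prevalence, (0.5 * 4 + 0 * 6) / 10)
  expect_equal(pooled$mean_intensity, 1.5)
})

test_that("unresolved built-in reports refuse a per-host summary", {
  inf <- builtin_infections()
  nguene <- inf[inf$report_key == "voreli_nguene", ]
  expect_error(summarize_infection(nguene$worm_counts[[1]][NA],
                                   nguene$n_examined),
               "unresolved|at least")
  tab <- summarize_builtin_infections()
  expect_true(is.na(tab$mean_intensity[tab$report_key == "voreli_nguene"]))
  expect_equal(tab$mean_intensity[tab$report_key == "sefcae_malebo"], 9.5)
})
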