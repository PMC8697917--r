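sim_records <- function(species, n, seed) {
  cfg <- simulation_config(species, n_per_species = n, seed = seed,
                           missing_rates = c(hVII = 0),
                           default_missing_rate = 0)
  suppressWarnings(simulate_specimens(cfg))
}

test_that("matrix preparation excludes hook VII and applies the 50% rule", {
  recs <- sim_records("K. sefcae", 10, 41)
  m <- prepare_matrix(recs)
  expect_false("hVII" %in% colnames(m))
  expect_setequal(colnames(m), kg_ordination_params())

  # a specimen missing 15 of 20 parameters is dropped at threshold 0.5
  recs2 <- recs
  gone <- setdiff(kg_ordination_params(), c("da_total", "va_total", "db_len",
                                            "vb_len", "hI"))
  recs2[1, gone] <- NA_real_
  m2 <- prepare_matrix(recs2, missing_threshold = 0.5)
  expect_identical(attr(m2, "dropped_rows"), recs2$specimen_id[1])

  # with no missing cells the output is the input minus hook VII
  expect_equal(nrow(attr(m, "imputed")), 0)
  expect_equal(unname(m[recs$specimen_id[1], "va_total"]),
               recs$va_total[1])

  # threshold 0: any missing cell drops its column and row
  recs3 <- recs
  recs3$hI[2] <- NA_real_
  m3 <- prepare_matrix(recs3, missing_threshold = 0)
  expect_true("hI" %in% attr(m3, "dropped_cols"))

  expect_error(prepare_matrix(recs[1:2, ]), "at least 3")
})

test_that("residual missing cells are mean-imputed and logged", {
  recs <- sim_records("K. sefcae", 12, 43)
  recs$hI[1:3] <- NA_real_  # 25% missing: below threshold, imputed
  m <- prepare_matrix(recs)
  imp <- attr(m, "imputed")
  expect_equal(nrow(imp), 3)
  expect_true(all(imp$param == "hI"))
  expect_equal(unname(m[1, "hI"]), mean(recs$hI, na.rm = TRUE))
})

test_that("PCA: rank-1 data put 100% on axis 1; variance shares behave", {
  set.seed(5)
  base <- rnorm(40)
  m <- cbind(a = 1 + 2 * base, b = 7 - base, c = 3 * base)
  p <- run_pca(m)
  expect_equal(p$explained_variance_pct[1], 100, tolerance = 1e-8)

  m2 <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, letters[1:6]))
  p2 <- run_pca(m2)
  ev <- p2$explained_variance_pct
  expect_equal(sum(ev), 100, tolerance = 1e-8)
  expect_true(all(diff(ev) <= 1e-8))
})

test_that("eigenvalue shares of independent columns concentrate near 1/p", {
  set.seed(11)
  m <- matrix(rnorm(2000 * 20), 2000, 20,
              dimnames = list(NULL, paste0("v", 1:20)))
  p <- run_pca(m)
  expect_true(all(abs(p$explained_variance_pct - 5) < 1))
})

test_that("PCA scores are invariant to per-column affine rescaling", {
  set.seed(7)
  m <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("v", 1:5)))
  m2 <- sweep(sweep(m, 2, c(2, 3, 0.5, 10, 1), "*"), 2, c(1, -4, 0, 2, 7), "+")
  expect_equal(run_pca(m)$scores, run_pca(m2)$scores, tolerance = 1e-8)
})

test_that("zero-variance columns are dropped with a warning", {
  set.seed(9)
  m <- cbind(matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))),
             flat = rep(4, 20))
  expect_warning(p <- run_pca(m), "zero-variance")
  expect_false("flat" %in% rownames(p$loadings))
})

test_that("NMDS recovers an exact configuration with ~zero stress", {
  set.seed(3)
  conf <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  n <- run_nmds(conf, k = 2, seed = 8, standardize = FALSE)
  expect_lt(n$stress, 1e-6)
})

test_that("duplicated specimens land on coincident NMDS coordinates", {
  recs <- sim_records("K. parisellei", 8, 17)
  recs2 <- rbind(recs, recs[1, , drop = FALSE])
  recs2$specimen_id[9] <- "dup"
  m <- prepare_matrix(recs2)
  n <- run_nmds(m, k = 2, seed = 2)
  d <- sqrt(sum((n$scores[1, ] - n$scores[9, ])^2))
  spread <- mean(dist(n$scores))
  expect_lt(d, 1e-3 * max(spread, 1))
})

test_that("NMDS stress does not increase with added dimensions", {
  recs <- sim_records(c("K. sefcae", "K. parisellei", "K. hugei"), 8, 19)
  m <- prepare_matrix(recs)
  s2 <- run_nmds(m, k = 2, seed = 5)$stress
  s3 <- run_nmds(m, k = 3, seed = 5)$stress
  expect_lte(s3, s2 + 1e-8)
  expect_error(run_nmds(m, k = nrow(m)), "smaller")
})

test_that("species with disjoint ranges separate in ordination space", {
  recs <- sim_records(c("K. sefcae", "K. parisellei"), 30, 23)
  m <- prepare_matrix(recs)
  p <- run_pca(m)
  expect_gte(separation_probability(p), 0.95)
  n <- run_nmds(m, k = 2, seed = 29)
  expect_gte(separation_probability(n), 0.95)
})
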