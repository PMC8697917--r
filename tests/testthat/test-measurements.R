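test_that("diagnostic ratios divide per specimen and propagate missingness", {
  r <- specimen_record("a", da_inner = 16.0, da_outer = 4.9)
  f <- compute_features(r)
  expect_equal(round(f$da_root_ratio, 2), 3.27)

  r2 <- specimen_record("b", da_inner = 12.0, hI = 12.0)
  expect_equal(compute_features(r2)$da_inner_over_h1, 1.0)

  r3 <- specimen_record("c", da_inner = 16.0)  # outer root missing
  f3 <- compute_features(r3)
  expect_true(is.na(f3$da_root_ratio))
  # every feature is either missing or a positive finite number
  full <- compute_features(full_specimen())
  vals <- unlist(full[-1])
  expect_true(all(is.finite(vals) & vals > 0))
})

test_that("ratio features are invariant to rescaling all lengths", {
  rec <- full_specimen()
  f1 <- compute_features(rec)
  for (c in c(0.5, 2, 13.7)) {
    f2 <- compute_features(scale_specimen(rec, c))
    expect_equal(f2[-1], f1[-1], tolerance = 1e-12)
  }
})

test_that("validation rejects impossible measurements by name", {
  bad <- full_specimen()
  bad$da_inner <- -1
  expect_error(validate_specimens(bad), "da_inner")
  bad2 <- full_specimen()
  bad2$va_ltn <- bad2$va_total + 5
  expect_error(validate_specimens(bad2), "va_ltn")
  bad3 <- full_specimen()
  bad3$ap_side <- "sideways"
  expect_error(validate_specimens(bad3), "ap_side")
  dup <- rbind(full_specimen("x"), full_specimen("x"))
  expect_error(validate_specimens(dup), "duplicate")
})

test_that("unknown fields are rejected at construction", {
  expect_error(specimen_record("a", wingspan = 3), "unknown")
})
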