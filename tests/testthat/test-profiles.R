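profiles <- builtin_profiles()

test_that("twelve species profiles load with the printed cells", {
  expect_length(profiles, 12)
  # 11 newly described + 1 previously described congener
  expect_equal(sum(vapply(profiles, `[[`, logical(1), "is_new")), 11)

  sef <- profile_summary_table(profiles[["K. sefcae"]])
  i <- match("va_total", sef$param)
  expect_equal(unlist(sef[i, c("min", "mean", "max", "n")]),
               c(min = 41.9, mean = 45.1, max = 50, n = 10))

  # the two-host species carries two measurement columns, type host first
  choch <- profiles[["K. chochamandai"]]
  expect_equal(choch$hosts, c("Microthrissa moeruensis",
                              "Potamothrissa acutirostris"))

  # range-only cells: no printed mean, midpoint working mean flagged imputed
  pel <- profile_summary_table(profiles[["K. pellonulae"]])
  i <- match("da_total", pel$param)
  expect_equal(pel$min[i], 40)
  expect_equal(pel$max[i], 50)
  expect_true(is.na(pel$mean[i]))
  expect_true(pel$imputed[i])
  expect_equal(pel$working_mean[i], 45)
})

test_that("every summary satisfies min <= mean <= max", {
  for (p in profiles) for (h in p$hosts) {
    tab <- profile_summary_table(p, h)
    ok <- is.na(tab$min) | is.na(tab$mean) | is.na(tab$max) |
      (tab$min <= tab$mean & tab$mean <= tab$max)
    expect_true(all(ok), info = paste(p$species, h))
  }
})

test_that("printed proportions agree with ratios of means up to averaging", {
  chk <- check_proportions(profiles, tol = 0.25)
  expect_gt(nrow(chk), 30)
  # mean-of-ratios vs ratio-of-means: near-agreement with logged exceptions,
  # never a hard failure
  expect_gt(mean(chk$consistent), 0.9)
  expect_true(all(abs(chk$printed - chk$ratio_of_means) < 1))
})

test_that("host survey totals and worm counts match the printed records", {
  sv <- builtin_surveys()
  expect_equal(sum(sv$n_examined), 172)

  itezhi <- sv[sv$host_species == "Limnothrissa miodon" &
                 sv$locality == "Lake Itezhi-Tezhi", ]
  expect_equal(itezhi$n_examined, 24)
  expect_identical(itezhi$worm_counts[[1]], integer(0))

  losera <- sv[sv$host_species == "Odaxothrissa losera", ]
  expect_equal(losera$n_examined, 2)
  expect_identical(sort(losera$worm_counts[[1]]), c(3L, 16L))

  # unresolved counts stay unresolved but expose n_infected and intensity
  inf <- builtin_infections()
  nguene <- inf[inf$report_key == "voreli_nguene", ]
  expect_false(nguene$resolved)
  expect_equal(nguene$n_infected, 4)
  expect_equal(nguene$printed_intensity, 2)
})

test_that("locality aliases normalize paragraph spellings", {
  expect_equal(unname(canonical_locality(c("Manianga", "Poko"))),
               c("Manyanga", "Poko"))
})
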