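key <- kapentagyrus_key()

test_that("the key has 13 couplets, 14 terminals spanning 11 hosts", {
  expect_length(key$couplets, 13)
  expect_length(key_terminals(key), 14)
  expect_length(unique(unlist(key_terminal_hosts(key))), 11)
})

test_that("couplet 9 separates the two Volta congeners on length to notch", {
  cpl <- key$couplets[[9]]
  expect_equal(cpl$a$species, "K. hahni")
  expect_equal(cpl$b$species, "K. hugei")
  expect_equal(cpl$a$conditions[[1]]$subject, "va_ltn")
  expect_equal(cpl$a$conditions[[1]]$threshold, 19)
})

test_that("worked identifications follow the printed couplet paths", {
  r1 <- specimen_record("s1", host_species = "Odaxothrissa losera",
                        va_ltn = 30, da_total = 39, va_total = 45.1,
                        va_inner = 26)
  res1 <- identify_specimen(r1, key)
  expect_identical(res1$candidates, "K. sefcae")
  expect_equal(res1$path$couplet, c(1L, 2L))
  expect_false(res1$ambiguous)

  r2 <- specimen_record("s2", host_species = "Pellonula leonensis",
                        da_total = 37.6)
  res2 <- identify_specimen(r2, key)
  expect_identical(res2$candidates, "K. verbisti")
  expect_equal(res2$path$couplet, c(1L, 4L, 6L, 7L, 8L))
})

test_that("a record with no measurements and no host reaches all terminals", {
  res <- identify_specimen(specimen_record("empty"), key)
  expect_setequal(res$candidates, key_terminals(key))
  expect_true(res$ambiguous)
})

test_that("boundary equality on a strict threshold is undecided and flagged", {
  # couplet 13 separates at 19 um with '< 19' vs '> 19': exactly 19 is
  # defined by neither lead
  r <- specimen_record("b1", host_species = "Nannothrissa parva",
                       da_inner = 11.8, hI = 13.7, va_ltn = 19)
  res <- identify_specimen(r, key)
  expect_true(res$ambiguous)
  expect_true(any(grepl("boundary", res$notes)))
  # both leads of couplet 13 were explored; the host filter then keeps the
  # N. parva parasite
  expect_true("K. parisellei" %in% res$candidates)
  expect_true(any(res$path$lead == "both"))
})

test_that("evaluation is pure and host-free mode treats host couplets as open", {
  r <- full_specimen()
  a <- identify_specimen(r, key)
  b <- identify_specimen(r, key)
  expect_identical(a[c("candidates", "path", "notes")],
                   b[c("candidates", "path", "notes")])
  free <- identify_specimen(r, key, use_host = FALSE)
  expect_true("K. sefcae" %in% free$candidates)
})

test_that("unknown hosts are rejected with the registry listed", {
  r <- specimen_record("u", host_species = "Clupea harengus")
  expect_error(identify_specimen(r, key), "Pellonula leonensis")
})

test_that("adding a measurement never enlarges the candidate set for
           range-recoverable species", {
  rec <- key_recoverable_species()
  ok_species <- rec$species[rec$recoverable]
  cfg <- simulation_config(ok_species, n_per_species = 5, seed = 21,
                           missing_rates = c(hVII = 0),
                           default_missing_rate = 0)
  sims <- suppressWarnings(simulate_specimens(cfg))
  set.seed(22)
  for (i in sample(nrow(sims), 20)) {
    r <- sims[i, , drop = FALSE]
    full <- identify_specimen(r, key)$candidates
    drop_param <- sample(kg_params()[!is.na(unlist(r[1, kg_params()]))], 1)
    r2 <- r
    r2[[drop_param]] <- NA_real_
    reduced <- identify_specimen(r2, key)$candidates
    expect_true(all(full %in% reduced),
                info = paste(r$specimen_id, "drop", drop_param))
  }
})

test_that("with host information candidates are hosts' recorded species", {
  rec <- key_recoverable_species()
  ok_species <- rec$species[rec$recoverable]
  cfg <- simulation_config(ok_species, n_per_species = 5, seed = 31,
                           missing_rates = c(hVII = 0),
                           default_missing_rate = 0)
  sims <- suppressWarnings(simulate_specimens(cfg))
  hosts <- key_terminal_hosts(key)
  res <- identify_specimens(sims, key, use_host = TRUE)
  for (i in seq_along(res)) {
    for (sp in res[[i]]$candidates)
      expect_true(sims$host_species[i] %in% hosts[[sp]])
  }
})

test_that("strict and annotated modes route identically; annotated warns", {
  r <- specimen_record("m1", host_species = "Microthrissa royauxi",
                       da_inner = 15.4, hI = 12.2, hVI = 13.3, hVII = 13.7,
                       ap_side = "left")
  strict <- identify_specimen(r, kapentagyrus_key("strict"))
  annot <- identify_specimen(r, kapentagyrus_key("annotated"))
  expect_identical(strict$candidates, annot$candidates)
  expect_identical(strict$path, annot$path)
  expect_true(any(grepl("annotated", annot$notes)))
  expect_false(any(grepl("annotated", strict$notes)))
})

test_that("the key survives a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  key_to_json(key, path)
  k2 <- key_from_json(path)
  expect_length(k2$couplets, 13)
  r <- full_specimen()
  expect_identical(identify_specimen(r, key)$candidates,
                   identify_specimen(r, k2)$candidates)
})

test_that("routing the reference means recovers terminals with the known
           exceptions", {
  v <- validate_key(key = key)
  expect_equal(nrow(v), 12)
  expect_equal(sum(v$own_terminal_recovered), 11)
  expect_identical(v$species[!v$own_terminal_recovered], "K. boegeri")
  exc <- attr(v, "exceptions")
  expect_true(any(grepl("K. boegeri", exc)))
  expect_true(any(grepl("chochamandai ex Potamothrissa acutirostris", exc)))
  expect_true(any(grepl("couplet 11", exc)))
})
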