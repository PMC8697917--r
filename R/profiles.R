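# -- embedded reference data --------------------------------------------------
#
# The package ships three plain-text fixtures under inst/extdata:
#   morphometry_tables.csv  per-species (min, mean, max, n) measurement
#                           summaries, one column per host where a species
#                           was measured on more than one host
#   host_surveys.csv        the host survey (museum lots), one row per lot
#   infection_reports.csv   per-species, per-locality infection outcomes
# Everything below parses those into the reference objects used by the key,
# the statistics and the simulator.

kg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "kapentagyrus")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Species registry
#'
#' All species the identification key can return, with the hosts each is
#' recorded from, the side from which the accessory piece loops the
#' copulatory tube (`left`/`right`/`unknown`), and whether measurement
#' summaries ship with the package (the two Lake Tanganyika endemics are key
#' terminals only; their measurements were published elsewhere).
#'
#' @return Data frame with columns `species`, `hosts`
#'   (semicolon-separated), `ap_side`, `has_profile`.
#' @export
species_registry <- function() {
  reg <- rbind(
    c("K. voreli",        "Odaxothrissa ansorgii",                         "right",   TRUE),
    c("K. marispastoris", "Odaxothrissa mento",                            "right",   TRUE),
    c("K. sefcae",        "Odaxothrissa losera",                           "left",    TRUE),
    c("K. parisellei",    "Nannothrissa parva",                            "right",   TRUE),
    c("K. hugei",         "Pellonula leonensis",                           "right",   TRUE),
    c("K. hahni",         "Pellonula leonensis",                           "right",   TRUE),
    c("K. verbisti",      "Pellonula leonensis",                           "unknown", TRUE),
    c("K. chochamandai",  "Microthrissa moeruensis;Potamothrissa acutirostris", "left", TRUE),
    c("K. bisthoveni",    "Microthrissa congica",                          "right",   TRUE),
    c("K. boegeri",       "Microthrissa congica",                          "left",    TRUE),
    c("K. rochetteae",    "Microthrissa royauxi",                          "left",    TRUE),
    c("K. pellonulae",    "Pellonula leonensis",                           "unknown", TRUE),
    c("K. limnotrissae",  "Limnothrissa miodon",                           "unknown", FALSE),
    c("K. tanganicanus",  "Limnothrissa miodon;Stolothrissa tanganicae",   "unknown", FALSE)
  )
  data.frame(species = reg[, 1], hosts = reg[, 2], ap_side = reg[, 3],
             has_profile = as.logical(reg[, 4]), stringsAsFactors = FALSE)
}

registry_hosts <- function(species) {
  reg <- species_registry()
  strsplit(reg$hosts[match(species, reg$species)], ";", fixed = TRUE)
}

#' All host species known from the survey and registry
#' @return Character vector of host binomials.
#' @export
host_registry <- function() {
  sort(unique(c(unlist(registry_hosts(species_registry()$species)),
                builtin_surveys()$host_species)))
}

#' Built-in species measurement profiles
#'
#' Parses the embedded measurement summary tables into one profile per
#' species (12 profiles: 11 newly described species plus the previously
#' described congener measured on the same host genus). A species measured
#' on two hosts carries one measurement column per host. Cells printed as a
#' range without an average get a midpoint working mean, flagged as imputed.
#'
#' @return A list of `kg_profile` objects (class `kg_profiles`). Each
#'   profile has `species`, `ap_side`, `hosts` (measurement columns, type
#'   host first) and `columns`: a named list of summary data frames with
#'   columns `param`, `min`, `mean`, `max`, `n`, `working_mean`, `imputed`.
#' @examples
#' p <- builtin_profiles()
#' length(p)  # 12
#' @export
builtin_profiles <- function() {
  tab <- read.csv(kg_extdata("morphometry_tables.csv"),
                  stringsAsFactors = FALSE)
  reg <- species_registry()
  out <- list()
  for (sp in unique(tab$species)) {
    sub <- tab[tab$species == sp, , drop = FALSE]
    cols <- list()
    for (h in unique(sub$host)) {
      s <- sub[sub$host == h, c("param", "min", "mean", "max", "n")]
      bad <- with(s, which(!is.na(min) & !is.na(mean) & !is.na(max) &
                             !(min <= mean & mean <= max)))
      if (length(bad))
        stop(sp, ": summary violates min <= mean <= max for ",
             paste(s$param[bad], collapse = ", "))
      s$imputed <- is.na(s$mean) & !is.na(s$min) & !is.na(s$max)
      s$working_mean <- ifelse(s$imputed, (s$min + s$max) / 2, s$mean)
      rownames(s) <- NULL
      cols[[h]] <- s
    }
    out[[sp]] <- structure(
      list(species = sp,
           ap_side = reg$ap_side[match(sp, reg$species)],
           hosts = names(cols),
           is_new = !(sp %in% "K. pellonulae"),
           columns = cols),
      class = "kg_profile")
  }
  structure(out, class = "kg_profiles")
}

#' @export
print.kg_profile <- function(x, ...) {
  cat(sprintf("<kg_profile> %s (%s), hosts: %s\n", x$species,
              if (x$is_new) "n. sp." else "previously described",
              paste(x$hosts, collapse = ", ")))
  cat(sprintf("  accessory piece loop: %s; %d measurement column(s)\n",
              x$ap_side, length(x$columns)))
  invisible(x)
}

#' @export
print.kg_profiles <- function(x, ...) {
  cat(sprintf("<kg_profiles> %d species profiles\n", length(x)))
  for (p in x)
    cat(sprintf("  %-17s hosts: %s\n", p$species,
                paste(p$hosts, collapse = ", ")))
  invisible(x)
}

#' Access a profile's summary column
#'
#' @param profile A `kg_profile`.
#' @param host Measurement column to use (default: type host).
#' @return The summary data frame (`param`, `min`, `mean`, `max`, `n`,
#'   `imputed`, `working_mean`).
#' @export
profile_summary_table <- function(profile, host = NULL) {
  if (is.null(host)) host <- profile$hosts[1]
  tab <- profile$columns[[host]]
  if (is.null(tab))
    stop(profile$species, ": no measurement column for host ", host)
  tab
}

#' @rdname profile_summary_table
#' @param tab A summary table from `profile_summary_table()`.
#' @param param Parameter name.
#' @param what Which summary statistic (`"min"`, `"mean"`, `"max"`, `"n"`,
#'   `"working_mean"`).
#' @export
profile_value <- function(tab, param, what = "working_mean") {
  i <- match(param, tab$param)
  if (is.na(i)) NA_real_ else tab[[what]][i]
}

#' Mean reference specimen for a profile
#'
#' Builds a synthetic specimen whose measurements are the working means of a
#' profile's summary column — the "typical individual" used to exercise the
#' identification key against the reference tables.
#'
#' @param profile A `kg_profile`.
#' @param host Which measurement column to use; defaults to the type host
#'   (first column).
#' @return One-row specimen data frame.
#' @export
profile_mean_specimen <- function(profile, host = NULL) {
  if (is.null(host)) host <- profile$hosts[1]
  tab <- profile_summary_table(profile, host)
  vals <- lapply(kg_params(), function(p) profile_value(tab, p))
  names(vals) <- kg_params()
  vals <- vals[!vapply(vals, is.na, logical(1))]
  do.call(specimen_record, c(
    list(specimen_id = paste0(gsub("[. ]+", "_", profile$species), "_mean_",
                              gsub(" ", "_", host)),
         species_label = profile$species, host_species = host,
         locality = "reference tables", country = "",
         ap_side = profile$ap_side),
    vals))
}

#' Consistency of printed proportion rows
#'
#' The reference tables print both raw length summaries and proportion rows
#' (mean of per-specimen ratios). Because a mean of ratios differs from a
#' ratio of means, the two need not agree exactly; this check compares the
#' printed mean proportion against the ratio of the corresponding mean
#' lengths and flags rows that differ by more than `tol`.
#'
#' @param profiles Output of [builtin_profiles()].
#' @param tol Absolute tolerance on the ratio scale.
#' @return Data frame with one row per printed proportion cell and a
#'   `consistent` flag; inconsistent rows are reported, not an error.
#' @export
check_proportions <- function(profiles = builtin_profiles(), tol = 0.25) {
  ops <- list(da_prop_io = c("da_inner", "da_outer"),
              va_prop_io = c("va_inner", "va_outer"),
              da_prop_ir_hI = c("da_inner", "hI"),
              va_prop_ir_hI = c("va_inner", "hI"))
  rows <- list()
  for (p in profiles) for (h in p$hosts) {
    tab <- profile_summary_table(p, h)
    for (prop in names(ops)) {
      printed <- profile_value(tab, prop, "mean")
      num <- profile_value(tab, ops[[prop]][1], "mean")
      den <- profile_value(tab, ops[[prop]][2], "mean")
      if (is.na(printed) || is.na(num) || is.na(den)) next
      rows[[length(rows) + 1]] <- data.frame(
        species = p$species, host = h, param = prop, printed = printed,
        ratio_of_means = num / den,
        consistent = abs(printed - num / den) <= tol,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# -- survey fixtures ----------------------------------------------------------

#' Locality alias map
#'
#' The survey table is the canonical authority for locality spellings; the
#' per-species infection paragraphs use a handful of variants. This map
#' normalizes variants to the canonical spelling.
#'
#' @return Named character vector `variant -> canonical`.
#' @export
locality_aliases <- function() {
  c("Manianga"            = "Manyanga",
    "Aboume"              = "Aboun, Noya River",
    "Noya River"          = "Aboun, Noya River",
    "Atena Island, Kinshasa" = "Kinshasa",
    "Leopoldville"        = "Kinshasa",
    "Sankuru River"       = "Inkongo, Sankuru River",
    "Coquilhatville"      = "Mbandaka")
}

#' @rdname locality_aliases
#' @param locality Character vector of locality names.
#' @export
canonical_locality <- function(locality) {
  al <- locality_aliases()
  hit <- match(locality, names(al))
  ifelse(is.na(hit), locality, al[hit])
}

parse_counts <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Built-in infection reports
#'
#' One record per species-by-locality infection outcome, including the
#' zero-infection screenings. `worm_counts` is a list column of per-infected-
#' host worm counts; reports whose counts are only bounded by a printed range
#' and intensity carry `resolved = FALSE` and expose `n_infected` plus the
#' printed intensity without a per-host vector.
#'
#' @return Data frame of survey records with a `worm_counts` list column.
#' @export
builtin_infections <- function() {
  inf <- read.csv(kg_extdata("infection_reports.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(worm_counts = "character"))
  inf$worm_counts <- parse_counts(inf$worm_counts)
  chk <- vapply(seq_len(nrow(inf)), function(i) {
    wc <- inf$worm_counts[[i]]
    !inf$resolved[i] || length(wc) == inf$n_infected[i]
  }, logical(1))
  stopifnot(all(chk), inf$n_infected <= inf$n_examined)
  inf
}

#' Built-in host survey
#'
#' The host survey table: one record per examined museum lot (or fresh
#' sample), with host species, locality, country and the number of host
#' specimens examined. Worm counts from the infection reports are attached
#' where a report maps one-to-one onto a survey row; pooled reports (one
#' paragraph covering several lots) leave `worm_counts` as `NA` on each row
#' and are available in full from [builtin_infections()].
#'
#' @return Data frame with one row per lot, `worm_counts` list column and
#'   `parasite_species`.
#' @examples
#' sum(builtin_surveys()$n_examined)  # 172 examined host fish
#' @export
builtin_surveys <- function() {
  sv <- read.csv(kg_extdata("host_surveys.csv"), stringsAsFactors = FALSE)
  inf <- builtin_infections()
  sv$parasite_species <- inf$species[match(sv$report_key, inf$report_key)]
  rows_per_key <- table(sv$report_key)
  sv$worm_counts <- vector("list", nrow(sv))
  for (i in seq_len(nrow(sv))) {
    key <- sv$report_key[i]
    j <- match(key, inf$report_key)
    one_to_one <- rows_per_key[[key]] == 1 && !is.na(j) &&
      inf$n_examined[j] == sv$n_examined[i]
    sv$worm_counts[[i]] <- if (one_to_one && inf$resolved[j])
      inf$worm_counts[[j]] else NA
  }
  sv
}
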