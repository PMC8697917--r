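# -- identification parameter recovery ----------------------------------------
#
# A species counts as range-recoverable when every couplet on its reference
# decision path is decided to a unique lead for the *whole* printed
# [min, max] box of its profile (printed proportion rows are used for ratio
# conditions where available, otherwise the interval implied by the operand
# ranges). For such species, specimens simulated inside the printed ranges
# must be routed to the species' own terminal essentially always; species
# whose ranges straddle a key threshold, lack a needed measurement, or hit a
# documented inconsistency of the printed key are exempt and reported.

# interval of possible values for a condition subject, from a summary table;
# NULL when the subject cannot be evaluated at all
subject_interval <- function(subject, tab) {
  ratio_ops <- list(da_root_ratio = c("da_inner", "da_outer"),
                    va_root_ratio = c("va_inner", "va_outer"),
                    da_inner_over_h1 = c("da_inner", "hI"),
                    va_inner_over_h1 = c("va_inner", "hI"),
                    da_ltn_over_h1 = c("da_ltn", "hI"),
                    db_branch_over_h1 = c("db_len", "hI"))
  prop_rows <- c(da_root_ratio = "da_prop_io", va_root_ratio = "va_prop_io",
                 da_inner_over_h1 = "da_prop_ir_hI",
                 va_inner_over_h1 = "va_prop_ir_hI")
  range_of <- function(param) {
    i <- match(param, tab$param)
    if (is.na(i)) return(NULL)
    lo <- tab$min[i]; hi <- tab$max[i]
    if (is.na(lo) || is.na(hi)) {
      wm <- tab$working_mean[i]
      if (is.na(wm)) return(NULL)
      lo <- hi <- wm
    }
    c(lo, hi)
  }
  if (subject %in% tab$param) return(range_of(subject))
  if (subject %in% names(ratio_ops)) {
    if (subject %in% names(prop_rows)) {
      r <- range_of(prop_rows[[subject]])
      if (!is.null(r)) return(r)
    }
    num <- range_of(ratio_ops[[subject]][1])
    den <- range_of(ratio_ops[[subject]][2])
    if (is.null(num) || is.null(den)) return(NULL)
    return(c(num[1] / den[2], num[2] / den[1]))
  }
  NULL
}

# possible truth statuses ("T", "F", "NA") of one condition over the box
condition_statuses <- function(cond, tab, host, ap_side) {
  if (cond$kind %in% c("measurement", "ratio")) {
    iv <- subject_interval(cond$subject, tab)
    if (is.null(iv)) return("NA")
    at <- function(v) isTRUE(apply_op(v, cond$op, cond$threshold))
    lo <- at(iv[1]); hi <- at(iv[2])
    if (lo && hi) "T" else if (!lo && !hi) {
      # monotone comparators: interior cannot differ from both endpoints
      "F"
    } else c("T", "F")
  } else if (cond$kind == "host") {
    if (host %in% cond$threshold) "T" else "F"
  } else if (cond$kind == "categorical") {
    if (is.na(ap_side) || ap_side == "unknown") "NA"
    else if (ap_side %in% cond$threshold) "T" else "F"
  } else if (cond$kind == "qualitative") {
    "T"  # unscored character is ignored, as in identification
  } else stop("unknown condition kind")
}

status_and <- function(A, B) {
  unique(unlist(lapply(A, function(a) lapply(B, function(b) {
    if (a == "F" || b == "F") "F" else if (a == "NA" || b == "NA") "NA"
    else "T"
  }))))
}

status_not <- function(A)
  unique(vapply(A, function(a) switch(a, T = "F", F = "T", "NA"), character(1)))

lead_statuses <- function(ld, tab, host, ap_side, sibling = NULL) {
  if (isTRUE(ld$complement))
    return(status_not(lead_statuses(sibling, tab, host, ap_side)))
  out <- "T"
  for (cond in ld$conditions)
    out <- status_and(out, condition_statuses(cond, tab, host, ap_side))
  out
}

# robust decision at a couplet over the whole box: unique lead or NA
robust_decision <- function(cpl, tab, host, ap_side) {
  SA <- lead_statuses(cpl$a, tab, host, ap_side, sibling = cpl$b)
  SB <- lead_statuses(cpl$b, tab, host, ap_side, sibling = cpl$a)
  to_logical <- function(s) switch(s, T = TRUE, F = FALSE, NA)
  decs <- unique(unlist(lapply(SA, function(sa) lapply(SB, function(sb)
    decide_couplet(to_logical(sa), to_logical(sb))))))
  if (length(decs) == 1 && decs != "both") decs else NA_character_
}

#' Range-recoverable species
#'
#' Determines, for each embedded profile, whether the printed measurement
#' ranges guarantee a unique decision at every couplet on the species'
#' path — i.e. whether any specimen drawn inside the printed ranges (with
#' host information) must reach the species' own terminal.
#'
#' @param profiles Output of [builtin_profiles()].
#' @param key A `kg_key`.
#' @return Data frame with `species`, `recoverable`, and `reason` for the
#'   species that are not.
#' @export
key_recoverable_species <- function(profiles = builtin_profiles(),
                                    key = kapentagyrus_key()) {
  rows <- lapply(profiles, function(p) {
    h <- p$hosts[1]
    tab <- profile_summary_table(p, h)
    id <- 1L
    reason <- NA_character_
    terminal <- NA_character_
    repeat {
      cpl <- key$couplets[[id]]
      dec <- robust_decision(cpl, tab, h, p$ap_side)
      if (is.na(dec)) {
        reason <- sprintf("couplet %d not decided by the printed ranges", id)
        break
      }
      ld <- cpl[[dec]]
      if (!is.null(ld$species)) { terminal <- ld$species; break }
      id <- ld$goto
    }
    recoverable <- !is.na(terminal) && terminal == p$species
    if (is.na(reason) && !recoverable)
      reason <- sprintf("ranges route to %s", terminal)
    data.frame(species = p$species, recoverable = recoverable,
               reason = if (recoverable) NA_character_ else reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assess identification recovery on simulated specimens
#'
#' Simulates `n_per_species` specimens per embedded species (no missing
#' data), identifies each with the key using host information, and reports
#' per-species accuracy (fraction of specimens whose sole candidate is the
#' generating species) together with a confusion matrix and the
#' range-recoverability flags of [key_recoverable_species()].
#'
#' @param n_per_species Specimens per species.
#' @param seed Integer seed.
#' @param profiles Output of [builtin_profiles()].
#' @param key A `kg_key`.
#' @return A `kg_recovery` object: `accuracy` data frame (species,
#'   accuracy, recoverable, reason), `confusion` matrix (true species x
#'   assigned outcome, with `ambiguous` and `other` columns), `n_per_species`.
#' @export
assess_recovery <- function(n_per_species = 1000, seed = 1L,
                            profiles = builtin_profiles(),
                            key = kapentagyrus_key()) {
  cfg <- simulation_config("all", n_per_species = n_per_species, seed = seed,
                           missing_rates = c(hVII = 0),
                           default_missing_rate = 0)
  sims <- suppressWarnings(simulate_specimens(cfg, profiles))
  ids <- identify_specimens(sims, key, use_host = TRUE)
  s <- as.data.frame(ids)
  assigned <- ifelse(s$n_candidates == 1, s$candidates, "ambiguous")
  species <- names(profiles)
  lvl <- c(species, setdiff(unique(assigned), species))
  confusion <- table(true = factor(sims$species_label, levels = species),
                     assigned = factor(assigned, levels = lvl))
  acc <- vapply(species, function(sp) {
    sel <- sims$species_label == sp
    mean(assigned[sel] == sp)
  }, numeric(1))
  rec <- key_recoverable_species(profiles, key)
  accuracy <- data.frame(species = species, accuracy = unname(acc),
                         stringsAsFactors = FALSE)
  accuracy <- merge(accuracy, rec, by = "species", sort = FALSE)
  structure(list(accuracy = accuracy, confusion = confusion,
                 n_per_species = n_per_species, seed = seed),
            class = "kg_recovery")
}

#' @export
print.kg_recovery <- function(x, ...) {
  cat(sprintf("<kg_recovery> %d simulated specimens per species (seed %d)\n",
              x$n_per_species, x$seed))
  a <- x$accuracy
  a$accuracy <- sprintf("%.1f%%", 100 * a$accuracy)
  print.data.frame(a, right = FALSE)
  cat("confusion matrix in $confusion\n")
  invisible(x)
}
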