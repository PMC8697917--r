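# -- quantitative parasitology ------------------------------------------------
#
# Standard definitions: prevalence = infected hosts / examined hosts;
# mean intensity = worms / infected hosts (undefined with no infected host);
# mean abundance = worms / examined hosts.

#' Round half away from zero
#'
#' The reporting convention used for infection parameters rounds halves up
#' (11/8 = 1.375 prints as 1.4), unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize an infection survey
#'
#' Computes prevalence, mean intensity and mean abundance from a survey
#' record: the number of hosts examined and the worm count of each infected
#' host. Arithmetic is exact (counts divided once at the end); rounding is
#' applied only by the print method, to one decimal.
#'
#' @param survey Either a list/data-frame row with fields `n_examined` and
#'   `worm_counts`, or the `worm_counts` vector itself (then pass
#'   `n_examined`).
#' @param n_examined Number of hosts examined (when `survey` is a bare
#'   counts vector).
#' @return A `kg_infection` object: `n_examined`, `n_infected`,
#'   `total_worms`, `prevalence`, `mean_intensity` (`NA` when no host is
#'   infected), `mean_abundance`.
#' @examples
#' s <- summarize_infection(c(3, 16), n_examined = 2)
#' s$mean_intensity  # 9.5
#' @export
summarize_infection <- function(survey, n_examined = NULL) {
  if (is.numeric(survey) || (is.null(survey) && !is.null(n_examined))) {
    counts <- as.numeric(survey)
  } else {
    counts <- survey$worm_counts
    if (is.list(counts)) counts <- counts[[1]]
    counts <- as.numeric(counts)
    n_examined <- survey$n_examined
  }
  if (is.null(n_examined) || is.na(n_examined) || n_examined < 1)
    stop("n_examined must be a positive count")
  if (anyNA(counts))
    stop("worm counts are unresolved for this record; per-host counts are ",
         "required to summarize")
  if (length(counts) > n_examined)
    stop("more infected hosts than hosts examined")
  if (any(counts < 1)) stop("each infected host carries at least one worm")
  n_inf <- length(counts)
  total <- sum(counts)
  structure(list(
    n_examined = as.integer(n_examined),
    n_infected = n_inf,
    total_worms = total,
    prevalence = n_inf / n_examined,
    mean_intensity = if (n_inf > 0) total / n_inf else NA_real_,
    mean_abundance = total / n_examined
  ), class = "kg_infection")
}

#' @export
print.kg_infection <- function(x, ...) {
  cat(sprintf(
    "infection summary: %d/%d hosts infected (prevalence %s), %d worms\n",
    x$n_infected, x$n_examined,
    format(round_half_up(x$prevalence, 2)), x$total_worms))
  cat(sprintf("  mean intensity %s, mean abundance %s\n",
              if (is.na(x$mean_intensity)) "undefined"
              else format(round_half_up(x$mean_intensity, 1)),
              format(round_half_up(x$mean_abundance, 1))))
  invisible(x)
}

#' Pool surveys
#'
#' Pools several survey records into one; prevalence of the pool is the
#' examined-host-weighted mean of the parts.
#'
#' @param ... `kg_infection` objects or survey records accepted by
#'   [summarize_infection()].
#' @return A pooled `kg_infection`.
#' @export
pool_surveys <- function(...) {
  parts <- list(...)
  parts <- lapply(parts, function(p)
    if (inherits(p, "kg_infection")) p else summarize_infection(p))
  n_ex <- sum(vapply(parts, `[[`, numeric(1), "n_examined"))
  n_inf <- sum(vapply(parts, `[[`, numeric(1), "n_infected"))
  total <- sum(vapply(parts, `[[`, numeric(1), "total_worms"))
  structure(list(
    n_examined = as.integer(n_ex), n_infected = as.integer(n_inf),
    total_worms = total, prevalence = n_inf / n_ex,
    mean_intensity = if (n_inf > 0) total / n_inf else NA_real_,
    mean_abundance = total / n_ex
  ), class = "kg_infection")
}

#' Infection summaries for all built-in reports
#'
#' Applies [summarize_infection()] to every resolved built-in infection
#' report; unresolved reports (counts only bounded by a printed range) are
#' carried through with the printed intensity and no computed one.
#'
#' @return Data frame, one row per report, with computed prevalence,
#'   mean intensity and mean abundance alongside the printed intensity.
#' @export
summarize_builtin_infections <- function() {
  inf <- builtin_infections()
  rows <- lapply(seq_len(nrow(inf)), function(i) {
    base <- data.frame(
      report_key = inf$report_key[i], species = inf$species[i],
      host_species = inf$host_species[i], locality = inf$locality[i],
      n_examined = inf$n_examined[i], n_infected = inf$n_infected[i],
      printed_intensity = inf$printed_intensity[i],
      stringsAsFactors = FALSE)
    if (inf$resolved[i]) {
      s <- summarize_infection(inf$worm_counts[[i]], inf$n_examined[i])
      base$prevalence <- s$prevalence
      base$mean_intensity <- s$mean_intensity
      base$mean_abundance <- s$mean_abundance
    } else {
      base$prevalence <- inf$n_infected[i] / inf$n_examined[i]
      base$mean_intensity <- NA_real_
      base$mean_abundance <- NA_real_
    }
    base
  })
  do.call(rbind, rows)
}
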