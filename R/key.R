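# -- the identification key as an executable decision tree -------------------
#
# 13 couplets, 14 terminal species. Each lead is a conjunction of atomic
# conditions over measurements (um), diagnostic ratios, the accessory-piece
# loop side, a qualitative anchor-root character, or the host identity.
# Condition evaluation is three-valued (TRUE / FALSE / NA for "cannot be
# evaluated"); couplet decision semantics are documented at eval_couplet().

cond_m <- function(param, op, threshold)
  list(kind = "measurement", subject = param, op = op, threshold = threshold)
cond_f <- function(feature, op, threshold)
  list(kind = "ratio", subject = feature, op = op, threshold = threshold)
cond_host <- function(hosts)
  list(kind = "host", subject = "host_species", op = "in", threshold = hosts)
cond_side <- function(side)
  list(kind = "categorical", subject = "ap_side", op = "in", threshold = side)
cond_broad <- function()
  list(kind = "qualitative", subject = "broad_roots", op = "is", threshold = TRUE)

lead <- function(conditions = list(), goto = NULL, species = NULL,
                 complement = FALSE) {
  stopifnot(is.null(goto) || is.null(species))
  list(conditions = conditions, goto = goto, species = species,
       complement = complement)
}

ODAX_HOSTS  <- c("Odaxothrissa ansorgii", "Odaxothrissa mento",
                 "Odaxothrissa losera")
TANG_HOSTS  <- c("Limnothrissa miodon", "Stolothrissa tanganicae")
MICRO_HOSTS <- c("Microthrissa congica", "Microthrissa moeruensis",
                 "Microthrissa royauxi")

#' Build the printed identification key
#'
#' Constructs the dichotomous key to the fourteen species of
#' *Kapentagyrus* as a decision tree: 13 couplets rooted at couplet 1, each
#' lead either forwarding to another couplet or terminating in a species.
#' The key is built exactly as printed; `mode = "annotated"` routes
#' identically but attaches warnings at the couplets where the printed key
#' conflicts with the species descriptions (accessory-piece loop side at
#' couplet 11; the couplet-10 dorsal root/hook ratio for one species; the
#' couplet-13 length-to-notch boundary for a two-host species). Graph
#' invariants (single root, acyclic, all 14 terminals reachable) are
#' asserted at build time.
#'
#' @param mode `"strict"` (default, exactly as printed) or `"annotated"`.
#' @return A `kg_key` object: list of couplets plus terminal/host metadata.
#' @examples
#' k <- kapentagyrus_key()
#' length(key_terminals(k))  # 14
#' @export
kapentagyrus_key <- function(mode = c("strict", "annotated")) {
  mode <- match.arg(mode)
  cp <- list()
  cp[[1]] <- list(
    id = 1L,
    a = lead(list(cond_m("va_ltn", ">", 24), cond_broad(),
                  cond_m("da_total", ">", 31), cond_host(ODAX_HOSTS)),
             goto = 2L),
    b = lead(complement = TRUE, goto = 4L))
  cp[[2]] <- list(
    id = 2L,
    a = lead(list(cond_m("va_total", ">", 40), cond_m("va_inner", ">", 22)),
             species = "K. sefcae"),
    b = lead(list(cond_m("va_total", "<", 40), cond_m("va_inner", "<", 22)),
             goto = 3L))
  cp[[3]] <- list(
    id = 3L,
    a = lead(list(cond_m("da_inner", ">", 18), cond_m("da_outer", ">", 7)),
             species = "K. marispastoris"),
    b = lead(list(cond_m("da_inner", "<", 18), cond_m("da_outer", "<", 7)),
             species = "K. voreli"))
  cp[[4]] <- list(
    id = 4L,
    a = lead(list(cond_host(TANG_HOSTS)), goto = 5L),
    b = lead(list(cond_host(c("Nannothrissa parva", "Pellonula leonensis",
                              "Potamothrissa acutirostris", MICRO_HOSTS))),
             goto = 6L))
  cp[[5]] <- list(
    id = 5L,
    a = lead(list(cond_f("va_root_ratio", ">", 2.6),
                  cond_f("da_ltn_over_h1", "<", 1.2),
                  cond_f("db_branch_over_h1", "<", 1.5)),
             species = "K. limnotrissae"),
    b = lead(list(cond_f("va_root_ratio", "<", 2.6),
                  cond_f("da_ltn_over_h1", ">", 1.2),
                  cond_f("db_branch_over_h1", ">", 1.5)),
             species = "K. tanganicanus"))
  cp[[6]] <- list(
    id = 6L,
    a = lead(list(cond_host("Pellonula leonensis")), goto = 7L),
    b = lead(list(cond_host(c("Nannothrissa parva",
                              "Potamothrissa acutirostris", MICRO_HOSTS))),
             goto = 10L))
  cp[[7]] <- list(
    id = 7L,
    a = lead(list(cond_m("da_total", ">=", 40), cond_m("va_total", ">=", 40)),
             species = "K. pellonulae"),
    b = lead(list(cond_m("da_total", "<", 40), cond_m("va_total", "<", 40)),
             goto = 8L))
  cp[[8]] <- list(
    id = 8L,
    a = lead(list(cond_m("da_total", ">=", 35), cond_m("da_total", "<", 40)),
             species = "K. verbisti"),
    b = lead(list(cond_m("da_total", "<", 35)), goto = 9L))
  cp[[9]] <- list(
    id = 9L,
    a = lead(list(cond_m("va_ltn", "<", 19)), species = "K. hahni"),
    b = lead(list(cond_m("va_ltn", ">=", 19)), species = "K. hugei"))
  cp[[10]] <- list(
    id = 10L,
    a = lead(list(cond_f("da_inner_over_h1", ">", 1)), goto = 11L),
    b = lead(list(cond_f("da_inner_over_h1", "<", 1)), goto = 13L))
  cp[[11]] <- list(
    id = 11L,
    a = lead(list(cond_side("right"), cond_m("hVI", "<", 15),
                  cond_m("hVII", "<", 15)),
             species = "K. rochetteae"),
    b = lead(list(cond_side("left"), cond_m("hVI", ">", 15),
                  cond_m("hVII", ">", 15)),
             goto = 12L))
  cp[[12]] <- list(
    id = 12L,
    a = lead(list(cond_m("da_inner", "<", 12)), species = "K. boegeri"),
    b = lead(list(cond_m("da_inner", ">=", 12)), species = "K. bisthoveni"))
  cp[[13]] <- list(
    id = 13L,
    a = lead(list(cond_m("va_ltn", "<", 19)), species = "K. parisellei"),
    b = lead(list(cond_m("va_ltn", ">", 19)), species = "K. chochamandai"))
  key <- structure(list(couplets = cp, mode = mode,
                        registry = species_registry()),
                   class = "kg_key")
  assert_key_graph(key)
  key
}

# warnings emitted in annotated mode, by couplet
kg_key_annotations <- function() {
  list(
    `10` = paste("the table means of K. boegeri place its dorsal inner",
                 "root/hook I ratio below 1, while the printed key resolves",
                 "the species on the '> 1' side at couplet 12"),
    `11` = paste("the printed key sends accessory-piece-right worms to",
                 "K. rochetteae, but the species descriptions give the loop",
                 "from the left in K. rochetteae and from the right in",
                 "K. bisthoveni"),
    `13` = paste("K. chochamandai ex Potamothrissa acutirostris has length",
                 "to notch of the ventral anchor 18.5 um, conflicting with",
                 "the '> 19 um' lead that names it"))
}

#' Terminal species of a key
#' @param key A `kg_key`.
#' @return Character vector of terminal species names.
#' @export
key_terminals <- function(key) {
  unlist(lapply(key$couplets, function(cpl)
    c(cpl$a$species, cpl$b$species)))
}

#' Hosts attached to the key terminals
#' @param key A `kg_key`.
#' @return Named list, species -> host species vector.
#' @export
key_terminal_hosts <- function(key) {
  term <- key_terminals(key)
  setNames(registry_hosts(term), term)
}

assert_key_graph <- function(key) {
  ids <- vapply(key$couplets, `[[`, integer(1), "id")
  stopifnot(identical(ids, seq_along(ids)))
  for (cpl in key$couplets) for (ld in list(cpl$a, cpl$b)) {
    if (!is.null(ld$goto)) stopifnot(ld$goto %in% ids)
    if (!is.null(ld$species))
      stopifnot(ld$species %in% key$registry$species)
  }
  # reachability + acyclicity from the single root
  seen_terminals <- character()
  visit <- function(id, stack) {
    if (id %in% stack) stop("cycle in key at couplet ", id)
    cpl <- key$couplets[[id]]
    for (ld in list(cpl$a, cpl$b)) {
      if (!is.null(ld$species))
        seen_terminals <<- union(seen_terminals, ld$species)
      else visit(ld$goto, c(stack, id))
    }
  }
  visit(1L, integer(0))
  stopifnot(length(seen_terminals) == 14L)
  # no couplet other than the root is unreachable
  invisible(TRUE)
}

#' @export
print.kg_key <- function(x, ...) {
  cat(sprintf("<kg_key> %d couplets, %d terminal species (mode: %s)\n",
              length(x$couplets), length(key_terminals(x)), x$mode))
  invisible(x)
}

# -- condition evaluation -----------------------------------------------------

kleene_and <- function(a, b) {
  if (isFALSE(a) || isFALSE(b)) FALSE
  else if (is.na(a) || is.na(b)) NA
  else TRUE
}

apply_op <- function(value, op, threshold) {
  if (is.na(value)) return(NA)
  switch(op,
         "<"  = value < threshold,
         "<=" = value <= threshold,
         ">"  = value > threshold,
         ">=" = value >= threshold,
         "in" = value %in% threshold,
         stop("unknown comparator ", op))
}

# ctx: list(values = named numerics (params + features), host, ap_side,
#           broad_roots, use_host)
eval_condition <- function(cond, ctx) {
  switch(cond$kind,
    measurement = ,
    ratio = apply_op(unname(ctx$values[cond$subject]), cond$op,
                     cond$threshold),
    host = {
      if (!ctx$use_host || is.na(ctx$host)) NA
      else apply_op(ctx$host, "in", cond$threshold)
    },
    categorical = {
      if (is.na(ctx$ap_side) || ctx$ap_side == "unknown") NA
      else apply_op(ctx$ap_side, "in", cond$threshold)
    },
    qualitative = {
      # no numeric definition exists for this character; when unscored the
      # remaining quantitative conditions alone decide
      if (is.na(ctx$broad_roots)) TRUE else isTRUE(ctx$broad_roots)
    },
    stop("unknown condition kind"))
}

eval_lead <- function(ld, ctx, sibling = NULL) {
  if (isTRUE(ld$complement)) {
    s <- eval_lead(sibling, ctx)
    return(if (is.na(s)) NA else !s)
  }
  out <- TRUE
  for (cond in ld$conditions) out <- kleene_and(out, eval_condition(cond, ctx))
  out
}

# Decision semantics at a couplet, from the two lead statuses (T/F/NA):
#  - a lead that alone is TRUE is taken;
#  - if one lead is definitively FALSE and the other unknown, the dichotomy
#    forces the non-FALSE lead;
#  - otherwise (both TRUE, both FALSE -- including boundary ties where a
#    value equals a strict threshold -- or both unknown) the couplet is
#    undecided and both leads are explored.
decide_couplet <- function(sa, sb) {
  if (isTRUE(sa) && !isTRUE(sb)) "a"
  else if (isTRUE(sb) && !isTRUE(sa)) "b"
  else if (isFALSE(sa) && is.na(sb)) "b"
  else if (isFALSE(sb) && is.na(sa)) "a"
  else "both"
}

# which conditions of a lead sit exactly on a strict threshold
boundary_hits <- function(ld, ctx) {
  hits <- character()
  for (cond in ld$conditions) {
    if (cond$kind %in% c("measurement", "ratio") &&
        cond$op %in% c("<", ">")) {
      v <- unname(ctx$values[cond$subject])
      if (!is.na(v) && v == cond$threshold)
        hits <- c(hits, sprintf("%s == %s", cond$subject,
                                format(cond$threshold)))
    }
  }
  hits
}

missing_operands <- function(ld, ctx) {
  out <- character()
  for (cond in ld$conditions) {
    if (cond$kind %in% c("measurement", "ratio")) {
      if (is.na(ctx$values[cond$subject])) out <- c(out, cond$subject)
    } else if (cond$kind == "host") {
      if (!ctx$use_host || is.na(ctx$host)) out <- c(out, "host")
    } else if (cond$kind == "categorical") {
      if (is.na(ctx$ap_side) || ctx$ap_side == "unknown")
        out <- c(out, "ap_side")
    }
  }
  out
}

# -- identification -----------------------------------------------------------

specimen_context <- function(record, features, use_host) {
  vals <- unlist(record[1, kg_params()])
  feats <- unlist(features[1, setdiff(names(features), "specimen_id")])
  host <- record$host_species[1]
  if (use_host && !is.na(host) && !(host %in% host_registry()))
    stop("unknown host species '", host, "'; known hosts: ",
         paste(host_registry(), collapse = ", "))
  list(values = c(vals, feats),
       host = if (is.null(host)) NA_character_ else host,
       ap_side = if (is.null(record$ap_side)) NA_character_
                 else record$ap_side[1],
       broad_roots = if (is.null(record$broad_roots)) NA
                     else record$broad_roots[1],
       use_host = use_host)
}

walk_key <- function(key, ctx) {
  steps <- list()
  notes <- character()
  annotations <- if (key$mode == "annotated") kg_key_annotations() else list()
  visit <- function(id) {
    cpl <- key$couplets[[id]]
    sa <- eval_lead(cpl$a, ctx, sibling = cpl$b)
    sb <- eval_lead(cpl$b, ctx, sibling = cpl$a)
    dec <- decide_couplet(sa, sb)
    steps[[length(steps) + 1]] <<- list(couplet = id, lead = dec)
    ann <- annotations[[as.character(id)]]
    if (!is.null(ann))
      notes <<- union(notes, sprintf("couplet %d (annotated): %s", id, ann))
    if (dec == "both") {
      miss <- union(missing_operands(cpl$a, ctx),
                    missing_operands(cpl$b, ctx))
      bnd <- union(boundary_hits(cpl$a, ctx), boundary_hits(cpl$b, ctx))
      why <- if (length(bnd)) paste("boundary:", paste(bnd, collapse = ", "))
        else if (length(miss)) paste("missing:", paste(miss, collapse = ", "))
        else "neither or both leads satisfied"
      notes <<- c(notes, sprintf("couplet %d undecided (%s)", id, why))
    }
    take <- switch(dec, a = list(cpl$a), b = list(cpl$b),
                   both = list(cpl$a, cpl$b))
    out <- character()
    for (ld in take) {
      out <- union(out, if (!is.null(ld$species)) ld$species
                        else visit(ld$goto))
    }
    out
  }
  candidates <- visit(1L)
  list(candidates = candidates, steps = steps, notes = notes)
}

#' Identify a single specimen with the key
#'
#' Routes one specimen record through the identification key. Evaluation is
#' deterministic; when a couplet cannot be decided (a missing operand, a
#' value exactly on a strict threshold, or neither/both leads satisfied)
#' both leads are explored, the candidate sets are unioned and a note is
#' recorded. With `use_host = TRUE` (default — two couplets are host-based)
#' host conditions are evaluated and terminal candidates are filtered
#' against the hosts each species is recorded from; if that filter would
#' empty the candidate set it is not applied and a note flags the conflict.
#'
#' @param record One-row specimen data frame.
#' @param key A `kg_key` (default: the printed key, strict mode).
#' @param use_host Evaluate host-based conditions and filter terminals by
#'   host? Default `TRUE`; with `FALSE` host couplets are undecided.
#' @param features Optional precomputed feature row ([compute_features()]).
#' @return A `kg_key_result`: `candidates`, `path` (data frame of couplet,
#'   lead in `a`/`b`/`both`), `ambiguous`, `notes`.
#' @export
identify_specimen <- function(record, key = kapentagyrus_key(),
                              use_host = TRUE, features = NULL) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  if (is.null(features)) features <- compute_features(record)
  ctx <- specimen_context(record, features, use_host)
  res <- walk_key(key, ctx)
  candidates <- res$candidates
  notes <- res$notes
  if (use_host && !is.na(ctx$host)) {
    hosts <- key_terminal_hosts(key)
    keep <- vapply(candidates, function(sp) ctx$host %in% hosts[[sp]],
                   logical(1))
    if (any(keep)) {
      if (!all(keep))
        notes <- c(notes, sprintf(
          "host filter (%s) removed: %s", ctx$host,
          paste(candidates[!keep], collapse = ", ")))
      candidates <- candidates[keep]
    } else {
      notes <- c(notes, sprintf(
        "no candidate is recorded from host %s; host filter not applied",
        ctx$host))
    }
  }
  path <- data.frame(
    couplet = vapply(res$steps, `[[`, integer(1), "couplet"),
    lead = vapply(res$steps, `[[`, character(1), "lead"),
    stringsAsFactors = FALSE)
  structure(list(
    specimen_id = record$specimen_id[1],
    candidates = candidates,
    path = path,
    ambiguous = length(candidates) > 1 || any(path$lead == "both"),
    notes = notes
  ), class = "kg_key_result")
}

#' @export
print.kg_key_result <- function(x, ...) {
  cat(sprintf("<kg_key_result> %s -> {%s}%s\n", x$specimen_id,
              paste(x$candidates, collapse = ", "),
              if (x$ambiguous) " [ambiguous]" else ""))
  trace <- paste(sprintf("%d%s", x$path$couplet,
                         ifelse(x$path$lead == "both", "*",
                                paste0(".", x$path$lead))),
                 collapse = " -> ")
  cat("  path: ", trace, "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Identify many specimens
#'
#' Vector interface over [identify_specimen()].
#'
#' @inheritParams identify_specimen
#' @param records Specimen data frame.
#' @return A list of `kg_key_result` plus a `summary` data frame attribute;
#'   use `as.data.frame()` on the return value for the summary.
#' @export
identify_specimens <- function(records, key = kapentagyrus_key(),
                               use_host = TRUE) {
  validate_specimens(records)
  feats <- compute_features(records)
  results <- lapply(seq_len(nrow(records)), function(i)
    identify_specimen(records[i, , drop = FALSE], key, use_host,
                      features = feats[i, , drop = FALSE]))
  summary <- data.frame(
    specimen_id = records$specimen_id,
    candidates = vapply(results, function(r)
      paste(r$candidates, collapse = "; "), character(1)),
    n_candidates = vapply(results, function(r)
      length(r$candidates), integer(1)),
    ambiguous = vapply(results, `[[`, logical(1), "ambiguous"),
    path = vapply(results, function(r)
      paste(r$path$couplet, collapse = ">"), character(1)),
    stringsAsFactors = FALSE)
  structure(results, summary = summary, class = "kg_key_results")
}

#' @export
as.data.frame.kg_key_results <- function(x, ...) attr(x, "summary")

#' @export
print.kg_key_results <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<kg_key_results> %d specimens, %d unambiguous\n",
              nrow(s), sum(!s$ambiguous)))
  print(utils::head(s, 10))
  if (nrow(s) > 10) cat("  ...\n")
  invisible(x)
}

# -- key serialization --------------------------------------------------------

#' Serialize / restore a key as JSON
#'
#' @param key A `kg_key`.
#' @param path File path to write to / read from.
#' @return `key_to_json` writes and returns `path` invisibly;
#'   `key_from_json` returns a `kg_key`.
#' @export
key_to_json <- function(key, path) {
  cps <- lapply(key$couplets, function(cpl) {
    enc_lead <- function(ld) list(
      conditions = lapply(ld$conditions, function(cond)
        list(kind = cond$kind, subject = cond$subject, op = cond$op,
             threshold = cond$threshold)),
      goto = ld$goto, species = ld$species,
      complement = isTRUE(ld$complement))
    list(id = cpl$id, a = enc_lead(cpl$a), b = enc_lead(cpl$b))
  })
  jsonlite::write_json(list(mode = key$mode, couplets = cps), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname key_to_json
#' @export
key_from_json <- function(path) {
  raw <- jsonlite::read_json(path)
  dec_lead <- function(ld) lead(
    conditions = lapply(ld$conditions, function(cond)
      list(kind = cond$kind, subject = cond$subject, op = cond$op,
           threshold = unlist(cond$threshold))),
    goto = if (!is.null(ld$goto)) as.integer(ld$goto),
    species = ld$species,
    complement = isTRUE(ld$complement))
  cps <- lapply(raw$couplets, function(cpl)
    list(id = as.integer(cpl$id), a = dec_lead(cpl$a), b = dec_lead(cpl$b)))
  key <- structure(list(couplets = cps, mode = raw$mode,
                        registry = species_registry()),
                   class = "kg_key")
  assert_key_graph(key)
  key
}

# -- validation of the key against the reference tables -----------------------

#' Route every reference profile through the key
#'
#' Builds the mean reference specimen of each embedded species profile and
#' routes it through the key with host information, reporting the terminal
#' reached, whether the species' own terminal is recovered, and every
#' undecided couplet or host conflict met on the way. For the species
#' measured on two hosts, both measurement columns are routed and the
#' secondary column's outcome is folded into the species' row notes. The
#' known inconsistencies of the printed key are collected in the
#' `exceptions` attribute.
#'
#' @param profiles Output of [builtin_profiles()].
#' @param key A `kg_key`.
#' @param use_host Use host conditions and the host filter (default `TRUE`).
#' @return A `kg_key_validation` data frame (one row per profile) with
#'   attribute `exceptions`.
#' @export
validate_key <- function(profiles = builtin_profiles(),
                         key = kapentagyrus_key(), use_host = TRUE) {
  rows <- list()
  exceptions <- character()
  for (p in profiles) {
    primary <- NULL
    extra_notes <- character()
    for (h in p$hosts) {
      rec <- profile_mean_specimen(p, h)
      res <- identify_specimen(rec, key, use_host = use_host)
      sole_match <- identical(res$candidates, p$species)
      own_in <- p$species %in% res$candidates
      if (h == p$hosts[1]) {
        primary <- list(res = res, sole = sole_match, own = own_in)
      } else {
        extra_notes <- c(extra_notes, sprintf(
          "column ex %s -> {%s}%s", h,
          paste(res$candidates, collapse = ", "),
          if (own_in) "" else " [own terminal not recovered]"))
        if (!own_in)
          exceptions <- c(exceptions, sprintf(
            "%s ex %s: mean specimen routed to {%s}, not its own terminal",
            p$species, h, paste(res$candidates, collapse = ", ")))
      }
      if (h == p$hosts[1] && !own_in)
        exceptions <- c(exceptions, sprintf(
          "%s: mean specimen routed to {%s}, not its own terminal (path %s)",
          p$species, paste(res$candidates, collapse = ", "),
          paste(res$path$couplet, collapse = ">")))
      if (h == p$hosts[1] &&
          any(res$path$lead == "both" & res$path$couplet == 11L))
        exceptions <- c(exceptions, sprintf(
          "%s: couplet 11 undecidable (accessory-piece side vs hook lengths conflict)",
          p$species))
    }
    res <- primary$res
    rows[[length(rows) + 1]] <- data.frame(
      species = p$species,
      host = p$hosts[1],
      candidates = paste(res$candidates, collapse = "; "),
      n_candidates = length(res$candidates),
      match = primary$sole,
      own_terminal_recovered = primary$own,
      path = paste(res$path$couplet, collapse = ">"),
      notes = paste(c(res$notes, extra_notes), collapse = " | "),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, exceptions = unique(exceptions),
            class = c("kg_key_validation", "data.frame"))
}

#' @export
print.kg_key_validation <- function(x, ...) {
  cat(sprintf("<kg_key_validation> %d profiles, %d recover their own terminal\n",
              nrow(x),
              if ("own_terminal_recovered" %in% names(x))
                sum(x$own_terminal_recovered) else NA))
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  show <- intersect(c("species", "host", "candidates", "match",
                      "own_terminal_recovered"), names(df))
  print.data.frame(df[, show, drop = FALSE], right = FALSE)
  exc <- attr(x, "exceptions")
  if (length(exc)) {
    cat("documented exceptions:\n")
    for (e in exc) cat("  - ", e, "\n", sep = "")
  }
  invisible(x)
}
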