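# -- measurement namespace ----------------------------------------------------
#
# One specimen = one worm's haptoral and genital hard-part measurements, all
# in micrometres. 21 haptoral parameters (two anchors x 5, two bars x 2,
# hook pairs I..VII) plus the two genital lengths.

KG_ANCHOR_FIELDS <- c("total", "ltn", "inner", "outer", "point")
KG_HOOK_PARAMS   <- paste0("h", c("I", "II", "III", "IV", "V", "VI", "VII"))

#' Measurement parameter names
#'
#' The fixed namespace of numeric measurement parameters carried by a
#' specimen record: five lengths per anchor (dorsal `da_*`, ventral `va_*`:
#' total length, length to notch, inner root length, outer root length,
#' point length), branch length and maximum branch width per transversal bar
#' (`db_*`, `vb_*`), hook pair lengths `hI`..`hVII`, and the two male
#' copulatory organ lengths (`mco_tube`, `mco_ap`). All values are in
#' micrometres.
#'
#' @return Character vector of parameter names.
#' @export
kg_params <- function() {
  c(paste0("da_", KG_ANCHOR_FIELDS), paste0("va_", KG_ANCHOR_FIELDS),
    "db_len", "db_width", "vb_len", "vb_width",
    KG_HOOK_PARAMS, "mco_tube", "mco_ap")
}

#' @rdname kg_params
#' @export
kg_haptoral_params <- function() setdiff(kg_params(), c("mco_tube", "mco_ap"))

#' @rdname kg_params
#' @details `kg_ordination_params()` is the 20-parameter haptoral set used by
#'   the multivariate protocol: hook pair VII is excluded because it is the
#'   pair most often unmeasurable on mounted specimens.
#' @export
kg_ordination_params <- function() setdiff(kg_haptoral_params(), "hVII")

# full column schema of the specimen CSV dialect (one row = one specimen)
kg_specimen_columns <- function() {
  c("specimen_id", "species_label", "host_species", "locality", "country",
    kg_params(), "ap_side", "broad_roots")
}

#' Construct specimen records
#'
#' Builds a specimen data frame in the standard column schema. Any
#' measurement not supplied is missing (`NA`), which is a first-class state
#' distinct from zero: derived quantities propagate it.
#'
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param ... Named measurement/metadata vectors; names must belong to the
#'   specimen schema (see [kg_params()], plus `species_label`,
#'   `host_species`, `locality`, `country`, `ap_side`, `broad_roots`).
#' @return A `data.frame` with one row per specimen and the full column
#'   schema.
#' @examples
#' specimen_record("w1", host_species = "Odaxothrissa losera",
#'                 da_inner = 16, da_outer = 4.9)
#' @export
specimen_record <- function(specimen_id, ...) {
  dots <- list(...)
  bad <- setdiff(names(dots), setdiff(kg_specimen_columns(), "specimen_id"))
  if (length(bad))
    stop("unknown specimen field(s): ", paste(bad, collapse = ", "))
  n <- length(specimen_id)
  out <- data.frame(specimen_id = as.character(specimen_id),
                    stringsAsFactors = FALSE)
  for (col in setdiff(kg_specimen_columns(), "specimen_id")) {
    if (col %in% names(dots)) {
      out[[col]] <- rep_len(dots[[col]], n)
    } else if (col == "ap_side") {
      out[[col]] <- rep("unknown", n)
    } else if (col == "broad_roots") {
      out[[col]] <- rep(NA, n)
    } else if (col %in% kg_params()) {
      out[[col]] <- rep(NA_real_, n)
    } else {
      out[[col]] <- rep(NA_character_, n)
    }
  }
  out[, kg_specimen_columns()]
}

#' Validate specimen records
#'
#' Checks the type invariants of a specimen table: unique ids, positive
#' measurements, length-to-notch and point length bounded by the anchor
#' total length, bar width smaller than branch length, and a legal
#' accessory-piece loop side. Violations are reported with the offending
#' field and row.
#'
#' @param records Specimen data frame (see [specimen_record()]).
#' @return `records`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_specimens <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(kg_specimen_columns(), names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  errs <- character()
  dup <- records$specimen_id[duplicated(records$specimen_id)]
  if (length(dup)) {
    for (id in unique(dup)) {
      rows <- which(records$specimen_id == id)
      errs <- c(errs, sprintf("duplicate specimen_id '%s' (rows %s)", id,
                              paste(rows, collapse = ", ")))
    }
  }
  for (p in kg_params()) {
    v <- records[[p]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      errs <- c(errs, sprintf("non-positive %s in row %s", p,
                              paste(bad, collapse = ", ")))
  }
  for (side in c("da", "va")) {
    tot <- records[[paste0(side, "_total")]]
    ltn <- records[[paste0(side, "_ltn")]]
    pt  <- records[[paste0(side, "_point")]]
    bad <- which(!is.na(tot) & !is.na(ltn) & ltn > tot)
    if (length(bad))
      errs <- c(errs, sprintf("%s_ltn exceeds %s_total in row %s", side, side,
                              paste(bad, collapse = ", ")))
    bad <- which(!is.na(tot) & !is.na(pt) & pt >= tot)
    if (length(bad))
      errs <- c(errs, sprintf("%s_point not below %s_total in row %s", side,
                              side, paste(bad, collapse = ", ")))
  }
  for (bar in c("db", "vb")) {
    len <- records[[paste0(bar, "_len")]]
    wid <- records[[paste0(bar, "_width")]]
    bad <- which(!is.na(len) & !is.na(wid) & wid >= len)
    if (length(bad))
      errs <- c(errs, sprintf("%s_width not below %s_len in row %s", bar, bar,
                              paste(bad, collapse = ", ")))
  }
  side <- records$ap_side
  bad <- which(!is.na(side) & !(side %in% c("left", "right", "unknown")))
  if (length(bad))
    errs <- c(errs, sprintf("ap_side must be left/right/unknown (row %s)",
                            paste(bad, collapse = ", ")))
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  invisible(records)
}

#' Diagnostic ratio features
#'
#' Computes the diagnostic length proportions used in species delimitation
#' of these monogeneans: the inner/outer root length ratio of each anchor,
#' the inner root length of each anchor relative to the first hook pair, the
#' dorsal length to notch relative to the first hook pair, and the dorsal
#' bar branch length relative to the first hook pair. Each ratio is computed
#' per specimen; a ratio is missing whenever any operand is missing.
#'
#' @param records Specimen data frame (validated with
#'   [validate_specimens()]).
#' @return Data frame with `specimen_id` and columns `da_root_ratio`,
#'   `va_root_ratio`, `da_inner_over_h1`, `va_inner_over_h1`,
#'   `da_ltn_over_h1`, `db_branch_over_h1`.
#' @examples
#' r <- specimen_record("w1", da_inner = 16, da_outer = 4.9)
#' compute_features(r)$da_root_ratio  # 3.265...
#' @export
compute_features <- function(records) {
  validate_specimens(records)
  safe_div <- function(num, den) ifelse(is.na(num) | is.na(den), NA_real_,
                                        num / den)
  data.frame(
    specimen_id       = records$specimen_id,
    da_root_ratio     = safe_div(records$da_inner, records$da_outer),
    va_root_ratio     = safe_div(records$va_inner, records$va_outer),
    da_inner_over_h1  = safe_div(records$da_inner, records$hI),
    va_inner_over_h1  = safe_div(records$va_inner, records$hI),
    da_ltn_over_h1    = safe_div(records$da_ltn, records$hI),
    db_branch_over_h1 = safe_div(records$db_len, records$hI),
    stringsAsFactors  = FALSE
  )
}
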