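# -- CSV dialect, fixtures export, pipeline -----------------------------------

#' Read specimen records from CSV
#'
#' Reads the standard specimen CSV dialect (one row per specimen; empty
#' cells are missing). Unknown columns, non-numeric measurements and
#' duplicate specimen ids are errors reported with row numbers; a file with
#' a header and no rows returns an empty record set with a warning.
#'
#' @param path CSV file path.
#' @return Specimen data frame in the standard schema.
#' @export
read_specimens <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  unknown <- setdiff(names(raw), kg_specimen_columns())
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  if (!"specimen_id" %in% names(raw)) stop("missing column specimen_id")
  if (nrow(raw) == 0) {
    warning("no specimen rows in ", path)
    return(specimen_record(character(0)))
  }
  blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA, x)
  args <- list(specimen_id = raw$specimen_id)
  errs <- character()
  for (col in setdiff(kg_specimen_columns(), "specimen_id")) {
    if (!col %in% names(raw)) next
    v <- blank_to_na(raw[[col]])
    if (col %in% kg_params()) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        errs <- c(errs, sprintf("non-numeric %s in row %s", col,
                                paste(bad, collapse = ", ")))
      args[[col]] <- num
    } else if (col == "broad_roots") {
      args[[col]] <- as.logical(v)
    } else {
      args[[col]] <- as.character(v)
    }
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  rec <- do.call(specimen_record, args)
  rec$ap_side[is.na(rec$ap_side)] <- "unknown"
  validate_specimens(rec)
  rec
}

#' Write specimen records to CSV
#'
#' Inverse of [read_specimens()]; the round trip is lossless (floats are
#' written at full precision, missing values as empty cells).
#'
#' @param records Specimen data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimens <- function(records, path) {
  out <- records[, kg_specimen_columns()]
  for (p in kg_params())
    out[[p]] <- ifelse(is.na(out[[p]]), "",
                       vapply(out[[p]], function(x)
                         formatC(x, digits = 17, format = "g"),
                         character(1)))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export the embedded reference fixtures
#'
#' Writes the mean reference specimen of every embedded profile column (13
#' records: 12 profiles, the two-host species contributing two) in the
#' standard specimen CSV dialect, plus copies of the survey and infection
#' tables.
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_fixtures <- function(dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- builtin_profiles()
  recs <- do.call(rbind, unlist(lapply(profiles, function(p)
    lapply(p$hosts, function(h) profile_mean_specimen(p, h))),
    recursive = FALSE))
  rownames(recs) <- NULL
  paths <- c(
    specimens = file.path(dir, "reference_mean_specimens.csv"),
    surveys = file.path(dir, "host_surveys.csv"),
    infections = file.path(dir, "infection_reports.csv"))
  write_specimens(recs, paths[["specimens"]])
  file.copy(kg_extdata("host_surveys.csv"), paths[["surveys"]],
            overwrite = TRUE)
  file.copy(kg_extdata("infection_reports.csv"), paths[["infections"]],
            overwrite = TRUE)
  invisible(paths)
}

#' Pipeline configuration
#'
#' @param input Path to a specimen CSV, or `NULL` to run on the exported
#'   reference mean specimens.
#' @param key_mode `"strict"` or `"annotated"` (see [kapentagyrus_key()]).
#' @param use_host Use host information in identification.
#' @param missing_threshold Missingness threshold for [prepare_matrix()].
#' @param seed Integer seed recorded in every output and used for NMDS.
#' @param outdir Output directory.
#' @param nmds Also run NMDS (default `TRUE`).
#' @return A `kg_run_config` list.
#' @export
run_config <- function(input = NULL, key_mode = "strict", use_host = TRUE,
                       missing_threshold = 0.5, seed = 1L,
                       outdir = tempfile("kapentagyrus_run_"), nmds = TRUE) {
  if (!is.null(input) && !file.exists(input))
    stop("configured input path does not exist: ", input)
  structure(list(input = input, key_mode = key_mode, use_host = use_host,
                 missing_threshold = missing_threshold,
                 seed = as.integer(seed), outdir = outdir, nmds = nmds),
            class = "kg_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes read -> diagnostic features -> identification -> key validation
#' -> infection statistics -> ordination on a specimen table (the embedded
#' reference mean specimens by default) and writes a JSON report plus CSV
#' outputs to the configured directory. Deterministic given the configured
#' seed. Any stage failure aborts with a stage-tagged message.
#'
#' @param config A [run_config()].
#' @return The report bundle (list), invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "kg_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  records <- stage("read", {
    if (is.null(config$input)) {
      tmp <- file.path(config$outdir, "reference_mean_specimens.csv")
      profiles <- builtin_profiles()
      recs <- do.call(rbind, unlist(lapply(profiles, function(p)
        lapply(p$hosts, function(h) profile_mean_specimen(p, h))),
        recursive = FALSE))
      rownames(recs) <- NULL
      write_specimens(recs, tmp)
      read_specimens(tmp)
    } else read_specimens(config$input)
  })
  features <- stage("features", compute_features(records))
  key <- stage("key", kapentagyrus_key(mode = config$key_mode))
  idents <- stage("identify",
                  identify_specimens(records, key, use_host = config$use_host))
  validation <- stage("key-validate", validate_key(key = key,
                                                   use_host = config$use_host))
  infections <- stage("stats", summarize_builtin_infections())
  surveys <- stage("stats", builtin_surveys())
  mat <- stage("ordinate",
               prepare_matrix(records, config$missing_threshold))
  pca <- stage("ordinate", run_pca(mat))
  nmds <- if (config$nmds && nrow(mat) > 3)
    stage("ordinate", run_nmds(mat, k = 2, seed = config$seed)) else NULL

  id_summary <- as.data.frame(idents)
  write.csv(cbind(id_summary,
                  features[match(id_summary$specimen_id,
                                 features$specimen_id), -1]),
            file.path(config$outdir, "identifications.csv"),
            row.names = FALSE)
  write.csv(data.frame(specimen_id = rownames(pca$scores), pca$scores),
            file.path(config$outdir, "pca_scores.csv"), row.names = FALSE)
  write.csv(infections, file.path(config$outdir, "infection_summaries.csv"),
            row.names = FALSE)

  report <- list(
    seed = config$seed,
    key_mode = config$key_mode,
    use_host = config$use_host,
    n_specimens = nrow(records),
    key = list(n_couplets = length(key$couplets),
               n_terminals = length(key_terminals(key)),
               n_terminal_hosts =
                 length(unique(unlist(key_terminal_hosts(key))))),
    survey_totals = list(n_lots = nrow(surveys),
                         hosts_examined = sum(surveys$n_examined)),
    key_validation = list(
      n_profiles = nrow(validation),
      n_own_terminal = sum(validation$own_terminal_recovered),
      exceptions = attr(validation, "exceptions")),
    pca = list(explained_variance_pct =
                 unname(pca$explained_variance_pct),
               dropped_rows = pca$dropped_rows,
               dropped_cols = pca$dropped_cols),
    nmds = if (!is.null(nmds)) list(stress = nmds$stress) else NULL)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(records = records, features = features, idents = idents,
                 validation = validation, infections = infections,
                 pca = pca, nmds = nmds, report = report,
                 outdir = config$outdir))
}
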