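#' Read a long-format feature table with exclusion rules
#'
#' Reads a CSV/TSV with header columns `subject`, `cohort`, `age`, `sex`
#' plus one column per feature, then applies the exclusion pass: rows with
#' missing age, sex or cohort are dropped; negative cells in features
#' declared non-negative are set to missing. Both exclusions are counted and
#' reported in the `"exclusions"` attribute (and logged to stderr).
#'
#' @param path File path (delimiter inferred from the extension: `.tsv` /
#'   `.txt` tab, otherwise comma).
#' @param features Feature column names; defaults to every column beyond
#'   subject/cohort/age/sex.
#' @param non_negative Logical, recycled over features: which features are
#'   zero-bounded (default all).
#' @param quiet Suppress the stderr log line.
#' @return A tibble with attribute `"exclusions"` (list: `rows_missing_covariates`,
#'   `negative_cells`) and `"non_negative"` (named logical).
#' @export
read_feature_table <- function(path, features = NULL, non_negative = TRUE,
                               quiet = FALSE) {
  if (!file.exists(path)) {
    stop_gamharm("input file '", path, "' not found", class = "gamharm_io_error")
  }
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) {
      stop_gamharm("could not parse '", path, "': ", conditionMessage(e),
                   class = "gamharm_io_error")
    })
  required <- c("subject", "cohort", "age", "sex")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop_gamharm("required column(s) missing: ",
                 paste(missing_cols, collapse = ", "),
                 class = "gamharm_io_error")
  }
  if (is.null(features)) features <- setdiff(names(raw), required)
  bad_num <- features[!vapply(raw[features], is.numeric, TRUE)]
  if (length(bad_num)) {
    stop_gamharm("feature column(s) not numeric: ",
                 paste(bad_num, collapse = ", "), class = "gamharm_io_error")
  }
  non_negative <- stats::setNames(rep_len(non_negative, length(features)),
                                  features)
  keep <- !(is.na(raw$age) | is.na(raw$sex) | is.na(raw$cohort) |
              raw$cohort == "")
  n_dropped <- sum(!keep)
  tab <- raw[keep, , drop = FALSE]
  n_neg <- 0L
  for (f in features) {
    if (non_negative[[f]]) {
      neg <- !is.na(tab[[f]]) & tab[[f]] < 0
      n_neg <- n_neg + sum(neg)
      tab[[f]][neg] <- NA_real_
    }
  }
  if (!quiet) {
    message("read ", nrow(tab), " rows from '", path, "' (excluded ",
            n_dropped, " rows with missing covariates, ", n_neg,
            " negative feature cells)")
  }
  out <- tibble::as_tibble(tab)
  attr(out, "exclusions") <- list(rows_missing_covariates = n_dropped,
                                  negative_cells = n_neg)
  attr(out, "non_negative") <- non_negative
  out
}

#' Write harmonisation outputs
#'
#' Writes the long-format per-observation output CSV and a JSON QC summary.
#'
#' @param result A [harmonise_table()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_harmonised <- function(result, dir, prefix = "harmonised") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  utils::write.csv(result$output, csv, row.names = FALSE)
  qc <- file.path(dir, paste0(prefix, "_qc.json"))
  jsonlite::write_json(result$qc_summary, qc, dataframe = "rows", auto_unbox = TRUE)
  invisible(c(csv = csv, qc = qc))
}

#' Machine-readable provenance record for a run
#'
#' @param config The run configuration (list), hashed with [rlang::hash()].
#' @param seed Run seed.
#' @param fits Named list of `gamharm_fit` objects.
#' @param qc_summary Per-feature QC counts.
#' @param path JSON output path.
#' @return Invisibly, the provenance list.
#' @export
write_provenance <- function(config, seed, fits, qc_summary, path) {
  prov <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("gamharm")),
    features = lapply(fits, function(f) {
      list(family_used = f$family$name, converged = f$converged,
           n_iterations = f$n_iter, deviance = f$deviance,
           fallback_attempts = length(f$fallback_path %||% list()))
    }),
    qc = qc_summary)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(prov)
}
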