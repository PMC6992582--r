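#' CRF CSV schema
#'
#' Case-report-form files are plain CSV, UTF-8, one row per couple, with the
#' eight required columns below (schema version 1). Unknown extra columns are
#' preserved on read and rewritten on write.
#'
#' \tabular{ll}{
#'   `patient_id`   \tab unique identifier (text) \cr
#'   `female_age`   \tab years, in `[18, 50]` \cr
#'   `sperm_source` \tab `ejaculate` / `surgical_non_noa` / `testicular_noa` \cr
#'   `center`       \tab `anatolia` / `androfert` / `genera` / `unspecified` \cr
#'   `n_mii`        \tab retrieved MII oocytes, `N >= 0` \cr
#'   `n_2pn`        \tab 2PN zygotes \cr
#'   `n_blast`      \tab blastocysts biopsied \cr
#'   `n_euploid`    \tab euploid blastocysts, `m` \cr
#' }
#'
#' Counts must satisfy `0 <= n_euploid <= n_blast <= n_2pn <= n_mii`.
#' Patients with `n_mii = 0` are legal (such records occur in real series and
#' must survive the round-trip); they are excluded from model fitting, not
#' from the file.
#'
#' @name crf-schema
NULL

crf_required <- c("patient_id", "female_age", "sperm_source", "center",
                  "n_mii", "n_2pn", "n_blast", "n_euploid")

validate_records <- function(records, where = "records") {
  if (!is.data.frame(records)) stop(where, " must be a data frame", call. = FALSE)
  miss <- setdiff(crf_required, names(records))
  if (length(miss))
    stop(where, " missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cnt <- c("n_mii", "n_2pn", "n_blast", "n_euploid")
  for (col in cnt) {
    v <- records[[col]]
    if (any(!is.finite(v) | v < 0 | v != round(v)))
      stop(sprintf("%s: column %s must be non-negative integers (rows %s)",
                   where, col,
                   paste(utils::head(which(!is.finite(v) | v < 0 | v != round(v)), 5),
                         collapse = ", ")), call. = FALSE)
    records[[col]] <- as.integer(v)
  }
  bad <- with(records, n_euploid > n_blast | n_blast > n_2pn | n_2pn > n_mii)
  if (any(bad))
    stop(sprintf("%s: count ordering m <= blast <= 2PN <= MII violated at rows %s",
                 where, paste(utils::head(which(bad), 10), collapse = ", ")),
         call. = FALSE)
  if (any(records$female_age < 18 | records$female_age > 50))
    stop(where, ": female_age outside [18, 50]", call. = FALSE)
  records$sperm_source <- match_level(records$sperm_source, sperm_levels,
                                      "sperm_source")
  records$center <- match_level(records$center, center_levels, "center")
  records
}

#' Read and write CRF CSV files
#'
#' `write_crf` writes a cohort to CSV; `read_crf` reads and validates one.
#' The round-trip is lossless for the required columns (counts as integers,
#' ages at full double precision) and preserves unknown optional columns.
#' Malformed rows — negative counts, non-integer counts, `m > N` orderings —
#' are rejected with the offending row indices.
#'
#' @param records Cohort data frame (see [crf-schema]).
#' @param path File path.
#' @return `read_crf` returns a validated `cohort` data frame; `write_crf`
#'   returns `path` invisibly.
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 5, seed = 3))
#' f <- tempfile(fileext = ".csv")
#' write_crf(co, f)
#' identical(read_crf(f)$n_euploid, co$n_euploid)
#' @export
write_crf <- function(records, path) {
  records <- validate_records(records)
  extra <- setdiff(names(records), crf_required)
  out <- records[c(crf_required, extra)]
  # %.17g round-trips doubles exactly; write.csv's default 15 digits does not
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  if (!file.exists(path)) stop("CRF file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- validate_records(raw, where = basename(path))
  class(out) <- c("cohort", class(out))
  out
}
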