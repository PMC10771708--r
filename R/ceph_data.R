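#' Cephalometric record schema
#'
#' Every stage of the pipeline operates on rows of sixteen cephalometric
#' indicators plus an identifier and sex. Lengths are millimetres, angles
#' degrees, and FHR (the posterior-anterior face height ratio S-Go/N-Me)
#' is a percentage on the 0-100 scale.
#'
#' @return `ceph_fields()`: character vector of the sixteen numeric
#'   indicator columns in canonical order.
#' @export
ceph_fields <- function() {
  c("N_ANS", "S_N", "Ptm_A", "SNA", "NA_FH", "PP_FH",
    "Go_Po", "Go_Co", "S_Go", "SN_OP",
    "FHR", "FA", "SNB", "ANB", "FH_MP", "SN_MP")
}

#' @rdname ceph_fields
#' @return `surrogate_inputs()`: the ten indicator columns the surrogate
#'   models take as inputs, in canonical order (SN-OP last).
#' @export
surrogate_input_fields <- function() {
  c("N_ANS", "S_N", "SNA", "NA_FH", "Ptm_A", "PP_FH",
    "Go_Po", "Go_Co", "S_Go", "SN_OP")
}

# mm-valued fields (must be strictly positive)
.length_fields <- c("N_ANS", "S_N", "Ptm_A", "Go_Po", "Go_Co", "S_Go")

# accepted header spellings -> canonical column names
.column_aliases <- c(
  "id" = "id", "sex" = "sex",
  "N-ANS" = "N_ANS", "S-N" = "S_N", "Ptm-A" = "Ptm_A",
  "NA-FH" = "NA_FH", "PP-FH" = "PP_FH",
  "Go-Po" = "Go_Po", "Go-Co" = "Go_Co", "S-Go" = "S_Go",
  "SN-OP" = "SN_OP",
  "S-Go/N-Me" = "FHR", "P-A face height" = "FHR", "P-A Face Height" = "FHR",
  "NPo-FH" = "FA", "FH-NPo" = "FA", "Facial Angle" = "FA",
  "FH-MP" = "FH_MP", "FMA" = "FH_MP", "SN-MP" = "SN_MP",
  "SNA" = "SNA", "SNB" = "SNB", "ANB" = "ANB"
)

canonical_column <- function(name) {
  if (name %in% ceph_fields() || name %in% c("id", "sex")) return(name)
  hit <- match(name, names(.column_aliases))
  if (!is.na(hit)) return(unname(.column_aliases[hit]))
  NA_character_
}

#' Construct a cohort
#'
#' A cohort is a tibble of validated cephalometric records (columns `id`,
#' `sex`, and the sixteen indicators of [ceph_fields()]) carrying optional
#' per-record skeletal labels, a provenance tag, and the generator seed.
#'
#' @param records Data frame with columns `id`, `sex` and all indicator
#'   columns.
#' @param labels Optional data frame with columns `id`, `sagittal`,
#'   `vertical` aligned one-to-one with `records`.
#' @param provenance `"generated"` or `"imported"`.
#' @param seed Integer seed used to generate the cohort, or `NULL`.
#' @param tolerance Degrees of slack allowed in the ANB = SNA - SNB
#'   identity during validation.
#' @return A `ceph_cohort` tibble.
#' @export
new_cohort <- function(records, labels = NULL, provenance = c("generated", "imported"),
                       seed = NULL, tolerance = 0.5) {
  provenance <- match.arg(provenance)
  records <- tibble::as_tibble(records)
  need <- c("id", "sex", ceph_fields())
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, need]
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    stop("cohort ids must be unique", call. = FALSE)
  }
  if (!all(records$sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    stopifnot(all(c("id", "sagittal", "vertical") %in% names(labels)))
    if (!identical(as.character(labels$id), records$id)) {
      stop("labels must align one-to-one with records by id", call. = FALSE)
    }
  }
  bad <- validate_cohort(records, tolerance = tolerance)
  if (nrow(bad) > 0) {
    first <- bad[1, ]
    stop(sprintf("cohort fails validation (%d violation(s)); first: row %s, %s",
                 nrow(bad), first$id, first$message), call. = FALSE)
  }
  structure(records,
            labels = labels, provenance = provenance, seed = seed,
            class = c("ceph_cohort", class(records)))
}

#' @rdname new_cohort
#' @param x Object to test or inspect.
#' @export
is_cohort <- function(x) inherits(x, "ceph_cohort")

#' @rdname new_cohort
#' @export
cohort_labels <- function(x) attr(x, "labels", exact = TRUE)

#' Implied anterior face height
#'
#' N-Me is not stored directly: FHR is the ratio S-Go/N-Me in percent, so
#' the anterior face height is recovered as `S_Go / (FHR / 100)`.
#'
#' @param cohort A cohort or record data frame with `S_Go` and `FHR`.
#' @return Numeric vector of implied N-Me distances (mm).
#' @export
implied_n_me <- function(cohort) {
  cohort$S_Go / (cohort$FHR / 100)
}

#' Validate a single cephalometric record
#'
#' Checks, in order: positivity of all linear (mm) measures, the angular
#' identity ANB = SNA - SNB (within `tolerance` degrees), 0 < FHR < 100,
#' and a per-field plausibility window (default: pooled calibration mean
#' +/- 5 pooled SD). Violations are reported, not raised.
#'
#' @param record A one-row data frame or named list with the sixteen
#'   indicator fields.
#' @param tolerance Allowed deviation (degrees) of ANB from SNA - SNB.
#' @param windows Optional tibble with columns `field`, `lower`, `upper`
#'   overriding the default plausibility windows.
#' @return A tibble of violations with columns `field`, `value`, `bound`,
#'   `message`; zero rows when the record is valid.
#' @export
validate_record <- function(record, tolerance = 0.5, windows = NULL) {
  record <- as.list(record)
  violations <- list()
  add <- function(field, value, bound, message) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(
      field = field, value = as.numeric(value), bound = bound, message = message)
  }
  for (f in ceph_fields()) {
    v <- record[[f]]
    if (is.null(v) || !is.finite(as.numeric(v))) {
      add(f, NA_real_, "finite", sprintf("%s is missing or non-finite", f))
    }
  }
  if (length(violations) > 0) {
    return(do.call(rbind, violations))
  }
  for (f in .length_fields) {
    if (record[[f]] <= 0) {
      add(f, record[[f]], "> 0", sprintf("%s must be a positive length (mm)", f))
    }
  }
  gap <- record$ANB - (record$SNA - record$SNB)
  if (abs(gap) > tolerance) {
    add("ANB", record$ANB, sprintf("SNA - SNB +/- %g", tolerance),
        sprintf("ANB identity violated: SNA - SNB = %g but ANB = %g",
                record$SNA - record$SNB, record$ANB))
  }
  if (record$FHR <= 0 || record$FHR >= 100) {
    add("FHR", record$FHR, "(0, 100)", "FHR must lie strictly between 0 and 100 percent")
  }
  if (is.null(windows)) windows <- default_windows()
  for (i in seq_len(nrow(windows))) {
    f <- windows$field[i]
    v <- record[[f]]
    if (v < windows$lower[i] || v > windows$upper[i]) {
      add(f, v, sprintf("[%.2f, %.2f]", windows$lower[i], windows$upper[i]),
          sprintf("%s = %g outside plausibility window", f, v))
    }
  }
  if (length(violations) == 0) {
    tibble::tibble(field = character(), value = numeric(),
                   bound = character(), message = character())
  } else {
    do.call(rbind, violations)
  }
}

#' @rdname validate_record
#' @return `default_windows()`: tibble of per-field plausibility bounds.
#' @export
default_windows <- function() {
  p <- pooled_field_stats()
  tibble::tibble(field = p$field,
                 lower = p$mean - 5 * p$sd,
                 upper = p$mean + 5 * p$sd)
}

#' Validate every record of a cohort
#'
#' @param records Data frame of records.
#' @inheritParams validate_record
#' @return Tibble of violations with an extra leading `id` column.
#' @export
validate_cohort <- function(records, tolerance = 0.5, windows = NULL) {
  if (is.null(windows)) windows <- default_windows()
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    v <- validate_record(records[i, ], tolerance = tolerance, windows = windows)
    if (nrow(v) > 0) {
      v <- cbind(tibble::tibble(id = as.character(records$id[i])), v)
      out[[i]] <- v
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    tibble::tibble(id = character(), field = character(), value = numeric(),
                   bound = character(), message = character())
  } else {
    tibble::as_tibble(do.call(rbind, out))
  }
}

#' Read a cohort from CSV
#'
#' Expects a comma-separated, dot-decimal file with one header row. Header
#' names may use either the canonical underscore form (`SN_OP`) or the
#' printed clinical form (`SN-OP`, `S-Go/N-Me`, `FMA`, ...); see the alias
#' map in the package source. Every row is validated on read.
#'
#' @param path CSV file path.
#' @param tolerance ANB-identity tolerance in degrees (imported data are
#'   typically rounded; default 0.5).
#' @param provenance Provenance tag to attach, default `"imported"`.
#' @return A validated `ceph_cohort`.
#' @export
read_cohort <- function(path, tolerance = 0.5, provenance = "imported") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, check.names = FALSE, nrows = 1))
  # keep id/sex textual ("F" would otherwise parse as logical FALSE)
  classes <- ifelse(vapply(header, canonical_column, character(1))
                    %in% c("id", "sex"), "character", NA)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = classes)
  canon <- vapply(names(raw), canonical_column, character(1))
  known <- !is.na(canon)
  raw <- raw[, known, drop = FALSE]
  names(raw) <- canon[known]
  missing <- setdiff(c("id", "sex", ceph_fields()), names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in ceph_fields()) {
    v <- raw[[f]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value in column %s at row %d: '%s'",
                     f, bad[1], v[bad[1]]), call. = FALSE)
      }
      raw[[f]] <- num
    }
  }
  new_cohort(raw, provenance = provenance, tolerance = tolerance)
}

#' Write a cohort to CSV
#'
#' Writes the canonical header (underscore column names); a cohort
#' written with [write_cohort()] and re-read with [read_cohort()] is
#' reproduced field-for-field to at least six decimals.
#'
#' @param cohort A `ceph_cohort`.
#' @param path Output CSV path.
#' @return Invisibly, the number of data rows written.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, c("id", "sex", ceph_fields())]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("failed to write cohort to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(nrow(df))
}
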