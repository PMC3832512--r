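#' Audiometric frequency grid
#'
#' Defines the frequencies at which hearing levels are measured and which
#' of them form the low- and the high-frequency band. Band means over these
#' two index sets are the predictors of the `LH` and `LH-` spaces and the
#' axes of the two-dimensional region search.
#'
#' The default is the standard clinical 10-frequency grid
#' 125, 250, 500, 1000, 1500, 2000, 3000, 4000, 6000, 8000 Hz with the five
#' lowest frequencies as the low band and the five highest as the high band.
#'
#' @param frequencies_hz Strictly increasing vector of positive frequencies
#'   (Hz).
#' @param low_band Integer indices (into `frequencies_hz`) of the
#'   low-frequency band; must be a non-empty contiguous range.
#' @param high_band Integer indices of the high-frequency band; non-empty,
#'   contiguous, disjoint from `low_band`.
#' @return An object of class `frequency_grid`.
#' @examples
#' g <- frequency_grid()
#' g$frequencies_hz
#' @export
frequency_grid <- function(frequencies_hz = c(125, 250, 500, 1000, 1500,
                                              2000, 3000, 4000, 6000, 8000),
                           low_band = 1:5,
                           high_band = 6:10) {
  if (length(frequencies_hz) < 1 || any(!is.finite(frequencies_hz)) ||
      any(frequencies_hz <= 0)) {
    stop("frequencies_hz must be finite and positive")
  }
  if (any(diff(frequencies_hz) <= 0)) {
    stop("frequencies_hz must be strictly increasing")
  }
  check_band <- function(band, name) {
    band <- as.integer(band)
    if (length(band) == 0) stop(name, " must be non-empty")
    if (any(band < 1) || any(band > length(frequencies_hz))) {
      stop(name, " indices out of range")
    }
    if (!identical(band, seq(min(band), max(band)))) {
      stop(name, " must be a contiguous index range")
    }
    band
  }
  low_band <- check_band(low_band, "low_band")
  high_band <- check_band(high_band, "high_band")
  if (length(intersect(low_band, high_band)) > 0) {
    stop("low_band and high_band must be disjoint")
  }
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz),
         low_band = low_band, high_band = high_band),
    class = "frequency_grid"
  )
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat("frequency_grid:", length(x$frequencies_hz), "frequencies (Hz):",
      paste(x$frequencies_hz, collapse = ", "), "\n")
  cat("  low band : ", paste(x$frequencies_hz[x$low_band], collapse = ", "),
      "Hz\n")
  cat("  high band: ", paste(x$frequencies_hz[x$high_band], collapse = ", "),
      "Hz\n")
  invisible(x)
}

# Hearing levels outside this range are treated as recording errors.
HL_RANGE <- c(-20, 140)

#' Construct a patient cohort
#'
#' A cohort bundles a [frequency_grid()] with one record per patient: the
#' pre-test audiogram (hearing level in dB HL at each grid frequency),
#' optionally the post-test audiogram, a precomputed aggregate threshold
#' reduction (`atr`, dB), and/or a binary test outcome (1 = positive).
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param pretest Numeric matrix, one row per patient, one column per grid
#'   frequency (dB HL).
#' @param posttest Optional numeric matrix with the same shape as `pretest`.
#' @param atr Optional numeric vector of aggregate threshold reductions (dB).
#' @param outcome Optional integer vector in \{0, 1\} (NA allowed).
#' @param grid A [frequency_grid()].
#' @return An object of class `cohort`: a list with elements `grid` and
#'   `data` (a data.frame with columns `patient_id`, `hl_<freq>`, optional
#'   `post_<freq>`, `atr`, `outcome`).
#' @seealso [read_cohort_csv()], [validate_cohort()]
#' @export
cohort <- function(patient_id, pretest, posttest = NULL, atr = NULL,
                   outcome = NULL, grid = frequency_grid()) {
  pretest <- as.matrix(pretest)
  n <- length(patient_id)
  nf <- length(grid$frequencies_hz)
  if (nrow(pretest) != n) stop("pretest must have one row per patient")
  if (ncol(pretest) != nf) {
    stop("pretest has ", ncol(pretest), " columns but the grid has ", nf,
         " frequencies")
  }
  dat <- data.frame(patient_id = as.character(patient_id),
                    stringsAsFactors = FALSE)
  colnames(pretest) <- paste0("hl_", grid$frequencies_hz)
  dat <- cbind(dat, as.data.frame(pretest))
  if (!is.null(posttest)) {
    posttest <- as.matrix(posttest)
    if (!all(dim(posttest) == dim(pretest))) {
      stop("posttest must have the same shape as pretest")
    }
    colnames(posttest) <- paste0("post_", grid$frequencies_hz)
    dat <- cbind(dat, as.data.frame(posttest))
  }
  if (!is.null(atr)) {
    if (length(atr) != n) stop("atr must have one value per patient")
    dat$atr <- as.numeric(atr)
  }
  if (!is.null(outcome)) {
    if (length(outcome) != n) stop("outcome must have one value per patient")
    if (!all(outcome %in% c(0, 1, NA))) stop("outcome values must be 0 or 1")
    dat$outcome <- as.integer(outcome)
  }
  rownames(dat) <- NULL
  obj <- structure(list(grid = grid, data = dat), class = "cohort")
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$data), "records,",
      length(x$grid$frequencies_hz), "frequencies\n")
  has <- c(posttest = any(startsWith(names(x$data), "post_")),
           atr = "atr" %in% names(x$data),
           outcome = "outcome" %in% names(x$data))
  cat("  fields present:", paste(names(has)[has], collapse = ", "), "\n")
  if ("outcome" %in% names(x$data)) {
    cat("  outcome prevalence:",
        format(mean(x$data$outcome, na.rm = TRUE), digits = 3), "\n")
  }
  invisible(x)
}

#' Number of records in a cohort
#' @param x A `cohort`.
#' @export
n_records <- function(x) nrow(x$data)

#' Extract the pre-test audiogram matrix
#' @param x A `cohort`.
#' @return Numeric matrix, patients x frequencies (dB HL).
#' @export
pretest_matrix <- function(x) {
  cols <- paste0("hl_", x$grid$frequencies_hz)
  as.matrix(x$data[, cols, drop = FALSE])
}

#' Extract the post-test audiogram matrix (or NULL if absent)
#' @param x A `cohort`.
#' @export
posttest_matrix <- function(x) {
  cols <- paste0("post_", x$grid$frequencies_hz)
  if (!all(cols %in% names(x$data))) return(NULL)
  as.matrix(x$data[, cols, drop = FALSE])
}

#' Read a cohort from CSV
#'
#' The file must have a header naming a `patient_id` column and one `hl_<freq>`
#' column per grid frequency; `post_<freq>`, `atr` and `outcome` columns are
#' optional. The reader validates rather than coerces: a missing required
#' column, a non-numeric threshold or a duplicate id is an error.
#'
#' @param path Path to a CSV file.
#' @param grid A [frequency_grid()].
#' @param allow_missing If `TRUE`, records with missing (NA) pretest values
#'   are dropped with a message rather than causing an error.
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path, grid = frequency_grid(),
                            allow_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  pre_cols <- paste0("hl_", grid$frequencies_hz)
  missing_cols <- setdiff(c("patient_id", pre_cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  post_cols <- paste0("post_", grid$frequencies_hz)
  have_post <- all(post_cols %in% names(raw))
  if (any(post_cols %in% names(raw)) && !have_post) {
    stop("post-test columns are incomplete: need all of ",
         paste(post_cols, collapse = ", "))
  }
  parse_num <- function(col) {
    v <- raw[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "" & is.na(out))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           ": '", v[bad[1]], "'")
    }
    out[v == ""] <- NA_real_
    out
  }
  pretest <- sapply(pre_cols, parse_num)
  if (nrow(raw) == 1) pretest <- matrix(pretest, nrow = 1)
  if (nrow(raw) == 0) pretest <- matrix(numeric(0), nrow = 0,
                                        ncol = length(pre_cols))
  if (anyNA(pretest)) {
    bad_rows <- which(apply(is.na(pretest), 1, any))
    if (allow_missing) {
      message("dropping ", length(bad_rows),
              " record(s) with missing pre-test values")
      keep <- setdiff(seq_len(nrow(raw)), bad_rows)
      raw <- raw[keep, , drop = FALSE]
      pretest <- pretest[keep, , drop = FALSE]
    } else {
      stop("missing pre-test value(s) at data row(s) ",
           paste(utils::head(bad_rows, 5), collapse = ", "),
           "; use allow_missing = TRUE to drop them")
    }
  }
  ids <- raw$patient_id
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  posttest <- NULL
  if (have_post && nrow(raw) > 0) {
    posttest <- sapply(post_cols, parse_num)
    if (nrow(raw) == 1) posttest <- matrix(posttest, nrow = 1)
  } else if (have_post) {
    posttest <- matrix(numeric(0), nrow = 0, ncol = length(post_cols))
  }
  atr <- if ("atr" %in% names(raw)) parse_num("atr") else NULL
  outcome <- NULL
  if ("outcome" %in% names(raw)) {
    oc <- parse_num("outcome")
    if (!all(oc %in% c(0, 1) | is.na(oc))) {
      stop("outcome column must contain only 0 and 1")
    }
    outcome <- as.integer(oc)
  }
  cohort(ids, pretest, posttest = posttest, atr = atr, outcome = outcome,
         grid = grid)
}

#' Write a cohort to CSV
#'
#' Round-trip safe: `read_cohort_csv(write_cohort_csv(x, p), x$grid)`
#' reproduces all fields for finite-decimal inputs.
#'
#' @param x A [cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort against its type invariants
#'
#' Checks hearing-level ranges, posttest shape, outcome coding, id uniqueness
#' and usability (at least one of posttest/atr/outcome per record for a record
#' to serve as training data). Reporting only: never throws for a data
#' violation.
#'
#' @param x A [cohort()].
#' @return A data.frame with columns `patient_id`, `field`, `message`; zero
#'   rows iff the cohort is valid. Also available as JSON via
#'   [validation_report_json()].
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  viol <- list()
  add <- function(id, field, msg) {
    viol[[length(viol) + 1]] <<- data.frame(patient_id = id, field = field,
                                            message = msg,
                                            stringsAsFactors = FALSE)
  }
  ids <- x$data$patient_id
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add(d, "patient_id", "duplicate patient_id")
  pre <- pretest_matrix(x)
  post <- posttest_matrix(x)
  for (i in seq_len(nrow(x$data))) {
    check_hl <- function(v, field) {
      if (any(!is.finite(v))) {
        add(ids[i], field, "non-finite hearing level")
      } else if (any(v < HL_RANGE[1] | v > HL_RANGE[2])) {
        add(ids[i], field,
            sprintf("hearing level outside [%g, %g] dB HL",
                    HL_RANGE[1], HL_RANGE[2]))
      }
    }
    check_hl(pre[i, ], "pretest")
    if (!is.null(post)) check_hl(post[i, ], "posttest")
    usable <- !is.null(post) ||
      ("atr" %in% names(x$data) && !is.na(x$data$atr[i])) ||
      ("outcome" %in% names(x$data) && !is.na(x$data$outcome[i]))
    if (!usable) {
      add(ids[i], "record",
          "no posttest, atr or outcome: unusable as training data")
    }
  }
  if (length(viol) == 0) {
    return(data.frame(patient_id = character(0), field = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, viol)
}

#' Render a validation report as JSON
#' @param report A data.frame from [validate_cohort()].
#' @return A JSON string.
#' @export
validation_report_json <- function(report) {
  jsonlite::toJSON(list(valid = nrow(report) == 0, violations = report),
                   auto_unbox = TRUE, pretty = TRUE)
}
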