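#' Aggregate threshold reduction (ATR)
#'
#' The ATR between a pre-test and a post-test audiogram is the largest total
#' hearing improvement over any contiguous frequency window: the maximum, over
#' all contiguous index windows, of the summed per-frequency threshold
#' reduction (pretest minus posttest), floored at 0 (the empty window). A
#' window may contain frequencies at which hearing worsened, as long as the
#' window total still wins.
#'
#' @param pretest,posttest Numeric vectors of hearing levels (dB HL), same
#'   length, ordered by frequency.
#' @return The ATR in dB (>= 0).
#' @examples
#' compute_atr(c(40, 50, 60), c(30, 45, 60))  # reductions 10, 5, 0 -> 15
#' @export
compute_atr <- function(pretest, posttest) {
  if (length(pretest) != length(posttest)) {
    stop("pretest and posttest must have the same length")
  }
  if (length(pretest) == 0) stop("audiograms must be non-empty")
  red <- pretest - posttest
  # Kadane's maximum-subarray scan, empty window allowed (floor at 0)
  best <- 0
  cur <- 0
  for (r in red) {
    cur <- max(0, cur + r)
    best <- max(best, cur)
  }
  best
}

#' Binary test outcome from the ATR criterion
#'
#' The test is positive iff the ATR reaches the criterion ("at least
#' `criterion` dB"); the default 30 dB criterion carries a false-positive
#' rate of about 5 % on test-retest audiometry.
#'
#' @param atr Numeric vector of ATR values (dB).
#' @param criterion Positive criterion (dB), default 30.
#' @return Integer vector in \{0, 1\}.
#' @export
classify_outcome <- function(atr, criterion = 30) {
  if (criterion <= 0) stop("criterion must be positive")
  as.integer(atr >= criterion)
}

#' Mean hearing level over a frequency band
#'
#' @param audiogram Numeric vector of hearing levels (dB HL).
#' @param band Integer indices of the band.
#' @return The band mean (dB HL).
#' @export
band_mean <- function(audiogram, band) {
  if (length(band) == 0) stop("band must be non-empty")
  if (any(band < 1) || any(band > length(audiogram))) {
    stop("band indices out of range")
  }
  mean(audiogram[band])
}

#' Named predictor spaces
#'
#' The spaces map an audiogram to a low-dimensional predictor vector:
#' \describe{
#'   \item{`kF` (`1F` ... `10F`)}{hearing losses at the `k` lowest grid
#'     frequencies (dimension `k`).}
#'   \item{`LH`}{mean low-band loss `L` and mean high-band loss `H`
#'     (dimension 2).}
#'   \item{`LH-`}{`L` and the difference `H - L` (dimension 2); the space in
#'     which low-frequency-dominant hearing loss sits below the zero line.}
#'   \item{`7F3d`}{the 7 lowest frequencies reduced to 3 predictors: the mean
#'     of the 3 lowest, then pairwise means of frequencies 4-5 and 6-7.}
#' }
#'
#' @param name One of `"1F"` ... `"10F"`, `"LH"`, `"LH-"`, `"7F3d"`.
#' @return An object of class `predictor_space` with fields `name` and
#'   `dimension`.
#' @export
predictor_space <- function(name) {
  kf <- paste0(1:10, "F")
  if (!name %in% c(kf, "LH", "LH-", "7F3d")) {
    stop("unknown predictor space: ", name)
  }
  dimension <- switch(name, "LH" = 2L, "LH-" = 2L, "7F3d" = 3L,
                      as.integer(sub("F$", "", name)))
  structure(list(name = name, dimension = dimension),
            class = "predictor_space")
}

#' Build the predictor matrix for a cohort
#'
#' @param x A [cohort()].
#' @param space A space name or [predictor_space()].
#' @return Numeric matrix, one row per record, `space$dimension` columns.
#' @export
make_predictors <- function(x, space) {
  stopifnot(inherits(x, "cohort"))
  if (is.character(space)) space <- predictor_space(space)
  pre <- pretest_matrix(x)
  g <- x$grid
  nf <- ncol(pre)
  name <- space$name
  if (grepl("^[0-9]+F$", name)) {
    k <- space$dimension
    if (k > nf) stop("space ", name, " needs ", k,
                     " frequencies but the grid has ", nf)
    out <- pre[, seq_len(k), drop = FALSE]
  } else if (name == "LH") {
    out <- cbind(L = rowMeans(pre[, g$low_band, drop = FALSE]),
                 H = rowMeans(pre[, g$high_band, drop = FALSE]))
  } else if (name == "LH-") {
    L <- rowMeans(pre[, g$low_band, drop = FALSE])
    H <- rowMeans(pre[, g$high_band, drop = FALSE])
    out <- cbind(L = L, HmL = H - L)
  } else if (name == "7F3d") {
    if (nf < 7) stop("space 7F3d needs 7 frequencies but the grid has ", nf)
    out <- cbind(rowMeans(pre[, 1:3, drop = FALSE]),
                 rowMeans(pre[, 4:5, drop = FALSE]),
                 rowMeans(pre[, 6:7, drop = FALSE]))
  } else {
    stop("unknown predictor space: ", name)
  }
  out <- as.matrix(out)
  rownames(out) <- x$data$patient_id
  out
}

#' Rule-of-thumb eligibility for the glycerol test
#'
#' A positive outcome is considered particularly likely when the mean
#' low-frequency hearing loss is between 30 and 70 dB (inclusive) and the
#' mean high-frequency loss does not exceed the mean low-frequency loss.
#'
#' @param low_mean,high_mean Mean low-/high-band hearing losses (dB HL);
#'   vectors are recycled in the usual way.
#' @return Integer vector in \{0, 1\}.
#' @export
rule_of_thumb <- function(low_mean, high_mean) {
  if (any(!is.finite(low_mean)) || any(!is.finite(high_mean))) {
    stop("inputs must be finite")
  }
  as.integer(low_mean >= 30 & low_mean <= 70 & high_mean <= low_mean)
}

#' Derive ATR and outcome columns for a cohort
#'
#' Fills the `atr` column from post-test audiograms where missing (a
#' precomputed `atr` value, when present, takes precedence) and the `outcome`
#' column from the ATR criterion.
#'
#' @param x A [cohort()] with post-test audiograms and/or `atr` values.
#' @param criterion ATR criterion in dB, default 30.
#' @return The cohort with `atr` and `outcome` columns populated.
#' @export
derive_outcomes <- function(x, criterion = 30) {
  stopifnot(inherits(x, "cohort"))
  pre <- pretest_matrix(x)
  post <- posttest_matrix(x)
  n <- nrow(pre)
  atr <- if ("atr" %in% names(x$data)) x$data$atr else rep(NA_real_, n)
  need <- is.na(atr)
  if (any(need)) {
    if (is.null(post)) {
      stop("cannot derive atr: no posttest audiograms and no atr column")
    }
    atr[need] <- vapply(which(need),
                        function(i) compute_atr(pre[i, ], post[i, ]),
                        numeric(1))
  }
  x$data$atr <- atr
  x$data$outcome <- classify_outcome(atr, criterion)
  x
}
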