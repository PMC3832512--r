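# Run code with a private RNG stream: the seed fully determines the output
# and the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate scores from the binormal model
#'
#' Outcomes are i.i.d. Bernoulli(`prevalence`); scores are class-conditionally
#' normal with `mu0 = 0`, `sigma0 = 1` for the negative class and
#' `mu1 = d_prime`, `sigma1 = sigma_ratio` for the positive class. The
#' theoretical AUC is `binormal_auc(0, d_prime, 1, sigma_ratio)`.
#'
#' @param n Cohort size (>= 2).
#' @param prevalence Probability of a positive outcome, in (0, 1).
#' @param d_prime Class separation (>= 0).
#' @param sigma_ratio `sigma1 / sigma0`, default 1 (equal variances).
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A data.frame with columns `score` and `outcome`.
#' @export
gen_scores_binormal <- function(n, prevalence = 0.39, d_prime = 1,
                                sigma_ratio = 1, seed = 1) {
  if (n < 2) stop("n must be at least 2")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be strictly inside (0, 1)")
  }
  if (d_prime < 0) stop("d_prime must be non-negative")
  if (sigma_ratio <= 0) stop("sigma_ratio must be positive")
  with_seed(seed, {
    outcome <- stats::rbinom(n, 1, prevalence)
    score <- stats::rnorm(n,
                          mean = ifelse(outcome == 1, d_prime, 0),
                          sd = ifelse(outcome == 1, sigma_ratio, 1))
    data.frame(score = score, outcome = outcome)
  })
}

#' Scenario parameters for the audiogram-level cohort generator
#'
#' Defaults emulate the glycerol-test study: 356 candidate patients, a latent
#' prevalence of 0.39 of glycerol-responsive ears, positive cases concentrated
#' at intermediate low-frequency hearing loss with the low-frequency loss
#' exceeding the high-frequency loss, and a test-retest jitter calibrated so
#' that a negative case reaches ATR >= 30 dB with probability about 0.05 (the
#' criterion's 5 % false-positive rate).
#'
#' @param n Number of patients.
#' @param prevalence Latent probability of a glycerol-responsive case.
#' @param low_mean,low_sd Low-band mean hearing loss distribution (dB HL) per
#'   class (`pos`, `neg`).
#' @param hml_mean,hml_sd High-minus-low band offset distribution (dB) per
#'   class.
#' @param freq_sd Within-band per-frequency spread around the band mean (dB).
#' @param improvement_mean,improvement_sd Post-test improvement per low-band
#'   frequency for positive cases (dB; truncated at 0 so the improvement
#'   profile is non-negative everywhere).
#' @param jitter_sd Test-retest jitter per frequency (dB); the default 4.92
#'   makes P(ATR >= 30) ~= 0.05 for a case with no true improvement.
#' @param seed Integer seed.
#' @return A list of class `audiogram_scenario`.
#' @export
audiogram_scenario <- function(n = 356, prevalence = 0.39,
                               low_mean = c(pos = 55, neg = 45),
                               low_sd = c(pos = 14, neg = 26),
                               hml_mean = c(pos = -10, neg = 0),
                               hml_sd = c(pos = 16, neg = 20),
                               freq_sd = 6,
                               improvement_mean = 12, improvement_sd = 4,
                               jitter_sd = 4.92,
                               seed = 1) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1,
            improvement_mean >= 0, jitter_sd >= 0)
  structure(list(n = n, prevalence = prevalence, low_mean = low_mean,
                 low_sd = low_sd, hml_mean = hml_mean, hml_sd = hml_sd,
                 freq_sd = freq_sd, improvement_mean = improvement_mean,
                 improvement_sd = improvement_sd, jitter_sd = jitter_sd,
                 seed = seed),
            class = "audiogram_scenario")
}

#' Simulate an audiogram-level cohort
#'
#' Generates pre- and post-test audiograms on the default 10-frequency grid.
#' Positive (latent) cases receive a non-negative low-band improvement whose
#' aggregate comfortably exceeds the 30 dB criterion; every case receives
#' test-retest jitter. The `outcome` column is then derived through the real
#' ATR pipeline ([compute_atr()] + [classify_outcome()]), not copied from the
#' latent class, so the criterion's ~5 % false-positive rate shows up in the
#' outcomes. The latent class is kept in the `latent_class` attribute for
#' diagnostics.
#'
#' @param scenario An [audiogram_scenario()].
#' @param grid A [frequency_grid()].
#' @return A [cohort()] with post-test audiograms, `atr` and `outcome`
#'   populated, and attribute `latent_class`.
#' @export
gen_cohort_audiograms <- function(scenario = audiogram_scenario(),
                                  grid = frequency_grid()) {
  stopifnot(inherits(scenario, "audiogram_scenario"))
  s <- scenario
  nf <- length(grid$frequencies_hz)
  with_seed(s$seed, {
    z <- stats::rbinom(s$n, 1, s$prevalence)
    cls <- ifelse(z == 1, "pos", "neg")
    L <- stats::rnorm(s$n, s$low_mean[cls], s$low_sd[cls])
    H <- L + stats::rnorm(s$n, s$hml_mean[cls], s$hml_sd[cls])
    band_of <- integer(nf)
    band_of[grid$low_band] <- 1L
    band_of[grid$high_band] <- 2L
    # frequencies in neither band track the overall mean
    band_of[band_of == 0L] <- 1L
    base <- cbind(L, H)[, band_of, drop = FALSE]
    pretest <- base + matrix(stats::rnorm(s$n * nf, 0, s$freq_sd), s$n, nf)
    pretest <- pmin(pmax(round(pretest, 1), -20), 140)
    improvement <- matrix(0, s$n, nf)
    if (any(z == 1)) {
      imp <- matrix(pmax(0, stats::rnorm(sum(z == 1) * length(grid$low_band),
                                         s$improvement_mean,
                                         s$improvement_sd)),
                    nrow = sum(z == 1))
      improvement[z == 1, grid$low_band] <- imp
    }
    jitter <- matrix(stats::rnorm(s$n * nf, 0, s$jitter_sd), s$n, nf)
    posttest <- pretest - improvement - jitter
    posttest <- pmin(pmax(round(posttest, 1), -20), 140)
    co <- cohort(patient_id = sprintf("P%04d", seq_len(s$n)),
                 pretest = pretest, posttest = posttest, grid = grid)
    co <- derive_outcomes(co)
    attr(co, "latent_class") <- z
    co
  })
}
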