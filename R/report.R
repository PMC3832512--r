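#' Cross-validated AUC comparison across predictor spaces and methods
#'
#' For each requested predictor space, computes leave-one-out cross-validated
#' posteriors by each method and summarises them by the AUC — a Table-2-style
#' comparison grid.
#'
#' @param x A [cohort()] with outcomes (see [derive_outcomes()]).
#' @param spaces Character vector of predictor-space names.
#' @param methods Any of `"knn"`, `"logit-lin"`, `"logit-quad"`.
#' @param k Number of neighbours for the KNN method.
#' @return A data.frame with one row per space and one AUC column per method.
#' @export
auc_table <- function(x,
                      spaces = c(paste0(1:10, "F"), "LH", "LH-", "7F3d"),
                      methods = c("knn", "logit-lin", "logit-quad"),
                      k = 10) {
  stopifnot(inherits(x, "cohort"))
  if (!"outcome" %in% names(x$data)) {
    stop("cohort has no outcomes; run derive_outcomes() first")
  }
  bad <- setdiff(methods, c("knn", "logit-lin", "logit-quad"))
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "))
  y <- x$data$outcome
  out <- data.frame(space = spaces, stringsAsFactors = FALSE)
  for (m in methods) out[[m]] <- NA_real_
  for (i in seq_along(spaces)) {
    X <- make_predictors(x, spaces[i])
    for (m in methods) {
      spec <- switch(m,
                     "knn" = knn_config(k = k),
                     "logit-lin" = "linear",
                     "logit-quad" = "quadratic")
      ps <- loocv_posteriors(X, y, method = spec, ids = x$data$patient_id)
      out[[m]][i] <- auc(ps$posterior, ps$outcome)
    }
  }
  out
}

#' Export a posterior set to CSV
#' @param ps A `posterior_set` from [loocv_posteriors()].
#' @param path Output path.
#' @export
write_posteriors_csv <- function(ps, path) {
  utils::write.csv(as.data.frame(ps), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a posterior set from CSV
#' @param path Path to a CSV with columns `patient_id`, `posterior`, `outcome`.
#' @export
read_posteriors_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "posterior", "outcome")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  structure(d[need], class = c("posterior_set", "data.frame"))
}
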