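# Per-gene audioprofiles (mean thresholds by age bin) and audioprofile
# surfaces (polynomial threshold = f(age, frequency) fits).

#' Default audioprofile age bins
#'
#' Decade bins `[0,10), [10,20), ..., [90,100)`, half-open on the right.
#'
#' @return Numeric matrix with columns `lo`, `hi`; one row per bin.
#' @export
default_age_bins <- function() {
  cbind(lo = seq(0, 90, by = 10), hi = seq(10, 100, by = 10))
}

bin_of_age <- function(age, bins) {
  hit <- which(age >= bins[, "lo"] & age < bins[, "hi"])
  if (length(hit)) hit[1L] else NA_integer_
}

#' Build a gene audioprofile
#'
#' The audioprofile of a gene is its characteristic audiogram by age group:
#' for every age bin and grid frequency, the arithmetic mean (and SD, where
#' at least two audiograms contribute) of the imputed thresholds of all
#' audiograms from patients labeled with that gene. Audiograms are weighted
#' equally (a patient with several audiograms contributes each of them).
#'
#' @param records List of imputed, labeled patient records.
#' @param gene Gene symbol to profile.
#' @param age_bins Bin matrix as returned by [default_age_bins()].
#' @return Object of class `"audioprofile"` with elements `gene`,
#'   `age_bins`, `mean_thr`, `sd_thr`, `count` (each matrix n_bins x 10;
#'   mean/sd are `NA` where too few audiograms fall in a bin).
#' @export
build_audioprofile <- function(records, gene, age_bins = default_age_bins()) {
  fl <- flatten_records(records)
  keep <- which(!is.na(fl$gene) & fl$gene == gene)
  if (!length(keep)) stop("no audiograms labeled with gene ", gene)
  grid <- freq_grid()
  n_bins <- nrow(age_bins)
  thr <- t(vapply(fl$audiograms[keep], function(a) {
    v <- as.numeric(a$thresholds[as.character(grid)])
    if (anyNA(v)) stop("audioprofiles require imputed audiograms")
    v
  }, numeric(length(grid))))
  bins <- vapply(fl$age[keep], bin_of_age, 0L, bins = age_bins)
  mean_thr <- matrix(NA_real_, n_bins, length(grid))
  sd_thr <- matrix(NA_real_, n_bins, length(grid))
  count <- matrix(0L, n_bins, length(grid))
  for (b in seq_len(n_bins)) {
    rows <- which(bins == b)
    if (!length(rows)) next
    count[b, ] <- length(rows)
    mean_thr[b, ] <- colMeans(thr[rows, , drop = FALSE])
    if (length(rows) >= 2L) {
      sd_thr[b, ] <- apply(thr[rows, , drop = FALSE], 2, stats::sd)
    }
  }
  dimnames(mean_thr) <- dimnames(sd_thr) <- dimnames(count) <-
    list(sprintf("[%g,%g)", age_bins[, "lo"], age_bins[, "hi"]),
         as.character(grid))
  structure(
    list(gene = gene, age_bins = age_bins, mean_thr = mean_thr,
         sd_thr = sd_thr, count = count),
    class = "audioprofile"
  )
}

#' @export
print.audioprofile <- function(x, ...) {
  n_bins_used <- sum(x$count[, 1] > 0)
  cat(sprintf("<audioprofile %s> %d audiograms across %d age bin(s)\n",
              x$gene, sum(x$count[, 1]), n_bins_used))
  invisible(x)
}

#' RMS distance between an audiogram and a gene audioprofile
#'
#' Root-mean-square difference across the 10 grid frequencies between an
#' audiogram's (imputed) thresholds and the profile row of the audiogram's
#' age bin. If that bin holds no data, the nearest non-empty bin (by bin
#' midpoint) is used and the result carries attribute `fallback = TRUE`.
#'
#' @param aud A complete audiogram.
#' @param profile An [build_audioprofile()] result.
#' @return RMS distance in dB, with attributes `bin` (bin index used) and
#'   `fallback`.
#' @export
profile_distance <- function(aud, profile) {
  thr <- as.numeric(aud$thresholds[as.character(freq_grid())])
  if (anyNA(thr)) stop("profile_distance requires a complete audiogram")
  non_empty <- which(profile$count[, 1] > 0)
  if (!length(non_empty)) stop("audioprofile for ", profile$gene,
                               " has no populated age bins")
  b <- bin_of_age(aud$age, profile$age_bins)
  fallback <- FALSE
  if (is.na(b) || profile$count[b, 1] == 0L) {
    mid <- rowMeans(profile$age_bins)
    b <- non_empty[which.min(abs(mid[non_empty] - aud$age))]
    fallback <- TRUE
  }
  d <- sqrt(mean((thr - profile$mean_thr[b, ])^2))
  structure(d, bin = b, fallback = fallback)
}

# Tensor-product polynomial design matrix over (age, frequency index).
aps_design <- function(age, fidx, degree_age, degree_freq) {
  cols <- list()
  for (i in 0:degree_age) for (j in 0:degree_freq) {
    cols[[paste0("a", i, "f", j)]] <- age^i * fidx^j
  }
  do.call(cbind, cols)
}

#' Fit an audioprofile surface
#'
#' Fits expected threshold as a smooth bivariate polynomial surface over
#' (age in years, grid-frequency index) by ordinary least squares on all
#' imputed audiogram-frequency observations of one gene. The surface view
#' of a gene shows its hearing-loss progression over time across the
#' frequency range.
#'
#' @param records Imputed, labeled patient records.
#' @param gene Gene to fit.
#' @param degree_age,degree_freq Polynomial degrees (default cubic x cubic).
#' @return Object of class `"aps_model"`: `gene`, `degree_age`,
#'   `degree_freq`, `coefficients` ((degree_age+1) x (degree_freq+1)
#'   matrix), `fit_rmse` in dB.
#' @export
fit_aps <- function(records, gene, degree_age = 3L, degree_freq = 3L) {
  fl <- flatten_records(records)
  keep <- which(!is.na(fl$gene) & fl$gene == gene)
  if (!length(keep)) stop("no audiograms labeled with gene ", gene)
  grid <- freq_grid()
  n_freq <- length(grid)
  age <- rep(fl$age[keep], each = n_freq)
  fidx <- rep(seq_len(n_freq), times = length(keep))
  y <- unlist(lapply(fl$audiograms[keep], function(a) {
    as.numeric(a$thresholds[as.character(grid)])
  }))
  if (anyNA(y)) stop("surface fitting requires imputed audiograms")
  p <- (degree_age + 1L) * (degree_freq + 1L)
  if (length(y) < p) {
    stop(sprintf(
      "underdetermined surface fit for %s: %d observations < %d coefficients; lower the polynomial degrees",
      gene, length(y), p))
  }
  X <- aps_design(age, fidx, degree_age, degree_freq)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  coef_mat <- matrix(beta, degree_age + 1L, degree_freq + 1L, byrow = TRUE,
                     dimnames = list(paste0("age^", 0:degree_age),
                                     paste0("fidx^", 0:degree_freq)))
  structure(
    list(gene = gene, degree_age = degree_age, degree_freq = degree_freq,
         coefficients = coef_mat,
         fit_rmse = sqrt(mean(fit$residuals^2))),
    class = "aps_model"
  )
}

#' Evaluate an audioprofile surface
#'
#' @param model An [fit_aps()] result.
#' @param age Age in years (vectorized).
#' @param frequency Grid frequency in Hz (vectorized, recycled against
#'   `age`).
#' @return Expected threshold(s) in dB HL, clamped to \[-10, 130\].
#' @export
eval_aps <- function(model, age, frequency) {
  fidx <- match(as.character(frequency), as.character(freq_grid()))
  if (anyNA(fidx)) {
    stop("frequency must be on the grid: ",
         paste(freq_grid(), collapse = ", "))
  }
  n <- max(length(age), length(fidx))
  age <- rep_len(age, n); fidx <- rep_len(fidx, n)
  X <- aps_design(age, fidx, model$degree_age, model$degree_freq)
  pred <- as.numeric(X %*% as.numeric(t(model$coefficients)))
  pmin(pmax(pred, DB_RANGE[1]), DB_RANGE[2])
}

#' @export
print.aps_model <- function(x, ...) {
  cat(sprintf("<aps_model %s> degree %d x %d, fit RMSE %.2f dB\n",
              x$gene, x$degree_age, x$degree_freq, x$fit_rmse))
  invisible(x)
}
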