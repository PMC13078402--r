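# Imputation of missing thresholds, feature-vector construction, and the
# audiogram shape taxonomy used for ensemble data partitioning.

#' Impute missing thresholds on the frequency grid
#'
#' Fills gaps by linear interpolation against the grid index (audiometric
#' frequencies are near-logarithmically spaced, so index-linear
#' interpolation approximates linearity in log-frequency). Leading and
#' trailing gaps are extrapolated linearly from the two nearest observed
#' points. Results are clamped to the audiometer range \[-10, 130\] dB HL.
#' Observed values are never altered, so imputation is idempotent.
#'
#' @param aud An [audiogram()] with at least 3 observed thresholds.
#' @return The audiogram, complete on all 10 grid frequencies.
#' @export
#' @examples
#' a <- audiogram("p", "a1", 30, c("250" = 20, "1000" = 40))
#' impute_thresholds(audiogram("p", "a1", 30,
#'   c("250" = 20, "500" = 30, "1000" = 40)))
impute_thresholds <- function(aud) {
  grid <- as.character(freq_grid())
  obs_idx <- match(names(aud$thresholds), grid)
  if (length(obs_idx) < 3L) {
    stop(sprintf("audiogram %s: %d observed thresholds; at least 3 required",
                 aud$audiogram_id, length(obs_idx)))
  }
  ord <- order(obs_idx)
  x <- obs_idx[ord]
  y <- as.numeric(aud$thresholds)[ord]
  full <- rep(NA_real_, length(grid))
  full[x] <- y
  # interior gaps: linear in grid index between bracketing observations
  interior <- which(is.na(full))
  if (length(interior)) {
    full[interior] <- stats::approx(x, y, xout = interior, rule = 1)$y
  }
  # edges: extrapolate from the two nearest observed points
  lead <- which(is.na(full) & seq_along(full) < min(x))
  if (length(lead)) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    full[lead] <- y[1] + slope * (lead - x[1])
  }
  trail <- which(is.na(full) & seq_along(full) > max(x))
  if (length(trail)) {
    m <- length(x)
    slope <- (y[m] - y[m - 1]) / (x[m] - x[m - 1])
    full[trail] <- y[m] + slope * (trail - x[m])
  }
  full <- pmin(pmax(full, DB_RANGE[1]), DB_RANGE[2])
  names(full) <- grid
  out <- aud
  out$thresholds <- full
  out
}

#' Build the 11-dimensional feature vector
#'
#' The representation consumed by every model in the package: age in years
#' followed by the 10 thresholds in ascending grid-frequency order.
#'
#' @param aud An audiogram complete on the grid (see [impute_thresholds()]).
#' @return Named numeric vector of length 11 (`age`, `thr_125`, ...,
#'   `thr_8000`).
#' @export
feature_vector <- function(aud) {
  grid <- as.character(freq_grid())
  thr <- aud$thresholds[grid]
  if (anyNA(thr)) {
    stop(sprintf("audiogram %s is incomplete on the grid; impute first",
                 aud$audiogram_id))
  }
  stats::setNames(c(aud$age, as.numeric(thr)),
                  c("age", paste0("thr_", grid)))
}

# Feature matrix (n x 11) for a list of complete audiograms.
feature_matrix <- function(audiograms) {
  m <- t(vapply(audiograms, function(a) feature_vector(a),
                numeric(1 + length(freq_grid()))))
  rownames(m) <- vapply(audiograms, `[[`, "", "audiogram_id")
  m
}

#' Classify audiogram shape
#'
#' Coarse morphological category used to partition ensemble training data.
#' Band means are L (125-500 Hz), M (1000-2000 Hz), H (3000-8000 Hz); with
#' threshold delta (default 15 dB) the rules are applied in order:
#' `flat` if all pairwise band differences are within delta; `downsloping`
#' if H - L > delta; `upsloping` if L - H > delta; `mid_dip` if M exceeds
#' both L and H by more than delta; audiograms matching no rule (e.g. a
#' mid-frequency *bump*) default to `flat`.
#'
#' @param aud A complete audiogram.
#' @param delta_db Band-difference threshold in dB (default 15).
#' @param band_edges Integer vector of length 2: grid indices at which the
#'   low/mid and mid/high band boundaries fall (defaults: low = indices
#'   1-3, mid = 4-6, high = 7-10).
#' @return One of `"flat"`, `"downsloping"`, `"upsloping"`, `"mid_dip"`.
#' @export
shape_class <- function(aud, delta_db = 15, band_edges = c(3L, 6L)) {
  thr <- as.numeric(aud$thresholds[as.character(freq_grid())])
  if (anyNA(thr)) stop("shape_class requires a complete audiogram")
  L <- mean(thr[seq_len(band_edges[1])])
  M <- mean(thr[(band_edges[1] + 1):band_edges[2]])
  H <- mean(thr[(band_edges[2] + 1):length(thr)])
  if (max(abs(c(L - M, L - H, M - H))) <= delta_db) return("flat")
  if (H - L > delta_db) return("downsloping")
  if (L - H > delta_db) return("upsloping")
  if (M - L > delta_db && M - H > delta_db) return("mid_dip")
  "flat"
}

#' Impute every audiogram in a list of patient records
#'
#' Convenience wrapper applying [impute_thresholds()] to each member
#' audiogram of each record.
#'
#' @param records List of [patient_record()] objects.
#' @return The records, complete on the frequency grid.
#' @export
impute_records <- function(records) {
  lapply(records, function(rec) {
    rec$audiograms <- lapply(rec$audiograms, impute_thresholds)
    rec
  })
}
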