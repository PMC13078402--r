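# Seeded synthetic audiogram simulator. Generates cohorts with the
# statistical structure the models assume: gene-specific baseline
# audiograms with per-frequency age-progression slopes, i.i.d. Gaussian
# measurement noise, long-tailed class prevalence, a mixture of single-
# and multi-audiogram patients, region labels, and optional missingness.

#' Construct a gene simulation profile
#'
#' @param gene Gene symbol.
#' @param baseline 10 thresholds in dB HL at age 0 (grid order).
#' @param slope 10 per-frequency progression rates in dB/year.
#' @param noise_sd Measurement noise SD in dB (default 10).
#' @param prevalence Non-negative prevalence weight (normalized over the
#'   panel at simulation time).
#' @param region_dist Named probability vector over region labels.
#' @param visits_dist Named probability vector over audiograms per patient
#'   (support `"1"`, `"2"`, `"3"`).
#' @return List of class `"gene_sim_profile"`.
#' @export
gene_sim_profile <- function(gene, baseline, slope, noise_sd = 10,
                             prevalence = 1,
                             region_dist = default_region_dist(),
                             visits_dist = default_visits_dist()) {
  stopifnot(length(baseline) == 10L, length(slope) == 10L,
            noise_sd >= 0, prevalence >= 0,
            abs(sum(region_dist) - 1) < 1e-9,
            abs(sum(visits_dist) - 1) < 1e-9)
  structure(
    list(gene = gene, baseline = as.numeric(baseline),
         slope = as.numeric(slope), noise_sd = noise_sd,
         prevalence = prevalence, region_dist = region_dist,
         visits_dist = visits_dist),
    class = "gene_sim_profile"
  )
}

#' @rdname gene_sim_profile
#' @export
default_region_dist <- function() {
  c(Dutch = 0.25, American = 0.25, German = 0.20, Chinese = 0.15,
    Spanish = 0.10, unknown = 0.05)
}

#' @rdname gene_sim_profile
#' @export
default_visits_dist <- function() {
  c("1" = 0.55, "2" = 0.30, "3" = 0.15)
}

# One archetype: baseline_f = level + tilt * s_f + notch * exp(-(f - c)^2/2),
# slope_f = max(0, s_level + s_tilt * s_f), with s_f the grid index scaled
# to [-1, 1]. Positive tilt = downsloping (worse at high frequency).
archetype <- function(level, tilt, s_level, s_tilt, notch = 0,
                      notch_center = 5.5) {
  f <- 1:10
  s <- (f - 5.5) / 4.5
  base <- level + tilt * s + notch * exp(-(f - notch_center)^2 / 2)
  list(
    baseline = pmin(pmax(base, DB_RANGE[1]), DB_RANGE[2]),
    slope = pmax(0, s_level + s_tilt * s)
  )
}

#' Default 23-gene simulation panel
#'
#' Gene-specific baseline audiograms and progression slopes covering the
#' audioprofile archetypes of the ADNSHL panel: low-frequency ascending
#' loss (WFS1-like), mid-frequency "cookie-bite" loss (TECTA/COL11A2-like),
#' flat progressive loss (EYA4-like), and high-frequency downsloping loss
#' (KCNQ4/COCH-like), with variants of severity and progression speed
#' filling the remaining slots. Prevalence weights follow a Zipf (1/rank)
#' law over the panel order, emulating the heavy class imbalance of
#' clinical audiometric collections. Measurement noise defaults to 10 dB
#' per threshold.
#'
#' @param noise_sd Noise SD applied to every gene (default 10 dB).
#' @return Named list of 23 [gene_sim_profile()] objects, in panel order.
#' @export
default_sim_panel <- function(noise_sd = 10) {
  # gene: level, tilt, slope level, slope tilt, notch, notch center
  pars <- list(
    WFS1    = c(45, -25, 0.35, -0.15, 0, 5.5),  # low-freq ascending
    ACTG1   = c(30,  25, 0.90,  0.40, 0, 5.5),  # downsloping progressive
    COCH    = c(10,  15, 1.40,  0.80, 0, 5.5),  # late-onset, steep
    KCNQ4   = c(15,  30, 0.80,  0.50, 0, 5.5),  # high-freq downsloping
    MYO7A   = c(35,  10, 0.70,  0.00, 0, 5.5),  # flat-to-downsloping
    EYA4    = c(25,   0, 0.90,  0.00, 0, 5.5),  # flat progressive
    MYO6    = c(40,   5, 0.50,  0.00, 0, 5.5),  # moderate flat, slow
    TECTA   = c(30,   0, 0.15,  0.00, 20, 5.0), # mid-freq, stable
    COL11A2 = c(35,   5, 0.30,  0.00, 25, 5.5), # mid-freq, moderate
    GSDME   = c(20,  35, 0.60,  0.30, 0, 5.5),  # steeply downsloping
    POU4F3  = c(28,  18, 0.55,  0.00, 0, 5.5),
    TMC1    = c(45,   8, 1.00,  0.00, 0, 5.5),  # severe flat progressive
    MYH14   = c(20,   5, 0.45,  0.00, 0, 5.5),
    MYH9    = c(12,  22, 0.50,  0.20, 0, 5.5),
    DIAPH1  = c(30, -18, 0.70, -0.20, 0, 5.5),  # low-freq progressive
    CCDC50  = c(18,  12, 0.80,  0.40, 0, 5.5),
    GRHL2   = c(15,   3, 0.65,  0.00, 0, 5.5),
    TJP2    = c(22,  -8, 0.90,  0.50, 0, 5.5),
    P2RX2   = c(33,  -3, 0.40,  0.00, 0, 5.5),
    SLC17A8 = c(18,  28, 0.35,  0.20, 0, 5.5),
    OSBPL2  = c(38,  22, 0.80,  0.00, 0, 5.5),
    TBC1D24 = c(28, -12, 0.50,  0.00, 10, 4.0),
    MIR96   = c(22,  -2, 1.10,  0.00, 0, 5.5)
  )
  stopifnot(identical(names(pars), gene_panel()))
  n <- length(pars)
  prevalence <- (1 / seq_len(n)) / sum(1 / seq_len(n))
  panel <- vector("list", n)
  for (i in seq_len(n)) {
    a <- archetype(pars[[i]][1], pars[[i]][2], pars[[i]][3], pars[[i]][4],
                   pars[[i]][5], pars[[i]][6])
    panel[[i]] <- gene_sim_profile(names(pars)[i], a$baseline, a$slope,
                                   noise_sd = noise_sd,
                                   prevalence = prevalence[i])
  }
  names(panel) <- names(pars)
  panel
}

#' Expected (noise-free) audiogram of a simulated gene
#'
#' @param profile A [gene_sim_profile()].
#' @param age Age in years.
#' @return Named threshold vector on the grid, clamped to \[-10, 130\].
#' @export
expected_audiogram <- function(profile, age) {
  thr <- pmin(pmax(profile$baseline + profile$slope * age, DB_RANGE[1]),
              DB_RANGE[2])
  stats::setNames(thr, as.character(freq_grid()))
}

#' Simulate a labeled patient cohort
#'
#' Per patient: the causative gene is drawn from the panel's prevalence
#' weights; the first-visit age from Uniform(5, 80); the number of
#' audiograms (1-3) from the gene's visit distribution, with follow-up
#' visits spaced 1-3 years apart; each threshold is the gene's expected
#' value at the visit age plus Gaussian noise, clamped to the audiometer
#' range; the region label is drawn from the gene's region distribution.
#' Fully deterministic under `seed`.
#'
#' @param panel Named list of gene simulation profiles
#'   (default [default_sim_panel()]).
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed.
#' @return List of labeled [patient_record()] objects.
#' @export
simulate_cohort <- function(panel = default_sim_panel(), n_patients,
                            seed = 1L) {
  stopifnot(n_patients >= 1L)
  set.seed(seed)
  prev <- vapply(panel, `[[`, 0, "prevalence")
  prev <- prev / sum(prev)
  grid <- as.character(freq_grid())
  lapply(seq_len(n_patients), function(i) {
    g <- sample(names(panel), 1L, prob = prev)
    pr <- panel[[g]]
    age0 <- stats::runif(1, 5, 80)
    n_visits <- as.integer(sample(names(pr$visits_dist), 1L,
                                  prob = pr$visits_dist))
    ages <- age0 + cumsum(c(0, stats::runif(max(n_visits - 1L, 0), 1, 3)))
    region <- sample(names(pr$region_dist), 1L, prob = pr$region_dist)
    pid <- sprintf("P%05d", i)
    auds <- lapply(seq_len(n_visits), function(v) {
      thr <- pr$baseline + pr$slope * ages[v] +
        stats::rnorm(length(grid), 0, pr$noise_sd)
      thr <- pmin(pmax(thr, DB_RANGE[1]), DB_RANGE[2])
      audiogram(pid, sprintf("%s-A%d", pid, v), ages[v],
                stats::setNames(thr, grid), region = region, gene = g)
    })
    patient_record(pid, auds, gene = g)
  })
}

#' Delete thresholds at random to emulate incomplete audiograms
#'
#' Each observed threshold is deleted independently with probability
#' `rate`, except that no audiogram is ever reduced below 3 observed
#' values (deletions beyond the floor are cancelled, least-likely-deleted
#' first). Deterministic under `seed`.
#'
#' @param records List of patient records.
#' @param rate Deletion probability in \[0, 0.5\].
#' @param seed Integer seed.
#' @return Records with thresholds removed.
#' @export
inject_missingness <- function(records, rate, seed = 1L) {
  if (rate < 0 || rate > 0.5) stop("rate must be within [0, 0.5]")
  if (rate == 0) return(records)
  set.seed(seed)
  lapply(records, function(rec) {
    rec$audiograms <- lapply(rec$audiograms, function(a) {
      n_obs <- length(a$thresholds)
      u <- stats::runif(n_obs)
      del <- which(u < rate)
      excess <- length(del) - (n_obs - 3L)
      if (excess > 0) {
        # cancel deletions with the largest u (closest to surviving)
        del <- del[order(u[del])][seq_len(max(n_obs - 3L, 0))]
      }
      if (length(del)) a$thresholds <- a$thresholds[-del]
      a
    })
    rec
  })
}
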