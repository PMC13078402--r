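one_gene_records <- function(specs, gene = "WFS1") {
  # specs: list of c(age, thr_flat) entries, one single-audiogram patient each
  lapply(seq_along(specs), function(i) {
    a <- mk_aud(sprintf("a%d", i), sprintf("p%d", i), specs[[i]][1],
                specs[[i]][2], gene = gene)
    patient_record(sprintf("p%d", i), list(a), gene = gene)
  })
}

test_that("audioprofile cells are per-bin means with half-open bins", {
  recs <- one_gene_records(list(c(25, 50)))
  pr <- build_audioprofile(recs, "WFS1")
  expect_equal(unname(pr$mean_thr[3, ]), rep(50, 10))  # bin [20,30)
  expect_true(all(is.na(pr$mean_thr[-3, ])))
  expect_equal(sum(pr$count), 10)

  recs2 <- one_gene_records(list(c(25, 40), c(29, 60)))
  pr2 <- build_audioprofile(recs2, "WFS1")
  expect_equal(unname(pr2$mean_thr[3, "1000"]), 50)
  expect_equal(unname(pr2$sd_thr[3, "1000"]), stats::sd(c(40, 60)))

  # age exactly 30 belongs to [30,40), not [20,30)
  pr3 <- build_audioprofile(one_gene_records(list(c(30, 50))), "WFS1")
  expect_true(all(is.na(pr3$mean_thr[3, ])))
  expect_equal(unname(pr3$mean_thr[4, 1]), 50)

  expect_error(build_audioprofile(recs, "COCH"), "COCH")
})

test_that("audioprofile construction is permutation-invariant", {
  recs <- one_gene_records(list(c(25, 40), c(29, 60), c(44, 70), c(61, 80)))
  a <- build_audioprofile(recs, "WFS1")
  b <- build_audioprofile(rev(recs), "WFS1")
  expect_equal(a$mean_thr, b$mean_thr)
  expect_equal(a$count, b$count)
})

test_that("profile distance is RMS over frequencies with bin fallback", {
  recs <- one_gene_records(list(c(25, 50)))
  pr <- build_audioprofile(recs, "WFS1")
  expect_equal(as.numeric(profile_distance(mk_aud(age = 22, thr = 50), pr)), 0)
  expect_equal(as.numeric(profile_distance(mk_aud(age = 22, thr = 60), pr)), 10)
  mixed <- mk_aud(age = 22, thr = 50 + rep(c(3, -3), 5))
  expect_equal(as.numeric(profile_distance(mixed, pr)), 3)
  # empty bin: falls back to nearest populated bin and says so
  d <- profile_distance(mk_aud(age = 75, thr = 50), pr)
  expect_true(attr(d, "fallback"))
  expect_equal(as.numeric(d), 0)
})

test_that("profile distance is a metric on threshold vectors", {
  recs <- one_gene_records(list(c(25, 40)))
  pr40 <- build_audioprofile(recs, "WFS1")
  set.seed(8)
  for (i in 1:10) {
    u <- mk_aud(age = 25, thr = runif(10, 0, 100))
    v <- mk_aud(age = 25, thr = runif(10, 0, 100))
    duv <- sqrt(mean((u$thresholds - v$thresholds)^2))
    du <- as.numeric(profile_distance(u, pr40))
    dv <- as.numeric(profile_distance(v, pr40))
    expect_gte(du + dv, duv - 1e-12)   # triangle through the profile row
    expect_gte(du, 0)
  }
})

test_that("surface fits recover generating polynomials exactly", {
  # plane thr = 10 + 0.5 age + 2 fidx, noise-free
  recs <- lapply(1:12, function(i) {
    age <- c(10, 20, 30, 40, 50, 60)[(i - 1) %% 6 + 1] + (i > 6) * 3
    thr <- 10 + 0.5 * age + 2 * (1:10)
    a <- audiogram(sprintf("p%d", i), sprintf("a%d", i), age,
                   stats::setNames(thr, as.character(freq_grid())),
                   gene = "COCH")
    patient_record(sprintf("p%d", i), list(a), gene = "COCH")
  })
  fit <- fit_aps(recs, "COCH", degree_age = 1, degree_freq = 1)
  expect_equal(fit$coefficients["age^0", "fidx^0"], 10, tolerance = 1e-6)
  expect_equal(fit$coefficients["age^1", "fidx^0"], 0.5, tolerance = 1e-6)
  expect_equal(fit$coefficients["age^0", "fidx^1"], 2, tolerance = 1e-6)
  expect_lt(fit$fit_rmse, 1e-8)
  expect_equal(eval_aps(fit, 40, 1000), 10 + 0.5 * 40 + 2 * 4,
               tolerance = 1e-6)

  const <- lapply(recs, function(r) {
    r$audiograms[[1]]$thresholds[] <- 30
    r
  })
  cfit <- fit_aps(const, "COCH", 1, 1)
  expect_lt(cfit$fit_rmse, 1e-8)
  expect_equal(eval_aps(cfit, 77, 8000), 30, tolerance = 1e-6)
  expect_error(eval_aps(cfit, 40, 777), "grid")
})

test_that("degree-1 surface fit matches the normal-equations oracle", {
  set.seed(21)
  recs <- lapply(1:12, function(i) {
    age <- runif(1, 5, 80)
    thr <- runif(10, 0, 100)
    a <- audiogram(sprintf("p%d", i), sprintf("a%d", i), age,
                   stats::setNames(thr, as.character(freq_grid())),
                   gene = "TMC1")
    patient_record(sprintf("p%d", i), list(a), gene = "TMC1")
  })
  fit <- fit_aps(recs, "TMC1", degree_age = 1, degree_freq = 1)
  # brute-force normal equations, built independently of the package
  age <- rep(vapply(recs, function(r) r$audiograms[[1]]$age, 0), each = 10)
  fidx <- rep(1:10, times = 12)
  y <- unlist(lapply(recs, function(r) unname(r$audiograms[[1]]$thresholds)))
  X <- cbind(1, fidx, age, age * fidx)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficients["age^0", "fidx^0"], beta[1],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$coefficients["age^0", "fidx^1"], beta[2],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$coefficients["age^1", "fidx^0"], beta[3],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$coefficients["age^1", "fidx^1"], beta[4],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("richer surface bases never fit worse than the constant surface", {
  recs <- impute_records(simulate_cohort(default_sim_panel(), 80, seed = 31))
  fit <- fit_aps(recs, "WFS1", 3, 3)
  fl <- otogene:::flatten_records(recs)
  keep <- fl$gene == "WFS1"
  y <- unlist(lapply(fl$audiograms[keep], function(a) unname(a$thresholds)))
  const_rmse <- sqrt(mean((y - mean(y))^2))
  expect_lte(fit$fit_rmse, const_rmse + 1e-12)
  expect_error(fit_aps(recs[1], "WFS1", 5, 5), "underdetermined|labeled")
})
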