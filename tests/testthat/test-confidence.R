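test_that("top-k ranking is deterministic with panel-order tie-breaks", {
  p <- stats::setNames(c(0.5, 0.3, 0.2, rep(0, 20)), gene_panel())
  names(p)[1:3] <- c("A", "B", "C")
  expect_identical(top_genes(p, 2), c("A", "B"))
  uniform <- stats::setNames(rep(1 / 23, 23), gene_panel())
  expect_identical(top_genes(uniform, 3), gene_panel()[1:3])
  # nesting: top-1 is a prefix of top-3
  set.seed(5)
  for (i in 1:10) {
    q <- stats::setNames(runif(23), gene_panel()); q <- q / sum(q)
    expect_identical(top_genes(q, 1), top_genes(q, 3)[1])
  }
  expect_error(top_genes(uniform, 24), "panel")
})

test_that("evaluation metrics match hand counts", {
  mk_p <- function(top) {
    p <- stats::setNames(rep(0, 23), gene_panel())
    p[top] <- c(0.5, 0.3, 0.2)[seq_along(top)]
    p / sum(p)
  }
  probs <- list(mk_p(c("WFS1", "COCH", "KCNQ4")),
                mk_p(c("COCH", "WFS1", "MYO6")),
                mk_p(c("ACTG1", "MYO6", "COCH")),
                mk_p(c("TECTA", "GSDME", "EYA4")))
  labels <- c("WFS1", "WFS1", "ACTG1", "COCH")
  m <- evaluate_predictions(probs, labels)
  expect_equal(m$top3_acc, 0.75)   # 3 of 4 labels inside the top 3
  expect_equal(m$top1_acc, 0.5)
  expect_lte(m$top1_acc, m$top3_acc)

  perfect <- evaluate_predictions(probs[c(1, 1)], c("WFS1", "WFS1"))
  expect_equal(perfect$top1_acc, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
})

test_that("macro precision/recall match the confusion-table oracle", {
  # confusion {A->A:2, A->B:1, B->B:1, C->A:1}
  mk_p <- function(g) {
    p <- stats::setNames(rep(0, 23), gene_panel())
    names(p)[1:3] <- c("A", "B", "C")
    p[g] <- 1
    p
  }
  probs <- list(mk_p("A"), mk_p("A"), mk_p("B"), mk_p("B"), mk_p("A"))
  labels <- c("A", "A", "A", "B", "C")
  m <- evaluate_predictions(probs, labels)
  expect_equal(m$macro_precision, (2 / 3 + 1 / 2 + 0) / 3)
  expect_equal(m$macro_recall, (2 / 3 + 1 + 0) / 3)
  # duplicating the dataset leaves all metrics unchanged
  m2 <- evaluate_predictions(c(probs, probs), c(labels, labels))
  expect_equal(m2[c("top1_acc", "top3_acc", "macro_precision",
                    "macro_recall")],
               m[c("top1_acc", "top3_acc", "macro_precision",
                   "macro_recall")])
})

test_that("concordance scores reflect profile distance and cluster makeup", {
  # three flat genes at 20/30/40 dB, several patients each, one age bin
  recs <- list()
  for (g in c("A", "B", "C")) {
    lvl <- c(A = 20, B = 30, C = 40)[[g]]
    for (i in 1:5) {
      pid <- paste0(g, i)
      a <- mk_aud(paste0(pid, "-1"), pid, 25 + i / 2, lvl, gene = g)
      recs[[length(recs) + 1]] <- patient_record(pid, list(a), gene = g)
    }
  }
  fl <- otogene:::flatten_records(recs)
  x <- otogene:::feature_matrix(fl$audiograms)
  cm <- fit_clusters(x, k = 3, seed = 2)
  labs <- stats::setNames(fl$gene, fl$audiogram_id)
  profiles <- lapply(stats::setNames(nm = c("A", "B", "C")), function(g) {
    build_audioprofile(recs, g)
  })
  # a patient offset >= +40 dB from every profile: all distances >= 40
  shifted <- patient_record("q", list(mk_aud("q-1", "q", 26, 90)))
  conc <- concordance_scores(shifted, c("A", "B", "C"), profiles, cm, labs)
  expect_true(all(conc$profile_rms >= 40))
  # a patient equal to gene A's profile: zero distance, full support
  match_a <- patient_record("q2", list(mk_aud("q2-1", "q2", 26, 20)))
  conc_a <- concordance_scores(match_a, "A", profiles, cm, labs)
  expect_equal(conc_a$profile_rms, 0)
  expect_equal(conc_a$cluster_support, 1)
  # genes never seen in a cluster have zero support; missing profile is NA
  conc2 <- concordance_scores(match_a, "WFS1", profiles, cm, labs)
  expect_equal(conc2$cluster_support, 0)
  expect_true(is.na(conc2$profile_rms))
})

test_that("the confidence flag is a monotone threshold rule", {
  conc <- data.frame(gene = c("A", "B", "C"),
                     profile_rms = c(20, 14, 30),
                     cluster_support = c(0.5, 0.2, 0.01))
  expect_identical(confidence_flag(conc), "green")
  # exactly at the thresholds still green (<=, >= conventions)
  edge <- data.frame(gene = "A", profile_rms = 15, cluster_support = 0.05)
  expect_identical(confidence_flag(edge), "green")
  red <- data.frame(gene = c("A", "B"),
                    profile_rms = c(40, 16),
                    cluster_support = c(0.5, 0.5))
  expect_identical(confidence_flag(red), "red")
  # monotonicity: lowering rms / raising support never flips green -> red
  set.seed(7)
  for (i in 1:50) {
    f <- data.frame(gene = LETTERS[1:3],
                    profile_rms = runif(3, 0, 40),
                    cluster_support = runif(3, 0, 0.4))
    before <- confidence_flag(f)
    f2 <- f
    f2$profile_rms <- f$profile_rms * runif(3, 0.3, 1)
    f2$cluster_support <- pmin(f$cluster_support * runif(3, 1, 3), 1)
    after <- confidence_flag(f2)
    if (before == "green") expect_identical(after, "green")
  }
  # NA scores cannot support green
  na_conc <- data.frame(gene = "A", profile_rms = NA_real_,
                        cluster_support = 0.5)
  expect_identical(confidence_flag(na_conc), "red")
})

test_that("dataset summaries count genes, regions, and ages exactly", {
  recs <- list(
    patient_record("p1", list(
      mk_aud("a1", "p1", 30, 40, gene = "ACTG1", region = "Dutch"),
      mk_aud("a2", "p1", 35, 45, gene = "ACTG1", region = "Dutch")
    ), gene = "ACTG1"),
    patient_record("p2", list(
      mk_aud("a3", "p2", 50, 60, gene = "ACTG1", region = "German")
    ), gene = "ACTG1"),
    patient_record("p3", list(
      mk_aud("a4", "p3", 20, 20, gene = "COCH", region = NA)
    ), gene = "COCH")
  )
  s <- dataset_summaries(recs)
  expect_equal(s$gene_counts[["ACTG1"]], 3L)
  expect_equal(s$gene_counts[["COCH"]], 1L)
  expect_equal(sum(s$region_pie), 1)
  expect_equal(s$region_pie[["unknown"]], 0.25)
  expect_identical(nrow(s$age_scatter), 4L)
  expect_setequal(s$age_scatter$age, c(30, 35, 50, 20))
})
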