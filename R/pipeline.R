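# End-to-end orchestration: ingest/simulate -> impute -> fit classifiers
# -> cluster/embed -> per-patient reports -> cross-validated metrics ->
# JSON exports for the six dashboard panels.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Cross-validated routing metrics
#'
#' Patient-level stratified k-fold cross-validation of the full prediction
#' path: on each fold, both classifiers are fitted on the training
#' patients' audiograms and every held-out patient is scored through
#' [route_predict()] (single audiogram -> single-instance ensemble,
#' repeated audiograms -> multi-instance bag model). Metrics are computed
#' over the pooled held-out predictions.
#'
#' @param records Labeled patient records.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (drives fold assignment and model fitting).
#' @param si_conf An [si_config()]; its seed is overridden by `seed`.
#' @param panel Gene panel.
#' @return [evaluate_predictions()] result with an added `n_patients`
#'   element and per-patient `routes`.
#' @export
cv_route_metrics <- function(records, folds = 5L, seed = 1L,
                             si_conf = si_config(), panel = gene_panel()) {
  labels <- vapply(records, `[[`, "", "gene")
  keep <- which(!is.na(labels))
  records <- records[keep]; labels <- labels[keep]
  # canonical order, then stratified fold assignment
  ord <- order(labels, vapply(records, `[[`, "", "patient_id"))
  records <- records[ord]; labels <- labels[ord]
  set.seed(seed)
  fold <- integer(length(records))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  si_conf$seed <- as.integer(seed)
  probs <- vector("list", length(records))
  routes <- character(length(records))
  for (f in seq_len(folds)) {
    tr <- records[fold != f]; te <- which(fold == f)
    if (!length(te)) next
    si <- suppressWarnings(si_fit(tr, si_conf, panel = panel))
    mi <- suppressWarnings(mi_fit(tr, seed = seed, panel = panel))
    bag_size <- vapply(te, function(i) length(records[[i]]$audiograms), 0L)
    singles <- te[bag_size == 1L]
    if (length(singles)) {
      auds <- lapply(records[singles], function(r) r$audiograms[[1L]])
      P <- si_predict_matrix(si, auds)
      for (jj in seq_along(singles)) {
        probs[[singles[jj]]] <- P[jj, ]
        routes[singles[jj]] <- "single_instance"
      }
    }
    multis <- te[bag_size > 1L]
    if (length(multis)) {
      auds <- unlist(lapply(records[multis], `[[`, "audiograms"),
                     recursive = FALSE)
      owner <- rep(seq_along(multis),
                   times = bag_size[bag_size > 1L])
      M <- if (isTRUE(mi$degenerate)) NULL else mi_instance_matrix(mi, auds)
      for (jj in seq_along(multis)) {
        i <- multis[jj]
        full <- stats::setNames(rep(0, length(panel)), panel)
        if (is.null(M)) {
          full[mi$classes] <- 1
        } else {
          full[colnames(M)] <- colMeans(M[owner == jj, , drop = FALSE])
        }
        probs[[i]] <- full / sum(full)
        routes[i] <- "multi_instance"
      }
    }
  }
  out <- evaluate_predictions(probs, labels)
  out$n_patients <- length(records)
  out$routes <- routes
  out
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    seed = 1L, outdir = NULL, input = NULL, simulate = NULL,
    cv_folds = 5L, k_clusters = 23L, top_k = 3L,
    tau_rms = 15, tau_sup = 0.05, n_neighbors = 15L,
    degree_age = 3L, degree_freq = 3L
  )
  config <- utils::modifyList(defaults, as.list(config))
  if (is.null(config$outdir)) stop("config error: 'outdir' is required")
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("config error: provide 'input' (CSV path) or 'simulate' ",
         "(list with n_patients)")
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    stop("config error: input file not found: ", config$input)
  }
  config
}

#' Run the full prediction pipeline
#'
#' Executes every stage in order — ingest (or simulate), impute, fit the
#' single- and multi-instance classifiers, build per-gene audioprofiles and
#' surfaces, cluster and embed the training audiograms, produce a
#' per-patient prediction report with confidence flag, compute
#' cross-validated metrics, and export the six dashboard payloads plus
#' metrics — writing all artifacts under `config$outdir`. Reruns with the
#' same configuration are byte-identical in metrics and exports.
#'
#' @param config Either a list or the path of a JSON file. Keys: `input`
#'   (CSV path) *or* `simulate` (list with `n_patients`, optional
#'   `missing_rate`); `outdir` (required); `seed`; `cv_folds` (0 disables
#'   cross-validated metrics); `k_clusters`; `top_k`; `tau_rms`; `tau_sup`;
#'   `n_neighbors`; `degree_age`; `degree_freq`.
#' @return Invisibly, a list of artifacts: `records`, `si_model`,
#'   `mi_model`, `profiles`, `aps`, `cluster_model`, `embedding`,
#'   `cluster_labels`, `reports`, `metrics`, `summaries`, `log`.
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  stage <- function(name, pars, expr) {
    message(sprintf("[%s] %s", name,
                    paste(names(pars), unlist(pars), sep = "=",
                          collapse = " ")))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[name]] <<- c(pars, list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3)))
    res
  }

  records <- if (!is.null(config$input)) {
    stage("ingest", list(input = config$input),
          read_audiograms(config$input))
  } else {
    sim <- config$simulate
    recs <- stage("simulate",
                  list(n_patients = sim$n_patients, seed = config$seed),
                  simulate_cohort(default_sim_panel(), sim$n_patients,
                                  seed = config$seed))
    if (!is.null(sim$missing_rate) && sim$missing_rate > 0) {
      recs <- stage("missingness", list(rate = sim$missing_rate),
                    inject_missingness(recs, sim$missing_rate,
                                       seed = config$seed + 1L))
    }
    recs
  }
  records <- stage("impute", list(n_records = length(records)),
                   impute_records(records))

  labeled <- Filter(function(r) !is.na(r$gene), records)
  panel <- gene_panel()
  si_conf <- si_config(seed = config$seed)
  si <- stage("fit_si", list(seed = config$seed),
              suppressWarnings(si_fit(labeled, si_conf, panel = panel)))
  mi <- stage("fit_mi", list(seed = config$seed),
              suppressWarnings(mi_fit(labeled, seed = config$seed,
                                      panel = panel)))

  fl <- flatten_records(labeled)
  genes_present <- sort(unique(fl$gene[!is.na(fl$gene)]))
  profiles <- stage("audioprofiles", list(genes = length(genes_present)), {
    out <- lapply(genes_present, function(g) build_audioprofile(labeled, g))
    stats::setNames(out, genes_present)
  })
  aps <- stage("aps_surfaces", list(degree_age = config$degree_age,
                                    degree_freq = config$degree_freq), {
    out <- lapply(genes_present, function(g) {
      tryCatch(fit_aps(labeled, g, config$degree_age, config$degree_freq),
               error = function(e) NULL)
    })
    Filter(Negate(is.null), stats::setNames(out, genes_present))
  })

  feats <- feature_matrix(fl$audiograms)
  cluster_labels <- stats::setNames(fl$gene, fl$audiogram_id)
  cluster_model <- stage("cluster", list(k = config$k_clusters),
                         fit_clusters(feats, k = config$k_clusters,
                                      seed = config$seed))
  embedding <- stage("embed", list(n_neighbors = config$n_neighbors),
                     embed3d(feats, n_neighbors = config$n_neighbors,
                             seed = config$seed))

  reports <- stage("predict", list(n_patients = length(records)), {
    lapply(records, prediction_report, si_model = si, mi_model = mi,
           profiles = profiles, cluster_model = cluster_model,
           cluster_labels = cluster_labels, k = config$top_k,
           tau_rms = config$tau_rms, tau_sup = config$tau_sup)
  })

  metrics <- if (config$cv_folds >= 2L) {
    stage("evaluate", list(cv_folds = config$cv_folds),
          cv_route_metrics(labeled, folds = config$cv_folds,
                           seed = config$seed, si_conf = si_conf,
                           panel = panel))
  } else NULL

  summaries <- dataset_summaries(records)
  arts <- list(records = records, si_model = si, mi_model = mi,
               profiles = profiles, aps = aps,
               cluster_model = cluster_model, embedding = embedding,
               cluster_labels = cluster_labels, reports = reports,
               metrics = metrics, summaries = summaries, log = log)
  stage("export", list(outdir = config$outdir), {
    export_dashboard(arts, config$outdir)
    if (!is.null(metrics)) {
      write_json_file(metrics[c("top1_acc", "top3_acc", "macro_precision",
                                "macro_recall", "n_patients")],
                      file.path(config$outdir, "metrics.json"))
    }
    write_json_file(lapply(reports, unclass),
                    file.path(config$outdir, "reports.json"))
    saveRDS(si, file.path(config$outdir, "si_model.rds"))
    saveRDS(mi, file.path(config$outdir, "mi_model.rds"))
  })
  arts$log <- log
  invisible(arts)
}

#' Export the six dashboard payloads
#'
#' Writes renderer-agnostic JSON payloads, one per visualization panel:
#' audioprofile curves per gene, audioprofile surface grids, the
#' region-of-origin pie, the per-gene audiogram count bars, the cluster
#' composition plus 3D embedding scatter (with optional red patient
#' marker), and the age-distribution scatter. Every payload carries
#' `schema_version`. Re-export is idempotent.
#'
#' @param artifacts Artifact list as produced by [run_pipeline()] (or a
#'   manually assembled list with the same element names; missing elements
#'   skip the corresponding payload).
#' @param dir Output directory.
#' @param patient Optional [patient_record()] to overlay as the red marker
#'   in the audioprofile and cluster payloads.
#' @return Character vector of the files written.
#' @export
export_dashboard <- function(artifacts, dir, patient = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  grid <- freq_grid()
  emit <- function(name, payload) {
    path <- file.path(dir, paste0(name, ".json"))
    write_json_file(c(list(schema_version = "1.0", panel = name), payload),
                    path)
    written <<- c(written, path)
  }

  overlay <- if (!is.null(patient)) {
    lapply(patient$audiograms, function(a) {
      a <- impute_thresholds(a)
      list(age = a$age, thresholds = as.numeric(a$thresholds))
    })
  } else NULL

  if (!is.null(artifacts$profiles)) {
    emit("audioprofiles", list(
      frequencies_hz = grid,
      genes = lapply(artifacts$profiles, function(p) {
        rows <- which(p$count[, 1] > 0)
        list(
          gene = p$gene,
          age_bins = lapply(rows, function(b) {
            list(lo = p$age_bins[b, "lo"], hi = p$age_bins[b, "hi"],
                 mean_thr = as.numeric(p$mean_thr[b, ]),
                 n = as.integer(p$count[b, 1]))
          })
        )
      }),
      patient = overlay
    ))
  }

  if (!is.null(artifacts$aps)) {
    ages <- seq(0, 100, by = 5)
    emit("aps_surfaces", list(
      ages = ages, frequencies_hz = grid,
      genes = lapply(artifacts$aps, function(m) {
        z <- outer(ages, grid, function(a, f) eval_aps(m, a, f))
        list(gene = m$gene, fit_rmse = m$fit_rmse, surface = z)
      })
    ))
  }

  if (!is.null(artifacts$summaries)) {
    s <- artifacts$summaries
    emit("region_pie", list(fractions = as.list(s$region_pie)))
    emit("gene_counts", list(counts = as.list(s$gene_counts)))
    emit("age_scatter", list(points = s$age_scatter))
  }

  if (!is.null(artifacts$cluster_model) && !is.null(artifacts$embedding)) {
    cm <- artifacts$cluster_model
    marker <- if (!is.null(patient)) {
      pl <- place_patient(cm, artifacts$embedding,
                          patient$audiograms[[1L]])
      list(cluster = pl$cluster, coords = pl$coords)
    } else NULL
    comp <- cluster_composition(cm, artifacts$cluster_labels)
    emit("clusters", list(
      k = cm$k,
      composition = lapply(seq_len(cm$k), function(cl) {
        cnt <- comp[cl, comp[cl, ] > 0]
        list(cluster = cl, genes = as.list(cnt))
      }),
      points = data.frame(
        audiogram_id = rownames(artifacts$embedding$coords),
        cluster = as.integer(cm$assignments[
          rownames(artifacts$embedding$coords)]),
        gene = as.character(artifacts$cluster_labels[
          rownames(artifacts$embedding$coords)]),
        d1 = artifacts$embedding$coords[, 1],
        d2 = artifacts$embedding$coords[, 2],
        d3 = artifacts$embedding$coords[, 3],
        stringsAsFactors = FALSE
      ),
      patient_marker = marker
    ))
  }

  written
}
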