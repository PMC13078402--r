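# Top-k ranking, green/red confidence flagging from audioprofile and
# cluster concordance, evaluation metrics, and dataset summaries.

#' Top-k genes of a probability vector
#'
#' @param p Named probability vector over the gene panel.
#' @param k Number of genes to return (default 3).
#' @return Character vector of the k highest-probability genes; exact ties
#'   are broken by panel order (the order of `p`).
#' @export
top_genes <- function(p, k = 3L) {
  if (k > length(p)) stop("k exceeds the panel size")
  names(p)[order(-p, seq_along(p))][seq_len(k)]
}

#' Concordance of top-ranked genes with the training landscape
#'
#' For each candidate gene the two interpretability signals behind the
#' confidence flag: `profile_rms`, the mean (over the patient's audiograms)
#' RMS distance between the audiogram and the gene's audioprofile row for
#' the patient's age bin; and `cluster_support`, the mean fraction of
#' audiograms in the patient's assigned cluster(s) carrying that gene
#' label. A gene without a trainable audioprofile gets `NA` profile
#' distance (marked unavailable).
#'
#' @param record Patient record under evaluation.
#' @param genes Candidate genes (usually the top 3).
#' @param profiles Named list of [build_audioprofile()] objects.
#' @param cluster_model A [fit_clusters()] result on the training
#'   audiograms.
#' @param cluster_labels Gene labels of the training audiograms, named by
#'   audiogram id.
#' @return Data frame with columns `gene`, `profile_rms`, `cluster_support`.
#' @export
concordance_scores <- function(record, genes, profiles, cluster_model,
                               cluster_labels) {
  auds <- lapply(record$audiograms, impute_thresholds)
  if (!is.null(names(cluster_labels))) {
    cluster_labels <- cluster_labels[names(cluster_model$assignments)]
  }
  # cluster of each of the patient's audiograms
  clusters <- vapply(auds, function(a) {
    fv <- feature_vector(a)
    xc <- matrix((fv - cluster_model$std$center) / cluster_model$std$scale,
                 nrow = 1)
    nearest_centroid(xc, cluster_model$centers)
  }, 0L)
  support_of <- function(g) {
    mean(vapply(clusters, function(cl) {
      members <- cluster_model$assignments == cl
      if (!any(members)) return(0)
      mean(cluster_labels[members] == g, na.rm = TRUE)
    }, 0))
  }
  rms_of <- function(g) {
    if (is.null(profiles[[g]])) return(NA_real_)
    mean(vapply(auds, function(a) {
      as.numeric(profile_distance(a, profiles[[g]]))
    }, 0))
  }
  data.frame(
    gene = genes,
    profile_rms = vapply(genes, rms_of, 0),
    cluster_support = vapply(genes, support_of, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Green/red confidence flag
#'
#' Green if at least one candidate gene is concordant with the training
#' landscape — its audioprofile distance is at most `tau_rms` **and** its
#' cluster support is at least `tau_sup` — otherwise red. Unavailable
#' (`NA`) scores never support a green flag. The rule is monotone:
#' decreasing any profile distance or increasing any cluster support can
#' only move red toward green.
#'
#' @param concordance A [concordance_scores()] frame.
#' @param tau_rms Profile-distance threshold in dB (default 15).
#' @param tau_sup Cluster-support threshold as a fraction (default 0.05).
#' @return `"green"` or `"red"`.
#' @export
confidence_flag <- function(concordance, tau_rms = 15, tau_sup = 0.05) {
  ok <- !is.na(concordance$profile_rms) &
    concordance$profile_rms <= tau_rms &
    concordance$cluster_support >= tau_sup
  if (any(ok)) "green" else "red"
}

#' Full prediction report for one patient
#'
#' Routes the patient to the single- or multi-instance classifier, ranks
#' the gene panel, scores top-3 concordance and sets the confidence flag.
#'
#' @param record Patient record.
#' @param si_model,mi_model Trained classifiers.
#' @param profiles Named list of gene audioprofiles.
#' @param cluster_model,cluster_labels Cluster geometry (see
#'   [concordance_scores()]).
#' @param k Number of top genes reported (default 3).
#' @param tau_rms,tau_sup Flag thresholds (see [confidence_flag()]).
#' @return Object of class `"prediction_report"`.
#' @export
prediction_report <- function(record, si_model, mi_model, profiles,
                              cluster_model, cluster_labels, k = 3L,
                              tau_rms = 15, tau_sup = 0.05) {
  p <- route_predict(record, si_model, mi_model)
  ord <- order(-p, seq_along(p))
  ranked <- data.frame(gene = names(p)[ord], probability = as.numeric(p[ord]),
                       stringsAsFactors = FALSE)
  top <- ranked$gene[seq_len(k)]
  conc <- concordance_scores(record, top, profiles, cluster_model,
                             cluster_labels)
  structure(
    list(patient_id = record$patient_id, route = attr(p, "route"),
         ranked = ranked, top3 = top, concordance = conc,
         flag = confidence_flag(conc, tau_rms, tau_sup)),
    class = "prediction_report"
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report %s> route %s, flag %s\n",
              x$patient_id, x$route, x$flag))
  hdr <- merge(x$concordance,
               x$ranked[x$ranked$gene %in% x$top3, ], by = "gene",
               sort = FALSE)
  hdr <- hdr[match(x$top3, hdr$gene),
             c("gene", "probability", "profile_rms", "cluster_support")]
  print(hdr, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Evaluate ranked predictions against known labels
#'
#' Top-k accuracy is the fraction of patients whose causative gene appears
#' among the k highest-ranked predictions. Precision and recall use the
#' top-1 gene as the hard prediction and are macro-averaged over the
#' classes present in the labels (a class that is never predicted
#' contributes precision 0).
#'
#' @param probs List of named probability vectors (one per patient).
#' @param labels Character vector of true gene labels, same length.
#' @param k Ranking depth for top-k accuracy (default 3).
#' @return List: `top1_acc`, `top3_acc`, `macro_precision`, `macro_recall`,
#'   `per_class` (data frame with per-class precision/recall/support).
#' @export
evaluate_predictions <- function(probs, labels, k = 3L) {
  stopifnot(length(probs) == length(labels), length(labels) >= 1L)
  top1 <- vapply(probs, function(p) top_genes(p, 1L), "")
  topk <- vapply(seq_along(probs), function(i) {
    labels[i] %in% top_genes(probs[[i]], k)
  }, NA)
  classes <- sort(unique(labels))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(top1 == cl & labels == cl)
    n_pred <- sum(top1 == cl)
    n_true <- sum(labels == cl)
    data.frame(
      gene = cl,
      precision = if (n_pred > 0) tp / n_pred else 0,
      recall = tp / n_true,
      support = n_true,
      stringsAsFactors = FALSE
    )
  }))
  list(
    top1_acc = mean(top1 == labels),
    top3_acc = mean(topk),
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    per_class = per_class
  )
}

#' Dataset summaries for the context panels
#'
#' Exact per-gene audiogram counts (class-imbalance view), region-of-origin
#' fractions (empty regions bucketed as `"unknown"`; fractions sum to 1),
#' and the per-audiogram (gene, age) scatter.
#'
#' @param records List of patient records.
#' @return List: `gene_counts` (named integer vector), `region_pie` (named
#'   fractions), `age_scatter` (data frame `gene`, `age`).
#' @export
dataset_summaries <- function(records) {
  fl <- flatten_records(records)
  gene <- ifelse(is.na(fl$gene), "unlabeled", fl$gene)
  region <- ifelse(is.na(fl$region) | !nzchar(fl$region), "unknown",
                   fl$region)
  counts <- table(gene)
  pie <- table(region) / length(region)
  list(
    gene_counts = stats::setNames(as.integer(counts), names(counts)),
    region_pie = stats::setNames(as.numeric(pie), names(pie)),
    age_scatter = data.frame(gene = gene, age = fl$age,
                             stringsAsFactors = FALSE)
  )
}
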