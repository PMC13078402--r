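# Multi-instance classifier for patients with repeated audiograms: one
# margin classifier with sigmoid probability calibration per unordered
# class pair, iterative pairwise coupling into a multiclass distribution
# per audiogram, then bag-level aggregation across the patient's
# audiograms.

#' Couple pairwise class probabilities into a multiclass distribution
#'
#' Reconstructs a probability vector over K classes from the K(K-1)/2
#' one-vs-one probabilities using the iterative coupling scheme of Hastie &
#' Tibshirani: starting from the uniform vector, each class probability is
#' rescaled by the ratio of its observed pairwise wins to the wins implied
#' by the current estimate, until the fixed point of the minimum
#' Kullback-Leibler criterion is reached.
#'
#' @param pairwise K x K numeric matrix; `pairwise[i, j]` is the estimated
#'   probability that class `i` beats class `j`. Off-diagonal entries must
#'   all be present and strictly inside (0, 1); the diagonal is ignored.
#'   Row/column names carry the class labels.
#' @param tol Convergence tolerance on the maximum absolute probability
#'   update (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return Named probability vector over the K classes (sums to 1).
#' @export
#' @examples
#' r <- matrix(c(NA, 0.7, 0.3, NA), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' pairwise_coupling(r)  # c(A = 0.7, B = 0.3)
pairwise_coupling <- function(pairwise, tol = 1e-8, max_iter = 1000L) {
  K <- nrow(pairwise)
  stopifnot(K >= 2L, ncol(pairwise) == K)
  classes <- rownames(pairwise)
  off <- row(pairwise) != col(pairwise)
  vals <- pairwise[off]
  if (anyNA(vals)) stop("all off-diagonal pairwise probabilities required")
  if (any(vals <= 0 | vals >= 1)) {
    stop("pairwise probabilities must lie strictly inside (0, 1)")
  }
  p <- rep(1 / K, K)
  num <- rowSums(pairwise, na.rm = TRUE) -
    ifelse(is.na(diag(pairwise)), 0, diag(pairwise))
  for (iter in seq_len(max_iter)) {
    p_old <- p
    for (i in seq_len(K)) {
      den <- sum(p[i] / (p[i] + p[-i]))
      p[i] <- p[i] * num[i] / den
      p <- p / sum(p)
    }
    if (max(abs(p - p_old)) < tol) break
  }
  stats::setNames(p, classes)
}

#' Fit the multi-instance bag model
#'
#' Trains one support-vector margin classifier per unordered pair of gene
#' classes on the standardized per-audiogram feature vectors, and a sigmoid
#' (logistic) probability calibration on each classifier's decision values.
#' Classes with fewer than 2 audiograms are excluded with a warning.
#' Deterministic under `seed`; training rows are sorted canonically so the
#' fit is invariant to record order.
#'
#' @param records Labeled patient records.
#' @param seed Integer seed.
#' @param cost SVM cost parameter (default 1).
#' @param panel Gene panel for prediction output.
#' @return Object of class `"mi_model"`.
#' @export
mi_fit <- function(records, seed = 1L, cost = 1, panel = gene_panel()) {
  records <- impute_records(records)
  fl <- flatten_records(records)
  keep <- which(!is.na(fl$gene))
  if (!length(keep)) stop("mi_fit requires labeled records")
  gene <- fl$gene[keep]
  counts <- table(gene)
  excluded <- names(counts)[counts < 2L]
  if (length(excluded)) {
    warning("excluding singleton gene class(es): ",
            paste(excluded, collapse = ", "), call. = FALSE)
    keep <- keep[!gene %in% excluded]
    gene <- fl$gene[keep]
  }
  auds <- fl$audiograms[keep]
  ord <- order(gene, fl$patient_id[keep], fl$audiogram_id[keep])
  auds <- auds[ord]; gene <- gene[ord]
  X_raw <- feature_matrix(auds)
  center <- colMeans(X_raw)
  scale_ <- apply(X_raw, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  X <- sweep(sweep(X_raw, 2, center), 2, scale_, "/")
  classes <- sort(unique(gene))
  if (length(classes) < 2L) {
    return(structure(
      list(classes = classes, excluded = excluded, panel = panel,
           center = center, scale = scale_, degenerate = TRUE),
      class = "mi_model"
    ))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  set.seed(seed)
  pair_models <- lapply(pairs, function(pr) {
    rows <- which(gene %in% pr)
    y <- factor(gene[rows], levels = pr)   # first level is the "positive"
    sv <- e1071::svm(X[rows, , drop = FALSE], y, kernel = "radial",
                     cost = cost, scale = FALSE)
    dec <- drop(attr(predict(sv, X[rows, , drop = FALSE],
                             decision.values = TRUE), "decision.values"))
    # sigmoid calibration of decision values (Platt scaling)
    cal <- suppressWarnings(stats::glm.fit(
      cbind(1, dec), as.numeric(y == pr[1]),
      family = stats::binomial()
    ))$coefficients
    if (anyNA(cal)) cal <- c(0, 1)   # constant decision values
    list(pair = pr, svm = sv, calibration = cal)
  })
  names(pair_models) <- vapply(pairs, paste, "", collapse = "|")
  structure(
    list(classes = classes, excluded = excluded, panel = panel,
         center = center, scale = scale_, pair_models = pair_models,
         seed = seed, degenerate = FALSE),
    class = "mi_model"
  )
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf("<mi_model> %d classes, %d pairwise classifiers\n",
              length(x$classes),
              if (isTRUE(x$degenerate)) 0L else length(x$pair_models)))
  invisible(x)
}

# Coupled per-audiogram probabilities for a list of audiograms, batched so
# each pairwise classifier scores all rows in one call. Returns an
# n x n_classes matrix.
mi_instance_matrix <- function(model, auds) {
  auds <- lapply(auds, impute_thresholds)
  X_raw <- feature_matrix(auds)
  X <- sweep(sweep(X_raw, 2, model$center), 2, model$scale, "/")
  n <- nrow(X)
  K <- length(model$classes)
  eps <- 1e-6
  pair_p <- vapply(model$pair_models, function(pm) {
    dec <- drop(attr(predict(pm$svm, X, decision.values = TRUE),
                     "decision.values"))
    p <- stats::plogis(pm$calibration[1] + pm$calibration[2] * dec)
    pmin(pmax(p, eps), 1 - eps)
  }, numeric(n))
  pair_p <- matrix(pair_p, nrow = n)
  out <- matrix(NA_real_, n, K, dimnames = list(rownames(X_raw),
                                                model$classes))
  R <- matrix(NA_real_, K, K, dimnames = list(model$classes, model$classes))
  for (i in seq_len(n)) {
    for (m in seq_along(model$pair_models)) {
      pr <- model$pair_models[[m]]$pair
      R[pr[1], pr[2]] <- pair_p[i, m]
      R[pr[2], pr[1]] <- 1 - pair_p[i, m]
    }
    out[i, ] <- pairwise_coupling(R)
  }
  out
}

#' Predict gene probabilities for a patient bag
#'
#' Computes coupled per-audiogram probabilities and aggregates them over
#' the bag by arithmetic mean, then renormalizes over the gene panel
#' (genes absent from training receive probability 0). A bag of one
#' audiogram therefore equals the single-instance coupled prediction, and
#' the result is invariant to the order (and duplication) of audiograms in
#' the bag.
#'
#' @param model An [mi_fit()] result.
#' @param record A [patient_record()] with at least one audiogram.
#' @return Named probability vector over the gene panel.
#' @export
mi_predict <- function(model, record) {
  stopifnot(length(record$audiograms) >= 1L)
  full <- stats::setNames(rep(0, length(model$panel)), model$panel)
  if (isTRUE(model$degenerate)) {
    full[model$classes] <- 1
    return(full / sum(full))
  }
  probs <- mi_instance_matrix(model, record$audiograms)
  full[model$classes] <- colMeans(probs)
  full / sum(full)
}

#' Route a patient to the appropriate classifier
#'
#' Patients with a single audiogram are scored by the single-instance
#' ensemble; patients with two or more audiograms by the multi-instance bag
#' model. The chosen route is attached as attribute `"route"`.
#'
#' @param record A patient record.
#' @param si_model Trained [si_fit()] model.
#' @param mi_model Trained [mi_fit()] model.
#' @return Named probability vector over the gene panel with attribute
#'   `route` (`"single_instance"` or `"multi_instance"`).
#' @export
route_predict <- function(record, si_model, mi_model) {
  if (length(record$audiograms) <= 1L) {
    p <- si_predict(si_model, record$audiograms[[1L]])
    attr(p, "route") <- "single_instance"
  } else {
    p <- mi_predict(mi_model, record)
    attr(p, "route") <- "multi_instance"
  }
  p
}
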