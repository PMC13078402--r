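# Single-instance classifier: a heterogeneous ensemble whose submodels are
# trained on partitions of the labeled audiograms (by gene data volume,
# patient age, and audiogram shape) and fused by regularized multinomial
# logistic regression over out-of-fold submodel probabilities.

#' Single-instance ensemble configuration
#'
#' Defaults instantiate the 11-submodel committee: 3 k-nearest-neighbour
#' models bound to the three age strata (k = 5, 15, 31), 6 adaptive
#' boosting models bound to the volume x shape grid ({high, low} x {flat,
#' downsloping, other}), and 2 random forests bound to the volume strata,
#' plus the multinomial logistic fusion stage.
#'
#' @param knn_k Neighbourhood sizes of the three KNN submodels.
#' @param ada_trees Number of boosted decision stumps per boosting submodel.
#' @param rf_trees Trees per random forest submodel.
#' @param fusion_lambda Ridge penalty of the multinomial logistic fuser.
#' @param stacking_folds Folds used to produce out-of-fold submodel
#'   probabilities for fusion training (avoids stacking leakage).
#' @param age_breaks Age stratum boundaries in years: young `< age_breaks[1]`,
#'   mid `[age_breaks[1], age_breaks[2])`, old `>= age_breaks[2]`.
#' @param delta_db Shape-classification band threshold (see [shape_class()]).
#' @param seed Integer seed controlling all stochastic submodels.
#' @return List of class `"si_config"`.
#' @export
si_config <- function(knn_k = c(5L, 15L, 31L), ada_trees = 100L,
                      rf_trees = 200L, fusion_lambda = 1e-3,
                      stacking_folds = 5L, age_breaks = c(20, 60),
                      delta_db = 15, seed = 1L) {
  stopifnot(length(knn_k) == 3L, length(age_breaks) == 2L)
  structure(
    list(knn_k = as.integer(knn_k), ada_trees = as.integer(ada_trees),
         rf_trees = as.integer(rf_trees), fusion_lambda = fusion_lambda,
         stacking_folds = as.integer(stacking_folds),
         age_breaks = age_breaks, delta_db = delta_db,
         seed = as.integer(seed)),
    class = "si_config"
  )
}

age_stratum <- function(age, breaks) {
  ifelse(age < breaks[1], "young", ifelse(age < breaks[2], "mid", "old"))
}

#' Partition labeled audiograms for ensemble training
#'
#' Assigns every labeled training audiogram to the three partition axes:
#' gene data volume (`high` if the gene's audiogram count is at least the
#' median per-gene count, else `low`), patient age stratum (young < 20,
#' mid 20-59, old >= 60 by default), and audiogram shape
#' (see [shape_class()]). Each of the 11 ensemble submodels trains on a
#' fixed subset of these strata; every audiogram reaches at least one
#' submodel because the age strata cover all ages.
#'
#' @param records Labeled, imputed patient records.
#' @param config An [si_config()].
#' @return Data frame with one row per labeled audiogram: `audiogram_id`,
#'   `gene`, `age`, `volume`, `age_stratum`, `shape`.
#' @export
partition_training <- function(records, config = si_config()) {
  fl <- flatten_records(records)
  keep <- which(!is.na(fl$gene))
  if (!length(keep)) stop("no labeled audiograms to partition")
  gene <- fl$gene[keep]
  counts <- table(gene)
  volume <- ifelse(counts[gene] >= stats::median(as.numeric(counts)),
                   "high", "low")
  shape <- vapply(fl$audiograms[keep], shape_class, "",
                  delta_db = config$delta_db)
  data.frame(
    audiogram_id = fl$audiogram_id[keep],
    gene = gene,
    age = fl$age[keep],
    volume = as.character(volume),
    age_stratum = age_stratum(fl$age[keep], config$age_breaks),
    shape = shape,
    stringsAsFactors = FALSE
  )
}

# The stratum binding of the 11 submodels. Each entry: submodel name, type,
# and a predicate over the partition frame selecting its training rows.
submodel_spec <- function(config) {
  shp_group <- function(s) {
    ifelse(s == "flat", "flat", ifelse(s == "downsloping", "downsloping",
                                       "other"))
  }
  spec <- list()
  ages <- c("young", "mid", "old")
  for (i in 1:3) {
    a <- ages[i]
    spec[[paste0("knn_", a)]] <- list(
      type = "knn", k = config$knn_k[i],
      select = local({a0 <- a; function(p) p$age_stratum == a0})
    )
  }
  for (v in c("high", "low")) for (g in c("flat", "downsloping", "other")) {
    spec[[paste0("ada_", v, "_", g)]] <- list(
      type = "ada",
      select = local({
        v0 <- v; g0 <- g
        function(p) p$volume == v0 & shp_group(p$shape) == g0
      })
    )
  }
  for (v in c("high", "low")) {
    spec[[paste0("rf_", v)]] <- list(
      type = "rf",
      select = local({v0 <- v; function(p) p$volume == v0})
    )
  }
  spec
}

# --- submodel primitives -------------------------------------------------

# KNN class-probability estimates. class::knn() reports only the winning
# class's vote share, so vote fractions over all classes are computed
# directly. Points tying with the k-th smallest distance are all included,
# which makes the estimate invariant to training-row order.
knn_prob <- function(Xtr, ytr, Xnew, k, classes) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(Xnew)), rowSums(Xtr^2)) - 2 * Xnew %*% t(Xtr)
  out <- matrix(0, nrow(Xnew), length(classes),
                dimnames = list(NULL, classes))
  for (i in seq_len(nrow(Xnew))) {
    di <- d2[i, ]
    kd <- sort(di, partial = k)[k]
    nb <- which(di <= kd + 1e-12)
    tab <- table(factor(ytr[nb], levels = classes))
    out[i, ] <- as.numeric(tab) / length(nb)
  }
  out
}

# Multiclass adaptive boosting (SAMME) over depth-1 decision stumps.
# No boosted-stump implementation ships with the imported model packages,
# so the reweighting loop is written here on top of rpart weak learners.
ada_fit <- function(X, y, n_trees, maxdepth = 1L) {
  classes <- levels(y)
  K <- length(classes)
  df <- data.frame(X, y = y)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = -1, minsplit = 2L,
                               xval = 0L, maxcompete = 0L,
                               maxsurrogate = 0L)
  for (m in seq_len(n_trees)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y])
    if (err <= 1e-10) {            # perfect stump: keep it, stop boosting
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 1 - 1 / K) break    # no better than chance: stop
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  priors <- as.numeric(table(y)) / n
  list(stumps = stumps, alphas = alphas, classes = classes,
       priors = priors, feat_names = colnames(X))
}

ada_prob <- function(model, Xnew) {
  classes <- model$classes
  out <- matrix(0, nrow(Xnew), length(classes),
                dimnames = list(NULL, classes))
  if (!length(model$stumps)) {     # degenerate: fall back to class priors
    out[] <- rep(model$priors, each = nrow(Xnew))
    return(out)
  }
  df <- as.data.frame(Xnew)
  colnames(df) <- model$feat_names
  for (m in seq_along(model$stumps)) {
    pred <- predict(model$stumps[[m]], df, type = "class")
    idx <- cbind(seq_len(nrow(df)), match(as.character(pred), classes))
    out[idx] <- out[idx] + model$alphas[m]
  }
  out / rowSums(out)
}

# Train one submodel on its stratum rows (or all rows with a warning if
# the stratum is empty). `rows` indexes into X/y.
fit_submodel <- function(name, def, X, y, rows, config, seed_offset,
                         warn = TRUE) {
  if (!length(rows) || length(unique(y[rows])) < 1L) {
    if (warn) {
      warning(sprintf("submodel %s: empty stratum; training on full data",
                      name), call. = FALSE)
    }
    rows <- seq_len(nrow(X))
  }
  Xs <- X[rows, , drop = FALSE]
  ys <- droplevels(y[rows])
  fit <- switch(def$type,
    knn = list(X = Xs, y = as.character(ys), k = def$k),
    ada = {
      set.seed(seed_offset)
      ada_fit(Xs, ys, config$ada_trees)
    },
    rf = {
      set.seed(seed_offset)
      if (nlevels(ys) >= 2L) {
        randomForest::randomForest(Xs, ys, ntree = config$rf_trees)
      } else {
        list(single_class = levels(ys))
      }
    }
  )
  list(type = def$type, fit = fit, k = def$k, classes = levels(ys))
}

predict_submodel <- function(sub, Xnew, classes) {
  raw <- switch(sub$type,
    knn = knn_prob(sub$fit$X, sub$fit$y, Xnew, sub$fit$k, sub$classes),
    ada = ada_prob(sub$fit, Xnew),
    rf = {
      if (!is.null(sub$fit$single_class)) {
        matrix(1, nrow(Xnew), 1, dimnames = list(NULL, sub$fit$single_class))
      } else {
        predict(sub$fit, Xnew, type = "prob")
      }
    }
  )
  out <- matrix(0, nrow(Xnew), length(classes),
                dimnames = list(NULL, classes))
  out[, colnames(raw)] <- raw
  out
}

# Stacked fusion features: one probability block per submodel, columns
# named submodel.class.
fusion_features <- function(prob_blocks) {
  do.call(cbind, lapply(names(prob_blocks), function(nm) {
    b <- prob_blocks[[nm]]
    colnames(b) <- paste(nm, colnames(b), sep = ".")
    b
  }))
}

#' Fit the single-instance ensemble
#'
#' Trains the 11 partitioned submodels and the multinomial logistic fusion
#' stage. Fusion is trained on out-of-fold submodel probabilities
#' (internal stratified k-fold stacking) so the fuser never sees a
#' submodel's prediction on its own training point. Gene classes with fewer
#' than 2 audiograms are excluded with a warning and recorded in the model
#' metadata. Training is deterministic under `config$seed` and invariant to
#' the order of the input records (rows are sorted canonically before any
#' stochastic step).
#'
#' @param records Labeled patient records (audiograms are imputed
#'   internally if incomplete).
#' @param config An [si_config()].
#' @param panel Gene panel over which predictions are reported.
#' @return Object of class `"si_model"`.
#' @export
si_fit <- function(records, config = si_config(), panel = gene_panel()) {
  records <- impute_records(records)
  fl <- flatten_records(records)
  keep <- which(!is.na(fl$gene))
  if (!length(keep)) stop("si_fit requires labeled records")
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
  # canonical ordering: determinism + invariance to input record order
  ord <- order(gene, fl$patient_id[keep], fl$audiogram_id[keep])
  auds <- auds[ord]; gene <- gene[ord]
  X_raw <- feature_matrix(auds)
  center <- colMeans(X_raw)
  scale_ <- apply(X_raw, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  X <- sweep(sweep(X_raw, 2, center), 2, scale_, "/")
  y <- factor(gene)
  classes <- levels(y)
  part <- partition_training_frame(auds, gene, config)

  spec <- submodel_spec(config)
  n <- nrow(X)

  if (length(classes) < 2L) {
    return(structure(
      list(config = config, panel = panel, center = center,
           scale = scale_, classes = classes, excluded = excluded,
           degenerate = TRUE),
      class = "si_model"
    ))
  }

  # out-of-fold stacking features for the fusion stage
  set.seed(config$seed)
  folds <- integer(n)
  for (cl in classes) {
    idx <- sample(which(gene == cl))
    folds[idx] <- rep_len(seq_len(config$stacking_folds), length(idx))
  }
  oof <- lapply(spec, function(def) {
    matrix(0, n, length(classes), dimnames = list(NULL, classes))
  })
  for (f in seq_len(config$stacking_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (!length(te)) next
    for (nm in names(spec)) {
      rows <- intersect(tr, which(spec[[nm]]$select(part)))
      sub <- fit_submodel(nm, spec[[nm]], X[tr, , drop = FALSE],
                          droplevels(y[tr]),
                          match(rows, tr), config,
                          seed_offset = config$seed + 1000L * f +
                            match(nm, names(spec)), warn = FALSE)
      oof[[nm]][te, ] <- predict_submodel(sub, X[te, , drop = FALSE],
                                          classes)
    }
  }

  # final submodels on the full strata
  submodels <- list()
  for (nm in names(spec)) {
    rows <- which(spec[[nm]]$select(part))
    submodels[[nm]] <- fit_submodel(nm, spec[[nm]], X, y, rows, config,
                                    seed_offset = config$seed +
                                      match(nm, names(spec)))
  }

  Z <- fusion_features(oof)
  lam <- config$fusion_lambda * c(1000, 100, 10, 1)
  fusion <- glmnet::glmnet(Z, y, family = "multinomial", alpha = 0,
                           lambda = lam, standardize = FALSE)
  structure(
    list(config = config, panel = panel, center = center, scale = scale_,
         classes = classes, excluded = excluded, partition = part,
         submodels = submodels, fusion = fusion,
         fusion_colnames = colnames(Z), degenerate = FALSE),
    class = "si_model"
  )
}

# partition frame for an already-flattened, labeled audiogram list
partition_training_frame <- function(auds, gene, config) {
  counts <- table(gene)
  data.frame(
    audiogram_id = vapply(auds, `[[`, "", "audiogram_id"),
    gene = gene,
    age = vapply(auds, `[[`, 0, "age"),
    volume = ifelse(counts[gene] >= stats::median(as.numeric(counts)),
                    "high", "low"),
    age_stratum = age_stratum(vapply(auds, `[[`, 0, "age"),
                              config$age_breaks),
    shape = vapply(auds, shape_class, "", delta_db = config$delta_db),
    stringsAsFactors = FALSE
  )
}

#' @export
print.si_model <- function(x, ...) {
  cat(sprintf(
    "<si_model> %d gene classes, %d submodels + logistic fusion%s\n",
    length(x$classes),
    if (isTRUE(x$degenerate)) 0L else length(x$submodels),
    if (length(x$excluded)) paste0(" (excluded: ",
                                   paste(x$excluded, collapse = ", "), ")")
    else ""
  ))
  invisible(x)
}

#' Predict gene probabilities for a single audiogram
#'
#' Every submodel scores the (standardized) feature vector of the
#' audiogram — each submodel having learned the regularities of its own
#' training stratum — and the logistic fusion stage combines the 11
#' probability blocks. The result is renormalized over the full gene
#' panel, with genes absent from training receiving probability 0.
#'
#' @param model An [si_fit()] result.
#' @param aud An audiogram (imputed internally if incomplete).
#' @return Named numeric vector over the gene panel, summing to 1.
#' @export
si_predict <- function(model, aud) {
  drop(si_predict_matrix(model, list(aud)))
}

# Batched prediction: one row per audiogram, columns = gene panel.
si_predict_matrix <- function(model, auds) {
  auds <- lapply(auds, impute_thresholds)
  X_raw <- feature_matrix(auds)
  X <- sweep(sweep(X_raw, 2, model$center), 2, model$scale, "/")
  full <- matrix(0, nrow(X), length(model$panel),
                 dimnames = list(rownames(X_raw), model$panel))
  if (isTRUE(model$degenerate)) {
    full[, model$classes] <- 1
    return(full / rowSums(full))
  }
  blocks <- lapply(model$submodels, predict_submodel, Xnew = X,
                   classes = model$classes)
  Z <- fusion_features(blocks)
  Z <- Z[, model$fusion_colnames, drop = FALSE]
  p <- predict(model$fusion, Z, type = "response",
               s = model$config$fusion_lambda)[, , 1]
  p <- matrix(p, nrow = nrow(Z), dimnames = list(NULL, model$classes))
  full[, model$classes] <- pmax(p, 0)
  full / rowSums(full)
}
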