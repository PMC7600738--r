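# Origin classifiers: precomputed-kernel SVM on MAP4 signatures with Platt
# probability calibration, MAP4 k-NN, and an RBF SVM on physico-chemical
# descriptors. Positive class is "bacterium" throughout.

ORIGIN_LEVELS <- c("fungus", "bacterium")
PHYSCHEM_FEATURES <- c("mw", "fsp3c", "hba", "hbd", "alogp", "tpsa", "t_joback")

#' Cross-validation configuration for the origin classifiers
#'
#' Defaults follow the published training protocol: 5 folds, `C` grid
#' {0.1, 1, 10, 100, 1000}, `k` grid {5, 7, 9, 11}, `gamma` grid
#' {0.01, 0.1, 1, 10, 100}, selection by validation ROC AUC. Folds are
#' stratified by class.
#'
#' @param folds Number of CV folds (>= 2).
#' @param C_grid,k_grid,gamma_grid Hyperparameter grids (non-empty).
#' @param seed Integer seed controlling fold assignment.
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 5L, C_grid = c(0.1, 1, 10, 100, 1000),
                      k_grid = c(5L, 7L, 9L, 11L),
                      gamma_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  stopifnot(folds >= 2, length(C_grid) > 0, length(k_grid) > 0,
            length(gamma_grid) > 0)
  structure(list(folds = as.integer(folds), C_grid = C_grid,
                 k_grid = as.integer(k_grid), gamma_grid = gamma_grid,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# Stratified fold assignment: within each class, molecules are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      ix <- which(labels == cl)
      fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    fold
  })
}

check_labels <- function(origin) {
  if (!all(origin %in% ORIGIN_LEVELS)) {
    stop("origin labels must be 'bacterium' or 'fungus'")
  }
  if (length(unique(origin)) < 2) {
    stop("single-class training set: both origins must be present")
  }
  factor(origin, levels = ORIGIN_LEVELS)
}

# Class weights inversely proportional to class frequency, normalized so
# the mean weight is 1.
inverse_class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

#' Similarity kernel matrix between two signature sets
#'
#' Entry `(i, j)` is [estimate_similarity()] of signature `i` of `A` and
#' signature `j` of `B`; a square matrix over one set is symmetric with a
#' unit diagonal.
#'
#' @param A,B Signature matrices with equal column counts (`B` defaults to
#'   `A`).
#' @return Numeric matrix of estimated Jaccard similarities.
#' @export
kernel_matrix <- function(A, B = A) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  if (ncol(A) != ncol(B)) stop("signature length mismatch")
  K <- simmat_cpp(A, B)
  dimnames(K) <- list(rownames(A), rownames(B))
  K
}

# Fit a C-SVC on a precomputed kernel; returns the pieces needed to score
# new rows (support indices, orientation so larger decision = bacterium).
fit_kernel_svc <- function(K, y, C, weights) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C,
                     class.weights = weights)
  sv <- kernlab::SVindex(m)
  dec <- as.numeric(kernlab::predict(
    m, kernlab::as.kernelMatrix(K[, sv, drop = FALSE]), type = "decision"))
  orient <- if (mean(dec[y == "bacterium"]) >= mean(dec[y == "fungus"])) 1 else -1
  list(model = m, sv = sv, orient = orient)
}

score_kernel_svc <- function(fit, Knew) {
  dec <- as.numeric(kernlab::predict(
    fit$model, kernlab::as.kernelMatrix(Knew[, fit$sv, drop = FALSE]),
    type = "decision"))
  fit$orient * dec
}

# Platt scaling: logistic fit of class on cross-validated decision values.
fit_platt <- function(decision, y) {
  df <- data.frame(d = decision, y = as.integer(y == "bacterium"))
  fit <- suppressWarnings(glm(y ~ d, family = binomial(), data = df))
  coef(fit)
}

apply_platt <- function(platt, decision) {
  1 / (1 + exp(-(platt[1] + platt[2] * decision)))
}

# Decision values for every training row, each scored by a model fitted
# with that row's fold held out.
cv_decision_values <- function(K, y, C, weights, fold) {
  dec <- numeric(length(y))
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); va <- which(fold == f)
    fit <- fit_kernel_svc(K[tr, tr, drop = FALSE], y[tr], C, weights)
    dec[va] <- score_kernel_svc(fit, K[va, tr, drop = FALSE])
  }
  dec
}

# .kind: dot-prefixed so short model fields like `k` cannot partially
# match the formal by name.
new_origin_model <- function(.kind, ...) {
  structure(list(kind = .kind, version = MAP4NP_ENCODING_VERSION, ...),
            class = "origin_model")
}

#' Train the MAP4-kernel SVM origin classifier
#'
#' A C-SVC on the precomputed estimated-Jaccard similarity kernel between
#' MAP4 signatures, with class weights inversely proportional to class
#' frequency. `C` is selected by stratified k-fold cross-validation
#' maximizing validation ROC AUC; probabilities come from Platt scaling
#' fitted on cross-validated decision values of the training set.
#'
#' @param train Molecule tibble with `compound_id`, `smiles_canonical` and
#'   `origin` in `{bacterium, fungus}` (deduplicated).
#' @param signatures Signature matrix for (at least) the training
#'   molecules, rownames = compound ids.
#' @param cv A [cv_config()].
#' @return An `origin_model` of kind `map4_svm`.
#' @export
train_map4_svm <- function(train, signatures, cv = cv_config()) {
  y <- check_labels(train$origin)
  sig <- signatures[train$compound_id, , drop = FALSE]
  K <- kernel_matrix(sig)
  weights <- inverse_class_weights(y)
  fold <- stratified_folds(as.character(y), cv$folds, cv$seed)
  cv_auc <- vapply(cv$C_grid, function(C) {
    dec <- cv_decision_values(K, y, C, weights, fold)
    roc_auc(as.character(y), dec)
  }, numeric(1))
  best <- which.max(cv_auc)
  C_star <- cv$C_grid[best]
  dec_cv <- cv_decision_values(K, y, C_star, weights, fold)
  platt <- fit_platt(dec_cv, y)
  fit <- fit_kernel_svc(K, y, C_star, weights)
  new_origin_model(
    "map4_svm",
    fit = fit, platt = platt, C = C_star,
    cv_results = tibble::tibble(C = cv$C_grid, cv_roc_auc = cv_auc),
    train_ids = train$compound_id, train_labels = as.character(y),
    train_signatures = sig, class_weights = weights, cv = cv
  )
}

#' Train the MAP4 k-NN origin classifier
#'
#' k-nearest neighbors under the estimated Jaccard distance (one minus the
#' signature similarity); `k` is selected by stratified cross-validation
#' maximizing ROC AUC. The predicted probability is the unweighted fraction
#' of bacterial neighbors; distance ties are broken by molecule id.
#'
#' @inheritParams train_map4_svm
#' @return An `origin_model` of kind `map4_knn`.
#' @export
train_map4_knn <- function(train, signatures, cv = cv_config()) {
  y <- check_labels(train$origin)
  sig <- signatures[train$compound_id, , drop = FALSE]
  if (any(cv$k_grid > nrow(sig) - 1)) {
    stop("k grid exceeds training-set size")
  }
  K <- kernel_matrix(sig)
  fold <- stratified_folds(as.character(y), cv$folds, cv$seed)
  knn_prob <- function(simrow, ids, lab, k) {
    ord <- order(1 - simrow, ids, method = "radix")
    mean(lab[utils::head(ord, k)] == "bacterium")
  }
  cv_auc <- vapply(cv$k_grid, function(k) {
    prob <- numeric(length(y))
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); va <- which(fold == f)
      prob[va] <- vapply(va, function(i) {
        knn_prob(K[i, tr], train$compound_id[tr], as.character(y)[tr], k)
      }, numeric(1))
    }
    roc_auc(as.character(y), prob)
  }, numeric(1))
  best <- which.max(cv_auc)
  new_origin_model(
    "map4_knn",
    k = cv$k_grid[best],
    cv_results = tibble::tibble(k = cv$k_grid, cv_roc_auc = cv_auc),
    train_ids = train$compound_id, train_labels = as.character(y),
    train_signatures = sig, cv = cv
  )
}

#' Train the physico-chemical RBF SVM origin classifier
#'
#' An RBF-kernel SVM on MW, fsp3C, HBA, HBD, AlogP, TPSA and the Joback
#' boiling point, scaled to zero mean and unit variance on the training set
#' only. `C` and `gamma` are selected by stratified grid-search
#' cross-validation on ROC AUC; class weights are inverse class
#' frequencies; probabilities via Platt scaling as for the kernel SVM.
#' Constant features are dropped with a warning.
#'
#' @param train Molecule tibble with `compound_id`, `origin`, and the
#'   descriptor columns (see [annotate_properties()]); descriptors are
#'   computed from SMILES when absent.
#' @param cv A [cv_config()].
#' @return An `origin_model` of kind `physchem_svm`.
#' @export
train_physchem_svm <- function(train, cv = cv_config()) {
  y <- check_labels(train$origin)
  if (!all(PHYSCHEM_FEATURES %in% names(train))) {
    train <- joback_boiling_point(compute_descriptors(train))
  }
  X <- as.matrix(train[, PHYSCHEM_FEATURES])
  X[is.na(X)] <- 0
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  keep <- sdev > 0
  if (any(!keep)) {
    warning("dropping constant feature(s): ",
            paste(PHYSCHEM_FEATURES[!keep], collapse = ", "))
  }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  weights <- inverse_class_weights(y)
  fold <- stratified_folds(as.character(y), cv$folds, cv$seed)
  rbf_K <- function(A, B, gamma) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    exp(-gamma * pmax(d2, 0))
  }
  grid <- expand.grid(C = cv$C_grid, gamma = cv$gamma_grid)
  cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    K <- rbf_K(Xs, Xs, grid$gamma[g])
    dec <- cv_decision_values(K, y, grid$C[g], weights, fold)
    roc_auc(as.character(y), dec)
  }, numeric(1))
  best <- which.max(cv_auc)
  C_star <- grid$C[best]; gamma_star <- grid$gamma[best]
  K <- rbf_K(Xs, Xs, gamma_star)
  dec_cv <- cv_decision_values(K, y, C_star, weights, fold)
  platt <- fit_platt(dec_cv, y)
  fit <- fit_kernel_svc(K, y, C_star, weights)
  new_origin_model(
    "physchem_svm",
    fit = fit, platt = platt, C = C_star, gamma = gamma_star,
    cv_results = tibble::as_tibble(cbind(grid, cv_roc_auc = cv_auc)),
    scaler = list(mu = mu[keep], sd = sdev[keep], features = PHYSCHEM_FEATURES[keep]),
    train_ids = train$compound_id, train_labels = as.character(y),
    train_features = Xs,
    train_signatures = NULL, class_weights = weights, cv = cv
  )
}

#' Predict the microbial origin of molecules
#'
#' Applies a trained [train_map4_svm()], [train_map4_knn()] or
#' [train_physchem_svm()] model. Output probabilities satisfy
#' `p_fungal + p_bacterial = 1`; the binary label uses a 0.5 threshold
#' (exactly 0.5 is called bacterial). For MAP4 models, the training-set
#' nearest neighbor and its estimated Jaccard distance are reported.
#'
#' @param model An `origin_model`.
#' @param data Molecule tibble with a SMILES column (unparseable rows are
#'   reported with `NA` probabilities and an `error` note), or a character
#'   vector of SMILES.
#' @param family [hash_family()] used for fingerprints (MAP4 models).
#' @return Tibble: `compound_id`, `smiles`, `p_fungal`, `p_bacterial`,
#'   `label`, `nn_id`, `nn_jaccard_distance`, `error`.
#' @export
predict_origin <- function(model, data, family = hash_family()) {
  stopifnot(inherits(model, "origin_model"))
  if (is.character(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- paste0("q", seq_along(data))
    data <- tibble::tibble(compound_id = ids, smiles_raw = unname(data))
  }
  smi_in <- pick_smiles(data)
  can <- smi_canonical(smi_in)
  ok <- !is.na(can)
  n <- nrow(data)
  out <- tibble::tibble(
    compound_id = data$compound_id,
    smiles = smi_in,
    p_fungal = NA_real_, p_bacterial = NA_real_,
    label = NA_character_, nn_id = NA_character_,
    nn_jaccard_distance = NA_real_,
    error = ifelse(ok, NA_character_, "SMILES failed to parse")
  )
  if (!any(ok)) return(out)
  qdf <- tibble::tibble(compound_id = data$compound_id[ok],
                        smiles_canonical = can[ok])
  p_bact <- rep(NA_real_, sum(ok))
  if (model$kind %in% c("map4_svm", "map4_knn")) {
    qsig <- map4_fingerprint(qdf, family)
    Kq <- kernel_matrix(qsig, model$train_signatures)
    if (model$kind == "map4_svm") {
      dec <- score_kernel_svc(model$fit, Kq)
      p_bact <- apply_platt(model$platt, dec)
    } else {
      p_bact <- vapply(seq_len(nrow(Kq)), function(i) {
        ord <- order(1 - Kq[i, ], model$train_ids, method = "radix")
        mean(model$train_labels[utils::head(ord, model$k)] == "bacterium")
      }, numeric(1))
    }
    nn <- apply(Kq, 1, which.max)
    out$nn_id[ok] <- model$train_ids[nn]
    out$nn_jaccard_distance[ok] <- 1 - Kq[cbind(seq_len(nrow(Kq)), nn)]
  } else {
    props <- joback_boiling_point(compute_descriptors(qdf))
    X <- as.matrix(props[, model$scaler$features])
    X[is.na(X)] <- 0
    Xs <- sweep(sweep(X, 2, model$scaler$mu), 2, model$scaler$sd, "/")
    d2 <- outer(rowSums(Xs^2), rowSums(model$train_features^2), "+") -
      2 * Xs %*% t(model$train_features)
    Kq <- exp(-model$gamma * pmax(d2, 0))
    dec <- score_kernel_svc(model$fit, Kq)
    p_bact <- apply_platt(model$platt, dec)
  }
  out$p_bacterial[ok] <- as.numeric(p_bact)
  out$p_fungal[ok] <- 1 - as.numeric(p_bact)
  out$label[ok] <- ifelse(p_bact >= 0.5, "bacterium", "fungus")
  out
}

#' Save / load an origin model bundle
#'
#' Single-file serialized bundle carrying the model, its encoding version
#' and hyperparameters; loading refuses bundles from an incompatible
#' encoding version.
#'
#' @param model An `origin_model`.
#' @param path File path.
#' @return The path (save) or the model (load).
#' @export
save_origin_model <- function(model, path) {
  stopifnot(inherits(model, "origin_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_origin_model
#' @export
load_origin_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "origin_model") ||
      !identical(model$version, MAP4NP_ENCODING_VERSION)) {
    stop("model bundle version does not match this package's encoding version")
  }
  model
}

#' @export
print.origin_model <- function(x, ...) {
  cat("<origin_model>", x$kind, "\n")
  cat("  training molecules:", length(x$train_ids), "\n")
  hp <- switch(x$kind,
    map4_svm = paste0("C = ", x$C),
    map4_knn = paste0("k = ", x$k),
    physchem_svm = paste0("C = ", x$C, ", gamma = ", x$gamma))
  cat("  hyperparameters:", hp, "\n")
  invisible(x)
}

#' Tidy the cross-validation trace of an origin model
#'
#' @param x An `origin_model`.
#' @param ... Unused.
#' @return Tibble of hyperparameter candidates and their validation ROC
#'   AUC, with the selected combination flagged.
#' @export
tidy.origin_model <- function(x, ...) {
  res <- x$cv_results
  res$selected <- switch(x$kind,
    map4_svm = res$C == x$C,
    map4_knn = res$k == x$k,
    physchem_svm = res$C == x$C & res$gamma == x$gamma)
  res
}

#' One-row summary of an origin model
#'
#' @param x An `origin_model`.
#' @param ... Unused.
#' @return One-row tibble: kind, selected hyperparameters, best validation
#'   ROC AUC, training size and class balance.
#' @export
glance.origin_model <- function(x, ...) {
  tibble::tibble(
    kind = x[["kind"]],
    C = if (is.null(x[["C"]])) NA_real_ else x[["C"]],
    gamma = if (is.null(x[["gamma"]])) NA_real_ else x[["gamma"]],
    k = if (is.null(x[["k"]])) NA_integer_ else as.integer(x[["k"]]),
    cv_roc_auc = max(x$cv_results$cv_roc_auc),
    n_train = length(x$train_ids),
    n_bacterium = sum(x$train_labels == "bacterium"),
    n_fungus = sum(x$train_labels == "fungus")
  )
}
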