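#' @title PDT classifiers: SVM, RBF network, random forest
#'
#' @description
#' Three classifier families under one contract: every model is fitted
#' from a [labeled_dataset()] and exposes a real-valued score that is
#' monotone in the evidence for the positive (patient) class, so all
#' three feed the same ROC machinery.
#' \itemize{
#'   \item SVM: maximum-margin separator with polynomial kernel
#'     `K(x, z) = (x . z + 1)^d`; the score is the signed margin
#'     `f(x) = sum_i alpha_i y_i K(x_i, x) + b`.
#'   \item RBFN: hidden neurons respond by Gaussian distance to K-means
#'     prototype vectors, `a_i(x) = exp(-beta_i ||x - mu_i||^2)`; class
#'     scores are linear read-outs `s_j(x) = sum_i w_ij a_i(x)` and the
#'     decision is the argmax; the ROC score is the positive-class
#'     softmax.
#'   \item RF: bootstrap ensemble of decision trees with random feature
#'     subsets per split; the score is the fraction of trees voting
#'     positive.
#' }
#' Ties at the decision boundary go to the negative (control) class.
#' Features are standardised (zero mean, unit variance, fitted on the
#' training data only) before SVM and RBFN training; the forest sees raw
#' features.
#'
#' @name pdt-classifiers
NULL

#' Construct a labelled dataset
#'
#' @param X numeric matrix, one row per subject.
#' @param y class labels, +1 (patient) or -1 (control).
#' @param feature_names optional column names.
#' @return An object of class `pdt_dataset` with elements `X`, `y`,
#'   `feature_names`.
#' @export
labeled_dataset <- function(X, y, feature_names = colnames(X)) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X)))
    stop_pdt("features contain missing or non-finite values",
             "pdt_data_error")
  if (nrow(X) != length(y))
    stop_pdt("X and y disagree in length", "pdt_data_error")
  if (nrow(X) < 2L)
    stop_pdt("need at least 2 subjects", "pdt_data_error")
  if (!all(y %in% c(-1, 1)))
    stop_pdt("labels must be +1 (patient) or -1 (control)",
             "pdt_data_error")
  if (is.null(feature_names))
    feature_names <- paste0("f", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, y = as.numeric(y), feature_names = feature_names),
            class = "pdt_dataset")
}

#' Restrict a dataset to a feature subset
#' @param data a [labeled_dataset()].
#' @param subset integer indices into the feature columns.
#' @return A [labeled_dataset()] on the selected columns.
#' @export
subset_features <- function(data, subset) {
  stopifnot(inherits(data, "pdt_dataset"))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0L)
    stop_pdt("feature subset is empty", "pdt_contract_error")
  if (any(subset < 1L | subset > ncol(data$X)))
    stop_pdt("feature subset out of range", "pdt_contract_error")
  labeled_dataset(data$X[, subset, drop = FALSE], data$y,
                  data$feature_names[subset])
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop_pdt("training data contain a single class", "pdt_training_error")
}

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

identity_scaler <- function(m) list(center = rep(0, m), scale = rep(1, m))

check_dims <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != length(model$scaler$center))
    stop_pdt(sprintf("input has %d features, model expects %d",
                     ncol(X), length(model$scaler$center)),
             "pdt_contract_error")
  X
}

#' Polynomial kernel
#'
#' `K(x, z) = (x . z + coef0)^degree`, the kernel used by the PDT SVM.
#'
#' @param x,z numeric vectors of equal length.
#' @param degree polynomial degree.
#' @param coef0 additive offset.
#' @return Kernel value.
#' @export
poly_kernel <- function(x, z, degree = 2, coef0 = 1) {
  (sum(x * z) + coef0)^degree
}

#' Train the polynomial-kernel SVM
#'
#' @param data a [labeled_dataset()] containing both classes.
#' @param degree polynomial degree (default 2).
#' @param C soft-margin cost (default 1).
#' @return A model of class `c("pdt_svm", "pdt_model")` with elements
#'   `alpha` (non-negative dual coefficients), `sv_labels`, `bias` and
#'   the fitted e1071 object.
#' @export
train_svm <- function(data, degree = 2, C = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  check_two_classes(data$y)
  scaler <- fit_scaler(data$X)
  Xs <- apply_scaler(scaler, data$X)
  fit <- e1071::svm(x = Xs, y = factor(data$y, levels = c(-1, 1)),
                    kernel = "polynomial", degree = degree, gamma = 1,
                    coef0 = 1, cost = C, scale = FALSE)
  # e1071 reports decision values for the first class it encountered;
  # orient so that positive score means the positive (patient) class.
  dv <- attr(predict(fit, Xs, decision.values = TRUE), "decision.values")
  first <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  flip <- if (first == "-1") -1 else 1
  structure(
    list(SV = unname(as.matrix(fit$SV)), coefs = as.numeric(fit$coefs),
         rho = fit$rho, scaler = scaler, flip = flip,
         degree = degree, C = C,
         alpha = abs(as.numeric(fit$coefs)),
         sv_labels = sign(as.numeric(fit$coefs)),
         bias = -flip * fit$rho,
         feature_names = data$feature_names),
    class = c("pdt_svm", "pdt_model"))
}

#' SVM decision score
#'
#' The signed margin
#' `f(x) = sum_i alpha_i y_i (x_i . x + 1)^d + b`, evaluated from the
#' stored support vectors; the predicted class is its sign, with an
#' exact zero assigned to the negative (control) class.
#'
#' @param model a `pdt_svm` model.
#' @param x a feature vector or matrix of rows.
#' @return Numeric score(s).
#' @export
svm_score <- function(model, x) {
  X <- check_dims(model, x)
  Xs <- apply_scaler(model$scaler, X)
  Km <- (Xs %*% t(model$SV) + 1)^model$degree
  model$flip * (as.numeric(Km %*% model$coefs) - model$rho)
}

#' Construct an RBF-network model directly
#'
#' Low-level constructor used by [train_rbfn()] and by hand-built
#' models: prototypes, widths and read-out weights are taken as given.
#'
#' @param prototypes `K x m` matrix of prototype vectors (in scaled
#'   feature space).
#' @param beta positive widths, length `K`: neuron `i` responds as
#'   `exp(-beta_i ||x - mu_i||^2)`.
#' @param weights `(K + 1) x 2` read-out matrix (first row is the bias);
#'   column 1 scores the negative class, column 2 the positive class.
#' @param scaler feature scaler as fitted by the trainer; defaults to
#'   the identity.
#' @return A model of class `c("pdt_rbfn", "pdt_model")`.
#' @export
rbfn_model <- function(prototypes, beta, weights,
                       scaler = identity_scaler(ncol(prototypes))) {
  prototypes <- as.matrix(prototypes)
  if (length(beta) != nrow(prototypes))
    stop_pdt("need one width per prototype", "pdt_contract_error")
  if (any(beta <= 0))
    stop_pdt("widths must be positive", "pdt_contract_error")
  weights <- as.matrix(weights)
  if (nrow(weights) != nrow(prototypes) + 1L || ncol(weights) != 2L)
    stop_pdt("weights must be (K+1) x 2 (bias row first)",
             "pdt_contract_error")
  structure(list(prototypes = prototypes, beta = beta, weights = weights,
                 scaler = scaler, K = nrow(prototypes)),
            class = c("pdt_rbfn", "pdt_model"))
}

rbf_activations <- function(model, Xs) {
  K <- model$K
  A <- matrix(0, nrow(Xs), K)
  for (i in seq_len(K)) {
    d2 <- rowSums(sweep(Xs, 2, model$prototypes[i, ])^2)
    A[, i] <- exp(-model$beta[i] * d2)
  }
  A
}

# seeded K-means that re-draws empty-cluster centroids from the data
kmeans_prototypes <- function(Xs, K, seed) {
  with_seed(seed, {
    for (attempt in 1:10) {
      centers <- Xs[sample.int(nrow(Xs), K), , drop = FALSE]
      centers <- centers + rnorm(length(centers), sd = 1e-8)
      km <- suppressWarnings(
        kmeans(Xs, centers = centers, iter.max = 100, algorithm = "Lloyd"))
      if (all(km$size > 0)) return(km)
    }
    km
  })
}

#' Train the RBF network
#'
#' Prototypes are K-means centroids of the (standardised) training
#' features; widths follow the within-cluster spread,
#' `beta_i = 1 / (2 sigma_i^2)` with `sigma_i` the RMS distance of the
#' cluster's members to its centroid (floored at 1e-6 for singleton
#' clusters); read-out weights are fitted by least squares against
#' one-hot class targets.
#'
#' @param data a [labeled_dataset()]; a single-class fit is permitted
#'   and degenerates to a constant predictor of that class.
#' @param K number of RBF neurons; the PDT pipeline uses 2 with feature
#'   selection and 4 without.
#' @param seed RNG seed for the K-means initialisation.
#' @return A `pdt_rbfn` model.
#' @export
train_rbfn <- function(data, K = 2, seed = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  n <- nrow(data$X)
  if (K < 1L || K > n)
    stop_pdt("K must be between 1 and the number of subjects",
             "pdt_parameter_error")
  scaler <- fit_scaler(data$X)
  Xs <- apply_scaler(scaler, data$X)
  km <- kmeans_prototypes(Xs, K, seed)
  sigma <- vapply(seq_len(K), function(i) {
    members <- Xs[km$cluster == i, , drop = FALSE]
    if (nrow(members) == 0L) return(1e-6)
    max(sqrt(mean(rowSums(sweep(members, 2, km$centers[i, ])^2))), 1e-6)
  }, numeric(1))
  model <- rbfn_model(km$centers, 1 / (2 * sigma^2),
                      weights = matrix(0, K + 1L, 2L), scaler = scaler)
  A <- cbind(1, rbf_activations(model, Xs))
  Y <- cbind(as.numeric(data$y == -1), as.numeric(data$y == 1))
  W <- suppressWarnings(lm.fit(A, Y)$coefficients)
  W[is.na(W)] <- 0
  model$weights <- matrix(W, ncol = 2)
  model$feature_names <- data$feature_names
  model
}

#' RBF-network class scores
#'
#' @param model a `pdt_rbfn` model.
#' @param x feature vector or matrix of rows.
#' @return A matrix of per-class scores with columns `"-1"` and `"1"`.
#'   The predicted class is the argmax (ties to the negative class); for
#'   ROC use, the positive-class softmax of the two scores is a
#'   probability surrogate.
#' @export
rbfn_predict <- function(model, x) {
  X <- check_dims(model, x)
  Xs <- apply_scaler(model$scaler, X)
  A <- cbind(1, rbf_activations(model, Xs))
  S <- A %*% model$weights
  colnames(S) <- c("-1", "1")
  S
}

rbfn_softmax_pos <- function(S) {
  m <- pmax(S[, 1], S[, 2])
  e1 <- exp(S[, 1] - m); e2 <- exp(S[, 2] - m)
  e2 / (e1 + e2)
}

#' Train the random forest
#'
#' Bootstrap-sampled trees with `ceiling(sqrt(m))` candidate features
#' per split; deterministic for a fixed seed.
#'
#' @param data a [labeled_dataset()] containing both classes.
#' @param n_trees number of trees (default 100).
#' @param mtry features tried per split; default `ceiling(sqrt(m))`.
#' @param seed RNG seed.
#' @return A model of class `c("pdt_rf", "pdt_model")`.
#' @export
train_rf <- function(data, n_trees = 100, mtry = NULL, seed = 1) {
  stopifnot(inherits(data, "pdt_dataset"))
  check_two_classes(data$y)
  if (n_trees < 1L)
    stop_pdt("n_trees must be at least 1", "pdt_parameter_error")
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(data$X)))
  fit <- with_seed(seed,
    randomForest::randomForest(
      x = data$X, y = factor(data$y, levels = c(-1, 1)),
      ntree = n_trees, mtry = mtry))
  structure(list(fit = fit, n_trees = n_trees, mtry = mtry, seed = seed,
                 scaler = identity_scaler(ncol(data$X)),
                 feature_names = data$feature_names),
            class = c("pdt_rf", "pdt_model"))
}

#' Random-forest positive-class vote fraction
#'
#' @param model a `pdt_rf` model.
#' @param x feature vector or matrix of rows.
#' @return Fraction of trees voting for the positive class, in `[0, 1]`.
#'   The predicted class is the majority vote; an exact tie goes to the
#'   negative class.
#' @export
rf_predict_proba <- function(model, x) {
  X <- check_dims(model, x)
  colnames(X) <- model$feature_names
  if (!is.null(model$fit))
    return(as.numeric(predict(model$fit, X, type = "prob")[, "1"]))
  # reloaded model: walk the serialized trees
  vapply(seq_len(nrow(X)), function(r) {
    votes <- vapply(model$trees, function(tr) {
      node <- 1L
      while (tr[node, "status"] != -1L) {
        v <- X[r, tr[node, "split var"]]
        node <- if (v <= tr[node, "split point"])
          tr[node, "left daughter"] else tr[node, "right daughter"]
      }
      tr[node, "prediction"]
    }, numeric(1))
    mean(votes == 2)  # class levels are c(-1, 1); index 2 is positive
  }, numeric(1))
}

#' Classifier specification
#'
#' Names one of the three families together with its hyperparameters;
#' used by the feature-selection wrapper and the LOOCV driver.
#'
#' @param family `"svm"`, `"rbfn"` or `"rf"`.
#' @param ... hyperparameters: `degree`, `C` (svm); `K` (rbfn);
#'   `n_trees`, `mtry` (rf).
#' @return A list of class `pdt_classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "rbfn", "rf"), ...) {
  family <- match.arg(family)
  params <- list(...)
  known <- switch(family,
                  svm = c("degree", "C"),
                  rbfn = c("K"),
                  rf = c("n_trees", "mtry"))
  bad <- setdiff(names(params), known)
  if (length(bad))
    stop_pdt(paste0("unknown ", family, " hyperparameters: ",
                    paste(bad, collapse = ", ")), "pdt_parameter_error")
  structure(list(family = family, params = params),
            class = "pdt_classifier_spec")
}

#' Fit any classifier family from its specification
#'
#' @param data a [labeled_dataset()].
#' @param spec a [classifier_spec()].
#' @param seed RNG seed for the stochastic trainers (RBFN, RF).
#' @return A `pdt_model`.
#' @export
fit_classifier <- function(data, spec, seed = 1) {
  stopifnot(inherits(spec, "pdt_classifier_spec"))
  p <- spec$params
  switch(spec$family,
    svm  = train_svm(data, degree = p$degree %||% 2, C = p$C %||% 1),
    rbfn = train_rbfn(data, K = min(p$K %||% 2, nrow(data$X)), seed = seed),
    rf   = train_rf(data, n_trees = p$n_trees %||% 100,
                    mtry = p$mtry, seed = seed))
}

#' Monotone ROC score of a fitted model
#'
#' SVM: signed margin; RBFN: positive-class softmax; RF: positive vote
#' fraction.  Higher always means more patient-like.
#'
#' @param model a `pdt_model`.
#' @param x feature vector or matrix of rows.
#' @return Numeric score(s).
#' @export
predict_score <- function(model, x) UseMethod("predict_score")

#' @export
predict_score.pdt_svm <- function(model, x) svm_score(model, x)

#' @export
predict_score.pdt_rbfn <- function(model, x)
  rbfn_softmax_pos(rbfn_predict(model, x))

#' @export
predict_score.pdt_rf <- function(model, x) rf_predict_proba(model, x)

#' Predicted class labels (+1 patient, -1 control)
#'
#' Decision-boundary ties go to the negative class for every family.
#'
#' @inheritParams predict_score
#' @return Vector of +1 / -1.
#' @export
predict_class <- function(model, x) UseMethod("predict_class")

#' @export
predict_class.pdt_svm <- function(model, x)
  ifelse(svm_score(model, x) > 0, 1, -1)

#' @export
predict_class.pdt_rbfn <- function(model, x) {
  S <- rbfn_predict(model, x)
  ifelse(S[, "1"] > S[, "-1"], 1, -1)
}

#' @export
predict_class.pdt_rf <- function(model, x)
  ifelse(rf_predict_proba(model, x) > 0.5, 1, -1)
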