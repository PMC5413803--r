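#' Save a fitted classifier as JSON
#'
#' Every family has a complete text serialization: the SVM stores its
#' support vectors, dual coefficients and bias; the RBFN its prototypes,
#' widths and read-out weights; the forest every tree as a node table
#' (left/right daughter, split variable, split point, status,
#' prediction).  [load_model()] restores a model whose predictions
#' match the original exactly.
#'
#' @param model a `pdt_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pdt_model"))
  common <- list(feature_names = model$feature_names,
                 scaler = model$scaler)
  body <- if (inherits(model, "pdt_svm")) {
    c(common, list(family = "svm", SV = model$SV, coefs = model$coefs,
                   rho = model$rho, flip = model$flip,
                   degree = model$degree, C = model$C))
  } else if (inherits(model, "pdt_rbfn")) {
    c(common, list(family = "rbfn", prototypes = model$prototypes,
                   beta = model$beta, weights = model$weights))
  } else if (inherits(model, "pdt_rf")) {
    trees <- lapply(seq_len(model$fit$ntree), function(k)
      as.data.frame(randomForest::getTree(model$fit, k), optional = TRUE))
    c(common, list(family = "rf", n_trees = model$n_trees,
                   mtry = model$mtry, seed = model$seed, trees = trees))
  } else stop_pdt("unknown model family", "pdt_contract_error")
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the restored `pdt_model`.
#' @export
load_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- list(center = as.numeric(b$scaler$center),
                 scale = as.numeric(b$scaler$scale))
  tree_cols <- c("left daughter", "right daughter", "split var",
                 "split point", "status", "prediction")
  switch(b$family,
    svm = structure(
      list(SV = as.matrix(b$SV), coefs = as.numeric(b$coefs), rho = b$rho,
           scaler = scaler, flip = b$flip, degree = b$degree, C = b$C,
           alpha = abs(as.numeric(b$coefs)),
           sv_labels = sign(as.numeric(b$coefs)),
           bias = -b$flip * b$rho, feature_names = b$feature_names),
      class = c("pdt_svm", "pdt_model")),
    rbfn = {
      m <- rbfn_model(as.matrix(b$prototypes), as.numeric(b$beta),
                      as.matrix(b$weights), scaler = scaler)
      m$feature_names <- b$feature_names
      m
    },
    rf = structure(
      list(fit = NULL,
           trees = lapply(b$trees, function(tr) {
             tr <- as.matrix(tr)
             colnames(tr) <- tree_cols
             tr
           }),
           n_trees = b$n_trees, mtry = b$mtry, seed = b$seed,
           scaler = scaler, feature_names = b$feature_names),
      class = c("pdt_rf", "pdt_model")),
    stop_pdt("unknown model family in file", "pdt_contract_error"))
}
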