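# Feature filtering, standardization, cross-validated LASSO logistic
# regression, and the radiomics score. Path fitting is delegated to
# glmnet (objective: -(1/n) binomial log-likelihood + lambda * ||beta||_1,
# unpenalized intercept); the cross-validation loop, metric, lambda
# selection and tie-breaking are implemented here.

#' Drop degenerate feature columns
#'
#' Removes features with zero variance or any non-finite value across
#' the cohort; penalized regression cannot use them and standardization
#' would divide by zero.
#'
#' @param x numeric feature matrix (patients x features).
#' @return list with `x` (reduced matrix) and `report` (data.frame of
#'   removed feature names and reasons; zero rows if nothing removed).
#' @export
drop_degenerate_features <- function(x) {
  stopifnot(is.matrix(x))
  nonfinite <- colSums(!is.finite(x)) > 0
  v <- apply(x, 2L, stats::var)
  constant <- !nonfinite & (v == 0)
  bad <- nonfinite | constant
  report <- data.frame(
    feature = colnames(x)[bad],
    reason = ifelse(nonfinite[bad], "non-finite", "zero variance"),
    stringsAsFactors = FALSE
  )
  list(x = x[, !bad, drop = FALSE], report = report)
}

#' Standardize features with training-cohort constants
#'
#' z = (x - mu_train) / sd_train, with mu and sd computed on the
#' training cohort only (sample SD). The validation cohort never
#' contributes to the constants.
#'
#' @param train training feature matrix.
#' @param apply_to optional further matrix to transform with the same
#'   constants (same columns).
#' @return list with `train`, `applied` (NULL if absent), `mu`, `sigma`.
#' @export
standardize_features <- function(train, apply_to = NULL) {
  mu <- colMeans(train)
  sigma <- apply(train, 2L, stats::sd)
  if (any(sigma == 0))
    stop("zero-variance feature retained; run drop_degenerate_features first")
  z <- sweep(sweep(train, 2L, mu), 2L, sigma, "/")
  applied <- NULL
  if (!is.null(apply_to)) {
    stopifnot(identical(colnames(apply_to), colnames(train)))
    applied <- sweep(sweep(apply_to, 2L, mu), 2L, sigma, "/")
  }
  list(train = z, applied = applied, mu = mu, sigma = sigma)
}

# Stratified fold assignment: positives and negatives are each permuted
# and dealt round-robin, so every fold holds both classes whenever
# feasible.
.stratified_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  foldid
}

#' Cross-validated LASSO logistic regression path
#'
#' Fits the L1-penalized logistic regression path on standardized
#' features and evaluates each lambda by stratified k-fold
#' cross-validation. The CV metric is held-out AUC (default) or binomial
#' deviance, averaged across folds with a standard error. `lambda_min`
#' is the lambda attaining the optimal CV metric; ties break to the
#' largest (sparsest) such lambda.
#'
#' @param x standardized feature matrix (n x p).
#' @param y binary 0/1 outcome vector.
#' @param n_folds number of CV folds (default 10).
#' @param seed fold-assignment seed (default 0).
#' @param metric "auc" (maximized) or "deviance" (minimized).
#' @param nlambda grid size (default 100).
#' @param lambda.min.ratio smallest lambda as a fraction of lambda_max
#'   (default 1e-3).
#' @param lambda optional explicit descending lambda grid.
#' @return a `lasso_path`: list with `lambda` (descending grid), `cvm`,
#'   `cvsd`, `nzero` (nonzero coefficients per lambda), `lambda_min`,
#'   `metric`, `fit` (the full-data glmnet fit), `foldid`.
#' @export
fit_lasso_cv <- function(x, y, n_folds = 10L, seed = 0L, metric = c("auc", "deviance"),
                         nlambda = 100L, lambda.min.ratio = 1e-3, lambda = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (nrow(x) < n_folds) stop("fewer patients than folds")

  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        nlambda = nlambda, lambda.min.ratio = lambda.min.ratio,
                        lambda = lambda, standardize = FALSE)
  grid <- fit$lambda

  foldid <- .stratified_folds(y, n_folds, seed)
  per_fold <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    hold <- foldid == f
    ffit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                           family = "binomial", alpha = 1, lambda = grid,
                           standardize = FALSE)
    eta <- stats::predict(ffit, x[hold, , drop = FALSE], type = "link")
    yv <- y[hold]
    if (metric == "auc") {
      per_fold[f, ] <- apply(eta, 2L, function(s) .auc_midrank(s, yv))
    } else {
      p <- 1 / (1 + exp(-eta))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      per_fold[f, ] <- apply(p, 2L, function(pr)
        -2 * mean(yv * log(pr) + (1 - yv) * log(1 - pr)))
    }
  }
  cvm <- colMeans(per_fold, na.rm = TRUE)
  cvsd <- apply(per_fold, 2L, function(v) stats::sd(v, na.rm = TRUE)) /
    sqrt(colSums(!is.na(per_fold)))
  best <- if (metric == "auc") max(cvm) else min(cvm)
  # grid is descending, so the first index attaining the optimum is the
  # largest (sparsest) lambda
  lambda_min <- grid[which(cvm == best)[1L]]
  nzero <- fit$df
  structure(list(lambda = grid, cvm = cvm, cvsd = cvsd, nzero = nzero,
                 lambda_min = lambda_min, metric = metric, fit = fit,
                 foldid = foldid, seed = seed),
            class = "lasso_path")
}

# midrank AUC used as CV metric; NA when the fold is single-class
.auc_midrank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a radiomics signature from a fitted LASSO path
#'
#' Retains the features with nonzero coefficients at `lambda_min` (or a
#' supplied lambda) together with the intercept and the training
#' standardization constants, giving a self-contained radiomics-score
#' formula.
#'
#' @param path a `lasso_path` from [fit_lasso_cv()].
#' @param mu,sigma named training standardization constants from
#'   [standardize_features()] (on the original feature scale).
#' @param lambda lambda at which to extract coefficients (default
#'   `path$lambda_min`).
#' @return a `radiomics_signature`: list with `intercept`,
#'   `coefficients` (named, nonzero only, standardized scale),
#'   `mu`, `sigma` (for the retained features), `lambda`.
#' @export
build_signature <- function(path, mu, sigma, lambda = path$lambda_min) {
  stopifnot(inherits(path, "lasso_path"))
  cf <- as.matrix(stats::coef(path$fit, s = lambda, exact = FALSE))
  intercept <- cf[1L, 1L]
  beta <- cf[-1L, 1L]
  keep <- beta != 0
  if (!any(keep))
    warning("no features selected at this lambda; intercept-only signature")
  sel <- names(beta)[keep]
  structure(list(
    intercept = intercept,
    coefficients = beta[keep],
    mu = mu[sel],
    sigma = sigma[sel],
    lambda = lambda
  ), class = "radiomics_signature")
}

#' @export
print.radiomics_signature <- function(x, ...) {
  cat(sprintf("<radiomics_signature: %d features, lambda = %.5g>\n",
              length(x$coefficients), x$lambda))
  if (length(x$coefficients)) {
    df <- data.frame(coefficient = x$coefficients)
    print(df)
  }
  invisible(x)
}

#' Radiomics score of one or more patients
#'
#' score = intercept + sum_i beta_i * (x_i - mu_i) / sigma_i over the
#' signature's selected features. Features are taken by name; a missing
#' feature is an error, never silently imputed.
#'
#' @param signature a `radiomics_signature`.
#' @param features named numeric vector (one patient) or matrix with
#'   feature columns (one row per patient), on the original (pre-
#'   standardization) feature scale.
#' @return numeric vector of scores (named by patient when `features`
#'   has rownames).
#' @export
rad_score <- function(signature, features) {
  stopifnot(inherits(signature, "radiomics_signature"))
  sel <- names(signature$coefficients)
  if (is.null(dim(features))) features <- t(as.matrix(features))
  miss <- setdiff(sel, colnames(features))
  if (length(miss))
    stop("missing signature features: ", paste(miss, collapse = ", "))
  if (!length(sel))
    return(stats::setNames(rep(signature$intercept, nrow(features)),
                           rownames(features)))
  z <- sweep(sweep(features[, sel, drop = FALSE], 2L, signature$mu),
             2L, signature$sigma, "/")
  drop(signature$intercept + z %*% signature$coefficients)
}

#' Serialize a radiomics signature to JSON
#' @param signature a `radiomics_signature`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "radiomics_signature"))
  obj <- list(
    lambda = signature$lambda,
    intercept = signature$intercept,
    coefficients = as.list(signature$coefficients),
    standardization = stats::setNames(
      lapply(names(signature$coefficients),
             function(nm) c(signature$mu[[nm]], signature$sigma[[nm]])),
      names(signature$coefficients)),
    registry_hash = registry_hash()
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized radiomics signature
#' @param path JSON path written by [write_signature()].
#' @return a `radiomics_signature`.
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sel <- names(obj$coefficients)
  structure(list(
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    mu = stats::setNames(vapply(obj$standardization, `[`, 0, 1L), sel),
    sigma = stats::setNames(vapply(obj$standardization, `[`, 0, 2L), sel),
    lambda = obj$lambda
  ), class = "radiomics_signature")
}
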