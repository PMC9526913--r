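#' Fit a LASSO potency model
#'
#' L1-penalised linear regression of serial-passage potency on the named
#' profile parameters, with parameters standardised internally (z-score on the
#' training data, as done by glmnet) and coefficients reported on the original
#' parameter scale. The penalty is chosen by inner cross-validation grouped by
#' clone (leave-one-clone-out on the training set, minimising MSE) unless a
#' fixed \code{lambda} is supplied.
#'
#' @param dataset A \code{cohort_dataset} (see [profile_dataset()]).
#' @param lambda Optional fixed penalty; NULL (default) selects by inner CV.
#' @return An object of class \code{model_fit}: list with \code{kind =
#'   "lasso"}, \code{weights} (named, 0 for unselected parameters),
#'   \code{intercept}, \code{lambda}, \code{selected} (names of nonzero
#'   weights), \code{condition}.
#' @export
fit_lasso <- function(dataset, lambda = NULL) {
  x <- dataset$x; y <- dataset$y
  if (nrow(x) < 3) stopf("need >= 3 training samples to fit LASSO")
  if (stats::var(y) == 0) stopf("degenerate target: potency is constant in the training set")
  if (is.null(lambda)) {
    foldid <- as.integer(factor(dataset$clone))
    cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = foldid,
                            standardize = TRUE, grouped = FALSE)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = lambda, standardize = TRUE)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  structure(list(kind = "lasso", weights = beta,
                 intercept = as.numeric(fit$a0), lambda = lambda,
                 selected = names(beta)[beta != 0],
                 condition = dataset_condition(dataset),
                 model = fit),
            class = "model_fit")
}

#' Fit a random-forest potency model
#'
#' Regression forest of potency on the profile parameters (500 trees, p/3
#' candidate parameters per split by default); per-parameter importance is the
#' total impurity (node purity) decrease. Seed-reproducible.
#'
#' @param dataset A \code{cohort_dataset}.
#' @param n_trees Number of trees (default 500).
#' @param mtry Parameters tried per split (default floor(p/3)).
#' @param seed Integer seed (default 1).
#' @return A \code{model_fit} with \code{kind = "rf"} and \code{importances}
#'   (named per-parameter impurity decrease; also exposed as \code{weights}).
#' @export
fit_rf <- function(dataset, n_trees = 500, mtry = NULL, seed = 1) {
  x <- dataset$x; y <- dataset$y
  if (nrow(x) < 3) stopf("need >= 3 training samples to fit a random forest")
  if (is.null(mtry)) mtry <- max(floor(ncol(x) / 3), 1)
  fit <- with_seed(seed, {
    randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry,
                               importance = FALSE)
  })
  imp <- fit$importance[, "IncNodePurity"]
  structure(list(kind = "rf", weights = imp, importances = imp,
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 condition = dataset_condition(dataset),
                 model = fit),
            class = "model_fit")
}

dataset_condition <- function(dataset) {
  list(n_samples = nrow(dataset$x), n_parameters = ncol(dataset$x),
       n_clones = length(unique(dataset$clone)),
       bootstrap = any(dataset$replicate > 0))
}

#' Predict potency from a fitted model
#' @param object A \code{model_fit}.
#' @param newx Matrix of profiles (columns = the fit's parameter names).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.model_fit <- function(object, newx, ...) {
  if (object$kind == "lasso")
    as.numeric(stats::predict(object$model, newx = newx, s = object$lambda))
  else
    as.numeric(stats::predict(object$model, newx))
}

#' Grouped leave-one-clone-out cross-validation
#'
#' One fold per clone: all replicates of the held-out clone leave the training
#' set together (the leakage guard for bootstrap-expanded datasets), the model
#' is refit on the remaining clones (standardisation statistics come from the
#' training fold only), and the held-out replicates are predicted. RMSE is the
#' root mean squared error over all held-out predictions.
#'
#' @param dataset A \code{cohort_dataset}.
#' @param model_spec List: \code{kind} ("lasso" or "rf") plus optional
#'   arguments for [fit_lasso()] / [fit_rf()].
#' @return An object of class \code{cv_result}: list with \code{predictions}
#'   (data.frame clone, replicate, truth, predicted), \code{rmse},
#'   \code{n_folds}, \code{condition}.
#' @export
loocv <- function(dataset, model_spec = list(kind = "lasso")) {
  clones <- unique(dataset$clone)
  if (length(clones) < 3) stopf("need >= 3 clones for leave-one-clone-out CV")
  kind <- match.arg(model_spec$kind, c("lasso", "rf"))
  preds <- vector("list", length(clones))
  for (i in seq_along(clones)) {
    hold <- dataset$clone == clones[i]
    if (length(unique(dataset$clone[!hold])) < 2)
      stopf("fold for clone %s leaves < 2 training clones", clones[i])
    train <- structure(list(x = dataset$x[!hold, , drop = FALSE],
                            y = dataset$y[!hold],
                            clone = dataset$clone[!hold],
                            replicate = dataset$replicate[!hold],
                            parameter_names = dataset$parameter_names),
                       class = "cohort_dataset")
    fit <- if (kind == "lasso")
      fit_lasso(train, lambda = model_spec$lambda)
    else
      fit_rf(train, n_trees = model_spec$n_trees %||% 500,
             mtry = model_spec$mtry, seed = model_spec$seed %||% 1)
    p <- predict(fit, dataset$x[hold, , drop = FALSE])
    preds[[i]] <- data.frame(clone = clones[i],
                             replicate = dataset$replicate[hold],
                             truth = dataset$y[hold], predicted = p)
  }
  predictions <- do.call(rbind, preds)
  structure(list(predictions = predictions,
                 rmse = sqrt(mean((predictions$truth - predictions$predicted)^2)),
                 n_folds = length(clones),
                 condition = c(dataset_condition(dataset), model = kind)),
            class = "cv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Data-usage sweep: time window x FOV count
#'
#' For every combination of window end and FOV count, builds profiles (one
#' random FOV draw per cell when \code{B = 0}; \code{B} bootstrap multiset
#' draws per clone otherwise), runs grouped leave-one-clone-out CV, and
#' records the RMSE together with a pass flag at the performance threshold
#' (RMSE < 1.0 marks a good model by default). Per-cell failures are recorded
#' and the grid is still returned.
#'
#' @param cohort A \code{synthetic_cohort} (or list with \code{clones},
#'   \code{labels}, \code{spec}).
#' @param windows Vector of window ends (hours).
#' @param fov_counts Vector of FOV counts (subset of 1..n_fov).
#' @param model_spec Model specification for [loocv()].
#' @param B 0 for raw single-draw profiles, else bootstrap repeats per clone.
#' @param seed Master seed; each grid cell uses a derived seed (recorded).
#' @param rmse_threshold Pass threshold (default 1.0).
#' @return An object of class \code{data_usage_grid}: long data.frame
#'   \code{grid} (window_end_h, fov_count, rmse, pass, seed, error) plus the
#'   CV results in \code{cv}.
#' @export
data_usage_grid <- function(cohort, windows, fov_counts,
                            model_spec = list(kind = "lasso"),
                            B = 0, seed = 1, rmse_threshold = 1.0) {
  n_fov <- cohort$spec$n_fov
  if (any(fov_counts < 1 | fov_counts > n_fov))
    stopf("'fov_counts' must lie in 1..%d", n_fov)
  tps <- cohort$spec$time_points
  if (!all(windows %in% tps)) stopf("'windows' must be a subset of the cohort time points")
  rows <- list(); cvs <- list()
  idx <- 0
  for (w in windows) for (k in fov_counts) {
    idx <- idx + 1
    cell_seed <- derive_seed(seed, idx)
    res <- tryCatch({
      profiles <- if (B == 0) {
        fovs <- subsample_fovs(seq_len(n_fov), k, seed = cell_seed)
        cohort_profiles(cohort, window_end_h = w, fov_ids = fovs)
      } else {
        unlist(lapply(seq_along(cohort$clones), function(i)
          bootstrap_profiles(cohort$clones[[i]]$cells, w, k, B,
                             seed = derive_seed(cell_seed, i),
                             available = seq_len(n_fov),
                             time_points = tps[tps <= w])),
          recursive = FALSE)
      }
      ds <- profile_dataset(profiles, cohort$labels)
      loocv(ds, model_spec)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[idx]] <- data.frame(window_end_h = w, fov_count = k, rmse = NA_real_,
                                pass = NA, seed = cell_seed,
                                error = conditionMessage(res))
    } else {
      rows[[idx]] <- data.frame(window_end_h = w, fov_count = k, rmse = res$rmse,
                                pass = res$rmse < rmse_threshold, seed = cell_seed,
                                error = NA_character_)
      cvs[[paste(w, k, sep = "_")]] <- res
    }
  }
  structure(list(grid = do.call(rbind, rows), cv = cvs,
                 rmse_threshold = rmse_threshold, B = B, seed = seed),
            class = "data_usage_grid")
}

#' @export
print.data_usage_grid <- function(x, ...) {
  cat(sprintf("data_usage_grid: %d cells, %s profiles, RMSE threshold %.2f\n",
              nrow(x$grid), if (x$B > 0) sprintf("%d-repeat bootstrap", x$B) else "raw",
              x$rmse_threshold))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Correlation of model structures
#'
#' Pearson correlation matrix of the weight vectors of several fits, aligned
#' on the union of their parameter names (absent parameters count as weight
#' 0). A zero-variance weight vector has undefined correlations, recorded as
#' NA with a warning.
#'
#' @param fits List of \code{model_fit}s.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
model_structure_correlation <- function(fits) {
  if (length(fits) < 2) stopf("need >= 2 fits to compare model structures")
  all_names <- unique(unlist(lapply(fits, function(f) names(f$weights))))
  w <- vapply(fits, function(f) {
    v <- stats::setNames(numeric(length(all_names)), all_names)
    v[names(f$weights)] <- f$weights
    v
  }, numeric(length(all_names)))
  colnames(w) <- names(fits) %||% paste0("fit", seq_along(fits))
  const <- apply(w, 2, stats::var) == 0
  if (any(const))
    warning(sprintf("zero-variance weight vector(s): %s; correlations recorded as NA",
                    paste(colnames(w)[const], collapse = ", ")))
  suppressWarnings(cm <- stats::cor(w))
  diag(cm) <- 1
  cm
}
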