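#' Cross-validated elastic net with MAE model selection
#'
#' Elastic-net regression (mixing parameter `l1_ratio`, 0.1 by default) over
#' a grid of regularisation strengths, selecting the strength whose 5-fold
#' cross-validated mean absolute error is lowest and refitting on the full
#' training data. Features are standardized with training-data parameters;
#' the solver is glmnet, while the fold loop, MAE selection and feature
#' accounting are implemented here.
#'
#' @param X numeric matrix, training subjects x features.
#' @param y numeric response.
#' @param l1_ratio elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @param alpha_grid regularisation strengths; default 30 log-spaced values
#'   on \[1e-4, 1\].
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return an `enet_cv` object: chosen `alpha`, `coef` (named vector),
#'   `intercept`, `cv_mae` (data.frame alpha x mean CV MAE), `selected`
#'   (names of nonzero-coefficient features) and the standardization
#'   parameters.
#' @export
elastic_net_cv <- function(X, y, l1_ratio = 0.1,
                           alpha_grid = default_alpha_grid(),
                           n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::sd(y) == 0)
    stop("constant response: nothing to predict", call. = FALSE)
  if (nrow(X) <= n_folds)
    stop("need more training subjects than folds", call. = FALSE)
  if (!length(alpha_grid)) stop("empty alpha grid", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))

  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, `/`)
  # the response is standardized on the training data so the fixed
  # regularisation grid is meaningful regardless of the trait's scale;
  # coefficients and predictions are mapped back to the original units
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  ys <- (y - y_center) / y_scale

  grid <- sort(unique(alpha_grid), decreasing = TRUE)
  folds <- local({
    set.seed(seed)
    sample(rep_len(seq_len(n_folds), nrow(X)))
  })
  fold_mae <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE], ys[tr],
                          alpha = l1_ratio, lambda = grid,
                          standardize = FALSE)
    pred <- stats::predict(fit, Xs[!tr, , drop = FALSE], s = grid,
                           exact = FALSE)
    fold_mae[f, ] <- colMeans(abs(pred * y_scale + y_center - y[!tr]))
  }
  cv_mae <- colMeans(fold_mae)
  best <- which.min(cv_mae)  # ties: strongest regularisation wins

  full <- glmnet::glmnet(Xs, ys, alpha = l1_ratio, lambda = grid,
                         standardize = FALSE)
  beta <- as.numeric(stats::coef(full, s = grid[best])) * y_scale
  beta[1] <- beta[1] + y_center
  names(beta) <- c("(Intercept)", colnames(X))
  coefs <- beta[-1]

  structure(list(alpha = grid[best], l1_ratio = l1_ratio,
                 coef = coefs, intercept = beta[1],
                 selected = names(coefs)[coefs != 0],
                 cv_mae = data.frame(alpha = grid, mae = cv_mae),
                 center = center, scale = scale_,
                 n_folds = n_folds, seed = seed),
            class = "enet_cv")
}

#' @export
print.enet_cv <- function(x, ...) {
  cat(sprintf(paste0("elastic net (l1_ratio = %g): alpha = %.5f, ",
                     "%d/%d features selected, CV MAE = %.3f\n"),
              x$l1_ratio, x$alpha, length(x$selected), length(x$coef),
              min(x$cv_mae$mae)))
  invisible(x)
}

#' @export
predict.enet_cv <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  drop(Xs %*% object$coef + object$intercept)
}

#' @rdname elastic_net_cv
#' @export
default_alpha_grid <- function() {
  exp(seq(log(1e-4), log(1), length.out = 30))
}

#' Permuted train/test elastic-net prediction of a trait
#'
#' The full prediction pipeline: subjects with a non-missing trait are
#' repeatedly split 4:1 into train and test samples; site effects are
#' harmonized and age regressed out within each part separately
#' (independent fits, not transform-from-train); the cross-validated
#' elastic net is fitted on the training part and evaluated on the test
#' part by MAE and the Pearson correlation between observed and predicted
#' scores. Feature selection counts are accumulated over permutations.
#'
#' @param features subjects x features matrix (e.g. 180 pairs x 3 gradients
#'   of one asymmetry pattern), rows aligned with `cohort`.
#' @param trait numeric trait scores (missing values drop the subject).
#' @param cohort `cohort` data.frame providing `site` and `age`.
#' @param n_perm number of random splits.
#' @param test_fraction held-out fraction (1/5 for the 4:1 scheme).
#' @param l1_ratio,alpha_grid,n_folds passed to [elastic_net_cv()].
#' @param seed master seed; permutation b uses `seed + b`.
#' @return a `prediction_result`: `permutations` data.frame (alpha,
#'   train/test MAE, test r), `selection_freq` per feature, and settings.
#'   A constant test prediction (empty model) scores `r = 0`.
#' @export
permutation_prediction <- function(features, trait, cohort, n_perm = 100L,
                                   test_fraction = 0.2, l1_ratio = 0.1,
                                   alpha_grid = default_alpha_grid(),
                                   n_folds = 5L, seed = 1L) {
  X_all <- as.matrix(features)
  stopifnot(nrow(X_all) == nrow(cohort), nrow(X_all) == length(trait))
  usable <- which(!is.na(trait))
  X_all <- X_all[usable, , drop = FALSE]
  y_all <- trait[usable]
  site <- cohort$site[usable]
  age <- cohort$age[usable]
  n <- length(y_all)
  n_test <- max(1L, round(n * test_fraction))
  if (n - n_test <= n_folds)
    stop("too few training subjects for ", n_folds, "-fold CV",
         call. = FALSE)
  if (is.null(colnames(X_all)))
    colnames(X_all) <- paste0("f", seq_len(ncol(X_all)))

  sel_counts <- stats::setNames(numeric(ncol(X_all)), colnames(X_all))
  perms <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + b)
    test_idx <- sort(sample(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)

    Xtr <- harmonize_split(X_all[train_idx, , drop = FALSE],
                           site[train_idx], age[train_idx])
    Xte <- harmonize_split(X_all[test_idx, , drop = FALSE],
                           site[test_idx], age[test_idx])
    fit <- elastic_net_cv(Xtr, y_all[train_idx], l1_ratio = l1_ratio,
                          alpha_grid = alpha_grid, n_folds = n_folds,
                          seed = seed + b)
    pr_tr <- predict(fit, Xtr)
    pr_te <- predict(fit, Xte)
    r <- if (stats::sd(pr_te) == 0) 0
         else stats::cor(pr_te, y_all[test_idx])
    sel_counts[fit$selected] <- sel_counts[fit$selected] + 1
    perms[[b]] <- data.frame(perm = b, alpha = fit$alpha,
                             n_selected = length(fit$selected),
                             train_mae = mean(abs(pr_tr - y_all[train_idx])),
                             test_mae = mean(abs(pr_te - y_all[test_idx])),
                             test_r = r)
  }
  structure(list(permutations = do.call(rbind, perms),
                 selection_freq = sel_counts / n_perm,
                 n_perm = n_perm, n_subjects = n,
                 test_fraction = test_fraction, l1_ratio = l1_ratio,
                 seed = seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  pm <- x$permutations
  cat(sprintf("permuted elastic-net prediction: %d permutations, n = %d\n",
              x$n_perm, x$n_subjects))
  cat(sprintf("  train MAE %.3f +/- %.3f, test MAE %.3f +/- %.3f\n",
              mean(pm$train_mae), stats::sd(pm$train_mae),
              mean(pm$test_mae), stats::sd(pm$test_mae)))
  cat(sprintf("  test r %.3f +/- %.3f\n",
              mean(pm$test_r), stats::sd(pm$test_r)))
  invisible(x)
}

# site/age removal within one split: empirical-Bayes location/scale
# harmonization when every site has >= 2 subjects, otherwise an OLS
# fallback on site dummies; age is regressed out afterwards either way
harmonize_split <- function(X, site, age) {
  site <- factor(site)
  site <- droplevels(site)
  if (nlevels(site) > 1L && min(table(site)) >= 2L) {
    adj <- combat_fit_transform(X, site, covariates = cbind(age = age),
                                eb = TRUE)$adjusted
  } else if (nlevels(site) > 1L) {
    adj <- residualize(X, stats::model.matrix(~site)[, -1, drop = FALSE])
  } else {
    adj <- X
  }
  residualize(adj, cbind(age = age))
}

#' Network-level summary of feature selection frequencies
#'
#' Aggregates per-feature selection frequencies by network and gradient for
#' reporting.
#'
#' @param result a `prediction_result`.
#' @param scheme a `parcellation`.
#' @return data.frame with `network`, `gradient`, `n_features`,
#'   `mean_freq`, `max_freq`.
#' @export
summarize_selection <- function(result, scheme) {
  freq <- result$selection_freq
  parts <- regmatches(names(freq),
                      regexec("^p(\\d+)_G(\\d+)$", names(freq)))
  ok <- lengths(parts) == 3L
  if (!all(ok))
    stop("feature names must follow the p<pair>_G<gradient> convention",
         call. = FALSE)
  pair <- as.integer(vapply(parts, `[`, character(1), 2))
  grad <- paste0("G", vapply(parts, `[`, character(1), 3))
  network <- pair_networks(scheme)[pair]
  agg <- stats::aggregate(freq,
                          by = list(network = network, gradient = grad),
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              max = max(v)))
  out <- data.frame(network = agg$network, gradient = agg$gradient,
                    n_features = agg$x[, "n"], mean_freq = agg$x[, "mean"],
                    max_freq = agg$x[, "max"], stringsAsFactors = FALSE)
  out[order(out$gradient, -out$mean_freq), ]
}
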