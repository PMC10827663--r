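#' Empirical-Bayes multi-site harmonization (location/scale model)
#'
#' Removes additive and multiplicative batch (scanner/site) effects from a
#' subjects x features matrix while preserving designated covariates, using
#' the classic parametric empirical-Bayes formulation: features are
#' standardized with covariate effects retained, per-batch location and scale
#' parameters are estimated and shrunk towards their across-feature moments
#' (normal prior on locations, inverse-gamma on scales, moment-matched,
#' solved by the standard fixed-point iteration), and the shrunken effects
#' are removed before restoring the covariate structure.
#'
#' @param features numeric matrix, subjects x features.
#' @param batch factor/vector of batch (site) labels, length = subjects.
#' @param covariates optional numeric matrix or data.frame of covariates to
#'   preserve (no intercept column; factors must be pre-expanded).
#' @param protect optional factor (e.g. diagnosis group); an error is raised
#'   if every batch is pure with respect to it, since removing batch would
#'   then remove the protected signal.
#' @param eb logical; `FALSE` uses the raw (unshrunken) batch estimates.
#' @param conv convergence tolerance of the EB fixed-point iteration.
#' @return list with `adjusted` (matrix like `features`) and `model`
#'   (class `combat_model`: standardization and batch parameters).
#' @export
combat_fit_transform <- function(features, batch, covariates = NULL,
                                 protect = NULL, eb = TRUE, conv = 1e-4) {
  Y <- as.matrix(features)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  G <- ncol(Y)
  batch <- factor(batch)
  if (length(batch) != n)
    stop("batch length does not match the number of subjects", call. = FALSE)
  nb <- nlevels(batch)
  sizes <- table(batch)
  if (nb < 2L) {
    warning("single batch: nothing to harmonize, returning input",
            call. = FALSE)
    model <- structure(list(batch_levels = levels(batch), identity = TRUE),
                       class = "combat_model")
    return(list(adjusted = Y, model = model))
  }
  if (any(sizes < 2L))
    stop("singleton batch(es): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  if (!is.null(protect)) {
    protect <- factor(protect)
    pure <- tapply(protect, batch, function(x) length(unique(x)) == 1L)
    if (all(pure))
      stop("batch is confounded with the protected factor; ",
           "harmonization would remove it", call. = FALSE)
  }

  B <- stats::model.matrix(~ 0 + batch)
  colnames(B) <- levels(batch)
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(as.data.frame(covariates))
    storage.mode(C) <- "double"
    if (nrow(C) != n)
      stop("covariates do not match the number of subjects", call. = FALSE)
  }
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design (batch dummies + covariates)", call. = FALSE)

  # least-squares batch + covariate coefficients, feature by feature
  Bhat <- solve(crossprod(X), crossprod(X, Y))          # (nb+q) x G
  w <- as.numeric(sizes) / n
  grand <- drop(w %*% Bhat[seq_len(nb), , drop = FALSE])  # length G
  resid <- Y - X %*% Bhat
  var_pooled <- colSums(resid^2) / n                      # MLE variance
  if (any(var_pooled <= 0))
    stop("feature(s) with zero pooled variance", call. = FALSE)
  stand_mean <- matrix(grand, n, G, byrow = TRUE)
  if (!is.null(C))
    stand_mean <- stand_mean + C %*% Bhat[-seq_len(nb), , drop = FALSE]
  s <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, G, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, nb, G)
  delta_hat <- matrix(NA_real_, nb, G)
  for (i in seq_len(nb)) {
    rows <- which(batch == levels(batch)[i])
    gamma_hat[i, ] <- colMeans(s[rows, , drop = FALSE])
    delta_hat[i, ] <- apply(s[rows, , drop = FALSE], 2, stats::var)
  }

  if (eb) {
    gamma_star <- matrix(NA_real_, nb, G)
    delta_star <- matrix(NA_real_, nb, G)
    iters <- integer(nb)
    for (i in seq_len(nb)) {
      rows <- which(batch == levels(batch)[i])
      sol <- eb_fixed_point(s[rows, , drop = FALSE],
                            gamma_hat[i, ], delta_hat[i, ], conv = conv)
      gamma_star[i, ] <- sol$gamma
      delta_star[i, ] <- sol$delta
      iters[i] <- sol$iterations
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    iters <- integer(nb)
  }

  adj <- s
  for (i in seq_len(nb)) {
    rows <- which(batch == levels(batch)[i])
    adj[rows, ] <- sweep(sweep(s[rows, , drop = FALSE], 2, gamma_star[i, ]),
                         2, sqrt(delta_star[i, ]), `/`)
  }
  adjusted <- adj * matrix(sqrt(var_pooled), n, G, byrow = TRUE) + stand_mean
  dimnames(adjusted) <- dimnames(Y)

  model <- structure(list(batch_levels = levels(batch),
                          grand_mean = grand,
                          var_pooled = var_pooled,
                          covariate_coef = if (is.null(C)) NULL
                                           else Bhat[-seq_len(nb), ,
                                                     drop = FALSE],
                          gamma_hat = gamma_hat, delta_hat = delta_hat,
                          gamma_star = gamma_star, delta_star = delta_star,
                          eb = eb, iterations = iters,
                          identity = FALSE),
                     class = "combat_model")
  list(adjusted = adjusted, model = model)
}

# moment-matched inverse-gamma hyperparameters and the standard EB
# fixed-point iteration for one batch (vectorized over features)
eb_fixed_point <- function(s_batch, g_hat, d_hat, conv = 1e-4,
                           max_iter = 1000L) {
  ni <- nrow(s_batch)
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * ni * g_hat + d_old * g_bar) / (t2 * ni + d_old)
    sum2 <- colSums((s_batch - matrix(g_new, ni, length(g_new),
                                      byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b_prior) / (ni / 2 + a_prior - 1)
    # signed-denominator relative change, the stopping rule of the classic
    # reference implementation (kept verbatim for numerical agreement)
    change <- max(abs(g_new - g_old) / g_old,
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma = g_old, delta = d_old, iterations = it)
}

#' @export
print.combat_model <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("combat model: single batch (identity transform)\n")
    return(invisible(x))
  }
  cat(sprintf("combat model: %d batches, %d features (%s)\n",
              nrow(x$gamma_star), ncol(x$gamma_star),
              if (x$eb) "empirical-Bayes shrinkage" else "raw estimates"))
  invisible(x)
}

#' Apply a fitted harmonization model to data
#'
#' Applying a model to its own training data reproduces the fit-time output
#' exactly. Batches must be known to the model.
#'
#' @param model a `combat_model`.
#' @param features subjects x features matrix.
#' @param batch batch labels.
#' @param covariates covariates matching the fit design (or `NULL`).
#' @return adjusted matrix.
#' @export
combat_apply <- function(model, features, batch, covariates = NULL) {
  Y <- as.matrix(features)
  if (isTRUE(model$identity)) return(Y)
  batch <- factor(batch, levels = model$batch_levels)
  if (anyNA(batch))
    stop("batch label(s) unknown to the fitted model", call. = FALSE)
  n <- nrow(Y)
  G <- ncol(Y)
  stand_mean <- matrix(model$grand_mean, n, G, byrow = TRUE)
  if (!is.null(model$covariate_coef)) {
    C <- as.matrix(as.data.frame(covariates))
    stand_mean <- stand_mean + C %*% model$covariate_coef
  }
  s <- (Y - stand_mean) / matrix(sqrt(model$var_pooled), n, G, byrow = TRUE)
  idx <- as.integer(batch)
  adj <- (s - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_star[idx, , drop = FALSE])
  adj * matrix(sqrt(model$var_pooled), n, G, byrow = TRUE) + stand_mean
}

#' Residualize features on covariates
#'
#' Ordinary-least-squares residuals per feature for covariates that must be
#' removed outright (e.g. age in the prediction stage), with the intercept
#' restored so features keep their original means.
#'
#' @param features subjects x features matrix.
#' @param covariates matrix/data.frame of covariates to remove (no
#'   intercept).
#' @return matrix of residualized features.
#' @export
residualize <- function(features, covariates) {
  Y <- as.matrix(features)
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  if (nrow(C) != nrow(Y))
    stop("covariates do not match the number of subjects", call. = FALSE)
  X <- cbind(intercept = 1, C)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient covariate design", call. = FALSE)
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X %*% beta
  res + matrix(beta[1, ], nrow(Y), ncol(Y), byrow = TRUE)
}
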