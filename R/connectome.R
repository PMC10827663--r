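#' Fisher-z functional connectivity from parcellated time series
#'
#' Computes the pairwise Pearson correlation between parcel time series and
#' applies the Fisher z-transform `atanh(r)`. Correlations are clipped to
#' `+/-(1 - eps)` first so the transform stays finite; the diagonal is set to
#' 0 by convention (self-connections are excluded before sparsification).
#'
#' @param timeseries numeric matrix, timepoints x parcels (at least 3 rows).
#' @param eps clipping margin for the Fisher transform.
#' @param constant_policy what to do with zero-variance parcels: `"error"`
#'   (default) names the parcel, `"nan"` leaves NaN correlations in place and
#'   attaches the offending parcel indices as attribute `degenerate_parcels`.
#' @return a symmetric parcels x parcels Fisher-z matrix of class
#'   `fc_matrix`.
#' @export
pearson_fc <- function(timeseries, eps = 1e-7,
                       constant_policy = c("error", "nan")) {
  constant_policy <- match.arg(constant_policy)
  stopifnot(is.matrix(timeseries), is.numeric(timeseries))
  if (nrow(timeseries) < 3L)
    stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(timeseries, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate) && constant_policy == "error")
    stop("constant/degenerate time series for parcel(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  r <- suppressWarnings(stats::cor(timeseries))
  r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  z <- atanh(r)
  diag(z) <- 0
  if (length(degenerate)) attr(z, "degenerate_parcels") <- degenerate
  class(z) <- c("fc_matrix", class(z))
  z
}

#' Global signal regression
#'
#' Replaces every parcel's time series by the residual of its least-squares
#' regression on the spatial mean series (with intercept). Residuals are by
#' construction orthogonal to the global signal.
#'
#' @param timeseries timepoints x parcels matrix.
#' @return residual matrix of the same shape.
#' @export
regress_global_signal <- function(timeseries) {
  stopifnot(is.matrix(timeseries), nrow(timeseries) >= 3L)
  g <- rowMeans(timeseries)
  if (stats::sd(g) == 0)
    stop("global signal has zero variance", call. = FALSE)
  X <- cbind(1, g)
  beta <- solve(crossprod(X), crossprod(X, timeseries))
  timeseries - X %*% beta
}

#' Split a connectome into hemispheric blocks
#'
#' Extracts the four seed-by-target blocks LL, LR, RL, RR of a full
#' connectivity matrix. Rows and columns are reordered so that index i of
#' every block refers to homolog pair i of the parcellation: LL and RR are
#' directly comparable across hemispheres, as are LR and RL.
#'
#' @param fc parcels x parcels matrix (row/column order = parcellation order).
#' @param scheme a `parcellation` object.
#' @return a `hemi_blocks` object: list with elements `LL`, `LR`, `RL`, `RR`.
#' @export
split_blocks <- function(fc, scheme) {
  n <- nrow(scheme)
  if (!all(dim(fc) == c(n, n)))
    stop(sprintf("connectome is %d x %d but parcellation has %d parcels",
                 nrow(fc), ncol(fc), n), call. = FALSE)
  li <- parcel_rows(scheme, "left")
  ri <- parcel_rows(scheme, "right")
  blocks <- list(LL = fc[li, li, drop = FALSE],
                 LR = fc[li, ri, drop = FALSE],
                 RL = fc[ri, li, drop = FALSE],
                 RR = fc[ri, ri, drop = FALSE])
  structure(blocks, class = "hemi_blocks")
}

#' @export
print.hemi_blocks <- function(x, ...) {
  cat(sprintf("hemispheric blocks: %d homolog pairs (LL, LR, RL, RR)\n",
              nrow(x$LL)))
  invisible(x)
}
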