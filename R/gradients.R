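#' Row-wise sparsification of a connectivity block
#'
#' Keeps, independently in each row, the largest `ceiling(density * ncol)`
#' values (the top 10% by default) and zeroes the rest; retained values are
#' unchanged. Ties at the cutoff are broken deterministically in favour of
#' the lowest column index.
#'
#' @param block numeric matrix (seed parcels x target parcels).
#' @param density fraction of entries kept per row, in (0, 1].
#' @return matrix of the same shape.
#' @export
sparsify_rows <- function(block, density = 0.10) {
  stopifnot(is.matrix(block))
  if (!(density > 0 && density <= 1))
    stop("density must lie in (0, 1]", call. = FALSE)
  if (!all(is.finite(block)))
    stop("block contains non-finite entries", call. = FALSE)
  n <- ncol(block)
  keep <- ceiling(density * n)
  if (keep >= n) return(block)
  out <- matrix(0, nrow(block), n, dimnames = dimnames(block))
  for (i in seq_len(nrow(block))) {
    row <- block[i, ]
    top <- order(-row, seq_len(n))[seq_len(keep)]
    out[i, top] <- row[top]
  }
  out
}

#' Normalized-angle cosine affinity between connectivity profiles
#'
#' Pairwise cosine similarity between (sparsified) seed rows, mapped to the
#' normalized angle `1 - acos(rho) / pi`, so identical profiles score 1,
#' orthogonal profiles 0.5, and anti-parallel profiles 0. The diagonal is 1
#' by definition. This is the de-facto standard kernel of the connectome
#' gradient literature.
#'
#' @param block numeric matrix whose rows are connectivity profiles.
#' @return symmetric affinity matrix with entries in \[0, 1\].
#' @export
cosine_affinity <- function(block) {
  stopifnot(is.matrix(block))
  norms <- sqrt(rowSums(block^2))
  zero <- which(norms == 0)
  if (length(zero))
    stop("all-zero connectivity profile for row(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  unit <- block / norms
  rho <- tcrossprod(unit)
  rho <- pmin(pmax(rho, -1), 1)
  aff <- 1 - acos(rho) / pi
  aff <- pmax(aff, 0)
  aff <- (aff + t(aff)) / 2
  diag(aff) <- 1
  aff
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Computes the diffusion-map embedding of a symmetric non-negative affinity
#' matrix: density normalisation `W' = D^-alpha W D^-alpha`, row-normalised
#' transition operator, eigendecomposition, removal of the trivial stationary
#' component, and eigenvector scaling. `alpha = 0.5` discounts sampling
#' density half-way; `diffusion_time = 0` selects the multiscale convention
#' that scales component j by `lambda_j / (1 - lambda_j)`, integrating over
#' all diffusion times; any positive time scales by `lambda_j ^ t`.
#'
#' @param affinity symmetric non-negative matrix (e.g. [cosine_affinity()]).
#' @param alpha density-normalisation exponent in \[0, 1\].
#' @param k number of non-trivial components to return (`k < nrow`).
#' @param diffusion_time non-negative scalar; 0 = multiscale.
#' @param on_disconnected `"error"` (default) or `"largest_component"`, which
#'   embeds the largest connected component and fills the remaining rows with
#'   `NA`.
#' @param tol symmetry/negativity tolerance for input validation.
#' @return a `gradient_set`: list with `components` (n x k), `eigenvalues`,
#'   `variance_explained`, `aligned = FALSE` and the embedding parameters.
#' @export
diffusion_embedding <- function(affinity, alpha = 0.5, k = 10L,
                                diffusion_time = 0,
                                on_disconnected = c("error",
                                                    "largest_component"),
                                tol = 1e-10) {
  on_disconnected <- match.arg(on_disconnected)
  stopifnot(is.matrix(affinity))
  n <- nrow(affinity)
  if (ncol(affinity) != n) stop("affinity must be square", call. = FALSE)
  if (max(abs(affinity - t(affinity))) > tol * max(1, max(abs(affinity))))
    stop("affinity must be symmetric", call. = FALSE)
  if (min(affinity) < -tol)
    stop("affinity must be non-negative", call. = FALSE)
  if (k >= n)
    stop("k must be smaller than the number of nodes", call. = FALSE)
  W <- (affinity + t(affinity)) / 2
  W[W < 0] <- 0

  comp <- graph_components(W)
  if (max(comp$membership) > 1L) {
    if (on_disconnected == "error")
      stop("affinity graph is disconnected (", max(comp$membership),
           " components); use on_disconnected = 'largest_component' ",
           "to embed the largest one", call. = FALSE)
    warning("affinity graph disconnected; embedding largest component (",
            comp$largest_size, " of ", n, " nodes)", call. = FALSE)
    keep <- which(comp$membership == comp$largest)
    sub <- diffusion_embedding(W[keep, keep, drop = FALSE], alpha = alpha,
                               k = min(k, length(keep) - 1L),
                               diffusion_time = diffusion_time)
    comps <- matrix(NA_real_, n, ncol(sub$components))
    comps[keep, ] <- sub$components
    sub$components <- comps
    sub$embedded_nodes <- keep
    return(sub)
  }

  d <- rowSums(W)
  if (any(d <= 0)) stop("node(s) with zero degree", call. = FALSE)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / sqrt(outer(d1, d1))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  vals <- es$values
  vecs <- es$vectors
  # right eigenvectors of the transition operator, scaled so the stationary
  # (trivial) component is the constant vector
  psi <- vecs / vecs[, 1]
  lambdas <- vals[2:(k + 1)]
  scale <- if (diffusion_time == 0) lambdas / (1 - lambdas)
           else lambdas^diffusion_time
  components <- psi[, 2:(k + 1), drop = FALSE] *
    rep(scale, each = n)
  nontrivial <- vals[-1]
  var_exp <- lambdas / sum(pmax(nontrivial, 0))

  structure(list(components = components,
                 eigenvalues = lambdas,
                 variance_explained = var_exp,
                 aligned = FALSE,
                 block_tag = NA_character_,
                 seed_hemisphere = NA_character_,
                 alpha = alpha,
                 diffusion_time = diffusion_time),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient set: %d parcels x %d components (%s%s)\n",
              nrow(x$components), ncol(x$components),
              if (isTRUE(x$aligned)) "aligned" else "raw",
              if (is.na(x$block_tag)) "" else paste0(", ", x$block_tag)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[
        seq_len(min(3, length(x$variance_explained)))]), collapse = ", "),
      "...\n")
  invisible(x)
}

# connected components of the nonzero-weight graph (simple BFS; avoids an
# igraph dependency for a validation step)
graph_components <- function(W) {
  n <- nrow(W)
  adj <- W > 0
  diag(adj) <- FALSE
  membership <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (membership[s] != 0L) next
    comp <- comp + 1L
    frontier <- s
    membership[s] <- comp
    while (length(frontier)) {
      nbrs <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nbrs <- nbrs[membership[nbrs] == 0L]
      membership[nbrs] <- comp
      frontier <- nbrs
    }
  }
  sizes <- tabulate(membership)
  list(membership = membership, largest = which.max(sizes),
       largest_size = max(sizes))
}

#' Orthogonal Procrustes rotation
#'
#' Returns the orthogonal k x k matrix `R` minimising
#' `|| source %*% R - template ||_F` (rotation/reflection only — no scaling
#' or translation), computed from the singular value decomposition of
#' `t(source) %*% template`.
#'
#' @param source,template numeric matrices of identical shape (n x k).
#' @return k x k orthogonal matrix.
#' @export
procrustes_rotation <- function(source, template) {
  stopifnot(is.matrix(source), is.matrix(template),
            all(dim(source) == dim(template)))
  if (!all(is.finite(source)) || !all(is.finite(template)))
    stop("non-finite values in Procrustes input", call. = FALSE)
  M <- crossprod(source, template)
  sv <- svd(M)
  if (min(sv$d) < 1e-12 * max(sv$d))
    warning("rank-deficient cross-product in Procrustes alignment; ",
            "rotation follows the SVD sign convention", call. = FALSE)
  sv$u %*% t(sv$v)
}

#' Embed one hemispheric block
#'
#' Convenience wrapper: sparsify rows, build the normalized-angle affinity,
#' run the diffusion embedding.
#'
#' @param block 180 x 180 (pairs x pairs) Fisher-z block.
#' @param config a [grad_config()].
#' @return a `gradient_set`.
#' @export
embed_block <- function(block, config = grad_config()) {
  sp <- sparsify_rows(block, config$sparsity_density)
  aff <- cosine_affinity(sp)
  diffusion_embedding(aff, alpha = config$alpha,
                      k = config$n_gradients_computed,
                      diffusion_time = config$diffusion_time)
}

#' Align a gradient set to a template
#'
#' Rotates the components of `gset` onto the template with an orthogonal
#' Procrustes rotation computed in the full k-dimensional space; the leading
#' aligned columns are then directly comparable across subjects and blocks.
#'
#' @param gset a `gradient_set`.
#' @param template a `gradient_template` (or any n x k matrix).
#' @return the aligned `gradient_set` (`aligned = TRUE`).
#' @export
align_gradients <- function(gset, template) {
  tmpl <- if (inherits(template, "gradient_template")) template$components
          else template
  R <- procrustes_rotation(gset$components, tmpl)
  gset$components <- gset$components %*% R
  gset$aligned <- TRUE
  gset
}

#' Embed and align all four hemispheric blocks of a subject
#'
#' Each block (LL, LR, RL, RR) is embedded independently and rotated onto the
#' same left-left template, so that gradients are comparable across blocks,
#' hemispheres and subjects. LL and LR gradients live on left seed parcels,
#' RL and RR on right seed parcels, both in homolog-pair order.
#'
#' @param blocks a `hemi_blocks` object.
#' @param template a `gradient_template` built with [build_template()].
#' @param config a [grad_config()].
#' @return named list of four aligned `gradient_set`s (`LL`, `LR`, `RL`,
#'   `RR`).
#' @export
align_subject <- function(blocks, template, config = grad_config()) {
  stopifnot(inherits(blocks, "hemi_blocks"))
  tags <- c("LL", "LR", "RL", "RR")
  seeds <- c(LL = "left", LR = "left", RL = "right", RR = "right")
  out <- lapply(tags, function(tag) {
    g <- embed_block(blocks[[tag]], config)
    g <- align_gradients(g, template)
    g$block_tag <- tag
    g$seed_hemisphere <- seeds[[tag]]
    g
  })
  names(out) <- tags
  out
}

#' Build a group-level left-left gradient template
#'
#' Averages the subjects' Fisher-z LL blocks and embeds the mean matrix
#' (average-then-embed, not embed-then-average). The result anchors the
#' Procrustes alignment of every individual block.
#'
#' @param ll_blocks a list of 180 x 180 LL matrices, a list of `hemi_blocks`,
#'   or a single mean matrix.
#' @param config a [grad_config()].
#' @return a `gradient_template` with the embedding's components,
#'   eigenvalues and variance-explained shares.
#' @export
build_template <- function(ll_blocks, config = grad_config()) {
  if (is.matrix(ll_blocks)) {
    mean_ll <- ll_blocks
  } else {
    if (length(ll_blocks) == 0L)
      stop("empty cohort: no LL blocks to average", call. = FALSE)
    mats <- lapply(ll_blocks, function(b)
      if (inherits(b, "hemi_blocks")) b$LL else b)
    mean_ll <- Reduce(`+`, mats) / length(mats)
  }
  g <- embed_block(mean_ll, config)
  structure(list(components = g$components,
                 eigenvalues = g$eigenvalues,
                 variance_explained = g$variance_explained,
                 alpha = g$alpha,
                 diffusion_time = g$diffusion_time),
            class = "gradient_template")
}

#' @rdname build_template
#' @param components a parcels x k reference matrix used verbatim as the
#'   alignment target (e.g. a published group-level gradient set, or a
#'   generator's planted axes padded to the embedding dimension).
#' @export
as_gradient_template <- function(components) {
  components <- as.matrix(components)
  structure(list(components = components,
                 eigenvalues = rep(NA_real_, ncol(components)),
                 variance_explained = rep(NA_real_, ncol(components)),
                 alpha = NA_real_, diffusion_time = NA_real_),
            class = "gradient_template")
}

#' @export
print.gradient_template <- function(x, ...) {
  cat(sprintf("gradient template: %d parcels x %d components\n",
              nrow(x$components), ncol(x$components)))
  cat("  variance explained (top 3):",
      paste(sprintf("%.1f%%", 100 * x$variance_explained[
        seq_len(min(3, length(x$variance_explained)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a gradient template
#'
#' The template matrix is stored as plain text next to a small JSON sidecar
#' recording the embedding parameters.
#'
#' @param template a `gradient_template`.
#' @param path base path for the matrix file (sidecar gets `.json` appended).
#' @export
write_template <- function(template, path) {
  write_matrix(template$components, path)
  side <- list(k = ncol(template$components),
               kernel = "normalized_angle_cosine",
               alpha = template$alpha,
               diffusion_time = template$diffusion_time,
               eigenvalues = template$eigenvalues,
               variance_explained = template$variance_explained)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  comps <- read_matrix(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(components = comps,
                 eigenvalues = side$eigenvalues,
                 variance_explained = side$variance_explained,
                 alpha = side$alpha,
                 diffusion_time = side$diffusion_time),
            class = "gradient_template")
}
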