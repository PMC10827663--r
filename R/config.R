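#' Pipeline configuration
#'
#' Collects every tunable parameter of the gradient-asymmetry pipeline in one
#' validated list. Defaults follow the standard practice for connectome
#' gradient analyses: 10 gradients computed, the first 3 analyzed, row-wise
#' sparsification keeping the top 10% of connections, diffusion-map anisotropy
#' `alpha = 0.5`, multiscale (diffusion time 0) eigenvector scaling.
#'
#' @param n_gradients_computed number of non-trivial diffusion components to
#'   retain in each embedding.
#' @param n_gradients_analyzed number of leading aligned gradients used for
#'   asymmetry indices and statistics (must not exceed
#'   `n_gradients_computed`).
#' @param sparsity_density fraction of entries kept per row before building
#'   the affinity (in (0, 1]).
#' @param alpha diffusion-map density-normalisation exponent in \[0, 1\];
#'   0.5 balances geometry and sampling density.
#' @param diffusion_time diffusion time for eigenvector scaling; 0 selects the
#'   multiscale convention (scale by lambda / (1 - lambda)).
#' @param fd_threshold_mm exclusion threshold on mean framewise displacement
#'   (millimetres).
#' @param age_group_boundaries numeric vector `c(lo, b1, b2, hi)` defining the
#'   half-open child/adolescent/adult intervals `[lo,b1) [b1,b2) [b2,hi]`.
#' @param age_max,fiq_min phenotype exclusion rules: subjects older than
#'   `age_max` years or with full-scale IQ below `fiq_min` are flagged.
#' @param gsr_flag logical; regress the global signal out of time series
#'   before computing connectivity.
#' @param fdr_q false-discovery-rate level for parcel- and network-wise
#'   multivariate tests.
#' @param posthoc_bonferroni_k divisor for the post-hoc per-gradient
#'   significance level (alpha / k).
#' @param random_seed integer seed recorded with the configuration.
#'
#' @return an object of class `grad_config` (a named list).
#' @export
grad_config <- function(n_gradients_computed = 10L,
                        n_gradients_analyzed = 3L,
                        sparsity_density = 0.10,
                        alpha = 0.5,
                        diffusion_time = 0,
                        fd_threshold_mm = 0.3,
                        age_group_boundaries = c(5, 12, 18, 40),
                        age_max = 40,
                        fiq_min = 70,
                        gsr_flag = FALSE,
                        fdr_q = 0.05,
                        posthoc_bonferroni_k = 3L,
                        random_seed = 1L) {
  cfg <- list(
    n_gradients_computed = as.integer(n_gradients_computed),
    n_gradients_analyzed = as.integer(n_gradients_analyzed),
    sparsity_density = sparsity_density,
    alpha = alpha,
    diffusion_time = diffusion_time,
    fd_threshold_mm = fd_threshold_mm,
    age_group_boundaries = age_group_boundaries,
    age_max = age_max,
    fiq_min = fiq_min,
    gsr_flag = isTRUE(gsr_flag),
    fdr_q = fdr_q,
    posthoc_bonferroni_k = as.integer(posthoc_bonferroni_k),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "grad_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "grad_config"))
  if (!(cfg$sparsity_density > 0 && cfg$sparsity_density <= 1))
    stop("sparsity_density must lie in (0, 1]", call. = FALSE)
  if (!(cfg$alpha >= 0 && cfg$alpha <= 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  if (cfg$n_gradients_analyzed > cfg$n_gradients_computed)
    stop("n_gradients_analyzed must not exceed n_gradients_computed",
         call. = FALSE)
  if (length(cfg$age_group_boundaries) != 4L ||
      is.unsorted(cfg$age_group_boundaries, strictly = TRUE))
    stop("age_group_boundaries must be 4 strictly increasing values",
         call. = FALSE)
  if (!(cfg$fdr_q > 0 && cfg$fdr_q < 1))
    stop("fdr_q must lie in (0, 1)", call. = FALSE)
  cfg
}

#' @export
print.grad_config <- function(x, ...) {
  cat("gradasym pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read / write a configuration as key-value text
#'
#' The on-disk format is one `key: value` pair per line (vector values are
#' space-separated), so that every run can log the exact configuration it
#' resolved.
#'
#' @param path file path.
#' @param cfg a [grad_config()] object.
#' @return `read_config` returns a `grad_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  lines <- vapply(names(cfg), function(nm) {
    sprintf("%s: %s", nm, paste(format(cfg[[nm]], digits = 15), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  vals <- list()
  for (pair in kv) {
    key <- trimws(pair[[1]])
    raw <- trimws(paste(pair[-1], collapse = ":"))
    parts <- strsplit(raw, "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    vals[[key]] <- if (anyNA(num)) {
      if (raw %in% c("TRUE", "FALSE")) as.logical(raw) else raw
    } else num
  }
  do.call(grad_config, vals)
}
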