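#' Percentile-bin a statistic map
#'
#' Ranks parcels by their statistic value (ascending) and cuts the ranking
#' into `n_bins` contiguous, equal-sized bins (20 bins of 5% each by
#' default). When the parcel count is not divisible by `n_bins`, the
#' lowest-rank bins receive one extra parcel. Ties are broken by parcel
#' index, so the binning is deterministic. A bin's loading is the mean
#' statistic of its parcels.
#'
#' @param stat_map numeric vector of per-parcel statistic values (e.g. the
#'   t map of one hemisphere).
#' @param n_bins number of percentile bins.
#' @return list with `assignment` (bin index per parcel, original order) and
#'   `loadings` (mean statistic per bin).
#' @export
bin_map <- function(stat_map, n_bins = 20L) {
  n <- length(stat_map)
  if (n_bins < 1L || n_bins > n)
    stop("n_bins must lie in [1, number of parcels]", call. = FALSE)
  if (any(!is.finite(stat_map)))
    stop("statistic map contains non-finite values", call. = FALSE)
  ord <- order(stat_map, seq_len(n))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bins_in_rank_order <- rep(seq_len(n_bins), times = sizes)
  assignment <- integer(n)
  assignment[ord] <- bins_in_rank_order
  loadings <- vapply(seq_len(n_bins), function(b)
    mean(stat_map[assignment == b]), numeric(1))
  list(assignment = assignment, loadings = loadings)
}

#' Weighted term score against a binned statistic map
#'
#' For each bin, the mean of the term's activation z values restricted to
#' strictly positive activations (0 when no parcel in the bin activates);
#' the score is the sum over bins of this mean multiplied by the bin's
#' loading.
#'
#' @param term_z per-parcel activation z values, aligned with the binned
#'   map.
#' @param bins,loadings output of [bin_map()].
#' @param abs_loadings use `abs(loading)` instead of the signed loading.
#' @return scalar weighted score.
#' @export
weighted_term_score <- function(term_z, bins, loadings,
                                abs_loadings = FALSE) {
  if (length(term_z) != length(bins$assignment))
    stop("term map and statistic map have different parcel counts",
         call. = FALSE)
  w <- if (abs_loadings) abs(loadings) else loadings
  score <- 0
  for (b in seq_along(w)) {
    z <- term_z[bins$assignment == b]
    z <- z[z > 0]
    if (length(z)) score <- score + mean(z) * w[b]
  }
  score
}

#' Decode a statistic map against a term dictionary
#'
#' Computes the percentile-bin weighted score of every term map against the
#' statistic map and ranks terms by score. Hemispheres are decoded
#' separately by passing the corresponding half of the map and dictionary.
#'
#' @param stat_map per-parcel statistic values for one hemisphere scope.
#' @param term_dictionary numeric matrix parcels x terms (column names are
#'   term labels), or a named list of per-parcel vectors.
#' @param n_bins number of percentile bins.
#' @param abs_loadings see [weighted_term_score()].
#' @return a `decoding_result` data.frame (`term`, `score`, `rank`), ordered
#'   by decreasing score.
#' @export
decode <- function(stat_map, term_dictionary, n_bins = 20L,
                   abs_loadings = FALSE) {
  if (is.list(term_dictionary) && !is.data.frame(term_dictionary))
    term_dictionary <- do.call(cbind, term_dictionary)
  term_dictionary <- as.matrix(term_dictionary)
  if (ncol(term_dictionary) < 1L)
    stop("term dictionary is empty", call. = FALSE)
  if (is.null(colnames(term_dictionary)))
    colnames(term_dictionary) <- paste0("term_", seq_len(ncol(term_dictionary)))
  bins <- bin_map(stat_map, n_bins)
  scores <- vapply(seq_len(ncol(term_dictionary)), function(j)
    weighted_term_score(term_dictionary[, j], bins, bins$loadings,
                        abs_loadings = abs_loadings), numeric(1))
  out <- data.frame(term = colnames(term_dictionary), score = scores,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$term), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("decoding_result", "data.frame")
  out
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding result: %d terms; top terms:\n", nrow(x)))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}
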