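#' Canonical functional network labels
#'
#' The 12 cortical network labels used to summarise parcel-wise results:
#' primary/secondary visual, somatomotor, cingulo-opercular, dorsal attention,
#' language, frontoparietal, auditory, default mode, posterior multimodal,
#' ventral multimodal and orbito-affective networks.
#' @export
NETWORK_LABELS <- c("Vis1", "Vis2", "SMN", "CON", "DAN", "Lan",
                    "FPN", "Aud", "DMN", "PMN", "VMN", "OAN")

#' Load and validate a parcellation scheme
#'
#' A parcellation scheme is the coordinate frame of every map in the pipeline:
#' a bilaterally matched parcel table in which every left parcel has exactly
#' one mirror (homolog) parcel on the right, and every parcel carries one of
#' the 12 network labels. The canonical ordering is parcel ids 0..(n-1) for
#' the left hemisphere followed by n..(2n-1) for the right, with
#' `homolog_id = parcel_id +/- n`; any other ordering must be declared in the
#' file and is reindexed on load.
#'
#' @param path TSV file with columns `parcel_id`, `parcel_name`, `hemisphere`,
#'   `homolog_id`, `network`.
#' @return a `parcellation` object: the validated data.frame (left parcels
#'   first, ordered by id) with attributes `n_per_hemi` and `pairs`
#'   (a data.frame mapping pair index to left/right row positions).
#' @export
load_parcellation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  as_parcellation(df)
}

#' @rdname load_parcellation
#' @param df a data.frame with the columns listed above.
#' @export
as_parcellation <- function(df) {
  required <- c("parcel_id", "hemisphere", "homolog_id", "network")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("parcellation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"parcel_name" %in% names(df))
    df$parcel_name <- paste0("parcel_", df$parcel_id)
  if (nrow(df) %% 2L != 0L)
    stop("parcellation must have an even number of parcels", call. = FALSE)

  df$hemisphere <- tolower(df$hemisphere)
  if (!all(df$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)

  bad_net <- setdiff(unique(df$network), NETWORK_LABELS)
  if (length(bad_net))
    stop("unknown network label(s): ", paste(bad_net, collapse = ", "),
         call. = FALSE)

  n_half <- nrow(df) / 2L
  if (sum(df$hemisphere == "left") != n_half)
    stop("parcellation must have equal parcel counts per hemisphere",
         call. = FALSE)
  if (anyDuplicated(df$parcel_id))
    stop("duplicate parcel_id values", call. = FALSE)

  # homolog map must be a symmetric bijection across hemispheres
  idx <- match(df$homolog_id, df$parcel_id)
  if (anyNA(idx))
    stop("homolog_id refers to unknown parcel id(s): ",
         paste(df$homolog_id[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(df$hemisphere[idx] == df$hemisphere))
    stop("homolog pairs must cross hemispheres; offending parcel id(s): ",
         paste(df$parcel_id[df$hemisphere[idx] == df$hemisphere],
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$homolog_id)) {
    dup <- df$homolog_id[duplicated(df$homolog_id)]
    stop("homolog map is not a bijection; right parcel(s) claimed twice: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  back <- df$homolog_id[idx]
  if (!all(back == df$parcel_id))
    stop("homolog pairing is not symmetric (homolog of homolog != self)",
         call. = FALSE)

  df <- df[order(df$hemisphere != "left", df$parcel_id), , drop = FALSE]
  rownames(df) <- NULL
  left <- which(df$hemisphere == "left")
  right_rows <- match(df$homolog_id[left], df$parcel_id)
  pairs <- data.frame(pair = seq_along(left), left_row = left,
                      right_row = right_rows)

  structure(df, class = c("parcellation", "data.frame"),
            n_per_hemi = n_half, pairs = pairs)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels (%d per hemisphere), %d networks\n",
              nrow(x), attr(x, "n_per_hemi"),
              length(unique(x$network))))
  invisible(x)
}

#' Write a parcellation scheme to TSV
#' @param scheme a `parcellation` object.
#' @param path output file.
#' @export
write_parcellation <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme)[, c("parcel_id", "parcel_name",
                                               "hemisphere", "homolog_id",
                                               "network")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Homolog-pair bookkeeping helpers
#'
#' `parcel_rows` returns the row positions of a hemisphere's parcels in
#' homolog-pair order, so that row i of every hemispheric block refers to
#' homolog pair i. `pair_networks` returns the network label of each pair
#' (taken from the left member).
#'
#' @param scheme a `parcellation` object.
#' @param hemisphere `"left"` or `"right"`.
#' @return an integer vector of row positions, or a character vector of
#'   network labels.
#' @export
parcel_rows <- function(scheme, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  pairs <- attr(scheme, "pairs")
  if (hemisphere == "left") pairs$left_row else pairs$right_row
}

#' @rdname parcel_rows
#' @export
pair_networks <- function(scheme) {
  scheme$network[parcel_rows(scheme, "left")]
}
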