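#' Homotopic asymmetry index of aligned gradients
#'
#' The asymmetry index (AI) of homolog pair i on gradient g is the left
#' hemisphere value minus the right hemisphere value; positive AI means
#' leftward dominance. The intra-hemispheric pattern contrasts the LL and RR
#' block gradients, the inter-hemispheric pattern contrasts LR and RL. AI is
#' deliberately non-normalised (no division by left + right): gradient values
#' take both signs, so a ratio index would be discontinuous.
#'
#' @param gradients_left,gradients_right matrices (pairs x gradients) in
#'   homolog-pair order, e.g. the leading aligned columns of the LL and RR
#'   gradient sets.
#' @return matrix of AI values (pairs x gradients).
#' @export
asymmetry_index <- function(gradients_left, gradients_right) {
  gl <- as.matrix(gradients_left)
  gr <- as.matrix(gradients_right)
  if (!all(dim(gl) == dim(gr)))
    stop(sprintf("left is %d x %d but right is %d x %d",
                 nrow(gl), ncol(gl), nrow(gr), ncol(gr)), call. = FALSE)
  gl - gr
}

#' Asymmetry maps for one subject
#'
#' Computes both asymmetry patterns from a subject's four aligned gradient
#' sets, restricted to the analyzed gradients (G1..Gk).
#'
#' @param aligned named list of aligned `gradient_set`s from
#'   [align_subject()].
#' @param config a [grad_config()].
#' @return list with matrices `intra` (LL - RR) and `inter` (LR - RL), each
#'   pairs x `n_gradients_analyzed`.
#' @export
subject_asymmetry <- function(aligned, config = grad_config()) {
  ka <- config$n_gradients_analyzed
  take <- function(tag) aligned[[tag]]$components[, seq_len(ka), drop = FALSE]
  list(intra = asymmetry_index(take("LL"), take("RR")),
       inter = asymmetry_index(take("LR"), take("RL")))
}

#' Network-wise mean asymmetry
#'
#' Unweighted mean of the member homolog pairs' AI per network and gradient.
#' A pair's network is the one shared by its two parcels (the generator
#' mirrors assignments; for schemes where homologs disagree, the left
#' member's label is used).
#'
#' @param ai matrix (pairs x gradients) of asymmetry indices.
#' @param scheme a `parcellation` object.
#' @return matrix (networks x gradients); networks with no member pairs get
#'   `NA` with a warning.
#' @export
network_mean <- function(ai, scheme) {
  ai <- as.matrix(ai)
  nets <- pair_networks(scheme)
  if (length(nets) != nrow(ai))
    stop("AI has ", nrow(ai), " pairs but parcellation has ", length(nets),
         call. = FALSE)
  out <- matrix(NA_real_, length(NETWORK_LABELS), ncol(ai),
                dimnames = list(NETWORK_LABELS, colnames(ai)))
  for (nw in NETWORK_LABELS) {
    rows <- which(nets == nw)
    if (length(rows) == 0L) next
    out[nw, ] <- colMeans(ai[rows, , drop = FALSE])
  }
  if (anyNA(out))
    warning("network(s) with no member pairs: ",
            paste(NETWORK_LABELS[rowSums(is.na(out)) > 0], collapse = ", "),
            call. = FALSE)
  out
}

#' Inter-subject similarity (idiosyncrasy) scores
#'
#' For each subject, the mean Pearson correlation between their AI map and
#' every other subject's map within the same reference cell. Lower scores
#' mean a more idiosyncratic asymmetry organisation. The default reference
#' population is all same-site subjects regardless of diagnosis; same-site
#' same-group and whole-cohort references are available.
#'
#' @param ai_stack matrix subjects x features (e.g. the concatenated G1..G3
#'   AI vector of one pattern); rows must align with `cohort` rows.
#' @param cohort a `cohort` data.frame.
#' @param scope `"site"` (default), `"site_group"` or `"cohort"`.
#' @return data.frame with `subject_id`, `site`, `group`, `similarity`;
#'   subjects with a zero-variance map get `NA` with a warning.
#' @export
intersubject_similarity <- function(ai_stack, cohort,
                                    scope = c("site", "site_group",
                                              "cohort")) {
  scope <- match.arg(scope)
  ai_stack <- as.matrix(ai_stack)
  stopifnot(nrow(ai_stack) == nrow(cohort))
  cell <- switch(scope,
                 site = as.character(cohort$site),
                 site_group = paste(cohort$site, cohort$group, sep = "|"),
                 cohort = rep("all", nrow(cohort)))
  sds <- apply(ai_stack, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate))
    warning("zero-variance AI map(s); similarity undefined for subject(s): ",
            paste(cohort$subject_id[degenerate], collapse = ", "),
            call. = FALSE)
  sim <- rep(NA_real_, nrow(cohort))
  for (cl in unique(cell)) {
    rows <- which(cell == cl & !degenerate)
    if (length(rows) < 3L)
      stop("fewer than 3 usable subjects in similarity cell '", cl, "'",
           call. = FALSE)
    cmat <- stats::cor(t(ai_stack[rows, , drop = FALSE]))
    diag(cmat) <- NA
    sim[rows] <- rowMeans(cmat, na.rm = TRUE)
  }
  data.frame(subject_id = cohort$subject_id, site = cohort$site,
             group = cohort$group, similarity = sim,
             stringsAsFactors = FALSE)
}

#' Tidy long-format export of asymmetry values
#'
#' Flattens per-subject AI matrices to the long format consumed by the
#' statistics and prediction stages.
#'
#' @param ai_by_subject named list (subject id -> list(intra, inter) of
#'   pairs x gradients matrices).
#' @return data.frame with columns `subject_id`, `pattern`, `pair`,
#'   `gradient`, `value`.
#' @export
asymmetry_long <- function(ai_by_subject) {
  rows <- lapply(names(ai_by_subject), function(sid) {
    maps <- ai_by_subject[[sid]]
    do.call(rbind, lapply(names(maps), function(pat) {
      m <- maps[[pat]]
      data.frame(subject_id = sid, pattern = pat,
                 pair = rep(seq_len(nrow(m)), ncol(m)),
                 gradient = rep(paste0("G", seq_len(ncol(m))),
                                each = nrow(m)),
                 value = as.vector(m), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Stack one pattern's AI into a subjects x features matrix
#'
#' Features are ordered pair-fastest within gradient (pair 1..P of G1, then
#' of G2, ...), with names `p<pair>_G<g>`.
#'
#' @param ai_by_subject as in [asymmetry_long()].
#' @param pattern `"intra"` or `"inter"`.
#' @return numeric matrix subjects x (pairs * gradients) with subject ids as
#'   row names.
#' @export
ai_feature_matrix <- function(ai_by_subject, pattern = c("intra", "inter")) {
  pattern <- match.arg(pattern)
  mats <- lapply(ai_by_subject, function(maps) as.vector(maps[[pattern]]))
  X <- do.call(rbind, mats)
  rownames(X) <- names(ai_by_subject)
  m1 <- ai_by_subject[[1]][[pattern]]
  colnames(X) <- paste0("p", rep(seq_len(nrow(m1)), ncol(m1)), "_G",
                        rep(seq_len(ncol(m1)), each = nrow(m1)))
  X
}
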