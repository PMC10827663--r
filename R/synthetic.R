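#' Generate a bilaterally mirrored synthetic parcellation
#'
#' Random, approximately balanced assignment of parcels to functional
#' networks, mirrored across hemispheres so homolog pairs share a network.
#' Parcel ids follow the canonical convention: 0..(n-1) left, n..(2n-1)
#' right, homolog id = parcel id +/- n.
#'
#' @param n_per_hemi parcels per hemisphere.
#' @param n_networks number of networks (at most 12, at most `n_per_hemi`).
#' @param seed integer seed.
#' @return a `parcellation` object.
#' @export
make_parcellation <- function(n_per_hemi = 180L, n_networks = 12L,
                              seed = 1L) {
  if (n_networks > n_per_hemi)
    stop("more networks than parcels per hemisphere", call. = FALSE)
  if (n_networks < 1L || n_networks > length(NETWORK_LABELS))
    stop("n_networks must lie in [1, ", length(NETWORK_LABELS), "]",
         call. = FALSE)
  set.seed(seed)
  nets <- sample(rep_len(NETWORK_LABELS[seq_len(n_networks)], n_per_hemi))
  ids <- seq_len(n_per_hemi) - 1L
  df <- data.frame(
    parcel_id = c(ids, ids + n_per_hemi),
    parcel_name = c(paste0("L_", ids), paste0("R_", ids)),
    hemisphere = rep(c("left", "right"), each = n_per_hemi),
    homolog_id = c(ids + n_per_hemi, ids),
    network = rep(nets, 2),
    stringsAsFactors = FALSE)
  as_parcellation(df)
}

#' Simulate a multi-site case-control cohort table
#'
#' Ages are uniform on the configured range, sites uniform, groups balanced
#' by construction. Full-scale IQ and mean framewise displacement are drawn
#' with configurable group mean offsets, emulating the FIQ and head-motion
#' differences reported in case-control samples.
#'
#' @param n_per_group subjects per diagnostic group.
#' @param n_sites number of acquisition sites.
#' @param age_range `c(lo, hi)` in years.
#' @param seed integer seed.
#' @param fiq_offset autism-minus-NAI mean FIQ difference (IQ points).
#' @param fd_offset autism-minus-NAI mean FD difference (mm).
#' @param config a [grad_config()] for age grouping and exclusion flags.
#' @return a `cohort` data.frame.
#' @export
simulate_cohort <- function(n_per_group = 70L, n_sites = 5L,
                            age_range = c(5, 40), seed = 1L,
                            fiq_offset = -8, fd_offset = 0.02,
                            config = grad_config()) {
  if (n_per_group < 1L || n_sites < 1L)
    stop("counts must be >= 1", call. = FALSE)
  if (age_range[1] >= age_range[2])
    stop("degenerate age range", call. = FALSE)
  set.seed(seed)
  n <- 2L * n_per_group
  group <- rep(c("autism", "NAI"), each = n_per_group)
  site <- paste0("site", c(sample(rep_len(seq_len(n_sites), n_per_group)),
                           sample(rep_len(seq_len(n_sites), n_per_group))))
  age <- stats::runif(n, age_range[1], age_range[2])
  fiq <- stats::rnorm(n, 110, 12) + ifelse(group == "autism", fiq_offset, 0)
  fd <- pmax(0.01, stats::rnorm(n, 0.12, 0.05) +
               ifelse(group == "autism", fd_offset, 0))
  df <- data.frame(subject_id = sprintf("sub%04d", seq_len(n)),
                   group = group, age = age, site = site,
                   fiq = fiq, mean_fd = fd,
                   ados_total = NA_real_, ados_comm = NA_real_,
                   ados_social = NA_real_, ados_rrb = NA_real_,
                   stringsAsFactors = FALSE)
  as_cohort(df, config)
}

#' Ground-truth parameters for the synthetic generator
#'
#' Defines everything the generator plants: low-rank gradient templates, the
#' homolog pairs carrying a group difference in asymmetry, per-group age
#' slopes, per-site batch effects, and the sparse weights coupling the trait
#' to intra-hemispheric asymmetry features. Effect sizes default to values
#' chosen for statistical power of the downstream detection tests (the
#' magnitude of real asymmetry effects is unknown in AI units).
#'
#' @param scheme a `parcellation`; effect pairs default to members of the
#'   language and default-mode networks.
#' @param k number of latent gradient axes.
#' @param group_effect_size standardized group difference in AI (in units of
#'   the AI noise SD) planted on `group_effect_pairs` along G1; the autism
#'   group gets lower leftward asymmetry.
#' @param group_effect_pairs,age_effect_pairs homolog-pair indices carrying
#'   the group and age effects (`NULL` = first 10 language-network pairs and
#'   first 10 default-mode pairs respectively).
#' @param age_slope_by_group named list of per-year AI slopes on
#'   `age_effect_pairs` along G3.
#' @param ai_noise_sd SD of the biological AI noise per pair and gradient.
#' @param site_shift_sd,site_scale_sd SDs of per-site mean additive shift
#'   and log multiplicative scale of the batch effects.
#' @param n_trait_features number of intra-hemispheric (pair, gradient)
#'   features coupled to the trait.
#' @param trait_r2 fraction of trait variance explained by the coupled
#'   features.
#' @param fc_noise_sd edgewise SD of Fisher-z noise on synthetic blocks.
#' @param n_sites number of sites (must match the cohort).
#' @param seed integer seed for the random parts (site effect draws, trait
#'   feature choice, template orientation).
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(scheme, k = 3L,
                         group_effect_size = 0.8,
                         group_effect_pairs = NULL,
                         age_effect_pairs = NULL,
                         age_slope_by_group = list(NAI = 0.025, autism = 0),
                         ai_noise_sd = 0.2,
                         site_shift_sd = 0.1, site_scale_sd = 0.1,
                         n_trait_features = 10L, trait_r2 = 0.5,
                         fc_noise_sd = 0.05,
                         n_sites = 5L, seed = 1L) {
  n_pairs <- attr(scheme, "n_per_hemi")
  nets <- pair_networks(scheme)
  if (is.null(group_effect_pairs))
    group_effect_pairs <- utils::head(which(nets == "Lan"), 10L)
  if (is.null(age_effect_pairs))
    age_effect_pairs <- utils::head(which(nets == "DMN"), 10L)
  if (any(group_effect_pairs > n_pairs) || any(age_effect_pairs > n_pairs))
    stop("effect pair index out of range", call. = FALSE)

  set.seed(seed)
  # latent geometry: parcels sit on a closed ring coordinate; the basis is
  # its Fourier harmonics with a decaying loading spectrum, so connectivity
  # profiles are local along the ring, the affinity is circulant, and the
  # diffusion embedding recovers the leading harmonics exactly (up to the
  # within-pair rotation that Procrustes alignment resolves)
  n_harmonics <- 10L
  tcoord <- (seq_len(n_pairs) - 0.5) / n_pairs
  basis <- do.call(cbind, lapply(seq_len(n_harmonics), function(m)
    cbind(sqrt(2) * cos(2 * pi * m * tcoord),
          sqrt(2) * sin(2 * pi * m * tcoord))))
  basis_loadings <- rep(0.3 / seq_len(n_harmonics)^1.5, each = 2)
  if (k > ncol(basis))
    stop("k exceeds the latent basis dimension", call. = FALSE)
  # the planted gradient axes are the first k harmonics (unit SD columns)
  template <- basis[, seq_len(k), drop = FALSE]
  loadings <- basis_loadings[seq_len(k)]

  n_features <- n_pairs * k
  site_shift <- stats::rnorm(n_sites, 0, site_shift_sd)
  site_scale <- exp(stats::rnorm(n_sites, 0, site_scale_sd))
  # per-feature realisations of each site's location/scale effect
  site_gamma <- matrix(stats::rnorm(n_sites * n_features, rep(site_shift,
                                                              n_features),
                                    0.05), n_sites, n_features)
  site_delta <- matrix(site_scale * exp(stats::rnorm(n_sites * n_features,
                                                     0, 0.05)),
                       n_sites, n_features)

  trait_features <- if (n_trait_features > 0L) {
    feat_pairs <- sample(group_effect_pairs, n_trait_features,
                         replace = n_trait_features >
                           length(group_effect_pairs))
    feat_grad <- sample.int(k, n_trait_features, replace = TRUE)
    unique((feat_grad - 1L) * n_pairs + feat_pairs)
  } else integer(0)
  trait_weights <- stats::setNames(
    sample(c(-1, 1), length(trait_features), replace = TRUE),
    trait_features)

  structure(list(n_pairs = n_pairs, k = k,
                 template = template, loadings = loadings,
                 basis = basis, basis_loadings = basis_loadings,
                 fc_baseline = 0.25,
                 group_effect_size = group_effect_size,
                 # absolute AI shift frozen at construction, so noise-free
                 # generators keep the planted contrast
                 group_effect_shift = group_effect_size * ai_noise_sd,
                 group_effect_pairs = group_effect_pairs,
                 group_effect_gradient = 1L,
                 age_effect_pairs = age_effect_pairs,
                 age_effect_gradient = min(3L, k),
                 age_slope_by_group = age_slope_by_group,
                 age_center = 20,
                 ai_noise_sd = ai_noise_sd,
                 site_shift = site_shift, site_scale = site_scale,
                 site_gamma = site_gamma, site_delta = site_delta,
                 trait_features = trait_features,
                 trait_weights = trait_weights,
                 trait_r2 = trait_r2,
                 fc_noise_sd = fc_noise_sd,
                 seed = seed),
            class = "ground_truth")
}

# per-subject planted AI signal (pairs x k), excluding noise and site
# effects; AI = left - right latent score
planted_ai_signal <- function(truth, group, age) {
  sig <- matrix(0, truth$n_pairs, truth$k)
  if (truth$group_effect_shift != 0 && group == "autism") {
    sig[truth$group_effect_pairs, truth$group_effect_gradient] <-
      sig[truth$group_effect_pairs, truth$group_effect_gradient] -
      truth$group_effect_shift
  }
  slope <- truth$age_slope_by_group[[group]]
  if (!is.null(slope) && slope != 0) {
    sig[truth$age_effect_pairs, truth$age_effect_gradient] <-
      sig[truth$age_effect_pairs, truth$age_effect_gradient] +
      slope * (age - truth$age_center)
  }
  sig
}

#' Simulate asymmetry-index features for a cohort
#'
#' The direct generative route for the statistics, harmonization and
#' prediction stages: each subject's AI at (pair, gradient) is the planted
#' signal (group difference, per-group age slope) plus Gaussian biological
#' noise, observed through the site's location/scale batch effect. The
#' inter-hemispheric pattern carries no planted effects by default (it
#' shares the noise and site-effect model). Both the observed and the
#' biological (pre-site) features are returned.
#'
#' @param cohort a `cohort` data.frame.
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @return a `synthetic_ai` object: list with `observed` and `biological`
#'   (each a list of `intra`/`inter` subjects x (pairs * k) matrices,
#'   feature names `p<pair>_G<g>`), plus `cohort` and `truth`.
#' @export
simulate_ai_features <- function(cohort, truth, seed = 1L) {
  set.seed(seed)
  n <- nrow(cohort)
  F_ <- truth$n_pairs * truth$k
  site_idx <- as.integer(factor(cohort$site))
  if (max(site_idx) > nrow(truth$site_gamma))
    stop("cohort has more sites than the ground truth parameterises",
         call. = FALSE)
  feat_names <- paste0("p", rep(seq_len(truth$n_pairs), truth$k), "_G",
                       rep(seq_len(truth$k), each = truth$n_pairs))
  out <- list(observed = list(), biological = list())
  for (pattern in c("intra", "inter")) {
    bio <- matrix(0, n, F_, dimnames = list(cohort$subject_id, feat_names))
    for (s in seq_len(n)) {
      sig <- if (pattern == "intra")
        planted_ai_signal(truth, cohort$group[s], cohort$age[s])
      else matrix(0, truth$n_pairs, truth$k)
      bio[s, ] <- as.vector(sig) +
        stats::rnorm(F_, 0, truth$ai_noise_sd)
    }
    obs <- truth$site_delta[site_idx, , drop = FALSE] * bio +
      truth$site_gamma[site_idx, , drop = FALSE]
    dimnames(obs) <- dimnames(bio)
    out$observed[[pattern]] <- obs
    out$biological[[pattern]] <- bio
  }
  structure(c(out, list(cohort = cohort, truth = truth, seed = seed)),
            class = "synthetic_ai")
}

#' Attach trait scores generated from asymmetry features
#'
#' ADOS-like scores are linear combinations of the designated biological
#' intra-hemispheric AI features plus Gaussian noise, scaled so the coupled
#' features explain `trait_r2` of the variance, then shifted, rounded and
#' clipped at zero (generator convention for integer scores). Communication
#' and social subscores share the signal; the restricted/repetitive
#' behaviour subscore is pure noise, emulating its reported decoupling from
#' asymmetry.
#'
#' @param synth a `synthetic_ai` object.
#' @param seed integer seed.
#' @param trait_mean,trait_sd location and scale of the integerized total
#'   score.
#' @return `synth` with the cohort's `ados_*` columns filled in.
#' @export
attach_trait_scores <- function(synth, seed = 1L, trait_mean = 10,
                                trait_sd = 4) {
  truth <- synth$truth
  set.seed(seed)
  n <- nrow(synth$cohort)
  feats <- truth$trait_features
  if (length(feats) > ncol(synth$biological$intra))
    stop("trait feature index out of range", call. = FALSE)
  if (length(feats)) {
    raw <- synth$biological$intra[, feats, drop = FALSE] %*%
      truth$trait_weights
    raw <- drop(raw)
    signal <- (raw - mean(raw)) / stats::sd(raw) *
      trait_sd * sqrt(truth$trait_r2)
    noise_sd <- trait_sd * sqrt(1 - truth$trait_r2)
  } else {
    signal <- rep(0, n)
    noise_sd <- trait_sd
  }
  total <- pmax(0, round(trait_mean + signal + stats::rnorm(n, 0, noise_sd)))
  comm <- pmax(0, round(0.35 * (trait_mean + signal) +
                          stats::rnorm(n, 0, 0.5 * noise_sd)))
  social <- pmax(0, round(0.45 * (trait_mean + signal) +
                            stats::rnorm(n, 0, 0.5 * noise_sd)))
  rrb <- pmax(0, round(stats::rnorm(n, 0.2 * trait_mean,
                                    0.3 * trait_sd)))
  synth$cohort$ados_total <- total
  synth$cohort$ados_comm <- comm
  synth$cohort$ados_social <- social
  synth$cohort$ados_rrb <- rrb
  synth
}

#' Simulate per-subject hemispheric connectome blocks
#'
#' The full generative route: per subject and hemisphere, latent per-parcel
#' gradient scores are the smooth templates plus half of the planted AI
#' signal with opposite signs on the two hemispheres (so left minus right
#' reproduces the planted AI), plus a shared symmetric subject deviation and
#' hemisphere-specific noise. Block connectivity is the loading-weighted
#' inner product of latent scores plus a baseline, squashed to (-1, 1) with
#' `tanh` and Fisher-z transformed — the two maps cancel, so the Fisher-z
#' blocks are exactly the latent low-rank form plus noise. Site batch
#' effects act on the Fisher-z values (scale then shift). Within-hemisphere
#' block diagonals are zeroed by the self-connection convention.
#'
#' @param cohort a `cohort`.
#' @param scheme a `parcellation` (must match the truth's pair count).
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @param subject_sd SD of the shared (symmetric) subject deviation of
#'   latent scores.
#' @param emit `"blocks"` returns `hemi_blocks` per subject;
#'   `"timeseries"` returns T x 2n parcel time series realising the same
#'   latent structure (to exercise the connectivity builder).
#' @param timepoints length of emitted time series.
#' @return named list (by subject id) of `hemi_blocks` or time-series
#'   matrices, with the `truth` attached as attribute `ground_truth`.
#' @export
simulate_connectomes <- function(cohort, scheme, truth, seed = 1L,
                                 subject_sd = 0.05,
                                 emit = c("blocks", "timeseries"),
                                 timepoints = 200L) {
  emit <- match.arg(emit)
  if (attr(scheme, "n_per_hemi") != truth$n_pairs)
    stop("parcellation and ground truth disagree on pair count",
         call. = FALSE)
  set.seed(seed)
  n_pairs <- truth$n_pairs
  k <- truth$k
  site_idx <- as.integer(factor(cohort$site))
  hemi_sd <- truth$ai_noise_sd / sqrt(2)
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$subject_id
  latent_ai <- matrix(NA_real_, nrow(cohort), n_pairs * k,
                      dimnames = list(cohort$subject_id,
                                      paste0("p", rep(seq_len(n_pairs), k),
                                             "_G", rep(seq_len(k),
                                                       each = n_pairs))))
  M <- ncol(truth$basis)
  for (s in seq_len(nrow(cohort))) {
    # planted AI effects, subject deviations and hemispheric noise act on
    # the analyzed leading harmonics; higher harmonics stay fixed and keep
    # the connectivity profiles local along the latent ring
    half <- matrix(0, n_pairs, M)
    half[, seq_len(k)] <-
      planted_ai_signal(truth, cohort$group[s], cohort$age[s]) / 2
    shared <- truth$basis
    shared[, seq_len(k)] <- shared[, seq_len(k)] +
      matrix(stats::rnorm(n_pairs * k, 0, subject_sd), n_pairs, k)
    XL <- shared + half
    XR <- shared - half
    XL[, seq_len(k)] <- XL[, seq_len(k)] +
      matrix(stats::rnorm(n_pairs * k, 0, hemi_sd), n_pairs, k)
    XR[, seq_len(k)] <- XR[, seq_len(k)] +
      matrix(stats::rnorm(n_pairs * k, 0, hemi_sd), n_pairs, k)
    latent_ai[s, ] <- as.vector(XL[, seq_len(k)] - XR[, seq_len(k)])
    if (emit == "timeseries") {
      U <- rbind(XL, XR)  # canonical order: left pairs then right pairs
      L <- matrix(stats::rnorm(timepoints * M), timepoints, M) %*%
        diag(sqrt(truth$basis_loadings), M)
      ts <- L %*% t(U) +
        matrix(stats::rnorm(timepoints * 2 * n_pairs, 0, 0.5),
               timepoints, 2 * n_pairs)
      out[[s]] <- ts
      next
    }
    W <- diag(truth$basis_loadings, M)
    noise_block <- function() {
      if (truth$fc_noise_sd == 0) return(0)
      E <- matrix(stats::rnorm(n_pairs^2, 0, truth$fc_noise_sd),
                  n_pairs, n_pairs)
      (E + t(E)) / 2
    }
    LL <- truth$fc_baseline + XL %*% W %*% t(XL) + noise_block()
    RR <- truth$fc_baseline + XR %*% W %*% t(XR) + noise_block()
    LRE <- if (truth$fc_noise_sd == 0) 0
           else matrix(stats::rnorm(n_pairs^2, 0, truth$fc_noise_sd),
                       n_pairs, n_pairs)
    LR <- truth$fc_baseline + XL %*% W %*% t(XR) + LRE
    # squash to (-1, 1) then Fisher-z: atanh(tanh(x)) = x, so the z-blocks
    # keep the latent low-rank form exactly
    sc <- truth$site_scale[site_idx[s]]
    sh <- truth$site_shift[site_idx[s]]
    adj <- function(B) sc * B + sh
    LL <- adj(LL); RR <- adj(RR); LR <- adj(LR)
    diag(LL) <- 0
    diag(RR) <- 0
    blocks <- structure(list(LL = LL, LR = LR, RL = t(LR), RR = RR),
                        class = "hemi_blocks")
    out[[s]] <- blocks
  }
  attr(out, "ground_truth") <- truth
  attr(out, "latent_ai") <- latent_ai
  out
}

#' Simulate a dictionary of term activation maps
#'
#' Smooth random z-activation maps over the parcels of one hemisphere; an
#' optional planted term is included verbatim so decoding self-match
#' behaviour can be tested.
#'
#' @param n_terms number of random terms.
#' @param n_parcels parcels per map.
#' @param planted optional per-parcel vector included as the first term
#'   (named `"planted"`).
#' @param seed integer seed.
#' @return matrix parcels x terms with term names as column names.
#' @export
simulate_term_maps <- function(n_terms = 24L, n_parcels = 180L,
                               planted = NULL, seed = 1L) {
  if (n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  set.seed(seed)
  base <- stats::poly(seq_len(n_parcels), degree = min(8L, n_parcels - 1L))
  maps <- vapply(seq_len(n_terms), function(j) {
    smooth <- base %*% stats::rnorm(ncol(base), 0, 1)
    z <- smooth / stats::sd(smooth) + stats::rnorm(n_parcels, 0, 0.5)
    as.numeric(z)
  }, numeric(n_parcels))
  colnames(maps) <- paste0("term_", seq_len(n_terms))
  if (!is.null(planted)) {
    stopifnot(length(planted) == n_parcels)
    maps <- cbind(planted = planted, maps)
  }
  maps
}

#' One-call synthetic study generator
#'
#' Builds parcellation, cohort, ground truth, AI features and trait scores
#' for a named study design: `"null"` (site effects only), `"group-effect"`
#' (planted group AI difference), `"interaction"` (group-specific age
#' slopes), `"trait"` (trait coupled to intra features only).
#'
#' @param preset study design.
#' @param n_per_group subjects per group.
#' @param n_sites number of sites.
#' @param seed master seed (sub-stages use fixed offsets).
#' @param scheme optional pre-built `parcellation` (default 180 pairs, 12
#'   networks).
#' @param ... overrides passed to [ground_truth()].
#' @return a `synthetic_ai` object with traits attached.
#' @export
simulate_study <- function(preset = c("group-effect", "null", "interaction",
                                      "trait"),
                           n_per_group = 70L, n_sites = 5L, seed = 1L,
                           scheme = NULL, ...) {
  preset <- match.arg(preset)
  if (is.null(scheme)) scheme <- make_parcellation(seed = seed)
  cohort <- simulate_cohort(n_per_group = n_per_group, n_sites = n_sites,
                            seed = seed + 1L)
  args <- list(scheme = scheme, n_sites = n_sites, seed = seed + 2L)
  preset_args <- switch(preset,
    "null" = list(group_effect_size = 0,
                  age_slope_by_group = list(NAI = 0, autism = 0),
                  n_trait_features = 0L),
    "group-effect" = list(age_slope_by_group = list(NAI = 0, autism = 0)),
    "interaction" = list(group_effect_size = 0),
    "trait" = list(group_effect_size = 0,
                   age_slope_by_group = list(NAI = 0, autism = 0)))
  truth <- do.call(ground_truth,
                   utils::modifyList(c(args, preset_args), list(...)))
  synth <- simulate_ai_features(cohort, truth, seed = seed + 3L)
  synth$scheme <- scheme
  synth$preset <- preset
  attach_trait_scores(synth, seed = seed + 4L)
}

#' @export
print.synthetic_ai <- function(x, ...) {
  cat(sprintf("synthetic AI cohort: %d subjects, %d pairs x %d gradients%s\n",
              nrow(x$cohort), x$truth$n_pairs, x$truth$k,
              if (is.null(x$preset)) "" else paste0(", preset '",
                                                   x$preset, "'")))
  invisible(x)
}
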