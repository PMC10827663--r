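#' Two-sample Hotelling T-squared test
#'
#' Multivariate generalisation of the two-sample pooled-variance t-test:
#' `T2 = n1 n2 / (n1 + n2) * d' S^-1 d` with `d` the mean-difference vector
#' and `S` the pooled covariance. The exact F transform
#' `F = T2 (n - p - 1) / ((n - 2) p)` on `(p, n - p - 1)` degrees of freedom
#' yields the p value. For `p = 1` this reduces to the square of the
#' two-sample t statistic.
#'
#' @param Xa,Xb numeric matrices (subjects x p), one per group.
#' @param ridge logical; on a singular pooled covariance, add
#'   `1e-6 * tr(S)/p` to the diagonal instead of failing.
#' @return list with `T2`, `F`, `df1`, `df2`, `p`, `direction` (sign of the
#'   mean difference per variable, Xa minus Xb) and `ridged`.
#' @export
hotelling_two_sample <- function(Xa, Xb, ridge = FALSE) {
  Xa <- as.matrix(Xa); Xb <- as.matrix(Xb)
  p <- ncol(Xa)
  if (ncol(Xb) != p) stop("groups have differing dimension", call. = FALSE)
  n1 <- nrow(Xa); n2 <- nrow(Xb); n <- n1 + n2
  if (n <= p + 1)
    stop("n1 + n2 must exceed p + 1", call. = FALSE)
  d <- colMeans(Xa) - colMeans(Xb)
  S <- ((n1 - 1) * stats::cov(Xa) + (n2 - 1) * stats::cov(Xb)) / (n - 2)
  ridged <- FALSE
  Sinv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Sinv)) {
    if (!ridge)
      stop("singular pooled covariance; retry with ridge = TRUE",
           call. = FALSE)
    S <- S + diag(1e-6 * sum(diag(S)) / p, p)
    Sinv <- solve(S)
    ridged <- TRUE
  }
  T2 <- as.numeric(n1 * n2 / n * crossprod(d, Sinv %*% d))
  Fstat <- T2 * (n - p - 1) / ((n - 2) * p)
  df1 <- p; df2 <- n - p - 1
  list(T2 = T2, F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       direction = sign(d), ridged = ridged)
}

#' Multivariate linear model term tests (Hotelling-Lawley trace)
#'
#' Fits a multivariate linear model `Y ~ <formula>` and tests each term
#' sequentially with the Hotelling-Lawley trace and its standard F
#' approximation. For a single two-level factor with no covariates the
#' last-term test is exactly the two-sample Hotelling T-squared test.
#'
#' @param Y numeric matrix, subjects x p responses.
#' @param design data.frame of predictors.
#' @param formula right-hand-side formula over `design` columns, e.g.
#'   `~ group * age_group`.
#' @return data.frame with one row per term: `term`, `df`, `HL` (trace),
#'   `F`, `df1`, `df2`, `p`.
#' @export
mglm_terms <- function(Y, design, formula = ~ group * age_group) {
  Y <- as.matrix(Y)
  mf <- stats::model.frame(formula, design)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(stats::as.formula(paste("Y ~",
                                           paste(deparse(formula[[2]]),
                                                 collapse = ""))),
                   data = design)
  av <- stats::anova(fit, test = "Hotelling-Lawley")
  av <- as.data.frame(av)
  keep <- !(rownames(av) %in% c("(Intercept)", "Residuals"))
  data.frame(term = rownames(av)[keep],
             df = av$Df[keep],
             HL = av[keep, "Hotelling-Lawley"],
             F = av[keep, "approx F"],
             df1 = av[keep, "num Df"],
             df2 = av[keep, "den Df"],
             p = av[keep, "Pr(>F)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Post-hoc per-gradient two-sample t-tests
#'
#' Pooled-variance t statistics per response column, with the sign convention
#' `mean(reference) - mean(other)`: when the reference level is the
#' comparison group (NAI) a positive t indicates lower leftward asymmetry in
#' the clinical group. Significance is assessed at `alpha / k`, correcting
#' for the `k` gradients considered.
#'
#' @param Y subjects x k matrix (one column per gradient).
#' @param group two-level factor.
#' @param reference level whose mean enters positively.
#' @param alpha nominal level before the /k correction.
#' @param k correction divisor (number of gradients).
#' @return data.frame with `column`, `t`, `df`, `p`, `significant`.
#' @export
posthoc_t <- function(Y, group, reference = "NAI", alpha = 0.05, k = 3L) {
  Y <- as.matrix(Y)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("group must have exactly two levels", call. = FALSE)
  if (!reference %in% levels(group))
    stop("reference level not found in group", call. = FALSE)
  other <- setdiff(levels(group), reference)
  a <- Y[group == reference, , drop = FALSE]
  b <- Y[group == other, , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  sp2 <- ((n1 - 1) * apply(a, 2, stats::var) +
          (n2 - 1) * apply(b, 2, stats::var)) / (n1 + n2 - 2)
  t <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  data.frame(column = colnames(Y) %||% paste0("G", seq_len(ncol(Y))),
             t = t, df = df, p = p,
             significant = p < alpha / k,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiple-testing adjustment with significance flags
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni over the supplied family.
#'
#' @param p vector of p values in \[0, 1\].
#' @param method `"bh_fdr"` or `"bonferroni"`.
#' @param level FDR level q, or family-wise alpha.
#' @return data.frame with `p`, `p_adjusted`, `significant`.
#' @export
p_adjust_flags <- function(p, method = c("bh_fdr", "bonferroni"),
                           level = 0.05) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p, method = switch(method, bh_fdr = "BH",
                                            bonferroni = "bonferroni"))
  data.frame(p = p, p_adjusted = adj, significant = adj <= level)
}

#' Parcel- and network-wise asymmetry statistics
#'
#' Runs the full inference workflow on harmonized AI features for one
#' contrast and both asymmetry patterns: parcel-wise multivariate tests
#' (FDR over homolog pairs), gatekept post-hoc per-gradient tests at
#' `alpha / k`, and the same at the network level (FDR over networks).
#' Contrasts: `"group"` (two-sample Hotelling, autism vs NAI),
#' `"interaction"` (group x age_group term of the multivariate GLM) and
#' `"age"` (within-group pairwise age-group comparisons, Bonferroni over the
#' three age-group pairs).
#'
#' @param features named list with elements `intra` and `inter`, each a
#'   subjects x (pairs * gradients) matrix as from [ai_feature_matrix()],
#'   already harmonized.
#' @param cohort `cohort` data.frame aligned with the feature rows.
#' @param scheme a `parcellation`.
#' @param config a [grad_config()].
#' @param contrast which effect to test.
#' @return a `grad_stats` object: list of data.frames `parcel` and
#'   `network`, plus the contrast and config echo.
#' @export
group_pipeline <- function(features, cohort, scheme,
                           config = grad_config(),
                           contrast = c("group", "interaction", "age")) {
  contrast <- match.arg(contrast)
  ka <- config$n_gradients_analyzed
  nets <- pair_networks(scheme)
  parcel_tabs <- list()
  network_tabs <- list()

  for (pattern in names(features)) {
    X <- as.matrix(features[[pattern]])
    P <- ncol(X) / ka
    stopifnot(P == round(P))
    get_pair <- function(i)
      X[, i + P * (seq_len(ka) - 1L), drop = FALSE]

    net_feats <- network_features(X, nets, ka)

    if (contrast %in% c("group", "interaction")) {
      parcel_tabs[[pattern]] <-
        unit_table(seq_len(P), get_pair, cohort, config, contrast,
                   pattern, unit_kind = "pair",
                   unit_label = as.character(seq_len(P)))
      network_tabs[[pattern]] <-
        unit_table(seq_along(net_feats$units),
                   function(i) net_feats$get(i), cohort, config, contrast,
                   pattern, unit_kind = "network",
                   unit_label = net_feats$units)
    } else {
      parcel_tabs[[pattern]] <-
        age_table(seq_len(P), get_pair, cohort, config, pattern,
                  unit_kind = "pair", unit_label = as.character(seq_len(P)))
      network_tabs[[pattern]] <-
        age_table(seq_along(net_feats$units), function(i) net_feats$get(i),
                  cohort, config, pattern, unit_kind = "network",
                  unit_label = net_feats$units)
    }
  }

  structure(list(parcel = do.call(rbind, parcel_tabs),
                 network = do.call(rbind, network_tabs),
                 contrast = contrast, config = config),
            class = "grad_stats")
}

#' @export
print.grad_stats <- function(x, ...) {
  cat(sprintf("asymmetry statistics, contrast = %s\n", x$contrast))
  sig <- x$parcel[x$parcel$significant, , drop = FALSE]
  cat(sprintf("  parcel-wise: %d/%d units significant (FDR q = %g)\n",
              nrow(sig), nrow(x$parcel), x$config$fdr_q))
  nsig <- x$network[x$network$significant, , drop = FALSE]
  cat(sprintf("  network-wise: %d/%d units significant\n",
              nrow(nsig), nrow(x$network)))
  invisible(x)
}

# network-mean features: average member pairs per gradient
network_features <- function(X, nets, ka) {
  P <- ncol(X) / ka
  units <- NETWORK_LABELS[NETWORK_LABELS %in% nets]
  mats <- lapply(units, function(nw) {
    rows <- which(nets == nw)
    vapply(seq_len(ka), function(g)
      rowMeans(X[, rows + P * (g - 1L), drop = FALSE]), numeric(nrow(X)))
  })
  list(units = units, get = function(i) mats[[i]])
}

# one row per unit: multivariate stat + gatekept post-hoc per-gradient t
unit_table <- function(idx, get_unit, cohort, config, contrast, pattern,
                       unit_kind, unit_label) {
  ka <- config$n_gradients_analyzed
  rows <- lapply(idx, function(i) {
    Y <- get_unit(i)
    colnames(Y) <- paste0("G", seq_len(ka))
    if (contrast == "group") {
      ht <- hotelling_two_sample(Y[cohort$group == "autism", , drop = FALSE],
                                 Y[cohort$group == "NAI", , drop = FALSE],
                                 ridge = TRUE)
      mv <- data.frame(T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
                       p = ht$p)
    } else {
      tt <- mglm_terms(Y, cohort, ~ group * age_group)
      it <- tt[tt$term == "group:age_group", ]
      mv <- data.frame(T2 = it$HL * it$df2, F = it$F, df1 = it$df1,
                       df2 = it$df2, p = it$p)
    }
    ph <- if (contrast == "group") {
      posthoc_t(Y, cohort$group, reference = "NAI",
                k = config$posthoc_bonferroni_k)
    } else {
      posthoc_interaction_f(Y, cohort, k = config$posthoc_bonferroni_k)
    }
    out <- data.frame(pattern = pattern, unit_kind = unit_kind,
                      unit = unit_label[i], mv,
                      stringsAsFactors = FALSE)
    for (g in seq_len(ka)) {
      out[[paste0("t_G", g)]] <- ph$t[g]
      out[[paste0("p_G", g)]] <- ph$p[g]
    }
    out
  })
  tab <- do.call(rbind, rows)
  adj <- p_adjust_flags(tab$p, "bh_fdr", config$fdr_q)
  tab$p_fdr <- adj$p_adjusted
  tab$significant <- adj$significant
  # gatekeeping: post-hoc flags only for units passing the multivariate gate
  for (g in seq_len(ka)) {
    tab[[paste0("sig_G", g)]] <- tab$significant &
      tab[[paste0("p_G", g)]] < 0.05 / config$posthoc_bonferroni_k
  }
  rownames(tab) <- NULL
  tab
}

# univariate interaction test per gradient (F of the group:age_group term);
# a signed t is also provided from the group contrast of age slopes
posthoc_interaction_f <- function(Y, cohort, alpha = 0.05, k = 3L) {
  res <- lapply(seq_len(ncol(Y)), function(g) {
    fit <- stats::lm(Y[, g] ~ group * age_group, data = cohort)
    av <- stats::anova(fit)
    i <- which(rownames(av) == "group:age_group")
    # signed summary: difference in (adult - child) change between groups
    mns <- tapply(Y[, g], list(cohort$group, cohort$age_group), mean)
    slope_diff <- (mns["NAI", "adult"] - mns["NAI", "child"]) -
      (mns["autism", "adult"] - mns["autism", "child"])
    data.frame(t = sign(slope_diff) * sqrt(av$`F value`[i]),
               F = av$`F value`[i], p = av$`Pr(>F)`[i])
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha / k
  out
}

# within-group pairwise age-group Hotelling contrasts, Bonferroni over the
# three age-group pairs
age_table <- function(idx, get_unit, cohort, config, pattern,
                      unit_kind, unit_label) {
  ka <- config$n_gradients_analyzed
  combos <- utils::combn(c("child", "adolescent", "adult"), 2)
  rows <- list()
  for (grp in c("autism", "NAI")) {
    sub <- cohort$group == grp
    for (jc in seq_len(ncol(combos))) {
      a_lv <- combos[1, jc]; b_lv <- combos[2, jc]
      for (i in idx) {
        Y <- get_unit(i)
        colnames(Y) <- paste0("G", seq_len(ka))
        ia <- sub & cohort$age_group == a_lv
        ib <- sub & cohort$age_group == b_lv
        ht <- hotelling_two_sample(Y[ia, , drop = FALSE],
                                   Y[ib, , drop = FALSE], ridge = TRUE)
        lab <- factor(c(rep(a_lv, sum(ia)), rep(b_lv, sum(ib))),
                      levels = c(a_lv, b_lv))
        ph <- posthoc_t(rbind(Y[ia, , drop = FALSE], Y[ib, , drop = FALSE]),
                        lab, reference = a_lv,
                        k = config$posthoc_bonferroni_k)
        out <- data.frame(pattern = pattern, unit_kind = unit_kind,
                          unit = unit_label[i], group = grp,
                          contrast = paste(a_lv, "vs", b_lv),
                          T2 = ht$T2, F = ht$F, df1 = ht$df1, df2 = ht$df2,
                          p = ht$p, stringsAsFactors = FALSE)
        for (g in seq_len(ka)) {
          out[[paste0("t_G", g)]] <- ph$t[g]
          out[[paste0("p_G", g)]] <- ph$p[g]
        }
        rows[[length(rows) + 1L]] <- out
      }
    }
  }
  tab <- do.call(rbind, rows)
  # the three age-group pairs form the correction family
  tab$significant <- tab$p < 0.05 / 3
  for (g in seq_len(ka)) {
    tab[[paste0("sig_G", g)]] <- tab$significant &
      tab[[paste0("p_G", g)]] < 0.05 / config$posthoc_bonferroni_k
  }
  rownames(tab) <- NULL
  tab
}
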