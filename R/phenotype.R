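#' Load and validate a phenotype table
#'
#' Reads subject phenotypes (diagnosis group, age, site, optionally full-scale
#' IQ, mean framewise displacement and ADOS scores), assigns age groups from
#' the configured boundaries, and flags — without dropping — subjects that hit
#' an exclusion rule (age above the maximum, FIQ below the minimum, mean FD
#' above the motion threshold). Downstream stages subset on `!excluded`.
#'
#' @param path CSV or TSV file with a header; required columns `subject_id`,
#'   `group`, `age`, `site`. Optional: `fiq`, `mean_fd`, `ados_total`,
#'   `ados_comm`, `ados_social`, `ados_rrb`.
#' @param config a [grad_config()] with the exclusion rules and age-group
#'   boundaries.
#' @return a `cohort` data.frame with added columns `age_group`,
#'   `excluded` (logical) and `exclusion_reason` (comma-separated tags).
#' @export
load_phenotype <- function(path, config = grad_config()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  as_cohort(df, config)
}

#' @rdname load_phenotype
#' @param df a phenotype data.frame.
#' @export
as_cohort <- function(df, config = grad_config()) {
  required <- c("subject_id", "group", "age", "site")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("phenotype table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  if (!all(df$group %in% c("autism", "NAI")))
    stop("group must be 'autism' or 'NAI'", call. = FALSE)
  for (opt in c("fiq", "mean_fd", "ados_total", "ados_comm",
                "ados_social", "ados_rrb")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
    df[[opt]] <- as.numeric(df[[opt]])
  }
  if (any(df$mean_fd < 0, na.rm = TRUE))
    stop("mean_fd must be non-negative", call. = FALSE)

  df$age <- as.numeric(df$age)
  df$age_group <- assign_age_group(df$age, config$age_group_boundaries)

  reasons <- character(nrow(df))
  add_reason <- function(reasons, hit, tag) {
    hit <- which(!is.na(hit) & hit)
    reasons[hit] <- ifelse(nzchar(reasons[hit]),
                           paste(reasons[hit], tag, sep = ","), tag)
    reasons
  }
  reasons <- add_reason(reasons, df$age > config$age_max, "age")
  reasons <- add_reason(reasons, df$fiq < config$fiq_min, "fiq")
  reasons <- add_reason(reasons, df$mean_fd > config$fd_threshold_mm, "motion")
  df$excluded <- nzchar(reasons)
  df$exclusion_reason <- reasons

  class(df) <- c("cohort", "data.frame")
  df
}

#' Assign age groups from configured boundaries
#'
#' Intervals are half-open on the left: with boundaries `c(5, 12, 18, 40)`
#' a 12-year-old is an adolescent and an 18-year-old an adult; the upper
#' boundary is inclusive. Ages outside `[lo, hi]` get `NA`.
#'
#' @param age numeric vector of ages in years.
#' @param boundaries numeric `c(lo, b1, b2, hi)`.
#' @return factor with levels `child`, `adolescent`, `adult`.
#' @export
assign_age_group <- function(age, boundaries = c(5, 12, 18, 40)) {
  stopifnot(length(boundaries) == 4L)
  grp <- cut(age, breaks = boundaries,
             labels = c("child", "adolescent", "adult"),
             right = FALSE, include.lowest = FALSE)
  # upper bound inclusive: age == hi belongs to the adult group
  grp[!is.na(age) & age == boundaries[4]] <- "adult"
  grp
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects (%d excluded), %d sites\n",
              nrow(x), sum(x$excluded), length(unique(x$site))))
  print(table(group = x$group, age_group = x$age_group))
  invisible(x)
}

#' Write a cohort phenotype table to CSV
#' @param cohort a `cohort` data.frame.
#' @param path output file.
#' @export
write_phenotype <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
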