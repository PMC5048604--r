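#' Fit a euploid reference panel
#'
#' The central model object of the pipeline. Given per-sample chromosome
#' profiles of euploid reference samples, this
#' \enumerate{
#'   \item stores the cross-sample normalization vector `S[j] = sum_i
#'     rf[i, j]` (per-chromosome column sums of the reads fractions) and
#'     the normalized fractions `rf_norm[i, j] = rf[i, j] / S[j]`;
#'   \item for each target chromosome fits the ordinary least-squares
#'     regression `rf_norm = alpha + beta * gc + e` of normalized reads
#'     fraction on per-chromosome GC content across panel samples, and
#'     retains the residuals, their mean and their sample standard
#'     deviation (the reference distribution for z-scoring).
#' }
#' Test samples are later normalized with the *stored* `S`, so a single
#' test sample can be scored against the panel.
#'
#' @param profiles A `profile_set` (see [bind_profiles()]) or list of
#'   `chrom_profile`s of reference samples.
#' @param chromosomes Integer target chromosomes to fit; default
#'   `c(13, 18, 21)`.
#' @return An object of class `nipt_panel` with elements `sample_id`,
#'   `rf`, `rf_norm`, `gc` (matrices, samples x 22), `S` (length-22
#'   normalization sums), `chromosomes`, `n`, and `fits` — one entry per
#'   target chromosome with `alpha`, `beta`, `resid_mean`, `resid_sd`,
#'   `residuals`, `n`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_euploid = 60, n_bins = 800,
#'                                      depth = 3e5, seed = 1))
#' panel <- nipt_panel(profile_cohort(cohort$counts, cohort$bins))
#' panel
#' @export
nipt_panel <- function(profiles, chromosomes = c(13L, 18L, 21L)) {
  ps <- bind_profiles(profiles)
  n <- n_samples(ps)
  if (n < 2L) stop("a reference panel needs at least 2 samples")
  chromosomes <- sort(unique(as.integer(chromosomes)))
  if (any(!chromosomes %in% 1:22))
    stop("target chromosomes must be autosomes 1-22")
  ## chromosomes may be empty: normalization and CVs without regressions
  S <- colSums(ps$rf)
  if (any(S <= 0)) stop("zero normalization sum on chromosome ",
                        which(S <= 0)[1L])
  rf_norm <- sweep(ps$rf, 2L, S, "/")
  obj <- structure(list(sample_id = ps$sample_id, rf = ps$rf,
                        rf_norm = rf_norm, gc = ps$gc, S = S,
                        chromosomes = chromosomes, n = n, fits = NULL),
                   class = "nipt_panel")
  obj$fits <- if (length(chromosomes))
    lapply(stats::setNames(chromosomes, paste0("chr", chromosomes)),
           function(ch) ols_fit(obj, ch))
  else list()
  obj
}

## Closed-form OLS of normalized rf on gc for one chromosome over a subset
## of panel members. Kept as the single scoring code path so that a refit
## on the full membership is bit-identical to the full-panel fit.
ols_fit <- function(panel, chrom, members = NULL) {
  if (is.null(members)) members <- seq_len(panel$n)
  x <- panel$gc[members, chrom]
  y <- panel$rf_norm[members, chrom]
  n <- length(x)
  if (n < 3L) stop("need at least 3 panel samples to fit chromosome ", chrom)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0)
    stop("degenerate GC values on chromosome ", chrom,
         ": regression is unidentifiable")
  beta <- sum((x - mx) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mx
  res <- y - (alpha + beta * x)
  list(chrom = as.integer(chrom), alpha = unname(alpha), beta = unname(beta),
       residuals = stats::setNames(res, panel$sample_id[members]),
       resid_mean = mean(res), resid_sd = stats::sd(res),
       scale = mean(abs(y)), n = n)
}

#' Predicted reads fraction at a given GC content
#'
#' Evaluates the panel's fitted line `alpha + beta * gc` for a target
#' chromosome. This fitted value — not the observed reads fraction — is
#' used as the centre of the adaptive reads-fraction window, so that a
#' trisomic test sample's inflated fraction cannot bias the reference
#' selection towards high-fraction samples.
#'
#' @param panel A fitted `nipt_panel`.
#' @param chrom Target chromosome (must be among `panel$chromosomes`).
#' @param gc GC content value(s).
#' @return Predicted normalized reads fraction(s).
#' @export
predicted_rf <- function(panel, chrom, gc) {
  fit <- panel_fit(panel, chrom)
  fit$alpha + fit$beta * gc
}

panel_fit <- function(panel, chrom) {
  stopifnot(inherits(panel, "nipt_panel"))
  fit <- panel$fits[[paste0("chr", as.integer(chrom))]]
  if (is.null(fit))
    stop("chromosome ", chrom, " was not fitted in this panel")
  fit
}

## Normalize a test profile onto the panel's scale using the stored S.
normalize_test <- function(panel, profile) {
  if (inherits(profile, "profile_set")) {
    if (n_samples(profile) != 1L)
      stop("expected a single test profile")
    list(sample_id = profile$sample_id, rf_norm = profile$rf[1L, ] / panel$S,
         gc = profile$gc[1L, ])
  } else {
    list(sample_id = attr(profile, "sample_id"),
         rf_norm = profile$rf / panel$S, gc = profile$gc)
  }
}

#' Coefficient of variation of a chromosome's reads fraction over a panel
#'
#' `sd / mean` (sample standard deviation, n - 1 denominator) of the
#' normalized reads fraction of `chrom` across the selected panel members.
#' This is the quality measure used to compare candidate reference sets:
#' a lower CV means tighter genomic representation of the chromosome and
#' hence higher detection sensitivity.
#'
#' @param panel A fitted `nipt_panel`.
#' @param chrom Autosome 1-22.
#' @param members Optional sample indices or ids; default all.
#' @return The coefficient of variation (non-negative scalar).
#' @export
panel_cv <- function(panel, chrom, members = NULL) {
  stopifnot(inherits(panel, "nipt_panel"))
  if (is.null(members)) members <- seq_len(panel$n)
  if (is.character(members)) members <- match(members, panel$sample_id)
  v <- panel$rf_norm[members, as.integer(chrom)]
  if (length(v) < 2L) stop("CV needs at least 2 panel members")
  m <- mean(v)
  if (m <= 0) stop("non-positive mean reads fraction on chromosome ", chrom)
  stats::sd(v) / m
}

#' Residual z-score of a test sample against a reference panel
#'
#' The test sample is normalized with the panel's stored column sums, its
#' residual `R = rf_norm - (alpha + beta * gc)` is computed against the
#' panel regression for the target chromosome, and standardized by the
#' panel residuals: `z = (R - resid_mean) / resid_sd`. When `members` is
#' supplied the regression is refitted on that panel subset only — the
#' selected subset *is* the reference distribution for adaptive scoring.
#'
#' @param panel A fitted `nipt_panel`.
#' @param test A `chrom_profile` (or single-sample `profile_set`) of the
#'   test sample, on the raw (un-normalized) reads-fraction scale.
#' @param chrom Target chromosome.
#' @param members Optional panel subset (indices or sample ids) on which
#'   to refit the regression before scoring.
#' @return The z-score (scalar).
#' @export
z_score <- function(panel, test, chrom, members = NULL) {
  fit <- if (is.null(members)) panel_fit(panel, chrom)
         else ols_fit(panel, as.integer(chrom),
                      members = resolve_members(panel, members))
  tn <- normalize_test(panel, test)
  if (fit$resid_sd <= 1e-10 * fit$scale)
    stop("degenerate panel: residual standard deviation is 0 on chromosome ",
         chrom)
  r <- tn$rf_norm[as.integer(chrom)] -
    (fit$alpha + fit$beta * tn$gc[as.integer(chrom)])
  unname((r - fit$resid_mean) / fit$resid_sd)
}

resolve_members <- function(panel, members) {
  if (is.character(members)) {
    idx <- match(members, panel$sample_id)
    if (anyNA(idx)) stop("unknown panel sample id: ",
                         members[which(is.na(idx))[1L]])
    idx
  } else as.integer(members)
}

#' Flag outlying samples in a cohort of profiles
#'
#' Robust per-chromosome screen applied before panel construction: for
#' every autosome, each sample's normalized reads fraction is converted to
#' a robust z-score `(x - median) / (1.4826 * MAD)`; samples exceeding
#' `threshold` in absolute value on *any* autosome are flagged. The
#' criterion is this package's own (configurable) convention for
#' reproducing an outlier-exclusion step whose exact rule is a matter of
#' laboratory policy. Chromosomes with zero MAD are skipped with a
#' warning.
#'
#' @param profiles A `profile_set` (or list of `chrom_profile`s) of at
#'   least 10 samples.
#' @param threshold Robust z threshold; default 3.
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(profiles, threshold = 3) {
  ps <- bind_profiles(profiles)
  n <- n_samples(ps)
  if (n < 10L) stop("outlier flagging needs at least 10 samples")
  rf_norm <- sweep(ps$rf, 2L, colSums(ps$rf), "/")
  flagged <- rep(FALSE, n)
  for (j in 1:22) {
    v <- rf_norm[, j]
    s <- stats::mad(v)
    if (s == 0) {
      warning("zero MAD on chromosome ", j, "; skipped in outlier screen")
      next
    }
    flagged <- flagged | abs(v - stats::median(v)) / s > threshold
  }
  ps$sample_id[flagged]
}

#' @export
print.nipt_panel <- function(x, ...) {
  cat("Euploid reference panel:", x$n, "samples\n")
  cat("Target chromosomes:", paste(x$chromosomes, collapse = ", "), "\n")
  tab <- summary(x)$fits
  print(tab, digits = 4)
  invisible(x)
}

#' Summarize a fitted reference panel
#'
#' @param object A `nipt_panel`.
#' @param ... Unused.
#' @return A `summary.nipt_panel` list with the per-chromosome regression
#'   table (`alpha`, `beta`, `resid_sd`, `cv`, `n`) and GC range.
#' @export
summary.nipt_panel <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(chrom = f$chrom, alpha = f$alpha, beta = f$beta,
               resid_sd = f$resid_sd,
               cv = panel_cv(object, f$chrom), n = f$n)))
  rownames(tab) <- NULL
  out <- list(n = object$n, fits = tab,
              gc_range = range(object$gc[, object$chromosomes]))
  class(out) <- "summary.nipt_panel"
  out
}

#' @export
print.summary.nipt_panel <- function(x, ...) {
  cat("Reference panel of", x$n, "euploid samples\n")
  cat(sprintf("Target-chromosome GC content range: %.3f - %.3f\n",
              x$gc_range[1L], x$gc_range[2L]))
  cat("Per-chromosome regression of normalized reads fraction on GC:\n")
  print(x$fits, digits = 4)
  invisible(x)
}

#' @export
coef.nipt_panel <- function(object, ...) {
  m <- t(vapply(object$fits, function(f) c(alpha = f$alpha, beta = f$beta),
                numeric(2L)))
  m
}

#' @export
residuals.nipt_panel <- function(object, ...) {
  sapply(object$fits, function(f) f$residuals)
}

#' Plot a panel's reads fraction against GC content
#'
#' Scatter of normalized reads fraction versus per-chromosome GC content
#' over the panel samples for one target chromosome, with the fitted
#' regression line.
#'
#' @param x A `nipt_panel`.
#' @param chrom Target chromosome; default the first fitted one.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nipt_panel <- function(x, chrom = x$chromosomes[1L], ...) {
  fit <- panel_fit(x, chrom)
  graphics::plot(x$gc[, chrom], x$rf_norm[, chrom],
                 xlab = sprintf("GC content (chr%d)", chrom),
                 ylab = "Normalized reads fraction",
                 main = sprintf("Reference panel, chr%d (n = %d)",
                                chrom, x$n), ...)
  graphics::abline(fit$alpha, fit$beta, col = "red3", lwd = 2)
  invisible(x)
}
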