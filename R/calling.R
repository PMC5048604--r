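#' Z-score threshold scheme for aneuploidy classification
#'
#' Two schemes are supported. `single`: z above `z_positive` (default 3,
#' the one-tailed 99.9th percentile of a standard normal) is positive,
#' anything else negative. `dual`: z below `z_negative` (default 2) is
#' negative, above `z_positive` (default 4) positive, and the band in
#' between a gray zone flagged for confirmatory follow-up. All
#' inequalities are strict, so a z exactly on a cutoff resolves to the
#' less severe category.
#'
#' @param mode `"single"` or `"dual"`.
#' @param z_positive Positive cutoff; defaults 3 (single) / 4 (dual).
#' @param z_negative Negative cutoff (dual only); default 2.
#' @return A `threshold_scheme` list.
#' @export
threshold_scheme <- function(mode = c("single", "dual"), z_positive = NULL,
                             z_negative = NULL) {
  mode <- match.arg(mode)
  if (is.null(z_positive)) z_positive <- if (mode == "single") 3 else 4
  if (mode == "single") {
    scheme <- list(mode = mode, z_positive = z_positive)
  } else {
    if (is.null(z_negative)) z_negative <- 2
    if (!(z_negative < z_positive))
      stop("dual scheme needs z_negative < z_positive")
    scheme <- list(mode = mode, z_positive = z_positive,
                   z_negative = z_negative)
  }
  structure(scheme, class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  if (x$mode == "single") {
    cat(sprintf("Single cutoff: positive if z > %g\n", x$z_positive))
  } else {
    cat(sprintf(
      "Dual cutoff: negative if z < %g, positive if z > %g, else gray zone\n",
      x$z_negative, x$z_positive))
  }
  invisible(x)
}

#' Classify z-scores under a threshold scheme
#'
#' @param z Numeric vector of finite z-scores.
#' @param scheme A [threshold_scheme()]; default the single z > 3 rule.
#' @return Character vector in `{"negative", "gray_zone", "positive"}`.
#' @export
classify <- function(z, scheme = threshold_scheme()) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  if (any(!is.finite(z))) stop("z scores must be finite for classification")
  if (scheme$mode == "single") {
    ifelse(z > scheme$z_positive, "positive", "negative")
  } else {
    ifelse(z < scheme$z_negative, "negative",
           ifelse(z > scheme$z_positive, "positive", "gray_zone"))
  }
}

#' Score test samples against a fitted reference panel
#'
#' For every test sample and target chromosome: select the adaptive
#' reference window ([expand_and_choose()]), refit the reads-fraction /
#' GC regression on the selected members only, compute the residual
#' z-score, and classify it. With `adaptive = FALSE` (or infinite window
#' maxima) every window is the full panel and the baseline method is
#' recovered exactly.
#'
#' @param object A fitted `nipt_panel`.
#' @param newdata A `profile_set`, list of `chrom_profile`s, or single
#'   `chrom_profile` of test samples (raw reads-fraction scale).
#' @param chromosomes Target chromosomes; default those fitted in the
#'   panel.
#' @param adaptive Use adaptive window selection (default `TRUE`).
#' @param params [selection_params()] controlling the window grid.
#' @param scheme [threshold_scheme()] for classification.
#' @param ... Unused.
#' @return An `aneuploidy_calls` data frame: `sample_id`, `chrom`, `z`,
#'   `panel_size`, `panel_cv`, `classification`.
#' @export
predict.nipt_panel <- function(object, newdata,
                               chromosomes = object$chromosomes,
                               adaptive = TRUE,
                               params = selection_params(),
                               scheme = threshold_scheme(), ...) {
  ps <- bind_profiles(newdata)
  chromosomes <- as.integer(chromosomes)
  if (adaptive && is.finite(params$gc_max) &&
      object$n < 3L * params$min_panel)
    warning("reference panel (n = ", object$n, ") is small relative to ",
            "min_panel = ", params$min_panel, ": CV-minimizing window ",
            "selection can understate the residual spread and inflate |z|; ",
            "consider a larger panel or adaptive = FALSE", call. = FALSE)
  rows <- vector("list", n_samples(ps) * length(chromosomes))
  k <- 0L
  for (i in seq_len(n_samples(ps))) {
    test <- ps[i]
    for (ch in chromosomes) {
      if (adaptive) {
        sel <- expand_and_choose(object, test, ch, params)
        members <- sel$members
      } else {
        members <- seq_len(object$n)
      }
      z <- z_score(object, test, ch, members = members)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = ps$sample_id[i], chrom = ch, z = z,
        panel_size = length(members),
        panel_cv = panel_cv(object, ch, members),
        classification = classify(z, scheme),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (k > 0L) do.call(rbind, rows) else empty_calls()
  rownames(calls) <- NULL
  class(calls) <- c("aneuploidy_calls", "data.frame")
  calls
}

empty_calls <- function() {
  data.frame(sample_id = character(0L), chrom = integer(0L),
             z = numeric(0L), panel_size = integer(0L),
             panel_cv = numeric(0L), classification = character(0L),
             stringsAsFactors = FALSE)
}

#' Run the full aneuploidy-screening pipeline
#'
#' End-to-end orchestration: read inputs (paths or in-memory objects),
#' restrict the panel to reference-eligible samples from the manifest,
#' GC-correct and profile every sample, fit the reference panel, score
#' each test sample with adaptive reference selection, and classify.
#' Each stage logs its input/output sizes via [message()].
#'
#' @param bins Bin table ([read_bins()]) or path to a bin file.
#' @param panel_counts Reference counts: a bins-by-samples matrix with
#'   sample-id column names, a list of `binned_counts`, or a directory of
#'   count TSVs.
#' @param test_counts Test counts, same forms as `panel_counts`; may be
#'   empty (`NULL` or empty list) in which case only the panel is fitted.
#' @param manifest Manifest data frame or path ([read_manifest()]).
#'   Samples absent from the manifest are assumed euploid singletons.
#' @param chromosomes Target chromosomes; default `c(13, 18, 21)`.
#' @param adaptive Use adaptive selection; default `TRUE`.
#' @param params [selection_params()].
#' @param scheme [threshold_scheme()].
#' @param span,min_usable_bins,clamp_floor GC-correction settings, see
#'   [gc_correct()].
#' @param report Optional output path for [write_report()].
#' @return A list of class `nipt_result` with `calls`
#'   (`aneuploidy_calls`), `panel` (the fitted `nipt_panel`) and
#'   `panel_summary`.
#' @export
run_pipeline <- function(bins, panel_counts, test_counts = NULL,
                         manifest = NULL, chromosomes = c(13L, 18L, 21L),
                         adaptive = TRUE, params = selection_params(),
                         scheme = threshold_scheme(), span = 0.3,
                         min_usable_bins = 100, clamp_floor = 0.01,
                         report = NULL) {
  if (is.character(bins)) bins <- read_bins(bins)
  panel_counts <- load_counts(panel_counts, bins)
  test_counts <- load_counts(test_counts, bins)
  if (is.character(manifest)) manifest <- read_manifest(manifest)

  panel_ids <- colnames(panel_counts)
  if (!is.null(manifest)) {
    eligible <- filter_reference_eligible(manifest)
    keep <- panel_ids %in% eligible | !panel_ids %in% manifest$sample_id
    message("stage=eligibility n_in=", length(panel_ids),
            " n_out=", sum(keep))
    panel_counts <- panel_counts[, keep, drop = FALSE]
  }
  if (ncol(panel_counts) < 3L)
    stop("fewer than 3 reference-eligible panel samples")

  message("stage=gc_correction n_panel=", ncol(panel_counts),
          " n_test=", ncol(test_counts))
  panel_profiles <- profile_cohort(panel_counts, bins, span = span,
                                   min_usable_bins = min_usable_bins,
                                   clamp_floor = clamp_floor)
  panel <- nipt_panel(panel_profiles, chromosomes = chromosomes)
  message("stage=panel_fit n=", panel$n,
          " chromosomes=", paste(chromosomes, collapse = ","))

  if (ncol(test_counts) > 0L) {
    test_profiles <- profile_cohort(test_counts, bins, span = span,
                                    min_usable_bins = min_usable_bins,
                                    clamp_floor = clamp_floor)
    calls <- predict(panel, test_profiles, chromosomes = chromosomes,
                     adaptive = adaptive, params = params, scheme = scheme)
  } else {
    calls <- empty_calls()
    class(calls) <- c("aneuploidy_calls", "data.frame")
  }
  message("stage=calling n_tests=", ncol(test_counts),
          " n_calls=", nrow(calls),
          " n_positive=", sum(calls$classification == "positive"))
  if (!is.null(report)) write_report(calls, report)
  structure(list(calls = calls, panel = panel,
                 panel_summary = summary(panel)),
            class = "nipt_result")
}

#' @export
print.nipt_result <- function(x, ...) {
  print(x$panel_summary)
  cat("\n", nrow(x$calls), " call(s); ",
      sum(x$calls$classification == "positive"), " positive\n", sep = "")
  invisible(x)
}

## Coerce the accepted count-input forms to a bins x samples matrix.
load_counts <- function(x, bins) {
  if (is.null(x))
    return(matrix(numeric(0L), nrow = nrow(bins), ncol = 0L))
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.(tsv|txt|counts)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no count files found in ", x)
    x <- lapply(files, read_counts, bins = bins)
  }
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) == 0L)
      return(matrix(numeric(0L), nrow = nrow(bins), ncol = 0L))
    m <- vapply(x, function(bc) {
      if (!inherits(bc, "binned_counts"))
        stop("count lists must contain binned_counts objects")
      bc$counts
    }, numeric(nrow(bins)))
    colnames(m) <- vapply(x, `[[`, character(1L), "sample_id")
    return(m)
  }
  m <- as.matrix(x)
  if (nrow(m) != nrow(bins))
    stop("count matrix rows (", nrow(m), ") do not match bins (",
         nrow(bins), ")")
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}
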