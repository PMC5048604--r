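#' GC-bias correction of binned counts by locally weighted regression
#'
#' Fits a LOESS-type local linear smooth (via [stats::lowess()]) of bin
#' count against bin GC fraction across the usable bins of one sample, and
#' rescales each usable bin multiplicatively so that the expected count is
#' flat in GC: `corrected_b = count_b * M / L(gc_b)`, where `L` is the
#' smoothed count at the bin's GC and `M` the mean usable-bin count.
#' Unusable bins are set to 0. The smoother's prediction is clamped below
#' at `clamp_floor * M` so that near-empty GC extremes cannot blow up the
#' correction factor.
#'
#' If the usable bins have essentially no GC spread the correction is
#' refused: counts are passed through unchanged (unusable bins still
#' zeroed) with a warning, since the smooth would be unidentifiable.
#'
#' @param counts A `binned_counts` object or a numeric count vector
#'   aligned to `bins`.
#' @param bins Bin table from [read_bins()].
#' @param span Smoother span in (0, 1] (fraction of bins in each local
#'   window). Default 0.3.
#' @param min_usable_bins Minimum number of usable, non-zero bins required
#'   to attempt a fit. Default 100.
#' @param clamp_floor Lower clamp on the smoothed count, as a fraction of
#'   the global mean. Default 0.01.
#' @return Numeric vector of corrected counts, one per bin.
#' @export
gc_correct <- function(counts, bins, span = 0.3, min_usable_bins = 100,
                       clamp_floor = 0.01) {
  if (inherits(counts, "binned_counts")) counts <- counts$counts
  counts <- as.numeric(counts)
  if (length(counts) != nrow(bins))
    stop("counts length ", length(counts), " does not match ",
         nrow(bins), " bins")
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must lie in (0, 1]")
  usable <- bins$usable
  if (sum(usable & counts > 0) < min_usable_bins)
    stop("fewer than ", min_usable_bins,
         " usable bins with positive counts; cannot fit GC correction")
  gc <- bins$gc[usable]
  y <- counts[usable]
  m <- mean(y)
  out <- numeric(length(counts))
  if (diff(range(gc)) < 1e-6) {
    warning("degenerate GC spread; GC correction skipped for this sample")
    out[usable] <- y
    return(out)
  }
  ord <- order(gc)
  sm <- stats::lowess(gc[ord], y[ord], f = span, iter = 2L)
  pred <- numeric(length(y))
  pred[ord] <- sm$y
  pred <- pmax(pred, clamp_floor * m)
  out[usable] <- y * m / pred
  out
}

#' Per-chromosome profile of a corrected sample
#'
#' Aggregates corrected bin counts to the 22 autosomes: `rc[j]` is the
#' summed corrected count of chromosome `j`, `rf[j] = rc[j] / sum(rc)` its
#' reads fraction, and `gc[j]` the sample's per-chromosome GC content,
#' computed as the count-weighted mean bin GC. The GC weighting uses the
#' *raw* counts when supplied (the reads the sample actually produced,
#' which is what "GC content of a sample" means); the GC-corrected counts
#' are deliberately not used as weights, because a perfect correction
#' flattens them and would erase the sample-to-sample GC signal.
#'
#' @param corrected Corrected count vector from [gc_correct()].
#' @param bins Bin table from [read_bins()].
#' @param sample_id Sample identifier.
#' @param raw Optional raw count vector (or `binned_counts`) used as GC
#'   weights; falls back to `corrected` when absent.
#' @return A `chrom_profile` data frame with columns `chrom` (1-22), `rc`,
#'   `rf`, `gc`, and a `sample_id` attribute. `rf` sums to 1.
#' @export
chromosome_profile <- function(corrected, bins, sample_id = "sample",
                               raw = NULL) {
  if (inherits(corrected, "binned_counts")) corrected <- corrected$counts
  if (inherits(raw, "binned_counts")) raw <- raw$counts
  if (length(corrected) != nrow(bins))
    stop("corrected length does not match bins")
  if (!setequal(unique(bins$chrom), 1:22))
    stop("bins must cover all 22 autosomes")
  w <- if (is.null(raw)) corrected else as.numeric(raw)
  if (length(w) != nrow(bins)) stop("raw length does not match bins")
  ch <- factor(bins$chrom, levels = 1:22)
  rc <- as.numeric(tapply(corrected, ch, sum))
  total <- sum(rc)
  if (total <= 0) stop("zero total corrected count for sample ", sample_id)
  wg <- as.numeric(tapply(w * bins$gc, ch, sum))
  ws <- as.numeric(tapply(w, ch, sum))
  gc <- ifelse(ws > 0, wg / ws,
               as.numeric(tapply(bins$gc, ch, mean)))
  prof <- data.frame(chrom = 1:22, rc = rc, rf = rc / total, gc = gc)
  attr(prof, "sample_id") <- as.character(sample_id)
  class(prof) <- c("chrom_profile", "data.frame")
  prof
}

#' Correct and profile one sample in a single step
#'
#' Convenience wrapper: [gc_correct()] followed by [chromosome_profile()]
#' with raw-count GC weighting.
#'
#' @inheritParams gc_correct
#' @param sample_id Sample identifier; defaults to the `binned_counts`
#'   sample id when available.
#' @return A `chrom_profile` data frame.
#' @export
profile_sample <- function(counts, bins, sample_id = NULL, span = 0.3,
                           min_usable_bins = 100, clamp_floor = 0.01) {
  if (is.null(sample_id))
    sample_id <- if (inherits(counts, "binned_counts")) counts$sample_id
                 else "sample"
  corrected <- gc_correct(counts, bins, span = span,
                          min_usable_bins = min_usable_bins,
                          clamp_floor = clamp_floor)
  chromosome_profile(corrected, bins, sample_id = sample_id, raw = counts)
}

#' Stack per-sample profiles into a profile set
#'
#' @param profiles A list of `chrom_profile` objects, or a single one.
#' @return A `profile_set`: list with `sample_id` (character vector) and
#'   `rc`, `rf`, `gc` numeric matrices (samples x 22 autosomes).
#' @export
bind_profiles <- function(profiles) {
  if (inherits(profiles, "profile_set")) return(profiles)
  if (inherits(profiles, "chrom_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0L)
  ids <- vapply(profiles, function(p) attr(p, "sample_id"), character(1L))
  grab <- function(col) {
    m <- t(vapply(profiles, function(p) p[[col]], numeric(22L)))
    dimnames(m) <- list(ids, paste0("chr", 1:22))
    m
  }
  if (anyDuplicated(ids))
    stop("duplicated sample_id among profiles: ", ids[duplicated(ids)][1L])
  structure(list(sample_id = ids, rc = grab("rc"), rf = grab("rf"),
                 gc = grab("gc")),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set:", length(x$sample_id), "samples x 22 autosomes\n")
  invisible(x)
}

#' Subset a profile set by sample
#'
#' @param x A `profile_set`.
#' @param i Sample indices or ids.
#' @param ... Unused.
#' @return A `profile_set` restricted to the selected samples.
#' @export
`[.profile_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  structure(list(sample_id = x$sample_id[i],
                 rc = x$rc[i, , drop = FALSE],
                 rf = x$rf[i, , drop = FALSE],
                 gc = x$gc[i, , drop = FALSE]),
            class = "profile_set")
}

#' Number of samples in a profile set
#' @param x A `profile_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) length(x$sample_id)

#' Correct and profile a whole cohort of count vectors
#'
#' @param counts A bins-by-samples count matrix with sample ids as column
#'   names, or a list of `binned_counts`.
#' @inheritParams gc_correct
#' @return A `profile_set`.
#' @export
profile_cohort <- function(counts, bins, span = 0.3,
                           min_usable_bins = 100, clamp_floor = 0.01) {
  if (is.list(counts) && !is.data.frame(counts)) {
    profs <- lapply(counts, profile_sample, bins = bins, span = span,
                    min_usable_bins = min_usable_bins,
                    clamp_floor = clamp_floor)
    return(bind_profiles(profs))
  }
  counts <- as.matrix(counts)
  ids <- colnames(counts)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(counts)))
  profs <- lapply(seq_len(ncol(counts)), function(i)
    profile_sample(counts[, i], bins, sample_id = ids[i], span = span,
                   min_usable_bins = min_usable_bins,
                   clamp_floor = clamp_floor))
  bind_profiles(profs)
}
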