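#' Read a bin definition file
#'
#' Reads a BED-like, headerless, tab-delimited bin table with columns
#' `chrom`, `start`, `end`, `gc` and an optional fifth `usable` flag.
#' Coordinates are 0-based, half-open. Only autosomes (1-22, with or
#' without a `chr` prefix) are retained; rows for other chromosomes are
#' dropped with a message. Bins wider than 20 kb are rejected: counting is
#' defined over fixed 20 kb windows and a trailing partial window at a
#' chromosome end is the only shorter bin expected (conventionally flagged
#' `usable = FALSE`).
#'
#' @param path Path to the bin file.
#' @return A `data.frame` of class `nipt_bins` with integer `chrom` (1-22),
#'   `start`, `end`, numeric `gc` and logical `usable`, sorted by
#'   chromosome then start.
#' @seealso [write_bins()], [read_counts()]
#' @export
read_bins <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("bin file must have at least 4 columns: chrom, start, end, gc")
  chrom_raw <- sub("^chr", "", raw[[1L]])
  autosomal <- chrom_raw %in% as.character(1:22)
  if (any(!autosomal))
    message(sum(!autosomal), " non-autosomal bin row(s) dropped")
  raw <- raw[autosomal, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no autosomal bins in ", path)
  bins <- data.frame(
    chrom  = as.integer(chrom_raw[autosomal]),
    start  = as.numeric(raw[[2L]]),
    end    = as.numeric(raw[[3L]]),
    gc     = as.numeric(raw[[4L]]),
    usable = if (ncol(raw) >= 5L) parse_flag(raw[[5L]]) else TRUE
  )
  validate_bins(bins)
}

#' Write a bin definition file
#'
#' Inverse of [read_bins()]: writes the BED-like tab-delimited form
#' (chrom, start, end, gc, usable; no header).
#'
#' @param bins A bin table as returned by [read_bins()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  out <- data.frame(bins$chrom, bins$start, bins$end,
                    format(bins$gc, trim = TRUE, digits = 15),
                    as.integer(bins$usable))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("1", "true", "t", "yes")
  bad <- !v %in% c("1", "true", "t", "yes", "0", "false", "f", "no")
  if (any(bad)) stop("unparseable logical flag value: ", v[which(bad)[1L]])
  out
}

validate_bins <- function(bins) {
  if (any(!is.finite(bins$gc)) || any(bins$gc < 0) || any(bins$gc > 1))
    stop("bin gc values must lie in [0, 1]")
  if (any(!is.finite(bins$start)) || any(!is.finite(bins$end)) ||
      any(bins$end <= bins$start))
    stop("bins must satisfy start < end")
  width <- bins$end - bins$start
  if (any(width > 20000))
    stop("bin wider than 20 kb found (width ", max(width), ")")
  ord <- order(bins$chrom, bins$start)
  bins <- bins[ord, , drop = FALSE]
  rownames(bins) <- NULL
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop("overlapping bins on chromosome ", ch)
  }
  class(bins) <- c("nipt_bins", "data.frame")
  bins
}

#' Read a per-sample binned count file
#'
#' Two tab-delimited layouts are accepted: a keyed, headerless
#' `chrom  start  count` table (rows matched to `bins` by chromosome and
#' start; bins with no row are filled with 0 and reported), or a
#' single-column vector whose one-field header line names the sample and
#' whose length equals `nrow(bins)`.
#'
#' @param path Path to the count file.
#' @param bins Bin table from [read_bins()].
#' @param sample_id Sample identifier; defaults to the file name (keyed
#'   layout) or the header (vector layout).
#' @return An object of class `binned_counts`: a list with elements
#'   `sample_id` and integer `counts` aligned to `bins`.
#' @export
read_counts <- function(path, bins, sample_id = NULL) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  keyed <- length(first) >= 3L && !is.na(suppressWarnings(as.numeric(first[2L])))
  if (keyed) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", stringsAsFactors = FALSE)
    chrom <- as.integer(sub("^chr", "", tab[[1L]]))
    start <- as.numeric(tab[[2L]])
    cnt <- as.numeric(tab[[3L]])
    key <- paste(chrom, start)
    if (anyDuplicated(key))
      stop("duplicated (chrom, start) row in ", path, ": ",
           key[duplicated(key)][1L])
    bin_key <- paste(bins$chrom, bins$start)
    idx <- match(key, bin_key)
    if (anyNA(idx))
      stop("count row with no matching bin: ", key[which(is.na(idx))[1L]])
    counts <- numeric(nrow(bins))
    counts[idx] <- cnt
    n_missing <- nrow(bins) - length(idx)
    if (n_missing > 0L)
      message(n_missing, " bin(s) absent from ", basename(path),
              "; filled with 0")
    if (is.null(sample_id))
      sample_id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    if (length(first) != 1L)
      stop("unrecognized count file layout in ", path)
    vals <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    counts <- as.numeric(vals[[1L]])
    if (length(counts) != nrow(bins))
      stop("count vector length ", length(counts),
           " does not match ", nrow(bins), " bins")
    if (is.null(sample_id)) sample_id <- names(vals)[1L]
  }
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("negative or non-finite count in ", path)
  binned_counts(sample_id, counts)
}

#' Construct a binned-count object
#'
#' @param sample_id Sample identifier.
#' @param counts Non-negative count vector, one entry per bin.
#' @return A `binned_counts` object.
#' @export
binned_counts <- function(sample_id, counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite")
  structure(list(sample_id = as.character(sample_id), counts = counts),
            class = "binned_counts")
}

#' @export
print.binned_counts <- function(x, ...) {
  cat("Binned counts for sample", x$sample_id, "-", length(x$counts),
      "bins,", format(sum(x$counts), big.mark = ","), "reads\n")
  invisible(x)
}

#' Read a cohort manifest
#'
#' Tab-delimited with header `sample_id  karyotype  twin  outlier`.
#' Karyotype labels: `euploid`, `T21`, `T18`, `T13`, `other_aneuploidy`.
#'
#' @param path Path to the manifest.
#' @return A `data.frame` with character `sample_id`, character
#'   `karyotype` and logical `twin`, `outlier`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "karyotype", "twin", "outlier")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m <- m[, need]
  m$twin <- parse_flag(m$twin)
  m$outlier <- parse_flag(m$outlier)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  if (anyDuplicated(m$sample_id))
    stop("duplicated sample_id in manifest: ",
         m$sample_id[duplicated(m$sample_id)][1L])
  allowed <- c("euploid", "T21", "T18", "T13", "other_aneuploidy")
  if (any(!m$karyotype %in% allowed))
    stop("unknown karyotype label: ",
         m$karyotype[!m$karyotype %in% allowed][1L])
  rownames(m) <- NULL
  m
}

#' Write a cohort manifest
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$twin <- as.integer(out$twin)
  out$outlier <- as.integer(out$outlier)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select reference-eligible samples from a manifest
#'
#' A sample is eligible for the euploid reference panel when it is euploid,
#' a singleton pregnancy and not flagged as an outlier. Exclusion reasons
#' may co-occur on one sample (e.g. an aneuploid twin pregnancy); the
#' exclusion is the set union, so such a sample is removed once.
#'
#' @param manifest Manifest data frame (see [read_manifest()]).
#' @return Character vector of eligible `sample_id`s, in manifest order.
#' @export
filter_reference_eligible <- function(manifest) {
  manifest <- validate_manifest(manifest)
  keep <- manifest$karyotype == "euploid" & !manifest$twin & !manifest$outlier
  manifest$sample_id[keep]
}

#' Write an aneuploidy-call report
#'
#' Tab-delimited with header
#' `sample_id  chrom  z  panel_size  panel_cv  classification`, one record
#' per test sample and target chromosome. Round-trips through
#' [read_report()].
#'
#' @param calls An `aneuploidy_calls` data frame from
#'   [predict.nipt_panel()] or [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(calls, path) {
  need <- c("sample_id", "chrom", "z", "panel_size", "panel_cv",
            "classification")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  out <- calls[, need]
  out$z <- format(out$z, trim = TRUE, digits = 15)
  out$panel_cv <- format(out$panel_cv, trim = TRUE, digits = 15)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an aneuploidy-call report written by [write_report()]
#'
#' @param path Path to the report.
#' @return An `aneuploidy_calls` data frame.
#' @export
read_report <- function(path) {
  r <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character",
                                        classification = "character"))
  r$chrom <- as.integer(r$chrom)
  r$panel_size <- as.integer(r$panel_size)
  class(r) <- c("aneuploidy_calls", "data.frame")
  r
}
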