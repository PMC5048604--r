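#' Parameters of the adaptive reference-selection grid
#'
#' The candidate windows are centred on the test sample's per-chromosome
#' GC content and on its *fitted* reads fraction (from the full-panel
#' regression), and expand on a stepped grid: GC half-widths
#' `gc_unit, 2 gc_unit, ..., gc_max` and reads-fraction half-widths
#' `rf_unit, 2 rf_unit, ..., rf_max`.
#'
#' @param gc_unit GC stepping unit; default 0.001.
#' @param rf_unit Reads-fraction stepping unit; default 0.00005.
#' @param gc_max Maximum GC half-width; default 0.02.
#' @param rf_max Maximum reads-fraction half-width; default 0.001.
#' @param min_panel Minimum admissible window membership; default 30.
#' @return A `selection_params` list.
#' @export
selection_params <- function(gc_unit = 0.001, rf_unit = 0.00005,
                             gc_max = 0.02, rf_max = 0.001,
                             min_panel = 30L) {
  if (!(gc_unit > 0 && gc_unit <= gc_max))
    stop("need 0 < gc_unit <= gc_max")
  if (!(rf_unit > 0 && rf_unit <= rf_max))
    stop("need 0 < rf_unit <= rf_max")
  ## infinite maxima disable the corresponding dimension: the single
  ## unbounded half-width recovers the baseline method
  if (is.infinite(gc_max)) gc_unit <- Inf
  if (is.infinite(rf_max)) rf_unit <- Inf
  min_panel <- as.integer(min_panel)
  if (min_panel < 2L) stop("min_panel must be at least 2")
  structure(list(gc_unit = gc_unit, rf_unit = rf_unit, gc_max = gc_max,
                 rf_max = rf_max, min_panel = min_panel),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf(
    "Selection grid: GC +/- k*%g up to %g; RF +/- k*%g up to %g; min panel %d\n",
    x$gc_unit, x$gc_max, x$rf_unit, x$rf_max, x$min_panel))
  invisible(x)
}

#' Extract the reference subset inside one (GC, RF) window
#'
#' Membership is `|gc_k - gc_center| <= g` and
#' `|rf_norm_k - rf_center| <= r` over the panel samples, where
#' `gc_center` is the test sample's per-chromosome GC content and
#' `rf_center` its fitted reads fraction [predicted_rf()] from the
#' full-panel regression. Both half-widths may be `Inf`, in which case the
#' full panel (the baseline, non-adaptive method) is recovered.
#'
#' @param panel A fitted `nipt_panel`.
#' @param test Test-sample `chrom_profile` (raw reads-fraction scale).
#' @param chrom Target chromosome.
#' @param g GC half-width (> 0, may be `Inf`).
#' @param r Reads-fraction half-width (> 0, may be `Inf`).
#' @return A `selection_window`: list with `chrom`, `gc_center`,
#'   `rf_center`, `g`, `r`, `members` (panel indices), `sample_id`
#'   (member ids), `n`, and `cv` (`NA` when fewer than 2 members).
#' @export
select_window <- function(panel, test, chrom, g, r) {
  stopifnot(g > 0, r > 0)
  chrom <- as.integer(chrom)
  tn <- normalize_test(panel, test)
  gc_center <- tn$gc[chrom]
  rf_center <- predicted_rf(panel, chrom, gc_center)
  members <- as.integer(which(abs(panel$gc[, chrom] - gc_center) <= g &
                              abs(panel$rf_norm[, chrom] - rf_center) <= r))
  structure(list(chrom = chrom, gc_center = gc_center,
                 rf_center = rf_center, g = g, r = r, members = members,
                 sample_id = panel$sample_id[members], n = length(members),
                 cv = if (length(members) >= 2L)
                   panel_cv(panel, chrom, members) else NA_real_),
            class = "selection_window")
}

#' @export
print.selection_window <- function(x, ...) {
  cat(sprintf(
    "Window chr%d: GC %.4f +/- %g, RF %.6g +/- %g -> %d members, CV %s\n",
    x$chrom, x$gc_center, x$g, x$rf_center, x$r, x$n,
    if (is.na(x$cv)) "NA" else format(x$cv, digits = 4)))
  invisible(x)
}

#' Expand selection windows on the stepped grid and choose the CV-optimal set
#'
#' Evaluates every window on the `(g, r)` grid defined by `params`. Among
#' windows with at least `min_panel` members, the one with minimal CV is
#' chosen; ties are broken in favour of larger membership, then smaller
#' GC half-width, then smaller reads-fraction half-width. If no window
#' reaches `min_panel`, the full panel is used as a fallback (with a
#' warning): the baseline method is always available.
#'
#' @inheritParams select_window
#' @param params A [selection_params()] object.
#' @return A `selection_grid`: list with `grid` (data frame of `g`, `r`,
#'   `n`, `cv` per window), `chosen` (row index into `grid`, or `NA` on
#'   fallback), `members` (panel indices of the chosen set), `fallback`
#'   (logical), `gc_center`, `rf_center`, `chrom`.
#' @export
expand_and_choose <- function(panel, test, chrom,
                              params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  chrom <- as.integer(chrom)
  tn <- normalize_test(panel, test)
  gc_center <- tn$gc[chrom]
  rf_center <- predicted_rf(panel, chrom, gc_center)
  dg <- abs(panel$gc[, chrom] - gc_center)
  dr <- abs(panel$rf_norm[, chrom] - rf_center)
  gs <- if (is.infinite(params$gc_max)) Inf
        else params$gc_unit * seq_len(floor(params$gc_max / params$gc_unit + 1e-9))
  rs <- if (is.infinite(params$rf_max)) Inf
        else params$rf_unit * seq_len(floor(params$rf_max / params$rf_unit + 1e-9))
  grid <- expand.grid(g = gs, r = rs, KEEP.OUT.ATTRS = FALSE)
  eval_window <- function(g, r) {
    members <- dg <= g & dr <= r
    n <- sum(members)
    cv <- if (n >= 2L) panel_cv(panel, chrom, which(members)) else NA_real_
    c(n = n, cv = cv)
  }
  stats <- mapply(eval_window, grid$g, grid$r)
  grid$n <- as.integer(stats["n", ])
  grid$cv <- stats["cv", ]
  eligible <- which(grid$n >= params$min_panel & is.finite(grid$cv))
  if (length(eligible) == 0L) {
    warning("no selection window on chr", chrom, " reached ",
            params$min_panel, " members; falling back to the full panel")
    return(structure(list(grid = grid, chosen = NA_integer_,
                          members = seq_len(panel$n), fallback = TRUE,
                          gc_center = gc_center, rf_center = rf_center,
                          chrom = chrom),
                     class = "selection_grid"))
  }
  ord <- eligible[order(grid$cv[eligible], -grid$n[eligible],
                        grid$g[eligible], grid$r[eligible])]
  chosen <- ord[1L]
  structure(list(grid = grid, chosen = chosen,
                 members = as.integer(which(dg <= grid$g[chosen] &
                                            dr <= grid$r[chosen])),
                 fallback = FALSE, gc_center = gc_center,
                 rf_center = rf_center, chrom = chrom),
            class = "selection_grid")
}

#' @export
print.selection_grid <- function(x, ...) {
  cat(sprintf("Selection grid chr%d: %d windows evaluated\n",
              x$chrom, nrow(x$grid)))
  if (x$fallback) {
    cat("No window reached the minimum membership; full panel used (",
        length(x$members), " samples)\n", sep = "")
  } else {
    w <- x$grid[x$chosen, ]
    cat(sprintf(
      "Chosen: GC +/- %g, RF +/- %g -> %d members, CV %.4g\n",
      w$g, w$r, w$n, w$cv))
  }
  invisible(x)
}

#' Turn a selection grid into a plain data frame
#'
#' One row per `(g, r)` window with membership size, CV and a flag for
#' the chosen window — the form used to export grid dumps for CV bar
#' charts.
#'
#' @param x A `selection_grid`.
#' @param ... Unused.
#' @return A data frame with columns `g`, `r`, `n`, `cv`, `chosen`.
#' @export
as.data.frame.selection_grid <- function(x, ...) {
  out <- x$grid
  out$chosen <- FALSE
  if (!x$fallback) out$chosen[x$chosen] <- TRUE
  out
}

#' Group samples into fixed-width GC-content regions
#'
#' Each sample is assigned to the region `floor(gc / width) * width` of
#' its per-chromosome GC content (e.g. GC 0.424 falls in region 0.42 at
#' the default width 0.01). Used to cluster positive samples by GC region
#' before picking a representative per region.
#'
#' @param profiles A `profile_set` or list of `chrom_profile`s.
#' @param chrom Target chromosome.
#' @param width Region width; default 0.01.
#' @return Named list of character vectors of sample ids; names are the
#'   region lower bounds (e.g. `"0.42"`). Empty input gives an empty list.
#' @export
group_by_gc_region <- function(profiles, chrom, width = 0.01) {
  stopifnot(width > 0)
  if (is.list(profiles) && length(profiles) == 0L) return(list())
  ps <- bind_profiles(profiles)
  gc <- ps$gc[, as.integer(chrom)]
  region <- floor(gc / width + 1e-9) * width
  split(ps$sample_id, format(region, trim = TRUE))
}

#' Choose the representative sample of a GC region group
#'
#' With more than two samples the one holding the median GC content is
#' chosen (lower median for even sizes); with exactly two, the
#' lexicographically smallest sample id (a deterministic stand-in for an
#' arbitrary choice); a singleton group is its own representative.
#'
#' @param profiles A `profile_set` or list of `chrom_profile`s forming
#'   one group.
#' @param chrom Target chromosome.
#' @return The representative `sample_id`.
#' @export
choose_representative <- function(profiles, chrom) {
  ps <- bind_profiles(profiles)
  n <- n_samples(ps)
  if (n == 0L) stop("cannot choose a representative of an empty group")
  if (n == 1L) return(ps$sample_id)
  if (n == 2L) return(sort(ps$sample_id)[1L])
  gc <- ps$gc[, as.integer(chrom)]
  ord <- order(gc, ps$sample_id)
  ps$sample_id[ord[floor((n + 1L) / 2L)]]
}
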