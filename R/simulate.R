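## Autosome lengths (Mb, hg19-proportional) used to size the toy genome.
.chrom_mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
               115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

## Per-chromosome mean bin GC of the synthetic genome. The relative
## ordering follows the human autosomes (GC-poor chr4/13/18, GC-rich
## chr19/22) but the values are compressed towards the 0.40-0.51 envelope
## that read-weighted per-sample GC contents are expected to occupy.
.chrom_gc <- 0.425 + 0.5 * (c(0.417, 0.402, 0.397, 0.382, 0.395, 0.396,
                              0.408, 0.402, 0.413, 0.416, 0.416, 0.408,
                              0.385, 0.408, 0.422, 0.447, 0.455, 0.398,
                              0.483, 0.442, 0.408, 0.479) - 0.412)

#' Configuration of the synthetic cfDNA cohort generator
#'
#' Defaults emulate the statistical structure of a shallow-sequencing
#' NIPT study: about 400 euploid reference samples, ~3.3 million unique
#' reads per sample, sample-specific unimodal GC-bias curves producing
#' per-chromosome GC contents inside the 0.40-0.51 envelope, and optional
#' trisomic samples whose target-chromosome expected counts are inflated
#' by `1 + f/2` at fetal fraction `f` (halved again for twin-diluted
#' cases). The genome is a scaled stand-in: 22 autosomes with bin counts
#' proportional to the human autosome lengths, ~5,000 bins in total.
#'
#' Counts are negative-binomial around the expected bin intensity; the
#' per-bin dispersion default (3e-4 at the 5,000-bin scale) is calibrated
#' so the baseline chromosome-21 reads-fraction CV lands near 0.4-0.5%,
#' the plausible range for well-behaved NIPT reference panels. Dispersion
#' is a per-bin quantity, so it must be rescaled if the bin count is
#' changed at fixed depth.
#'
#' @param n_euploid Number of euploid singleton samples; default 400.
#' @param n_bins Total bins across the 22 autosomes; default 5000.
#' @param depth Mean unique reads per sample; default 3.3e6.
#' @param depth_sdlog Log-normal spread of per-sample depth; default 0.1.
#' @param noise `"nb"` (negative binomial) or `"poisson"`.
#' @param dispersion Negative-binomial per-bin dispersion (`size =
#'   1/dispersion`); `0` is the Poisson limit. Default 3e-4.
#' @param bias_mode_range Range of the per-sample GC-bias curve mode (on
#'   the GC axis); default `c(0.40, 0.55)`.
#' @param bias_amp_range Range of the per-sample bias amplitude in
#'   `[0, 1)` (0 = flat, no bias); default `c(0.4, 0.6)`.
#' @param bias_concentration Sharpness of the beta-shaped bias curve;
#'   default 6.
#' @param bin_gc_sd Within-chromosome spread of bin GC; default 0.04.
#' @param frag_gc_sd Spread of the latent fragment-level GC around the
#'   bin GC; the part of the bias that bin-level correction cannot see.
#'   Default 0.015.
#' @param gc_envelope Target envelope for per-sample target-chromosome GC
#'   contents; default `c(0.40, 0.51)`.
#' @param trisomy `NULL`, or a data frame with columns `chrom` (13, 18 or
#'   21), `f` (fetal fraction in `[0, 0.5]`) and optional `twin`
#'   (logical); one trisomic sample per row.
#' @param seed Optional integer seed for reproducible generation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_euploid = 400L, n_bins = 5000L, depth = 3.3e6,
                       depth_sdlog = 0.1, noise = c("nb", "poisson"),
                       dispersion = 3e-4,
                       bias_mode_range = c(0.40, 0.55),
                       bias_amp_range = c(0.4, 0.6),
                       bias_concentration = 6, bin_gc_sd = 0.04,
                       frag_gc_sd = 0.015, gc_envelope = c(0.40, 0.51),
                       trisomy = NULL, seed = NULL) {
  noise <- match.arg(noise)
  if (depth <= 0) stop("depth must be positive")
  if (n_bins < 22L * 5L) stop("n_bins too small for 22 autosomes")
  if (!is.null(trisomy)) {
    trisomy <- as.data.frame(trisomy)
    if (!all(c("chrom", "f") %in% names(trisomy)))
      stop("trisomy spec needs columns chrom and f")
    if (is.null(trisomy$twin)) trisomy$twin <- FALSE
    if (any(!trisomy$chrom %in% c(13L, 18L, 21L)))
      stop("trisomy chrom must be 13, 18 or 21")
    if (any(trisomy$f < 0 | trisomy$f > 0.5))
      stop("fetal fraction must lie in [0, 0.5]")
  }
  structure(list(n_euploid = as.integer(n_euploid),
                 n_bins = as.integer(n_bins), depth = depth,
                 depth_sdlog = depth_sdlog, noise = noise,
                 dispersion = dispersion,
                 bias_mode_range = bias_mode_range,
                 bias_amp_range = bias_amp_range,
                 bias_concentration = bias_concentration,
                 bin_gc_sd = bin_gc_sd, frag_gc_sd = frag_gc_sd,
                 gc_envelope = gc_envelope, trisomy = trisomy,
                 seed = seed),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Build the scaled synthetic genome's bin table
#'
#' 22 autosomes with bin counts proportional to the human autosome
#' lengths; 20 kb bins; per-chromosome Gaussian bin-GC around
#' chromosome-characteristic means; the last bin of each chromosome is
#' flagged unusable (a trailing partial window). A latent fragment-level
#' GC track (bin GC plus noise) is attached as attribute `gc_latent`; the
#' bias curves act on it, so bin-level GC correction can never remove the
#' bias exactly — the residual, GC-correlated structure that the
#' regression and adaptive-selection stages exist to handle.
#'
#' @param cfg A [sim_config()].
#' @return An `nipt_bins` table with `gc_latent` attribute.
#' @export
synthetic_bins <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    per_chrom <- pmax(5L, round(cfg$n_bins * .chrom_mb / sum(.chrom_mb)))
    chrom <- rep(1:22, per_chrom)
    start <- unlist(lapply(per_chrom, function(k) (0:(k - 1L)) * 20000))
    end <- start + 20000
    gc <- stats::rnorm(length(chrom), mean = .chrom_gc[chrom],
                       sd = cfg$bin_gc_sd)
    gc <- pmin(pmax(gc, 0.30), 0.62)
    usable <- rep(TRUE, length(chrom))
    usable[cumsum(per_chrom)] <- FALSE
    bins <- validate_bins(data.frame(chrom = chrom, start = start,
                                     end = end, gc = gc, usable = usable))
    gc_lat <- bins$gc + stats::rnorm(nrow(bins), 0, cfg$frag_gc_sd)
    attr(bins, "gc_latent") <- pmin(pmax(gc_lat, 0.28), 0.64)
    bins
  })
}

## Per-sample multiplicative bias over the latent fragment GC: a flat
## floor blended with a beta-density bump of given mode; normalized to
## mean 1 over bins.
bias_curve <- function(gc_latent, mode, amplitude, concentration) {
  lo <- 0.28; hi <- 0.64
  u <- (pmin(pmax(gc_latent, lo), hi) - lo) / (hi - lo)
  um <- (pmin(pmax(mode, lo + 0.01), hi - 0.01) - lo) / (hi - lo)
  shape <- stats::dbeta(u, 1 + concentration * um,
                        1 + concentration * (1 - um))
  g <- (1 - amplitude) + amplitude * shape / mean(shape)
  g / mean(g)
}

#' Simulate a binned-count cfDNA cohort
#'
#' Per sample `i` and bin `b` the expected count is
#' `lambda[i, b] = depth[i] * w[b] * g_i(gc_latent[b]) / Z_i` with `w` the
#' bin weight (unusable trailing bins get weight 0.4), `g_i` the sample's
#' bias curve and `Z_i` normalizing the sum to the sample's depth.
#' Trisomic samples have `lambda` over the target chromosome's bins
#' multiplied by `1 + f_eff/2`, where `f_eff = f/2` for twin-diluted
#' cases. Counts are then drawn from the configured noise family.
#'
#' @param cfg A [sim_config()].
#' @param bins Optionally a pre-built [synthetic_bins()] table, so panel
#'   and test cohorts can share one genome.
#' @return A `nipt_cohort` list: `bins`, `counts` (bins x samples matrix
#'   with sample-id column names), `manifest`, `truth` (per-sample
#'   simulation parameters: karyotype, fetal fraction, twin flag, bias
#'   mode/amplitude, depth), and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_euploid = 20, n_bins = 600,
#'                                      depth = 2e5, seed = 7))
#' dim(cohort$counts)
#' @export
simulate_cohort <- function(cfg = sim_config(), bins = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    if (is.null(bins)) bins <- synthetic_bins(sim_config_noseed(cfg))
    simulate_cohort_impl(cfg, bins, bias_modes = NULL)
  })
}

## cfg copy without seed, for nested generation inside with_seed().
sim_config_noseed <- function(cfg) { cfg$seed <- NULL; cfg }

simulate_cohort_impl <- function(cfg, bins, bias_modes = NULL,
                                 subpop = NULL) {
  gc_lat <- attr(bins, "gc_latent")
  if (is.null(gc_lat)) gc_lat <- bins$gc
  n_tri <- if (is.null(cfg$trisomy)) 0L else nrow(cfg$trisomy)
  n <- cfg$n_euploid + n_tri
  if (n < 1L) stop("infeasible config: no samples requested")
  ids <- c(sprintf("E%04d", seq_len(cfg$n_euploid)),
           if (n_tri > 0L)
             sprintf("T%02d_%03d", cfg$trisomy$chrom, seq_len(n_tri)))
  kary <- c(rep("euploid", cfg$n_euploid),
            if (n_tri > 0L) paste0("T", cfg$trisomy$chrom))
  twin <- c(rep(FALSE, cfg$n_euploid),
            if (n_tri > 0L) as.logical(cfg$trisomy$twin))
  f <- c(rep(0, cfg$n_euploid), if (n_tri > 0L) cfg$trisomy$f)
  tri_chrom <- c(rep(NA_integer_, cfg$n_euploid),
                 if (n_tri > 0L) as.integer(cfg$trisomy$chrom))

  if (is.null(bias_modes))
    bias_modes <- stats::runif(n, cfg$bias_mode_range[1L],
                               cfg$bias_mode_range[2L])
  amps <- stats::runif(n, cfg$bias_amp_range[1L], cfg$bias_amp_range[2L])
  depths <- cfg$depth * stats::rlnorm(n, -cfg$depth_sdlog^2 / 2,
                                      cfg$depth_sdlog)
  w <- ifelse(bins$usable, 1, 0.4)

  counts <- matrix(0, nrow = nrow(bins), ncol = n,
                   dimnames = list(NULL, ids))
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  for (i in seq_len(n)) {
    g <- bias_curve(gc_lat, bias_modes[i], amps[i], cfg$bias_concentration)
    lam <- w * g
    lam <- depths[i] * lam / sum(lam)
    if (!is.na(tri_chrom[i])) {
      f_eff <- if (twin[i]) f[i] / 2 else f[i]
      lam[bins$chrom == tri_chrom[i]] <-
        lam[bins$chrom == tri_chrom[i]] * (1 + f_eff / 2)
    }
    counts[, i] <- if (cfg$noise == "poisson" || !is.finite(size))
      stats::rpois(length(lam), lam)
    else
      stats::rnbinom(length(lam), mu = lam, size = size)
  }
  manifest <- data.frame(sample_id = ids, karyotype = kary, twin = twin,
                         outlier = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, karyotype = kary, chrom = tri_chrom,
                      f = f, twin = twin, bias_mode = bias_modes,
                      bias_amp = amps, depth = depths,
                      stringsAsFactors = FALSE)
  if (!is.null(subpop)) truth$subpop <- subpop
  structure(list(bins = bins, counts = counts, manifest = manifest,
                 truth = truth, config = cfg),
            class = "nipt_cohort")
}

#' @export
print.nipt_cohort <- function(x, ...) {
  cat("Synthetic cfDNA cohort:", ncol(x$counts), "samples,",
      nrow(x$bins), "bins,",
      sum(x$manifest$karyotype != "euploid"), "aneuploid\n")
  invisible(x)
}

#' Simulate a GC-stratified reference cohort
#'
#' Generates a cohort whose euploid samples fall into two or more GC-bias
#' subpopulations (distinct bias-curve modes), emulating a reference
#' panel with an unbalanced reads-fraction distribution along GC — the
#' failure mode that adaptive reference selection addresses. After
#' generation it verifies that the subpopulations' expected chromosome-21
#' GC contents are separated by at least `2 * gc_unit` and that the
#' full-panel chr21 reads-fraction CV exceeds every within-subpopulation
#' CV (computed on expected fractions); otherwise the requested
#' separation is infeasible and an error is raised.
#'
#' @param cfg A [sim_config()]; its `bias_mode_range` is ignored in
#'   favour of `subpop_modes`.
#' @param subpop_modes Bias-curve modes of the subpopulations; default
#'   `c(0.40, 0.54)`.
#' @param mode_sd Within-subpopulation spread of the mode; default 0.01.
#' @param gc_unit GC stepping unit used for the separation check;
#'   default 0.001.
#' @param bins Optional shared [synthetic_bins()] table.
#' @param subpop Optional integer vector (recycled over samples) forcing
#'   each sample's subpopulation — e.g. to draw test samples from one
#'   known subpopulation; default random assignment.
#' @param check Run the generation-time feasibility check (default
#'   `TRUE`); disable for small auxiliary draws such as a handful of test
#'   samples.
#' @return A `nipt_cohort` whose `truth$subpop` labels each sample's
#'   subpopulation (trisomic samples are assigned randomly too).
#' @export
simulate_gc_stratified_panel <- function(cfg = sim_config(),
                                         subpop_modes = c(0.40, 0.54),
                                         mode_sd = 0.01, gc_unit = 0.001,
                                         bins = NULL, subpop = NULL,
                                         check = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), length(subpop_modes) >= 1L)
  if (length(subpop_modes) == 1L) return(simulate_cohort(cfg, bins = bins))
  with_seed(cfg$seed, {
    if (is.null(bins)) bins <- synthetic_bins(sim_config_noseed(cfg))
    n_tri <- if (is.null(cfg$trisomy)) 0L else nrow(cfg$trisomy)
    n <- cfg$n_euploid + n_tri
    subpop <- if (is.null(subpop))
      sample(seq_along(subpop_modes), n, replace = TRUE)
    else rep_len(as.integer(subpop), n)
    modes <- stats::rnorm(n, subpop_modes[subpop], mode_sd)
    cohort <- simulate_cohort_impl(cfg, bins, bias_modes = modes,
                                   subpop = subpop)
    if (check) check_stratification(cohort, gc_unit)
    cohort
  })
}

## Expected (noise-free) per-sample chr21 GC content and reads fraction,
## from the bias curves; used for the generation-time stratification check.
check_stratification <- function(cohort, gc_unit) {
  bins <- cohort$bins
  gc_lat <- attr(bins, "gc_latent")
  if (is.null(gc_lat)) gc_lat <- bins$gc
  w <- ifelse(bins$usable, 1, 0.4)
  is21 <- bins$chrom == 21L
  eu <- cohort$truth$karyotype == "euploid"
  gc21 <- rf21 <- numeric(nrow(cohort$truth))
  for (i in seq_len(nrow(cohort$truth))) {
    g <- w * bias_curve(gc_lat, cohort$truth$bias_mode[i],
                        cohort$truth$bias_amp[i],
                        cohort$config$bias_concentration)
    gc21[i] <- sum((g * bins$gc)[is21]) / sum(g[is21])
    rf21[i] <- sum(g[is21]) / sum(g)
  }
  sp <- cohort$truth$subpop[eu]
  centers <- tapply(gc21[eu], sp, mean)
  if (min(diff(sort(centers))) < 2 * gc_unit)
    stop("stratification infeasible: subpopulation GC separation below ",
         2 * gc_unit)
  cv <- function(v) stats::sd(v) / mean(v)
  full_cv <- cv(rf21[eu])
  within_cv <- tapply(rf21[eu], sp, cv)
  if (!(full_cv > max(within_cv)))
    stop("stratification infeasible: full-panel CV does not exceed ",
         "within-subpopulation CVs")
  invisible(cohort)
}

#' Write a simulated cohort to disk
#'
#' Writes `bins.bed` ([write_bins()]), one `<sample_id>.tsv` count file
#' per sample (keyed `chrom  start  count` layout) and `manifest.tsv`,
#' i.e. exactly the on-disk inputs [run_pipeline()] consumes.
#'
#' @param cohort A `nipt_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bins(cohort$bins, file.path(dir, "bins.bed"))
  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, showWarnings = FALSE)
  for (id in colnames(cohort$counts)) {
    out <- data.frame(cohort$bins$chrom, cohort$bins$start,
                      cohort$counts[, id])
    utils::write.table(out, file.path(counts_dir, paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
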