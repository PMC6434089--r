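# Synthetic per-window count generator emulating whole-genome-amplification
# noise, and calibration routines tying its dispersion parameters to target
# MAPD / repeat-correlation values.
#
# Generative model, per window i:
#   mu_i = D * (CN_i / 2) * g(gc_i) * b_i,   count_i ~ Poisson(mu_i)
# with log2 b_i a stationary AR(1) Gaussian process along windows (restarted
# per chromosome) of marginal SD sigma, split into a component shared
# between amplification repeats of the same cell and a repeat-private
# component (fraction `shared_fraction` of the variance is shared);
# g(gc) = 2^(c1*(gc - 0.40) + c2*(gc - 0.40)^2) is a smooth GC response; and
# dropout multiplies a window's expectation by ~0 with probability
# `dropout_rate`. This separates depth-dependent sequencing sampling noise
# (Poisson) from depth-independent amplification bias (b), which is exactly
# the axis on which WGA chemistries differ.

#' Kit noise profiles
#'
#' Parameter sets standing in for the empirical amplification behaviour of
#' common WGA chemistries, plus `"bulk"` (unamplified many-cell DNA) and
#' `"none"` (pure Poisson sampling, used for the control). The defaults were
#' derived with the calibration routines under the default study conditions
#' (scaled hg19 grid, 30 reads per 20-kb window, 100-kb QC windows):
#' `bias_sd_log2` via [calibrate_bias_sd()] against each kit's target MAPD,
#' and `gc_bias_coeffs[1]` ([calibrate_gc_bias()]) or `shared_fraction`
#' ([calibrate_shared_fraction()]) against its target repeat correlation —
#' the Pearson correlation of depth-normalized raw counts in 100-kb windows
#' between two amplification repeats ([count_correlation()]). The
#' reproducible component of a kit's bias is dominated by its deterministic
#' GC response (shared between repeats, and removed downstream by
#' [gc_correct()]), while `bias_sd_log2` captures the residual stochastic
#' roughness that survives GC correction and drives MAPD.
#'
#' @param kit One of `"MALBAC"`, `"PicoPLEX"`, `"GenomePlex"`, `"MDA"`,
#'   `"bulk"`, `"none"`.
#' @return A list of class `kit_noise_profile` with fields `kit`,
#'   `bias_sd_log2`, `autocorr`, `shared_fraction`, `gc_bias_coeffs`,
#'   `dropout_rate`, `target_mapd_100kb`, `target_repeat_cor`.
#' @export
kit_noise_profile <- function(kit = c("PicoPLEX", "MALBAC", "GenomePlex",
                                      "MDA", "bulk", "none")) {
  kit <- match.arg(kit)
  p <- switch(kit,
    bulk = list(bias_sd_log2 = 0.1875, autocorr = 0.5, shared_fraction = 0.9,
                gc_bias_coeffs = c(0, 0), dropout_rate = 0,
                target_mapd_100kb = 0.20, target_repeat_cor = NA_real_),
    PicoPLEX = list(bias_sd_log2 = 0.3125, autocorr = 0.5,
                    shared_fraction = 0.95, gc_bias_coeffs = c(4.125, 0),
                    dropout_rate = 0, target_mapd_100kb = 0.24,
                    target_repeat_cor = 0.85),
    MALBAC = list(bias_sd_log2 = 0.4531, autocorr = 0.5,
                  shared_fraction = 0.95, gc_bias_coeffs = c(3.75, 0),
                  dropout_rate = 0, target_mapd_100kb = 0.31,
                  target_repeat_cor = 0.88),
    GenomePlex = list(bias_sd_log2 = 0.625, autocorr = 0.5,
                      shared_fraction = 0.625, gc_bias_coeffs = c(1, 0),
                      dropout_rate = 0.02, target_mapd_100kb = 0.42,
                      target_repeat_cor = 0.55),
    MDA = list(bias_sd_log2 = 3.6348, autocorr = 0.5,
               shared_fraction = 0.01, gc_bias_coeffs = c(0, 0),
               dropout_rate = 0.20, target_mapd_100kb = 2.48,
               target_repeat_cor = 0.01),
    none = list(bias_sd_log2 = 0, autocorr = 0, shared_fraction = 0,
                gc_bias_coeffs = c(0, 0), dropout_rate = 0,
                target_mapd_100kb = NA_real_, target_repeat_cor = NA_real_)
  )
  structure(c(list(kit = kit), p), class = "kit_noise_profile")
}

#' Describe a karyotype for simulation
#'
#' @param sex `"XX"`, `"XY"` or `"XO"` (one X, no Y).
#' @param events Tibble/data frame with columns `chrom`, `start_bp`,
#'   `end_bp`, `copy_number` (integer >= 0); events must not overlap within
#'   a chromosome. Regions outside events are diploid (autosomes) or at the
#'   sex-determined X dosage.
#' @return A list of class `karyotype_spec`.
#' @export
karyotype_spec <- function(sex = c("XX", "XY", "XO"), events = NULL) {
  sex <- match.arg(sex)
  if (is.null(events))
    events <- tibble(chrom = character(), start_bp = numeric(),
                     end_bp = numeric(), copy_number = integer())
  events <- as_tibble(events)
  stopifnot(all(c("chrom", "start_bp", "end_bp", "copy_number") %in%
                  names(events)))
  if (any(events$copy_number < 0)) abort("copy_number must be >= 0.")
  for (chrom in unique(events$chrom)) {
    e <- events[events$chrom == chrom, ]
    e <- e[order(e$start_bp), ]
    if (nrow(e) > 1 && any(e$start_bp[-1] < e$end_bp[-nrow(e)]))
      abort(paste0("overlapping karyotype events on ", chrom))
  }
  structure(list(sex = sex, events = events), class = "karyotype_spec")
}

# Window-level copy number implied by a karyotype spec (window assigned the
# event CN when its midpoint lies inside the event).
karyotype_cn <- function(spec, grid) {
  cn <- rep(2, nrow(grid))
  cn[is_chrx(grid$chrom)] <- switch(spec$sex, XX = 2, XY = 1, XO = 1)
  cn[is_chry(grid$chrom)] <- switch(spec$sex, XX = 0, XY = 1, XO = 0)
  if (nrow(spec$events)) {
    mid <- (grid$start + grid$end) / 2
    for (i in seq_len(nrow(spec$events))) {
      e <- spec$events[i, ]
      hit <- grid$chrom == e$chrom & mid >= e$start_bp & mid < e$end_bp
      if (!any(hit))
        abort(sprintf("karyotype event %s:%g-%g covers no window.",
                      e$chrom, e$start_bp, e$end_bp))
      cn[hit] <- e$copy_number
    }
  }
  cn
}

# Event table (gain/loss intervals) implied by a spec, for concordance.
spec_events <- function(spec, chrom_lengths) {
  rows <- list()
  if (spec$sex == "XO") {
    chrom <- grep("X$", names(chrom_lengths), value = TRUE)[1]
    rows[[1]] <- tibble(chrom = chrom, start_bp = 0,
                        end_bp = chrom_lengths[[chrom]], kind = "loss",
                        whole = TRUE)
  }
  if (nrow(spec$events)) {
    e <- spec$events
    base <- ifelse(is_chrx(e$chrom) & spec$sex != "XX", 1, 2)
    rows[[length(rows) + 1L]] <- tibble(
      chrom = e$chrom, start_bp = e$start_bp, end_bp = e$end_bp,
      kind = ifelse(e$copy_number > base, "gain", "loss"),
      whole = (e$end_bp - e$start_bp) >= 0.8 * chrom_lengths[e$chrom])
  }
  if (!length(rows))
    return(tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), kind = character(), whole = logical()))
  bind_rows(rows)
}

gc_response <- function(gc, coeffs) {
  2^(coeffs[1] * (gc - 0.40) + coeffs[2] * (gc - 0.40)^2)
}

#' Simulate per-window counts for a karyotype under kit noise
#'
#' Generates one or more amplification repeats of a sample with the given
#' karyotype, plus a matched diploid XX control (pure Poisson sampling at
#' the same depth, i.e. a deeply characterized unamplified control profile).
#' Fully reproducible from `seed`.
#'
#' @param grid An annotated `window_grid` (GC filled in).
#' @param karyotype A [karyotype_spec()].
#' @param kit A [kit_noise_profile()] (or kit name).
#' @param mean_reads_per_window Expected reads per full diploid window
#'   (default 30, the depth of a ~5M-read run in 20-kb windows).
#' @param seed Integer seed.
#' @param n_repeats Number of amplification repeats sharing the
#'   `shared_fraction` bias component (default 1).
#' @param control_kit Noise profile of the control (default `"none"`).
#' @param expectation If `TRUE`, return the expected counts `mu` instead of
#'   Poisson draws (dropout is also skipped) — with `bias_sd_log2 = 0` and a
#'   flat GC curve this gives exact copy-number ratios, useful for
#'   exactness checks.
#' @return A list of class `wga_sim`: `samples` (list of `window_counts`),
#'   `control` (`window_counts`), `karyotype`, `kit`; `$sample` is the first
#'   repeat.
#' @export
simulate_counts <- function(grid, karyotype = karyotype_spec("XX"),
                            kit = kit_noise_profile("PicoPLEX"),
                            mean_reads_per_window = 30, seed = 1L,
                            n_repeats = 1L,
                            control_kit = kit_noise_profile("none"),
                            expectation = FALSE) {
  if (is.character(kit)) kit <- kit_noise_profile(kit)
  if (is.character(control_kit)) control_kit <- kit_noise_profile(control_kit)
  if (mean_reads_per_window <= 0)
    abort("`mean_reads_per_window` must be positive.")
  cn <- karyotype_cn(karyotype, grid)
  width_frac <- (grid$end - grid$start) / grid_window_size(grid)

  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  base_mu <- mean_reads_per_window * (cn / 2) * width_frac
  samples <- vector("list", n_repeats)

  shared <- per_chrom_ar1(grid, kit$autocorr,
                          kit$bias_sd_log2 * sqrt(kit$shared_fraction))
  for (r in seq_len(n_repeats)) {
    private <- per_chrom_ar1(grid, kit$autocorr,
                             kit$bias_sd_log2 * sqrt(1 - kit$shared_fraction))
    b <- 2^(shared + private)
    g <- gc_response(grid$gc, kit$gc_bias_coeffs)
    # cap protects rpois from astronomically large means that extreme
    # bias-SD probes during calibration can produce; unreachable otherwise
    mu <- pmin(base_mu * g * b, 2^30)
    if (!expectation && kit$dropout_rate > 0) {
      drop <- runif(nrow(grid)) < kit$dropout_rate
      mu[drop] <- mu[drop] * 1e-3
    }
    count <- if (expectation) mu else rpois(length(mu), mu)
    samples[[r]] <- new_window_counts(
      count, grid,
      sample_id = sprintf("sim_%s_seed%d_rep%d", kit$kit, seed, r),
      kit = kit$kit, sample_type = "single_cell")
  }

  ctrl_cn <- karyotype_cn(karyotype_spec("XX"), grid)
  ctrl_mu <- mean_reads_per_window * (ctrl_cn / 2) * width_frac *
    gc_response(grid$gc, control_kit$gc_bias_coeffs) *
    2^(per_chrom_ar1(grid, control_kit$autocorr, control_kit$bias_sd_log2))
  ctrl_count <- if (expectation) ctrl_mu else rpois(length(ctrl_mu), ctrl_mu)
  control <- new_window_counts(ctrl_count, grid,
                               sample_id = sprintf("sim_control_seed%d", seed),
                               kit = control_kit$kit, sample_type = "bulk")

  structure(list(samples = samples, sample = samples[[1]], control = control,
                 karyotype = karyotype, kit = kit, seed = seed),
            class = "wga_sim")
}

per_chrom_ar1 <- function(grid, rho, sd) {
  if (sd == 0) return(numeric(nrow(grid)))
  unlist(lapply(split(seq_len(nrow(grid)), factor(grid$chrom,
                                                  unique(grid$chrom))),
                function(idx) ar1_series(length(idx), rho, sd)),
         use.names = FALSE)
}

# MAPD of a freshly simulated diploid sample at the QC window size, averaged
# over seeds — the objective function of calibrate_bias_sd().
simulated_mapd <- function(sigma, kit, grid, mean_reads_per_window,
                           qc_factor, seeds, span = 0.3) {
  kit$bias_sd_log2 <- sigma
  mean(vapply(seeds, function(s) {
    sim <- simulate_counts(grid, karyotype_spec("XX"), kit,
                           mean_reads_per_window, seed = s)
    g <- aggregate_grid(grid, qc_factor)
    sc <- aggregate_counts(sim$sample, qc_factor, grid)
    kc <- aggregate_counts(sim$control, qc_factor, grid)
    prof <- normalize_to_control(gc_correct(sc, g, span = span),
                                 gc_correct(kc, g, span = span), g)
    mapd(prof)
  }, numeric(1)))
}

#' Calibrate the amplification-bias SD against a target MAPD
#'
#' Finds the log2 bias SD `sigma` such that diploid counts simulated with
#' the kit's remaining parameters reproduce `target_mapd` at the QC window
#' size, by monotone bisection with a Monte-Carlo objective (MAPD averaged
#' over `seeds`, full GC-correction + control-normalization path).
#'
#' @param target_mapd Target MAPD (e.g. a kit's published value).
#' @param kit A [kit_noise_profile()] providing autocorrelation, GC curve
#'   and dropout; its `bias_sd_log2` is ignored.
#' @param grid Annotated `window_grid`.
#' @param mean_reads_per_window Simulated depth at the base window size.
#' @param qc_factor Aggregation factor to the MAPD evaluation window size
#'   (default 5: 100 kb on a 20-kb grid).
#' @param seeds Seeds averaged per evaluation (>= 5 recommended).
#' @param tol Absolute MAPD tolerance of the search (default 0.01).
#' @param sigma_max Upper search bound.
#' @return Calibrated `sigma`, with attribute `achieved` (the simulated
#'   MAPD at the returned value).
#' @export
calibrate_bias_sd <- function(target_mapd, kit = kit_noise_profile("bulk"),
                              grid = default_grid(),
                              mean_reads_per_window = 30, qc_factor = 5L,
                              seeds = 1:5, tol = 0.01, sigma_max = 8) {
  if (is.character(kit)) kit <- kit_noise_profile(kit)
  f <- function(sigma) simulated_mapd(sigma, kit, grid,
                                      mean_reads_per_window, qc_factor,
                                      seeds)
  floor_mapd <- f(0)
  if (target_mapd < floor_mapd - tol)
    abort(sprintf(
      "target MAPD %.3f is below the Poisson noise floor %.3f at this depth.",
      target_mapd, floor_mapd))
  if (target_mapd <= floor_mapd) return(structure(0, achieved = floor_mapd))
  lo <- 0; hi <- sigma_max
  f_hi <- f(hi)
  if (f_hi < target_mapd)
    abort(sprintf("target MAPD %.3f unreachable below sigma = %.1f (max %.3f).",
                  target_mapd, sigma_max, f_hi))
  val <- NA_real_
  for (it in 1:18) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - target_mapd) < tol / 2) break
    if (val < target_mapd) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, achieved = val)
}

#' Correlation of depth-normalized counts between two samples
#'
#' Pearson correlation of `count / total` over usable windows, the
#' reproducibility metric of the kit-comparison experiment (two
#' amplification repeats plotted against each other at the QC window size,
#' before any GC correction or control normalization).
#'
#' @param a,b `window_counts` on the same grid.
#' @param grid The shared `window_grid`.
#' @return Pearson correlation coefficient.
#' @export
count_correlation <- function(a, b, grid) {
  stopifnot(nrow(a) == nrow(grid), nrow(b) == nrow(grid))
  ok <- grid$usable
  if (sum(ok) < 3) abort("fewer than 3 usable windows.")
  cor(a$count[ok] / sum(a$count[ok]), b$count[ok] / sum(b$count[ok]))
}

# Mean repeat correlation of freshly simulated pairs at the QC window size —
# the shared objective of calibrate_shared_fraction() / calibrate_gc_bias().
simulated_repeat_cor <- function(kit, grid, mean_reads_per_window, qc_factor,
                                 seeds) {
  g <- aggregate_grid(grid, qc_factor)
  mean(vapply(seeds, function(s) {
    sim <- simulate_counts(grid, karyotype_spec("XX"), kit,
                           mean_reads_per_window, seed = s, n_repeats = 2L)
    count_correlation(aggregate_counts(sim$samples[[1]], qc_factor, grid),
                      aggregate_counts(sim$samples[[2]], qc_factor, grid),
                      g)
  }, numeric(1)))
}

#' Calibrate the repeat-shared bias fraction against a target correlation
#'
#' Finds `shared_fraction` such that two simulated amplification repeats
#' reach the target Pearson correlation of their depth-normalized raw count
#' profiles at the QC window size ([count_correlation()]).
#'
#' @param target_cor Target correlation (e.g. a kit's published
#'   repeat-vs-repeat value).
#' @inheritParams calibrate_bias_sd
#' @param tol Correlation tolerance.
#' @return Calibrated shared fraction in \[0, 1\], attribute `achieved`.
#' @export
calibrate_shared_fraction <- function(target_cor,
                                      kit = kit_noise_profile("GenomePlex"),
                                      grid = default_grid(),
                                      mean_reads_per_window = 30,
                                      qc_factor = 5L, seeds = 1:5,
                                      tol = 0.01) {
  if (is.character(kit)) kit <- kit_noise_profile(kit)
  f <- function(s) {
    kit$shared_fraction <- s
    simulated_repeat_cor(kit, grid, mean_reads_per_window, qc_factor, seeds)
  }
  lo <- 0; hi <- 1
  if (f(1) < target_cor - tol)
    abort("target correlation unreachable even with fully shared bias.")
  val <- NA_real_
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - target_cor) < tol / 2) break
    if (val < target_cor) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, achieved = val)
}

#' Calibrate the GC-response strength against a target correlation
#'
#' Finds the linear GC-bias coefficient (`gc_bias_coeffs[1]`) such that two
#' simulated repeats reach the target repeat correlation
#' ([count_correlation()] at the QC window size), holding the kit's other
#' parameters fixed. Used for chemistries whose reproducible bias is
#' dominated by a deterministic GC response (the response is shared between
#' repeats, so a stronger response raises the correlation without raising
#' post-GC-correction noise).
#'
#' @inheritParams calibrate_shared_fraction
#' @param c1_max Upper search bound for the coefficient.
#' @return Calibrated coefficient, attribute `achieved`.
#' @export
calibrate_gc_bias <- function(target_cor,
                              kit = kit_noise_profile("PicoPLEX"),
                              grid = default_grid(),
                              mean_reads_per_window = 30,
                              qc_factor = 5L, seeds = 1:5, tol = 0.01,
                              c1_max = 12) {
  if (is.character(kit)) kit <- kit_noise_profile(kit)
  f <- function(c1) {
    kit$gc_bias_coeffs[1] <- c1
    simulated_repeat_cor(kit, grid, mean_reads_per_window, qc_factor, seeds)
  }
  if (f(c1_max) < target_cor - tol)
    abort(sprintf("target correlation unreachable below c1 = %.1f.", c1_max))
  lo <- 0; hi <- c1_max
  val <- NA_real_
  for (it in 1:16) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    if (abs(val - target_cor) < tol / 2) break
    if (val < target_cor) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, achieved = val)
}
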