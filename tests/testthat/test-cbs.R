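# Oracle 1: arc_statistic agrees with the textbook pooled-variance t
# statistic computed by t.test(var.equal = TRUE).
test_that("arc_statistic matches the pooled two-sample t statistic", {
  set.seed(601)
  n <- 12L
  x <- rnorm(n)
  for (i in 0:(n - 1)) for (j in (i + 1):n) {
    if (j - i >= n) next
    arc <- x[(i + 1):j]
    comp <- x[-((i + 1):j)]
    if (length(arc) < 2 || length(comp) < 2) next
    want <- abs(unname(t.test(arc, comp, var.equal = TRUE)$statistic))
    expect_equal(arc_statistic(x, i, j), want, tolerance = 1e-10)
  }
})

test_that("arc_statistic is symmetric under arc/complement exchange", {
  set.seed(602)
  x <- rnorm(20)
  # complement of [i, j) as an arc of the circle: statistic is identical, so
  # scanning ordinary arcs covers wrapped arcs too
  expect_equal(arc_statistic(x, 3, 11),
               abs(unname(t.test(x[4:11], x[-(4:11)],
                                 var.equal = TRUE)$statistic)))
  expect_equal(arc_statistic(x, 0, 5), arc_statistic(x, 5, 20))
})

test_that("arc_statistic validates bounds", {
  x <- rnorm(5)
  expect_error(arc_statistic(x, -1, 2))
  expect_error(arc_statistic(x, 2, 2))
  expect_error(arc_statistic(x, 0, 5))  # complement empty
})

# Oracle 2: the compiled max-arc scan agrees with an exhaustive R search.
test_that("cpp_max_arc equals an exhaustive R search", {
  r_max_arc <- function(x, min_w) {
    n <- length(x)
    best <- list(stat = -1, i = NA, j = NA)
    for (i in 0:(n - min_w)) for (j in (i + min_w):n) {
      if (n - (j - i) < min_w) next
      s <- arc_statistic(x, i, j)
      if (s > best$stat) best <- list(stat = s, i = i, j = j)
    }
    best
  }
  for (seed in 1:5) {
    set.seed(700 + seed)
    x <- rnorm(25) + rep(c(0, 0.8, 0), c(8, 9, 8))
    got <- wgacnv:::cpp_max_arc(x, 3L, FALSE)
    want <- r_max_arc(x, 3L)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$stat, want$stat, tolerance = 1e-10)
  }
})

cbs_profile <- function(x, window_size = 1000L) {
  grid <- make_window_grid(c(chr1 = length(x) * window_size),
                           window_size = window_size)
  grid$gc <- 0.4; grid$n_fraction <- 0
  toy_profile(grid, x)
}

fast_cbs <- function(...) cbs_config(n_permutations = 1000L, ...)

test_that("a perfect step is segmented exactly", {
  set.seed(603)
  x <- c(rnorm(60, 0, 0.05), rnorm(40, 1, 0.05))
  fit <- segment_cbs(cbs_profile(x), fast_cbs())
  expect_s3_class(fit, "cbs_fit")
  expect_equal(nrow(fit$segments), 2L)
  expect_equal(fit$segments$n_windows, c(60L, 40L))
  expect_equal(fit$segments$mean_log2_ratio, c(mean(x[1:60]), mean(x[61:100])),
               tolerance = 1e-12)
  expect_equal(fit$segments$start_bp, c(0, 60000))
})

test_that("a single-copy-gain step is localized within 2 windows", {
  set.seed(604)
  x <- c(rnorm(200, 0, 0.1), rnorm(200, log2(1.5), 0.1))
  fit <- segment_cbs(cbs_profile(x), fast_cbs())
  expect_equal(nrow(fit$segments), 2L)
  expect_lte(abs(fit$segments$end_window[1] - 200L), 2L)
  expect_equal(fit$segments$mean_log2_ratio[2], log2(1.5), tolerance = 0.05)
})

test_that("pure noise yields a single segment", {
  for (seed in 1:5) {
    set.seed(800 + seed)
    x <- rnorm(300, 0, 0.2)
    fit <- segment_cbs(cbs_profile(x), fast_cbs(seed = seed))
    expect_equal(nrow(fit$segments), 1L)
    expect_equal(fit$segments$n_windows, 300L)
  }
})

test_that("an interior event produces three segments (arc splitting)", {
  set.seed(605)
  x <- rnorm(300, 0, 0.1)
  x[121:180] <- x[121:180] + log2(1.5)   # 60-window interior gain
  fit <- segment_cbs(cbs_profile(x), fast_cbs())
  expect_equal(nrow(fit$segments), 3L)
  expect_lte(abs(fit$segments$start_window[2] - 121L), 2L)
  expect_lte(abs(fit$segments$end_window[2] - 180L), 2L)
  expect_equal(fit$segments$mean_log2_ratio[2], log2(1.5), tolerance = 0.05)
})

test_that("segmentation is deterministic and shift-invariant", {
  set.seed(606)
  x <- rnorm(250, 0, 0.15)
  x[100:170] <- x[100:170] + 0.5
  f1 <- segment_cbs(cbs_profile(x), fast_cbs(seed = 42L))
  f2 <- segment_cbs(cbs_profile(x), fast_cbs(seed = 42L))
  expect_identical(f1$segments, f2$segments)
  f3 <- segment_cbs(cbs_profile(x + 2.5), fast_cbs(seed = 42L))
  expect_equal(f3$segments$start_window, f1$segments$start_window)
  expect_equal(f3$segments$mean_log2_ratio,
               f1$segments$mean_log2_ratio + 2.5, tolerance = 1e-12)
})

test_that("accepted boundaries are monotone in alpha", {
  set.seed(607)
  x <- rnorm(240, 0, 0.25)
  x[61:120] <- x[61:120] + 0.30     # moderate-evidence event
  x[181:240] <- x[181:240] - 0.25   # weaker event
  prof <- cbs_profile(x)
  bounds <- lapply(c(0.001, 0.01, 0.05, 0.2), function(a)
    segment_cbs(prof, cbs_config(alpha = a, n_permutations = 2000L,
                                 seed = 9L, prune_sd = 0))$segments$start_window)
  for (k in seq_len(length(bounds) - 1))
    expect_true(all(bounds[[k]] %in% bounds[[k + 1]]))
})

test_that("segments partition the unmasked windows per chromosome", {
  grid <- toy_grid(120L, 80L)
  set.seed(608)
  x <- rnorm(200, 0, 0.2)
  x[1:60] <- x[1:60] + 0.8
  mask <- rep(FALSE, 200); mask[c(10, 90, 150)] <- TRUE
  prof <- toy_profile(grid, x, mask = mask)
  fit <- segment_cbs(prof, fast_cbs())
  expect_equal(sum(fit$segments$n_windows), sum(!mask))
  # per chromosome, consecutive segments abut in window index space
  for (ch in unique(fit$segments$chrom)) {
    s <- fit$segments[fit$segments$chrom == ch, ]
    expect_true(all(diff(s$start_window) > 0))
  }
})

test_that("binary mode finds single changepoints", {
  set.seed(609)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 0.6, 0.1))
  fit <- segment_cbs(cbs_profile(x), fast_cbs(mode = "binary"))
  expect_equal(nrow(fit$segments), 2L)
  expect_lte(abs(fit$segments$end_window[1] - 100L), 2L)
})

test_that("pruning merges segments with close means", {
  set.seed(610)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 0.6, 0.1))
  prof <- cbs_profile(x)
  # threshold far above the step: everything merges back to one segment
  noise_sd <- mapd(prof) / (sqrt(2) * qnorm(0.75))
  f_loose <- segment_cbs(prof, fast_cbs(prune_sd = 0.6 / noise_sd + 1))
  expect_equal(nrow(f_loose$segments), 1L)
  # prune_sd = 0 keeps the split
  f_keep <- segment_cbs(prof, fast_cbs(prune_sd = 0))
  expect_equal(nrow(f_keep$segments), 2L)
})

test_that("tidy and glance summarize a cbs_fit", {
  set.seed(611)
  x <- c(rnorm(80, 0, 0.1), rnorm(80, 1, 0.1))
  fit <- segment_cbs(cbs_profile(x), fast_cbs())
  expect_identical(tidy(fit), fit$segments)
  g <- glance(fit)
  expect_equal(g$n_segments, nrow(fit$segments))
  expect_equal(g$n_windows, 160L)
  expect_equal(g$noise_sd, fit$noise_sd)
})
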