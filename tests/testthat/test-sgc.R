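pipeline_samples <- function(sim) {
  ann <- annotate_gait(sim$rotation, sim$force)
  list(samples = normalize_cycles(sim$rotation, ann$cycles), ann = ann)
}

test_that("time normalization maps frames to [0, 100) with the right counts", {
  sim <- noiseless_sim()
  ps <- pipeline_samples(sim)
  s <- ps$samples
  expect_true(all(s$pct >= 0 & s$pct < 100))
  # cycle starts map to pct 0; the midpoint frame of a 72-frame cycle to 50
  first <- s[s$cycle_index == 1 & s$segment == "PELVIS", ]
  expect_equal(first$pct[first$frame == 0], 0)
  expect_equal(first$pct[first$frame == 36], 50)
  # a 72-frame cycle yields 72 samples per segment
  expect_equal(nrow(first), 72)
  expect_error(normalize_cycles(sim$rotation, ps$ann$cycles[0, ]), "no complete")
})

test_that("an SGC requires at least three cycles and reproduces constants", {
  sim <- noiseless_sim()
  ps <- pipeline_samples(sim)
  two <- ps$samples[ps$samples$cycle_index <= 2, ]
  expect_error(fit_sgc(two), "at least 3 gait cycles")

  const <- ps$samples
  const$rotation_deg <- 4.2
  for (sm in list("auto", 0.5)) {
    sgc <- fit_sgc(const, smoothing = sm)
    for (seg in segment_labels()) {
      expect_equal(sgc$curves[[seg]], rep(4.2, 101))
    }
  }
})

test_that("the SGC grid is always the 101 points 0..100 with finite values", {
  for (seed in c(1, 5)) {
    sim <- noisy_sim(seed)
    sgc <- fit_sgc(pipeline_samples(sim)$samples)
    expect_equal(sgc$curves$pct, 0:100)
    expect_equal(nrow(sgc$curves), 101)
    expect_true(all(is.finite(as.matrix(sgc$curves))))
  }
})

test_that("a noiseless single-harmonic curve is recovered to high accuracy", {
  sim <- noiseless_sim()
  sgc <- fit_sgc(pipeline_samples(sim)$samples)
  pelvis <- sgc$curves$PELVIS
  amp <- (max(pelvis) - min(pelvis)) / 2
  expect_lt(abs(amp - 6) / 6, 0.02)               # amplitude within 2%
  expect_lte(abs(sgc$grid[which.max(pelvis)] - 25), 1)  # phase within 1% of cycle
  # against the closed-form sinusoid on the whole grid
  truth <- 6 * sin(2 * pi * sgc$grid / 100)
  expect_lt(max(abs(pelvis - truth)), 0.12)
})

test_that("pooling three noisy cycles beats any single raw cycle", {
  sim <- noisy_sim(8)
  ps <- pipeline_samples(sim)
  sgc <- fit_sgc(ps$samples)
  truth_fun <- function(pct) 6 * sin(2 * pi * pct / 100)
  rmse_sgc <- sqrt(mean((sgc$curves$PELVIS - truth_fun(sgc$grid))^2))
  rmse_raw <- purrr::map_dbl(1:3, function(i) {
    d <- ps$samples[ps$samples$cycle_index == i & ps$samples$segment == "PELVIS", ]
    sqrt(mean((d$rotation_deg - truth_fun(d$pct))^2))
  })
  expect_lt(rmse_sgc, min(rmse_raw))
})

test_that("as smoothing -> 0 the noiseless SGC approaches the interpolant", {
  sim <- noiseless_sim()
  s <- pipeline_samples(sim)$samples
  sgc <- fit_sgc(s, smoothing = 1e-9)
  truth <- 6 * sin(2 * pi * (0:100) / 100)
  expect_lt(max(abs(sgc$curves$PELVIS - truth)), 0.02)
})

test_that("recordings at different cadences give comparable SGCs", {
  fast <- noiseless_sim(stride_duration = 1.0)   # 60 frames per cycle
  slow <- noiseless_sim(stride_duration = 1.4)   # 84 frames per cycle
  sgc_f <- fit_sgc(pipeline_samples(fast)$samples)
  sgc_s <- fit_sgc(pipeline_samples(slow)$samples)
  rmse <- sqrt(mean((sgc_f$curves$T8 - sgc_s$curves$T8)^2))
  expect_lt(rmse, 0.1)
})

test_that("jittered cycle boundaries still yield one well-defined SGC maximum", {
  # a continuous 72-frame-period sinusoid cut at uneven cycle boundaries:
  # per-cycle raw maxima fall at different percents, the pooled SGC has a
  # single maximum over the period
  frames <- 0:219
  rot <- tibble::as_tibble(c(
    list(frame = frames, time_s = frames / 60),
    stats::setNames(lapply(segment_labels(), function(s) {
      6 * sin(2 * pi * frames / 72)
    }), segment_labels())
  ))
  cycles <- tibble::tibble(
    cycle_index = 1:3, start_frame = c(0L, 68L, 140L),
    end_frame = c(68L, 140L, 216L),
    n_frames = c(68L, 72L, 76L), stance_right_pct = 60
  )
  samples <- normalize_cycles(rot, cycles)
  raw_max_pct <- purrr::map_dbl(1:3, function(i) {
    d <- samples[samples$cycle_index == i & samples$segment == "PELVIS", ]
    d$pct[which.max(d$rotation_deg)]
  })
  expect_gt(diff(range(raw_max_pct)), 2)  # raw maxima disagree
  sgc <- fit_sgc(samples)
  y <- sgc$curves$PELVIS[1:100]
  turning <- sum(abs(diff(sign(diff(y)))) > 0)
  expect_equal(turning, 2)  # exactly one max and one min
})

test_that("standardization preserves a superimposed rhythm", {
  sim <- noiseless_sim(preset = "superimposed")
  ps <- pipeline_samples(sim)
  sgc <- fit_sgc(ps$samples)
  harmonic_power <- function(pct, y, k) {
    z <- sum((y - mean(y)) * exp(-2i * pi * k * pct / 100)) / length(y)
    4 * Mod(z)^2  # squared amplitude of harmonic k
  }
  p_sgc <- harmonic_power(sgc$grid[1:100], sgc$curves$PELVIS[1:100], 3)
  p_raw <- mean(purrr::map_dbl(1:3, function(i) {
    d <- ps$samples[ps$samples$cycle_index == i & ps$samples$segment == "PELVIS", ]
    harmonic_power(d$pct, d$rotation_deg, 3)
  }))
  expect_gt(p_sgc, 0.5 * p_raw)
})

test_that("periodic fitting closes the curve exactly", {
  sim <- noisy_sim(3)
  sgc <- fit_sgc(pipeline_samples(sim)$samples, periodic = TRUE)
  for (seg in c("PELVIS", "T8", "C7")) {
    expect_equal(sgc$curves[[seg]][1], sgc$curves[[seg]][101], tolerance = 1e-8)
  }
})

test_that("all-NA segments are omitted with a warning, NA samples excluded", {
  sim <- noisy_sim(2)
  s <- pipeline_samples(sim)$samples
  s$rotation_deg[s$segment == "C7"] <- NA
  expect_warning(sgc <- fit_sgc(s), "C7")
  expect_false("C7" %in% names(sgc$curves))
  expect_equal(sgc$segments_omitted, "C7")
  # scattered NAs elsewhere are just excluded from the fit
  s2 <- pipeline_samples(sim)$samples
  s2$rotation_deg[which(s2$segment == "T8")[c(3, 50)]] <- NA
  sgc2 <- fit_sgc(s2)
  expect_true(all(is.finite(sgc2$curves$T8)))
})

test_that("SGC tables round-trip losslessly through CSV", {
  sim <- noisy_sim(5)
  ann <- annotate_gait(sim$rotation, sim$force)
  sgc <- fit_sgc(normalize_cycles(sim$rotation, ann$cycles),
                 mean_stance_pct = ann$mean_stance_pct)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sgc_csv(sgc, path)
  back <- read_sgc_csv(path)
  expect_equal(back$curves, sgc$curves, tolerance = 1e-12)
  expect_equal(back$n_cycles_used, sgc$n_cycles_used)
  expect_equal(back$mean_stance_pct, sgc$mean_stance_pct)
  expect_equal(back$curves$pct, 0:100)
  expect_true(all(diff(back$curves$pct) > 0))

  # malformed grid is rejected
  broken <- withr::local_tempfile(fileext = ".csv")
  tab <- sgc$curves[-5, ]
  readr::write_csv(tab, broken)
  expect_error(read_sgc_csv(broken), "malformed SGC grid")
})

test_that("tidy and glance summarize an SGC", {
  sim <- noisy_sim(1)
  ann <- annotate_gait(sim$rotation, sim$force)
  sgc <- fit_sgc(normalize_cycles(sim$rotation, ann$cycles),
                 mean_stance_pct = ann$mean_stance_pct)
  td <- tidy(sgc)
  expect_equal(nrow(td), 18 * 101)
  expect_equal(levels(td$segment), segment_labels())
  gl <- glance(sgc)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_cycles_used, 3L)
  expect_equal(gl$n_segments, 18L)
})
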