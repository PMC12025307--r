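test_that("noiseless detection recovers ground-truth contact times", {
  sim <- noiseless_sim()
  ev <- detect_events(sim$force)
  ic_r <- ev$time[ev$kind == "IC_RIGHT"]
  is_r <- ev$time[ev$kind == "IS_RIGHT"]
  expect_length(ic_r, 4)
  expect_true(all(abs(ic_r - sim$truth$ic_right_times) <= 1 / 120))
  expect_true(all(abs(is_r - sim$truth$is_right_times) <= 1 / 120))
  ic_l <- ev$time[ev$kind == "IC_LEFT"]
  expect_true(all(abs(ic_l - sim$truth$ic_left_times) <= 1 / 120))
})

test_that("detector equals the brute-force threshold scan on noiseless input", {
  for (seed in c(1, 7)) {
    sim <- noiseless_sim(seed = seed, n_strides = 5)
    ev <- detect_events(sim$force)
    for (foot in c("right", "left")) {
      f <- sim$force[[paste0("force_", foot)]]
      thr <- 0.05 * stats::quantile(f, 0.95, names = FALSE)
      oracle <- brute_force_events(f, thr)
      expect_equal(
        ev$force_sample_index[ev$kind == paste0("IC_", toupper(foot))],
        oracle$ic_samples
      )
      expect_equal(
        ev$force_sample_index[ev$kind == paste0("IS_", toupper(foot))],
        oracle$is_samples
      )
    }
  }
})

test_that("IC frame error stays within +/-3 frames across 20 noisy recordings", {
  errs <- purrr::map_int(1:20, function(seed) {
    sim <- noisy_sim(seed)
    ev <- detect_events(sim$force)
    det <- ev$frame_index[ev$kind == "IC_RIGHT"]
    true_frames <- round(sim$truth$ic_right_times * 60)
    max(purrr::map_int(true_frames, ~ min(abs(det - .x))))
  })
  expect_lte(max(errs), 3L)
})

test_that("degenerate force traces are handled explicitly", {
  sim <- noiseless_sim()
  flat <- sim$force
  flat$force_left <- 0
  flat$force_right <- 0
  expect_warning(ev <- detect_events(flat), "no contact")
  expect_equal(nrow(ev), 0)
  expect_error(detect_events(sim$force, threshold_frac = 0), "threshold_frac")
  expect_error(detect_events(sim$force, threshold_frac = 1), "threshold_frac")
})

test_that("longer debounce windows never increase the event count", {
  sim <- noisy_sim(4)
  counts <- purrr::map_int(c(0.01, 0.05, 0.1, 0.2, 0.3),
                           ~ nrow(detect_events(sim$force, min_phase_duration = .x)))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-foot events alternate IC, IS, IC, IS", {
  sim <- noisy_sim(6)
  ev <- detect_events(sim$force)
  for (foot in c("right", "left")) {
    kinds <- sub("_.*", "", ev$kind[ev$foot == foot])
    expect_equal(kinds[1], "IC")
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
    expect_true(all(diff(ev$time[ev$foot == foot]) > 0))
  }
})

test_that("phase encoding recovers the 60/40 stance-swing split", {
  sim <- noiseless_sim()
  ev <- detect_events(sim$force)
  phases <- encode_phases(ev, nrow(sim$rotation))
  cycles <- segment_cycles(phases, ev)
  # one full cycle of 72 frames at 60% stance has 43 stance frames
  # (round-half-up of 43.2)
  for (i in seq_len(nrow(cycles))) {
    sel <- phases$frame >= cycles$start_frame[i] & phases$frame < cycles$end_frame[i]
    expect_equal(sum(phases$stance_right[sel]), 43)
  }
  expect_true(all(abs(cycles$stance_right_pct - 60) <= 100 / 72))
})

test_that("empty event lists leave every frame unannotated", {
  empty <- detect_events(tibble::tibble(sample = 0:9, time_s = 0:9 / 120,
                                        force_left = 0, force_right = 0)) |>
    suppressWarnings()
  phases <- encode_phases(empty, 20)
  expect_true(all(is.na(phases$stance_right)))
  expect_true(all(is.na(phases$stance_left)))
})

test_that("frames before the first event of a foot are unannotated", {
  sim <- noiseless_sim()
  # drop the first left stance so the left foot's first event comes late
  frc <- sim$force
  first_left <- sim$truth$ic_left_times[1]
  in_first <- frc$time_s >= first_left & frc$time_s < first_left + 0.72
  frc$force_left[in_first] <- 0
  ev <- detect_events(frc)
  phases <- encode_phases(ev, nrow(sim$rotation))
  first_ic_left_frame <- min(ev$frame_index[ev$kind == "IC_LEFT"])
  expect_true(all(is.na(phases$stance_left[phases$frame < first_ic_left_frame])))
  expect_false(anyNA(phases$stance_left[phases$frame >= first_ic_left_frame]))
})

test_that("synchronization pairs frame k with force sample 2k", {
  sim <- noiseless_sim()
  sync <- synchronize(sim$force, sim$rotation)
  expect_equal(sync$force_sample[sync$frame == 0], 0)
  expect_equal(sync$force_sample[sync$frame == 30], 60)  # t = 0.5 s
  expect_equal(sync$force_sample, 2L * sync$frame)
  expect_true(all(sync$annotated))
})

test_that("a truncated force stream marks exactly the trailing frames", {
  sim <- noiseless_sim()
  half <- sim$force[sim$force$sample < floor(nrow(sim$force) / 2), ]
  expect_warning(sync <- synchronize(half, sim$rotation), "trailing")
  cutoff <- max(half$sample)
  expect_equal(sync$annotated, 2L * sync$frame <= cutoff)
  expect_true(all(is.na(sync$force_right[!sync$annotated])))
})

test_that("n right initial contacts delimit n - 1 complete, tiling cycles", {
  sim <- noiseless_sim()                        # 4 ICs
  ev <- detect_events(sim$force)
  phases <- encode_phases(ev, nrow(sim$rotation))
  cycles <- segment_cycles(phases, ev)
  expect_equal(nrow(cycles), 3)
  # cycles tile: end(i) == start(i+1)
  expect_equal(cycles$end_frame[-3], cycles$start_frame[-1])

  # fencepost base case: exactly 2 ICs span 1 cycle
  two <- ev[ev$time < 1.3 | ev$kind != "IC_RIGHT", ]
  two <- two[!(two$kind == "IC_RIGHT" & two$time > 1.3), ]
  cyc1 <- segment_cycles(phases, two)
  expect_equal(nrow(cyc1), 1)
  expect_equal(cyc1$start_frame, 0L)
  expect_equal(cyc1$end_frame, 72L)

  one <- ev[ev$kind != "IC_RIGHT", ]
  expect_warning(none <- segment_cycles(phases, one), "fewer than 2")
  expect_equal(nrow(none), 0)
})

test_that("stance and swing percentages sum to 100 per cycle (random fixtures)", {
  for (seed in c(2, 9, 13)) {
    sim <- noisy_sim(seed, n_strides = sample(4:6, 1))
    ann <- annotate_gait(sim$rotation, sim$force)
    for (i in seq_len(nrow(ann$cycles))) {
      sel <- ann$phases$frame >= ann$cycles$start_frame[i] &
        ann$phases$frame < ann$cycles$end_frame[i]
      stance <- sum(ann$phases$stance_right[sel])
      swing <- sum(!ann$phases$stance_right[sel])
      expect_equal(100 * (stance + swing) / ann$cycles$n_frames[i], 100)
    }
    # cycles tile the annotated region without overlap
    expect_true(all(ann$cycles$end_frame[-nrow(ann$cycles)] ==
                      ann$cycles$start_frame[-1]))
  }
})
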