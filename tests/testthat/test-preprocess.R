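test_that("20-h window keeps boundary exams and re-references times to t0", {
  d <- delivery_record("w", data.frame(time = c(5, 30, 35), dilation = c(2, 4, 6),
                                       effacement = c(50, 60, 70),
                                       station = c(-2, -1, 0)),
                       delivery_time = 40)
  w <- window_and_reference(d)
  expect_equal(w$exams$time, c(0, 5))
  expect_equal(w$exams$dilation, c(4, 6))
  expect_equal(w$delivery_time, 10)

  ## single exam exactly at delivery_time - 20 is kept, defining t0 = 0
  d2 <- delivery_record("b", data.frame(time = 20, dilation = 3,
                                        effacement = 50, station = -1),
                        delivery_time = 40)
  w2 <- window_and_reference(d2)
  expect_equal(w2$exams$time, 0)

  ## all exams before the window signal exclusion
  d3 <- delivery_record("x", data.frame(time = c(1, 5), dilation = c(2, 3),
                                        effacement = c(40, 50),
                                        station = c(-2, -2)),
                        delivery_time = 40)
  expect_error(window_and_reference(d3), class = "laborgp_excluded")
})

test_that("descending-dilation and 5-minute filters drop the specified exams", {
  ex <- data.frame(time = c(0, 2, 3, 5),
                   dilation = c(3, 5, 4, 6),
                   effacement = c(40, 50, 55, 60),
                   station = c(-2, -1, -1, 0))
  f <- filter_exams(ex)
  expect_equal(f$time, c(0, 2, 5))
  expect_equal(f$dilation, c(3, 5, 6))

  ex2 <- data.frame(time = c(0, 3 / 60), dilation = c(3, 3),
                    effacement = c(40, 40), station = c(-2, -2))
  expect_equal(nrow(filter_exams(ex2)), 1)
  expect_equal(filter_exams(ex2)$time, 0)

  empty <- ex[0, ]
  expect_equal(nrow(filter_exams(empty)), 0)

  ## idempotence
  expect_identical(filter_exams(f), f)
})

test_that("missing fields are linearly interpolated only with both neighbors", {
  ex <- data.frame(time = c(0, 2, 4),
                   dilation = c(4, NA, 8),
                   effacement = c(40, 50, 60),
                   station = c(-2, -1, 0))
  out <- interpolate_missing(ex)
  expect_equal(out$dilation, c(4, 6, 8))

  ## missing at the last exam: no later neighbor, exam removed
  ex2 <- data.frame(time = c(0, 2, 4),
                    dilation = c(4, 5, NA),
                    effacement = c(40, 50, 60),
                    station = c(-2, -1, 0))
  expect_equal(interpolate_missing(ex2)$time, c(0, 2))

  ## complete input returned unchanged
  ex3 <- data.frame(time = c(0, 1), dilation = c(2, 3),
                    effacement = c(10, 20), station = c(-3, -2))
  expect_identical(interpolate_missing(ex3), ex3)
})

test_that("cumulative contraction count uses the closed interval [0, t]", {
  on <- c(0.2, 0.5, 1.0)
  expect_equal(cumulative_contractions(on, 0.8), 2)
  expect_equal(cumulative_contractions(on, 0.1), 0)
  expect_equal(cumulative_contractions(on, 0.5), 2)  # onset at t counted
  expect_error(cumulative_contractions(on, -1), "before t0")
  ## non-decreasing in t, total at the end
  ts <- seq(0, 2, by = 0.1)
  counts <- cumulative_contractions(on, ts)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], length(on))
})

test_that("intervention flags are inclusive at the exam time", {
  d <- delivery_record("f", data.frame(time = c(0, 3), dilation = c(2, 4),
                                       effacement = c(40, 60),
                                       station = c(-2, -1)),
                       epidural_time = 2, delivery_time = 6)
  expect_equal(annotate_flags(d, 3)$epidural, 1L)
  expect_equal(annotate_flags(d, 1)$epidural, 0L)
  expect_equal(annotate_flags(d, 2)$epidural, 1L)   # boundary inclusive
  expect_equal(annotate_flags(d, 3)$rom, 0L)        # absent event -> 0
})

test_that("the full cleaning pipeline reproduces the hand-worked fixture", {
  d <- preprocess_delivery(fixture_delivery())
  expect_equal(d$exams$time, c(0, 2, 5, 8, 11))
  expect_equal(d$exams$dilation, c(3, 5, 6, 7, 9))
  expect_equal(d$exams$effacement, c(40, 50, 70, 80, 90))
  expect_equal(d$exams$station, c(-2, -2, 0, 1, 2))
  expect_equal(d$contraction_onsets, c(1, 1.5, 4, 6, 7, 10, 10.5))
  expect_equal(d$epidural_time, 6.5)
})

test_that("transition samples are causal with predictors from the previous exam", {
  tr <- fixture_transitions()
  expect_equal(nrow(tr), 4)
  expect_equal(tr$prev_dilation, c(3, 5, 6, 7))
  expect_equal(tr$target_dilation, c(5, 6, 7, 9))
  expect_equal(tr$target_station, c(-2, 0, 1, 2))
  expect_equal(tr$cum_contractions, c(2, 3, 5, 7))
  expect_equal(tr$epidural, c(0, 0, 1, 1))
  expect_equal(tr$induced, rep(1L, 4))
  expect_equal(tr$elapsed, c(2, 3, 3, 3))
  expect_true(all(tr$elapsed > 5 / 60))
  ## monotone prev_dilation within the delivery
  expect_true(!is.unsorted(tr$prev_dilation))

  ## causality audit: recompute each predictor from data strictly before
  ## the target exam time
  d <- preprocess_delivery(fixture_delivery())
  for (i in seq_len(nrow(tr))) {
    tt <- tr$exam_time[i]
    past <- d$exams[d$exams$time < tt, ]
    prev <- past[nrow(past), ]
    expect_equal(tr$prev_dilation[i], prev$dilation)
    expect_equal(tr$prev_station[i], prev$station)
    expect_equal(tr$prev_effacement[i], prev$effacement)
    ## contraction count/flags at the target time use only events <= tt,
    ## all of which occurred before the exam outcome is known
    expect_equal(tr$cum_contractions[i],
                 sum(d$contraction_onsets <= tt))
    expect_equal(tr$epidural[i],
                 as.integer(!is.na(d$epidural_time) && d$epidural_time <= tt))
  }

  ## fewer than 2 exams -> no samples
  d1 <- d; d1$exams <- d1$exams[1, ]
  expect_equal(nrow(build_transitions(d1)), 0)
})

test_that("CSV round trip preserves deliveries and transitions", {
  dir <- withr::local_tempdir()
  dels <- list(fixture_delivery())
  paths <- write_delivery_tables(dels, dir)
  back <- read_delivery_tables(paths[1], paths[2], paths[3])
  expect_equal(back[[1]]$exams$dilation, dels[[1]]$exams$dilation)
  expect_equal(back[[1]]$delivery_time, dels[[1]]$delivery_time)
  expect_equal(back[[1]]$induced, TRUE)
  tr <- build_transition_table(back)
  expect_equal(tr, fixture_transitions())
  f <- file.path(dir, "transitions.csv")
  write_transitions(tr, f)
  tr2 <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(tr2$target_dilation, tr$target_dilation)
})
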