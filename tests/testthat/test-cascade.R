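test_that("a fresh cascade starts at stage 1 with an empty green window", {
  st <- init_cascade()
  expect_s3_class(st, "cascade_state")
  expect_equal(st$stage, 1L)
  expect_equal(st$denominator, 0L)
  expect_equal(st$zone, "GREEN")
  expect_identical(init_cascade(), init_cascade())

  st1 <- cascade_update(st, 1L)
  expect_equal(st1$class1_count, 1L)
  expect_equal(st1$denominator, 1L)
  expect_equal(st1$fraction, 1)
})

test_that("zone thresholds follow the 26/35 traffic-light rule", {
  counts <- 0:50
  expect_equal(cascade_zone(counts),
               ifelse(counts >= 35, "RED",
                      ifelse(counts >= 26, "YELLOW", "GREEN")))
})

test_that("all-class-0 streams never switch and stay green", {
  r <- run_prediction_stream(rep(0L, 200))
  expect_equal(nrow(r$switches), 0)
  expect_true(all(r$annotations$stage == 1L))
  expect_true(all(r$annotations$zone == "GREEN"))
  expect_equal(r$annotations$denominator, pmin(1:200, 50))
})

test_that("the count-35 rule fires exactly when 35 of the last 50 are class 1", {
  # 100 class-0 frames then all class-1: count first reaches 35 at frame 135
  r <- run_prediction_stream(c(rep(0L, 100), rep(1L, 200)))
  expect_equal(r$switches$frame[1], 135L)

  # 16 zeros + 34 ones -> 34/50, YELLOW, no switch; one more 1 evicts a 0
  st <- init_cascade()
  for (p in c(rep(0L, 16), rep(1L, 34))) st <- cascade_update(st, p)
  expect_equal(st$class1_count, 34L)
  expect_equal(st$zone, "YELLOW")
  expect_equal(st$stage, 1L)
  st <- cascade_update(st, 1L)
  expect_equal(st$zone, "RED")
  expect_equal(st$stage, 2L)
  expect_equal(st$switch_log$frame, 51L)
})

test_that("stage 4 never switches and displays no fraction", {
  r <- run_prediction_stream(rep(1L, 200))
  expect_equal(r$switches$frame, c(35L, 70L, 105L))
  ann <- r$annotations
  expect_true(all(ann$stage[106:200] == 4L))
  expect_true(all(is.na(ann$fraction[106:200])))
  expect_true(all(is.na(ann$zone[106:200])))
  expect_true(all(!is.na(ann$fraction[1:105])))
  # stages are nondecreasing with at most 3 switches
  expect_true(all(diff(ann$stage) >= 0))
  expect_lte(nrow(r$switches), 3)
})

test_that("incremental updates agree with the naive recount reference", {
  withr::with_seed(31, {
    for (i in 1:40) {
      n <- sample(100:2000, 1)
      p <- rbinom(n, 1, runif(1, 0.4, 0.8))
      r <- run_prediction_stream(p)
      expect_equal(r$switches$frame, naive_switch_frames(p))
    }
    # window kept across switches when reset is disabled
    p <- rbinom(500, 1, 0.7)
    st <- init_cascade(reset_on_switch = FALSE)
    r <- run_prediction_stream(p, state = st)
    expect_equal(r$switches$frame, naive_switch_frames(p, reset = FALSE))
  })
})

test_that("cascade_update and the stream core share semantics", {
  withr::with_seed(17, {
    p <- rbinom(400, 1, 0.6)
    st <- init_cascade()
    for (x in p) st <- cascade_update(st, x)
    r <- run_prediction_stream(p)
    expect_equal(st$switch_log, r$switches)
    expect_equal(st$stage, max(r$annotations$stage))
  })
})

test_that("closed streams and bad predictions are rejected", {
  st <- close_cascade(init_cascade())
  expect_error(cascade_update(st, 1L), "closed")
  expect_error(cascade_update(init_cascade(), 2), "0 or 1")
  expect_error(run_prediction_stream(c(0, 1, 2)), "0/1")
})

test_that("the truth-oracle insertion stream switches at frames 135, 835, 935", {
  seqd <- fixture("default_sequence", function() {
    simulate_insertion_sequence(seed = 301)
  })
  r <- run_stream(seqd, "oracle")
  expect_equal(r$switches$frame, c(135L, 835L, 935L))
  expect_true(all(r$annotations$stage[936:1150] == 4L))
  expect_true(all(is.na(r$annotations$fraction[936:1150])))
  expect_equal(r$accuracy, 1)  # oracle predictions label every frame correctly
})
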