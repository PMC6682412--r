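# Centroid tracking: optimal linking vs brute force, track assembly,
# quality filters, Sytox fate calls and decision-time extraction.

test_that("simple links respect the distance limit", {
  a <- data.frame(x = 10, y = 10)
  b <- data.frame(x = 12, y = 10)
  expect_equal(nrow(link_frames(a, b, max_dist = 10)), 1)
  far <- data.frame(x = 22, y = 10)
  expect_equal(nrow(link_frames(a, far, max_dist = 10)), 0)
  expect_equal(nrow(link_frames(a[0, ], b, max_dist = 10)), 0)
})

test_that("optimal linking equals the exhaustive minimum on small instances", {
  set.seed(20)
  for (rep in 1:40) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- data.frame(x = runif(na, 0, 40), y = runif(na, 0, 40))
    b <- data.frame(x = runif(nb, 0, 40), y = runif(nb, 0, 40))
    max_dist <- runif(1, 5, 25)
    got <- link_frames(a, b, max_dist = max_dist)
    oracle <- brute_force_matching(a, b, max_dist)
    expect_equal(nrow(got), oracle$card)
    expect_equal(sum(got$dist), oracle$total, tolerance = 1e-6)
    expect_false(any(duplicated(got$a)))
    expect_false(any(duplicated(got$b)))
    expect_true(all(got$dist <= max_dist))
  }
  # crossing configuration: optimal matching picks the non-greedy pairing
  a <- data.frame(x = c(0, 4), y = c(0, 0))
  b <- data.frame(x = c(3, 9), y = c(0, 0))
  got <- link_frames(a, b, max_dist = 10)
  oracle <- brute_force_matching(a, b, 10)
  expect_equal(sum(got$dist), oracle$total, tolerance = 1e-9)
})

test_that("static cells give one track per cell spanning all frames", {
  set.seed(21)
  n <- 8; frames <- 10
  base <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100))
  cells <- do.call(rbind, lapply(1:frames, function(f)
    data.frame(frame = f, label = 1:n,
               x = base$x + rnorm(n, 0, 0.3),
               y = base$y + rnorm(n, 0, 0.3))))
  bt <- build_tracks(cells, max_dist = 5, min_len = 6)
  expect_equal(nrow(bt$tracks), n)
  expect_true(all(bt$tracks$length == frames))
  expect_true(all(bt$tracks$resolved))
  # conservation: every record belongs to exactly one track
  expect_false(any(is.na(bt$cells$track_id)))
})

test_that("tracks shorter than six consecutive frames are unresolved", {
  cells <- data.frame(frame = 1:5, label = 1, x = 10, y = 10)
  bt <- build_tracks(cells, max_dist = 5, min_len = 6)
  expect_false(bt$tracks$resolved[1])
  cells6 <- data.frame(frame = 1:6, label = 1, x = 10, y = 10)
  expect_true(build_tracks(cells6, max_dist = 5, min_len = 6)$tracks$resolved[1])
})

test_that("a cell disappearing and a new one appearing start separate tracks", {
  cells <- rbind(
    data.frame(frame = 1, label = 1, x = 10, y = 10),
    data.frame(frame = 2, label = 1, x = 60, y = 60))  # jump > max_dist
  bt <- build_tracks(cells, max_dist = 15, min_len = 1)
  expect_equal(nrow(bt$tracks), 2)
})

test_that("fate assignment requires Sytox overlap of the dilated cell region", {
  labels <- matrix(0L, 40, 40); labels[18:24, 18:24] <- 1L
  syt_dead <- matrix(0, 40, 40); syt_dead[20:22, 20:22] <- 0.5
  syt_edge <- matrix(0, 40, 40); syt_edge[27, 21] <- 0.5  # within 3 px dilation
  syt_far <- matrix(0, 40, 40); syt_far[35, 35] <- 0.5
  tc <- data.frame(frame = 5, label = 1)
  expect_equal(assign_fate(tc, syt_dead, labels, 5, 0.1, 3), "dead")
  expect_equal(assign_fate(tc, syt_edge, labels, 5, 0.1, 3), "dead")
  expect_equal(assign_fate(tc, syt_far, labels, 5, 0.1, 3), "alive")
  expect_equal(assign_fate(tc, syt_far, labels, 5, 0.1, 0), "alive")
  # absent at the sytox frame -> unresolved
  expect_equal(assign_fate(data.frame(frame = 4, label = 1),
                           syt_dead, labels, 5, 0.1, 3), "unresolved")
  expect_error(assign_fate(tc, NULL, labels, 5, 0.1, 3), "Sytox")
})

test_that("decision OxD uses the nearest frame with earlier-frame ties", {
  tc <- data.frame(frame = 1:3, median_oxd = c(0.2, 0.5, 0.9))
  expect_equal(extract_decision_oxd(tc, c(20, 40, 60), 40), 0.5)
  # decision at 50 min: frames at 40 and 60 equally near -> earlier wins
  expect_equal(extract_decision_oxd(tc, c(20, 40, 60), 50), 0.5)
  expect_equal(extract_decision_oxd(tc, c(20, 40, 60), 45), 0.5)
  expect_true(is.na(extract_decision_oxd(tc[-2, ], c(20, 40, 60), 40)))
})

test_that("tracking on simulated stacks recovers ground-truth tracks and fates", {
  cfg <- imaging_sim_config(seed = 23, n_frames = 10)
  sim <- simulate_timelapse(cfg)
  an <- analyze_stack(sim$stack, cfg$calibration)
  tr <- track_cells(an, sytox_frame = 10,
                    decision_time = cfg$decision_time)
  resolved <- subset(tr$tracks, fate != "unresolved")
  # track purity: every resolved track follows a single ground-truth cell
  # track coordinates are in the registered (frame-1) system, so ground
  # truth is matched at the cells' initial positions (x0, y0)
  tcs <- sim$truth_cells
  purity_ok <- 0
  for (i in seq_len(nrow(resolved))) {
    tc <- subset(tr$cells, track_id == resolved$track_id[i])
    ids <- vapply(seq_len(nrow(tc)), function(k) {
      tcs$cell_id[which.min((tcs$x0 - tc$x[k])^2 + (tcs$y0 - tc$y[k])^2)]
    }, integer(1))
    if (length(unique(ids)) == 1) purity_ok <- purity_ok + 1
  }
  expect_gte(purity_ok / nrow(resolved), 0.98)
  # fates match ground truth for every resolved track
  for (i in seq_len(nrow(resolved))) {
    tc <- subset(tr$cells, track_id == resolved$track_id[i] & frame == 1)
    gt_id <- tcs$cell_id[which.min((tcs$x0 - tc$x)^2 + (tcs$y0 - tc$y)^2)]
    gt_dead <- tcs$dead[tcs$cell_id == gt_id]
    expect_equal(resolved$fate[i] == "dead", gt_dead)
  }
})
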