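test_that("initiation obeys the sustain contract exactly", {
  n <- 3000
  vals <- matrix(0, n, 9)
  vals[1001:2200, 1] <- 10          # clean step to 10 sigma at 1000 ms
  vals[1501:1502, 2] <- 10          # 2 ms blip: below the sustain
  vals[1201:2200, 3] <- 10
  wf <- makeWaveformSet(vals, 3, 3, baseline_sd = rep(1, 9))
  im <- initiationTimes(wf, sustain_ms = 5)
  expect_equal(im[1, 1], 1000)
  expect_true(is.na(im[2, 1]))      # blip never initiates
  expect_equal(im[3, 1], 1200)
  expect_true(is.na(im[1, 2]))      # silent pixel
  expect_error(initiationTimes(wf, sustain_ms = 2), "sustain_ms")
  # masked pixels never appear
  mask <- matrix(FALSE, 3, 3); mask[1, 1] <- TRUE
  wfm <- makeWaveformSet(vals, 3, 3, mask = mask, baseline_sd = rep(1, 9))
  expect_true(is.na(initiationTimes(wfm)[1, 1]))
})

test_that("latency binning follows the 1/5/10/20 ms edge scheme", {
  edges <- gevipipe:::initiationBinEdges()
  expect_equal(nrow(edges), 26)                  # 10 + 6 + 4 + 6
  mkmap <- function(delays) {
    m <- matrix(NA_real_, 10, 10)
    m[seq_along(delays)] <- 1000 + delays
    m
  }
  # 3 ms latency lands in the third 1 ms bin
  b3 <- binInitiations(mkmap(rep(3, 5)), t0 = 1000)
  expect_equal(b3$edges$n[3], 5)
  expect_equal(sum(b3$edges$n), 5)
  # 12 ms lands in the first 5 ms bin (11-15 ms)
  b12 <- binInitiations(mkmap(12), t0 = 1000)
  expect_equal(b12$edges$n[11], 1)
  expect_equal(unname(unlist(b12$edges[11, c("t_lo", "t_hi")])), c(10, 15))
  # 250 ms is outside the scheme
  b250 <- binInitiations(mkmap(250), t0 = 1000)
  expect_equal(sum(b250$edges$n), 0)
})

test_that("the Hopkins statistic separates random, clustered and regular sets", {
  grid <- as.matrix(expand.grid(row = 1:80, col = 1:80))
  set.seed(123)
  # exchangeable points and pool: H near 1/2
  hs <- vapply(1:30, function(i) {
    pts_idx <- sample(nrow(grid), 200)
    hopkinsStat(grid[pts_idx, ], grid[-pts_idx, ], repeats = 20, seed = i)
  }, numeric(1))
  expect_equal(mean(hs), 0.5, tolerance = 0.05)
  # a tight 8 x 8 block: clustered, H well above 1/2
  block <- as.matrix(expand.grid(row = 31:38, col = 31:38))
  pool <- grid[!(grid[, 1] %in% 31:38 & grid[, 2] %in% 31:38), ]
  expect_gt(hopkinsStat(block, pool, seed = 1), 0.5)
  # an evenly spaced lattice: regular, H below 1/2
  lattice <- as.matrix(expand.grid(row = seq(4, 77, by = 8),
                                   col = seq(4, 77, by = 8)))
  lat_idx <- paste(lattice[, 1], lattice[, 2])
  pool2 <- grid[!(paste(grid[, 1], grid[, 2]) %in% lat_idx), ]
  expect_lt(hopkinsStat(lattice, pool2, seed = 1), 0.5)
  expect_error(hopkinsStat(grid[1, , drop = FALSE], grid), "2 points")
  expect_error(hopkinsStat(grid[1:50, ], grid[1:10, ]), "pool")
})

test_that("Hopkins is invariant to point order and global translation", {
  set.seed(9)
  pts <- cbind(row = sample(1:40, 60, TRUE), col = sample(1:40, 60, TRUE))
  pool <- as.matrix(expand.grid(row = 1:40, col = 1:40))
  h1 <- hopkinsStat(pts, pool, seed = 4)
  h2 <- hopkinsStat(pts[sample(60), ], pool, seed = 4)
  expect_equal(h1, h2)
  h3 <- hopkinsStat(pts + 100, pool + 100, seed = 4)
  expect_equal(h1, h3)
})

test_that("origin profiles flag planted early clusters and stay flat otherwise", {
  mask <- matrix(FALSE, 40, 40)
  # planted origin: a 10 x 10 block initiates within the first 5 ms,
  # scattered pixels follow later
  m <- matrix(NA_real_, 40, 40)
  block <- as.matrix(expand.grid(row = 11:20, col = 11:20))
  m[block] <- 1000 + runif(100, 0, 5)
  set.seed(55)
  scatter <- cbind(sample(1:40, 300, TRUE), sample(1:40, 300, TRUE))
  scatter <- scatter[is.na(m[scatter]), , drop = FALSE]
  m[scatter] <- 1000 + runif(nrow(scatter), 20, 180)
  prof <- originProfile(m, mask, t0 = 1000, seed = 2)
  early <- prof$t_hi <= 10 & prof$n >= 2
  expect_gt(mean(prof$h_mean[early], na.rm = TRUE), 0.7)
  late <- prof$t_lo >= 20 & prof$n >= 10
  expect_equal(mean(prof$h_mean[late], na.rm = TRUE), 0.5, tolerance = 0.1)
  # empty bins are recorded with n = 0 and no H
  expect_true(all(is.na(prof$h_mean[prof$n < 2])))
  expect_true(all(prof$n >= 0))
  # spatially random participants: every populated bin stays near 1/2
  m2 <- matrix(NA_real_, 40, 40)
  set.seed(66)
  pick <- sample(1600, 800)
  m2[pick] <- 1000 + runif(800, 0, 180)
  prof2 <- originProfile(m2, mask, t0 = 1000, seed = 3)
  ok <- prof2$n >= 20
  expect_true(all(abs(prof2$h_mean[ok] - 0.5) < 0.1))
})

test_that("substrate comparison separates shared and disjoint oscillations", {
  set.seed(14)
  n <- 3000
  sig1 <- dampedOsc(n, onset_ms = 700, amp = 1, f = 15, n_fluct = 5,
                    tau = 300)
  sig2 <- dampedOsc(n, onset_ms = 2000, amp = 1, f = 15, n_fluct = 5,
                    tau = 300)
  noise_sd <- 0.05
  mkwf <- function(pix1, pix2) {
    vals <- matrix(rnorm(n * 400, sd = noise_sd), n, 400)
    vals[, pix1] <- vals[, pix1] + sig1
    vals[, pix2] <- vals[, pix2] + sig2
    makeWaveformSet(vals, 20, 20)
  }
  windows <- list(c(700, 1100), c(2000, 2400))
  shared_px <- sample(400, 100)   # matches the top-group size (400 / 4)
  wf_shared <- mkwf(shared_px, shared_px)
  res_s <- substrateComparison(wf_shared, windows)
  expect_gte(res_s$pairs$overlap[1], 0.8)
  expect_true(res_s$pairs$shared[1])
  disjoint <- mkwf(1:120, 201:320)
  res_d <- substrateComparison(disjoint, windows)
  expect_lte(res_d$pairs$overlap[1], 0.2)
  expect_false(res_d$pairs$shared[1])
  # a single oscillation yields an empty comparison
  res_1 <- substrateComparison(wf_shared, windows[1])
  expect_equal(nrow(res_1$pairs), 0)
  # overlapping windows are rejected
  expect_error(substrateComparison(wf_shared,
                                   list(c(700, 1200), c(1100, 1600))),
               "overlap")
  # identical windows give overlap exactly 1
  res_id <- substrateComparison(wf_shared,
                                list(c(700, 1100), c(2000, 2400)),
                                references = list(c(1, 1), c(1, 1)))
  expect_equal(res_id$pairs$overlap,
               res_id$pairs$overlap[1])   # symmetry of the single pair
})
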