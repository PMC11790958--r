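test_that("peak detection finds exactly the enumerated local maxima", {
  v <- c(0, 1, 5, 1, 0, 2, 8, 2, 0)
  k <- make_kymo(cbind(v))
  p <- detect_peaks_per_line(k, min_prominence = 0.05)[[1]]
  expect_equal(p$row, c(3L, 7L))
  expect_equal(p$intensity, c(5, 8))
})

test_that("monotone and uniform lines have no peaks", {
  k <- make_kymo(cbind(1:10, rep(4, 10)))
  p <- detect_peaks_per_line(k, min_prominence = 0.001)
  expect_equal(nrow(p[[1]]), 0L)
  expect_equal(nrow(p[[2]]), 0L)
})

test_that("prominence threshold suppresses minor bumps", {
  v <- c(0, 0, 100, 0, 0, 3, 0, 0)  # bump of 3 on a line totalling 103
  k <- make_kymo(cbind(v))
  p <- detect_peaks_per_line(k, min_prominence = 0.05)[[1]]
  expect_equal(p$row, 3L)
})

test_that("a steady single candidate links into one full-length track", {
  peaks <- replicate(12, data.frame(row = 20L, intensity = 10,
                                    prominence = 5), simplify = FALSE)
  tr <- select_and_link(peaks, min_track_length = 5)
  expect_equal(nrow(tr), 12L)
  expect_true(all(tr$row == 20L))
  expect_true(has_loop_track(tr))
})

test_that("the most intense candidate wins within each line", {
  peaks <- replicate(12, data.frame(row = c(10L, 40L),
                                    intensity = c(3, 10),
                                    prominence = c(3, 10)),
                     simplify = FALSE)
  tr <- select_and_link(peaks, min_track_length = 5)
  expect_true(all(tr$row == 40L))
})

test_that("a jump beyond the search range splits the track", {
  rows <- c(rep(20L, 6), rep(70L, 10))
  peaks <- lapply(rows, function(r)
    data.frame(row = r, intensity = 10, prominence = 5))
  tr <- select_and_link(peaks, search_range = 10, min_track_length = 5)
  expect_equal(length(attr(tr, "tracks")), 2L)
  expect_true(all(tr$row == 70L))  # longer segment retained as primary
})

test_that("linking equals exhaustive segmentation on small instances", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    rows <- sample(1:60, n, replace = TRUE)
    present <- runif(n) < 0.8
    peaks <- lapply(seq_len(n), function(i) {
      if (!present[i]) return(data.frame(row = integer(0),
                                         intensity = numeric(0),
                                         prominence = numeric(0)))
      data.frame(row = rows[i], intensity = 1, prominence = 1)
    })
    tr <- select_and_link(peaks, search_range = 15, memory = 2,
                          min_track_length = 1)
    # oracle: break whenever displacement > range or gap > memory + 1
    keep <- which(present)
    breaks <- which(abs(diff(rows[keep])) > 15 | diff(keep) > 3)
    seg_lengths <- diff(c(0, breaks, length(keep)))
    got_lengths <- vapply(attr(tr, "tracks"), nrow, integer(1))
    expect_equal(got_lengths, seg_lengths)
    expect_equal(nrow(tr), max(seg_lengths))
  }
})

test_that("partition covers all rows disjointly with a 9-row loop window", {
  k <- make_kymo(matrix(1, 100, 3))
  tr <- structure(data.frame(frame = 1:3, row = c(21L, 50L, 90L),
                             intensity = 1),
                  tracks = list(), class = c("peak_track", "data.frame"))
  part <- partition_lines(k, tr)
  expect_equal(part$lo[1], 17L)
  expect_equal(part$hi[1], 25L)
  expect_false(part$edge[1])
  widths <- part$hi - part$lo + 1L
  expect_true(all(widths == 9L))
  # union of the three regions is all rows by construction
  expect_true(all(part$lo >= 1 & part$hi <= 100))
})

test_that("a loop centre near the edge is flagged", {
  k <- make_kymo(matrix(1, 100, 1))
  tr <- structure(data.frame(frame = 1L, row = 3L, intensity = 1),
                  tracks = list(), class = c("peak_track", "data.frame"))
  part <- partition_lines(k, tr)
  expect_true(part$edge[1])
  expect_equal(part$lo[1], 1L)
  tr$row <- 200L
  expect_error(partition_lines(k, tr), class = "loopx_bad_track")
})

test_that("intensity fractions convert to kbp by ratio times 48.5", {
  # 19-row line with a bright loop window about a centre at row 9
  line <- c(rep(2, 7), 2, 32, 2, rep(2, 9))
  k <- make_kymo(cbind(line))
  tr <- structure(data.frame(frame = 1L, row = 9L, intensity = 32),
                  tracks = list(), class = c("peak_track", "data.frame"))
  part <- partition_lines(k, tr, loop_halfwidth = 1)  # loop rows 8:10
  d <- estimate_dna_amounts(k, part)
  tot <- sum(line)
  expect_equal(d$up_kbp, 48.5 * sum(line[1:7]) / tot)
  expect_equal(d$loop_kbp, 48.5 * sum(line[8:10]) / tot)
  expect_equal(d$down_kbp, 48.5 * sum(line[11:19]) / tot)
  expect_equal(d$up_kbp + d$loop_kbp + d$down_kbp, 48.5)
  # quarter / half / quarter fractions force (12.125, 24.25, 12.125)
  line2 <- numeric(19); line2[5] <- 1; line2[9] <- 2; line2[15] <- 1
  k2 <- make_kymo(cbind(4 * line2))
  d2 <- estimate_dna_amounts(k2, partition_lines(k2, tr, loop_halfwidth = 1))
  expect_equal(c(d2$up_kbp, d2$loop_kbp, d2$down_kbp),
               c(12.125, 24.25, 12.125))
})

test_that("zero loop intensity yields zero loop kbp; dead lines invalid", {
  line <- c(rep(5, 20), rep(0, 3), rep(5, 20))
  k <- make_kymo(cbind(line, 0 * line))
  tr <- structure(data.frame(frame = 1:2, row = c(22L, 22L), intensity = 0),
                  tracks = list(), class = c("peak_track", "data.frame"))
  part <- partition_lines(k, tr, loop_halfwidth = 1)
  d <- estimate_dna_amounts(k, part)
  expect_equal(d$loop_kbp[1], 0)
  expect_false(d$valid[2])
})

test_that("DNA conservation holds to machine precision end to end", {
  res <- sim_and_quantify(9)
  d <- res$q$dna[res$q$dna$valid, ]
  expect_true(nrow(d) > 5)
  expect_true(all(abs(d$up_kbp + d$loop_kbp + d$down_kbp - 48.5) < 1e-9))
})

test_that("a larger true loop yields a larger estimated loop", {
  # noise-free ramp: estimates must increase with the ground truth
  res <- sim_and_quantify(1, n_frames = 40,
                          noise_model = list(poisson = FALSE,
                                             gaussian_sd = 0),
                          background_mean = 0)
  d <- res$q$dna[res$q$dna$valid & !res$q$dna$edge, ]
  m <- merge(d, res$truth, by = "frame")
  m <- m[m$loop_kbp.y > 2 & m$loop_kbp.y < 30, ]
  expect_true(all(diff(m$loop_kbp.x[order(m$loop_kbp.y)]) > 0))
})

test_that("noise-free estimates track ground truth closely", {
  # raw band summation reproduces the rendered fractions to within 2%;
  # the default radius-2 disc median erodes some punctum mass (roughly a
  # constant ~1 kbp, so worst in relative terms for mid-sized loops), and
  # the full default pipeline is held to 8% (attenuation documented in
  # the methods vignette)
  for (seed in c(2, 3, 4)) {
    cfg <- tether_sim_config(n_frames = 45,
                             loop_events = list(std_loop_event()),
                             noise_model = list(poisson = FALSE,
                                                gaussian_sd = 0),
                             background_mean = 0, seed = seed)
    sim <- simulate_tether_movie(cfg)
    for (cand in list(list(mr = 0, tol = 0.02), list(mr = 2, tol = 0.08))) {
      q <- quantify_tether(sim$series, pipeline_config(median_radius = cand$mr))
      m <- merge(q$dna[q$dna$valid & !q$dna$edge, ], sim$truth, by = "frame")
      m <- m[m$loop_kbp.y > 8 & m$loop_kbp.y < 30, ]
      expect_true(nrow(m) > 10)
      rel <- abs(m$loop_kbp.x - m$loop_kbp.y) / m$loop_kbp.y
      expect_lt(max(rel), cand$tol)
    }
  }
})
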