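# stream with one body sitting at `seat`, visible over each interval in
# `windows` (list of c(from, to)), sampled at `hz`
seatedStream <- function(seat, windows, hz = 5, body = 0L) {
  ts <- unlist(lapply(windows, function(w)
    seq(w[1], w[2], by = 1 / hz)))
  pos <- matrix(rep(seat, each = length(ts)), ncol = 3)
  makeStream(ts, positions = list(spine_base = pos), body = body,
             default = seat + c(0, 0.3, 0))
}

test_that("a continuously detected body yields one track holding all frames", {
  stream <- seatedStream(c(0, 0, 2), list(c(0, 10)))
  ts <- assignIdentities(stream)
  expect_identical(trackIds(ts), 1L)
  expect_identical(nrow(trackData(bodyTrack(ts, 1))),
                   nrow(frameData(stream)))
})

test_that("a body reappearing near its anchor is re-identified", {
  seat <- c(0, 0, 2)
  near <- seat + c(0.1, 0, 0)
  s1 <- seatedStream(seat, list(c(0, 5)))
  s2 <- seatedStream(near, list(c(15, 20)))  # 10 s gone, 0.1 m away
  ts <- assignIdentities(mergeStreams(s1, s2),
                         gapPolicy(reidRadius = 0.5))
  expect_identical(trackIds(ts), 1L)
})

test_that("a body reappearing beyond the radius gets a fresh identity", {
  s1 <- seatedStream(c(0, 0, 2), list(c(0, 5)))
  s2 <- seatedStream(c(2, 0, 2), list(c(15, 20)))
  ts <- assignIdentities(mergeStreams(s1, s2),
                         gapPolicy(reidRadius = 0.5))
  expect_identical(trackIds(ts), c(1L, 2L))
})

test_that("re-identification picks the nearest inactive anchor", {
  # two inactive tracks at (0,0,2) and (1,0,2); reappearance at (0.9,0,2)
  s1 <- seatedStream(c(0, 0, 2), list(c(0, 5)), body = 0L)
  s2 <- seatedStream(c(1, 0, 2), list(c(0, 5)), body = 1L)
  s3 <- seatedStream(c(0.9, 0, 2), list(c(15, 18)), body = 0L)
  ts <- assignIdentities(mergeStreams(s1, s2, s3),
                         gapPolicy(reidRadius = 0.5))
  expect_identical(trackIds(ts), c(1L, 2L))
  dt <- trackData(ts)
  late <- unique(dt$persistent_id[dt$timestamp_s >= 15])
  expect_identical(late, 2L)
})

test_that("re-identification matches a brute-force nearest-anchor oracle", {
  set.seed(101)
  radius <- 0.5
  for (case in 1:15) {
    k <- sample(2:5, 1)
    anchors <- cbind(runif(k, -3, 3), runif(k, -0.2, 0.2), runif(k, 1.5, 4))
    # keep anchors well separated so the EMA anchor equals the seat exactly
    p <- anchors[sample(k, 1), ] + runif(3, -0.45, 0.45) / sqrt(3)
    streams <- lapply(seq_len(k), function(i)
      seatedStream(anchors[i, ], list(c(0, 2)), body = i - 1L))
    reapp <- seatedStream(p, list(c(10, 11)), body = 0L)
    ts <- assignIdentities(do.call(mergeStreams, c(streams, list(reapp))),
                           gapPolicy(reidRadius = radius))
    d <- sqrt(colSums((t(anchors) - p)^2))
    expected <- if (min(d) <= radius) which.min(d) else k + 1L
    dt <- trackData(ts)
    got <- unique(dt$persistent_id[dt$timestamp_s >= 10])
    expect_identical(got, as.integer(expected))
  }
})

test_that("identity stability: sub-radius disappearances never split a track", {
  seat <- c(0.5, 0, 2.5)
  windows <- list(c(0, 2), c(4, 6), c(9, 11), c(14, 20))
  stream <- seatedStream(seat, windows)
  ts <- assignIdentities(stream)
  expect_identical(trackIds(ts), 1L)
})

test_that("relabelling device slots changes numbering only, not grouping", {
  sA <- seatedStream(c(-1, 0, 2), list(c(0, 5), c(10, 15)), body = 0L)
  sB <- seatedStream(c(1, 0, 2), list(c(0, 5), c(10, 15)), body = 1L)
  base <- mergeStreams(sA, sB)
  # permute slot labels globally (0 <-> 1)
  df <- as.data.frame(frameData(base))
  df$body_index <- 1L - df$body_index
  permuted <- SkeletonStream(df)
  sig <- function(ts) {
    dt <- trackData(ts)
    parts <- split(paste(dt$timestamp_s, dt$joint), dt$persistent_id)
    unname(sort(vapply(parts, function(v)
      paste(sort(v), collapse = "|"), "")))
  }
  # same partition of frames into identities, possibly renumbered
  expect_identical(sig(assignIdentities(base)),
                   sig(assignIdentities(permuted)))
})

test_that("needing a seventh identity is a capacity error", {
  streams <- lapply(0:5, function(i)
    seatedStream(c(i * 2, 0, 2), list(c(0, 2)), body = i))
  seventh <- seatedStream(c(20, 0, 2), list(c(10, 12)), body = 0L)
  expect_error(
    assignIdentities(do.call(mergeStreams, c(streams, list(seventh)))),
    "capacity")
})

test_that("short drop-outs are filled linearly and marked inferred", {
  t <- c(0, 0.5, 1)
  pos <- matrix(c(0, 0, 1, 0, 0, 0, 2, 2, 2), 3)  # (0,0,2) -> (1,0,2)
  stream <- makeStream(t, positions = list(head = pos),
                       states = list(head = c("tracked", "not_tracked",
                                              "tracked")))
  tr <- makeTrack(stream, gapPolicy(maxInterpGap = 2))
  filled <- interpolateGaps(tr)
  h <- trackData(filled)[joint == "head"]
  expect_equal(h$x_m[2], 0.5, tolerance = 1e-12)
  expect_identical(h$tracking_state[2], "inferred")
})

test_that("gaps longer than the policy bound stay missing", {
  t <- c(0, 2.5, 5)
  stream <- makeStream(t, states = list(
    head = c("tracked", "not_tracked", "tracked")))
  tr <- makeTrack(stream, gapPolicy(maxInterpGap = 0.5))
  h <- trackData(interpolateGaps(tr))[joint == "head"]
  expect_identical(h$tracking_state[2], "not_tracked")
})

test_that("runs at track ends are never extrapolated", {
  t <- 0:3
  stream <- makeStream(t, states = list(
    head = c("not_tracked", "tracked", "tracked", "not_tracked")))
  tr <- makeTrack(stream, gapPolicy(maxInterpGap = 10))
  h <- trackData(interpolateGaps(tr))[joint == "head"]
  expect_identical(h$tracking_state, c("not_tracked", "tracked",
                                       "tracked", "not_tracked"))
})

test_that("multi-point gap filling equals per-axis 1-D interpolation", {
  set.seed(7)
  t <- seq(0, 2, by = 0.1)
  n <- length(t)
  pos <- cbind(cumsum(rnorm(n, 0, 0.05)), cumsum(rnorm(n, 0, 0.05)),
               2 + cumsum(rnorm(n, 0, 0.02)))
  states <- rep("tracked", n)
  gap <- 8:12
  states[gap] <- "not_tracked"
  stream <- makeStream(t, positions = list(left_wrist = pos),
                       states = list(left_wrist = states))
  tr <- makeTrack(stream, gapPolicy(maxInterpGap = 1))
  w <- trackData(interpolateGaps(tr))[joint == "left_wrist"]
  keep <- setdiff(seq_len(n), gap)
  for (col in 1:3) {
    oracle <- approx(t[keep], pos[keep, col], xout = t[gap])$y
    expect_equal(w[[c("x_m", "y_m", "z_m")[col]]][gap], oracle,
                 tolerance = 1e-12)
  }
})

test_that("interpolation is exact for linear motion", {
  t <- seq(0, 1, by = 0.05)
  true_pos <- cbind(0.3 * t, -0.1 * t + 0.2, 2 + 0.5 * t)
  states <- rep("tracked", length(t))
  states[5:15] <- "not_tracked"
  stream <- makeStream(t, positions = list(neck = true_pos),
                       states = list(neck = states))
  tr <- makeTrack(stream, gapPolicy(maxInterpGap = 1))
  nk <- trackData(interpolateGaps(tr))[joint == "neck"]
  expect_lt(max(abs(nk$x_m - true_pos[, 1])), 1e-9)
  expect_lt(max(abs(nk$y_m - true_pos[, 2])), 1e-9)
  expect_lt(max(abs(nk$z_m - true_pos[, 3])), 1e-9)
})
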