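# Small in-code fixtures: streams built from explicit trajectories, and
# movement-matrix lists built from explicit per-minute values.

# One frame = 25 joints. `positions` maps joint name -> n x 3 matrix of
# positions over the n timestamps; every other joint sits at `default` plus
# a small per-joint offset so joints do not coincide. `states` maps joint
# name -> character vector of tracking states over the timestamps.
makeStream <- function(t, positions = list(), states = list(),
                       body = 0L, default = c(0, 0, 2)) {
  n <- length(t)
  joints <- kinectJoints()
  rows <- lapply(seq_along(joints), function(j) {
    jn <- joints[j]
    pos <- positions[[jn]]
    if (is.null(pos)) {
      pos <- matrix(rep(default + c(j * 1e-3, 0, 0), each = n), n, 3)
    }
    st <- states[[jn]]
    if (is.null(st)) st <- rep("tracked", n)
    data.frame(timestamp_s = t, body_index = rep(body, n),
               joint = rep(jn, n),
               x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
               tracking_state = st)
  })
  SkeletonStream(do.call(rbind, rows))
}

# combine several single-body streams into one
mergeStreams <- function(...) {
  SkeletonStream(do.call(rbind, lapply(list(...), function(s)
    as.data.frame(frameData(s)))))
}

makeTrack <- function(stream, policy = gapPolicy(), id = 1L) {
  bodyTrack(assignIdentities(stream, policy), id)
}

# list of MovementMatrix objects with values drawn by gen(nJoints, nMinutes)
makeMatrixList <- function(nSubjects, nMinutes, gen,
                           group = "experimental", prefix = "s") {
  lapply(seq_len(nSubjects), function(i) {
    v <- gen(17L, nMinutes)
    rownames(v) <- analysisJoints()
    MovementMatrix(v, meta = sessionMeta(
      sprintf("%s%02d", prefix, i), group = group,
      sessionLength = nMinutes))
  })
}

# brute-force oracle: sum ||dp|| over consecutive valid pairs, binned by the
# later endpoint, computed with a plain loop
brutePathPerMinute <- function(t, pos, nMinutes, maxGap) {
  out <- rep(NA_real_, nMinutes)
  for (i in seq_along(t)[-1]) {
    dt <- t[i] - t[i - 1]
    if (dt <= 0 || dt > maxGap) next
    if (t[i] >= 60 * nMinutes) next
    b <- floor(t[i] / 60) + 1
    d <- sqrt(sum((pos[i, ] - pos[i - 1, ])^2))
    out[b] <- if (is.na(out[b])) d else out[b] + d
  }
  out
}

# brute-force AUC by exhaustive pair counting with 1/2 for ties
bruteAuc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random rigid rotation (det +1)
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
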