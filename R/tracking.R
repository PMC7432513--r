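## Persistent identity assignment and occlusion-gap repair.
##
## The device reports bodies in volatile slots 0-5. Identities are made
## persistent the way the original capture application behaves: skeletons are
## numbered 1-6 in order of first detection and the smoothed location of each
## is remembered, so that a skeleton that vanishes (subject occluded or out of
## frame) and later reappears near its remembered location gets its old number
## back.

#' @import data.table
NULL

.ANCHOR_HALFLIFE_S <- 2  # EMA half-life of the spine-base anchor

#' Assign persistent subject identities
#'
#' Walks the stream in time order and attaches every detected skeleton to a
#' persistent identity (1-6, in order of first detection). A raw body slot
#' seen again within \code{maxInterpGap} seconds continues its current
#' identity, provided the detection has not jumped beyond \code{reidRadius}
#' of the identity's anchor -- a jump means the device handed the slot to a
#' different body. A slot (re)appearing after a longer absence is a new detection:
#' it is attached to the inactive identity whose anchor -- an exponential
#' moving average (half-life 2 s) of the spine-base position -- lies nearest,
#' provided that distance is within \code{reidRadius}; ties break toward the
#' lower identity. Otherwise the next unused identity is issued; needing a
#' seventh identity is a capacity error, as the sensor tracks at most six
#' bodies.
#'
#' @param stream A [SkeletonStream()].
#' @param policy A [gapPolicy()].
#' @return A [BodyTrackSet()].
#' @examples
#' sim <- simulateSession(list(subjectProfile("s1")),
#'                        simConfig(nSubjects = 1, sessionLength = 1,
#'                                  frameRate = 5, seed = 1))
#' trackIds(assignIdentities(sim$stream))
#' @export
assignIdentities <- function(stream, policy = gapPolicy()) {
  stopifnot(is(stream, "SkeletonStream"), is(policy, "GapPolicy"))
  dt <- frameData(stream)
  if (!nrow(dt))
    return(new("BodyTrackSet",
               frames = cbind(as.data.frame(dt), persistent_id = integer(0)),
               anchors = matrix(numeric(0), 0, 3,
                                dimnames = list(NULL, c("x", "y", "z"))),
               policy = policy))
  data.table::setkeyv(dt, c("timestamp_s", "body_index"))

  ## one row per detection, positioned at the spine base (fallback: centroid
  ## of tracked joints in that frame)
  det <- dt[joint == "spine_base",
            .(timestamp_s, body_index, x = x_m, y = y_m, z = z_m,
              ok = tracking_state != "not_tracked")]
  if (any(!det$ok)) {
    cen <- dt[tracking_state != "not_tracked",
              .(cx = mean(x_m), cy = mean(y_m), cz = mean(z_m)),
              by = .(timestamp_s, body_index)]
    det <- cen[det, on = c("timestamp_s", "body_index")]
    fix <- !det$ok & !is.na(det$cx)
    det[fix, `:=`(x = cx, y = cy, z = cz)]
    det[, c("cx", "cy", "cz") := NULL]
  }
  data.table::setorderv(det, c("timestamp_s", "body_index"))

  n <- nrow(det)
  pid_out <- integer(n)
  slotPid <- rep(NA_integer_, 6L)     # slot (1-based) -> persistent id
  slotSeen <- rep(-Inf, 6L)
  pidSeen <- rep(-Inf, 6L)            # persistent id -> last time attached
  anchors <- matrix(NA_real_, 6L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  anchorT <- rep(-Inf, 6L)
  nPid <- 0L
  tv <- det$timestamp_s; bv <- det$body_index + 1L
  px <- det$x; py <- det$y; pz <- det$z
  gap <- policy@maxInterpGap; rad <- policy@reidRadius

  for (i in seq_len(n)) {
    t <- tv[i]; b <- bv[i]
    pid <- slotPid[b]
    cont <- !is.na(pid) && (t - slotSeen[b]) <= gap
    ## slot continuity must also be spatial: a slot that jumps beyond the
    ## re-identification radius was handed to a different body by the device
    if (cont && is.finite(px[i]) && is.finite(anchors[pid, 1L]) &&
        (anchors[pid, 1L] - px[i])^2 + (anchors[pid, 2L] - py[i])^2 +
          (anchors[pid, 3L] - pz[i])^2 > rad^2)
      cont <- FALSE
    if (!cont) {
      ## new appearance: try to re-identify against inactive anchors
      inactive <- which(seq_len(6L) <= nPid & (t - pidSeen) > gap)
      pid <- NA_integer_
      if (length(inactive) && is.finite(px[i])) {
        dsq <- (anchors[inactive, 1L] - px[i])^2 +
               (anchors[inactive, 2L] - py[i])^2 +
               (anchors[inactive, 3L] - pz[i])^2
        j <- which(dsq <= rad^2)
        if (length(j)) {
          j <- j[order(dsq[j], inactive[j])][1L]  # nearest; tie -> lower id
          pid <- inactive[j]
        }
      }
      if (is.na(pid)) {
        if (nPid >= 6L)
          stop("capacity error: a 7th identity would be required, but at ",
               "most 6 bodies can be detected and tracked")
        nPid <- nPid + 1L
        pid <- nPid
      }
    }
    slotPid[b] <- pid; slotSeen[b] <- t
    pidSeen[pid] <- t
    if (is.finite(px[i])) {
      if (!is.finite(anchorT[pid])) {
        anchors[pid, ] <- c(px[i], py[i], pz[i])
      } else {
        w <- 0.5^((t - anchorT[pid]) / .ANCHOR_HALFLIFE_S)
        anchors[pid, ] <- w * anchors[pid, ] +
          (1 - w) * c(px[i], py[i], pz[i])
      }
      anchorT[pid] <- t
    }
    pid_out[i] <- pid
  }

  det[, persistent_id := pid_out]
  out <- det[, .(timestamp_s, body_index, persistent_id)][
    dt, on = c("timestamp_s", "body_index")]
  data.table::setcolorder(out, c(.STREAM_COLS, "persistent_id"))
  am <- anchors[seq_len(nPid), , drop = FALSE]
  rownames(am) <- as.character(seq_len(nPid))
  new("BodyTrackSet", frames = as.data.frame(out), anchors = am,
      policy = policy)
}

#' Interpolate short joint drop-outs
#'
#' Per joint, runs of \code{not_tracked} samples that are bounded on both
#' sides by observed (\code{tracked}/\code{inferred}) samples and span less
#' than \code{maxInterpGap} seconds are filled by linear interpolation of each
#' coordinate and relabelled \code{inferred} -- mirroring what the sensor SDK
#' itself does for occluded joints. Longer runs, and runs touching either end
#' of the track, are left missing; the interval they span is later excluded
#' from path-length accumulation rather than bridged.
#'
#' @param x A [BodyTrackSet()] or [BodyTrack()].
#' @param policy A [gapPolicy()]; defaults to the policy stored in \code{x}.
#' @return An object of the same class with gaps filled.
#' @export
setGeneric("interpolateGaps",
           function(x, policy = NULL) standardGeneric("interpolateGaps"))

.interpFrames <- function(df, maxGap) {
  dt <- data.table::as.data.table(df)
  byCols <- intersect(c("persistent_id", "joint"), names(dt))
  data.table::setorderv(dt, c(byCols, "timestamp_s"))
  dt[, c("x_m", "y_m", "z_m", "tracking_state") := {
    v <- tracking_state != "not_tracked"
    if (any(!v) && any(v)) {
      x <- x_m; y <- y_m; z <- z_m; st <- tracking_state
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (r$values[k]) next
        i <- starts[k]; j <- ends[k]
        if (i == 1L || j == length(v)) next            # run at track end
        span <- timestamp_s[j + 1L] - timestamp_s[i - 1L]
        if (span >= maxGap) next                       # too long to bridge
        tt <- timestamp_s[i:j]
        tb <- timestamp_s[c(i - 1L, j + 1L)]
        x[i:j] <- approx(tb, x[c(i - 1L, j + 1L)], xout = tt)$y
        y[i:j] <- approx(tb, y[c(i - 1L, j + 1L)], xout = tt)$y
        z[i:j] <- approx(tb, z[c(i - 1L, j + 1L)], xout = tt)$y
        st[i:j] <- "inferred"
      }
      list(x, y, z, st)
    } else {
      list(x_m, y_m, z_m, tracking_state)
    }
  }, by = byCols]
  as.data.frame(dt)
}

#' @rdname interpolateGaps
#' @export
setMethod("interpolateGaps", "BodyTrackSet", function(x, policy = NULL) {
  if (is.null(policy)) policy <- x@policy
  new("BodyTrackSet", frames = .interpFrames(x@frames, policy@maxInterpGap),
      anchors = x@anchors, policy = policy)
})

#' @rdname interpolateGaps
#' @export
setMethod("interpolateGaps", "BodyTrack", function(x, policy = NULL) {
  if (is.null(policy)) policy <- x@policy
  new("BodyTrack", persistentId = x@persistentId,
      frames = .interpFrames(x@frames, policy@maxInterpGap),
      anchor = x@anchor, policy = policy)
})
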