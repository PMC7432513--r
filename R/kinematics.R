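## Path length per minute: the core movement quantity.
##
## For one joint, consecutive observed samples define trajectory segments;
## each valid segment (both endpoints observed, spacing <= maxInterpGap)
## contributes its Euclidean length ||p1 - p0|| to the minute bin containing
## its later endpoint t1 (bin k is [60k, 60(k+1))). Assigning by the later
## endpoint counts every segment exactly once, so minute sums conserve the
## total path length. A minute with no valid segment is missing (NA), never
## zero: zero would fabricate stillness during occlusion.

## Compute per-minute path lengths for the given joints from a long frame
## table. Returns list(values = joints x minutes matrix (NA = missing),
## trailing = TRUE if data beyond the session end was dropped).
.pathLengths <- function(df, joints, sessionLength, maxGap,
                         includeInferred = TRUE, smoothWindow = 1L) {
  states <- if (includeInferred) c("tracked", "inferred") else "tracked"
  dt <- data.table::as.data.table(df)
  dt <- dt[joint %in% joints & tracking_state %in% states &
             is.finite(x_m) & is.finite(y_m) & is.finite(z_m)]
  data.table::setorderv(dt, c("joint", "timestamp_s"))
  if (smoothWindow > 1L) {
    w <- as.integer(smoothWindow)
    sm <- function(v) {
      out <- as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
      ifelse(is.na(out), v, out)  # keep raw samples at the run edges
    }
    dt[, c("x_m", "y_m", "z_m") :=
         .(sm(x_m), sm(y_m), sm(z_m)), by = joint]
  }
  nMin <- as.integer(ceiling(sessionLength))
  vals <- matrix(NA_real_, length(joints), nMin,
                 dimnames = list(joints, paste0("minute_", seq_len(nMin))))
  if (!nrow(dt))
    return(list(values = vals, trailing = FALSE))
  segs <- dt[, {
    d <- sqrt(diff(x_m)^2 + diff(y_m)^2 + diff(z_m)^2)
    list(t1 = timestamp_s[-1L], dt_s = diff(timestamp_s), d = d)
  }, by = joint]
  segs <- segs[dt_s > 0 & dt_s <= maxGap]
  trailing <- any(segs$t1 >= 60 * sessionLength)
  segs <- segs[t1 < 60 * sessionLength]
  if (nrow(segs)) {
    segs[, bin := as.integer(floor(t1 / 60)) + 1L]
    agg <- segs[, .(len = sum(d)), by = .(joint, bin)]
    vals[cbind(match(agg$joint, joints), agg$bin)] <- agg$len
  }
  list(values = vals, trailing = trailing)
}

#' Path length per minute for one joint
#'
#' Sums the Euclidean lengths of the joint's valid trajectory segments within
#' each minute bin of the session. A segment is valid when both endpoints are
#' observed (\code{tracked} or \code{inferred}) and its time spacing does not
#' exceed the track's \code{maxInterpGap}; it is assigned to the minute
#' containing its later endpoint. Minutes with no valid segment are \code{NA}.
#'
#' @param track A [BodyTrack()] (run [interpolateGaps()] first if short
#'   drop-outs should be bridged).
#' @param joint Canonical joint name.
#' @param sessionLength Session length in minutes; samples beyond it are
#'   ignored with a warning.
#' @param includeInferred Use \code{inferred} samples like \code{tracked}
#'   ones (default; the sensor SDK itself interpolates occluded joints)?
#'   When \code{FALSE} they are treated as missing.
#' @param smoothWindow Odd width of an optional centred moving-average
#'   position filter applied before differencing; 1 (default) disables it.
#' @return Numeric vector of length \code{sessionLength} (metres per minute,
#'   \code{NA} = missing).
#' @seealso [buildMovementMatrix()]
#' @export
pathLengthPerMinute <- function(track, joint, sessionLength,
                                includeInferred = TRUE, smoothWindow = 1L) {
  stopifnot(is(track, "BodyTrack"))
  joint <- as.character(.normalizeJoints(joint))
  if (!joint %in% .JOINTS_25)
    stop("unknown joint name '", joint, "'")
  if (!joint %in% track@frames$joint)
    stop("joint '", joint, "' not present in track ", track@persistentId)
  res <- .pathLengths(track@frames, joint, sessionLength,
                      track@policy@maxInterpGap, includeInferred,
                      smoothWindow)
  if (res$trailing)
    warning("track extends beyond the ", sessionLength,
            "-minute session; trailing data ignored")
  drop(res$values[joint, ])
}

#' Build the movement matrix of one subject
#'
#' Applies [pathLengthPerMinute()] to every joint of the 17-joint analysis
#' set (in report row order) over the session's minutes.
#'
#' @param track A [BodyTrack()].
#' @param meta A [sessionMeta()]; its \code{sessionLength} defines the number
#'   of minute columns.
#' @inheritParams pathLengthPerMinute
#' @return A [MovementMatrix()].
#' @examples
#' sim <- simulateSession(list(subjectProfile("s1")),
#'                        simConfig(nSubjects = 1, sessionLength = 2,
#'                                  frameRate = 5, seed = 7))
#' tr <- bodyTrack(assignIdentities(sim$stream), 1)
#' mm <- buildMovementMatrix(tr, sessionMeta("s1", sessionLength = 2))
#' dim(pathLength(mm))  # 17 x 2
#' @export
buildMovementMatrix <- function(track, meta, includeInferred = TRUE,
                                smoothWindow = 1L) {
  stopifnot(is(track, "BodyTrack"), is(meta, "SessionMeta"))
  res <- .pathLengths(track@frames, .JOINTS_17, meta@sessionLength,
                      track@policy@maxInterpGap, includeInferred,
                      smoothWindow)
  if (res$trailing)
    warning("track extends beyond the ", meta@sessionLength,
            "-minute session; trailing data ignored")
  MovementMatrix(res$values, meta = meta)
}

#' Quantify every subject of a session
#'
#' Convenience wrapper running the full per-session pipeline: identity
#' assignment, gap interpolation, and one movement matrix per persistent
#' identity.
#'
#' @param stream A [SkeletonStream()].
#' @param metas Named list of [sessionMeta()] keyed by persistent id (as
#'   character), or a single \code{SessionMeta} template applied to all ids
#'   (subject ids become \code{<subjectId>_<pid>}).
#' @param policy A [gapPolicy()].
#' @param interpolate Bridge short joint drop-outs first? Default \code{TRUE}.
#' @inheritParams pathLengthPerMinute
#' @return Named list of [MovementMatrix()], one per persistent id.
#' @export
quantifySession <- function(stream, metas, policy = gapPolicy(),
                            interpolate = TRUE, includeInferred = TRUE,
                            smoothWindow = 1L) {
  ts <- assignIdentities(stream, policy)
  if (interpolate) ts <- interpolateGaps(ts)
  ids <- trackIds(ts)
  out <- lapply(ids, function(id) {
    meta <- if (is(metas, "SessionMeta")) {
      if (length(ids) == 1L) metas else
        sessionMeta(paste0(metas@subjectId, "_", id), group = metas@group,
                    medication = metas@medication, sex = metas@sex,
                    age = metas@age, sessionLength = metas@sessionLength)
    } else metas[[as.character(id)]]
    if (is.null(meta))
      stop("no session metadata supplied for persistent id ", id)
    buildMovementMatrix(bodyTrack(ts, id), meta, includeInferred,
                        smoothWindow)
  })
  names(out) <- as.character(ids)
  out
}
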