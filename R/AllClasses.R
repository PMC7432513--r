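## S4 classes for skeleton streams, tracking results and movement matrices.

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

setOldClass(c("data.table", "data.frame"))

## ---- GapPolicy --------------------------------------------------------------

#' Tracking gap policy
#'
#' Two knobs govern gap handling. \code{reidRadius} (metres) is the maximum
#' distance between a new detection's spine base and a lost track's anchor for
#' the detection to be re-attached to that track; beyond it a new identity is
#' issued. \code{maxInterpGap} (seconds) bounds both the joint drop-out runs
#' that are bridged by linear interpolation and the frame spacing beyond which
#' a trajectory segment is excluded from path-length accumulation. A raw device
#' body slot absent for longer than \code{maxInterpGap} is considered lost and
#' its track goes inactive.
#'
#' The defaults (0.5 m, 0.5 s) reflect seated subjects in writing-pad chairs
#' spaced at least a chair width apart: an occluded subject reappears
#' essentially at their seat, well inside 0.5 m, while two neighbouring seats
#' are outside it.
#'
#' @param reidRadius Positive number, metres.
#' @param maxInterpGap Positive number, seconds.
#' @return A \code{GapPolicy} object.
#' @examples
#' gapPolicy()
#' gapPolicy(reidRadius = 0.3, maxInterpGap = 1)
#' @export gapPolicy
#' @exportClass GapPolicy
#' @aliases GapPolicy-class
setClass("GapPolicy",
  representation(reidRadius = "numeric", maxInterpGap = "numeric"),
  prototype(reidRadius = 0.5, maxInterpGap = 0.5),
  validity = function(object) {
    if (length(object@reidRadius) != 1L || !is.finite(object@reidRadius) ||
        object@reidRadius <= 0)
      return("reidRadius must be a single positive number (metres)")
    if (length(object@maxInterpGap) != 1L || !is.finite(object@maxInterpGap) ||
        object@maxInterpGap <= 0)
      return("maxInterpGap must be a single positive number (seconds)")
    TRUE
  })

gapPolicy <- function(reidRadius = 0.5, maxInterpGap = 0.5) {
  new("GapPolicy", reidRadius = reidRadius, maxInterpGap = maxInterpGap)
}

setMethod("show", "GapPolicy", function(object) {
  cat(sprintf("GapPolicy: reidRadius = %g m, maxInterpGap = %g s\n",
              object@reidRadius, object@maxInterpGap))
})

## ---- SessionMeta ------------------------------------------------------------

#' Session / subject metadata
#'
#' Describes one recorded subject-session: who was recorded, to which study
#' group they belong, whether medication was taken for that session, and the
#' nominal session length in minutes.
#'
#' @param subjectId Character scalar.
#' @param group \code{"experimental"} or \code{"control"}.
#' @param medication \code{"with"}, \code{"without"} or \code{"n/a"}.
#' @param sex \code{"boy"}, \code{"girl"} or \code{NA}.
#' @param age Years, or \code{NA}.
#' @param sessionLength Positive number of minutes.
#' @return A \code{SessionMeta} object.
#' @examples
#' sessionMeta("s01", group = "experimental", sessionLength = 30)
#' @export sessionMeta
#' @exportClass SessionMeta
#' @aliases SessionMeta-class
setClass("SessionMeta",
  representation(subjectId = "character", group = "character",
                 medication = "character", sex = "character",
                 age = "numeric", sessionLength = "numeric"),
  validity = function(object) {
    if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
      return("subjectId must be a non-empty string")
    if (!object@group %in% c("experimental", "control"))
      return("group must be 'experimental' or 'control'")
    if (!object@medication %in% c("with", "without", "n/a"))
      return("medication must be 'with', 'without' or 'n/a'")
    if (!object@sex %in% c("boy", "girl") && !is.na(object@sex))
      return("sex must be 'boy', 'girl' or NA")
    if (length(object@sessionLength) != 1L || is.na(object@sessionLength) ||
        object@sessionLength <= 0)
      return("sessionLength must be a positive number of minutes")
    TRUE
  })

sessionMeta <- function(subjectId, group = c("experimental", "control"),
                        medication = "n/a", sex = NA_character_,
                        age = NA_real_, sessionLength = 30) {
  new("SessionMeta", subjectId = as.character(subjectId),
      group = match.arg(group), medication = medication,
      sex = as.character(sex), age = as.numeric(age),
      sessionLength = as.numeric(sessionLength))
}

setMethod("show", "SessionMeta", function(object) {
  cat(sprintf("SessionMeta: %s [%s, medication %s, sex %s], %g min\n",
              object@subjectId, object@group, object@medication,
              object@sex, object@sessionLength))
})

## ---- SkeletonStream ---------------------------------------------------------

#' A skeleton-frame stream
#'
#' Long-format container for a session's raw skeleton observations: one row
#' per joint sample, with columns \code{timestamp_s} (seconds from session
#' start), \code{body_index} (device slot 0-5), \code{joint} (canonical name),
#' \code{x_m}, \code{y_m}, \code{z_m} (metres, camera space; \code{z} is the
#' distance to the sensor) and \code{tracking_state} (\code{tracked},
#' \code{inferred} or \code{not_tracked}). Within each body slot timestamps
#' are non-decreasing, every (timestamp, body) frame carries all 25 joints
#' exactly once, and positions are finite whenever the state is not
#' \code{not_tracked}.
#'
#' @param frames A data.frame with the columns above.
#' @return A \code{SkeletonStream}.
#' @seealso [readSkeletonStream()], [assignIdentities()]
#' @export SkeletonStream
#' @exportClass SkeletonStream
#' @aliases SkeletonStream-class
setClass("SkeletonStream",
  representation(frames = "data.frame"),
  validity = function(object) .validateStreamFrames(object@frames))

.STREAM_COLS <- c("timestamp_s", "body_index", "joint",
                  "x_m", "y_m", "z_m", "tracking_state")

.validateStreamFrames <- function(df, full = TRUE) {
  miss <- setdiff(.STREAM_COLS, names(df))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(!df$joint %in% .JOINTS_25))
    return(paste("joint name(s) outside the 25-joint canon:",
                 paste(unique(df$joint[!df$joint %in% .JOINTS_25]),
                       collapse = ", ")))
  if (any(!df$tracking_state %in% .TRACKING_STATES))
    return("tracking_state must be tracked/inferred/not_tracked")
  if (any(df$timestamp_s < 0, na.rm = TRUE))
    return("timestamps must be non-negative seconds from session start")
  if (any(df$body_index < 0 | df$body_index > 5, na.rm = TRUE))
    return("body_index must lie in 0..5 (the device tracks at most 6 bodies)")
  obs <- df$tracking_state != "not_tracked"
  if (any(!is.finite(df$x_m[obs])) || any(!is.finite(df$y_m[obs])) ||
      any(!is.finite(df$z_m[obs])))
    return("positions must be finite whenever tracking_state != not_tracked")
  if (any(df$z_m[obs] < 0))
    return("z (distance to sensor) must be >= 0")
  if (full) {
    dt <- data.table::as.data.table(df)
    if (anyDuplicated(dt, by = c("timestamp_s", "body_index", "joint")))
      return("duplicate (timestamp, body, joint) sample")
    unsorted <- dt[, .(bad = is.unsorted(timestamp_s)), by = body_index]
    if (any(unsorted$bad))
      return("timestamps must be non-decreasing within each body_index")
    nj <- dt[, .(n = data.table::uniqueN(joint)),
             by = .(timestamp_s, body_index)]
    if (any(nj$n != 25L))
      return("every (timestamp, body) frame must carry exactly 25 joints")
  }
  TRUE
}

SkeletonStream <- function(frames) {
  frames <- as.data.frame(frames)[, .STREAM_COLS]
  frames$joint <- as.character(.normalizeJoints(frames$joint))
  frames$tracking_state <- as.character(frames$tracking_state)
  frames$body_index <- as.integer(frames$body_index)
  o <- order(frames$timestamp_s, frames$body_index,
             match(frames$joint, .JOINTS_25))
  new("SkeletonStream", frames = frames[o, , drop = FALSE])
}

#' @describeIn SkeletonStream Extract the long-format frame table.
#' @param x,object A \code{SkeletonStream}.
#' @export
frameData <- function(x) {
  stopifnot(is(x, "SkeletonStream"))
  data.table::as.data.table(x@frames)
}

setMethod("show", "SkeletonStream", function(object) {
  df <- object@frames
  nfr <- nrow(unique(df[, c("timestamp_s", "body_index")]))
  cat(sprintf(
    "SkeletonStream: %d joint samples, %d frames, %d body slot(s), %.1f s span\n",
    nrow(df), nfr, length(unique(df$body_index)),
    if (nrow(df)) diff(range(df$timestamp_s)) else 0))
})

## ---- BodyTrack / BodyTrackSet ----------------------------------------------

#' Persistent body tracks
#'
#' \code{assignIdentities()} converts a \code{SkeletonStream} into a
#' \code{BodyTrackSet}: the same long frame table with a \code{persistent_id}
#' column (1-6, in order of first detection), plus the final anchor (smoothed
#' spine-base location) of every identity and the policy used. A single
#' identity is extracted as a \code{BodyTrack} with \code{bodyTrack()}.
#'
#' @seealso [assignIdentities()], [interpolateGaps()], [buildMovementMatrix()]
#' @aliases BodyTrackSet-class BodyTrack-class
#' @exportClass BodyTrackSet
#' @exportClass BodyTrack
setClass("BodyTrackSet",
  representation(frames = "data.frame", anchors = "matrix",
                 policy = "GapPolicy"),
  validity = function(object) {
    if (!"persistent_id" %in% names(object@frames))
      return("frames must carry a persistent_id column")
    ids <- unique(object@frames$persistent_id)
    if (length(ids) && (any(ids < 1L) || any(ids > 6L)))
      return("persistent ids must lie in 1..6")
    if (length(ids) > 6L) return("at most 6 persistent identities")
    TRUE
  })

setClass("BodyTrack",
  representation(persistentId = "integer", frames = "data.frame",
                 anchor = "numeric", policy = "GapPolicy"),
  validity = function(object) {
    if (length(object@persistentId) != 1L) return("one persistentId")
    if (is.unsorted(unique(object@frames$timestamp_s)))
      return("track frames must be time-ordered")
    TRUE
  })

#' @describeIn BodyTrackSet Persistent ids present, in numeric order.
#' @param x,object A \code{BodyTrackSet}.
#' @export
trackIds <- function(x) {
  stopifnot(is(x, "BodyTrackSet"))
  sort(unique(x@frames$persistent_id))
}

#' @describeIn BodyTrackSet Extract one identity as a \code{BodyTrack}.
#' @param id Persistent id (1-6).
#' @export
bodyTrack <- function(x, id) {
  stopifnot(is(x, "BodyTrackSet"))
  id <- as.integer(id)
  if (!id %in% x@frames$persistent_id)
    stop("no track with persistent id ", id)
  fr <- x@frames[x@frames$persistent_id == id, , drop = FALSE]
  new("BodyTrack", persistentId = id, frames = fr,
      anchor = x@anchors[as.character(id), ], policy = x@policy)
}

#' @describeIn BodyTrackSet Frame table (with \code{persistent_id}) of the set.
#' @export
trackData <- function(x) {
  stopifnot(is(x, "BodyTrackSet") || is(x, "BodyTrack"))
  data.table::as.data.table(x@frames)
}

setMethod("show", "BodyTrackSet", function(object) {
  cat(sprintf("BodyTrackSet: %d track(s) [%s], %d joint samples\n",
              length(trackIds(object)),
              paste(trackIds(object), collapse = ", "),
              nrow(object@frames)))
})

setMethod("show", "BodyTrack", function(object) {
  ts <- unique(object@frames$timestamp_s)
  cat(sprintf(
    "BodyTrack %d: %d frames, %.1f-%.1f s, anchor (%.2f, %.2f, %.2f)\n",
    object@persistentId, length(ts), min(ts), max(ts),
    object@anchor[1], object@anchor[2], object@anchor[3]))
})

## ---- MovementMatrix ---------------------------------------------------------

#' Per-joint, per-minute movement matrix
#'
#' The core quantity of the package: for one subject-session, the distance
#' (metres) covered by each analysis joint in three-dimensional space during
#' each minute. Stored as a \code{SummarizedExperiment} with one
#' \code{pathLength} assay (rows = joints in report order, columns = minutes);
#' a minute in which a joint contributed no valid trajectory segment is
#' \code{NA} (missing), never zero. Subject metadata lives in
#' \code{metadata()}.
#'
#' @param values Numeric joints x minutes matrix (rownames = canonical joint
#'   names), \code{NA} for missing minutes, all other entries \code{>= 0}.
#' @param meta A [sessionMeta()] object (or \code{NULL} with
#'   \code{subjectId} given).
#' @param subjectId Used when \code{meta} is \code{NULL}.
#' @return A \code{MovementMatrix}.
#' @seealso [buildMovementMatrix()], [readMovementMatrix()], [compareGroups()]
#' @export MovementMatrix
#' @exportClass MovementMatrix
#' @aliases MovementMatrix-class
setClass("MovementMatrix", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"pathLength" %in% names(assays(object)))
      return("must carry a 'pathLength' assay")
    v <- assay(object, "pathLength")
    if (is.null(rownames(v)) || any(!rownames(v) %in% .JOINTS_25))
      return("rownames must be canonical joint names")
    if (any(v < 0, na.rm = TRUE))
      return("path lengths must be non-negative (missing minutes are NA)")
    TRUE
  })

MovementMatrix <- function(values, meta = NULL, subjectId = "subject") {
  values <- as.matrix(values)
  mode(values) <- "numeric"
  if (is.null(rownames(values)))
    stop("values must have joint rownames")
  rn <- .normalizeJoints(rownames(values))
  if (length(attr(rn, "bad")))
    stop("unknown joint name(s): ",
         paste(rownames(values)[attr(rn, "bad")], collapse = ", "))
  rownames(values) <- as.character(rn)
  colnames(values) <- paste0("minute_", seq_len(ncol(values)))
  if (is.null(meta))
    meta <- sessionMeta(subjectId, sessionLength = max(1, ncol(values)))
  se <- SummarizedExperiment(
    assays = SimpleList(pathLength = values),
    rowData = DataFrame(joint = rownames(values)),
    colData = DataFrame(minute = seq_len(ncol(values)),
                        row.names = colnames(values)),
    metadata = list(subjectId = meta@subjectId, group = meta@group,
                    medication = meta@medication, sex = meta@sex,
                    age = meta@age, sessionLength = meta@sessionLength))
  new("MovementMatrix", se)
}

#' @describeIn MovementMatrix The joints x minutes path-length matrix
#'   (metres per minute; \code{NA} = missing).
#' @param x A \code{MovementMatrix}.
#' @export
pathLength <- function(x) {
  stopifnot(is(x, "MovementMatrix"))
  assay(x, "pathLength")
}

#' @describeIn MovementMatrix Subject identifier.
#' @export
subjectId <- function(x) {
  stopifnot(is(x, "MovementMatrix"))
  metadata(x)$subjectId
}

#' @describeIn MovementMatrix Study group of the subject.
#' @export
subjectGroup <- function(x) {
  stopifnot(is(x, "MovementMatrix"))
  metadata(x)$group
}
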