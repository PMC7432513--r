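## Synthetic classroom sessions with known ground truth.
##
## Each joint follows a tethered (mean-reverting, AR(1)) random walk around
## its rest pose relative to the subject's seat: seated children fidget
## around their chairs, they do not diffuse away. The per-coordinate step
## noise is calibrated analytically so that the expected per-minute path
## length equals the profile intensity:
##
##   E||step|| for a 3-D Gaussian step with per-coordinate sd s is the
##   chi_3 mean  s * sqrt(2) * Gamma(2) / Gamma(3/2) = 2 s sqrt(2/pi),
##
## so with n = 60 * frameRate steps per minute the target intensity lambda
## fixes the stationary step sd s = lambda / (n * 2 sqrt(2/pi)). For an
## AR(1) x_t = phi x_{t-1} + e_t the stationary step variance is
## 2 sigma_e^2 / (1 + phi), giving sigma_e = s sqrt((1 + phi) / 2); additive
## observation noise nu contributes 2 nu^2 per coordinate to the step
## variance and is subtracted from the dynamic part, keeping the calibration
## exact. The constant is re-verified by Monte Carlo in the test suite.

.CHI3_MEAN <- 2 * sqrt(2 / pi)      # E||N(0, I3)||
.CHI3_VARFAC <- 3 - 8 / pi          # Var(||N(0, I3)||)
.TETHER_HALFLIFE_S <- 2             # mean-reversion half-life of the walk

## per-coordinate stationary step sd realizing intensity lambda (m/min)
.stepSd <- function(lambda, stepsPerMin) lambda / (stepsPerMin * .CHI3_MEAN)

## variance of one minute's path length caused by within-minute step noise
.withinMinuteVar <- function(lambda, frameRate) {
  n <- 60 * frameRate
  .CHI3_VARFAC * .stepSd(lambda, n)^2 * n
}

## Seated rest pose: joint offsets (x right, y up, z toward sensor) from the
## spine base, metres. Rough anthropometry of a seated child; only the
## spine-base offset (zero) matters for tracking, the rest is realism.
.REST_OFFSETS <- local({
  o <- list(
    spine_base = c(0, 0, 0), spine_mid = c(0, 0.25, 0),
    spine_shoulder = c(0, 0.45, 0), neck = c(0, 0.55, 0),
    head = c(0, 0.70, 0),
    left_shoulder = c(-0.18, 0.45, 0), right_shoulder = c(0.18, 0.45, 0),
    left_elbow = c(-0.25, 0.25, 0.05), right_elbow = c(0.25, 0.25, 0.05),
    left_wrist = c(-0.28, 0.10, 0.15), right_wrist = c(0.28, 0.10, 0.15),
    left_hand = c(-0.30, 0.05, 0.20), right_hand = c(0.30, 0.05, 0.20),
    left_hand_tip = c(-0.31, 0.02, 0.23),
    right_hand_tip = c(0.31, 0.02, 0.23),
    left_thumb = c(-0.28, 0.04, 0.21), right_thumb = c(0.28, 0.04, 0.21),
    left_hip = c(-0.10, -0.05, 0), right_hip = c(0.10, -0.05, 0),
    left_knee = c(-0.12, -0.35, 0.25), right_knee = c(0.12, -0.35, 0.25),
    left_ankle = c(-0.12, -0.70, 0.20), right_ankle = c(0.12, -0.70, 0.20),
    left_foot = c(-0.12, -0.75, 0.35), right_foot = c(0.12, -0.75, 0.35))
  o[.JOINTS_25]
})

## Typical seated per-joint intensities (metres/minute): trunk and head move
## a few metres per minute, wrists an order of magnitude more, ankles in
## between. Two presets reflect the group contrast of a clinical
## hyperactivity sample vs a control sample.
.INTENSITY_EXPERIMENTAL <- c(
  spine_base = 2.9, spine_mid = 2.1, neck = 3.0, head = 3.5,
  left_shoulder = 2.8, left_elbow = 7.7, left_wrist = 13.4,
  right_shoulder = 2.8, right_elbow = 9.5, right_wrist = 16.8,
  left_hip = 3.0, left_knee = 4.0, left_ankle = 8.2,
  right_hip = 3.0, right_knee = 4.2, right_ankle = 9.0,
  spine_shoulder = 2.7)[.JOINTS_17]
.INTENSITY_CONTROL <- c(
  spine_base = 2.5, spine_mid = 1.6, neck = 2.3, head = 2.4,
  left_shoulder = 2.1, left_elbow = 6.5, left_wrist = 12.8,
  right_shoulder = 2.0, right_elbow = 7.9, right_wrist = 15.4,
  left_hip = 2.7, left_knee = 3.2, left_ankle = 8.2,
  right_hip = 2.7, right_knee = 3.1, right_ankle = 8.6,
  spine_shoulder = 2.0)[.JOINTS_17]
.MEDICATION_FACTOR <- 0.55  # intensity multiplier when medicated

## the 8 non-analysis joints ride on the wrist / ankle of their limb
.deriveFull25 <- function(int17) {
  c(int17,
    left_hand = unname(int17["left_wrist"]) * 1.10,
    left_hand_tip = unname(int17["left_wrist"]) * 1.20,
    left_thumb = unname(int17["left_wrist"]) * 1.10,
    right_hand = unname(int17["right_wrist"]) * 1.10,
    right_hand_tip = unname(int17["right_wrist"]) * 1.20,
    right_thumb = unname(int17["right_wrist"]) * 1.10,
    left_foot = unname(int17["left_ankle"]) * 1.05,
    right_foot = unname(int17["right_ankle"]) * 1.05)[.JOINTS_25]
}

## ---- profiles and config ----------------------------------------------------

#' Subject profile for the session generator
#'
#' Describes one synthetic subject: study group, medication state, target
#' expected path length per minute for each of the 17 analysis joints
#' (metres; the hand/foot-region joints are derived from the wrist/ankle
#' intensity of their limb), minute-to-minute intensity variability, seat
#' position, and occlusion behaviour.
#'
#' Defaults encode the study conditions being emulated: trunk/head
#' intensities of a few metres per minute and wrist intensities an order of
#' magnitude larger, with a clinical (\code{"experimental"}) sample moving
#' more than the \code{"control"} sample; taking medication multiplies
#' intensities by 0.55, reproducing the uniform direction of the
#' with/without-medication contrast. Occlusions (temporary loss of the whole
#' body) arrive as a Poisson process at 0.3 events/minute with exponentially
#' distributed durations of mean 3 s.
#'
#' @param subjectId Character scalar.
#' @param group \code{"experimental"} or \code{"control"}; selects the
#'   default intensity preset.
#' @param medication \code{"with"}, \code{"without"} or \code{"n/a"}.
#' @param sex \code{"boy"}, \code{"girl"} or \code{NA}.
#' @param intensity Named numeric vector over the 17 analysis joints
#'   (metres/minute), or a scalar applied to all joints; \code{NULL} for the
#'   group preset.
#' @param minuteSd Per-minute intensity SD: either a single fraction of the
#'   intensity (default 0.25) or a named absolute vector (metres/minute).
#' @param seat Seat position (3-vector, metres, camera space) or \code{NULL}
#'   to let [simulateSession()] place seats 1 m apart in a row.
#' @param occlusionRate Whole-body occlusion events per minute.
#' @param occlusionDuration Mean occlusion duration, seconds.
#' @param jointDropoutRate Per-joint drop-out events per minute (samples
#'   marked \code{not_tracked}); default 0.
#' @param jointDropoutDuration Mean drop-out duration, seconds.
#' @return A \code{SubjectProfile} object.
#' @examples
#' subjectProfile("s1", group = "control")
#' @export subjectProfile
#' @exportClass SubjectProfile
#' @aliases SubjectProfile-class
setClass("SubjectProfile",
  representation(subjectId = "character", group = "character",
                 medication = "character", sex = "character",
                 intensity = "numeric", minuteSd = "numeric",
                 seat = "numeric", occlusionRate = "numeric",
                 occlusionDuration = "numeric", jointDropoutRate = "numeric",
                 jointDropoutDuration = "numeric"),
  validity = function(object) {
    if (!identical(names(object@intensity), .JOINTS_17))
      return("intensity must be named over the 17 analysis joints")
    if (any(object@intensity < 0)) return("intensities must be >= 0")
    if (!identical(names(object@minuteSd), .JOINTS_17))
      return("minuteSd must be named over the 17 analysis joints")
    if (any(object@minuteSd < 0)) return("minuteSd must be >= 0")
    if (object@occlusionRate < 0 || object@occlusionDuration < 0 ||
        object@jointDropoutRate < 0 || object@jointDropoutDuration < 0)
      return("occlusion/drop-out parameters must be >= 0")
    if (length(object@seat) != 3L)
      return("seat must be a 3-vector (possibly NA)")
    TRUE
  })

subjectProfile <- function(subjectId, group = c("experimental", "control"),
                           medication = "n/a", sex = NA_character_,
                           intensity = NULL, minuteSd = 0.25, seat = NULL,
                           occlusionRate = 0.3, occlusionDuration = 3,
                           jointDropoutRate = 0, jointDropoutDuration = 0.25) {
  group <- match.arg(group)
  if (is.null(intensity))
    intensity <- if (group == "experimental") .INTENSITY_EXPERIMENTAL
                 else .INTENSITY_CONTROL
  if (length(intensity) == 1L && is.null(names(intensity)))
    intensity <- setNames(rep(intensity, 17L), .JOINTS_17)
  intensity <- intensity[.JOINTS_17]
  if (identical(medication, "with"))
    intensity <- intensity * .MEDICATION_FACTOR
  if (length(minuteSd) == 1L && is.null(names(minuteSd)))
    minuteSd <- intensity * minuteSd
  minuteSd <- minuteSd[.JOINTS_17]
  new("SubjectProfile", subjectId = as.character(subjectId), group = group,
      medication = medication, sex = as.character(sex),
      intensity = intensity, minuteSd = minuteSd,
      seat = if (is.null(seat)) rep(NA_real_, 3L) else as.numeric(seat),
      occlusionRate = occlusionRate, occlusionDuration = occlusionDuration,
      jointDropoutRate = jointDropoutRate,
      jointDropoutDuration = jointDropoutDuration)
}

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf(
    "SubjectProfile %s [%s, medication %s]: mean intensity %.1f m/min, occlusion %.2g/min\n",
    object@subjectId, object@group, object@medication,
    mean(object@intensity), object@occlusionRate))
})

#' Session generator configuration
#'
#' @param nSubjects 1-6 subjects (the sensor tracks at most 6 bodies).
#' @param sessionLength Minutes (default 30, the nominal workshop length).
#' @param frameRate Sampling rate in Hz (default 30, the sensor's nominal
#'   rate; the intensity calibration is exact at any rate).
#' @param noiseSd Additive per-coordinate observation noise sd (metres),
#'   folded into the calibration; default 0.
#' @param seed Integer seed; every run is fully reproducible from it.
#' @return A \code{SimConfig} object.
#' @examples
#' simConfig(nSubjects = 2, sessionLength = 5, frameRate = 10, seed = 1)
#' @export simConfig
#' @exportClass SimConfig
#' @aliases SimConfig-class
setClass("SimConfig",
  representation(nSubjects = "integer", sessionLength = "numeric",
                 frameRate = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nSubjects < 1L || object@nSubjects > 6L)
      return("nSubjects must lie in 1..6")
    if (object@sessionLength <= 0) return("sessionLength must be > 0")
    if (object@frameRate <= 0) return("frameRate must be > 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

simConfig <- function(nSubjects = 4, sessionLength = 30, frameRate = 30,
                      noiseSd = 0, seed = 1) {
  new("SimConfig", nSubjects = as.integer(nSubjects),
      sessionLength = as.numeric(sessionLength),
      frameRate = as.numeric(frameRate), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d subject(s), %g min at %g Hz, noise %g m, seed %d\n",
    object@nSubjects, object@sessionLength, object@frameRate,
    object@noiseSd, object@seed))
})

## ---- session generation -----------------------------------------------------

## Simulate the 3 x T displacement of one joint: stationary AR(1) around 0,
## per-minute step sd from lambdaMin (vector over minutes), plus observation
## noise nu. Returns a T x 3 matrix.
.simJointDisplacement <- function(lambdaMin, stepsPerMin, frameRate, phi, nu) {
  TT <- length(lambdaMin) * stepsPerMin
  sTot <- .stepSd(lambdaMin, stepsPerMin)           # calibrated total step sd
  sDyn2 <- sTot^2 - 2 * nu^2
  if (any(sDyn2 < 0))
    stop("noiseSd too large for the requested intensity: 2*noiseSd^2 ",
         "exceeds the calibrated step variance")
  sigmaE <- sqrt(sDyn2 * (1 + phi) / 2)             # AR(1) innovation sd
  sigmaRep <- rep(sigmaE, each = stepsPerMin)
  s0 <- sqrt(sDyn2[1L] / (2 * (1 - phi)))           # stationary position sd
  out <- matrix(0, TT, 3L)
  for (k in 1:3) {
    e <- rnorm(TT, 0, sigmaRep)
    x0 <- rnorm(1L, 0, s0)
    x <- c(x0, as.numeric(stats::filter(e[-1L], phi, method = "recursive",
                                        init = x0)))
    if (nu > 0) x <- x + rnorm(TT, 0, nu)
    out[, k] <- x
  }
  out
}

## Path length per minute from a T x 3 position matrix on the regular grid.
.truthPerMinute <- function(pos, stepsPerMin, nMinutes) {
  d <- sqrt(rowSums(diff(pos)^2))
  bin <- rep(seq_len(nMinutes), each = stepsPerMin)[-1L]  # later endpoint
  rs <- rowsum(d, bin)
  out <- rep(NA_real_, nMinutes)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Simulate a multi-subject classroom session
#'
#' Generates a fully reproducible skeleton stream for up to six seated
#' subjects, together with the ground-truth movement matrix of each subject.
#' Per joint, motion is a tethered random walk whose step noise is calibrated
#' so the expected per-minute path length equals the profile intensity (see
#' the package vignette for the derivation); minute-to-minute intensity
#' varies by the profile's \code{minuteSd}. Whole-body occlusions remove the
#' subject's frames for their duration, after which the body reappears at its
#' seat -- in the lowest free device slot, which exercises the
#' re-identification logic downstream. Joint drop-outs (if enabled) mark
#' samples \code{not_tracked}.
#'
#' Ground truth is computed from the generated trajectories before occlusion
#' masking, so truth minutes are never missing.
#'
#' @param profiles List of [subjectProfile()] (at most 6).
#' @param config A [simConfig()]; \code{config@nSubjects} must equal
#'   \code{length(profiles)}.
#' @return List with \code{stream} (a [SkeletonStream()]), \code{truth}
#'   (named list of [MovementMatrix()] keyed by subject id) and
#'   \code{slotMap} (data frame mapping each subject id to its first device
#'   slot, first detection time, and the persistent id the tracker is
#'   expected to issue).
#' @examples
#' sim <- simulateSession(list(subjectProfile("a"), subjectProfile("b")),
#'                        simConfig(nSubjects = 2, sessionLength = 1,
#'                                  frameRate = 5, seed = 42))
#' sim$stream
#' @export
simulateSession <- function(profiles, config) {
  stopifnot(is(config, "SimConfig"))
  if (length(profiles) > 6L)
    stop("capacity error: at most 6 subjects can be simulated ",
         "(the sensor tracks at most 6 bodies)")
  if (length(profiles) != config@nSubjects)
    stop("config@nSubjects must match length(profiles)")
  lapply(profiles, function(p) stopifnot(is(p, "SubjectProfile")))
  set.seed(config@seed)

  ns <- length(profiles)
  L <- as.integer(ceiling(config@sessionLength))
  f <- config@frameRate
  stepsPerMin <- as.integer(round(60 * f))
  TT <- L * stepsPerMin
  tgrid <- (seq_len(TT) - 1L) / f
  phi <- exp(-log(2) / (.TETHER_HALFLIFE_S * f))

  ## seats: 1 m apart in a row, 2.5 m from the sensor, unless given
  seats <- lapply(seq_len(ns), function(i) {
    s <- profiles[[i]]@seat
    if (all(is.finite(s))) s
    else c((i - (ns + 1) / 2) * 1.0, 0.3, 2.5)
  })

  presence <- matrix(TRUE, TT, ns)
  subjectRows <- vector("list", ns)
  truth <- vector("list", ns)

  for (i in seq_len(ns)) {
    pr <- profiles[[i]]
    int25 <- .deriveFull25(pr@intensity)
    sd25 <- .deriveFull25(pr@minuteSd)
    ## whole-body occlusion windows
    nOcc <- rpois(1L, pr@occlusionRate * L)
    if (nOcc > 0L) {
      st <- runif(nOcc, 0, 60 * L)
      du <- rexp(nOcc, 1 / pr@occlusionDuration)
      for (k in seq_len(nOcc))
        presence[tgrid >= st[k] & tgrid < st[k] + du[k], i] <- FALSE
    }
    jointTabs <- vector("list", 25L)
    truthMat <- matrix(NA_real_, 17L, L, dimnames = list(.JOINTS_17, NULL))
    for (j in seq_along(.JOINTS_25)) {
      jn <- .JOINTS_25[j]
      lambdaMin <- pmax(0, rnorm(L, int25[jn], sd25[jn]))
      disp <- .simJointDisplacement(lambdaMin, stepsPerMin, f, phi,
                                    config@noiseSd)
      pos <- sweep(disp, 2L, seats[[i]] + .REST_OFFSETS[[jn]], `+`)
      if (jn %in% .JOINTS_17)
        truthMat[jn, ] <- .truthPerMinute(pos, stepsPerMin, L)
      state <- rep("tracked", TT)
      nDrop <- if (pr@jointDropoutRate > 0)
        rpois(1L, pr@jointDropoutRate * L) else 0L
      if (nDrop > 0L) {
        st <- runif(nDrop, 0, 60 * L)
        du <- rexp(nDrop, 1 / pr@jointDropoutDuration)
        for (k in seq_len(nDrop)) {
          m <- tgrid >= st[k] & tgrid < st[k] + du[k]
          state[m] <- "not_tracked"
          pos[m, ] <- NA_real_
        }
      }
      jointTabs[[j]] <- data.table::data.table(
        frame = seq_len(TT), joint = jn,
        x_m = pos[, 1L], y_m = pos[, 2L], z_m = pos[, 3L],
        tracking_state = state)
    }
    subjectRows[[i]] <- data.table::rbindlist(jointTabs)
    meta <- sessionMeta(pr@subjectId, group = pr@group,
                        medication = pr@medication, sex = pr@sex,
                        sessionLength = L)
    truth[[i]] <- MovementMatrix(truthMat, meta = meta)
  }
  names(truth) <- vapply(profiles, function(p) p@subjectId, "")

  ## device slots: continuing bodies keep their slot, (re)appearing bodies
  ## take the lowest slot free at that moment
  slots <- matrix(NA_integer_, TT, ns)
  pat <- presence %*% (2^(seq_len(ns) - 1L))
  r <- rle(as.numeric(pat))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  prev <- rep(NA_integer_, ns)
  for (k in seq_along(starts)) {
    here <- presence[starts[k], ]
    cur <- ifelse(here, prev, NA_integer_)
    for (i in which(here & is.na(cur))) {
      free <- setdiff(0:5, cur)
      cur[i] <- free[1L]
    }
    slots[starts[k]:ends[k], ] <- matrix(cur, r$lengths[k], ns, byrow = TRUE)
    prev <- cur
  }

  frames <- data.table::rbindlist(lapply(seq_len(ns), function(i) {
    dt <- subjectRows[[i]]
    keep <- presence[dt$frame, i]
    dt <- dt[keep]
    dt[, `:=`(timestamp_s = tgrid[frame],
              body_index = slots[cbind(frame, i)])]
    dt[, frame := NULL]
    dt
  }))
  data.table::setcolorder(frames, .STREAM_COLS)
  ## expected persistent numbering: order of first detection, ties broken by
  ## device slot (matches how identities are issued downstream)
  firstFrame <- vapply(seq_len(ns), function(i) which(presence[, i])[1L], 0L)
  slotAtFirst <- vapply(seq_len(ns), function(i)
    slots[firstFrame[i], i], 0L)
  pid <- integer(ns)
  pid[order(firstFrame, slotAtFirst)] <- seq_len(ns)
  list(stream = SkeletonStream(frames), truth = truth,
       slotMap = data.frame(
         subject_id = names(truth),
         initial_slot = slotAtFirst,
         first_seen_s = tgrid[firstFrame],
         persistent_id = pid))
}

#' Simulate two groups with a programmed effect size
#'
#' Builds one set of sessions per group in which group 2's per-joint
#' intensities are shifted upward so that the standardized mean difference of
#' per-minute path lengths equals \code{effectSizeD} in expectation. Both
#' groups share the same absolute minute-to-minute SD, so the per-minute
#' values are (approximately) equal-variance Gaussians and the binormal
#' identity \eqn{AUC = \Phi(d/\sqrt{2})} applies. The shift accounts for both
#' the programmed minute-level variability and the analytic within-minute
#' path-length noise.
#'
#' Subjects are packed into sessions of at most \code{config@nSubjects}
#' bodies; session seeds are derived deterministically from
#' \code{config@seed}.
#'
#' @param nPerGroup Subjects per group.
#' @param effectSizeD Programmed standardized mean difference (>= 0).
#' @param config A [simConfig()].
#' @param baseProfile A [subjectProfile()] template for group 1 (default: the
#'   experimental intensity preset with default occlusion behaviour).
#' @return List with elements \code{group1} and \code{group2}, each a list of
#'   [simulateSession()] results, plus \code{shift}, the per-joint intensity
#'   shift applied to group 2 (metres/minute).
#' @examples
#' tg <- simulateTwoGroups(2, 0.8,
#'                         simConfig(nSubjects = 2, sessionLength = 1,
#'                                   frameRate = 5, seed = 3))
#' names(tg)
#' @export
simulateTwoGroups <- function(nPerGroup, effectSizeD, config,
                              baseProfile = NULL) {
  stopifnot(effectSizeD >= 0)
  if (is.null(baseProfile))
    baseProfile <- subjectProfile("template", group = "experimental")
  lam1 <- baseProfile@intensity
  tau <- baseProfile@minuteSd
  sdTot <- sqrt(tau^2 + .withinMinuteVar(lam1, config@frameRate))
  shift <- effectSizeD * sdTot
  mkProfiles <- function(lam, grp, tag) {
    lapply(seq_len(nPerGroup), function(i) {
      subjectProfile(sprintf("%s_%02d", tag, i), group = grp,
                     medication = baseProfile@medication,
                     intensity = lam, minuteSd = tau,
                     occlusionRate = baseProfile@occlusionRate,
                     occlusionDuration = baseProfile@occlusionDuration,
                     jointDropoutRate = baseProfile@jointDropoutRate,
                     jointDropoutDuration = baseProfile@jointDropoutDuration)
    })
  }
  p1 <- mkProfiles(lam1, "control", "g1")
  p2 <- mkProfiles(lam1 + shift, "experimental", "g2")
  runGroup <- function(profs, offset) {
    chunks <- split(profs, ceiling(seq_along(profs) / config@nSubjects))
    lapply(seq_along(chunks), function(k) {
      cfg <- simConfig(nSubjects = length(chunks[[k]]),
                       sessionLength = config@sessionLength,
                       frameRate = config@frameRate,
                       noiseSd = config@noiseSd,
                       seed = as.integer((as.numeric(config@seed) + offset +
                                            1009 * k) %% 2147483647))
      simulateSession(chunks[[k]], cfg)
    })
  }
  list(group1 = runGroup(p1, 0L), group2 = runGroup(p2, 500000L),
       shift = shift)
}

#' Stationary per-minute path-length values (analytic shortcut)
#'
#' Draws per-minute path-length observations directly from the distribution
#' the frame-level generator realizes for one joint: Gaussian with mean
#' \code{intensity} and variance \code{minuteSd^2} plus the analytic
#' within-minute path-length variance, truncated at zero. Useful for fast
#' calibration studies (e.g. type-I error of the testing battery) that do not
#' need frames.
#'
#' @param n Number of minutes to draw.
#' @param intensity Expected path length per minute (metres).
#' @param minuteSd Minute-level intensity SD (metres; absolute).
#' @param frameRate Frame rate governing the within-minute noise.
#' @return Numeric vector of length \code{n}.
#' @export
simulateMinuteValues <- function(n, intensity = 6, minuteSd = 1.5,
                                 frameRate = 30) {
  sdTot <- sqrt(minuteSd^2 + .withinMinuteVar(intensity, frameRate))
  pmax(0, rnorm(n, intensity, sdTot))
}

#' Simulate dual-observer behaviour counts
#'
#' Observer A's per-subject count of each behaviour (\code{leave_seat},
#' \code{squirm}) is Poisson with mean \code{rateA}; observer B reproduces
#' A's count with probability \code{agreementProb} and otherwise draws an
#' independent Poisson count.
#'
#' @param nSubjects Number of subjects.
#' @param rateA Poisson mean of observer A's counts.
#' @param agreementProb Probability that B copies A exactly.
#' @param seed Integer seed.
#' @return Data frame with columns \code{subject_id}, \code{behaviour},
#'   \code{observer_a}, \code{observer_b}.
#' @seealso [observerKappa()]
#' @examples
#' oc <- simulateObserverCounts(20, rateA = 6, agreementProb = 1, seed = 1)
#' observerKappa(oc)  # 1
#' @export
simulateObserverCounts <- function(nSubjects, rateA = 6, agreementProb = 0.9,
                                   seed = 1) {
  stopifnot(nSubjects >= 1, rateA >= 0,
            agreementProb >= 0, agreementProb <= 1)
  set.seed(as.integer(seed))
  beh <- c("leave_seat", "squirm")
  out <- expand.grid(subject_id = sprintf("s%02d", seq_len(nSubjects)),
                     behaviour = beh, stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$behaviour), ]
  n <- nrow(out)
  a <- rpois(n, rateA)
  copy <- runif(n) < agreementProb
  b <- ifelse(copy, a, rpois(n, rateA))
  out$observer_a <- a
  out$observer_b <- b
  rownames(out) <- NULL
  out
}
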