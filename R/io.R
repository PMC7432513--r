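## Reading and writing skeleton streams and movement matrices.
##
## Skeleton stream, CSV flavour: '#'-prefixed metadata lines, then the header
##   timestamp_s,body_index,joint,x_m,y_m,z_m,tracking_state
## and one row per joint sample. JSON-lines flavour: one frame object per line,
##   {"timestamp_s": t, "body_index": b, "joints": [{joint,x_m,y_m,z_m,
##    tracking_state}, ...]}.
## Movement matrix: TSV, first column `joint`, then minute_1..minute_N;
## an empty cell is a missing minute. Units are metres throughout and are
## declared in the leading comment line of every file written.

#' Read a skeleton-frame stream
#'
#' Parses a long-format CSV or JSON-lines skeleton stream into a
#' [SkeletonStream()]. Joint names are validated against the 25-joint canon
#' (Kinect SDK spellings such as \code{"SpineBase"} are accepted); malformed
#' rows are rejected with the offending line number; duplicate
#' (timestamp, body, joint) samples and time-disordered bodies are validation
#' errors, never silently repaired.
#'
#' @param path File path (or connection for \code{format = "csv"}).
#' @param format \code{"csv"} (default) or \code{"jsonl"}.
#' @return A \code{SkeletonStream}.
#' @seealso [writeSkeletonStream()]
#' @export
readSkeletonStream <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "csv") .readStreamCsv(lines) else .readStreamJsonl(lines)
}

.readStreamCsv <- function(lines) {
  lineno <- seq_along(lines)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) stop("empty stream: no header line found")
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (!identical(trimws(header), .STREAM_COLS))
    stop("line ", lineno[[1L]], ": header must be '",
         paste(.STREAM_COLS, collapse = ","), "'")
  body <- lines[-1L]; lineno <- lineno[-1L]
  if (!length(body)) {
    empty <- as.data.frame(setNames(
      list(numeric(), integer(), character(), numeric(), numeric(),
           numeric(), character()), .STREAM_COLS))
    return(SkeletonStream(empty))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L))
    stop("line ", lineno[which(nf != 7L)[1L]],
         ": expected 7 comma-separated fields, found ", nf[nf != 7L][1L])
  m <- matrix(trimws(unlist(parts, use.names = FALSE)), ncol = 7L,
              byrow = TRUE)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v) & !(m[, col] %in% c("NA", "NaN", "")))
    if (length(bad))
      stop("line ", lineno[bad[1L]], ": non-numeric ", name, " '",
           m[bad[1L], col], "'")
    v
  }
  joints <- .normalizeJoints(m[, 3L])
  if (length(attr(joints, "bad"))) {
    i <- attr(joints, "bad")[1L]
    stop("line ", lineno[i], ": unknown joint name '", m[i, 3L],
         "' (not in the 25-joint canon)")
  }
  states <- m[, 7L]
  if (any(!states %in% .TRACKING_STATES))
    stop("line ", lineno[which(!states %in% .TRACKING_STATES)[1L]],
         ": invalid tracking_state '",
         states[!states %in% .TRACKING_STATES][1L], "'")
  df <- data.frame(
    timestamp_s = num(1L, "timestamp_s"),
    body_index = as.integer(num(2L, "body_index")),
    joint = as.character(joints),
    x_m = num(4L, "x_m"), y_m = num(5L, "y_m"), z_m = num(6L, "z_m"),
    tracking_state = states)
  SkeletonStream(df)
}

.readStreamJsonl <- function(lines) {
  lineno <- seq_along(lines)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fr <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                   error = function(e)
                     stop("line ", lineno[i], ": malformed JSON frame: ",
                          conditionMessage(e), call. = FALSE))
    if (!all(c("timestamp_s", "body_index", "joints") %in% names(fr)))
      stop("line ", lineno[i],
           ": frame needs timestamp_s, body_index and joints")
    j <- as.data.frame(fr$joints)
    jn <- .normalizeJoints(j$joint)
    if (length(attr(jn, "bad")))
      stop("line ", lineno[i], ": unknown joint name '",
           j$joint[attr(jn, "bad")[1L]], "'")
    rows[[i]] <- data.frame(
      timestamp_s = as.numeric(fr$timestamp_s),
      body_index = as.integer(fr$body_index),
      joint = as.character(jn),
      x_m = as.numeric(j$x_m), y_m = as.numeric(j$y_m),
      z_m = as.numeric(j$z_m),
      tracking_state = as.character(j$tracking_state))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(
      list(numeric(), integer(), character(), numeric(), numeric(),
           numeric(), character()), .STREAM_COLS))
  SkeletonStream(df)
}

#' Write a skeleton-frame stream
#'
#' Writes a [SkeletonStream()] so that re-reading reproduces it: timestamps
#' and coordinates are printed with 7 decimals (sub-micrometre /
#' sub-microsecond round-trip). A leading comment line declares the units.
#'
#' @param stream A \code{SkeletonStream}.
#' @param path Output file path.
#' @param format \code{"csv"} (default) or \code{"jsonl"}.
#' @return Invisibly, \code{path}.
#' @seealso [readSkeletonStream()]
#' @export
writeSkeletonStream <- function(stream, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(is(stream, "SkeletonStream"))
  df <- stream@frames
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# units: metres (camera space); timestamps: seconds from session start",
             con)
  fmt <- function(v) {
    out <- sprintf("%.7f", v)
    out[is.na(v)] <- "NA"
    out
  }
  if (format == "csv") {
    writeLines(paste(.STREAM_COLS, collapse = ","), con)
    if (nrow(df))
      writeLines(paste(fmt(df$timestamp_s), df$body_index, df$joint,
                       fmt(df$x_m), fmt(df$y_m), fmt(df$z_m),
                       df$tracking_state, sep = ","), con)
  } else {
    dt <- data.table::as.data.table(df)
    if (nrow(dt)) {
      grp <- dt[, .(line = jsonlite::toJSON(
        list(timestamp_s = timestamp_s[1L], body_index = body_index[1L],
             joints = data.frame(joint = joint, x_m = x_m, y_m = y_m,
                                 z_m = z_m,
                                 tracking_state = tracking_state)),
        auto_unbox = TRUE, digits = NA, na = "null")),
        by = .(timestamp_s, body_index)]
      writeLines(grp$line, con)
    }
  }
  invisible(path)
}

#' Read / write a movement matrix
#'
#' TSV interchange for [MovementMatrix()] objects: first column \code{joint},
#' then \code{minute_1..minute_N}; an empty cell marks a missing minute and is
#' read back as \code{NA}, never as zero. Metadata (subject id, group,
#' medication, sex, session length) is carried in \code{#}-prefixed
#' \code{key: value} comment lines. Negative values and ragged rows are
#' validation errors.
#'
#' @param path File path.
#' @return \code{readMovementMatrix}: a \code{MovementMatrix}.
#' @seealso [buildMovementMatrix()]
#' @export
readMovementMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  cm <- grep("^#", lines, value = TRUE)
  for (l in cm) {
    kv <- sub("^#\\s*", "", l)
    if (grepl(":", kv, fixed = TRUE)) {
      k <- trimws(sub(":.*$", "", kv))
      v <- trimws(sub("^[^:]*:", "", kv))
      meta[[k]] <- v
    }
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty movement matrix file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  if (header[1L] != "joint")
    stop("first column must be 'joint'")
  ncol_exp <- length(header)
  body <- parts[-1L]
  ## a trailing empty cell is dropped by strsplit; pad it back
  body <- lapply(body, function(p)
    if (length(p) < ncol_exp) c(p, rep("", ncol_exp - length(p))) else p)
  nf <- lengths(body)
  if (any(nf != ncol_exp))
    stop("ragged row: expected ", ncol_exp, " fields, found ",
         nf[nf != ncol_exp][1L])
  m <- do.call(rbind, body)
  vals <- suppressWarnings(
    matrix(as.numeric(m[, -1L, drop = FALSE]), nrow = nrow(m)))
  raw <- m[, -1L, drop = FALSE]
  badnum <- nzchar(raw) & raw != "NA" & is.na(vals)
  if (any(badnum))
    stop("non-numeric value '", raw[badnum][1L], "' in movement matrix")
  if (any(vals < 0, na.rm = TRUE))
    stop("negative path length in movement matrix: values must be >= 0")
  rownames(vals) <- m[, 1L]
  sl <- suppressWarnings(as.numeric(meta[["session_length_min"]]))
  sm <- sessionMeta(
    subjectId = meta[["subject_id"]] %||% "subject",
    group = meta[["group"]] %||% "experimental",
    medication = meta[["medication"]] %||% "n/a",
    sex = if (is.null(meta[["sex"]]) || meta[["sex"]] == "NA")
      NA_character_ else meta[["sex"]],
    sessionLength = if (length(sl) && !is.na(sl)) sl else ncol(vals))
  MovementMatrix(vals, meta = sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readMovementMatrix
#' @param x A \code{MovementMatrix}.
#' @return \code{writeMovementMatrix}: invisibly, \code{path}.
#' @export
writeMovementMatrix <- function(x, path) {
  stopifnot(is(x, "MovementMatrix"))
  v <- pathLength(x)
  md <- metadata(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# units: metres per minute",
               paste0("# subject_id: ", md$subjectId),
               paste0("# group: ", md$group),
               paste0("# medication: ", md$medication),
               paste0("# sex: ", md$sex),
               paste0("# session_length_min: ", md$sessionLength)), con)
  writeLines(paste(c("joint", colnames(v)), collapse = "\t"), con)
  cells <- matrix(sprintf("%.9g", v), nrow = nrow(v))
  cells[is.na(v)] <- ""
  writeLines(paste(rownames(v), apply(cells, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}
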