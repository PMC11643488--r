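# Extended-XYZ and minimal PDB readers/writers.
#
# Extended-XYZ dialect: per frame,
#   line 1: particle count
#   line 2: key=value metadata (box=<A> time=<ps> wrapped=<0|1>), free order
#   lines 3..n+2: label x y z [element]
# Coordinates are written with 6 decimals (A), below any analysis tolerance.

.parse_kv <- function(line) {
  toks <- regmatches(line, gregexpr("[A-Za-z_]+=[^ ]+", line))[[1]]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

#' Read an extended-XYZ trajectory
#'
#' The comment line of each frame carries `box=`, `time=` (ps) and
#' `wrapped=` key=value metadata. Particle counts and ordering must be
#' constant across frames; `dt` is taken from the time stamps of the first
#' two frames (1 ps for single-frame files without time metadata).
#'
#' @param path file path.
#' @return A [Trajectory-class].
#' @seealso [writeXYZ()]
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  i <- 1L
  frames <- list(); times <- numeric(); boxes <- numeric(); wraps <- logical()
  labels0 <- NULL; elements0 <- NULL
  fno <- 0L
  while (i <= length(lines)) {
    fno <- fno + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L)
      .stop_labeled("parse_error", "frame %d: bad particle count line", fno)
    if (i + 1L + n > length(lines))
      .stop_labeled("parse_error",
                    "frame %d: declared %d atoms but file ends early", fno, n)
    meta <- .parse_kv(lines[i + 1L])
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "[ \t]+")
    nt <- lengths(toks)
    if (any(nt < 4L))
      .stop_labeled("parse_error",
                    "frame %d: coordinate line with fewer than 4 fields", fno)
    lab <- vapply(toks, `[`, "", 1L)
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(toks, `[`, 2:4)))), ncol = 3, byrow = TRUE)
    if (anyNA(xyz))
      .stop_labeled("parse_error", "frame %d: non-numeric coordinate", fno)
    ele <- ifelse(nt >= 5L, vapply(toks, function(t) t[5L], ""), lab)
    if (is.null(labels0)) { labels0 <- lab; elements0 <- ele }
    else if (length(lab) != length(labels0))
      .stop_labeled("inconsistent_frames",
                    "frame %d has %d particles, frame 1 has %d",
                    fno, length(lab), length(labels0))
    frames[[fno]] <- xyz
    times[fno] <- if (!is.null(meta$time)) as.numeric(meta$time) else NA_real_
    boxes[fno] <- if (!is.null(meta$box)) as.numeric(meta$box) else NA_real_
    wraps[fno] <- if (!is.null(meta$wrapped)) meta$wrapped %in% c("1", "T", "TRUE") else FALSE
    i <- i + 2L + n
  }
  dt <- if (length(times) > 1L && !anyNA(times[1:2])) times[2] - times[1] else 1
  ele_mapped <- ifelse(elements0 %in% names(.VDW_RADII), elements0, "C")
  trajectory(frames, dt = dt, boxEdge = boxes[1], labels = labels0,
             elements = ele_mapped, wrapped = isTRUE(wraps[1]))
}

#' Write an extended-XYZ trajectory
#'
#' @param traj a [Trajectory-class] or [Configuration-class].
#' @param path output file path.
#' @param digits coordinate decimals (default 6).
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(traj, path, digits = 6) {
  if (is(traj, "Configuration"))
    traj <- trajectory(list(traj@positions), dt = 1, boxEdge = traj@boxEdge,
                       labels = traj@labels, elements = traj@elements,
                       wrapped = FALSE)
  d <- dim(traj@coords)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df %%s", digits, digits, digits)
  for (f in seq_len(d[1])) {
    writeLines(as.character(d[2]), con)
    writeLines(sprintf("box=%s time=%s wrapped=%d",
                       format(traj@boxEdge, digits = 10),
                       format((f - 1) * traj@dt, digits = 10),
                       as.integer(traj@wrapped)), con)
    writeLines(sprintf(fmt, traj@labels, traj@coords[f, , 1],
                       traj@coords[f, , 2], traj@coords[f, , 3],
                       traj@elements), con)
  }
  invisible(path)
}

#' Read a minimal single-model PDB configuration
#'
#' Parses ATOM/HETATM coordinate records; the element is taken from
#' columns 77-78 when present, otherwise from the leading letter of the
#' atom name. A cubic CRYST1 record, when present, populates the box edge.
#' Elements are mapped to default van der Waals radii; unknown elements
#' raise a labeled error.
#'
#' @param path file path.
#' @return A [Configuration-class].
#' @export
readPDB <- function(path) {
  lines <- readLines(path)
  box <- NA_real_
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    a <- as.numeric(substr(cry[1], 7, 15))
    box <- a
  }
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (!length(at)) .stop_labeled("parse_error", "no ATOM/HETATM records")
  x <- as.numeric(substr(at, 31, 38))
  y <- as.numeric(substr(at, 39, 46))
  z <- as.numeric(substr(at, 47, 54))
  if (anyNA(x) || anyNA(y) || anyNA(z))
    .stop_labeled("parse_error", "malformed coordinate fields")
  name <- trimws(substr(at, 13, 16))
  ele <- trimws(substr(at, 77, 78))
  fallback <- toupper(substr(gsub("[^A-Za-z].*", "", name), 1, 1))
  ele <- ifelse(nzchar(ele), ele, fallback)
  if (any(!nzchar(ele)))
    .stop_labeled("missing_element", "atom without element assignment")
  bad <- setdiff(unique(ele), names(.VDW_RADII))
  if (length(bad))
    .stop_labeled("unknown_element", "unknown element symbol(s): %s",
                  paste(bad, collapse = ", "))
  configuration(cbind(x, y, z), boxEdge = box, labels = name, elements = ele)
}
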