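#' Binary multichannel event raster
#'
#' An `event_raster` stores suprathreshold events on a grid of channels
#' (rows) by 4-ms time bins (columns). Because rasters from long runs are
#' sparse, events are kept as a 0-based (bin, channel) list rather than a
#' dense matrix; [raster_matrix()] densifies when needed.
#'
#' @param bin,channel integer vectors of equal length, 0-based event
#'   coordinates. Duplicate (bin, channel) pairs are collapsed: the raster is
#'   binary.
#' @param n_channels,n_bins raster dimensions; must cover all events.
#' @param bin_ms nominal bin width in milliseconds (metadata only).
#' @return An object of class `event_raster` with fields `bin`, `channel`,
#'   `n_channels`, `n_bins`, `bin_ms`.
#' @examples
#' r <- event_raster(bin = c(0, 1, 1), channel = c(2, 0, 5),
#'                   n_channels = 60, n_bins = 10)
#' raster_matrix(r)[1:6, 1:3]
#' @export
event_raster <- function(bin, channel, n_channels, n_bins, bin_ms = 4) {
  bin <- as.integer(bin)
  channel <- as.integer(channel)
  if (length(bin) != length(channel))
    stop("`bin` and `channel` must have equal length", call. = FALSE)
  n_channels <- as.integer(n_channels)
  n_bins <- as.integer(n_bins)
  if (n_channels < 1L || n_bins < 1L)
    stop("raster dimensions must be at least 1 x 1", call. = FALSE)
  if (length(bin)) {
    if (anyNA(bin) || anyNA(channel))
      stop("event coordinates must not contain NA", call. = FALSE)
    if (min(bin) < 0L || max(bin) >= n_bins)
      stop("event bin index out of range [0, n_bins)", call. = FALSE)
    if (min(channel) < 0L || max(channel) >= n_channels)
      stop("event channel index out of range [0, n_channels)", call. = FALSE)
    o <- order(bin, channel)
    bin <- bin[o]; channel <- channel[o]
    dup <- duplicated(bin * as.double(n_channels) + channel)
    bin <- bin[!dup]; channel <- channel[!dup]
  }
  structure(list(bin = bin, channel = channel,
                 n_channels = n_channels, n_bins = n_bins,
                 bin_ms = bin_ms),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("event_raster: %d channels x %d bins (%g ms), %d events\n",
              x$n_channels, x$n_bins, x$bin_ms, length(x$bin)))
  invisible(x)
}

#' Densify an event raster
#'
#' @param raster an [event_raster()].
#' @return A 0/1 integer matrix, channels x bins.
#' @export
raster_matrix <- function(raster) {
  stopifnot(inherits(raster, "event_raster"))
  m <- matrix(0L, raster$n_channels, raster$n_bins)
  if (length(raster$bin))
    m[cbind(raster$channel + 1L, raster$bin + 1L)] <- 1L
  m
}

#' Build an event raster from a dense 0/1 matrix
#'
#' @param m a channels x bins matrix with entries in {0, 1}.
#' @param bin_ms bin width in milliseconds.
#' @return An [event_raster()].
#' @export
raster_from_matrix <- function(m, bin_ms = 4) {
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1)))
    stop("dense raster entries must be 0 or 1", call. = FALSE)
  idx <- which(m == 1, arr.ind = TRUE)
  event_raster(bin = idx[, 2] - 1L, channel = idx[, 1] - 1L,
               n_channels = nrow(m), n_bins = ncol(m), bin_ms = bin_ms)
}

#' Write an event raster to delimited text
#'
#' Two dialects share a self-describing header line
#' `# raster format=<events|dense> channels=<n> bins=<n> bin_ms=<w>`.
#' The `events` dialect then holds a `bin,channel` header and one 0-based
#' event per row; the `dense` dialect holds one comma-separated 0/1 row per
#' channel. Both round-trip losslessly through [read_raster()].
#'
#' @param raster an [event_raster()].
#' @param path output file path.
#' @param format `"events"` (default; compact for sparse data) or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = c("events", "dense")) {
  stopifnot(inherits(raster, "event_raster"))
  format <- match.arg(format)
  hdr <- sprintf("# raster format=%s channels=%d bins=%d bin_ms=%g",
                 format, raster$n_channels, raster$n_bins, raster$bin_ms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "events") {
    writeLines("bin,channel", con)
    if (length(raster$bin))
      writeLines(paste(raster$bin, raster$channel, sep = ","), con)
  } else {
    m <- raster_matrix(raster)
    writeLines(apply(m, 1L, paste, collapse = ","), con)
  }
  invisible(path)
}

parse_raster_header <- function(line) {
  if (!grepl("^# raster ", line))
    stop("line 1: expected raster header '# raster format=... channels=... bins=...'",
         call. = FALSE)
  kv <- regmatches(line, gregexpr("[a-z_]+=[^ ]+", line))[[1]]
  keys <- sub("=.*", "", kv)
  vals <- sub("^[a-z_]+=", "", kv)
  out <- as.list(vals)
  names(out) <- keys
  for (need in c("format", "channels", "bins"))
    if (is.null(out[[need]]))
      stop(sprintf("line 1: raster header missing '%s'", need), call. = FALSE)
  out
}

#' Read an event raster written by [write_raster()]
#'
#' The dialect (`events` or `dense`) is auto-detected from the header line.
#' Malformed input fails with a message naming the offending line.
#'
#' @param path file path.
#' @return An [event_raster()].
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("line 1: empty raster file", call. = FALSE)
  hdr <- parse_raster_header(lines[[1]])
  n_channels <- as.integer(hdr$channels)
  n_bins <- as.integer(hdr$bins)
  bin_ms <- if (is.null(hdr$bin_ms)) 4 else as.numeric(hdr$bin_ms)
  if (hdr$format == "events") {
    if (length(lines) < 2L || lines[[2]] != "bin,channel")
      stop("line 2: expected 'bin,channel' column header", call. = FALSE)
    body <- lines[-(1:2)]
    body <- body[nzchar(body)]
    if (!length(body))
      return(event_raster(integer(), integer(), n_channels, n_bins, bin_ms))
    parts <- strsplit(body, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop(sprintf("line %d: expected two comma-separated fields", bad[1] + 2L),
           call. = FALSE)
    bin <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    ch <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(bin) | is.na(ch) | bin < 0L | ch < 0L |
                   bin >= n_bins | ch >= n_channels)
    if (length(bad))
      stop(sprintf("line %d: event out of range or not an integer", bad[1] + 2L),
           call. = FALSE)
    key <- bin * as.double(n_channels) + ch
    if (anyDuplicated(key))
      stop(sprintf("line %d: duplicate event", which(duplicated(key))[1] + 2L),
           call. = FALSE)
    event_raster(bin, ch, n_channels, n_bins, bin_ms)
  } else if (hdr$format == "dense") {
    body <- lines[-1]
    if (length(body) != n_channels)
      stop(sprintf("line %d: expected %d dense rows", length(lines), n_channels),
           call. = FALSE)
    rows <- lapply(seq_along(body), function(i) {
      v <- suppressWarnings(as.integer(strsplit(body[[i]], ",", fixed = TRUE)[[1]]))
      if (length(v) != n_bins || anyNA(v) || !all(v %in% c(0L, 1L)))
        stop(sprintf("line %d: malformed dense row", i + 1L), call. = FALSE)
      v
    })
    raster_from_matrix(do.call(rbind, rows), bin_ms = bin_ms)
  } else {
    stop(sprintf("line 1: unknown raster format '%s'", hdr$format), call. = FALSE)
  }
}

#' Read a reference group-length distribution
#'
#' Reads a two-column delimited table `L,probability` with lengths in 2..9.
#' Missing lengths are filled with probability 0; if the probabilities do not
#' sum to 1 (beyond 1e-6) they are renormalized with a warning.
#'
#' @param path file path to a CSV with header `L,probability`.
#' @return A named numeric vector of probabilities over lengths 2..9
#'   (class `group_length_distribution`).
#' @export
read_reference <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L)
    stop("reference table needs two columns (L, probability)", call. = FALSE)
  L <- as.integer(tab[[1]])
  p <- as.numeric(tab[[2]])
  if (anyNA(L) || anyNA(p))
    stop("reference table contains non-numeric entries", call. = FALSE)
  if (any(p < 0))
    stop("reference probabilities must be non-negative", call. = FALSE)
  if (any(L < 2L | L > 9L))
    stop("reference lengths must lie in 2..9", call. = FALSE)
  if (anyDuplicated(L))
    stop("duplicate length in reference table", call. = FALSE)
  out <- stats::setNames(numeric(8L), as.character(2:9))
  out[as.character(L)] <- p
  s <- sum(out)
  if (s <= 0) stop("reference probabilities sum to zero", call. = FALSE)
  if (abs(s - 1) > 1e-6) {
    warning(sprintf("reference probabilities sum to %.6g; renormalizing", s))
    out <- out / s
  }
  group_length_distribution(out)
}

#' Construct a group-length distribution over L = 2..9
#'
#' @param p numeric vector of 8 non-negative values for lengths 2..9; an
#'   all-zero vector is allowed and flagged empty.
#' @return Named numeric vector of class `group_length_distribution`, summing
#'   to 1 unless empty (attribute `empty`).
#' @export
group_length_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 8L)
    stop("a group-length distribution has 8 entries (L = 2..9)", call. = FALSE)
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  empty <- sum(p) == 0
  if (!empty) p <- p / sum(p)
  structure(stats::setNames(p, as.character(2:9)),
            empty = empty, class = "group_length_distribution")
}
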