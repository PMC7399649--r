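#' Construct a tractogram
#'
#' A tractogram is an ordered collection of streamlines, each an ordered
#' polyline of 3D world-mm points, with optional per-streamline metadata
#' (e.g. the generating bundle when known).
#'
#' @param streamlines list of numeric matrices (n_i x 3), each with >= 2
#'   finite points.
#' @param labels optional data.frame of per-streamline metadata with one row
#'   per streamline.
#' @return An object of class \code{tractogram}.
#' @export
tractogram <- function(streamlines, labels = NULL) {
  if (!is.list(streamlines)) stop("'streamlines' must be a list of matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- to_point_matrix(s)
    storage.mode(s) <- "double"
    if (nrow(s) < 2L) stop("each streamline needs at least 2 points")
    if (any(!is.finite(s))) stop("streamline coordinates must be finite")
    dimnames(s) <- NULL
    s
  })
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    if (nrow(labels) != length(streamlines))
      stop("'labels' must have one row per streamline")
  }
  structure(list(streamlines = streamlines, labels = labels),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("<tractogram> %d streamlines, %d points total\n",
              length(x$streamlines), sum(np)))
  invisible(x)
}

#' Arc length of a polyline in mm
#' @param points numeric matrix (n x 3).
#' @return total length of the polyline.
#' @export
polyline_length <- function(points) {
  points <- to_point_matrix(points)
  if (nrow(points) < 2L) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Read an MRtrix TCK streamline file
#'
#' Parses the MRtrix tracks dialect: a text header terminated by
#' \code{END}, followed by little-endian float32 coordinate triplets where a
#' NaN triplet separates streamlines and an Inf triplet ends the file.
#' Coordinates are world mm (TCK stores scanner/world space directly).
#'
#' @param path file path.
#' @return A \code{tractogram}.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (missing 'mrtrix tracks' magic): ", path)
  offset <- NA_integer_
  dtype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated TCK header in ", path)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "file") offset <- as.integer(sub("^\\.\\s+", "", val))
      if (key == "datatype") dtype <- val
    }
  }
  if (!identical(dtype, "Float32LE"))
    stop("unsupported TCK datatype: ", dtype)
  if (is.na(offset)) stop("TCK header lacks a 'file' offset")
  seek(con, where = offset, origin = "start")
  raw_vals <- readBin(con, what = "numeric", size = 4L,
                      n = file.size(path) %/% 4L, endian = "little")
  m <- matrix(raw_vals, ncol = 3L, byrow = TRUE)
  is_sep <- is.nan(m[, 1L])
  is_eof <- is.infinite(m[, 1L])
  stop_at <- which(is_eof)
  if (length(stop_at)) m <- m[seq_len(stop_at[1L] - 1L), , drop = FALSE]
  is_sep <- is.nan(m[, 1L])
  grp <- cumsum(c(TRUE, head(is_sep, -1L)))
  keep <- !is_sep
  pieces <- split.data.frame(m[keep, , drop = FALSE], grp[keep])
  streamlines <- lapply(unname(pieces), function(p) {
    p <- as.matrix(p); dimnames(p) <- NULL; p
  })
  tractogram(streamlines)
}

#' Write a tractogram as an MRtrix TCK file
#'
#' @param tract a \code{tractogram}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tck <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  header_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: Float32LE\n",
           sprintf("count: %d\n", length(tract$streamlines)),
           sprintf("file: . %d\n", offset),
           "END\n")
  }
  # header length depends on the printed offset; iterate to a fixed point
  offset <- nchar(header_for(0L), type = "bytes")
  offset <- nchar(header_for(offset), type = "bytes")
  hdr <- header_for(offset)
  stopifnot(nchar(hdr, type = "bytes") == offset)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}
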