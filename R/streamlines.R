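#' Streamline sets
#'
#' A streamline is an ordered polyline of at least two distinct 3D points in
#' subject RAS-mm space; a `streamline_set` is a list of such polylines plus
#' a space tag. Whole-brain tractograms are `streamline_set`s; segmented
#' bundles index into them.
#'
#' @param streamlines List of n x 3 numeric matrices.
#' @param space Space tag; only `"subject-RAS"` is used internally.
#' @return A `streamline_set`.
#' @export
streamline_set <- function(streamlines, space = "subject-RAS") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3) stop("streamline points must be n x 3")
    if (nrow(s) < 2) stop("a streamline needs at least 2 points")
    steps <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
    if (any(steps == 0)) stop("consecutive streamline points must be distinct")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  structure(list(streamlines = streamlines, space = space),
            class = "streamline_set")
}

#' @rdname streamline_set
#' @param x Object to test.
#' @export
is_streamline_set <- function(x) inherits(x, "streamline_set")

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %d streamlines (%s)\n",
              length(x$streamlines), x$space))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Arc length of a polyline
#' @param s n x 3 matrix of points.
#' @return Total length in mm.
#' @export
arc_length <- function(s) {
  s <- as.matrix(s)
  sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
}

#' Densify a polyline to a maximum step size
#'
#' Inserts points along each segment so that no consecutive pair is farther
#' apart than `max_step` (used for voxel-membership tests, where the step is
#' half the voxel size).
#'
#' @param s n x 3 matrix.
#' @param max_step Maximum allowed spacing in mm.
#' @return m x 3 matrix (m >= n) including all original vertices.
#' @export
densify_polyline <- function(s, max_step) {
  s <- as.matrix(s)
  n <- nrow(s)
  seg <- s[-1, , drop = FALSE] - s[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  nsub <- pmax(1L, ceiling(len / max_step))
  pieces <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    t <- seq(0, 1, length.out = nsub[i] + 1L)[-(nsub[i] + 1L)]
    pieces[[i]] <- cbind(s[i, 1] + t * seg[i, 1],
                         s[i, 2] + t * seg[i, 2],
                         s[i, 3] + t * seg[i, 3])
  }
  rbind(do.call(rbind, pieces), s[n, , drop = FALSE])
}

tck_magic <- "mrtrix tracks"

read_tck <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == as.raw(10L))
  if (length(nl) == 0L) stop("not a TCK file: ", path)
  first <- rawToChar(raw[seq_len(nl[1] - 1L)])
  if (!identical(first, tck_magic)) stop("not a TCK file: ", path)
  dtype <- "Float32LE"; offset <- NA_real_
  prev <- nl[1]
  for (pos in nl[-1]) {
    line <- if (pos - prev > 1L) rawToChar(raw[(prev + 1L):(pos - 1L)]) else ""
    prev <- pos
    if (grepl("^END", line)) break
    ci <- regexpr(":", line, fixed = TRUE)
    if (ci > 0L) {
      key <- trimws(substr(line, 1L, ci - 1L))
      val <- trimws(substr(line, ci + 1L, nchar(line)))
      if (key == "datatype") dtype <- val
      if (key == "file") offset <- as.numeric(sub("^\\.\\s*", "", val))
    }
  }
  if (is.na(offset)) stop("TCK header missing 'file' offset: ", path)
  endian <- if (grepl("BE$", dtype)) "big" else "little"
  size <- if (grepl("64", dtype)) 8L else 4L
  if (!grepl("^Float", dtype)) stop("unsupported TCK datatype: ", dtype)
  if (offset >= length(raw)) stop("no streamlines in file: ", path)
  body <- raw[(offset + 1L):length(raw)]
  vals <- readBin(body, "double", n = length(body) %/% size, size = size,
                  endian = endian)
  vals <- vals[seq_len((length(vals) %/% 3) * 3)]
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  fin <- is.finite(pts[, 1]) & is.finite(pts[, 2]) & is.finite(pts[, 3])
  streams <- list()
  cur_start <- 1L
  for (i in seq_len(nrow(pts))) {
    if (!fin[i]) {
      if (i > cur_start) streams[[length(streams) + 1L]] <-
          pts[cur_start:(i - 1L), , drop = FALSE]
      if (any(is.infinite(pts[i, ]))) break
      cur_start <- i + 1L
    }
  }
  if (length(streams) == 0L) stop("no streamlines in file: ", path)
  streamline_set(streams)
}

write_tck <- function(set, path) {
  header <- c(tck_magic,
              "datatype: Float32LE",
              sprintf("count: %d", length(set$streamlines)))
  # the 'file: . <offset>' line length feeds back into the offset; iterate
  # until the offset is consistent with the header it terminates
  base_len <- sum(nchar(header)) + length(header) + nchar("END") + 1L
  off <- base_len
  repeat {
    total <- base_len + nchar(sprintf("file: . %d", off)) + 1L
    if (total == off) break
    off <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_txt <- paste0(paste(c(header, sprintf("file: . %d", off), "END"),
                          collapse = "\n"), "\n")
  writeBin(charToRaw(hdr_txt), con)
  for (s in set$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1000L)
  if (length(hdr) < 1000L) stop("truncated TRK header: ", path)
  id <- rawToChar(hdr[1:5])
  if (!identical(id, "TRACK")) stop("not a TRK file: ", path)
  rd <- function(what, off, n, size) {
    readBin(hdr[(off + 1L):1000L], what, n = n, size = size, endian = "little")
  }
  voxel_size <- rd("double", 12L, 3L, 4L)
  n_scalars <- rd("integer", 36L, 1L, 2L)
  n_properties <- rd("integer", 238L, 1L, 2L)
  vox2ras <- matrix(rd("double", 440L, 16L, 4L), 4, 4, byrow = TRUE)
  version <- rd("integer", 992L, 1L, 4L)
  hdr_size <- rd("integer", 996L, 1L, 4L)
  if (hdr_size != 1000L) stop("unexpected TRK header size: ", hdr_size)
  if (version < 2L || vox2ras[4, 4] == 0 || all(vox2ras == 0))
    stop("TRK vox_to_ras affine missing or degenerate")
  if (any(voxel_size <= 0)) stop("TRK header has non-positive voxel size")
  aff <- affine4x4(vox2ras)
  streams <- list()
  repeat {
    npts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "double", n = npts * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_properties > 0L)
      readBin(con, "double", n = n_properties, size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    # TRK stores voxel-mm coordinates with the *corner* of voxel (0,0,0) at
    # the origin: voxel index = p / voxel_size - 0.5, then vox_to_ras applies
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    streams[[length(streams) + 1L]] <- apply_affine(aff, vox)
  }
  if (length(streams) == 0L) stop("no streamlines in file: ", path)
  streamline_set(streams)
}

#' Read streamlines from TCK or TRK
#'
#' TCK coordinates are already world (RAS mm). TRK voxel-mm coordinates are
#' resolved to RAS mm through the header's voxel size and vox_to_ras affine,
#' so all streamlines come out in a single internal space.
#'
#' @param path Path to a `.tck` or `.trk` file (detected by magic bytes).
#' @return A [streamline_set] in subject RAS mm.
#' @export
read_streamlines <- function(path) {
  magic <- readBin(path, "raw", n = 13L)
  txt <- rawToChar(magic[magic != as.raw(0)])
  if (startsWith(txt, tck_magic)) return(read_tck(path))
  if (startsWith(txt, "TRACK")) return(read_trk(path))
  stop("unknown streamline format (expected TCK or TRK): ", path)
}

#' Write streamlines to TCK
#'
#' TCK is the single output dialect: coordinates are written as-is
#' (subject RAS mm), Float32 little-endian.
#'
#' @param set A [streamline_set].
#' @param path Output `.tck` path.
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(set, path) {
  stopifnot(is_streamline_set(set))
  write_tck(set, path)
}
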