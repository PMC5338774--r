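#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected), welds the per-facet corner
#' soup into an indexed mesh and discards the stored facet normals —
#' many exporters write garbage normals, so orientation is always taken
#' from the vertex winding. Coordinates are interpreted as millimetres
#' (STL itself is unitless; all CT-derived surfaces handled here are mm).
#'
#' @param path path to an `.stl` file.
#' @param weld_tol weld tolerance in mm passed to [weld_vertices()].
#' @return a [triangle_mesh()].
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.size(path)
  if (sz == 0) stop("STL format error: empty file")
  # binary STL cannot be shorter than header + count
  head_raw <- readBin(path, "raw", n = min(sz, 512))
  # keep printable ASCII only before text sniffing: binary STL headers
  # routinely contain bytes that are not valid in any text encoding
  printable <- head_raw[(head_raw >= as.raw(0x20) & head_raw <= as.raw(0x7e)) |
                          head_raw == as.raw(0x0a) | head_raw == as.raw(0x0d) |
                          head_raw == as.raw(0x09)]
  txt <- rawToChar(printable)
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt, fixed = TRUE)
  corners <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  nfac <- nrow(corners) / 3L
  soup <- triangle_mesh(corners,
                        matrix(seq_len(3L * nfac), ncol = 3L, byrow = TRUE))
  weld_vertices(soup, weld_tol)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84) stop("STL format error: binary file shorter than header")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nfac <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nfac < 0) stop("STL format error: bad facet count")
  if (sz != 84 + 50 * nfac)
    stop(sprintf(
      "STL format error: facet count %d implies %d bytes but file has %d",
      nfac, 84 + 50 * nfac, sz))
  raw <- readBin(con, "raw", n = 50 * nfac)
  if (length(raw) != 50 * nfac)
    stop("STL format error: truncated facet record")
  # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
  idx <- rep(seq(0L, length.out = nfac) * 50L, each = 48L) +
    rep(seq_len(48L), times = nfac)
  floats <- readBin(raw[idx], "double", n = 12L * nfac, size = 4,
                    endian = "little")
  fm <- matrix(floats, ncol = 12L, byrow = TRUE)  # n1..3, v1, v2, v3
  corners <- matrix(0, nrow = 3L * nfac, ncol = 3L)
  corners[seq(1, by = 3, length.out = nfac), ] <- fm[, 4:6, drop = FALSE]
  corners[seq(2, by = 3, length.out = nfac), ] <- fm[, 7:9, drop = FALSE]
  corners[seq(3, by = 3, length.out = nfac), ] <- fm[, 10:12, drop = FALSE]
  if (any(!is.finite(corners)))
    stop("STL format error: non-finite vertex coordinates")
  corners
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3L != 0L)
    stop("STL format error: ASCII vertex count not a multiple of 3")
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(p) {
    if (length(p) != 4L) stop("STL format error: malformed vertex line")
    as.numeric(p[2:4])
  })
  corners <- do.call(rbind, nums)
  if (any(!is.finite(corners)))
    stop("STL format error: non-numeric vertex coordinate")
  corners
}

#' Write an STL surface mesh
#'
#' Writes a mesh as binary (default) or ASCII STL. Facet normals are
#' recomputed from winding; the binary attribute byte count is zero.
#' Output is deterministic: identical meshes give byte-identical files.
#'
#' @param m a non-empty [triangle_mesh()].
#' @param path output path.
#' @param dialect `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(m, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_mesh(m)
  if (nrow(m$faces) == 0) stop("refusing to write an empty mesh")
  n <- face_normals(m)
  fc <- face_corners(m)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(m$faces)), con, size = 4, endian = "little")
    rec <- cbind(n, fc$a, fc$b, fc$c)      # 12 floats per facet
    for (i in seq_len(nrow(rec))) {
      writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    fmt_v <- function(p) sprintf("vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
    body <- paste0("  facet normal ",
                   sprintf("%.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]),
                   "\n    outer loop\n      ", fmt_v(fc$a),
                   "\n      ", fmt_v(fc$b),
                   "\n      ", fmt_v(fc$c),
                   "\n    endloop\n  endfacet")
    writeLines(c("solid cranioplan", body, "endsolid cranioplan"), path)
  }
  invisible(path)
}
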