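## PLY reading/writing. Only the vertex element is interpreted; the
## parser accepts ASCII and binary_little_endian dialects, red/green/blue
## or r/g/b color property names, and rescales 0-1 float colors to the
## canonical 0-255 scale.

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!length(magic) || trimws(magic) != "ply")
    stop("not a PLY file (missing 'ply' magic line)")
  format <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header")
    line <- trimws(line)
    if (line == "" ) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[1] == "end_header") break
    if (tok[1] == "format") {
      format <- tok[2]
    } else if (tok[1] %in% c("comment", "obj_info")) {
      next
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  props = character(), types = character(),
                  has_list = FALSE)
    } else if (tok[1] == "property") {
      if (is.null(cur)) stop("PLY property declared outside an element")
      if (tok[2] == "list") {
        cur$has_list <- TRUE
      } else {
        cur$types <- c(cur$types, tok[2])
        cur$props <- c(cur$props, tok[3])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(format) ||
      !format %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ",
         if (is.null(format)) "<missing>" else format)
  list(format = format, elements = elements)
}

.ply_read_binary_vertex <- function(con, el) {
  sizes <- .ply_type_size[el$types]
  if (anyNA(sizes)) stop("unknown PLY property type in vertex element")
  stride <- sum(sizes)
  raw <- readBin(con, what = "raw", n = stride * el$count)
  if (length(raw) < stride * el$count)
    stop("truncated PLY vertex data")
  bytes <- matrix(raw, nrow = stride)
  offset <- c(0L, cumsum(sizes))
  out <- vector("list", length(el$props))
  names(out) <- el$props
  for (k in seq_along(el$props)) {
    chunk <- as.vector(bytes[(offset[k] + 1L):offset[k + 1L], , drop = FALSE])
    ty <- el$types[k]
    out[[k]] <- switch(ty,
      float = , float32 = readBin(chunk, "double", n = el$count, size = 4L,
                                  endian = "little"),
      double = , float64 = readBin(chunk, "double", n = el$count, size = 8L,
                                   endian = "little"),
      uchar = , uint8 = as.numeric(readBin(chunk, "integer", n = el$count,
                                           size = 1L, signed = FALSE,
                                           endian = "little")),
      char = , int8 = as.numeric(readBin(chunk, "integer", n = el$count,
                                         size = 1L, signed = TRUE,
                                         endian = "little")),
      ushort = , uint16 = as.numeric(readBin(chunk, "integer", n = el$count,
                                             size = 2L, signed = FALSE,
                                             endian = "little")),
      short = , int16 = as.numeric(readBin(chunk, "integer", n = el$count,
                                           size = 2L, signed = TRUE,
                                           endian = "little")),
      int = , int32 = , uint = ,
      uint32 = as.numeric(readBin(chunk, "integer", n = el$count, size = 4L,
                                  endian = "little")),
      stop("unknown PLY property type: ", ty))
  }
  out
}

#' Read a colored point cloud from a PLY file
#'
#' Supports ASCII and binary (little-endian) PLY with per-vertex
#' `x`, `y`, `z` coordinates and `red`, `green`, `blue` (or `r`, `g`,
#' `b`) colors. Float colors on the 0--1 scale are rescaled to 0--255.
#'
#' @param path path to a PLY file.
#' @param units_per_cm optional metric scale attached to the returned
#'   cloud (coordinate units per centimetre).
#' @return A [point_cloud()] object with one point per PLY vertex.
#' @seealso [write_ply()]
#' @export
read_ply <- function(path, units_per_cm = NULL) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .ply_read_header(con)
  el <- hdr$elements[["vertex"]]
  if (is.null(el)) stop("PLY has no 'vertex' element")
  if (el$count < 1L) stop("PLY contains zero vertices (empty input)")
  for (need in c("x", "y", "z"))
    if (!need %in% el$props)
      stop("PLY is missing coordinate property '", need, "'")
  cprop <- character(3)
  for (k in 1:3) {
    long <- c("red", "green", "blue")[k]
    short <- c("r", "g", "b")[k]
    cprop[k] <- if (long %in% el$props) long
      else if (short %in% el$props) short
      else stop("PLY is missing color property '", long, "'")
  }
  if (hdr$format == "ascii") {
    if (names(hdr$elements)[1] != "vertex")
      stop("unsupported PLY layout: vertex is not the first element")
    lines <- readLines(con, n = el$count)
    if (length(lines) < el$count) stop("truncated PLY vertex data")
    vals <- scan(text = lines, what = numeric(), quiet = TRUE)
    if (length(vals) != el$count * length(el$props))
      stop("malformed ASCII PLY vertex rows")
    m <- matrix(vals, ncol = length(el$props), byrow = TRUE)
    colnames(m) <- el$props
    cols <- lapply(seq_along(el$props), function(k) {
      v <- m[, k]
      if (el$types[k] %in% c("float", "float32")) {
        # an ASCII 'float' property is semantically float32: quantize
        # so both dialects reload identically
        v <- readBin(writeBin(v, raw(), size = 4L, endian = "little"),
                     "double", n = length(v), size = 4L,
                     endian = "little")
      }
      v
    })
    names(cols) <- el$props
  } else {
    if (names(hdr$elements)[1] != "vertex")
      stop("unsupported PLY layout: vertex is not the first element")
    cols <- .ply_read_binary_vertex(con, el)
  }
  coords <- cbind(cols[["x"]], cols[["y"]], cols[["z"]])
  colors <- cbind(cols[[cprop[1]]], cols[[cprop[2]]], cols[[cprop[3]]])
  ctypes <- el$types[match(cprop, el$props)]
  float_cols <- ctypes %in% c("float", "float32", "double", "float64")
  if (all(float_cols) && max(colors) <= 1 && min(colors) >= 0)
    colors <- colors * 255
  colors[colors < 0] <- 0
  colors[colors > 255] <- 255
  point_cloud(coords, colors, units_per_cm = units_per_cm)
}

#' Write a colored point cloud to a PLY file
#'
#' Coordinates are stored as 32-bit floats and colors as 8-bit unsigned
#' integers (rounded), the canonical PLY vertex layout. A cloud written
#' and re-read round-trips exactly on colors and within float32
#' precision on coordinates.
#'
#' @param cloud a [point_cloud()] object.
#' @param path output path.
#' @param ascii logical: write the ASCII dialect instead of
#'   binary_little_endian (default `FALSE`).
#' @return `path`, invisibly.
#' @seealso [read_ply()]
#' @export
write_ply <- function(cloud, path, ascii = FALSE) {
  stopifnot(inherits(cloud, "pointcloud"))
  n <- nrow(cloud$coords)
  if (n < 1L) stop("refusing to write an empty point cloud")
  col8 <- round(cloud$colors)
  col8[col8 < 0] <- 0
  col8[col8 > 255] <- 255
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (ascii) "ascii" else "binary_little_endian"),
    "comment written by panicle3d",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "end_header")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste0(header, collapse = "\n"), "\n")), con)
  if (ascii) {
    # quantize through float32 so ASCII and binary dialects reload
    # identically (%.9g round-trips a float32 exactly)
    q32 <- function(v) readBin(writeBin(as.numeric(v), raw(), size = 4L,
                                        endian = "little"),
                               "double", n = length(v), size = 4L,
                               endian = "little")
    rows <- sprintf("%.9g %.9g %.9g %d %d %d",
                    q32(cloud$coords[, 1]), q32(cloud$coords[, 2]),
                    q32(cloud$coords[, 3]),
                    as.integer(col8[, 1]), as.integer(col8[, 2]),
                    as.integer(col8[, 3]))
    writeBin(charToRaw(paste0(paste0(rows, collapse = "\n"), "\n")), con)
  } else {
    stride <- 15L  # 3 * float32 + 3 * uchar
    raw <- raw(stride * n)
    bytes <- matrix(raw, nrow = stride)
    for (k in 1:3) {
      b <- writeBin(as.numeric(cloud$coords[, k]), raw(), size = 4L,
                    endian = "little")
      bytes[(4L * (k - 1L) + 1L):(4L * k), ] <- matrix(b, nrow = 4L)
    }
    cb <- writeBin(as.integer(t(col8)), raw(), size = 1L)
    bytes[13:15, ] <- matrix(cb, nrow = 3L)
    writeBin(as.vector(bytes), con)
  }
  invisible(path)
}
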