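#' Read and write LAS point clouds
#'
#' Minimal LAS 1.2 reader/writer (point data record format 0, the format
#' used for discrete-return topographic clouds). Coordinates are stored on
#' disk as scaled 32-bit integers, so a write/read round trip preserves them
#' to the declared scale (default 0.01 m). Classification codes follow the
#' LAS standard: 2 = ground, 7 (or the LAS 1.4 code 18) = outlier, anything
#' else reads back as unclassified. LAZ compression is not supported;
#' decompress externally first.
#'
#' @param cloud a [point_cloud()].
#' @param path file path (`.las`).
#' @param scale coordinate quantization step in metres.
#' @return `write_point_cloud` returns `path` invisibly; `read_point_cloud`
#'   returns a [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path, scale = 0.01) {
  n <- nrow(cloud)
  offset <- if (n) c(floor(min(cloud$x)), floor(min(cloud$y)),
                     floor(min(cloud$z))) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))

  pad_char <- function(s, width) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), width))], rep(as.raw(0), max(0, width - length(r))))
  }
  writeBin(charToRaw("LASF"), con)
  writeBin(integer(2), con, size = 2, endian = "little")   # source id, encoding
  writeBin(raw(16), con)                                   # GUID
  writeBin(as.raw(c(1L, 2L)), con)                         # version 1.2
  writeBin(pad_char("amazonagb", 32), con)
  writeBin(pad_char("amazonagb R package", 32), con)
  writeBin(c(1L, 2026L), con, size = 2, endian = "little") # day, year
  writeBin(227L, con, size = 2, endian = "little")         # header size
  writeBin(227L, con, size = 4, endian = "little")         # offset to points
  writeBin(0L, con, size = 4, endian = "little")           # VLR count
  writeBin(as.raw(0L), con)                                # point format 0
  writeBin(20L, con, size = 2, endian = "little")          # record length
  writeBin(n, con, size = 4, endian = "little")
  by_ret <- vapply(1:5, function(k) sum(cloud$return_number == k), 0L)
  writeBin(as.integer(by_ret), con, size = 4, endian = "little")
  writeBin(as.double(c(scale, scale, scale, offset)), con, endian = "little")
  rng <- function(v) if (n) c(max(v), min(v)) else c(0, 0)
  writeBin(as.double(c(rng(cloud$x), rng(cloud$y), rng(cloud$z))), con,
           endian = "little")

  if (n) {
    to_raw <- function(v, size) {
      rc <- rawConnection(raw(0), "wb")
      on.exit(close(rc), add = TRUE)
      writeBin(v, rc, size = size, endian = "little")
      matrix(rawConnectionValue(rc), nrow = size)
    }
    quant <- function(v, off) {
      q <- round((v - off) / scale)
      if (any(abs(q) > 2^31 - 1)) stop_amz("coordinates overflow LAS int32 at scale %g", scale)
      as.integer(q)
    }
    rec <- matrix(as.raw(0), nrow = 20, ncol = n)
    rec[1:4, ] <- to_raw(quant(cloud$x, offset[1]), 4L)
    rec[5:8, ] <- to_raw(quant(cloud$y, offset[2]), 4L)
    rec[9:12, ] <- to_raw(quant(cloud$z, offset[3]), 4L)
    rn <- pmin(pmax(cloud$return_number, 1L), 7L)
    rec[15, ] <- as.raw(bitwOr(rn, bitwShiftL(rn, 3)))    # return k of k
    cls_code <- c(unclassified = 1L, ground = 2L, outlier = 7L)
    rec[16, ] <- as.raw(cls_code[cloud$classification])
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (grepl("\\.laz$", path, ignore.case = TRUE)) {
    stop_amz("LAZ compression is not supported; decompress to LAS first")
  }
  if (!file.exists(path)) stop_amz("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 4)
  if (!identical(rawToChar(sig), "LASF")) {
    stop_amz("malformed LAS header at byte offset 0: signature %s != LASF",
             paste(sig, collapse = " "))
  }
  seek(con, 24)                                   # skip ids, GUID
  ver <- as.integer(readBin(con, "raw", 2))
  seek(con, 94)
  header_size <- readBin(con, "integer", 1, size = 2, endian = "little")
  offset_to_points <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 4, endian = "little")  # VLR count
  fmt <- as.integer(readBin(con, "raw", 1))
  if (bitwAnd(fmt, 128L) != 0L) {
    stop_amz("point format %d is LAZ-compressed; not supported", fmt)
  }
  rec_len <- readBin(con, "integer", 1, size = 2, endian = "little")
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 5, size = 4, endian = "little")  # by-return counts
  sc <- readBin(con, "double", 6, endian = "little")       # scales, offsets
  if (header_size < 227 || rec_len < 20 || n < 0) {
    stop_amz("malformed LAS header at byte offset 94: implausible sizes")
  }
  if (n == 0) return(point_cloud())
  seek(con, offset_to_points)
  body <- readBin(con, "raw", n * rec_len)
  if (length(body) < n * rec_len) {
    stop_amz("truncated LAS point block: expected %d bytes, got %d",
             n * rec_len, length(body))
  }
  base <- rep((0:(n - 1)) * rec_len, each = 4)
  field_int32 <- function(start) {
    readBin(body[base + rep(start:(start + 3), times = n)], "integer",
            n = n, size = 4, endian = "little")
  }
  xi <- field_int32(1)
  yi <- field_int32(5)
  zi <- field_int32(9)
  flags <- as.integer(body[(0:(n - 1)) * rec_len + 15])
  cls <- as.integer(body[(0:(n - 1)) * rec_len + 16])
  cls_lab <- rep("unclassified", n)
  cls_lab[cls == 2L] <- "ground"
  cls_lab[cls %in% c(7L, 18L)] <- "outlier"
  point_cloud(
    x = xi * sc[1] + sc[4],
    y = yi * sc[2] + sc[5],
    z = zi * sc[3] + sc[6],
    return_number = bitwAnd(flags, 7L),
    classification = cls_lab
  )
}
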