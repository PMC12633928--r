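# Minimal NRRD I/O for integer annotation volumes.
#
# Supports the subset of NRRD used for atlas annotation images: 3-D,
# integer types, attached data, encodings "raw" (little-endian unless the
# header says otherwise) and "text"/"ascii". Voxel size is taken from the
# "spacings" field or from diagonal "space directions".

.nrrdTypes <- list(
  "uchar"  = list(size = 1L, signed = FALSE), "uint8"  = list(size = 1L, signed = FALSE),
  "uint8_t" = list(size = 1L, signed = FALSE),
  "short"  = list(size = 2L, signed = TRUE),  "int16"  = list(size = 2L, signed = TRUE),
  "ushort" = list(size = 2L, signed = FALSE), "uint16" = list(size = 2L, signed = FALSE),
  "int"    = list(size = 4L, signed = TRUE),  "int32"  = list(size = 4L, signed = TRUE),
  "uint"   = list(size = 4L, signed = FALSE), "uint32" = list(size = 4L, signed = FALSE))

#' Read an NRRD annotation volume
#'
#' Reads a 3D integer NRRD file (attached data; raw or text encoding) into
#' an [AnnotationVolume-class]. NRRD stores data with the first axis
#' fastest, which matches R's column-major array layout, so
#' \code{values[i, j, k]} is the voxel at index (i, j, k) of the file.
#'
#' @param path path to the .nrrd file.
#' @param voxelSize optional numeric(3) voxel size in um, overriding (or
#'   supplying, when the header has none) the header's spacings.
#' @return an [AnnotationVolume-class].
#' @export
readNrrd <- function(path, voxelSize = NULL) {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  nl <- which(bytes == as.raw(10L))
  # header ends at the first blank line (two consecutive newlines)
  blank <- nl[which(diff(nl) == 1L)[1]]
  if (is.na(blank)) stop("NRRD header ended before blank line")
  header <- strsplit(rawToChar(bytes[seq_len(blank)]), "\n")[[1]]
  data_raw <- bytes[(blank + 2L):length(bytes)]
  if (!grepl("^NRRD000", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    line <- sub("\r$", "", line)
    if (line == "" || startsWith(line, "#")) next
    kv <- regmatches(line, regexpr("^[^:]+:=?", line))
    key <- tolower(trimws(sub(":=?$", "", kv)))
    val <- trimws(substring(line, nchar(kv) + 1L))
    fields[[key]] <- val
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L) stop("only 3-D NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  typ <- .nrrdTypes[[tolower(fields[["type"]])]]
  if (is.null(typ)) stop("unsupported NRRD type: ", fields[["type"]])
  enc <- tolower(fields[["encoding"]])
  endian <- if (!is.null(fields[["endian"]]) &&
                tolower(fields[["endian"]]) == "big") "big" else "little"
  if (enc %in% c("raw")) {
    vals <- readBin(data_raw, what = "integer", n = n, size = typ$size,
                    signed = if (typ$size >= 4L) TRUE else typ$signed,
                    endian = endian)
  } else if (enc %in% c("text", "txt", "ascii")) {
    vals <- as.integer(scan(text = rawToChar(data_raw), what = numeric(),
                            quiet = TRUE))
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("NRRD data length mismatch")
  if (is.null(voxelSize)) {
    if (!is.null(fields[["spacings"]])) {
      voxelSize <- as.numeric(strsplit(trimws(fields[["spacings"]]),
                                       "\\s+")[[1]])
    } else if (!is.null(fields[["space directions"]])) {
      vecs <- regmatches(fields[["space directions"]],
                         gregexpr("\\(([^)]*)\\)",
                                  fields[["space directions"]]))[[1]]
      voxelSize <- vapply(seq_along(vecs), function(i) {
        v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
        sqrt(sum(v^2))
      }, numeric(1))
    } else stop("NRRD header has no voxel size; supply voxelSize=")
  }
  AnnotationVolume(array(vals, dim = sizes), voxelSize)
}

#' Write an AnnotationVolume as NRRD
#'
#' @param vol an [AnnotationVolume-class].
#' @param path output path.
#' @param encoding "raw" (little-endian int32) or "text".
#' @return \code{path}, invisibly.
#' @export
writeNrrd <- function(vol, path, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  d <- dim(vol@values)
  hdr <- c("NRRD0004",
           "type: int32",
           "dimension: 3",
           paste("sizes:", paste(d, collapse = " ")),
           paste("spacings:", paste(format(vol@voxelSize, trim = TRUE),
                                    collapse = " ")),
           paste0("encoding: ", if (encoding == "raw") "raw" else "text"),
           if (encoding == "raw") "endian: little",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.integer(vol@values), con, size = 4L, endian = "little")
  } else {
    writeLines(paste(as.integer(vol@values), collapse = " "), con)
  }
  invisible(path)
}
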