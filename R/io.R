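#' Read a 3D scalar volume from MetaImage, NRRD or NIfTI-1
#'
#' Supported formats: single-file MetaImage (`.mha`, uncompressed), NRRD
#' (`.nrrd`, raw encoding) and NIfTI-1 (`.nii`, `.nii.gz`, via RNifti).
#' Grid metadata (spacing, origin, axis-aligned direction) round-trips
#' losslessly with [write_volume()]. Files without explicit spacing, and
#' non-3D images, are rejected rather than silently defaulted.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"mha"`, `"nrrd"`, `"nifti"`; `"auto"`
#'   infers from the file extension.
#' @param kind value semantics passed to [volume3d()] (`"ct"`, `"dose"`,
#'   `"mask"`, `"scalar"`).
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = c("auto", "mha", "nrrd", "nifti"),
                        kind = "scalar") {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file does not exist: ", path)
  out <- switch(format,
                mha = read_mha(path),
                nrrd = read_nrrd(path),
                nifti = read_nifti_vol(path))
  volume3d(out$values, out$grid, kind = kind)
}

#' Write a 3D scalar volume
#'
#' @param vol a [volume3d()].
#' @param path output path; extension selects the format unless `format`
#'   is given.
#' @param format one of `"auto"`, `"mha"`, `"nrrd"`, `"nifti"`.
#' @return `path`, invisibly.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path, format = c("auto", "mha", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         mha = write_mha(vol, path),
         nrrd = write_nrrd(vol, path),
         nifti = write_nifti_vol(vol, path))
  invisible(path)
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.mha$", lp)) return("mha")
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  stop("cannot infer volume format from extension of: ", path)
}

## ---- MetaImage (single-file .mha, uncompressed) -------------------------
## Minimal reader/writer for the ITK MetaImage header + raw little-endian
## payload. Only what the pipeline needs: 3D scalar, MET_SHORT/FLOAT/DOUBLE.

write_mha <- function(vol, path) {
  g <- vol$grid
  dirflat <- as.vector(g$direction)  # column-major = ITK row-major transpose
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(format(t(g$direction), digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(g$origin, digits = 17), collapse = " ")),
    sprintf("CenterOfRotation = 0 0 0"),
    sprintf("ElementSpacing = %s",
            paste(format(g$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %s", paste(g$size, collapse = " ")),
    "ElementType = MET_DOUBLE",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  marker <- grepRaw("ElementDataFile", raw, fixed = TRUE)
  if (length(marker) == 0) {
    stop("MetaImage format error: only single-file (LOCAL) ",
         ".mha volumes are supported")
  }
  nl <- grepRaw("\n", raw, offset = marker, fixed = TRUE)
  header_end <- if (length(nl)) nl[1] else length(raw)
  txt <- rawToChar(raw[seq_len(header_end)])
  if (!grepl("ElementDataFile\\s*=\\s*LOCAL", txt)) {
    stop("MetaImage format error: only single-file (LOCAL) ",
         ".mha volumes are supported")
  }
  fields <- parse_kv_header(txt, sep = "=")
  ndims <- as.integer(fields[["NDims"]])
  if (is.na(ndims) || ndims != 3L) {
    stop("MetaImage format error: expected 3D data, got NDims = ",
         fields[["NDims"]])
  }
  if (is.null(fields[["ElementSpacing"]])) {
    stop("MetaImage format error: missing ElementSpacing")
  }
  size <- as.integer(strsplit(trimws(fields[["DimSize"]]), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(fields[["ElementSpacing"]]), "\\s+")[[1]])
  origin <- if (!is.null(fields[["Offset"]])) {
    as.numeric(strsplit(trimws(fields[["Offset"]]), "\\s+")[[1]])
  } else c(0, 0, 0)
  direction <- if (!is.null(fields[["TransformMatrix"]])) {
    t(matrix(as.numeric(strsplit(trimws(fields[["TransformMatrix"]]),
                                 "\\s+")[[1]]), 3, 3))
  } else diag(3)
  if (!is.null(fields[["CompressedData"]]) &&
      tolower(trimws(fields[["CompressedData"]])) == "true") {
    stop("MetaImage format error: compressed payloads are not supported")
  }
  type <- trimws(fields[["ElementType"]])
  payload <- raw[(header_end + 1L):length(raw)]
  values <- decode_raw_payload(payload, type_mha = type, n = prod(size))
  list(values = array(values, size), grid = grid3d(size, spacing, origin,
                                                   direction))
}

## ---- NRRD (.nrrd, raw encoding) -----------------------------------------

write_nrrd <- function(vol, path) {
  g <- vol$grid
  dirs <- apply(g$direction * rep(g$spacing, each = 3), 2, function(col)
    sprintf("(%s)", paste(format(col, digits = 17), collapse = ",")))
  hdr <- c(
    "NRRD0004",
    "# Complete NRRD file format specification at:",
    "# http://teem.sourceforge.net/nrrd/format.html",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(g$size, collapse = " ")),
    sprintf("space directions: %s", paste(dirs, collapse = " ")),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%s)",
            paste(format(g$origin, digits = 17), collapse = ",")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n\n")), con)
  writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  blank <- grepRaw("\n\n", raw, fixed = TRUE)
  if (length(blank) == 0) {
    stop("NRRD format error: header terminator not found")
  }
  blank <- blank[1]
  header <- rawToChar(raw[seq_len(blank)])
  if (!startsWith(header, "NRRD")) stop("not an NRRD file: ", path)
  fields <- parse_kv_header(header, sep = ":")
  dim_n <- as.integer(fields[["dimension"]])
  if (is.na(dim_n) || dim_n != 3L) {
    stop("NRRD format error: expected 3D data, got dimension ",
         fields[["dimension"]])
  }
  if (tolower(trimws(fields[["encoding"]])) != "raw") {
    stop("NRRD format error: only raw encoding is supported")
  }
  size <- as.integer(strsplit(trimws(fields[["sizes"]]), "\\s+")[[1]])
  sd <- fields[["space directions"]]
  if (is.null(sd)) {
    if (!is.null(fields[["spacings"]])) {
      spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), "\\s+")[[1]])
      direction <- diag(3)
    } else {
      stop("NRRD format error: missing space directions / spacings")
    }
  } else {
    vecs <- regmatches(sd, gregexpr("\\(([^)]*)\\)", sd))[[1]]
    cols <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- unname(sqrt(colSums(cols^2)))
    direction <- unname(sweep(cols, 2, spacing, `/`))
  }
  origin <- if (!is.null(fields[["space origin"]])) {
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  } else c(0, 0, 0)
  endian <- if (is.null(fields[["endian"]])) "little" else
    tolower(trimws(fields[["endian"]]))
  payload <- raw[(blank + 2L):length(raw)]
  values <- decode_raw_payload(payload, type_nrrd = trimws(fields[["type"]]),
                               n = prod(size), endian = endian)
  list(values = array(values, size),
       grid = grid3d(size, spacing, origin, direction))
}

parse_kv_header <- function(txt, sep) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines) & grepl(sep, lines, fixed = TRUE)]
  kv <- regmatches(lines, regexpr(sep, lines, fixed = TRUE), invert = TRUE)
  out <- lapply(kv, function(p) trimws(p[2]))
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}

decode_raw_payload <- function(payload, n, type_mha = NULL, type_nrrd = NULL,
                               endian = "little") {
  spec <- if (!is.null(type_mha)) {
    switch(type_mha,
           MET_DOUBLE = list("double", 8L), MET_FLOAT = list("double", 4L),
           MET_SHORT = list("integer", 2L), MET_INT = list("integer", 4L),
           MET_UCHAR = list("integer", 1L),
           stop("unsupported MetaImage ElementType: ", type_mha))
  } else {
    switch(type_nrrd,
           double = list("double", 8L), float = list("double", 4L),
           short = list("integer", 2L), int = list("integer", 4L),
           uchar = list("integer", 1L),
           stop("unsupported NRRD type: ", type_nrrd))
  }
  if (length(payload) < n * spec[[2]]) {
    stop("format error: payload shorter than sizes promise")
  }
  as.numeric(readBin(payload, what = spec[[1]], n = n, size = spec[[2]],
                     endian = endian, signed = spec[[2]] > 1L))
}

## ---- NIfTI-1 via RNifti --------------------------------------------------

write_nifti_vol <- function(vol, path) {
  stop_if_not_identity_direction(vol$grid, "NIfTI export")
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$spacing
  m <- diag(4)
  diag(m)[1:3] <- vol$grid$spacing
  m[1:3, 4] <- vol$grid$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("NIfTI format error: expected 3D data, got ", length(d), "D")
  }
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  if (any(spacing <= 0) || any(!is.finite(spacing))) {
    stop("NIfTI format error: missing or invalid voxel spacing")
  }
  direction <- sweep(m[1:3, 1:3], 2, spacing, `/`)
  origin <- m[1:3, 4]
  list(values = array(as.numeric(img), d),
       grid = grid3d(d, spacing, origin, direction))
}
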