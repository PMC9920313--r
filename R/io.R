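#' Read a 3D volume with spatial metadata
#'
#' Reads NIfTI (`.nii`, `.nii.gz`), NRRD (`.nrrd`) or MetaImage
#' (`.mha`, `.mhd`) files into a [volume3d]. The format is inferred from the
#' file extension. Voxel spacing and origin are taken from the file header;
#' intensities are assumed to be on the Hounsfield-unit scale
#' (`scale_tag = "hu"`).
#'
#' Array data are stored in `(z, y, x)` index order internally while headers
#' keep the conventional `(x, y, z)` ordering for spacing and origin; the
#' reader and writer convert between the two. Direction matrices other than
#' the identity are not interpreted: offsets and spacings are stored verbatim.
#'
#' @param path path to an existing volume file.
#' @return A [volume3d] with `scale_tag = "hu"`.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("read_volume: `path` must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop("read_volume: cannot read '", path, "': no such file", call. = FALSE)
  fmt <- volume_format(path)
  out <- switch(fmt,
    nifti = read_nifti_vol(path),
    nrrd  = read_nrrd_vol(path),
    meta  = read_meta_vol(path),
    stop("read_volume: unsupported extension on '", path,
         "' (expected .nii, .nii.gz, .nrrd, .mha or .mhd)", call. = FALSE))
  out
}

#' Write a 3D volume with spatial metadata
#'
#' Writes a [volume3d] to NIfTI, NRRD or MetaImage format (inferred from the
#' extension of `path`). The written file round-trips through [read_volume()]
#' to an identical volume (exact metadata; intensities stored as 64-bit
#' floats, NRRD/MetaImage, or 32-bit floats, NIfTI).
#'
#' @param vol a [volume3d].
#' @param path destination path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_volume3d(vol)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("write_volume: directory '", dir, "' does not exist", call. = FALSE)
  if (file.access(dir, mode = 2L) != 0L)
    stop("write_volume: cannot write to '", path, "': directory not writable",
         call. = FALSE)
  fmt <- volume_format(path)
  ok <- try(switch(fmt,
    nifti = write_nifti_vol(vol, path),
    nrrd  = write_nrrd_vol(vol, path),
    meta  = write_meta_vol(vol, path),
    stop("write_volume: unsupported extension on '", path, "'", call. = FALSE)),
    silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("write_volume: failed to write '", path, "': ",
         attr(ok, "condition")$message, call. = FALSE)
  invisible(path)
}

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.(mha|mhd)$", lp)) return("meta")
  "unknown"
}

check_dims3 <- function(d, path) {
  d <- d[d > 1L | seq_along(d) <= 3L]  # RNifti may append singleton dims
  if (length(d) != 3L)
    stop("read_volume: '", path, "' is ", length(d),
         "-dimensional; only 3D volumes are supported", call. = FALSE)
  d
}

# ---- NIfTI (RNifti) --------------------------------------------------------

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop("read_volume: '", path, "' is not a 3D image (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  arr <- aperm(array(as.numeric(img), d), c(3L, 2L, 1L))
  volume3d(arr, spacing = as.numeric(sp), origin = as.numeric(org))
}

write_nifti_vol <- function(vol, path) {
  arr <- aperm(vol$data, c(3L, 2L, 1L))  # (x, y, z) for the file
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vol$spacing
  m <- rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- NRRD ------------------------------------------------------------------
# Minimal NRRD implementation: attached raw little-endian data, double type.

read_nrrd_vol <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic))
    stop("read_volume: '", path, "' is not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("read_volume: '", path, "': truncated NRRD header", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (!identical(fields[["dimension"]], "3"))
    stop("read_volume: '", path, "' has dimension ", fields[["dimension"]],
         "; only 3D volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])  # (x, y, z)
  type <- fields[["type"]]
  n <- prod(sizes)
  enc <- tolower(fields[["encoding"]] %||% "raw")
  if (enc != "raw")
    stop("read_volume: '", path, "': NRRD encoding '", enc,
         "' not supported (raw only)", call. = FALSE)
  what <- nrrd_read_type(type, path)
  vals <- readBin(con, what$what, n = n, size = what$size, endian = "little",
                  signed = what$signed)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      xyz <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(xyz^2))
    }, numeric(1))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  arr <- aperm(array(as.numeric(vals), sizes), c(3L, 2L, 1L))
  volume3d(arr, spacing = spacing, origin = origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nrrd_read_type <- function(type, path) {
  switch(type,
    "double" = list(what = "double", size = 8L, signed = TRUE),
    "float"  = list(what = "double", size = 4L, signed = TRUE),
    "short"  = list(what = "integer", size = 2L, signed = TRUE),
    "int"    = list(what = "integer", size = 4L, signed = TRUE),
    "uchar"  = list(what = "integer", size = 1L, signed = FALSE),
    stop("read_volume: '", path, "': NRRD type '", type, "' not supported",
         call. = FALSE))
}

write_nrrd_vol <- function(vol, path) {
  d <- dim(vol$data)
  sizes <- c(d[3], d[2], d[1])  # (x, y, z)
  sp <- vol$spacing
  hdr <- c(
    "NRRD0004",
    "# generated by freqgan",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(sizes, collapse = " ")),
    paste0("space directions: (", sp[1], ",0,0) (0,", sp[2], ",0) (0,0,", sp[3], ")"),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: (", paste(vol$origin, collapse = ","), ")"),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(aperm(vol$data, c(3L, 2L, 1L))), con, size = 8L,
           endian = "little")
  invisible(path)
}

# ---- MetaImage -------------------------------------------------------------
# .mha stores data inline (ElementDataFile = LOCAL); .mhd points to a .raw.

read_meta_vol <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("read_volume: '", path, "': truncated MetaImage header",
           call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L)
      stop("read_volume: '", path, "': malformed MetaImage header line: ",
           line, call. = FALSE)
    key <- trimws(kv[1])
    fields[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["NDims"]], "3"))
    stop("read_volume: '", path, "' has NDims ", fields[["NDims"]],
         "; only 3D volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(fields[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(fields[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  et <- fields[["ElementType"]] %||% "MET_DOUBLE"
  what <- switch(et,
    "MET_DOUBLE" = list(what = "double", size = 8L, signed = TRUE),
    "MET_FLOAT"  = list(what = "double", size = 4L, signed = TRUE),
    "MET_SHORT"  = list(what = "integer", size = 2L, signed = TRUE),
    "MET_UCHAR"  = list(what = "integer", size = 1L, signed = FALSE),
    stop("read_volume: '", path, "': ElementType '", et, "' not supported",
         call. = FALSE))
  n <- prod(sizes)
  datafile <- fields[["ElementDataFile"]]
  if (identical(datafile, "LOCAL")) {
    vals <- readBin(con, what$what, n = n, size = what$size,
                    endian = "little", signed = what$signed)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop("read_volume: '", path, "': data file '", rawpath, "' not found",
           call. = FALSE)
    vals <- readBin(rawpath, what$what, n = n, size = what$size,
                    endian = "little", signed = what$signed)
  }
  if (length(vals) < n)
    stop("read_volume: '", path, "': data shorter than DimSize implies",
         call. = FALSE)
  arr <- aperm(array(as.numeric(vals), sizes), c(3L, 2L, 1L))
  volume3d(arr, spacing = spacing, origin = origin)
}

write_meta_vol <- function(vol, path) {
  d <- dim(vol$data)
  sizes <- c(d[3], d[2], d[1])
  detached <- grepl("\\.mhd$", tolower(path))
  datafile <- if (detached) paste0(basename(tools::file_path_sans_ext(path)),
                                   ".raw") else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(sizes, collapse = " ")),
    paste("ElementSpacing =", paste(vol$spacing, collapse = " ")),
    paste("Offset =", paste(vol$origin, collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", datafile))
  vec <- as.vector(aperm(vol$data, c(3L, 2L, 1L)))
  if (detached) {
    writeLines(hdr, path)
    writeBin(vec, file.path(dirname(path), datafile), size = 8L,
             endian = "little")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(vec, con, size = 8L, endian = "little")
  }
  invisible(path)
}
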