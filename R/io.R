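#' Read a 3D volume from NIfTI or NRRD
#'
#' Dispatches on the file extension: `.nii` / `.nii.gz` are read with the
#' NIfTI-1 reader, `.nrrd` with a compact NRRD reader supporting `raw` and
#' `gzip` encodings of scalar 3D data.  Spacing is taken from the header
#' (`pixdim` / `space directions`), the origin from the stored transform /
#' `space origin`.
#'
#' @param path file to read.
#' @return a [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: '%s'", path), class = "segda_io_error")
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    data <- as.array(img)
    attributes(data) <- list(dim = dim(data))
    spacing <- RNifti::pixdim(img)[1:3]
    m <- RNifti::xform(img)
    origin <- as.numeric(m[1:3, 4])
    volume(data, spacing = spacing, origin = origin)
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    read_nrrd(path)
  } else {
    abort(sprintf("Unsupported volume format: '%s' (use .nii, .nii.gz or .nrrd)", path),
          class = "segda_io_error")
  }
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' Data are stored as 64-bit floats so values round-trip exactly; spacing
#' and origin are written to the header.  The format follows the file
#' extension as in [read_volume()].
#'
#' @param vol a [volume()] or [label_map()].
#' @param path destination path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!(is_volume(vol) || is_labelmap(vol))) {
    abort("`vol` must be a segda_volume or segda_labelmap.", class = "segda_usage_error")
  }
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Directory does not exist: '%s'", dirname(path)),
          class = "segda_io_error")
  }
  data <- array(as.numeric(vol$data), dim(vol$data))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(data)
    m <- diag(4)
    diag(m)[1:3] <- vol$spacing
    m[1:3, 4] <- vol$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    write_nrrd(vol, path)
  } else {
    abort(sprintf("Unsupported volume format: '%s' (use .nii, .nii.gz or .nrrd)", path),
          class = "segda_io_error")
  }
  invisible(path)
}

#' Read a label map
#'
#' Reads with [read_volume()] and reinterprets the voxel values as integer
#' class labels (rounding guards against lossy storage).
#'
#' @param path file to read.
#' @param n_classes number of classes including background.
#' @return a [label_map()].
#' @export
read_label_map <- function(path, n_classes = 4L) {
  v <- read_volume(path)
  label_map(array(as.integer(round(v$data)), dim(v$data)),
            spacing = v$spacing, origin = v$origin, n_classes = n_classes)
}

# ---- minimal NRRD support (text header + raw/gzip payload) ------------------

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) {
    abort(sprintf("Not an NRRD file: '%s'", path), class = "segda_io_error")
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L) {
    abort("Only 3D NRRD volumes are supported.", class = "segda_io_error")
  }
  type <- fields$type
  enc <- tolower(fields$encoding %||% "raw")
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    dirs <- lapply(vecs, function(s) as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]))
    spacing <- vapply(dirs, function(d) sqrt(sum(d^2)), 0)
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]])) {
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  }
  payload <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    abort(sprintf("Unsupported NRRD encoding '%s' in '%s'", enc, path),
          class = "segda_io_error")
  }
  n <- prod(sizes)
  data <- switch(type,
    "double" = , "float64" = readBin(payload, "double", n = n, size = 8, endian = "little"),
    "float" = , "float32" = readBin(payload, "double", n = n, size = 4, endian = "little"),
    "short" = , "int16" = , "signed short" =
      readBin(payload, "integer", n = n, size = 2, endian = "little"),
    "int" = , "int32" = readBin(payload, "integer", n = n, size = 4, endian = "little"),
    "uchar" = , "uint8" = as.integer(readBin(payload, "raw", n = n)),
    abort(sprintf("Unsupported NRRD type '%s' in '%s'", type, path),
          class = "segda_io_error")
  )
  volume(array(as.numeric(data), sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(vol, path) {
  d <- dim(vol$data)
  dirs <- sprintf("(%s,0,0) (0,%s,0) (0,0,%s)",
                  format(vol$spacing[1], digits = 17),
                  format(vol$spacing[2], digits = 17),
                  format(vol$spacing[3], digits = 17))
  header <- c(
    "NRRD0004",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    "encoding: gzip",
    "endian: little",
    "space dimension: 3",
    sprintf("space directions: %s", dirs),
    sprintf("space origin: (%s,%s,%s)",
            format(vol$origin[1], digits = 17),
            format(vol$origin[2], digits = 17),
            format(vol$origin[3], digits = 17)),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  payload <- writeBin(as.numeric(vol$data), raw(), size = 8, endian = "little")
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}

# ---- cohort manifest --------------------------------------------------------

manifest_cols <- c("case_id", "image_path", "label_path", "split", "domain", "labeled")

#' Write a cohort manifest CSV
#'
#' @param manifest tibble with columns `case_id`, `image_path`,
#'   `label_path`, `split`, `domain`, `labeled`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(manifest_cols, names(manifest))
  if (length(missing)) {
    abort(paste0("manifest is missing columns: ", paste(missing, collapse = ", ")),
          class = "segda_usage_error")
  }
  readr::write_csv(manifest[manifest_cols], path)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' @param path manifest CSV written by [write_manifest()].
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: '%s'", path), class = "segda_io_error")
  }
  readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    image_path = readr::col_character(),
    label_path = readr::col_character(),
    split = readr::col_character(),
    domain = readr::col_character(),
    labeled = readr::col_logical()
  ))
}
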