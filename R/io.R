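# Volume and manifest I/O. NIfTI goes through RNifti; NRRD (attached
# single-file, raw or gzip encoding) is read and written directly since no
# installed package covers it.

#' Read a volume from NIfTI or NRRD
#'
#' @param path file ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return An object of class `volume_record`: list with `grid` (3D numeric
#'   array), `spacing` (voxel size per axis), `format` and `path`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
    if (length(d) != 3L)
      stop("expected a 3-dimensional single-channel volume, got ",
           length(d), " dimensions")
    grid <- array(as.numeric(img), d)   # plain array, no header attributes
    spacing <- RNifti::pixdim(img)[1:3]
    fmt <- "nifti"
  } else if (grepl("\\.nrrd$", lp)) {
    rec <- read_nrrd(path)
    grid <- rec$grid
    spacing <- rec$spacing
    fmt <- "nrrd"
  } else {
    stop("unrecognized volume extension (use .nii, .nii.gz or .nrrd): ", path)
  }
  if (any(spacing <= 0) || any(is.na(spacing))) spacing <- rep(1, 3)
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 format = fmt, path = path),
            class = "volume_record")
}

#' Write a volume to NIfTI or NRRD
#'
#' Voxel data are stored as float32; `read_volume(write_volume(v))`
#' round-trips float32 grids bit-exactly and preserves spacing.
#'
#' @param record a `volume_record`, or a plain 3D array.
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param spacing voxel spacing, used when `record` is a plain array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(record, path, spacing = c(1, 1, 1)) {
  if (is.array(record)) {
    if (length(dim(record)) != 3L)
      stop("expected a 3-dimensional single-channel volume, got ",
           length(dim(record)), " dimensions")
    record <- structure(list(grid = record, spacing = spacing),
                        class = "volume_record")
  }
  stopifnot(inherits(record, "volume_record"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(record$grid)
    RNifti::pixdim(img) <- record$spacing
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (grepl("\\.nrrd$", lp)) {
    write_nrrd(record$grid, path, spacing = record$spacing)
  } else {
    stop("unrecognized volume extension (use .nii, .nii.gz or .nrrd): ", path)
  }
  invisible(path)
}

# Minimal NRRD reader: detached headers are not supported; data types float
# and double; encodings raw and gzip; little-endian.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("corrupt NRRD header: missing magic in ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("corrupt NRRD header: no blank line before data")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr("^[^:]+: *", line))
    if (length(kv) == 0L) next
    key <- tolower(trimws(sub(": *$", "", kv)))
    fields[[key]] <- trimws(sub("^[^:]+: *", "", line))
  }
  dim_n <- as.integer(fields[["dimension"]])
  sizes <- as.integer(strsplit(fields[["sizes"]], " +")[[1]])
  if (is.na(dim_n) || dim_n != 3L || length(sizes) != 3L)
    stop("expected a 3-dimensional single-channel volume in ", path)
  type <- fields[["type"]]
  if (!type %in% c("float", "double")) stop("unsupported NRRD type: ", type)
  enc <- fields[["encoding"]]
  nbytes <- if (type == "float") 4L else 8L
  want <- prod(sizes) * nbytes
  payload <- readBin(con, "raw", n = file.size(path))
  if (identical(enc, "gzip")) payload <- memDecompress(payload, type = "gzip")
  else if (!identical(enc, "raw")) stop("unsupported NRRD encoding: ", enc)
  if (length(payload) < want) stop("corrupt NRRD payload in ", path)
  vals <- readBin(payload[seq_len(want)], "numeric", n = prod(sizes),
                  size = nbytes, endian = "little")
  spacing <- rep(1, 3)
  if (!is.null(fields[["spacings"]]))
    spacing <- as.numeric(strsplit(fields[["spacings"]], " +")[[1]])
  else if (!is.null(fields[["space directions"]])) {
    rows <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    vecs <- lapply(rows, function(r)
      as.numeric(strsplit(gsub("[()]", "", r), ",")[[1]]))
    spacing <- vapply(vecs, function(v) sqrt(sum(v^2)), numeric(1))
  }
  list(grid = array(vals, sizes), spacing = spacing)
}

write_nrrd <- function(grid, path, spacing = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by nodulecam",
           "type: float",
           "dimension: 3",
           sprintf("sizes: %d %d %d", dim(grid)[1], dim(grid)[2], dim(grid)[3]),
           sprintf("spacings: %.17g %.17g %.17g", spacing[1], spacing[2], spacing[3]),
           "endian: little",
           "encoding: raw",
           "")
  writeLines(hdr, con)
  writeBin(as.numeric(grid), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `path`, `label`, `split`, `seed`: one
#' volume file per row with its 0/1 label, its split assignment
#' (`train`/`validation`/`test`) and the generator seed that produced it.
#'
#' @param path CSV file.
#' @return A `data.frame` of class `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label", "split", "seed")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  if (any(!df$label %in% c(0, 1)))
    stop("manifest labels must be 0 or 1; offending values: ",
         paste(unique(df$label[!df$label %in% c(0, 1)]), collapse = ", "))
  df$label <- as.integer(df$label)
  bad <- setdiff(unique(df$split), c("train", "validation", "test"))
  if (length(bad)) stop("unknown split name(s): ", paste(bad, collapse = ", "))
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Write a dataset manifest
#'
#' @param manifest a `data.frame` with columns `path`, `label`, `split`, `seed`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "label", "split", "seed") %in% names(manifest)))
  utils::write.csv(as.data.frame(manifest)[, c("path", "label", "split", "seed")],
                   path, row.names = FALSE)
  invisible(path)
}
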