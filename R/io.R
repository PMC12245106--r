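# Volume and table I/O. A volume is stored as three single-channel
# multi-page 16-bit TIFF stacks (one page per z-slice) plus a JSON sidecar
# with the voxel size, origin and channel roles; intensities are rounded to
# integers on write, so integer-valued volumes round-trip exactly.

#' Write a volume to TIFF stacks
#'
#' Writes `<basename>_green.tif`, `<basename>_blue.tif`, `<basename>_red.tif`
#' (16-bit, one page per z-slice) and `<basename>_meta.json`.
#'
#' @param volume A [volume_image()]; intensities in \[0, 65535\].
#' @param basename Path prefix for the four files.
#' @param metadata Optional named list merged into the JSON sidecar (e.g.
#'   seed, generator settings).
#' @return `basename`, invisibly.
#' @export
write_volume <- function(volume, basename, metadata = list()) {
  if (!inherits(volume, "volume_image")) abort_input("`volume` must be a volume_image")
  if (max(volume$green, volume$blue, volume$red) > 65535) {
    abort_input("intensities exceed the 16-bit range")
  }
  for (ch in c("green", "blue", "red")) {
    a <- round(volume[[ch]])
    pages <- lapply(seq_len(dim(a)[3]), function(k) {
      # tiff stores matrices row-major as (row = y); keep x as rows of the
      # transposed matrix so read_volume can invert exactly
      t(a[, , k]) / 65535
    })
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", basename, ch),
                    bits.per.sample = 16L)
  }
  meta <- c(list(
    voxel_size_um = volume$voxel_size,
    origin_um = volume$origin,
    dim = dim(volume$green),
    channels = list(green = "scaffold", blue = "live", red = "dead")
  ), metadata)
  jsonlite::write_json(meta, sprintf("%s_meta.json", basename),
                       auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Read a volume written by [write_volume()]
#'
#' @param basename The path prefix used at write time.
#' @return A [volume_image()].
#' @export
read_volume <- function(basename) {
  meta_path <- sprintf("%s_meta.json", basename)
  if (!file.exists(meta_path)) abort_input(sprintf("missing sidecar: %s", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("voxel_size_um", "dim")) {
    if (is.null(meta[[field]])) {
      abort_input(sprintf("volume metadata is missing `%s`", field))
    }
  }
  dims <- as.integer(meta$dim)
  chans <- lapply(c("green", "blue", "red"), function(ch) {
    path <- sprintf("%s_%s.tif", basename, ch)
    if (!file.exists(path)) abort_input(sprintf("missing channel file: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != dims[3]) abort_input("page count does not match metadata")
    a <- array(0, dim = dims)
    for (k in seq_along(pages)) a[, , k] <- t(pages[[k]]) * 65535
    round(a)
  })
  volume_image(chans[[1]], chans[[2]], chans[[3]],
               voxel_size = meta$voxel_size_um,
               origin = meta$origin_um %||% c(0, 0, 0))
}

#' Write a spheroid record table as CSV
#'
#' @param result An `hc_result` from [process_volume()] or its `records`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spheroid_records <- function(result, path) {
  records <- if (inherits(result, "hc_result")) result$records else as_tibble(result)
  readr::write_csv(records, path)
  invisible(path)
}
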