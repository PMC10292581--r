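#' Construct a band set
#'
#' A `band_set` records the wavelengths (nm) of the image planes in a
#' [spectral_image()] and their common bandwidth. The default is the
#' nine-band set in [SPECQTL_WAVELENGTHS].
#'
#' @param wavelengths_nm Integer vector of band centre wavelengths in nm,
#'   strictly increasing, no duplicates.
#' @param bandwidth_nm Bandwidth in nm shared by all bands (default 10).
#' @return An object of class `band_set`.
#' @export
band_set <- function(wavelengths_nm = SPECQTL_WAVELENGTHS, bandwidth_nm = 10L) {
  wavelengths_nm <- as.integer(wavelengths_nm)
  if (length(wavelengths_nm) < 1L || anyNA(wavelengths_nm))
    stop("wavelengths must be a non-empty integer vector")
  if (anyDuplicated(wavelengths_nm))
    stop("duplicate wavelengths in band set")
  if (is.unsorted(wavelengths_nm, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(
    list(wavelengths_nm = wavelengths_nm,
         bandwidth_nm = rep_len(as.integer(bandwidth_nm), length(wavelengths_nm))),
    class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat("<band_set> ", length(x$wavelengths_nm), " bands: ",
      paste(x$wavelengths_nm, collapse = ", "), " nm (bandwidth ",
      x$bandwidth_nm[1], " nm)\n", sep = "")
  invisible(x)
}

#' Construct a spectral image
#'
#' A co-registered multiband reflectance raster for one plant. Pixel values
#' are dimensionless relative intensities in `[0, 1]`; co-registration of the
#' band planes is assumed, not computed.
#'
#' @param pixels Numeric `H x W x B` array, values in `[0, 1]`, band planes in
#'   ascending-wavelength order.
#' @param bands A [band_set()] with `B` wavelengths.
#' @param plant_id Identifier string.
#' @param capture_date ISO date string (or `Date`).
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(pixels, bands = band_set(), plant_id = "plant",
                           capture_date = NA_character_) {
  if (length(dim(pixels)) != 3L)
    stop("pixels must be an H x W x B array")
  if (dim(pixels)[3] != length(bands$wavelengths_nm))
    stop("third array dimension must match the number of bands")
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  dimnames(pixels) <- list(NULL, NULL, as.character(bands$wavelengths_nm))
  structure(
    list(pixels = pixels, bands = bands, plant_id = as.character(plant_id),
         capture_date = as.character(capture_date)),
    class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<spectral_image> ", x$plant_id, ": ", d[1], "x", d[2], " px, ",
      d[3], " bands\n", sep = "")
  invisible(x)
}

band_index <- function(img, wavelength_nm) {
  i <- match(as.integer(wavelength_nm), img$bands$wavelengths_nm)
  if (is.na(i)) stop("band ", wavelength_nm, " nm not present in image")
  i
}

read_plane <- function(path) {
  ext <- tolower(tools::file_ext(path))
  plane <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext))
  collapse_gray(plane)
}

# multi-channel images collapse to the first channel (grayscale stacks often
# decode as replicated RGB); genuinely colored input is refused
collapse_gray <- function(plane) {
  if (length(dim(plane)) == 3L) {
    ch <- dim(plane)[3]
    first <- plane[, , 1L]
    for (k in seq_len(ch)[-1L]) {
      if (max(abs(plane[, , k] - first)) > 1 / 255)
        stop("image has unequal color channels; expected grayscale")
    }
    plane <- first
  }
  plane
}

#' Load per-band image files into a spectral image
#'
#' Reads one grayscale image per wavelength (TIFF preferred, PNG and JPEG
#' accepted) or a single multi-page TIFF whose page order is ascending
#' wavelength, and assembles a [spectral_image()]. Raw integer values are
#' rescaled to `[0, 1]` by `value / (2^bitdepth - 1)`; 8- and 16-bit input is
#' supported. Band planes are always ordered by ascending wavelength,
#' regardless of the order the paths are supplied in.
#'
#' @param paths Either a character vector of per-band file paths whose names
#'   are the wavelengths in nm (e.g. `c("800" = "p800.tif", ...)`), or a
#'   single unnamed path to a multi-page TIFF.
#' @param bands Expected [band_set()].
#' @param plant_id,capture_date Passed through to [spectral_image()].
#' @return A [spectral_image()].
#' @export
load_band_images <- function(paths, bands = band_set(), plant_id = "plant",
                             capture_date = NA_character_) {
  wl <- bands$wavelengths_nm
  if (length(paths) == 1L && is.null(names(paths))) {
    if (!file.exists(paths)) stop("file not found: ", paths)
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < length(wl))
      stop("missing band ", wl[length(pages) + 1L],
           ": stack has ", length(pages), " pages, expected ", length(wl))
    if (length(pages) > length(wl))
      stop("stack has more pages than bands")
    planes <- lapply(pages, collapse_gray)
  } else {
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stop("per-band paths must be named by wavelength (nm)")
    got <- suppressWarnings(as.integer(names(paths)))
    if (anyNA(got)) stop("path names must be integer wavelengths")
    miss <- setdiff(wl, got)
    if (length(miss)) stop("missing band ", miss[1])
    extra <- setdiff(got, wl)
    if (length(extra)) stop("unexpected band ", extra[1])
    paths <- paths[order(got)]
    absent <- !file.exists(paths)
    if (any(absent))
      stop("missing band ", sort(got)[which(absent)[1]],
           ": file not found: ", paths[absent][1])
    planes <- lapply(paths, read_plane)
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("unregistered stack: band planes have differing dimensions")
  pixels <- array(unlist(planes, use.names = FALSE),
                  dim = unname(c(dims[1, 1], dims[2, 1], length(wl))))
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  spectral_image(pixels, bands, plant_id, capture_date)
}

#' Write a spectral image as a multi-page TIFF
#'
#' Pages are written in ascending-wavelength order so the file round-trips
#' through [load_band_images()].
#'
#' @param img A [spectral_image()].
#' @param path Output path (`.tif`).
#' @param bits_per_sample 8 or 16.
#' @export
write_band_images <- function(img, path, bits_per_sample = 16L) {
  stopifnot(inherits(img, "spectral_image"))
  planes <- lapply(seq_along(img$bands$wavelengths_nm),
                   function(b) img$pixels[, , b])
  tiff::writeTIFF(planes, path, bits.per.sample = as.integer(bits_per_sample))
  invisible(path)
}

#' Write a tabular artifact to CSV
#'
#' UTF-8 CSV with a header row and `.` decimal separator; round-trips
#' losslessly through [read_table_csv()] (numeric values at full double
#' precision).
#'
#' @param records A non-empty data frame.
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty table")
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   utf8, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a tabular artifact written by [write_table()]
#'
#' @param path CSV path.
#' @return A data frame; column types are re-inferred.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

#' Construct a marker genotype container
#'
#' Genotypes are coded `A` (homozygous, matching the recurrent class), `H`
#' (heterozygous) and `-` (missing). The two parent rows are kept separate
#' from the F1 block.
#'
#' @param parents Character matrix `2 x M`, rownames the parent ids
#'   (conventionally `P1`, `P2`).
#' @param f1 Character matrix `N x M`, rownames the F1 ids.
#' @param marker_names Optional; defaults to the column names.
#' @return An object of class `marker_genotypes` with fields `parents`, `f1`,
#'   `marker_names`, and `all_missing` (logical flag per marker: no F1 calls).
#' @export
marker_genotypes <- function(parents, f1, marker_names = colnames(f1)) {
  parents <- as.matrix(parents); f1 <- as.matrix(f1)
  if (nrow(parents) != 2L) stop("exactly two parent rows expected")
  if (ncol(parents) != ncol(f1)) stop("parents and F1 must share markers")
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(f1)))
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  bad <- setdiff(unique(c(parents, f1)), c("A", "H", "-"))
  if (length(bad))
    stop("invalid genotype symbol(s): ", paste(bad, collapse = ", "),
         " (allowed: A, H, -)")
  colnames(parents) <- colnames(f1) <- marker_names
  if (is.null(rownames(parents))) rownames(parents) <- c("P1", "P2")
  if (is.null(rownames(f1))) rownames(f1) <- paste0("F1_", seq_len(nrow(f1)))
  structure(
    list(parents = parents, f1 = f1, marker_names = marker_names,
         all_missing = apply(f1 == "-", 2, all)),
    class = "marker_genotypes")
}

#' @export
print.marker_genotypes <- function(x, ...) {
  cat("<marker_genotypes> ", nrow(x$f1), " F1 individuals x ",
      length(x$marker_names), " markers (+2 parents)\n", sep = "")
  invisible(x)
}

#' Read a genotype CSV
#'
#' Expected dialect: one row per individual with the individual id in the
#' first column, one column per marker, cells in `{A, H, -}` (empty cells and
#' `NA` are read as missing). The first two rows are the parents `P1` and
#' `P2`; all remaining rows are the F1 population. Marker columns with no F1
#' calls are retained but flagged in `$all_missing`.
#'
#' @param path CSV path.
#' @return A [marker_genotypes()] object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (nrow(raw) < 3L) stop("need two parent rows plus at least one F1 row")
  header <- colnames(raw)[-1]
  if (anyDuplicated(header)) stop("duplicate marker names")
  ids <- raw[[1]]
  geno <- as.matrix(raw[, -1, drop = FALSE])
  colnames(geno) <- header
  geno[is.na(geno) | geno == ""] <- "-"
  bad <- setdiff(unique(as.vector(geno)), c("A", "H", "-"))
  if (length(bad))
    stop("parse error: invalid genotype symbol(s): ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(colnames(geno))) stop("duplicate marker names")
  rownames(geno) <- ids
  marker_genotypes(geno[1:2, , drop = FALSE], geno[-(1:2), , drop = FALSE])
}

#' Write genotypes in the CSV dialect read by [read_genotypes()]
#'
#' @param g A [marker_genotypes()] object.
#' @param path Output path.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "marker_genotypes"))
  m <- rbind(g$parents, g$f1)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_table(df, path)
}
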