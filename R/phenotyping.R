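#' Segment plant pixels by the NIR-versus-red rule
#'
#' A pixel is plant if its reflectance at the NIR band (default 800 nm)
#' strictly exceeds its reflectance at the red band (default 680 nm); ties and
#' everything else (pot, soil, background) are masked out. Healthy leaf tissue
#' reflects strongly in the NIR while soil does not, so this single
#' inequality separates vegetation from background without training data.
#'
#' @param img A [spectral_image()].
#' @param nir_nm NIR wavelength, must be present in the image (default 800).
#' @param red_nm Red wavelength (default 680).
#' @return An object of class `plant_mask`: list with `mask` (H x W logical)
#'   and `n_plant_pixels`.
#' @export
segment_plant <- function(img, nir_nm = 800, red_nm = 680) {
  stopifnot(inherits(img, "spectral_image"))
  nir <- img$pixels[, , band_index(img, nir_nm)]
  red <- img$pixels[, , band_index(img, red_nm)]
  mask <- nir > red
  structure(list(mask = mask, n_plant_pixels = sum(mask)),
            class = "plant_mask")
}

#' @export
print.plant_mask <- function(x, ...) {
  cat("<plant_mask> ", x$n_plant_pixels, " plant pixels of ",
      length(x$mask), "\n", sep = "")
  invisible(x)
}

#' Vegetation cover area
#'
#' The number of plant-classified pixels, optionally converted to a physical
#' area.
#'
#' @param mask A [segment_plant()] mask.
#' @param pixel_area Optional physical area of one pixel; if given, the
#'   result is `n_plant_pixels * pixel_area`.
#' @return Scalar area.
#' @export
cover_area <- function(mask, pixel_area = NULL) {
  stopifnot(inherits(mask, "plant_mask"))
  n <- mask$n_plant_pixels
  if (is.null(pixel_area)) n else n * pixel_area
}

#' Per-band median spectrum of the segmented plant
#'
#' For each band, the median intensity over the plant pixels (even counts:
#' mean of the two middle values). The median is robust to specular
#' highlights and residual mis-segmented pixels.
#'
#' @param img A [spectral_image()].
#' @param mask A [segment_plant()] mask with at least one plant pixel.
#' @return An object of class `raw_spectrum`: list with `plant_id`, `date`,
#'   and `r`, a named numeric vector (`r445` ... `r800`) of per-band medians.
#' @export
median_spectrum <- function(img, mask) {
  stopifnot(inherits(img, "spectral_image"), inherits(mask, "plant_mask"))
  if (!identical(dim(mask$mask), dim(img$pixels)[1:2]))
    stop("mask dimensions do not match image")
  if (mask$n_plant_pixels < 1L)
    stop("no plant pixels: plant absent or image invalid")
  wl <- img$bands$wavelengths_nm
  r <- vapply(seq_along(wl),
              function(b) stats::median(img$pixels[, , b][mask$mask]),
              numeric(1))
  names(r) <- paste0("r", wl)
  structure(list(plant_id = img$plant_id, date = img$capture_date, r = r),
            class = "raw_spectrum")
}

#' Standardize a raw spectrum to sum-to-one proportions
#'
#' Rescales the nine per-band medians so they sum to 1, removing the global
#' illumination scale and making spectra comparable across capture days with
#' different light conditions.
#'
#' @param raw A [median_spectrum()] result, or a named numeric vector of
#'   per-band medians.
#' @return An object of class `standardized_spectrum`: list with `plant_id`,
#'   `date`, and `p`, a named numeric vector (`p445` ... `p800`) summing to 1.
#' @export
standardize_spectrum <- function(raw) {
  if (inherits(raw, "raw_spectrum")) {
    r <- raw$r; plant_id <- raw$plant_id; date <- raw$date
  } else {
    r <- raw; plant_id <- NA_character_; date <- NA_character_
  }
  if (any(r < 0)) stop("negative band medians")
  s <- sum(r)
  if (!is.finite(s) || s <= 0) stop("degenerate spectrum: band sum is zero")
  p <- r / s
  names(p) <- sub("^r", "p", names(p))
  structure(list(plant_id = plant_id, date = date, p = p),
            class = "standardized_spectrum")
}

# band accessor on the proportion scale; x is the named proportion vector
pband <- function(p, wl) {
  v <- p[[paste0("p", wl)]]
  if (is.null(v)) stop("band ", wl, " nm absent from spectrum")
  v
}

#' Compute the fifteen vegetation indices from a standardized spectrum
#'
#' Evaluates the index formulas on the sum-to-one band proportions, writing
#' the proportion at wavelength w as `w`:
#'
#' * biomass: `NDVI = (800-676)/(800+676)`; `SR = 800/676`;
#'   `EVI = 2.5(800-676)/(800 + 6*676 - 7.5*500 + 1)`;
#'   `VARI = (550-676)/(550+676-500)`; `ViGreen = (550-676)/(550+676)`
#' * pigments: `SIPI = (800-445)/(800-680)`; `PSND = (800-445)/(800+445)`
#' * chlorophyll: `CARI = 700-676-0.2(700-550)`; `MCARI = CARI * 700/676`
#' * anthocyanins: `ARI = 1/550 - 1/700`; `RGRI = 676/550`; `ACI = 550/800`
#' * carotenoids: `CRI1 = 1/500 - 1/550`; `CRI2 = 1/500 - 1/700`
#' * light-use efficiency: `PRI = (532-568)/(532+568)`
#'
#' Ratio-form indices are invariant to the overall illumination scale;
#' CARI, MCARI, ARI, CRI1 and CRI2 are not (their formulas are not pure
#' ratios), but a shared illumination factor preserves the between-plant
#' ranking of each, which is what the downstream genetic analysis uses.
#' A zero denominator makes that one index `NaN` with a warning; the other
#' indices are still computed.
#'
#' @param s A [standardize_spectrum()] result (or named proportion vector
#'   `p445` ... `p800`).
#' @return An object of class `vegetation_index_set`: list with `plant_id`,
#'   `date`, and `values`, a named numeric vector of the 15 indices.
#' @export
compute_vegetation_indices <- function(s) {
  if (inherits(s, "standardized_spectrum")) {
    p <- s$p; plant_id <- s$plant_id; date <- s$date
  } else {
    p <- s; plant_id <- NA_character_; date <- NA_character_
  }
  b <- function(wl) pband(p, wl)
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning("undefined index ", name, ": zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  v <- c(
    NDVI    = ratio(b(800) - b(676), b(800) + b(676), "NDVI"),
    SR      = ratio(b(800), b(676), "SR"),
    EVI     = ratio(2.5 * (b(800) - b(676)),
                    b(800) + 6 * b(676) - 7.5 * b(500) + 1, "EVI"),
    VARI    = ratio(b(550) - b(676), b(550) + b(676) - b(500), "VARI"),
    ViGreen = ratio(b(550) - b(676), b(550) + b(676), "ViGreen"),
    SIPI    = ratio(b(800) - b(445), b(800) - b(680), "SIPI"),
    PSND    = ratio(b(800) - b(445), b(800) + b(445), "PSND"),
    CARI    = b(700) - b(676) - 0.2 * (b(700) - b(550)),
    MCARI   = (b(700) - b(676) - 0.2 * (b(700) - b(550))) *
              ratio(b(700), b(676), "MCARI"),
    ARI     = ratio(1, b(550), "ARI") - ratio(1, b(700), "ARI"),
    RGRI    = ratio(b(676), b(550), "RGRI"),
    ACI     = ratio(b(550), b(800), "ACI"),
    CRI1    = ratio(1, b(500), "CRI1") - ratio(1, b(550), "CRI1"),
    CRI2    = ratio(1, b(500), "CRI2") - ratio(1, b(700), "CRI2"),
    PRI     = ratio(b(532) - b(568), b(532) + b(568), "PRI"))
  structure(list(plant_id = plant_id, date = date, values = v),
            class = "vegetation_index_set")
}
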