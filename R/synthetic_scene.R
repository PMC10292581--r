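#' Spectral profiles for synthetic scenes
#'
#' A `spectral_profile` holds per-band mean relative reflectances and noise
#' SDs for one scene material. Plant profiles (`green_leaf`, `dormant_leaf`)
#' must reflect more at 800 nm (NIR) than at 680 nm (red) - the contrast the
#' segmentation rule exploits - while `background` must not. The default
#' green leaf peaks in the green (550 nm) with strong NIR; the default
#' dormant (anthocyanic, red/brown) leaf depresses the green bands and
#' elevates 676-700 nm, the red/far-red shape of anthocyanin-rich overwintering
#' foliage; the default background is a flat soil-like spectrum with low NIR.
#'
#' @param means Named numeric vector of 9 band means in `[0, 1]` (names
#'   `445` ... `800`), or unnamed in ascending-wavelength order.
#' @param sds Per-band Gaussian noise SD (recycled; default 0.02).
#' @param label One of `"green_leaf"`, `"dormant_leaf"`, `"background"`.
#' @return An object of class `spectral_profile`.
#' @export
spectral_profile <- function(means, sds = 0.02,
                             label = c("green_leaf", "dormant_leaf",
                                       "background")) {
  label <- match.arg(label)
  wl <- SPECQTL_WAVELENGTHS
  means <- as.numeric(means)
  if (length(means) != length(wl)) stop("need ", length(wl), " band means")
  if (any(means < 0 | means > 1)) stop("band means must lie in [0, 1]")
  names(means) <- as.character(wl)
  nir <- means[["800"]]; red <- means[["680"]]
  if (label %in% c("green_leaf", "dormant_leaf") && nir <= red)
    stop("plant profile must have 800 nm mean > 680 nm mean")
  if (label == "background" && nir > red)
    stop("background profile must have 800 nm mean <= 680 nm mean")
  structure(list(means = means,
                 sds = rep_len(as.numeric(sds), length(wl)),
                 label = label),
            class = "spectral_profile")
}

#' @rdname spectral_profile
#' @export
default_profile <- function(label = c("green_leaf", "dormant_leaf",
                                      "background")) {
  label <- match.arg(label)
  means <- switch(label,
    green_leaf   = c(0.05, 0.08, 0.20, 0.25, 0.20, 0.07, 0.07, 0.12, 0.55),
    dormant_leaf = c(0.06, 0.08, 0.10, 0.11, 0.11, 0.16, 0.16, 0.22, 0.45),
    background   = c(0.15, 0.16, 0.17, 0.18, 0.18, 0.21, 0.22, 0.20, 0.10))
  spectral_profile(means, label = label)
}

#' Convex mixture of the green and dormant leaf profiles
#'
#' `weight = 1` is fully green, `weight = 0` fully dormant; intermediate
#' weights model partially broken dormancy.
#'
#' @param weight Green mixture weight in `[0, 1]`.
#' @param nir_gain Multiplier applied to the 800 nm mean (capped at 1),
#'   modelling leaf-structure differences in NIR reflectance.
#' @param sds Noise SDs, as in [spectral_profile()].
#' @return A `spectral_profile` labelled by the dominant component.
#' @export
mix_leaf_profile <- function(weight, nir_gain = 1, sds = 0.02) {
  weight <- min(max(weight, 0), 1)
  gm <- default_profile("green_leaf")$means
  dm <- default_profile("dormant_leaf")$means
  means <- weight * gm + (1 - weight) * dm
  means[["800"]] <- min(1, means[["800"]] * nir_gain)
  spectral_profile(means, sds = sds,
                   label = if (weight >= 0.5) "green_leaf" else "dormant_leaf")
}

#' Rasterize plant geometry into a logical mask
#'
#' Pixel centres sit at half-integer offsets from the image centre; a pixel
#' is inside a disk iff its centre satisfies the strict inequality
#' `x^2 + y^2 < r^2`. A blob is the union of `lobes` jittered disks around
#' the centre. The fixed rasterization rule makes area oracles exact.
#'
#' @param shape `c(H, W)`.
#' @param geometry List with `type` (`"disk"` or `"blob"`), `radius`, and for
#'   blobs `lobes` (default 4) and `jitter` (centre offset SD, default
#'   `radius / 2`; drawn from the current RNG stream).
#' @return Logical `H x W` matrix.
#' @export
rasterize_geometry <- function(shape, geometry) {
  H <- shape[1]; W <- shape[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H) - cy, H, W)
  xx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  type <- geometry$type %||% "disk"
  r <- geometry$radius
  if (type == "disk") return(xx^2 + yy^2 < r^2)
  if (type != "blob") stop("unknown geometry type: ", type)
  lobes <- geometry$lobes %||% 4L
  jit <- geometry$jitter %||% (r / 2)
  mask <- matrix(FALSE, H, W)
  for (k in seq_len(lobes)) {
    ox <- stats::rnorm(1, 0, jit); oy <- stats::rnorm(1, 0, jit)
    rk <- r * stats::runif(1, 0.5, 0.9)
    mask <- mask | ((xx - ox)^2 + (yy - oy)^2 < rk^2)
  }
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic multispectral scene with ground truth
#'
#' Draws plant pixels from a plant [spectral_profile()] and background pixels
#' from a background profile, adds per-band Gaussian noise, truncates to
#' `[0, 1]`, and records the generating mask. With `noise_sd = 0` the
#' rule-based segmentation of the scene equals the ground-truth mask by
#' construction. The generator is a pure function of `seed` and its
#' parameters.
#'
#' @param shape `c(H, W)` (default 64 x 64).
#' @param geometry Plant geometry, see [rasterize_geometry()] (default a
#'   disk of radius 16).
#' @param profile Plant profile (default [default_profile]`("green_leaf")`).
#' @param background_profile Background profile.
#' @param noise_sd Scalar noise SD overriding the profiles' own (use 0 for
#'   noise-free scenes); `NULL` keeps the per-profile SDs.
#' @param seed Integer seed.
#' @param plant_id,capture_date Metadata for the embedded image.
#' @return An object of class `synthetic_scene`: `image` (a
#'   [spectral_image()]), `truth_mask`, `profile`, `background_profile`,
#'   `seed`.
#' @export
generate_scene <- function(shape = c(64, 64),
                           geometry = list(type = "disk", radius = 16),
                           profile = default_profile("green_leaf"),
                           background_profile = default_profile("background"),
                           noise_sd = NULL, seed = 1L,
                           plant_id = "synthetic", capture_date = NA) {
  stopifnot(inherits(profile, "spectral_profile"),
            inherits(background_profile, "spectral_profile"))
  if (background_profile$label != "background")
    stop("background_profile must be labelled 'background'")
  if (profile$label == "background")
    stop("profile must be a plant profile")
  set.seed(seed)
  if (geometry$radius >= min(shape) / 2)
    stop("geometry does not fit in the scene")
  mask <- rasterize_geometry(shape, geometry)
  wl <- SPECQTL_WAVELENGTHS
  pix <- array(0, dim = c(shape[1], shape[2], length(wl)))
  for (b in seq_along(wl)) {
    sd_fg <- if (is.null(noise_sd)) profile$sds[b] else noise_sd
    sd_bg <- if (is.null(noise_sd)) background_profile$sds[b] else noise_sd
    plane <- matrix(background_profile$means[b], shape[1], shape[2])
    plane[mask] <- profile$means[b]
    if (sd_fg > 0 || sd_bg > 0) {
      noise <- matrix(stats::rnorm(length(plane)), shape[1], shape[2])
      plane <- plane + noise * ifelse(mask, sd_fg, sd_bg)
    }
    pix[, , b] <- pmin(pmax(plane, 0), 1)
  }
  img <- spectral_image(pix, band_set(), plant_id, capture_date)
  structure(list(image = img, truth_mask = mask, profile = profile,
                 background_profile = background_profile, seed = seed),
            class = "synthetic_scene")
}
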