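#' Default nine-band wavelength set
#'
#' The multispectral camera records nine narrow (10 nm bandwidth) bands
#' spanning blue to near-infrared. All phenotyping functions assume this band
#' set unless told otherwise.
#'
#' @format Integer vector of nine wavelengths in nanometres.
#' @export
SPECQTL_WAVELENGTHS <- c(445L, 500L, 532L, 550L, 568L, 676L, 680L, 700L, 800L)

#' Names of the fifteen vegetation indices
#'
#' @format Character vector in the canonical reporting order: biomass
#'   (NDVI, SR, EVI, VARI, ViGreen), pigments (SIPI, PSND), chlorophyll
#'   (CARI, MCARI), anthocyanins (ARI, RGRI, ACI), carotenoids (CRI1, CRI2),
#'   light-use efficiency (PRI).
#' @export
VEGETATION_INDICES <- c("NDVI", "SR", "EVI", "VARI", "ViGreen", "SIPI",
                        "PSND", "CARI", "MCARI", "ARI", "RGRI", "ACI",
                        "CRI1", "CRI2", "PRI")

#' Canonical trait order for the 27-trait phenotype table
#'
#' Cover area, the nine standardized band proportions, the first two
#' principal components of the standardized spectra, and the fifteen
#' vegetation indices.
#'
#' @format Character vector of 27 trait names.
#' @export
TRAIT_NAMES <- c("area", paste0("p", SPECQTL_WAVELENGTHS), "PC1", "PC2",
                 VEGETATION_INDICES)
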