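# Shared fixtures and independent oracles.

# fixture standardized spectrum used for the index formula oracle
fixture_spectrum <- function() {
  p <- c(0.05, 0.06, 0.10, 0.12, 0.10, 0.07, 0.07, 0.09, 0.34)
  names(p) <- paste0("p", SPECQTL_WAVELENGTHS)
  p
}

# the 15 index values for fixture_spectrum(), derived by independent rational
# arithmetic from the printed formulas (exact fractions where they exist)
oracle_index_values <- c(
  NDVI    = 27 / 41,
  SR      = 34 / 7,
  EVI     = 0.675 / 1.31,
  VARI    = 5 / 13,
  ViGreen = 5 / 19,
  SIPI    = 29 / 27,
  PSND    = 29 / 39,
  CARI    = 0.026,
  MCARI   = 0.026 * 9 / 7,
  ARI     = 1 / 0.12 - 1 / 0.09,
  RGRI    = 7 / 12,
  ACI     = 6 / 17,
  CRI1    = 1 / 0.06 - 1 / 0.12,
  CRI2    = 1 / 0.06 - 1 / 0.09,
  PRI     = 0)

# brute-force disk pixel count under the package's stated rasterization rule
# (pixel centres at half-integer offsets from the image centre, strict <)
brute_force_disk_area <- function(shape, radius) {
  cy <- (shape[1] + 1) / 2
  cx <- (shape[2] + 1) / 2
  n <- 0L
  for (i in seq_len(shape[1]))
    for (j in seq_len(shape[2]))
      if ((i - cy)^2 + (j - cx)^2 < radius^2) n <- n + 1L
  n
}

# build a marker_genotypes object from an F1 character matrix and parent rows
make_genotypes <- function(f1, p1 = NULL, p2 = NULL) {
  M <- ncol(f1)
  if (is.null(p1)) p1 <- rep("H", M)
  if (is.null(p2)) p2 <- rep("A", M)
  parents <- rbind(P1 = p1, P2 = p2)
  colnames(parents) <- colnames(f1)
  marker_genotypes(parents, f1)
}

# exhaustive minimum-adjacent-rf marker order (independent of the package's
# search): enumerates every permutation
brute_force_order <- function(markers, rf) {
  k <- length(markers)
  perm_rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_rec(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perm_rec(seq_len(k))) {
    cost <- sum(rf[cbind(p[-k], p[-1])])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- p }
  }
  ord <- markers[best]
  if (ord[k] < ord[1]) rev(ord) else ord
}
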