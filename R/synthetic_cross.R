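#' Simulate an F1 pseudo-testcross population
#'
#' For each parent, simulates `groups_per_parent` linkage groups of
#' `markers_per_group` markers spaced `spacing_cM` apart. Along each group
#' and individual, the transmitted parental haplotype follows a two-state
#' Markov chain whose adjacent transition probability is the inverse map
#' function of the spacing, so every marker segregates 1:1 A:H in
#' expectation and the genotypes are consistent with the map. Markers of one
#' parent's map segregate only through that parent (the other parent is
#' homozygous there). With `phase = "random"` each marker's A/H coding is
#' flipped with probability 1/2, producing the mixed coupling/repulsion
#' phases of real outbred data; `"coupling"` leaves all markers on one
#' orientation.
#'
#' @param n_f1 F1 population size (default 94).
#' @param groups_per_parent Linkage groups per parent (default 2).
#' @param markers_per_group Markers per group (default 8).
#' @param spacing_cM Adjacent marker spacing (default 10).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param missing_rate Fraction of F1 genotype calls masked to `-`.
#' @param phase `"coupling"` or `"random"`.
#' @param seed Integer seed.
#' @return An object of class `simulated_cross`: `genotypes` (a
#'   [marker_genotypes()]), `true_map` (data frame `parent`, `group`,
#'   `marker`, `pos_cM`, `flipped`), `states` (latent 0/1 haplotype states,
#'   individuals x markers), `map_function`, `seed`.
#' @export
simulate_pseudo_testcross <- function(n_f1 = 94, groups_per_parent = 2,
                                      markers_per_group = 8, spacing_cM = 10,
                                      map_function = c("haldane", "kosambi"),
                                      missing_rate = 0,
                                      phase = c("coupling", "random"),
                                      seed = 1L) {
  map_function <- match.arg(map_function)
  phase <- match.arg(phase)
  if (spacing_cM <= 0) stop("spacing must be positive")
  set.seed(seed)
  r <- distance_to_rf(spacing_cM, map_function)
  ids <- sprintf("F1_%03d", seq_len(n_f1))
  map_rows <- list(); state_cols <- list(); flip_all <- logical(0)
  for (parent in c("P1", "P2")) {
    for (grp in seq_len(groups_per_parent)) {
      mk <- sprintf("%s_G%d_M%02d", parent, grp, seq_len(markers_per_group))
      s <- matrix(0L, n_f1, markers_per_group, dimnames = list(ids, mk))
      s[, 1] <- stats::rbinom(n_f1, 1, 0.5)
      for (j in seq_len(markers_per_group - 1L)) {
        rec <- stats::rbinom(n_f1, 1, r)
        s[, j + 1L] <- ifelse(rec == 1L, 1L - s[, j], s[, j])
      }
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        parent = parent, group = paste0(grp, ".", parent), marker = mk,
        pos_cM = spacing_cM * (seq_len(markers_per_group) - 1L))
      state_cols[[length(state_cols) + 1L]] <- s
    }
  }
  true_map <- do.call(rbind, c(map_rows, make.row.names = FALSE))
  states <- do.call(cbind, state_cols)
  # flips drawn after the states so the latent genetics is identical across
  # phase regimes under one seed
  flip_all <- if (phase == "random")
    stats::rbinom(ncol(states), 1, 0.5) == 1L else rep(FALSE, ncol(states))
  true_map$flipped <- flip_all
  # observed genotype: latent state, phase-flipped where flagged
  coded <- sweep(states, 2, as.integer(flip_all), function(s, f) abs(s - f))
  f1 <- matrix(ifelse(coded == 1L, "H", "A"), nrow = n_f1,
               dimnames = dimnames(states))
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(f1)) < missing_rate, nrow = n_f1)
    f1[drop] <- "-"
  }
  parents <- matrix("A", 2, ncol(states),
                    dimnames = list(c("P1", "P2"), colnames(states)))
  parents[1, true_map$parent == "P1"] <- "H"
  parents[2, true_map$parent == "P2"] <- "H"
  structure(list(genotypes = marker_genotypes(parents, f1),
                 true_map = true_map, states = states,
                 map_function = map_function, seed = seed),
            class = "simulated_cross")
}

nearest_marker <- function(cross, parent, group_index, pos_cM) {
  grp <- paste0(group_index, ".", parent)
  tm <- cross$true_map[cross$true_map$group == grp, , drop = FALSE]
  if (nrow(tm) == 0L) stop("QTL position not on a simulated group: ", grp)
  tm$marker[which.min(abs(tm$pos_cM - pos_cM))]
}

#' Plant additive QTL effects on a simulated cross
#'
#' Builds a quantitative trait `y = sum(effect * I(state at the nearest
#' marker = H)) + e`. Effects act through the nearest marker's latent state
#' (exactly recoverable by a marker scan); noise is Gaussian, scaled either
#' by an explicit `noise_sd` or to a requested narrow-sense heritability
#' `h2 = var(g) / (var(g) + noise_sd^2)`.
#'
#' @param cross A [simulate_pseudo_testcross()] result.
#' @param qtls List of QTLs, each `list(parent, group, pos_cM, effect)` with
#'   `effect` in trait-SD-like units.
#' @param h2 Target heritability in `(0, 1]` (mutually exclusive with
#'   `noise_sd`).
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return Named numeric trait vector with attributes `genetic_values` and
#'   `qtl_markers` (the nearest marker per planted QTL).
#' @export
plant_qtl_effects <- function(cross, qtls, h2 = NULL, noise_sd = NULL,
                              seed = 1L) {
  stopifnot(inherits(cross, "simulated_cross"))
  if (is.null(h2) == is.null(noise_sd))
    stop("give exactly one of h2 or noise_sd")
  if (!is.null(h2) && (h2 <= 0 || h2 > 1)) stop("h2 must lie in (0, 1]")
  set.seed(seed)
  n <- nrow(cross$states)
  gval <- numeric(n)
  mks <- character(0)
  for (q in qtls) {
    mk <- nearest_marker(cross, q$parent, q$group, q$pos_cM)
    mks <- c(mks, mk)
    gval <- gval + q$effect * (cross$states[, mk] == 1L)
  }
  if (is.null(noise_sd)) {
    vg <- stats::var(gval)
    noise_sd <- if (h2 == 1) 0 else sqrt(vg * (1 - h2) / h2)
  }
  y <- gval + stats::rnorm(n, 0, noise_sd)
  names(y) <- rownames(cross$states)
  attr(y, "genetic_values") <- gval
  attr(y, "qtl_markers") <- mks
  y
}

#' Render one multispectral scene per F1 individual
#'
#' Gives every simulated F1 a scene whose foreground spectrum and plant size
#' depend on its genotypes at two planted QTLs, enabling full
#' image-to-QTL end-to-end runs:
#'
#' * the *color* QTL sets the green-versus-dormant leaf mixture weight
#'   (heterozygotes greener) and the disk radius (greener plants have broken
#'   dormancy and grown larger), so green-band traits (VARI, ViGreen, RGRI,
#'   PC1) and cover area respond to it;
#' * the *NIR* QTL multiplies the 800 nm reflectance, so NIR-based traits
#'   (NDVI, SR, EVI, p800) respond to it.
#'
#' Plant-level Gaussian variation of the mixture weight, NIR gain and radius
#' models non-genetic individual differences; pixel-level noise comes on top.
#'
#' @param cross A [simulate_pseudo_testcross()] result.
#' @param color_qtl,nir_qtl Lists `list(parent, group, pos_cM)` locating the
#'   two QTLs on the simulated map.
#' @param green_weight Named vector `c(A = , H = )` of mixture weights by
#'   color-QTL genotype (default A 0.30, H 0.70).
#' @param weight_sd Plant-level SD of the mixture weight (default 0.10).
#' @param radius Named vector `c(A = , H = )` of disk radii in px by
#'   color-QTL genotype (default A 10, H 13).
#' @param radius_sd Plant-level radius SD in px (default 1).
#' @param nir_gain Named vector `c(A = , H = )` of 800 nm multipliers by
#'   NIR-QTL genotype (default A 0.90, H 1.15).
#' @param nir_gain_sd Plant-level SD of the NIR gain (default 0.05).
#' @param shape Scene shape (default 64 x 64).
#' @param noise_sd Pixel noise SD (default 0.02).
#' @param capture_date Metadata for the scenes.
#' @param seed Integer seed.
#' @return List of [generate_scene()] scenes, one per F1, named by plant id,
#'   with attribute `qtl_markers` (nearest markers of the color and NIR
#'   QTLs).
#' @export
render_population_images <- function(cross,
                                     color_qtl = list(parent = "P2", group = 1,
                                                      pos_cM = 30),
                                     nir_qtl = list(parent = "P1", group = 1,
                                                    pos_cM = 30),
                                     green_weight = c(A = 0.30, H = 0.70),
                                     weight_sd = 0.10,
                                     radius = c(A = 10, H = 13),
                                     radius_sd = 1,
                                     nir_gain = c(A = 0.90, H = 1.15),
                                     nir_gain_sd = 0.05,
                                     shape = c(64, 64), noise_sd = 0.02,
                                     capture_date = NA, seed = 1L) {
  stopifnot(inherits(cross, "simulated_cross"))
  set.seed(seed)
  mk_color <- nearest_marker(cross, color_qtl$parent, color_qtl$group,
                             color_qtl$pos_cM)
  mk_nir <- nearest_marker(cross, nir_qtl$parent, nir_qtl$group,
                           nir_qtl$pos_cM)
  ids <- rownames(cross$states)
  g_color <- ifelse(cross$states[, mk_color] == 1L, "H", "A")
  g_nir <- ifelse(cross$states[, mk_nir] == 1L, "H", "A")
  n <- length(ids)
  w <- green_weight[g_color] + stats::rnorm(n, 0, weight_sd)
  rad <- pmax(3, radius[g_color] + stats::rnorm(n, 0, radius_sd))
  gain <- pmax(0.5, nir_gain[g_nir] + stats::rnorm(n, 0, nir_gain_sd))
  scene_seeds <- sample.int(.Machine$integer.max - 1L, n)
  scenes <- vector("list", n)
  names(scenes) <- ids
  for (i in seq_len(n)) {
    prof <- mix_leaf_profile(w[i], nir_gain = gain[i])
    scenes[[i]] <- generate_scene(
      shape = shape, geometry = list(type = "disk", radius = rad[i]),
      profile = prof, noise_sd = noise_sd, seed = scene_seeds[i],
      plant_id = ids[i], capture_date = capture_date)
  }
  attr(scenes, "qtl_markers") <- c(color = mk_color, nir = mk_nir)
  scenes
}
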