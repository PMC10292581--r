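#' Phenotype a set of multispectral scenes or images
#'
#' For each image: segment plant pixels with the NIR > red rule, count cover
#' area, take per-band medians over the mask, standardize to sum-to-one
#' proportions, and compute the fifteen vegetation indices. A covariance PCA
#' of the standardized spectra of all successfully phenotyped plants then
#' adds PC1 and PC2 scores, giving the 27-trait phenotype table (cover area,
#' nine band proportions, PC1, PC2, fifteen indices). Per-plant failures
#' (e.g. an empty mask) are logged and skipped, not fatal; zero successes is
#' an error.
#'
#' @param images A list of [spectral_image()] objects or
#'   [generate_scene()] scenes (their `$image` is used).
#' @return A data frame with `plant_id`, `date` and the 27 trait columns in
#'   [TRAIT_NAMES] order; attributes `log` (character vector, one entry per
#'   plant) and `pca` (the [run_pca()] fit).
#' @export
run_phenotyping <- function(images) {
  imgs <- lapply(images, function(x)
    if (inherits(x, "synthetic_scene")) x$image else x)
  log <- character(0)
  rows <- list()
  for (img in imgs) {
    stopifnot(inherits(img, "spectral_image"))
    res <- tryCatch({
      mask <- segment_plant(img)
      spec <- standardize_spectrum(median_spectrum(img, mask))
      idx <- compute_vegetation_indices(spec)
      row <- data.frame(plant_id = img$plant_id, date = img$capture_date,
                        area = cover_area(mask))
      row[names(spec$p)] <- as.list(spec$p)
      row[names(idx$values)] <- as.list(idx$values)
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log <- c(log, paste0("SKIP ", img$plant_id, ": ",
                           conditionMessage(res)))
    } else {
      log <- c(log, paste0("OK ", img$plant_id))
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("zero successfully phenotyped plants")
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  pca <- run_pca(tab[, paste0("p", SPECQTL_WAVELENGTHS)])
  tab$PC1 <- pca$scores[, 1]
  tab$PC2 <- if (ncol(pca$scores) >= 2) pca$scores[, 2] else 0
  tab <- tab[, c("plant_id", "date", TRAIT_NAMES)]
  attr(tab, "log") <- log
  attr(tab, "pca") <- pca
  tab
}

#' QTL analysis of a phenotype table
#'
#' Builds the parent-specific pseudo-testcross maps (unless one is given),
#' computes genotype probabilities on the pseudomarker grid, and for each
#' trait runs the scan (`"hk"` or `"cim"`), trait-specific permutation
#' thresholds, and QTL calls. When at least two QTLs are significant at the
#' strict level, the two top QTLs (highest peak LOD on distinct groups)
#' define the four two-letter genotype classes via their nearest markers,
#' and the top trait of each QTL is compared across the classes by one-way
#' ANOVA with Tukey letters.
#'
#' @param phenotypes Phenotype table from [run_phenotyping()] (plants are
#'   matched to genotype ids by `plant_id`).
#' @param genotypes A [marker_genotypes()] object.
#' @param traits Trait columns to scan (default all 27).
#' @param map Optional pre-built [build_maps()] result.
#' @param method `"hk"` or `"cim"`.
#' @param step_cM Grid step (default 2).
#' @param window_cM CIM exclusion window (default 30).
#' @param n_cofactors CIM cofactors (default 3).
#' @param n_perm Permutations per trait (default 1000).
#' @param alphas Significance levels (default 5% and 10%).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param seed Integer seed driving all permutation draws.
#' @return An object of class `qtl_run`: `map`, `scans` (per trait),
#'   `thresholds` (per trait), `qtls` (data frame with `trait`), `peak_lod`
#'   (trait x group matrix), `classes`, `anova` (per compared trait), `log`.
#' @export
run_qtl <- function(phenotypes, genotypes, traits = TRAIT_NAMES, map = NULL,
                    method = c("hk", "cim"), step_cM = 2, window_cM = 30,
                    n_cofactors = 3, n_perm = 1000, alphas = c(0.05, 0.10),
                    map_function = c("haldane", "kosambi"), seed = 1L) {
  method <- match.arg(method)
  map_function <- match.arg(map_function)
  stopifnot(inherits(genotypes, "marker_genotypes"))
  if (is.null(map)) map <- build_maps(genotypes, map_function = map_function)
  probs <- genotype_probabilities(map, genotypes, step_cM = step_cM)
  ids <- probs$individuals
  ph <- as.data.frame(phenotypes)
  at <- match(ids, ph$plant_id)
  log <- character(0)
  scans <- list(); thresholds <- list(); qtl_rows <- list()
  groups <- unique(map$table$group)
  peak_lod <- matrix(0, length(traits), length(groups),
                     dimnames = list(traits, groups))
  trait_seeds <- seed + seq_along(traits)
  for (k in seq_along(traits)) {
    tr <- traits[k]
    y <- ph[[tr]][at]
    sc <- tryCatch({
      if (method == "hk") hk_scan(probs, y, trait = tr)
      else cim_scan(probs, y, window_cM = window_cM,
                    n_cofactors = n_cofactors, trait = tr)
    }, error = function(e) e)
    if (inherits(sc, "error")) {
      log <- c(log, paste0("SKIP trait ", tr, ": ", conditionMessage(sc)))
      next
    }
    thr <- permutation_thresholds(probs, y, n_perm = n_perm, alphas = alphas,
                                  seed = trait_seeds[k], method = method,
                                  window_cM = window_cM,
                                  n_cofactors = n_cofactors)
    hits <- significant_qtls(sc, thr)
    scans[[tr]] <- sc
    thresholds[[tr]] <- thr
    pk <- tapply(sc$lod, sc$group, max)
    peak_lod[tr, names(pk)] <- pk
    log <- c(log, paste0("OK trait ", tr, ": ", nrow(hits), " QTL(s)"))
    if (nrow(hits))
      qtl_rows[[tr]] <- data.frame(trait = tr, hits)
  }
  qtls <- if (length(qtl_rows))
    do.call(rbind, c(qtl_rows, make.row.names = FALSE))
  else data.frame(trait = character(0), group = character(0),
                  pos = numeric(0), lod = numeric(0), level = character(0))
  classes <- NULL; anova_out <- list()
  strict_lvl <- sprintf("%g%%", 100 * min(alphas))
  strict <- qtls[qtls$level == strict_lvl, , drop = FALSE]
  if (nrow(strict) && length(unique(strict$group)) >= 2L) {
    # top two QTL groups by peak LOD, each with its best trait
    byg <- split(strict, strict$group)
    best <- do.call(rbind, lapply(byg, function(d) d[which.max(d$lod), ]))
    best <- best[order(-best$lod), ][1:2, ]
    near <- vapply(1:2, function(i) {
      gt <- map$table[map$table$group == best$group[i], ]
      gt$marker[which.min(abs(gt$pos_cM - best$pos[i]))]
    }, "")
    classes <- classify_by_qtl_markers(genotypes, near[1], near[2])
    for (i in 1:2) {
      tr <- best$trait[i]
      y <- ph[[tr]][at]
      names(y) <- ids
      anova_out[[tr]] <- compare_groups_anova(classes, y)
    }
    log <- c(log, paste0("ANOVA on classes from ", near[1], " x ", near[2]))
  }
  structure(list(map = map, scans = scans, thresholds = thresholds,
                 qtls = qtls, peak_lod = peak_lod, classes = classes,
                 anova = anova_out, method = method, seed = seed, log = log),
            class = "qtl_run")
}

#' @export
print.qtl_run <- function(x, ...) {
  cat("<qtl_run> ", length(x$scans), " traits scanned; ",
      nrow(x$qtls), " QTL call(s)\n", sep = "")
  invisible(x)
}

#' One configured end-to-end synthetic study
#'
#' Simulates an F1 pseudo-testcross with a color QTL and a NIR QTL, renders
#' one multispectral scene per individual, phenotypes the scenes into the
#' 27-trait table, and runs the QTL analysis. All randomness derives from
#' `seed`, so a rerun with the same configuration is reproducible.
#'
#' @param n_f1 Population size (default 94).
#' @param groups_per_parent,markers_per_group,spacing_cM Map geometry
#'   (defaults 2 groups/parent, 8 markers/group, 10 cM).
#' @param traits Traits to scan (default all 27).
#' @param n_perm Permutations per trait (default 1000).
#' @param method `"hk"` or `"cim"`.
#' @param step_cM,window_cM,n_cofactors,alphas Scan settings (defaults 2 cM,
#'   30 cM, 3, 5%/10%).
#' @param map_function `"haldane"` or `"kosambi"`.
#' @param phase Marker phase regime for the simulated genotypes.
#' @param seed Integer seed.
#' @param ... Passed to [render_population_images()].
#' @return List with `cross`, `scenes`, `phenotypes`, `qtl` (a `qtl_run`),
#'   and `truth` (nearest markers of the planted QTLs).
#' @export
run_pipeline <- function(n_f1 = 94, groups_per_parent = 2,
                         markers_per_group = 8, spacing_cM = 10,
                         traits = TRAIT_NAMES, n_perm = 1000,
                         method = c("hk", "cim"), step_cM = 2,
                         window_cM = 30, n_cofactors = 3,
                         alphas = c(0.05, 0.10),
                         map_function = c("haldane", "kosambi"),
                         phase = c("coupling", "random"), seed = 1L, ...) {
  method <- match.arg(method)
  map_function <- match.arg(map_function)
  phase <- match.arg(phase)
  cross <- simulate_pseudo_testcross(
    n_f1 = n_f1, groups_per_parent = groups_per_parent,
    markers_per_group = markers_per_group, spacing_cM = spacing_cM,
    map_function = map_function, phase = phase, seed = seed)
  mid <- spacing_cM * (markers_per_group - 1) / 2
  scenes <- render_population_images(
    cross, color_qtl = list(parent = "P2", group = 1, pos_cM = mid),
    nir_qtl = list(parent = "P1", group = 1, pos_cM = mid),
    seed = seed + 1L, ...)
  phenotypes <- run_phenotyping(scenes)
  qtl <- run_qtl(phenotypes, cross$genotypes, traits = traits,
                 method = method, step_cM = step_cM, window_cM = window_cM,
                 n_cofactors = n_cofactors, n_perm = n_perm, alphas = alphas,
                 map_function = map_function, seed = seed + 2L)
  list(cross = cross, scenes = scenes, phenotypes = phenotypes, qtl = qtl,
       truth = attr(scenes, "qtl_markers"))
}
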