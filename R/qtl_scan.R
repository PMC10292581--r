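#' Conditional genotype probabilities on a pseudomarker grid
#'
#' For each linkage group, lays a grid of positions every `step_cM`
#' centimorgans (marker positions are always included) and computes, for each
#' individual and grid position, the probability of the heterozygous state
#' given all observed markers on the group. The testcross has two genotype
#' states, modelled as a two-state Markov chain along the chromosome whose
#' transition probability over `d` cM is the inverse map function of `d`;
#' conditioning on the observed flanking markers is done by the
#' forward-backward algorithm with genotyping-error rate 0. Markers mapped in
#' repulsion phase are flipped to the group's reference orientation first.
#'
#' @param map A [build_maps()] result.
#' @param g The [marker_genotypes()] the map was built from.
#' @param step_cM Grid step in cM (default 2).
#' @return An object of class `genotype_probs`: per group a list with `pos`,
#'   `is_marker`, `marker` (name or `NA`), `probs` (individuals x positions,
#'   `P(H)` in the reference orientation) and `marker_obs` (individuals x
#'   markers, observed 0/1 states after phase alignment, `NA` = missing).
#'   Individuals untyped on an entire group get probability 0.5 everywhere
#'   (with a warning).
#' @export
genotype_probabilities <- function(map, g, step_cM = 2) {
  stopifnot(inherits(map, "genetic_map"), inherits(g, "marker_genotypes"))
  mf <- map$map_function
  ids <- rownames(g$f1)
  n <- length(ids)
  groups <- list()
  warned_untyped <- 0L
  for (grp in unique(map$table$group)) {
    gt <- map$table[map$table$group == grp, , drop = FALSE]
    gt <- gt[order(gt$pos_cM), , drop = FALSE]
    missing_mk <- setdiff(gt$marker, g$marker_names)
    if (length(missing_mk))
      stop("map marker(s) not in genotypes: ", paste(missing_mk, collapse = ", "))
    obs <- vapply(seq_len(nrow(gt)), function(j) {
      s <- geno_numeric(g$f1[, gt$marker[j]])
      if (gt$flipped[j]) 1 - s else s
    }, numeric(n))
    obs <- matrix(obs, nrow = n,
                  dimnames = list(ids, gt$marker))
    L <- max(gt$pos_cM)
    grid <- unique(sort(round(c(seq(0, L, by = step_cM), L, gt$pos_cM), 8)))
    mk_at <- match(round(gt$pos_cM, 8), grid)
    is_marker <- seq_along(grid) %in% mk_at
    marker_at <- rep(NA_character_, length(grid))
    marker_at[mk_at] <- gt$marker
    P <- length(grid)
    # emissions: N x 2 per position; c(1,1) at pseudomarkers / missing calls
    emis <- function(t) {
      e <- matrix(1, n, 2)
      if (is_marker[t]) {
        o <- obs[, marker_at[t]]
        e[which(o == 0), 2] <- 0
        e[which(o == 1), 1] <- 0
      }
      e
    }
    r <- distance_to_rf(diff(grid), mf)
    fwd <- vector("list", P)
    a <- matrix(0.5, n, 2) * emis(1)
    fwd[[1]] <- a / pmax(rowSums(a), .Machine$double.xmin)
    for (t in seq_len(P - 1L)) {
      rp <- r[t]
      prev <- fwd[[t]]
      trans <- cbind(prev[, 1] * (1 - rp) + prev[, 2] * rp,
                     prev[, 1] * rp + prev[, 2] * (1 - rp))
      a <- trans * emis(t + 1L)
      fwd[[t + 1L]] <- a / pmax(rowSums(a), .Machine$double.xmin)
    }
    bwd <- matrix(1, n, 2)
    post <- matrix(0, n, P, dimnames = list(ids, NULL))
    for (t in rev(seq_len(P))) {
      u <- fwd[[t]] * bwd
      post[, t] <- u[, 2] / pmax(rowSums(u), .Machine$double.xmin)
      if (t > 1L) {
        rp <- r[t - 1L]
        eb <- emis(t) * bwd
        bwd <- cbind(eb[, 1] * (1 - rp) + eb[, 2] * rp,
                     eb[, 1] * rp + eb[, 2] * (1 - rp))
        bwd <- bwd / pmax(rowSums(bwd), .Machine$double.xmin)
      }
    }
    untyped <- rowSums(!is.na(obs)) == 0L
    if (any(untyped)) {
      post[untyped, ] <- 0.5
      warned_untyped <- warned_untyped + sum(untyped)
    }
    groups[[grp]] <- list(group = grp, parent = gt$parent[1], pos = grid,
                          is_marker = is_marker, marker = marker_at,
                          probs = post, marker_obs = obs)
  }
  if (warned_untyped > 0L)
    warning(warned_untyped,
            " individual-by-group combination(s) fully untyped; ",
            "probabilities set to 0.5")
  structure(list(groups = groups, map_function = mf, individuals = ids,
                 step_cM = step_cM),
            class = "genotype_probs")
}

# residualize columns of M on [1, C]; C may be NULL
residualize <- function(M, C, n) {
  Z <- if (is.null(C)) matrix(1, n, 1) else cbind(1, C)
  qz <- qr(Z)
  qr.resid(qz, M)
}

scan_one <- function(res_P, res_y, n, yscale = NULL) {
  rss0 <- sum(res_y^2)
  sxx <- colSums(res_P^2)
  sxy <- colSums(res_P * res_y)
  lod <- numeric(length(sxx))
  if (is.null(yscale)) yscale <- 1
  # a phenotype absorbed entirely by the null model scans flat at 0
  if (rss0 <= 1e-20 * (yscale + 1e-300)) return(lod)
  sing <- sxx <= 1e-12
  if (any(sing))
    warning("singular design at ", sum(sing),
            " position(s); LOD set to 0", call. = FALSE)
  ok <- !sing
  rss1 <- rss0 - sxy[ok]^2 / sxx[ok]
  rss1 <- pmax(rss1, rss0 * 1e-12)
  lod[ok] <- (n / 2) * log10(rss0 / rss1)
  lod
}

#' Haley-Knott regression QTL scan
#'
#' At every grid position, regresses the phenotype on the conditional
#' probability of the heterozygous genotype (plus any covariates, which are
#' kept in both models) and reports
#' `LOD = (n/2) log10(RSS0 / RSS1)`, the null model being the same
#' regression without the genotype probability. Individuals with missing
#' phenotype are dropped (complete-case).
#'
#' @param probs A [genotype_probabilities()] result.
#' @param y Phenotype vector aligned with `probs$individuals` (`NA` allowed).
#' @param covariates Optional numeric matrix of covariates (same alignment).
#' @param min_n Minimum phenotyped individuals (default 20).
#' @param trait Trait name carried into the result.
#' @return An object of class `scan_result`: data frame with `group`,
#'   `parent`, `pos`, `lod` plus attributes `trait` and `n`.
#' @export
hk_scan <- function(probs, y, covariates = NULL, min_n = 20L,
                    trait = "trait") {
  stopifnot(inherits(probs, "genotype_probs"))
  N <- length(probs$individuals)
  if (length(y) != N) stop("y must align with probs individuals")
  keep <- is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & apply(is.finite(covariates), 1, all)
  }
  n <- sum(keep)
  if (n < min_n) stop("fewer than ", min_n, " phenotyped individuals")
  C <- if (is.null(covariates)) NULL
       else covariates[keep, , drop = FALSE]
  res_y <- residualize(matrix(y[keep], ncol = 1), C, n)[, 1]
  yscale <- sum(y[keep]^2)
  out <- lapply(probs$groups, function(gr) {
    res_P <- residualize(gr$probs[keep, , drop = FALSE], C, n)
    data.frame(group = gr$group, parent = gr$parent, pos = gr$pos,
               lod = scan_one(res_P, res_y, n, yscale))
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "trait") <- trait
  attr(res, "n") <- n
  class(res) <- c("scan_result", "data.frame")
  res
}

# probability columns at marker positions, one per mapped marker
marker_prob_columns <- function(probs) {
  cols <- list(); meta <- list()
  for (gr in probs$groups) {
    at <- which(gr$is_marker)
    for (t in at) {
      mk <- gr$marker[t]
      cols[[mk]] <- gr$probs[, t]
      meta[[mk]] <- data.frame(marker = mk, group = gr$group, pos = gr$pos[t])
    }
  }
  list(X = do.call(cbind, cols),
       meta = do.call(rbind, c(meta, make.row.names = FALSE)))
}

select_cofactors <- function(probs, y, n_cofactors) {
  mp <- marker_prob_columns(probs)
  keep <- is.finite(y)
  obs <- do.call(cbind, lapply(probs$groups, function(gr) gr$marker_obs))
  obs <- obs[keep, colnames(mp$X), drop = FALSE]
  yk <- y[keep]
  chosen <- character(0)
  for (step in seq_len(min(n_cofactors, ncol(obs)))) {
    best <- NA_character_; best_r2 <- -Inf
    for (cand in setdiff(colnames(obs), chosen)) {
      Xc <- obs[, c(chosen, cand), drop = FALSE]
      cc <- stats::complete.cases(Xc) & is.finite(yk)
      if (sum(cc) < ncol(Xc) + 2L) next
      fit <- stats::lm.fit(cbind(1, Xc[cc, , drop = FALSE]), yk[cc])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((yk[cc] - mean(yk[cc]))^2)
      if (is.finite(r2) && r2 > best_r2) { best <- cand; best_r2 <- r2 }
    }
    if (is.na(best)) break
    chosen <- c(chosen, best)
  }
  mp$meta[match(chosen, mp$meta$marker), , drop = FALSE]
}

#' Composite interval mapping scan
#'
#' Haley-Knott interval mapping with marker cofactors: up to `n_cofactors`
#' markers are chosen by forward selection (largest model R-squared first,
#' complete-case on the observed genotypes), then at each scan position the
#' cofactors lying on the scanned group within `window_cM` cM of the position
#' are dropped and the remaining cofactors enter the regression as
#' covariates. Cofactor covariate values are the marker-position genotype
#' probabilities, which equal the observed 0/1 genotype where typed and its
#' conditional expectation where missing. With `n_cofactors = 0` the result
#' is identical to [hk_scan()].
#'
#' @inheritParams hk_scan
#' @param window_cM Exclusion window around the scan position (default 30).
#' @param n_cofactors Maximum marker cofactors (default 3).
#' @return A `scan_result` as in [hk_scan()], with attribute `cofactors`
#'   (data frame `marker`, `group`, `pos`).
#' @export
cim_scan <- function(probs, y, window_cM = 30, n_cofactors = 3,
                     min_n = 20L, trait = "trait") {
  stopifnot(inherits(probs, "genotype_probs"))
  if (n_cofactors == 0L) return(hk_scan(probs, y, min_n = min_n, trait = trait))
  cof <- select_cofactors(probs, y, n_cofactors)
  if (is.null(cof) || nrow(cof) == 0L)
    return(hk_scan(probs, y, min_n = min_n, trait = trait))
  mp <- marker_prob_columns(probs)
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < min_n) stop("fewer than ", min_n, " phenotyped individuals")
  Call <- mp$X[keep, cof$marker, drop = FALSE]
  yk <- y[keep]
  out <- lapply(probs$groups, function(gr) {
    drop_mat <- vapply(seq_len(nrow(cof)), function(ci) {
      cof$group[ci] == gr$group & abs(cof$pos[ci] - gr$pos) <= window_cM
    }, logical(length(gr$pos)))
    drop_mat <- matrix(drop_mat, nrow = length(gr$pos))
    sig <- apply(drop_mat, 1, function(z) paste(which(!z), collapse = ","))
    lod <- numeric(length(gr$pos))
    for (s in unique(sig)) {
      at <- which(sig == s)
      active <- as.integer(strsplit(s, ",")[[1]])
      C <- if (length(active)) Call[, active, drop = FALSE] else NULL
      res_y <- residualize(matrix(yk, ncol = 1), C, n)[, 1]
      res_P <- residualize(gr$probs[keep, at, drop = FALSE], C, n)
      lod[at] <- scan_one(res_P, res_y, n, sum(yk^2))
    }
    data.frame(group = gr$group, parent = gr$parent, pos = gr$pos, lod = lod)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "trait") <- trait
  attr(res, "n") <- n
  attr(res, "cofactors") <- cof
  class(res) <- c("scan_result", "data.frame")
  res
}

#' Genome-wide permutation significance thresholds
#'
#' Permutes the phenotype over individuals (genotypes fixed), reruns the full
#' scan for each permutation - for CIM including cofactor reselection - and
#' records the genome-wide maximum LOD. Thresholds are the empirical
#' `1 - alpha` quantiles (type 7) of that null sample. Cofactor-free scans
#' use a closed-form vectorized path that is numerically identical to
#' [hk_scan()].
#'
#' @inheritParams cim_scan
#' @param n_perm Number of permutations (default 1000; below 100 the upper
#'   tail is unstable and a warning is given).
#' @param alphas Significance levels (default 5% and 10%).
#' @param seed Random seed (required for reproducibility).
#' @param method `"hk"` or `"cim"`.
#' @return An object of class `permutation_thresholds`: `n_permutations`,
#'   `max_lods` (the null sample), `thresholds` (named by alpha),
#'   `threshold_5`/`threshold_10` when the default alphas are used, `seed`.
#' @export
permutation_thresholds <- function(probs, y, n_perm = 1000,
                                   alphas = c(0.05, 0.10), seed = NULL,
                                   method = c("hk", "cim"), window_cM = 30,
                                   n_cofactors = 3, min_n = 20L) {
  method <- match.arg(method)
  stopifnot(inherits(probs, "genotype_probs"))
  if (n_perm < 100) warning("fewer than 100 permutations: unstable tail")
  if (!is.null(seed)) set.seed(seed)
  keep <- is.finite(y)
  n <- sum(keep)
  if (n < min_n) stop("fewer than ", min_n, " phenotyped individuals")
  if (method == "hk") {
    P <- do.call(cbind, lapply(probs$groups,
                               function(gr) gr$probs[keep, , drop = FALSE]))
    Pc <- scale(P, center = TRUE, scale = FALSE)
    nrm <- sqrt(colSums(Pc^2))
    ok <- nrm > 1e-8
    Pn <- sweep(Pc[, ok, drop = FALSE], 2, nrm[ok], "/")
    yk <- y[keep]
    perm_idx <- replicate(n_perm, sample.int(n))
    Y <- matrix(yk[perm_idx], nrow = n)
    Yc <- scale(Y, center = TRUE, scale = FALSE)
    ynrm <- sqrt(colSums(Yc^2))
    r2 <- crossprod(Pn, sweep(Yc, 2, pmax(ynrm, 1e-300), "/"))^2
    r2 <- pmin(r2, 1 - 1e-12)
    max_lods <- apply(r2, 2, function(col) max(-(n / 2) * log10(1 - col)))
    max_lods[ynrm <= 1e-300] <- 0
  } else {
    yk <- y[keep]
    ywork <- y
    max_lods <- vapply(seq_len(n_perm), function(i) {
      ywork[keep] <- yk[sample.int(n)]
      sc <- suppressWarnings(
        cim_scan(probs, ywork, window_cM = window_cM,
                 n_cofactors = n_cofactors, min_n = min_n))
      max(sc$lod)
    }, numeric(1))
  }
  thr <- stats::quantile(max_lods, probs = 1 - alphas, type = 7, names = FALSE)
  names(thr) <- as.character(alphas)
  out <- list(n_permutations = n_perm, max_lods = max_lods, thresholds = thr,
              alphas = alphas, seed = seed, method = method)
  if (all(c(0.05, 0.10) %in% alphas)) {
    out$threshold_5 <- unname(thr[["0.05"]])
    out$threshold_10 <- unname(thr[["0.1"]])
  }
  structure(out, class = "permutation_thresholds")
}

#' @export
print.permutation_thresholds <- function(x, ...) {
  cat("<permutation_thresholds> ", x$n_permutations, " permutations; ",
      paste(sprintf("%g%%: %.3f", 100 * x$alphas, x$thresholds),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Call significant QTLs from a scan and its permutation thresholds
#'
#' Contiguous runs of positions above the marginal (largest-alpha) threshold
#' collapse to one peak each (the run's argmax); peaks that also clear the
#' strict (smallest-alpha) threshold are labelled at that level, the rest are
#' labelled marginal.
#'
#' @param scan A [hk_scan()]/[cim_scan()] result.
#' @param thr The matching [permutation_thresholds()].
#' @return Data frame with `group`, `pos`, `lod`, `level` (e.g. `"5%"`,
#'   `"10%"`); zero rows when nothing clears the marginal threshold.
#' @export
significant_qtls <- function(scan, thr) {
  stopifnot(inherits(scan, "scan_result"),
            inherits(thr, "permutation_thresholds"))
  a_strict <- min(thr$alphas); a_marg <- max(thr$alphas)
  t_strict <- thr$thresholds[[as.character(a_strict)]]
  t_marg <- thr$thresholds[[as.character(a_marg)]]
  out <- list()
  for (grp in unique(scan$group)) {
    s <- scan[scan$group == grp, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    above <- s$lod >= t_marg
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      seg <- s[starts[k]:ends[k], , drop = FALSE]
      peak <- seg[which.max(seg$lod), , drop = FALSE]
      lvl <- if (peak$lod >= t_strict) sprintf("%g%%", 100 * a_strict)
             else sprintf("%g%%", 100 * a_marg)
      out[[length(out) + 1L]] <- data.frame(
        group = grp, pos = peak$pos, lod = peak$lod, level = lvl)
    }
  }
  if (!length(out))
    return(data.frame(group = character(0), pos = numeric(0),
                      lod = numeric(0), level = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Two-QTL genotype classes from the nearest markers
#'
#' Each F1 individual gets a two-letter class from its genotypes at the
#' markers nearest the two QTLs: the first letter is the genotype at
#' `marker_q1`, the second at `marker_q2` (possible classes `AA`, `AH`,
#' `HA`, `HH`). Individuals missing either genotype are omitted with a
#' message.
#'
#' @param g A [marker_genotypes()] object.
#' @param marker_q1,marker_q2 Marker names.
#' @return Data frame with `plant_id` and `class`.
#' @export
classify_by_qtl_markers <- function(g, marker_q1, marker_q2) {
  stopifnot(inherits(g, "marker_genotypes"))
  for (mk in c(marker_q1, marker_q2))
    if (!mk %in% g$marker_names) stop("unknown marker name: ", mk)
  g1 <- g$f1[, marker_q1]; g2 <- g$f1[, marker_q2]
  ok <- g1 != "-" & g2 != "-"
  if (any(!ok))
    message(sum(!ok), " individual(s) omitted: missing genotype at a QTL marker")
  data.frame(plant_id = rownames(g$f1)[ok],
             class = paste0(g1[ok], g2[ok]))
}

# Piepho-style insert-and-absorb compact letter display from a significance
# matrix over groups ordered by decreasing mean
letter_display <- function(groups_desc, signif_pair) {
  k <- length(groups_desc)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      if (!signif_pair[groups_desc[i], groups_desc[j]]) next
      for (ci in seq_along(cols)) {
        if (cols[[ci]][i] && cols[[ci]][j]) {
          a <- cols[[ci]]; a[i] <- FALSE
          b <- cols[[ci]]; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(!cols[[ci]] | cols[[cj]]) &&
              !identical(cols[[ci]], cols[[cj]])) keep[ci] <- FALSE
        }
      }
      dup <- duplicated(vapply(cols, paste, "", collapse = ""))
      cols <- cols[keep & !dup]
    }
  }
  first <- vapply(cols, function(cl) which(cl)[1], integer(1))
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cl) cl[i], logical(1)))],
          collapse = "")
  }, "")
  names(letters_out) <- groups_desc
  letters_out
}

#' Compare a trait across QTL genotype classes by one-way ANOVA
#'
#' Omnibus one-way ANOVA of the trait across the genotype classes, followed
#' by Tukey HSD pairwise comparisons at `alpha` and a compact letter display
#' (classes sharing no letter differ significantly; the class with the
#' highest mean gets letter `a`). Classes with fewer than 2 members are
#' dropped with a warning.
#'
#' @param classes Character/factor vector of class labels aligned with `y`,
#'   or the data frame returned by [classify_by_qtl_markers()] together with
#'   a named `y`.
#' @param y Trait values.
#' @param alpha Post-hoc significance level (default 0.01).
#' @return List with `F`, `p`, `df`, `means` (sorted decreasing), `letters`,
#'   `tukey` (data frame of pairwise comparisons), `n`.
#' @export
compare_groups_anova <- function(classes, y, alpha = 0.01) {
  if (is.data.frame(classes)) {
    ids <- classes$plant_id
    y <- y[ids]
    classes <- classes$class
  }
  ok <- !is.na(classes) & is.finite(y)
  classes <- as.character(classes)[ok]; y <- y[ok]
  tabn <- table(classes)
  small <- names(tabn)[tabn < 2]
  if (length(small)) {
    warning("dropping class(es) with <2 members: ",
            paste(small, collapse = ", "))
    keep <- !classes %in% small
    classes <- classes[keep]; y <- y[keep]
  }
  if (length(unique(classes)) < 2L)
    stop("need at least 2 classes with at least 2 members")
  cls <- factor(classes)
  means <- sort(tapply(y, cls, mean), decreasing = TRUE)
  if (stats::var(y) == 0) {
    lts <- rep("a", length(means)); names(lts) <- names(means)
    return(list(F = 0, p = 1, df = c(length(means) - 1L,
                                     length(y) - length(means)),
                means = means, letters = lts,
                tukey = data.frame(), n = length(y)))
  }
  fit <- stats::aov(y ~ cls)
  an <- stats::anova(fit)
  Fv <- an$`F value`[1]; pv <- an$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cls
  pmat <- matrix(FALSE, nlevels(cls), nlevels(cls),
                 dimnames = list(levels(cls), levels(cls)))
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  for (i in seq_len(nrow(tk))) {
    pmat[pairs[i, 1], pairs[i, 2]] <- tk[i, "p adj"] <= alpha
    pmat[pairs[i, 2], pairs[i, 1]] <- tk[i, "p adj"] <= alpha
  }
  lts <- letter_display(names(means), pmat)
  list(F = Fv, p = pv, df = an$Df, means = means, letters = lts,
       tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL,
                          check.names = FALSE),
       n = length(y))
}
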