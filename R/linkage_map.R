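#' Classify markers for pseudo-testcross mapping
#'
#' In an F1 of two outbred (heterozygous) parents, a marker heterozygous in
#' one parent and homozygous in the other segregates 1:1 in the F1 and maps
#' on that parent's side only ("pseudo-testcross"). Markers heterozygous or
#' homozygous in both parents are excluded, as are markers whose F1
#' segregation rejects 1:1 by a chi-square test at `alpha` (distortion causes
#' pseudo-linkage).
#'
#' @param g A [marker_genotypes()] object.
#' @param alpha Distortion test level (default 0.001).
#' @return An object of class `testcross_partition`: `p1_markers`,
#'   `p2_markers` (character vectors) and `excluded` (data frame with
#'   `marker`, `reason`). The three sets are disjoint and cover all markers.
#' @export
classify_testcross_markers <- function(g, alpha = 0.001) {
  stopifnot(inherits(g, "marker_genotypes"))
  p1 <- character(0); p2 <- character(0)
  exc_m <- character(0); exc_r <- character(0)
  exclude <- function(m, why) {
    exc_m <<- c(exc_m, m); exc_r <<- c(exc_r, why)
  }
  for (m in g$marker_names) {
    a <- g$parents[1, m]; b <- g$parents[2, m]
    if (a == "-" || b == "-") { exclude(m, "parent genotype missing"); next }
    side <- if (a == "H" && b == "A") "p1"
            else if (a == "A" && b == "H") "p2"
            else NA_character_
    if (is.na(side)) {
      exclude(m, if (a == "H") "heterozygous in both parents"
                 else "homozygous in both parents")
      next
    }
    f1 <- g$f1[, m]
    nA <- sum(f1 == "A"); nH <- sum(f1 == "H")
    if (nA + nH == 0L) { exclude(m, "no F1 calls"); next }
    e <- (nA + nH) / 2
    x2 <- (nA - e)^2 / e + (nH - e)^2 / e
    if (stats::pchisq(x2, df = 1, lower.tail = FALSE) < alpha) {
      exclude(m, "distorted segregation"); next
    }
    if (side == "p1") p1 <- c(p1, m) else p2 <- c(p2, m)
  }
  structure(list(p1_markers = p1, p2_markers = p2,
                 excluded = data.frame(marker = exc_m, reason = exc_r)),
            class = "testcross_partition")
}

# A/H/- columns to 0/1/NA
geno_numeric <- function(x) {
  out <- rep(NA_real_, length(x))
  out[x == "A"] <- 0
  out[x == "H"] <- 1
  out
}

two_point_lod <- function(R, n) {
  r <- R / n
  ifelse(R == 0, n * log10(2),
         R * log10(2 * r) + (n - R) * log10(2 * (1 - r)))
}

#' Two-point recombination fraction between same-parent markers
#'
#' Testcross markers have two genotype classes, so a recombination event
#' between two markers shows as a genotype difference (coupling phase) or a
#' genotype match (repulsion phase). Both phases are scored and the one with
#' estimated `r <= 0.5` is kept. The LOD is the log10 likelihood ratio
#' against free recombination: `LOD = R log10(r/0.5) + (n-R) log10((1-r)/0.5)`
#' with `R` recombinants out of `n`; in the limit `R = 0`, `LOD = n log10 2`.
#'
#' @param mi,mj Genotype vectors over the same F1 individuals, coded
#'   `A`/`H`/`-` (or 0/1/`NA`).
#' @param min_n Minimum complete pairs (default 10); below it `rf` is `NA`.
#' @return List with `rf`, `lod`, `phase` (`"coupling"`/`"repulsion"`), `n`.
#' @export
estimate_rf <- function(mi, mj, min_n = 10L) {
  if (is.character(mi)) mi <- geno_numeric(mi)
  if (is.character(mj)) mj <- geno_numeric(mj)
  ok <- !is.na(mi) & !is.na(mj)
  n <- sum(ok)
  if (n < min_n)
    return(list(rf = NA_real_, lod = NA_real_, phase = NA_character_, n = n))
  d <- sum(mi[ok] != mj[ok])
  if (d <= n - d) {
    R <- d; phase <- "coupling"
  } else {
    R <- n - d; phase <- "repulsion"
  }
  list(rf = R / n, lod = two_point_lod(R, n), phase = phase, n = n)
}

# all-pairs rf/lod/phase for a 0/1/NA genotype matrix (individuals x markers)
pairwise_rf <- function(X, min_n = 10L) {
  O <- !is.na(X)
  X1 <- X == 1 & O; X0 <- X == 0 & O
  mode(O) <- mode(X1) <- mode(X0) <- "numeric"
  n <- crossprod(O)
  d <- crossprod(X1, X0) + crossprod(X0, X1)
  coupling <- d <= n - d
  R <- ifelse(coupling, d, n - d)
  rf <- R / n
  lod <- two_point_lod(R, n)
  bad <- n < min_n
  rf[bad] <- NA; lod[bad] <- NA
  diag(rf) <- NA; diag(lod) <- NA
  phase <- ifelse(coupling, "coupling", "repulsion")
  dimnames(rf) <- dimnames(lod) <- dimnames(phase) <-
    list(colnames(X), colnames(X))
  list(rf = rf, lod = lod, phase = phase, n = n)
}

#' Group markers by single-linkage transitive closure
#'
#' Two markers join the same linkage group if their estimated recombination
#' fraction is at most `max_rf` and the two-point LOD is at least `min_lod`;
#' groups are the connected components of that graph. Singletons are allowed.
#' Group numbering is deterministic: groups are ordered by their
#' lexicographically smallest marker name.
#'
#' @param rf_est A [pairwise_rf()] result (fields `rf`, `lod`).
#' @param max_rf Maximum rf to link (default 0.35).
#' @param min_lod Minimum LOD to link (default 3).
#' @return List of character vectors of marker names.
#' @export
group_markers <- function(rf_est, max_rf = 0.35, min_lod = 3.0) {
  markers <- colnames(rf_est$rf)
  m <- length(markers)
  adj <- !is.na(rf_est$rf) & rf_est$rf <= max_rf &
         !is.na(rf_est$lod) & rf_est$lod >= min_lod
  comp <- rep(0L, m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  groups <- split(markers, comp)
  groups <- unname(groups[order(vapply(groups, function(g) min(g), ""))])
  groups
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    idx <- c(seq_len(n)[-k])
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, idx[sub[i, ]])
    }
  }
  out
}

order_cost <- function(ord, rf) {
  adj <- rf[cbind(ord[-length(ord)], ord[-1])]
  # unsupported adjacencies (too few data) are worst-case
  adj[is.na(adj)] <- 0.5
  sum(adj)
}

normalize_orientation <- function(markers) {
  if (length(markers) > 1L && markers[length(markers)] < markers[1])
    rev(markers) else markers
}

#' Order markers within a linkage group
#'
#' Minimizes the sum of adjacent recombination fractions: exhaustively for
#' groups of up to 8 markers (global optimum), otherwise greedy
#' nearest-neighbour seeded at the most distant marker pair (the putative
#' ends) and refined by 2-opt moves until no improvement. The orientation is
#' normalized so the lexicographically smaller terminal marker comes first.
#'
#' @param markers Character vector of marker names in one group.
#' @param rf_est A [pairwise_rf()] result covering the group.
#' @param exhaustive_max Largest group ordered exhaustively (default 8).
#' @return Marker names in map order.
#' @export
order_markers <- function(markers, rf_est, exhaustive_max = 8L) {
  k <- length(markers)
  if (k <= 2L) return(normalize_orientation(markers))
  rf <- rf_est$rf[markers, markers, drop = FALSE]
  if (k <= exhaustive_max) {
    perms <- permutations_of(k)
    keep <- perms[, 1] < perms[, k]   # each order once, not its reverse
    perms <- perms[keep, , drop = FALSE]
    costs <- apply(perms, 1, function(p) order_cost(p, rf))
    best <- perms[which.min(costs), ]
    return(normalize_orientation(markers[best]))
  }
  rfw <- rf
  rfw[is.na(rfw)] <- 0.5
  ends <- which(rfw == max(rfw), arr.ind = TRUE)[1, ]
  ord <- ends[1]
  left <- setdiff(seq_len(k), ord)
  while (length(left)) {
    nxt <- left[which.min(rfw[ord[length(ord)], left])]
    ord <- c(ord, nxt)
    left <- setdiff(left, nxt)
  }
  # 2-opt: reverse segments while the adjacent-rf sum drops
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    cur <- order_cost(ord, rf)
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        if (order_cost(cand, rf) < cur - 1e-12) {
          ord <- cand
          cur <- order_cost(cand, rf)
          improved <- TRUE
        }
      }
    }
  }
  normalize_orientation(markers[ord])
}

#' Convert recombination fraction to map distance
#'
#' Haldane (no crossover interference): `d = -50 ln(1 - 2r)`;
#' Kosambi (partial interference): `d = 25 ln((1 + 2r) / (1 - 2r))`.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Distance(s) in centimorgans.
#' @export
rf_to_distance <- function(r, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(r < 0 | r >= 0.5, na.rm = TRUE))
    stop("r must lie in [0, 0.5): unlinked markers have no finite distance")
  switch(map_function,
         haldane = -50 * log(1 - 2 * r),
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' Convert map distance to recombination fraction (inverse map function)
#'
#' @param d Distance(s) in centimorgans, `d >= 0`.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
distance_to_rf <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  switch(map_function,
         haldane = 0.5 * (1 - exp(-d / 50)),
         kosambi = 0.5 * tanh(d / 50))
}

#' Build parent-specific linkage maps from F1 genotypes
#'
#' Composes the pseudo-testcross pipeline: classify markers to a parent (or
#' exclude them), estimate all two-point recombination fractions from
#' pairwise-complete observations, group by single linkage, order within
#' groups, resolve each marker's linkage phase along the order, and assign
#' cumulative cM positions with the chosen map function. Adjacent
#' recombination fractions at or above 0.5 (possible for weakly supported
#' transitive links) are clamped just below 0.5 with a warning.
#'
#' @param g A [marker_genotypes()] object.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param max_rf,min_lod Grouping thresholds (defaults 0.35 and 3).
#' @param alpha Segregation-distortion exclusion level (default 0.001).
#' @param min_n Minimum complete pairs for an rf estimate (default 10).
#' @return An object of class `genetic_map`: `table` (data frame with
#'   `group`, `parent`, `marker`, `pos_cM`, `flipped`), `map_function`,
#'   `partition` (the marker classification) and `summary` (group counts,
#'   total length, mean adjacent spacing `total / (markers - groups)`).
#' @export
build_maps <- function(g, map_function = c("haldane", "kosambi"),
                       max_rf = 0.35, min_lod = 3.0, alpha = 0.001,
                       min_n = 10L) {
  map_function <- match.arg(map_function)
  part <- classify_testcross_markers(g, alpha = alpha)
  rows <- list()
  for (parent in c("P1", "P2")) {
    markers <- if (parent == "P1") part$p1_markers else part$p2_markers
    if (!length(markers)) next
    X <- apply(g$f1[, markers, drop = FALSE], 2, geno_numeric)
    if (is.null(dim(X))) X <- matrix(X, ncol = length(markers),
                                     dimnames = list(NULL, markers))
    est <- pairwise_rf(X, min_n = min_n)
    groups <- group_markers(est, max_rf = max_rf, min_lod = min_lod)
    for (gi in seq_along(groups)) {
      ord <- order_markers(groups[[gi]], est)
      k <- length(ord)
      flipped <- logical(k)
      pos <- numeric(k)
      if (k > 1L) {
        for (j in 2:k) {
          r <- est$rf[ord[j - 1], ord[j]]
          ph <- est$phase[ord[j - 1], ord[j]]
          if (is.na(r)) {
            warning("no rf estimate between adjacent markers ", ord[j - 1],
                    " and ", ord[j], "; using max_rf")
            r <- max_rf; ph <- "coupling"
          }
          if (r >= 0.5) {
            warning("adjacent rf >= 0.5 between ", ord[j - 1], " and ",
                    ord[j], "; clamped")
            r <- 0.4999
          }
          flipped[j] <- xor(flipped[j - 1], identical(ph, "repulsion"))
          pos[j] <- pos[j - 1] + rf_to_distance(r, map_function)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = paste0(gi, ".", parent), parent = parent, marker = ord,
        pos_cM = pos, flipped = flipped)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(group = character(0), parent = character(0),
                         marker = character(0), pos_cM = numeric(0),
                         flipped = logical(0))
  glen <- tapply(tab$pos_cM, tab$group, max)
  n_groups <- length(glen)
  total <- sum(glen)
  n_mark <- nrow(tab)
  summary <- list(
    n_groups = n_groups,
    n_groups_p1 = length(unique(tab$group[tab$parent == "P1"])),
    n_groups_p2 = length(unique(tab$group[tab$parent == "P2"])),
    n_markers = n_mark,
    total_length_cM = total,
    mean_spacing_cM = if (n_mark > n_groups) total / (n_mark - n_groups)
                      else NA_real_)
  structure(list(table = tab, map_function = map_function, partition = part,
                 summary = summary),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- x$summary
  cat("<genetic_map> ", s$n_markers, " markers in ", s$n_groups,
      " linkage groups (", s$n_groups_p1, " P1 + ", s$n_groups_p2,
      " P2); total ", sprintf("%.2f", s$total_length_cM), " cM, mean spacing ",
      sprintf("%.2f", s$mean_spacing_cM), " cM [", x$map_function, "]\n",
      sep = "")
  invisible(x)
}
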