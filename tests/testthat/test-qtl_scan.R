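cross_map_probs <- function(seed = 1, n_f1 = 94, groups_per_parent = 2,
                            markers_per_group = 8, spacing_cM = 10,
                            phase = "coupling", missing_rate = 0,
                            step_cM = 2) {
  cross <- simulate_pseudo_testcross(
    n_f1 = n_f1, groups_per_parent = groups_per_parent,
    markers_per_group = markers_per_group, spacing_cM = spacing_cM,
    phase = phase, missing_rate = missing_rate, seed = seed)
  map <- build_maps(cross$genotypes)
  probs <- genotype_probabilities(map, cross$genotypes, step_cM = step_cM)
  list(cross = cross, map = map, probs = probs)
}

test_that("genotype probabilities are exact at observed markers", {
  cmp <- cross_map_probs(seed = 51)
  gr <- cmp$probs$groups[[1]]
  at <- which(gr$is_marker)
  for (t in at[1:3]) {
    obs <- gr$marker_obs[, gr$marker[t]]
    typed <- !is.na(obs)
    expect_equal(gr$probs[typed, t], obs[typed], tolerance = 1e-12)
  }
  expect_true(all(gr$probs >= 0 & gr$probs <= 1))
})

test_that("midpoint of a 20 cM Haldane interval with both flanks A", {
  # enumeration oracle: P(A at mid | A, A) with r_half = 0.0906, giving
  # (1-r)^2 / ((1-r)^2 + r^2) ~ 0.990
  r_half <- 0.5 * (1 - exp(-10 / 50))
  p_oracle <- (1 - r_half)^2 / ((1 - r_half)^2 + r_half^2)
  f1 <- matrix("A", 20, 2, dimnames = list(NULL, c("Ma", "Mb")))
  f1[1:10, ] <- "H"   # keep segregation 1:1 so the marker survives filters
  g <- make_genotypes(f1)
  map <- build_maps(g)
  # force the two markers 20 cM apart regardless of sampled rf
  map$table$pos_cM <- c(0, 20)
  probs <- genotype_probabilities(map, g, step_cM = 10)
  gr <- probs$groups[[1]]
  mid <- which(gr$pos == 10)
  expect_equal(unname(1 - gr$probs[11, mid]), p_oracle, tolerance = 1e-9)
  expect_equal(unname(gr$probs[1, mid]), p_oracle, tolerance = 1e-9)
})

test_that("fully untyped individuals get probability 0.5 with a warning", {
  cmp <- cross_map_probs(seed = 53, n_f1 = 30, groups_per_parent = 1,
                         markers_per_group = 4)
  g <- cmp$cross$genotypes
  g$f1[1, ] <- "-"
  expect_warning(probs <- genotype_probabilities(cmp$map, g), "untyped")
  for (gr in probs$groups)
    expect_true(all(gr$probs[1, ] == 0.5))
})

test_that("phase-flipped codings give the same map and scan", {
  cmpA <- cross_map_probs(seed = 55, phase = "coupling")
  cmpB <- cross_map_probs(seed = 55, phase = "random")
  # identical latent states, different codings
  expect_identical(cmpA$cross$states, cmpB$cross$states)
  y <- plant_qtl_effects(cmpA$cross,
                         list(list(parent = "P1", group = 1, pos_cM = 30,
                                   effect = 1)), h2 = 0.5, seed = 56)
  sA <- hk_scan(cmpA$probs, y)
  sB <- hk_scan(cmpB$probs, y)
  expect_equal(max(sA$lod), max(sB$lod), tolerance = 1e-6)
  expect_identical(sA$group[which.max(sA$lod)], sB$group[which.max(sB$lod)])
})

test_that("constant phenotype scans flat at LOD 0", {
  cmp <- cross_map_probs(seed = 57, n_f1 = 40, groups_per_parent = 1,
                         markers_per_group = 4)
  sc <- hk_scan(cmp$probs, rep(1.7, 40))
  expect_true(all(sc$lod == 0))
})

test_that("scan LOD at complete markers equals the regression identity", {
  # LOD = -(n/2) log10(1 - R^2) of y on the 0/1 genotype, an algebraic
  # identity checked against a direct lm oracle on 20 random datasets
  for (rep in 1:20) {
    cmp <- cross_map_probs(seed = 100 + rep, n_f1 = 60,
                           groups_per_parent = 1, markers_per_group = 5)
    set.seed(200 + rep)
    gr1 <- cmp$probs$groups[[1]]
    mk <- gr1$marker[which(gr1$is_marker)[2]]
    x <- gr1$marker_obs[, mk]
    y <- 0.8 * x + rnorm(60)
    sc <- hk_scan(cmp$probs, y)
    at <- which(sc$group == gr1$group)[which(gr1$is_marker)[2]]
    r2 <- summary(lm(y ~ x))$r.squared
    expect_equal(sc$lod[at], -(60 / 2) * log10(1 - r2), tolerance = 1e-10)
  }
})

test_that("LOD is invariant to affine transforms of the phenotype", {
  cmp <- cross_map_probs(seed = 61, n_f1 = 50, groups_per_parent = 1,
                         markers_per_group = 5)
  set.seed(62)
  y <- rnorm(50) + cmp$cross$states[, 3]
  s1 <- hk_scan(cmp$probs, y)
  s2 <- hk_scan(cmp$probs, -3.2 * y + 7)
  expect_equal(s1$lod, s2$lod, tolerance = 1e-9)
})

test_that("a planted QTL is recovered on the true group at the peak", {
  hits <- 0L
  for (s in 1:20) {
    cmp <- cross_map_probs(seed = 300 + s)
    y <- plant_qtl_effects(cmp$cross,
                           list(list(parent = "P2", group = 2, pos_cM = 35,
                                     effect = 1)), noise_sd = 1,
                           seed = 400 + s)
    sc <- hk_scan(cmp$probs, y)
    if (sc$group[which.max(sc$lod)] == "2.P2") hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90% of seeds
})

test_that("peak location error is small with dense markers", {
  errs <- vapply(1:40, function(s) {
    cmp <- cross_map_probs(seed = 500 + s)
    y <- plant_qtl_effects(cmp$cross,
                           list(list(parent = "P1", group = 1, pos_cM = 30,
                                     effect = 1)), noise_sd = 1,
                           seed = 600 + s)
    sc <- hk_scan(cmp$probs, y)
    peak <- sc[which.max(sc$lod), ]
    if (peak$group == "1.P1") abs(peak$pos - 30) else Inf
  }, numeric(1))
  expect_lte(median(errs), 10)
})

test_that("CIM with zero cofactors reduces exactly to the HK scan", {
  cmp <- cross_map_probs(seed = 63)
  set.seed(64)
  y <- rnorm(94) + cmp$cross$states[, 4]
  expect_identical(cim_scan(cmp$probs, y, n_cofactors = 0),
                   hk_scan(cmp$probs, y))
})

test_that("CIM drops cofactors inside the window on the scanned group", {
  cmp <- cross_map_probs(seed = 65)
  y <- plant_qtl_effects(cmp$cross,
                         list(list(parent = "P1", group = 1, pos_cM = 30,
                                   effect = 1.5)), noise_sd = 0.7,
                         seed = 66)
  sc <- cim_scan(cmp$probs, y, window_cM = 30, n_cofactors = 2)
  cof <- attr(sc, "cofactors")
  expect_gte(nrow(cof), 1L)
  # at a cofactor's own position the cofactor is excluded, so the LOD there
  # must still see the QTL (a retained self-cofactor would absorb it to ~0)
  own <- sc[sc$group == cof$group[1] & sc$pos == cof$pos[1], ]
  expect_gt(own$lod, 1)
})

test_that("CIM sharpens multi-QTL scans at least as often as not", {
  wins <- 0L; total <- 0L
  for (s in 1:30) {
    cmp <- cross_map_probs(seed = 700 + s)
    y <- plant_qtl_effects(cmp$cross,
                           list(list(parent = "P1", group = 1, pos_cM = 30,
                                     effect = 1),
                                list(parent = "P2", group = 2, pos_cM = 40,
                                     effect = 1)),
                           noise_sd = 1, seed = 800 + s)
    hk <- hk_scan(cmp$probs, y)
    cim <- cim_scan(cmp$probs, y)
    for (grp in c("1.P1", "2.P2")) {
      total <- total + 1L
      if (max(cim$lod[cim$group == grp]) >=
          max(hk$lod[hk$group == grp]) - 1e-9) wins <- wins + 1L
    }
  }
  expect_gte(wins / total, 0.7)
})

test_that("permutation thresholds are seed-deterministic and ordered", {
  cmp <- cross_map_probs(seed = 67, n_f1 = 60, groups_per_parent = 1,
                         markers_per_group = 5)
  set.seed(68); y <- rnorm(60)
  t1 <- suppressWarnings(
    permutation_thresholds(cmp$probs, y, n_perm = 80, seed = 7))
  t2 <- suppressWarnings(
    permutation_thresholds(cmp$probs, y, n_perm = 80, seed = 7))
  expect_identical(t1$thresholds, t2$thresholds)
  expect_lte(t1$threshold_10, t1$threshold_5)
  expect_length(t1$max_lods, 80L)
  expect_warning(permutation_thresholds(cmp$probs, y, n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("the vectorized permutation path matches explicit HK rescans", {
  cmp <- cross_map_probs(seed = 69, n_f1 = 40, groups_per_parent = 1,
                         markers_per_group = 4)
  set.seed(70); y <- rnorm(40)
  thr <- suppressWarnings(
    permutation_thresholds(cmp$probs, y, n_perm = 5, seed = 71))
  set.seed(71)
  manual <- replicate(5, max(hk_scan(cmp$probs, y[sample.int(40)])$lod))
  expect_equal(sort(thr$max_lods), sort(manual), tolerance = 1e-8)
})

test_that("doubling the permutation count moves the threshold little", {
  cmp <- cross_map_probs(seed = 73)
  y <- plant_qtl_effects(cmp$cross,
                         list(list(parent = "P1", group = 2, pos_cM = 20,
                                   effect = 0.5)), noise_sd = 1, seed = 74)
  tA <- permutation_thresholds(cmp$probs, y, n_perm = 500, seed = 75)
  tB <- permutation_thresholds(cmp$probs, y, n_perm = 1000, seed = 75)
  expect_lt(abs(tA$threshold_5 - tB$threshold_5), 0.15)
})

test_that("QTL calls collapse runs, label marginal peaks, or stay empty", {
  cmp <- cross_map_probs(seed = 77)
  fake_thr <- structure(list(alphas = c(0.05, 0.10),
                             thresholds = c("0.05" = 3, "0.1" = 2)),
                        class = "permutation_thresholds")
  sc <- hk_scan(cmp$probs, plant_qtl_effects(
    cross = cmp$cross,
    qtls = list(list(parent = "P1", group = 1, pos_cM = 30, effect = 2)),
    noise_sd = 0.5, seed = 78))
  hits <- significant_qtls(sc, fake_thr)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$group, "1.P1")
  expect_identical(hits$level, "5%")
  expect_equal(hits$lod, max(sc$lod))
  # marginal-only labelling
  fake_hi <- fake_thr
  fake_hi$thresholds <- c("0.05" = max(sc$lod) + 1, "0.1" = 2)
  expect_identical(significant_qtls(sc, fake_hi)$level, "10%")
  # everything below the marginal threshold
  fake_imp <- fake_thr
  fake_imp$thresholds <- c("0.05" = 1e6, "0.1" = 1e6)
  expect_identical(nrow(significant_qtls(sc, fake_imp)), 0L)
})

test_that("QTL genotype classes follow first-letter/second-letter order", {
  f1 <- matrix(c("A", "H", "H", "A",
                 "H", "H", "A", "-"), 4, 2,
               dimnames = list(paste0("F1_", 1:4), c("Q1", "Q2")))
  g <- make_genotypes(f1)
  expect_message(cls <- classify_by_qtl_markers(g, "Q1", "Q2"), "omitted")
  expect_identical(cls$class, c("AH", "HH", "HA"))
  expect_identical(cls$plant_id, paste0("F1_", 1:3))
  expect_error(classify_by_qtl_markers(g, "Q1", "nope"), "unknown marker")
  # full population tally matches a brute-force table
  cmp <- cross_map_probs(seed = 79)
  mks <- cmp$cross$true_map$marker[c(3, 20)]
  cls2 <- classify_by_qtl_markers(cmp$cross$genotypes, mks[1], mks[2])
  brute <- table(paste0(cmp$cross$genotypes$f1[, mks[1]],
                        cmp$cross$genotypes$f1[, mks[2]]))
  expect_identical(as.vector(table(cls2$class)), as.vector(brute))
})

test_that("genotype-class ANOVA reproduces the hand ANOVA table", {
  # two classes {1,2,3} vs {7,8,9}: between-SS 54 (df 1), within-SS 4
  # (df 4), so F = 54 / 1 = 54
  y <- c(1, 2, 3, 7, 8, 9)
  cls <- rep(c("AA", "HH"), each = 3)
  res <- compare_groups_anova(cls, y, alpha = 0.01)
  expect_equal(res$F, 54, tolerance = 1e-10)
  expect_identical(names(res$means), c("HH", "AA"))
  expect_identical(unname(res$letters["HH"]), "a")
  # constant trait: F = 0 and a single shared letter
  resc <- compare_groups_anova(rep(c("AA", "HH", "AH"), each = 2), rep(5, 6))
  expect_equal(resc$F, 0)
  expect_true(all(resc$letters == "a"))
  # a singleton class is dropped with a warning
  expect_warning(
    compare_groups_anova(c(cls, "HA"), c(y, 5), alpha = 0.01), "<2 members")
})

test_that("a depressed class earns its own Tukey letter", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(900 + s)
    cls <- sample(c("AH", "AA", "HH", "HA"), 94, replace = TRUE)
    y <- rnorm(94) - 2 * (cls == "HA")   # 2 SD depression
    res <- compare_groups_anova(cls, y, alpha = 0.01)
    others <- res$letters[setdiff(names(res$letters), "HA")]
    if (!any(grepl(res$letters[["HA"]], others, fixed = TRUE)))
      hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
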