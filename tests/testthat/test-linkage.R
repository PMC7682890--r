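test_that("correlation LOD matches the closed form and its limits", {
  # n = 100, r = 0.5 -> -100*ln(0.75)/(2 ln 10) ~ 6.247
  expect_equal(zincmap:::.lod_from_r(0.5, 100), -100 * log(0.75) / (2 * log(10)),
               tolerance = 1e-12)
  expect_equal(zincmap:::.lod_from_r(0, 57), 0)
  # perfect correlation is capped, with a warning
  expect_warning(cap <- zincmap:::.lod_from_r(1, 50), "capped")
  expect_equal(cap, (50 / 2) * log10(1 / 1e-12), tolerance = 1e-6)
})

test_that("scan equals the regression likelihood-ratio LOD on random data", {
  set.seed(21)
  cr <- rand_cross_small(n = 80, mpc = 15, seed = 3)
  y <- simulate_phenotypes(cr, data.frame(marker = 10, frac = 0.2, sign = 1),
                           seed = 4)
  sc <- lod_scan(cr, y)
  for (m in c(1, 10, 23, 45)) {
    expect_equal(sc$lod[m], lr_lod_oracle(cr$geno[, m], y),
                 tolerance = 1e-10)
  }
})

test_that("scan is invariant to strain order and flips sign with alleles", {
  cr <- rand_cross_small(seed = 5)
  y <- simulate_phenotypes(cr, data.frame(marker = 30, frac = 0.3, sign = 1),
                           seed = 6)
  sc <- lod_scan(cr, y)
  set.seed(7)
  perm <- sample(nrow(cr$geno))
  cr2 <- cross_genotypes(cr$geno[perm, ], cr$map)
  sc2 <- lod_scan(cr2, y[perm])
  expect_equal(sc$lod, sc2$lod, tolerance = 1e-12)
  # global allele swap: LOD unchanged, correlation flips
  cr3 <- cross_genotypes(1 - cr$geno, cr$map)
  sc3 <- lod_scan(cr3, y)
  expect_equal(sc$lod, sc3$lod, tolerance = 1e-12)
  expect_equal(sc$r, -sc3$r, tolerance = 1e-12)
})

test_that("constant phenotype scans flat and maps nothing", {
  cr <- rand_cross_small(seed = 8)
  y0 <- rep(3, nrow(cr$geno))
  expect_warning(sc <- lod_scan(cr, y0), "constant")
  expect_true(all(sc$lod == 0))
  pk <- forward_search(cr, y0, threshold = 3)
  expect_equal(nrow(pk), 0)
})

test_that("permutation thresholds are reproducible and monotone in alpha", {
  cr <- rand_cross_small(seed = 9)
  y <- simulate_phenotypes(cr, NULL, seed = 10)
  t1 <- permutation_threshold(cr, y, n_perm = 150, alpha = 0.05, seed = 11)
  t2 <- permutation_threshold(cr, y, n_perm = 150, alpha = 0.05, seed = 11)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t10 <- permutation_threshold(cr, y, n_perm = 150, alpha = 0.10, seed = 11)
  t01 <- permutation_threshold(cr, y, n_perm = 150, alpha = 0.01, seed = 11)
  expect_lte(as.numeric(t10), as.numeric(t1))
  expect_lte(as.numeric(t1), as.numeric(t01))
})

test_that("forward search respects its threshold semantics", {
  cr <- rand_cross_small(n = 100, seed = 12)
  y <- simulate_phenotypes(cr, data.frame(marker = 25, frac = 0.3, sign = 1),
                           seed = 13)
  # infinite threshold: nothing detected
  expect_equal(nrow(forward_search(cr, y, threshold = Inf)), 0)
  # zero threshold: first peak is the global maximum; runaway guarded
  expect_error(forward_search(cr, y, threshold = 0, max_iter = 2),
               "iterations")
  sc <- lod_scan(cr, y)
  pk <- forward_search(cr, y, threshold = max(sc$lod) - 0.5)
  expect_gte(nrow(pk), 1)
  expect_identical(pk$marker[1], sc$marker[which.max(sc$lod)])
})

test_that("peak annotation produces sane intervals and effect sizes", {
  cr <- simulate_cross(n_strains = 200, n_chrom = 3, markers_per_chrom = 40,
                       seed = 14)
  y <- simulate_phenotypes(cr, data.frame(marker = 60, frac = 0.35,
                                          sign = -1), seed = 15)
  thr <- permutation_threshold(cr, y, n_perm = 150, seed = 16)
  pk <- forward_search(cr, y, threshold = thr)
  expect_gte(nrow(pk), 1)
  top <- pk[which.max(pk$lod), ]
  # interval is on the peak chromosome, ordered, and covers the peak
  expect_identical(top$chrom, "II")
  expect_lte(top$ci_left_pos, top$pos)
  expect_gte(top$ci_right_pos, top$pos)
  # negative planted effect: the N2 allele raises the trait
  expect_identical(top$effect_sign, "N2-up")
  expect_lt(top$effect, 0)
  # interval markers all have conditional LOD above peak - 1.5
  others <- setdiff(pk$marker, top$marker)
  csc <- lod_scan(cr, y, cofactors = others)
  on_ci <- csc$chrom == top$chrom & csc$pos >= top$ci_left_pos &
    csc$pos <= top$ci_right_pos
  expect_true(all(csc$lod[on_ci] >= top$lod - 1.5 - 1e-9))
  expect_true(attr(pk, "total_variance_explained") >= top$variance_explained - 1e-9)
})

test_that("per-QTL variance explained recovers a planted 20% effect", {
  est <- vapply(1:50, function(s) {
    cr <- simulate_cross(n_strains = 250, n_chrom = 3,
                         markers_per_chrom = 60, seed = 2500 + s)
    y <- simulate_phenotypes(cr, data.frame(marker = 90, frac = 0.20,
                                            sign = 1), seed = 2600 + s)
    pk <- suppressMessages(forward_search(cr, y, n_perm = 150,
                                          seed = 2700 + s))
    if (nrow(pk) == 0) return(NA_real_)
    pk$variance_explained[which.max(pk$lod)]
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.20), 0.05)
})

test_that("two-dimensional scan orders nested models correctly", {
  cr <- rand_cross_small(n = 120, mpc = 12, seed = 17)
  set.seed(18)
  gA <- cr$geno[, 5]; gB <- cr$geno[, 30]
  y <- gA * gB + rnorm(120, sd = 0.6)
  st <- scan_two(cr, y, grid_max = 36)
  expect_true(all(st$pairs$lod_interaction >= -1e-9, na.rm = TRUE))
  expect_true(all(st$pairs$lod_full >= st$pairs$lod_additive - 1e-9,
                  na.rm = TRUE))
  top <- st$pairs[which.max(st$pairs$lod_interaction), ]
  expect_setequal(c(top$marker_a, top$marker_b),
                  cr$map$marker[c(5, 30)])
  # threshold reproducible given seed
  s1 <- scan_two(cr, y, grid_max = 36, n_perm = 25, seed = 19)
  s2 <- scan_two(cr, y, grid_max = 36, n_perm = 25, seed = 19)
  expect_identical(s1$interaction_threshold, s2$interaction_threshold)
})

test_that("interaction ANOVA separates additive from epistatic signals", {
  set.seed(20)
  n <- 100
  gA <- rbinom(n, 1, 0.5); gB <- rbinom(n, 1, 0.5)
  # pure interaction with tiny noise
  y <- gA * gB + rnorm(n, sd = 0.05)
  expect_lt(interaction_anova(y, gA, gB), 1e-6)
  # additive cell means {0,1,1,2}: interaction estimate ~ 0
  y2 <- gA + gB + rnorm(n, sd = 1)
  p2 <- interaction_anova(y2, gA, gB)
  expect_lt(abs(attr(p2, "estimate")), 0.75)  # ~ 2 SE at n = 25/cell
  # empty cell errors
  gC <- ifelse(gA == 1, 1, 0)
  expect_error(interaction_anova(y, gA, 1 - gA), "cell")
})

test_that("interaction p-values are uniform under additivity", {
  set.seed(22)
  ps <- vapply(1:200, function(i) {
    gA <- rbinom(80, 1, 0.5); gB <- rbinom(80, 1, 0.5)
    if (any(table(gA, gB) == 0)) return(NA_real_)
    as.numeric(interaction_anova(gA + gB + rnorm(80), gA, gB))
  }, numeric(1))
  ks <- ks.test(ps[!is.na(ps)], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("cross construction validates its invariants", {
  g <- matrix(c(0, 1, 0, 1, 1, 0, 0, 0), 4, 2)
  map <- data.frame(marker = c("m1", "m2"), chrom = "I", pos = c(10, 20))
  expect_s3_class(cross_genotypes(g, map), "cross_genotypes")
  # unsorted map
  map2 <- data.frame(marker = c("m1", "m2"), chrom = "I", pos = c(20, 10))
  expect_error(cross_genotypes(g, map2), "sorted")
  # monomorphic marker
  g2 <- g; g2[, 2] <- 0
  expect_error(cross_genotypes(g2, map), "segregating")
})
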