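make_records <- function(tof, ext, strain = "s1", assay = "a1",
                         well = "w1", condition = "zinc") {
  data.frame(strain = strain, assay = assay, plate = "p1", well = well,
              condition = condition, tof = tof, ext = ext,
              stringsAsFactors = FALSE)
}

test_that("well summaries are the documented order statistics", {
  # single animal
  w <- summarize_wells(make_records(200, 50), parents_sorted = 3)
  expect_equal(w$median.TOF, 200)
  expect_equal(w$median.EXT, 50)
  expect_equal(w$median.norm.EXT, 0.25)
  expect_equal(w$n_animals, 1)
  # hand-computed medians; median.norm.EXT is the median of per-animal
  # ratios, not the ratio of medians
  w <- summarize_wells(make_records(c(100, 200, 300), c(10, 20, 60)),
                       parents_sorted = 3)
  expect_equal(w$median.TOF, 200)
  expect_equal(w$median.EXT, 20)
  expect_equal(w$median.norm.EXT, 0.10)
  expect_equal(w$norm.n, 1.0)
  # exactly the four named traits come out
  expect_true(all(c("median.TOF", "median.EXT", "median.norm.EXT",
                    "norm.n") %in% names(w)))
  expect_identical(table_stage(w), "raw")
})

test_that("non-positive TOF records are rejected; zero parents error", {
  rec <- make_records(c(100, -5, 200), c(10, 1, 20))
  expect_warning(w <- summarize_wells(rec, 3), "non-positive TOF")
  expect_equal(w$n_animals, 2)
  expect_error(summarize_wells(make_records(100, 10), parents_sorted = 0),
               "parents_sorted")
})

test_that("assay regression centers per assay level and sums to zero", {
  tab <- data.frame(strain = "s", assay = rep(c("a1", "a2"), each = 2),
                    plate = "p", well = paste0("w", 1:4), condition = "z",
                    median.TOF = c(4, 6, 8, 10), stringsAsFactors = FALSE)
  tab <- as_trait_table(tab, "raw")
  out <- regress_assay(tab)
  expect_equal(out$median.TOF, c(-1, 1, -1, 1))
  expect_identical(table_stage(out), "assay_regressed")
  # residuals sum to zero within every level, on arbitrary data
  set.seed(4)
  tab2 <- data.frame(strain = "s", assay = sample(c("a1", "a2", "a3"), 30,
                                                  replace = TRUE),
                     plate = "p", well = paste0("w", 1:30), condition = "z",
                     median.EXT = rnorm(30, 5), stringsAsFactors = FALSE)
  out2 <- regress_assay(as_trait_table(tab2, "raw"))
  sums <- tapply(out2$median.EXT, out2$assay, sum)
  expect_true(all(abs(sums) < 1e-10))
})

test_that("bamf pruning removes the far point unless too many strains stick out", {
  v <- c(1:20, 100)
  tab <- data.frame(strain = paste0("s", 1:21), assay = "a1", plate = "p",
                    well = paste0("w", 1:21), condition = "z",
                    median.TOF = v, stringsAsFactors = FALSE)
  tab <- as_trait_table(tab, "assay_regressed")
  # type-7 quartiles: Q1 = 6, Q3 = 16, upper fence 36; 1/21 of strains
  # outside (< 5%) -> 100 removed
  out <- prune_wells(tab, method = "bamf")
  expect_equal(nrow(out), 20)
  expect_false(100 %in% out$median.TOF)
  expect_identical(table_stage(out), "pruned")
  # same data but only 10 strains with wells outside the fences in > 5%
  tab5 <- tab
  tab5$strain <- c(rep(paste0("t", 1:10), 2), "t1")
  tab5$median.TOF[21] <- 100
  expect_message(out5 <- prune_wells(as_trait_table(tab5, "assay_regressed"),
                                     method = "bamf"), "no removal")
  expect_equal(nrow(out5), 21)
})

test_that("sd pruning uses the two-SD rule within (condition, strain)", {
  v <- c(1:20, 100)  # mean 13.95, sd 20.58 -> cut at ~55.1
  tab <- data.frame(strain = "s1", assay = "a1", plate = "p",
                    well = paste0("w", 1:21), condition = "z",
                    median.TOF = v, stringsAsFactors = FALSE)
  out <- prune_wells(as_trait_table(tab, "assay_regressed"), method = "sd")
  expect_equal(sort(out$median.TOF), 1:20)
  # all equal -> nothing removed under either method
  tab$median.TOF <- 7
  t2 <- as_trait_table(tab, "assay_regressed")
  expect_equal(nrow(prune_wells(t2, "sd")), 21)
  expect_equal(nrow(prune_wells(t2, "bamf")), 21)
  # pruning is idempotent for sd with single-pass bounds
  out2 <- prune_wells(as_trait_table(as.data.frame(out), "assay_regressed"),
                      method = "sd")
  expect_equal(nrow(out2), nrow(out))
})

test_that("control regression residualizes on per-strain control means", {
  mk <- function(strain, v, condition) {
    data.frame(strain = strain, assay = "a1", plate = "p",
               well = paste0(strain, condition, seq_along(v)),
               condition = condition, median.TOF = v,
               stringsAsFactors = FALSE)
  }
  ctrl <- as_trait_table(mk(c("s1", "s2", "s3"), c(1, 2, 3), "control"),
                         "pruned")
  drug <- as_trait_table(mk(c("s1", "s2", "s3"), c(2, 4, 6), "zinc"),
                         "pruned")
  out <- regress_control(drug, ctrl)
  expect_equal(out$median.TOF, c(0, 0, 0))
  expect_identical(table_stage(out), "control_regressed")
  # residuals orthogonal to control means
  set.seed(7)
  strains <- paste0("s", 1:30)
  ctrl2 <- as_trait_table(mk(strains, rnorm(30), "control"), "pruned")
  drug2 <- as_trait_table(mk(strains, rnorm(30), "zinc"), "pruned")
  out2 <- regress_control(drug2, ctrl2)
  cm <- tapply(ctrl2$median.TOF, ctrl2$strain, mean)[out2$strain]
  expect_lt(abs(sum(out2$median.TOF)), 1e-10)
  expect_lt(abs(cor(out2$median.TOF, as.numeric(cm))), 1e-8)
  # drug strain missing from control is dropped with a warning
  drug3 <- as_trait_table(mk(c(strains, "s99"), rnorm(31), "zinc"), "pruned")
  expect_warning(out3 <- regress_control(drug3, ctrl2), "s99")
  expect_false("s99" %in% out3$strain)
})

test_that("unit normalization maps min to 0 and max to 1", {
  expect_equal(normalize_unit(c(-3, 0, 3)), c(0, 0.5, 1))
  expect_equal(normalize_unit(c(2, 4, 10)), c(0, 0.25, 1))
  set.seed(1)
  v <- rnorm(50)
  u <- normalize_unit(v)
  expect_equal(u[which.min(v)], 0)
  expect_equal(u[which.max(v)], 1)
  expect_error(normalize_unit(rep(2, 5)), "constant")
})

test_that("dose selection maximizes the between/within variance ratio", {
  set.seed(11)
  mk_dose <- function(dose, means, sd = 1, reps = 6) {
    data.frame(strain = rep(names(means), each = reps), dose = dose,
               median.TOF = rnorm(length(means) * reps,
                                  rep(means, each = reps), sd),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(mk_dose("A", c(s1 = 0, s2 = 1)),
               mk_dose("B", c(s1 = 0, s2 = 10)))
  expect_equal(as.character(select_dose(tab)), "B")
  # single candidate dose is returned unchanged
  one <- mk_dose("C", c(s1 = 0, s2 = 1))
  expect_equal(select_dose(one), "C")
})

test_that("the pipeline is invariant to input row order", {
  eff <- setNames(rnorm(12, sd = 0.2), paste0("s", 1:12))
  rec <- simulate_sorter_records(eff, seed = 3)
  w1 <- summarize_wells(rec)
  set.seed(9)
  w2 <- summarize_wells(rec[sample(nrow(rec)), ])
  ord <- do.call(order, w1[c("strain", "assay", "well", "condition")])
  ord2 <- do.call(order, w2[c("strain", "assay", "well", "condition")])
  expect_equal(w1[ord, ], w2[ord2, ], ignore_attr = TRUE)
})

test_that("control-regressed strain ranking recovers planted drug effects", {
  eff <- setNames(seq(-0.4, 0.4, length.out = 20), paste0("s%02d", 1:20))
  names(eff) <- sprintf("s%02d", 1:20)
  rec <- simulate_sorter_records(eff, n_wells = 4, noise_sd = 0.05,
                                 assay_sd = 0.05, seed = 5)
  w <- summarize_wells(rec)
  a <- suppressMessages(regress_assay(w))
  p <- suppressMessages(prune_wells(a, "bamf"))
  drug <- as_trait_table(as.data.frame(p[p$condition != "control", ]),
                         "pruned")
  ctrl <- as_trait_table(as.data.frame(p[p$condition == "control", ]),
                         "pruned")
  out <- regress_control(drug, ctrl)
  sm <- tapply(out$median.TOF, out$strain, mean, na.rm = TRUE)
  expect_gt(cor(as.numeric(sm[names(eff)]), eff, method = "spearman"), 0.9)
})
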