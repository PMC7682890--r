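#' Broad-sense heritability from strain replicates
#'
#' Fits the random-intercept model `value = mu + strain + e` by REML
#' (\code{lme4::lmer}) and returns
#' `H2 = sigma2_strain / (sigma2_strain + sigma2_resid)`, the fraction of
#' phenotypic variance attributable to among-strain differences. The
#' confidence interval is a nonparametric strain-level bootstrap: strains
#' are resampled with replacement (keeping all their replicates), the model
#' refit, and a percentile interval taken.
#'
#' @param values numeric phenotype per well/replicate.
#' @param strain strain label per value.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap (required).
#' @param conf confidence level (default 0.95).
#' @return list of class `heritability_estimate` with `h2`, `ci_low`,
#'   `ci_high`, `sigma2_strain`, `sigma2_resid`, `n_strains`, `n_wells`.
#' @export
estimate_heritability <- function(values, strain, n_boot = 1000, seed,
                                  conf = 0.95) {
  stopifnot(length(values) == length(strain))
  ok <- is.finite(values) & !is.na(strain)
  values <- values[ok]; strain <- as.character(strain)[ok]
  if (length(unique(strain)) < 2) stop("need >= 2 strains")
  if (max(table(strain)) < 2) stop("need replicates for >= 1 strain")
  if (var(values) == 0) stop("total variance is zero")
  if (missing(seed)) stop("seed is required")

  fit_h2 <- function(v, s) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(v ~ 1 + (1 | s),
                 control = lme4::lmerControl(check.conv.singular =
                                               lme4::.makeCC("ignore", tol = 1e-4)))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2s <- vc$vcov[vc$grp == "s"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    s2s / (s2s + s2e)
  }
  h2 <- fit_h2(values, strain)

  set.seed(seed)
  strains <- unique(strain)
  by_strain <- split(seq_along(values), strain)
  boot <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(strains, length(strains), replace = TRUE)
    idx <- unlist(by_strain[pick], use.names = FALSE)
    lab <- rep(seq_along(pick), lengths(by_strain[pick]))
    tryCatch(fit_h2(values[idx], factor(lab)), error = function(e) NA_real_)
  }, numeric(1))
  qs <- if (n_boot > 0) {
    quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  } else c(NA_real_, NA_real_)

  structure(list(h2 = h2, ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 sigma2_strain = h2 * var(values),  # informational scale
                 sigma2_resid = (1 - h2) * var(values),
                 n_strains = length(strains), n_wells = length(values),
                 n_boot = n_boot),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("Broad-sense heritability H2 = %.3f  [%.3f, %.3f]  (%d strains, %d wells)\n",
              x$h2, x$ci_low, x$ci_high, x$n_strains, x$n_wells))
  invisible(x)
}

#' Pairwise strain comparisons with Tukey's HSD
#'
#' Runs an ANOVA of the phenotype on strain followed by Tukey's honest
#' significant differences, and annotates each pair with the conventional
#' significance stars (`ns` for p > 0.05, then `*`, `**`, `***`, `****` at
#' 0.05, 0.01, 0.001 and 0.0001). Bonferroni-adjusted pairwise t-test
#' p-values are reported alongside.
#'
#' @param values numeric phenotype.
#' @param strain strain label per value.
#' @param stars_from `"tukey"` (default) or `"bonferroni"`: which adjusted
#'   p-value drives the stars.
#' @return data.frame with `strain_a`, `strain_b`, `diff`, `p_adj`
#'   (Tukey), `p_bonferroni`, `stars`.
#' @export
tukey_pairwise <- function(values, strain, stars_from = c("tukey",
                                                          "bonferroni")) {
  stars_from <- match.arg(stars_from)
  ok <- is.finite(values) & !is.na(strain)
  values <- values[ok]; strain <- factor(as.character(strain)[ok])
  if (nlevels(strain) < 2) stop("need >= 2 strains")
  if (min(table(strain)) < 2) stop("need >= 2 replicates per strain")
  fit <- aov(values ~ strain)
  if (anova(fit)$`Mean Sq`[2] == 0) {
    stop("zero within-group variance: Tukey p-values undefined")
  }
  tk <- TukeyHSD(fit)$strain
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    strain_a = vapply(pair, `[`, character(1), 2),
    strain_b = vapply(pair, `[`, character(1), 1),
    diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  pb <- pairwise.t.test(values, strain, p.adjust.method = "bonferroni",
                        pool.sd = TRUE)$p.value
  out$p_bonferroni <- mapply(function(a, b) {
    if (b %in% rownames(pb) && a %in% colnames(pb) && !is.na(pb[b, a])) {
      pb[b, a]
    } else if (a %in% rownames(pb) && b %in% colnames(pb)) {
      pb[a, b]
    } else NA_real_
  }, out$strain_a, out$strain_b)
  p <- if (stars_from == "tukey") out$p_adj else out$p_bonferroni
  out$stars <- significance_stars(p)
  out
}

#' Significance stars for adjusted p-values
#'
#' `ns` for p > 0.05, `*` <= 0.05, `**` <= 0.01, `***` <= 0.001,
#' `****` <= 0.0001.
#'
#' @param p numeric p-values.
#' @return character vector of star labels.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
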