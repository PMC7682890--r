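#' Mediation of a QTL effect by an expression trait
#'
#' Product-of-coefficients mediation with two linear models: a mediator
#' model `m ~ g` (expression on QTL genotype, slope `a`) and an outcome
#' model `y ~ g + m` (phenotype on genotype and expression, expression
#' slope `b`, genotype slope = direct effect). The average causal
#' mediation effect is `acme = a * b`, the direct effect `ade` is the
#' genotype slope of the outcome model, and the total effect is the slope
#' of `y ~ g`; with linear models and no treatment-mediator interaction,
#' `total = acme + ade` exactly at the point estimates. Uncertainty comes
#' from a nonparametric strain bootstrap: percentile confidence interval
#' and a two-sided sign-based p-value for the acme.
#'
#' @param phenotype numeric vector per strain.
#' @param mediator numeric expression values per strain (same order).
#' @param genotype 0/1 genotype codes at the QTL peak marker.
#' @param n_sim bootstrap resamples (default 1000).
#' @param seed integer seed (results bit-reproducible given seed, n_sim).
#' @param conf confidence level.
#' @return list of class `mediation_estimate`: `acme`, `ade`, `total`,
#'   `prop_mediated` (acme/total clipped to `[0, 1]`, flagged when the
#'   total is near zero), `p_acme`, `ci_low`, `ci_high`, `n`, `boot_se`.
#' @export
mediate <- function(phenotype, mediator, genotype, n_sim = 1000, seed = 1,
                    conf = 0.95) {
  ok <- is.finite(phenotype) & is.finite(mediator) & !is.na(genotype)
  y <- phenotype[ok]; m <- mediator[ok]; g <- as.numeric(genotype[ok])
  n <- length(y)
  if (n < 30) stop("need >= 30 strains with phenotype, mediator and genotype")
  if (var(m) == 0) stop("zero variance in mediator")
  if (var(g) == 0) stop("zero variance in genotype")

  est <- .med_point(y, m, g)
  if (anyNA(est)) stop("singular fit in mediation models")

  set.seed(seed)
  boot <- matrix(NA_real_, n_sim, 3)
  for (b in seq_len(n_sim)) {
    i <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- .med_point(y[i], m[i], g[i])
  }
  acme_b <- boot[, 1]
  qs <- quantile(acme_b, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  p <- 2 * min(mean(acme_b <= 0, na.rm = TRUE),
               mean(acme_b >= 0, na.rm = TRUE))
  p <- min(max(p, 1 / n_sim), 1)

  total <- est[3]
  near_zero <- abs(total) < 1e-8 * sd(y)
  prop <- if (near_zero) NA_real_ else .clip(est[1] / total, 0, 1)

  structure(list(acme = est[1], ade = est[2], total = total,
                 prop_mediated = prop, total_near_zero = near_zero,
                 p_acme = p, ci_low = unname(qs[1]), ci_high = unname(qs[2]),
                 boot_se = sd(acme_b, na.rm = TRUE), n = n, n_sim = n_sim),
            class = "mediation_estimate")
}

# closed-form (acme, ade, total) from sufficient statistics
.med_point <- function(y, m, g) {
  vg <- var(g)
  if (vg == 0) return(rep(NA_real_, 3))
  a <- cov(g, m) / vg
  total <- cov(g, y) / vg
  # outcome y ~ g + m: 2-predictor least squares
  vm <- var(m); cgm <- cov(g, m)
  det <- vg * vm - cgm^2
  if (abs(det) < 1e-14 * vg * vm || det == 0) return(rep(NA_real_, 3))
  cy_g <- cov(g, y); cy_m <- cov(m, y)
  ade <- (vm * cy_g - cgm * cy_m) / det
  b <- (vg * cy_m - cgm * cy_g) / det
  c(a * b, ade, total)
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat(sprintf("ACME %.4f [%.4f, %.4f] p=%.3g | ADE %.4f | total %.4f | prop mediated %s\n",
              x$acme, x$ci_low, x$ci_high, x$p_acme, x$ade, x$total,
              ifelse(is.na(x$prop_mediated), "NA (total ~ 0)",
                     sprintf("%.3f", x$prop_mediated))))
  invisible(x)
}

#' Screen expression probes for mediation at one QTL
#'
#' Runs [mediate] for every probe at the same QTL marker and flags probes
#' whose mediation estimate exceeds the 95th percentile of the acme
#' distribution across probes (the screen's distribution cutoff).
#' Per-probe failures (e.g. zero-variance probes) become missing rows, not
#' a global failure.
#'
#' @param phenotype numeric vector per strain.
#' @param probes matrix of expression values, probes x strains (rownames =
#'   probe ids), strains aligned with `phenotype`.
#' @param genotype 0/1 genotype codes at the QTL peak marker.
#' @param n_sim bootstrap resamples per probe.
#' @param seed integer root seed; each probe gets a derived stream.
#' @param cutoff_quantile quantile of the acme distribution used as the
#'   flagging cutoff (default 0.95).
#' @return data.frame (class `mediation_screen`) with one row per probe:
#'   `probe`, `acme`, `ade`, `total`, `prop_mediated`, `p_acme`, `ci_low`,
#'   `ci_high`, `flagged`; the cutoff is the `"cutoff"` attribute.
#' @export
mediation_screen <- function(phenotype, probes, genotype, n_sim = 1000,
                             seed = 1, cutoff_quantile = 0.95) {
  stopifnot(is.matrix(probes), nrow(probes) >= 2)
  ids <- rownames(probes) %||% paste0("probe", seq_len(nrow(probes)))
  rows <- lapply(seq_len(nrow(probes)), function(k) {
    est <- tryCatch(
      mediate(phenotype, probes[k, ], genotype, n_sim = n_sim,
              seed = .child_seed(seed, k)),
      error = function(e) {
        message("probe ", ids[k], " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(est)) {
      data.frame(probe = ids[k], acme = NA_real_, ade = NA_real_,
                 total = NA_real_, prop_mediated = NA_real_,
                 p_acme = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(probe = ids[k], acme = est$acme, ade = est$ade,
                 total = est$total, prop_mediated = est$prop_mediated,
                 p_acme = est$p_acme, ci_low = est$ci_low,
                 ci_high = est$ci_high, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  cutoff <- quantile(out$acme, cutoff_quantile, na.rm = TRUE, type = 7)
  out$flagged <- !is.na(out$acme) & out$acme > cutoff
  attr(out, "cutoff") <- unname(cutoff)
  class(out) <- c("mediation_screen", class(out))
  out
}
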