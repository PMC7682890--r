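#' Construct a biallelic cross genotype object
#'
#' Holds a strains x markers genotype matrix for a two-parent inbred panel,
#' coded 0 for the N2 allele and 1 for the CB4856 allele (NA = missing),
#' with a physical marker map. Markers must be sorted by (chromosome,
#' position), marker ids unique, and every marker segregating (both
#' alleles observed among non-missing strains).
#'
#' @param geno integer/numeric matrix, strains x markers, values in
#'   `{0, 1, NA}`; rownames are strain ids.
#' @param map data.frame with columns `marker`, `chrom`, `pos` (bp,
#'   1-based), one row per genotype column.
#' @return object of class `cross_genotypes` (list with `geno`, `map`).
#' @export
cross_genotypes <- function(geno, map) {
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno),
            all(c("marker", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) stop("duplicate marker ids")
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    stop("markers must be sorted by (chromosome, position)")
  }
  vals <- unique(as.vector(geno))
  if (!all(vals %in% c(0, 1, NA))) stop("genotypes must be 0/1/NA")
  seg <- apply(geno, 2, function(g) length(unique(g[!is.na(g)])) == 2L)
  if (!all(seg)) {
    stop(sum(!seg), " marker(s) are not segregating (both alleles required)")
  }
  if (is.null(rownames(geno))) rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  colnames(geno) <- map$marker
  structure(list(geno = geno, map = map), class = "cross_genotypes")
}

#' @export
print.cross_genotypes <- function(x, ...) {
  cat(sprintf("cross_genotypes: %d strains x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  invisible(x)
}

# LOD from a Pearson correlation: -n * ln(1 - r^2) / (2 ln 10)
.lod_from_r <- function(r, n, eps = 1e-12) {
  r2 <- pmin(r^2, 1 - eps)
  capped <- r^2 >= 1 - eps
  if (any(capped, na.rm = TRUE)) {
    warning("perfect correlation: LOD capped at (n/2)*log10(1/eps)")
  }
  -n * log(1 - r2) / (2 * log(10))
}

# residualize y on a set of genotype columns (mean-imputed), returning the
# least-squares residual; used for cofactor conditioning
.residualize <- function(y, G) {
  if (is.null(G) || ncol(G) == 0L) return(y)
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  ok <- is.finite(y)
  r <- y
  r[ok] <- residuals(lm(y[ok] ~ G[ok, , drop = FALSE]))
  r
}

#' Single-marker correlation-LOD genome scan
#'
#' For each marker computes the Pearson correlation `r` between the 0/1
#' genotype code and the phenotype over strains non-missing at both, and
#' the LOD score `-n * ln(1 - r^2) / (2 ln 10)`, which equals the
#' likelihood-ratio LOD of the single-marker linear regression. If
#' cofactor markers are supplied the phenotype is first residualized on
#' their genotype columns (marker-regression analogue of adding the QTL to
#' the model as a cofactor). Markers with zero genotype or phenotype
#' variance get LOD 0; a perfect correlation is capped at
#' `(n/2)*log10(1/1e-12)` with a warning.
#'
#' @param cross a [cross_genotypes] object.
#' @param phenotype numeric vector, one value per strain (NA allowed);
#'   if named, aligned to `rownames(cross$geno)`.
#' @param cofactors character vector of marker ids (or integer indices)
#'   used as cofactors; default none.
#' @return data.frame (class `lod_scan`) with `marker`, `chrom`, `pos`,
#'   `r`, `n`, `lod`.
#' @export
lod_scan <- function(cross, phenotype, cofactors = NULL) {
  stopifnot(inherits(cross, "cross_genotypes"))
  y <- .align_phenotype(phenotype, rownames(cross$geno))
  if (sum(is.finite(y)) < 10) stop("need >= 10 strains with phenotype")
  if (sd(y, na.rm = TRUE) == 0 || !is.finite(sd(y, na.rm = TRUE))) {
    warning("constant phenotype: all LOD = 0")
    out <- cbind(cross$map, r = 0, n = sum(is.finite(y)), lod = 0)
    class(out) <- c("lod_scan", class(out))
    return(out)
  }
  cof_idx <- .marker_index(cross, cofactors)
  y <- .residualize(y, cross$geno[, cof_idx, drop = FALSE])

  G <- cross$geno
  ok_y <- is.finite(y)
  if (anyNA(G)) {
    r <- suppressWarnings(as.vector(cor(G, y, use = "pairwise.complete.obs")))
    n <- colSums(!is.na(G) & ok_y)
  } else {
    r <- suppressWarnings(as.vector(cor(G[ok_y, , drop = FALSE], y[ok_y])))
    n <- rep(sum(ok_y), ncol(G))
  }
  r[!is.finite(r)] <- 0  # zero-variance marker (or residual phenotype)
  lod <- .lod_from_r(r, n)
  out <- cbind(cross$map, r = r, n = n, lod = lod)
  rownames(out) <- NULL
  class(out) <- c("lod_scan", class(out))
  out
}

.align_phenotype <- function(phenotype, strains) {
  if (!is.null(names(phenotype))) {
    y <- as.numeric(phenotype[strains])
  } else {
    stopifnot(length(phenotype) == length(strains))
    y <- as.numeric(phenotype)
  }
  y
}

.marker_index <- function(cross, markers) {
  if (is.null(markers) || length(markers) == 0L) return(integer(0))
  if (is.numeric(markers)) return(as.integer(markers))
  idx <- match(markers, cross$map$marker)
  if (anyNA(idx)) stop("unknown marker(s): ",
                       paste(markers[is.na(idx)], collapse = ", "))
  idx
}

#' Permutation genome-wide LOD threshold
#'
#' Permutes the phenotype vector against the whole genotype matrix (so
#' marker-marker linkage is preserved), records the genome-wide maximum
#' LOD of each permutation, and returns the `1 - alpha` empirical quantile
#' of that null distribution -- the LOD threshold controlling the
#' genome-wide error rate at `alpha`. The study protocol is
#' `n_perm = 1000`, `alpha = 0.05`.
#'
#' @inheritParams lod_scan
#' @param n_perm number of permutations (>= 100).
#' @param alpha genome-wide error rate.
#' @param seed integer seed; results are bit-reproducible given
#'   (seed, n_perm).
#' @return numeric threshold with the max-LOD null distribution in the
#'   `"max_lods"` attribute.
#' @export
permutation_threshold <- function(cross, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1, cofactors = NULL) {
  stopifnot(n_perm >= 100)
  y <- .align_phenotype(phenotype, rownames(cross$geno))
  cof_idx <- .marker_index(cross, cofactors)
  y <- .residualize(y, cross$geno[, cof_idx, drop = FALSE])
  ok <- is.finite(y)
  yy <- y[ok]
  G <- cross$geno[ok, , drop = FALSE]
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(b) sample(yy), numeric(length(yy)))
  if (anyNA(G)) {
    R <- suppressWarnings(cor(G, P, use = "pairwise.complete.obs"))
    n <- colSums(!is.na(G))
  } else {
    R <- suppressWarnings(cor(G, P))
    n <- rep(length(yy), ncol(G))
  }
  R[!is.finite(R)] <- 0
  L <- -n * log(1 - pmin(R^2, 1 - 1e-12)) / (2 * log(10))
  max_lods <- apply(L, 2, max)
  thr <- unname(quantile(max_lods, 1 - alpha, type = 7))
  attr(thr, "max_lods") <- max_lods
  thr
}

#' Forward-search QTL mapping
#'
#' Iterative marker-cofactor search: scan the genome, and if the maximum
#' LOD exceeds the permutation threshold, add that marker (leftmost in map
#' order on ties) to the cofactor set and rescan with the phenotype
#' residualized on all cofactors; stop when no marker clears the
#' threshold. The threshold is computed once from the unconditioned
#' phenotype. Detected peaks are annotated with [annotate_peaks].
#'
#' @inheritParams permutation_threshold
#' @param threshold optional pre-computed LOD threshold; when supplied, no
#'   permutations are run.
#' @param max_iter safety cap on iterations (default 20; exceeding it is
#'   an error, indicating a runaway model).
#' @return a `qtl_peaks` data.frame (possibly empty); see
#'   [annotate_peaks]. The threshold used is in the `"threshold"`
#'   attribute.
#' @export
forward_search <- function(cross, phenotype, n_perm = 1000, alpha = 0.05,
                           seed = 1, threshold = NULL, max_iter = 20) {
  y <- .align_phenotype(phenotype, rownames(cross$geno))
  if (is.null(threshold)) {
    if (sd(y, na.rm = TRUE) == 0) {
      threshold <- Inf  # constant phenotype cannot map
    } else {
      threshold <- permutation_threshold(cross, y, n_perm = n_perm,
                                         alpha = alpha, seed = seed)
    }
  }
  cofactors <- integer(0)
  for (it in seq_len(max_iter + 1L)) {
    if (it > max_iter) stop("forward search exceeded ", max_iter,
                            " iterations (runaway model)")
    sc <- suppressWarnings(lod_scan(cross, y, cofactors = cofactors))
    mx <- max(sc$lod)
    if (!is.finite(mx) || mx <= as.numeric(threshold)) break
    cofactors <- c(cofactors, which(sc$lod == mx)[1])  # leftmost on ties
  }
  peaks <- annotate_peaks(cross, y, peak_idx = cofactors)
  attr(peaks, "threshold") <- as.numeric(threshold)
  peaks
}

#' Annotate QTL peaks with intervals and effect sizes
#'
#' For each detected peak, rescans with all *other* peaks as cofactors and
#' takes the 1.5-LOD-drop interval on the peak's chromosome: the outermost
#' contiguous run of markers around the peak whose conditional LOD stays
#' within 1.5 of the peak LOD (`cutoff = chromosomal` behaviour). Effect
#' sizes come from the joint additive model over all peak markers:
#' `variance_explained` is the squared partial correlation of the peak
#' marker given the others (marginal R-squared also reported), the sign of
#' the marker coefficient gives the direction (positive = CB4856 allele
#' raises the trait), and the joint-model R-squared is attached as the
#' `"total_variance_explained"` attribute.
#'
#' @inheritParams lod_scan
#' @param peak_idx integer column indices (or marker ids) of the detected
#'   peak markers.
#' @param drop LOD-drop defining the interval (default 1.5).
#' @return data.frame of class `qtl_peaks`: `marker`, `chrom`, `pos`,
#'   `lod`, `ci_left_marker`, `ci_right_marker`, `ci_left_pos`,
#'   `ci_right_pos`, `variance_explained`, `marginal_r2`, `effect`,
#'   `effect_sign`.
#' @export
annotate_peaks <- function(cross, phenotype, peak_idx, drop = 1.5) {
  y <- .align_phenotype(phenotype, rownames(cross$geno))
  peak_idx <- .marker_index(cross, peak_idx)
  empty <- data.frame(marker = character(), chrom = character(),
                      pos = numeric(), lod = numeric(),
                      ci_left_marker = character(),
                      ci_right_marker = character(),
                      ci_left_pos = numeric(), ci_right_pos = numeric(),
                      variance_explained = numeric(),
                      marginal_r2 = numeric(), effect = numeric(),
                      effect_sign = character(), stringsAsFactors = FALSE)
  class(empty) <- c("qtl_peaks", class(empty))
  if (length(peak_idx) == 0L) return(empty)

  G <- apply(cross$geno[, peak_idx, drop = FALSE], 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE); g
  })
  ok <- is.finite(y)
  joint <- lm(y[ok] ~ G[ok, , drop = FALSE])
  total_r2 <- summary(joint)$r.squared
  betas <- coef(joint)[-1]

  rows <- vector("list", length(peak_idx))
  for (k in seq_along(peak_idx)) {
    i <- peak_idx[k]
    others <- peak_idx[-k]
    csc <- suppressWarnings(lod_scan(cross, y, cofactors = others))
    peak_lod <- csc$lod[i]
    chrom <- cross$map$chrom[i]
    on_chr <- which(cross$map$chrom == chrom)
    above <- csc$lod[on_chr] >= peak_lod - drop
    pos_in <- match(i, on_chr)
    # contiguous run through the peak
    left <- pos_in
    while (left > 1 && above[left - 1]) left <- left - 1
    right <- pos_in
    while (right < length(on_chr) && above[right + 1]) right <- right + 1
    if (left == 1 || right == length(on_chr)) {
      message("peak ", cross$map$marker[i],
              ": interval reaches a chromosome edge (one-sided)")
    }
    li <- on_chr[left]; ri <- on_chr[right]

    # partial correlation of peak marker given other peaks
    g <- G[, k]
    yr <- .residualize(y, if (length(others))
      cross$geno[, others, drop = FALSE] else NULL)
    gr <- if (length(others)) {
      Go <- apply(cross$geno[, others, drop = FALSE], 2, function(z) {
        z[is.na(z)] <- mean(z, na.rm = TRUE); z
      })
      residuals(lm(g ~ Go))
    } else g
    pr <- suppressWarnings(cor(yr[ok], gr[ok]))
    mr <- suppressWarnings(cor(y[ok], g[ok]))

    rows[[k]] <- data.frame(
      marker = cross$map$marker[i], chrom = chrom, pos = cross$map$pos[i],
      lod = peak_lod,
      ci_left_marker = cross$map$marker[li],
      ci_right_marker = cross$map$marker[ri],
      ci_left_pos = cross$map$pos[li], ci_right_pos = cross$map$pos[ri],
      variance_explained = pr^2, marginal_r2 = mr^2,
      effect = unname(betas[k]),
      effect_sign = if (betas[k] >= 0) "CB4856-up" else "N2-up",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "total_variance_explained") <- total_r2
  class(out) <- c("qtl_peaks", class(out))
  out
}

#' Two-dimensional genome scan for interacting loci
#'
#' For every ordered pair of (optionally grid-thinned) markers fits the
#' full two-locus model `y ~ gA + gB + gA:gB` and the additive model
#' `y ~ gA + gB`, each scored against the null as a likelihood-ratio LOD
#' `(n/2) * log10(RSS0 / RSS)`. The interaction LOD is their difference
#' (always >= 0 since the models are nested). An interaction threshold is
#' the 95th percentile of the permuted genome-wide maximum interaction LOD.
#'
#' @inheritParams permutation_threshold
#' @param grid_max thin the marker grid to at most this many markers by
#'   taking every k-th marker (default 1000); set `Inf` for the full grid.
#' @param n_perm interaction-threshold permutations (0 = skip).
#' @return list of class `two_dim_scan`: `pairs` (data.frame with
#'   `marker_a`, `marker_b`, `lod_full`, `lod_additive`,
#'   `lod_interaction`), `chrom_pair_max` (per chromosome-pair maxima of
#'   the interaction LOD), and `interaction_threshold` (NA when
#'   `n_perm = 0`).
#' @export
scan_two <- function(cross, phenotype, grid_max = 1000, n_perm = 0,
                     alpha = 0.05, seed = 1) {
  y <- .align_phenotype(phenotype, rownames(cross$geno))
  ok <- is.finite(y)
  M <- ncol(cross$geno)
  k <- max(1L, ceiling(M / grid_max))
  grid <- seq(1L, M, by = k)
  G <- cross$geno[ok, grid, drop = FALSE]
  G[is.na(G)] <- 0.5  # rare residual missing: mid-imputation on the grid
  yy <- y[ok]
  res <- .scan_two_core(G, yy)
  pairs <- data.frame(
    marker_a = cross$map$marker[grid[res$ia]],
    marker_b = cross$map$marker[grid[res$ib]],
    chrom_a = cross$map$chrom[grid[res$ia]],
    chrom_b = cross$map$chrom[grid[res$ib]],
    lod_full = res$lod_full, lod_additive = res$lod_add,
    lod_interaction = res$lod_full - res$lod_add,
    stringsAsFactors = FALSE
  )
  cp <- aggregate(lod_interaction ~ chrom_a + chrom_b, data = pairs, FUN = max)
  thr <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    mx <- vapply(seq_len(n_perm), function(b) {
      rp <- .scan_two_core(G, sample(yy))
      max(rp$lod_full - rp$lod_add, na.rm = TRUE)
    }, numeric(1))
    thr <- unname(quantile(mx, 1 - alpha, type = 7))
  }
  structure(list(pairs = pairs, chrom_pair_max = cp,
                 interaction_threshold = thr, grid_markers = length(grid)),
            class = "two_dim_scan")
}

# vectorized-by-first-index two-locus scan over all pairs; binary markers,
# closed-form RSS from sufficient statistics
.scan_two_core <- function(G, y) {
  n <- length(y)
  M <- ncol(G)
  sy <- sum(y); syy <- sum(y^2)
  rss0 <- syy - sy^2 / n
  cs <- colSums(G)            # sum g
  gy <- drop(crossprod(G, y)) # sum g*y
  np <- M * (M - 1) / 2
  ia <- rep.int(seq_len(M - 1), times = (M - 1):1)
  ib <- sequence((M - 1):1, from = 2:M)
  lod_full <- lod_add <- rep(NA_real_, np)
  ptr <- 0L
  for (a in seq_len(M - 1)) {
    ga <- G[, a]
    bs <- (a + 1L):M
    Gb <- G[, bs, drop = FALSE]
    nab <- drop(crossprod(Gb, ga))       # sum ga*gb
    gaby <- drop(crossprod(Gb, ga * y))  # sum ga*gb*y
    na_ <- cs[a]; gya <- gy[a]
    nb_ <- cs[bs]; gyb <- gy[bs]
    m <- length(bs)
    rss_add <- rss_full <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      # additive model [1, ga, gb]: 3x3 normal equations
      XtX <- matrix(c(n, na_, nb_[j],
                      na_, na_, nab[j],
                      nb_[j], nab[j], nb_[j]), 3, 3)
      Xty <- c(sy, gya, gyb[j])
      bet <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
      if (is.null(bet)) next  # collinear pair: skipped
      rss_add[j] <- syy - sum(bet * Xty)
      # full model adds ga*gb: 4x4
      XtX4 <- rbind(cbind(XtX, c(nab[j], nab[j], nab[j])),
                    c(nab[j], nab[j], nab[j], nab[j]))
      Xty4 <- c(Xty, gaby[j])
      bet4 <- tryCatch(solve(XtX4, Xty4), error = function(e) NULL)
      rss_full[j] <- if (is.null(bet4)) rss_add[j] else
        syy - sum(bet4 * Xty4)
    }
    rng <- ptr + seq_len(m)
    lod_add[rng] <- (n / 2) * log10(rss0 / pmax(rss_add, 1e-300))
    lod_full[rng] <- (n / 2) * log10(rss0 / pmax(rss_full, 1e-300))
    ptr <- ptr + m
  }
  # numerical guard: nested models, so full >= additive
  lod_full <- pmax(lod_full, lod_add)
  list(ia = ia, ib = ib, lod_full = lod_full, lod_add = lod_add)
}

#' Two-locus interaction ANOVA
#'
#' F-test p-value of the `gA:gB` term in the linear model
#' `y ~ gA + gB + gA:gB`, the direct test of non-additivity between two
#' detected QTL.
#'
#' @param phenotype numeric vector.
#' @param genoA,genoB genotype codes at the two markers (each biallelic
#'   with both classes populated).
#' @return the interaction p-value, with the interaction coefficient in
#'   the `"estimate"` attribute.
#' @export
interaction_anova <- function(phenotype, genoA, genoB) {
  ok <- is.finite(phenotype) & !is.na(genoA) & !is.na(genoB)
  y <- phenotype[ok]; a <- factor(genoA[ok]); b <- factor(genoB[ok])
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("both markers must be biallelic")
  if (any(table(a, b) == 0)) stop("empty genotype cell")
  fit <- lm(y ~ a * b)
  an <- anova(fit)
  p <- an["a:b", "Pr(>F)"]
  est <- coef(fit)[["a1:b1"]]
  attr(p, "estimate") <- est
  p
}
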