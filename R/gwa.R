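#' Construct a wild-isolate variant matrix
#'
#' Biallelic variants for homozygous inbred isolates, dosage-coded 0
#' (reference) / 1 (alternate) with NA for missing calls, plus a variant
#' map. Positions must be sorted within chromosome.
#'
#' @param dosage numeric matrix strains x variants in `{0, 1, NA}`.
#' @param map data.frame with columns `variant`, `chrom`, `pos` (bp,
#'   1-based); `ref`/`alt` optional.
#' @return object of class `variant_matrix` (list with `dosage`, `map`).
#' @export
variant_matrix <- function(dosage, map) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage),
            all(c("variant", "chrom", "pos") %in% names(map)))
  for (ch in unique(map$chrom)) {
    if (is.unsorted(map$pos[map$chrom == ch])) {
      stop("positions not sorted within chromosome ", ch)
    }
  }
  vals <- unique(as.vector(dosage))
  if (!all(vals %in% c(0, 1, NA))) stop("dosage must be 0/1/NA")
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("WI", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- map$variant
  structure(list(dosage = dosage, map = map), class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d strains x %d variants (%d chromosome(s))\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' Read a biallelic variant matrix from a VCF
#'
#' Keeps biallelic SNVs only; multiallelic and indel records are skipped
#' with a logged count. Homozygous-alternate calls become dosage 1,
#' homozygous-reference 0; heterozygous or missing calls become NA (the
#' panel is expected to be inbred).
#'
#' @param path VCF file (plain or bgzipped).
#' @return a [variant_matrix].
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  if (any(!snv)) {
    message(sum(!snv), " non-biallelic-SNV record(s) skipped")
  }
  gt <- vcfR::extract.gt(v)[snv, , drop = FALSE]
  code <- function(x) {
    x <- sub(":.*", "", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0/0", "0|0", "0")] <- 0
    out[x %in% c("1/1", "1|1", "1")] <- 1
    out
  }
  dos <- t(apply(gt, 2, code))
  dimnames(dos) <- list(colnames(gt), NULL)
  map <- data.frame(
    variant = paste0(fix[snv, "CHROM"], ":", fix[snv, "POS"]),
    chrom = fix[snv, "CHROM"], pos = as.numeric(fix[snv, "POS"]),
    ref = ref[snv], alt = alt[snv], stringsAsFactors = FALSE)
  variant_matrix(dos, map)
}

#' Filter variants on missingness and minor allele frequency
#'
#' Default behaviour is strict: any variant with a missing call is
#' dropped, then variants with minor allele frequency below `maf_min`
#' (monomorphic variants included) are dropped.
#'
#' @param vm a [variant_matrix].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum fraction of missing calls tolerated
#'   (default 0 = strict).
#' @return the filtered [variant_matrix]; an empty result is an error.
#' @export
filter_variants <- function(vm, maf_min = 0.05, max_missing = 0) {
  stopifnot(inherits(vm, "variant_matrix"))
  miss <- colMeans(is.na(vm$dosage))
  keep <- miss <= max_missing
  p <- colMeans(vm$dosage, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- keep & !is.na(maf) & maf >= maf_min
  if (!any(keep)) stop("no variants survive filtering")
  variant_matrix(vm$dosage[, keep, drop = FALSE],
                 vm$map[keep, , drop = FALSE])
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_size` variants (per chromosome, advancing
#' by `step`), pairs with squared genotype correlation above `r2_max` are
#' visited in order and one member removed: the variant with the lower
#' minor allele frequency, or the rightmost on a tie. Already-removed
#' variants are ignored in later pairs and windows.
#'
#' @param vm a filtered [variant_matrix].
#' @param r2_max r-squared ceiling (default 0.8).
#' @param window_size variants per window (default 50).
#' @param step window advance in variants (default 10).
#' @return the pruned [variant_matrix].
#' @export
ld_prune <- function(vm, r2_max = 0.8, window_size = 50, step = 10) {
  stopifnot(inherits(vm, "variant_matrix"), window_size >= 2, step >= 1)
  dos <- vm$dosage
  p <- colMeans(dos, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  removed <- rep(FALSE, ncol(dos))
  for (ch in unique(vm$map$chrom)) {
    idx <- which(vm$map$chrom == ch)
    starts <- seq(1L, max(length(idx) - 1L, 1L), by = step)
    for (s in starts) {
      w <- idx[s:min(s + window_size - 1L, length(idx))]
      w <- w[!removed[w]]
      if (length(w) < 2) next
      r2 <- suppressWarnings(cor(dos[, w, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      for (i in seq_len(length(w) - 1L)) {
        if (removed[w[i]]) next
        for (j in (i + 1L):length(w)) {
          if (removed[w[i]]) break
          if (removed[w[j]]) next
          if (!is.na(r2[i, j]) && r2[i, j] > r2_max) {
            # drop the lower-MAF member; rightmost (j) on a tie
            if (maf[w[i]] < maf[w[j]]) {
              removed[w[i]] <- TRUE
            } else {
              removed[w[j]] <- TRUE
            }
          }
        }
      }
    }
  }
  variant_matrix(dos[, !removed, drop = FALSE],
                 vm$map[!removed, , drop = FALSE])
}

#' VanRaden-style additive kinship for inbred dosages
#'
#' Missing calls are imputed to the per-variant mean, dosage columns are
#' centered at their allele frequency, and
#' `A = Z Z' / sum(p * (1 - p))` -- the normalizer is the summed dosage
#' variance for homozygous 0/1 coding, so the expected diagonal is 1.
#'
#' @param vm a filtered [variant_matrix].
#' @return symmetric n x n kinship matrix.
#' @export
kinship_additive <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  dos <- vm$dosage
  p <- colMeans(dos, na.rm = TRUE)
  for (j in which(colSums(is.na(dos)) > 0)) {
    dos[is.na(dos[, j]), j] <- p[j]
  }
  c0 <- sum(p * (1 - p))
  if (c0 == 0) stop("zero-variance variant matrix")
  Z <- sweep(dos, 2, p)
  tcrossprod(Z) / c0
}

#' Effective number of independent tests (Li & Ji)
#'
#' Eigen-decomposes the variant correlation matrix and applies the
#' Li & Ji (2005) estimator: each eigenvalue `l` contributes
#' `I(l >= 1) + (l - floor(l))`; the sum is floored and kept >= 1. For
#' panels with more variants than strains the eigenvalues are obtained
#' from the singular values of the standardized genotype matrix (the
#' remaining eigenvalues are exactly zero and contribute nothing).
#'
#' @param vm a filtered [variant_matrix].
#' @return integer `n_eff` with the eigenvalues in the `"eigenvalues"`
#'   attribute.
#' @export
effective_tests <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  X <- scale(vm$dosage)
  if (anyNA(X)) {
    X[is.na(X)] <- 0  # mean after standardization
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  lam <- sv^2 / (nrow(X) - 1)
  if (all(lam < 1e-12)) stop("degenerate correlation matrix")
  # round at 1e-9 so eigenvalues sitting numerically at an integer (e.g.
  # exactly-orthogonal designs, all lambda = 1) do not lose a whole unit
  # to the fractional-part rule
  lam <- round(lam, 9)
  n_eff <- max(1L, as.integer(floor(sum(ifelse(lam >= 1, 1, 0) +
                                          (lam - floor(lam))) + 1e-8)))
  attr(n_eff, "eigenvalues") <- lam
  n_eff
}

# EMMA-style spectral REML for y = Xb + u + e, u ~ N(0, sg^2 K):
# given eigen(K) = U S U', profiles the REML log-likelihood over
# delta = se^2/sg^2 on the rotated data.
.reml_delta <- function(y, X, eK) {
  n <- length(y)
  q <- ncol(X)
  Uy <- drop(crossprod(eK$vectors, y))
  UX <- crossprod(eK$vectors, X)
  S <- pmax(eK$values, 0)
  nll <- function(logd) {
    d <- exp(logd)
    w <- 1 / (S + d)
    XtWX <- crossprod(UX * w, UX)
    XtWy <- drop(crossprod(UX * w, Uy))
    beta <- solve(XtWX, XtWy)
    r <- Uy - drop(UX %*% beta)
    s2 <- sum(w * r^2) / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(S + d)) + log(det(XtWX)) + (n - q))
  }
  opt <- optimize(nll, interval = c(-10, 10))
  exp(opt$minimum)
}

#' Mixed-model genome-wide association scan
#'
#' Per-variant score test from the linear mixed model
#' `y = mu + x b + u + e` with `u ~ N(0, sg^2 K)`, solved through the
#' spectral decomposition of the kinship matrix. Variance components are
#' estimated once by REML on the null (intercept-only) model and reused
#' for every marker (P3D). The reported score is `-log10 p` of the Wald
#' t-test on the marker coefficient under the rotated generalized
#' least-squares fit. A non-positive-semidefinite kinship is shrunk toward
#' the identity with a warning.
#'
#' @param vm a filtered [variant_matrix].
#' @param kinship n x n kinship matrix (see [kinship_additive]).
#' @param phenotype numeric vector per strain (names aligned to
#'   `rownames(vm$dosage)` if present).
#' @return data.frame of class `gwa_scan`: `variant`, `chrom`, `pos`,
#'   `beta`, `score` (-log10 p), plus the estimated `delta`
#'   (`se^2/sg^2`) as an attribute.
#' @export
mixed_model_scan <- function(vm, kinship, phenotype) {
  stopifnot(inherits(vm, "variant_matrix"))
  y <- .align_phenotype(phenotype, rownames(vm$dosage))
  ok <- is.finite(y)
  y <- y[ok]
  G <- vm$dosage[ok, , drop = FALSE]
  K <- kinship[ok, ok]
  n <- length(y)
  eK <- eigen(K, symmetric = TRUE)
  if (min(eK$values) < -1e-8) {
    warning("kinship not positive semi-definite; shrinking toward identity")
    lam <- -min(eK$values) + 1e-6
    K <- (K + lam * diag(n)) / (1 + lam)
    eK <- eigen(K, symmetric = TRUE)
  }
  X0 <- matrix(1, n, 1)
  delta <- .reml_delta(y, X0, eK)
  w <- 1 / (pmax(eK$values, 0) + delta)
  U <- eK$vectors
  Uy <- drop(crossprod(U, y))
  U1 <- drop(crossprod(U, X0))
  # per-variant missing calls: strain dropped per variant (loop fallback);
  # complete variants go through the vectorized path
  miss <- colSums(is.na(G)) > 0
  UG <- crossprod(U, ifelse(is.na(G), 0, G))
  a11 <- sum(w * U1^2)
  b1 <- sum(w * U1 * Uy)
  syy <- sum(w * Uy^2)
  a12 <- drop(crossprod(UG, w * U1))
  a22 <- colSums(w * UG^2)
  b2 <- drop(crossprod(UG, w * Uy))
  det <- a11 * a22 - a12^2
  beta <- (a11 * b2 - a12 * b1) / det
  beta0 <- (a22 * b1 - a12 * b2) / det
  rss <- syy - beta0 * b1 - beta * b2
  s2 <- rss / (n - 2)
  se <- sqrt(s2 * a11 / det)
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df = n - 2)
  score <- -log10(p)
  bad <- det <= 1e-12 | !is.finite(score)
  score[bad] <- 0; beta[bad] <- NA_real_
  if (any(miss)) {
    for (j in which(miss)) {
      okj <- !is.na(vm$dosage[ok, j])
      if (sum(okj) < 3 || var(vm$dosage[ok, j][okj]) == 0) {
        score[j] <- 0; beta[j] <- NA_real_
        next
      }
      # exact GLS on the strain subset, same delta
      Kj <- K[okj, okj]
      ej <- eigen(Kj, symmetric = TRUE)
      wj <- 1 / (pmax(ej$values, 0) + delta)
      Xj <- cbind(1, vm$dosage[ok, j][okj])
      UXj <- crossprod(ej$vectors, Xj)
      Uyj <- drop(crossprod(ej$vectors, y[okj]))
      XtWX <- crossprod(UXj * wj, UXj)
      XtWy <- drop(crossprod(UXj * wj, Uyj))
      bj <- solve(XtWX, XtWy)
      rj <- Uyj - drop(UXj %*% bj)
      s2j <- sum(wj * rj^2) / (sum(okj) - 2)
      sej <- sqrt(s2j * solve(XtWX)[2, 2])
      score[j] <- -log10(2 * pt(-abs(bj[2] / sej), df = sum(okj) - 2))
      beta[j] <- bj[2]
    }
  }
  out <- cbind(vm$map[, c("variant", "chrom", "pos")],
               beta = beta, score = score)
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  class(out) <- c("gwa_scan", class(out))
  out
}

#' Call significant regions from a GWA scan
#'
#' Thresholds: Bonferroni `-log10(alpha / M)` over all `M` scanned
#' variants, and the more lenient eigenvalue threshold
#' `-log10(alpha / n_eff)` using the effective number of tests. Variants
#' above the eigen threshold are padded by `pad` variants on each side
#' (clipped at chromosome ends) and overlapping padded stretches are
#' merged into regions.
#'
#' @param scan a `gwa_scan` from [mixed_model_scan].
#' @param n_eff effective number of tests (see [effective_tests]).
#' @param alpha significance level (default 0.05).
#' @param pad variants of padding each side (default 150).
#' @return data.frame of regions (`chrom`, `start_bp`, `end_bp`, `n_sig`,
#'   `peak_variant`, `peak_score`), possibly empty, with `eigen_threshold`
#'   and `bonferroni_threshold` attributes.
#' @export
call_regions <- function(scan, n_eff, alpha = 0.05, pad = 150) {
  M <- nrow(scan)
  thr_eigen <- -log10(alpha / n_eff)
  thr_bonf <- -log10(alpha / M)
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_sig = integer(),
                      peak_variant = character(), peak_score = numeric(),
                      stringsAsFactors = FALSE)
  regions <- list()
  for (ch in unique(scan$chrom)) {
    ix <- which(scan$chrom == ch)
    sig <- which(scan$score[ix] > thr_eigen)
    if (!length(sig)) next
    lo <- pmax(sig - pad, 1L)
    hi <- pmin(sig + pad, length(ix))
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    s <- lo[1]; e <- hi[1]
    for (k in seq_along(lo)[-1]) {
      if (lo[k] <= e + 1L) e <- max(e, hi[k]) else {
        regions[[length(regions) + 1L]] <- list(ch = ch, s = s, e = e, ix = ix)
        s <- lo[k]; e <- hi[k]
      }
    }
    regions[[length(regions) + 1L]] <- list(ch = ch, s = s, e = e, ix = ix)
  }
  if (!length(regions)) {
    out <- empty
  } else {
    out <- do.call(rbind, lapply(regions, function(r) {
      span <- r$ix[r$s:r$e]
      pk <- span[which.max(scan$score[span])]
      data.frame(chrom = r$ch, start_bp = scan$pos[r$ix[r$s]],
                 end_bp = scan$pos[r$ix[r$e]],
                 n_sig = sum(scan$score[span] > thr_eigen),
                 peak_variant = scan$variant[pk],
                 peak_score = scan$score[pk], stringsAsFactors = FALSE)
    }))
  }
  attr(out, "eigen_threshold") <- thr_eigen
  attr(out, "bonferroni_threshold") <- thr_bonf
  out
}

#' Phenotypic variance explained by a haplotype class
#'
#' One-way ANOVA of the phenotype on a class label (e.g. functional vs
#' deletion vs other structural variant at a locus): returns the model
#' R-squared and the F-test p-value.
#'
#' @param phenotype numeric vector.
#' @param class_labels factor-like class per strain (>= 2 classes, each
#'   with >= 2 strains).
#' @return list with `r_squared`, `p_value`, `n`, `k` (classes).
#' @export
variance_explained_by_class <- function(phenotype, class_labels) {
  ok <- is.finite(phenotype) & !is.na(class_labels)
  y <- phenotype[ok]; cl <- factor(as.character(class_labels)[ok])
  if (nlevels(cl) < 2) stop("need >= 2 classes")
  if (min(table(cl)) < 2) stop("each class needs >= 2 strains")
  fit <- lm(y ~ cl)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = sm$r.squared,
       p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       n = length(y), k = nlevels(cl))
}
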