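#' Simulate a recombinant inbred advanced intercross genotype panel
#'
#' Each strain's chromosome is generated as a two-state Markov mosaic of the
#' two parental alleles (N2 coded 0, CB4856 coded 1). The switch probability
#' between adjacent markers is the Haldane recombination fraction for their
#' map distance, scaled by an intercross map-expansion factor; the output is
#' fully homozygous, as in an inbred panel. Defaults scale the study design
#' down to a desk-size panel: 6 chromosomes, ~1,000 markers, 250 strains.
#'
#' @param n_strains number of inbred strains.
#' @param n_chrom number of chromosomes.
#' @param markers_per_chrom markers per chromosome.
#' @param chrom_length_morgans genetic length of each chromosome (Morgans).
#' @param chrom_length_bp physical length of each chromosome (bp).
#' @param map_expansion map-expansion factor of the advanced intercross
#'   relative to an F2 (default 2).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a [cross_genotypes] object.
#' @export
simulate_cross <- function(n_strains = 250, n_chrom = 6,
                           markers_per_chrom = 167,
                           chrom_length_morgans = 0.5,
                           chrom_length_bp = 15e6,
                           map_expansion = 2,
                           seed = 1) {
  stopifnot(n_strains >= 2, n_chrom >= 1, markers_per_chrom >= 1)
  set.seed(seed)
  d <- chrom_length_morgans / max(markers_per_chrom - 1, 1)
  # Haldane map function with intercross expansion
  r <- 0.5 * (1 - exp(-2 * d * map_expansion))
  chroms <- as.character(as.roman(seq_len(n_chrom)))
  geno <- matrix(NA_integer_, n_strains, n_chrom * markers_per_chrom)
  for (ci in seq_len(n_chrom)) {
    start0 <- matrix(rbinom(n_strains, 1, 0.5), ncol = 1)
    if (markers_per_chrom > 1) {
      switches <- matrix(rbinom(n_strains * (markers_per_chrom - 1), 1, r),
                         nrow = n_strains)
      cum <- t(apply(cbind(start0, switches), 1, cumsum)) %% 2L
    } else {
      cum <- start0
    }
    geno[, (ci - 1) * markers_per_chrom + seq_len(markers_per_chrom)] <- cum
  }
  pos <- round(seq(1e5, chrom_length_bp, length.out = markers_per_chrom))
  map <- data.frame(
    marker = paste0(rep(chroms, each = markers_per_chrom), "_",
                    rep(seq_len(markers_per_chrom), n_chrom)),
    chrom = rep(chroms, each = markers_per_chrom),
    pos = rep(pos, n_chrom),
    stringsAsFactors = FALSE
  )
  colnames(geno) <- map$marker
  rownames(geno) <- sprintf("QX%03d", seq_len(n_strains))
  cross_genotypes(geno, map)
}

#' Simulate strain phenotypes with planted additive QTL
#'
#' Builds `y = sum(beta_i * g_i) + e` with the effect sizes calibrated so
#' each QTL's expected variance fraction matches the request: at allele
#' frequency `p` the genotype variance is `p(1-p)`, so
#' `beta = sign * sqrt(frac / (p(1-p)))` on a unit-total-variance scale.
#' The residual picks up the remaining `1 - sum(frac)`.
#'
#' @param cross a [cross_genotypes] object.
#' @param qtl data.frame with columns `marker` (marker id or column index),
#'   `frac` (phenotypic variance fraction in `[0,1]`) and `sign` (+1/-1).
#'   Use `NULL` or zero rows for a pure-noise phenotype.
#' @param seed integer seed.
#' @return named numeric vector of strain phenotypes, with a `truth`
#'   attribute recording markers, effects and fractions.
#' @export
simulate_phenotypes <- function(cross, qtl = NULL, seed = 1) {
  stopifnot(inherits(cross, "cross_genotypes"))
  set.seed(seed)
  n <- nrow(cross$geno)
  if (is.null(qtl) || nrow(qtl) == 0L) {
    y <- rnorm(n)
    names(y) <- rownames(cross$geno)
    attr(y, "truth") <- data.frame(marker = character(), frac = numeric(),
                                   beta = numeric())
    return(y)
  }
  idx <- if (is.numeric(qtl$marker)) as.integer(qtl$marker) else
    match(as.character(qtl$marker), cross$map$marker)
  if (anyNA(idx)) stop("qtl marker not found in cross")
  if (sum(qtl$frac) > 1) stop("qtl variance fractions sum > 1")
  g <- cross$geno[, idx, drop = FALSE]
  p <- colMeans(g)
  beta <- qtl$sign * sqrt(qtl$frac / (p * (1 - p)))
  y <- drop(g %*% beta) + rnorm(n, sd = sqrt(1 - sum(qtl$frac)))
  names(y) <- rownames(cross$geno)
  attr(y, "truth") <- data.frame(marker = cross$map$marker[idx],
                                 index = idx, frac = qtl$frac, beta = beta)
  y
}

#' Simulate per-animal sorter records
#'
#' Emulates large-particle-sorter output: per-animal length (TOF) and
#' optical density (EXT) drawn lognormally around strain-and-condition
#' means, with multiplicative assay offsets and optional injected outlier
#' wells (all animals in an outlier well shifted by a common factor).
#'
#' @param strain_effects named numeric vector of per-strain log-scale trait
#'   effects (e.g. planted zinc sensitivities).
#' @param n_wells wells per strain per condition per assay.
#' @param animals_per_well expected animals per well (Poisson, floored at 1).
#' @param conditions character vector of condition labels; the first is
#'   treated as the control when downstream stages need one.
#' @param n_assays number of assay (experiment day) levels.
#' @param assay_sd SD of log-scale assay offsets.
#' @param noise_sd per-animal lognormal noise SD.
#' @param condition_shift log-scale shift applied to non-control conditions
#'   on top of `strain_effects` (strain effects only act in non-control
#'   conditions, emulating a drug-specific response).
#' @param outlier_frac fraction of wells shifted to be outliers.
#' @param outlier_shift log-scale magnitude of the outlier shift.
#' @param parents_sorted number of parents sorted per well.
#' @param seed integer seed.
#' @return data.frame of animal records (strain, assay, plate, well,
#'   condition, tof, ext) with a `truth` attribute marking outlier wells.
#' @export
simulate_sorter_records <- function(strain_effects, n_wells = 3,
                                    animals_per_well = 30,
                                    conditions = c("control", "zinc-500uM"),
                                    n_assays = 2, assay_sd = 0.1,
                                    noise_sd = 0.15,
                                    condition_shift = -0.3,
                                    outlier_frac = 0, outlier_shift = 1.5,
                                    parents_sorted = 3, seed = 1) {
  stopifnot(!is.null(names(strain_effects)), n_wells >= 1)
  set.seed(seed)
  strains <- names(strain_effects)
  assay_off <- rnorm(n_assays, sd = assay_sd)
  grid <- expand.grid(strain = strains, condition = conditions,
                      assay = paste0("a", seq_len(n_assays)),
                      wrep = seq_len(n_wells),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$well <- sprintf("%s_%s_%s_w%d", grid$strain, grid$condition,
                       grid$assay, grid$wrep)
  grid$plate <- paste0("p_", grid$assay)
  n_out <- round(outlier_frac * nrow(grid))
  out_idx <- if (n_out > 0) sample.int(nrow(grid), n_out) else integer(0)
  grid$is_outlier <- seq_len(nrow(grid)) %in% out_idx
  rec <- vector("list", nrow(grid))
  base_tof <- log(250)
  base_ext <- log(60)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    drug <- g$condition != conditions[1]
    mu <- assay_off[match(g$assay, paste0("a", seq_len(n_assays)))] +
      if (drug) condition_shift + strain_effects[[g$strain]] else 0
    if (g$is_outlier) mu <- mu + sample(c(-1, 1), 1) * outlier_shift
    k <- max(1L, rpois(1, animals_per_well))
    tof <- rlnorm(k, base_tof + mu, noise_sd)
    ext <- rlnorm(k, base_ext + mu, noise_sd)
    rec[[i]] <- data.frame(strain = g$strain, assay = g$assay,
                           plate = g$plate, well = g$well,
                           condition = g$condition, tof = tof, ext = ext,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  attr(records, "truth") <- grid[, c("strain", "assay", "well", "condition",
                                     "is_outlier")]
  attr(records, "parents_sorted") <- parents_sorted
  records
}

#' Simulate expression traits with a planted mediator
#'
#' One mediator probe follows `m = a*g + e` and the phenotype
#' `y = b*m + c*g + e'`, where `g` is the genotype at a chosen marker;
#' decoy probes are independent noise. With `c = 0` the QTL effect on the
#' phenotype is fully mediated.
#'
#' @param cross a [cross_genotypes] object.
#' @param marker marker id or column index of the eQTL/QTL.
#' @param a,b,c path coefficients (genotype->mediator, mediator->phenotype,
#'   direct genotype->phenotype).
#' @param noise_m,noise_y residual SDs of the mediator and outcome models.
#' @param n_decoys number of noise probes.
#' @param seed integer seed.
#' @return list with `expression` (probe x strain matrix), `phenotype`
#'   (named vector), `marker`, and `truth`.
#' @export
simulate_expression <- function(cross, marker, a = 1, b = 1, c = 0,
                                noise_m = 0.5, noise_y = 0.5,
                                n_decoys = 16, seed = 1) {
  stopifnot(inherits(cross, "cross_genotypes"))
  set.seed(seed)
  idx <- if (is.numeric(marker)) as.integer(marker) else
    match(as.character(marker), cross$map$marker)
  if (is.na(idx)) stop("marker not found in cross")
  g <- cross$geno[, idx]
  n <- length(g)
  m <- a * g + rnorm(n, sd = noise_m)
  y <- b * m + c * g + rnorm(n, sd = noise_y)
  probes <- rbind(mediator = m,
                  matrix(rnorm(n_decoys * n), n_decoys, n,
                         dimnames = list(paste0("decoy", seq_len(n_decoys)),
                                         NULL)))
  colnames(probes) <- rownames(cross$geno)
  names(y) <- rownames(cross$geno)
  list(expression = probes, phenotype = y,
       marker = cross$map$marker[idx],
       truth = list(mediator = "mediator", a = a, b = b, c = c,
                    acme = a * b))
}

#' Simulate a structured wild-isolate panel
#'
#' Variants get ancestral frequencies uniform on (0.1, 0.9), diverged
#' between subpopulations by a Balding-Nichols draw at the requested Fst;
#' homozygous inbred dosages are Bernoulli within subpopulation. The
#' phenotype is a polygenic background (independent per-variant effects,
#' so its covariance follows the realized kinship) plus an optional causal
#' haplotype-class effect calibrated to a target variance fraction, plus
#' residual noise.
#'
#' @param n_strains isolates (default 81, the study's panel size).
#' @param n_variants biallelic variants.
#' @param n_subpop subpopulations.
#' @param divergence Fst-like divergence between subpopulations.
#' @param causal_frac phenotypic variance fraction of the causal class
#'   (default 0.115, the study's *sqst-5* design point); 0 plants no signal.
#' @param polygenic_frac variance fraction of the polygenic background.
#' @param n_chrom chromosomes the variants are spread over.
#' @param seed integer seed.
#' @return list with `panel` (a [variant_matrix]), `phenotype` (named
#'   vector), `classes` (factor of haplotype classes), and `truth`.
#' @export
simulate_wild_panel <- function(n_strains = 81, n_variants = 2000,
                                n_subpop = 2, divergence = 0.2,
                                causal_frac = 0.115, polygenic_frac = 0.3,
                                n_chrom = 6, seed = 1) {
  stopifnot(causal_frac + polygenic_frac <= 1)
  set.seed(seed)
  subpop <- rep_len(seq_len(n_subpop), n_strains)
  p0 <- runif(n_variants, 0.1, 0.9)
  fr <- matrix(0, n_subpop, n_variants)
  if (divergence > 0) {
    shp <- (1 - divergence) / divergence
    for (s in seq_len(n_subpop)) {
      fr[s, ] <- rbeta(n_variants, p0 * shp, (1 - p0) * shp)
    }
  } else {
    fr <- matrix(rep(p0, each = n_subpop), n_subpop, n_variants)
  }
  dos <- matrix(rbinom(n_strains * n_variants, 1, fr[subpop, ]),
                n_strains, n_variants)
  chroms <- as.character(as.roman(seq_len(n_chrom)))
  per <- ceiling(n_variants / n_chrom)
  chrom <- rep(chroms, each = per)[seq_len(n_variants)]
  pos <- unlist(lapply(split(seq_len(n_variants), factor(chrom, chroms)),
                       function(ix) sort(sample.int(2e7, length(ix)))),
                use.names = FALSE)
  map <- data.frame(variant = paste0(chrom, ":", pos), chrom = chrom,
                    pos = pos, ref = "A", alt = "T",
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$variant
  rownames(dos) <- sprintf("WI%03d", seq_len(n_strains))
  vm <- variant_matrix(dos, map)

  # causal haplotype class from a common variant's dosage
  mafs <- pmin(colMeans(dos), 1 - colMeans(dos))
  causal_idx <- which.max(mafs)  # most balanced variant: stable class sizes
  classes <- factor(ifelse(dos[, causal_idx] == 1, "deletion", "functional"))
  g <- dos[, causal_idx]
  cl_eff <- if (causal_frac > 0) {
    (g - mean(g)) / sd(g) * sqrt(causal_frac)
  } else rep(0, n_strains)

  # polygenic background: independent effects over centered dosages. In a
  # structured panel this background lies largely along the subpopulation
  # axis, so when a causal class is planted it is orthogonalized against
  # the causal genotype -- otherwise the realized class variance fraction
  # would be confounded with the background rather than equal to the spec.
  Z <- scale(dos, center = TRUE, scale = FALSE)
  u <- rnorm(n_variants)
  poly <- drop(Z %*% u)
  if (causal_frac > 0 && sd(poly) > 0) {
    poly <- residuals(lm(poly ~ g))
  }
  poly <- if (sd(poly) > 0) poly / sd(poly) * sqrt(polygenic_frac) else poly

  y <- poly + cl_eff +
    rnorm(n_strains, sd = sqrt(1 - polygenic_frac - causal_frac))
  names(y) <- rownames(dos)
  list(panel = vm, phenotype = y, classes = classes, subpop = subpop,
       truth = list(causal_variant = map$variant[causal_idx],
                    causal_index = causal_idx, causal_frac = causal_frac,
                    polygenic_frac = polygenic_frac))
}

#' Simulate neutral haplotypes under the standard coalescent
#'
#' Draws a Kingman genealogy for `n` haploid samples, places
#' `Poisson(theta/2 * branch length)` infinite-sites mutations on it, and
#' assigns each mutation a uniform position on the region. Used to
#' calibrate Tajima's D against its neutral expectation.
#'
#' @param n sample size (haplotypes), >= 2.
#' @param theta population mutation rate (per region).
#' @param region_length bp length over which positions are drawn.
#' @param seed integer seed.
#' @return list with `haplotypes` (n x S 0/1 matrix), `positions` (bp),
#'   and `tmrca` (coalescent time units).
#' @export
simulate_neutral_haplotypes <- function(n, theta, region_length = 1e4,
                                        seed = 1) {
  stopifnot(n >= 2, theta >= 0)
  set.seed(seed)
  # active lineages as lists of descendant leaf indices
  lineages <- as.list(seq_len(n))
  # accumulated exposure time of each active lineage
  exposure <- list()
  tmrca <- 0
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t <- rexp(1, rate = k * (k - 1) / 2)
    tmrca <- tmrca + t
    for (ln in lineages) {
      exposure[[length(exposure) + 1L]] <- list(leaves = ln, time = t)
    }
    pair <- sample.int(k, 2)
    merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages <- c(lineages[-pair], list(merged))
  }
  total_len <- sum(vapply(exposure, `[[`, numeric(1), "time"))
  n_mut <- rpois(1, theta / 2 * total_len)
  hap <- matrix(0L, n, max(n_mut, 0))
  if (n_mut > 0) {
    w <- vapply(exposure, `[[`, numeric(1), "time")
    seg <- sample.int(length(exposure), n_mut, replace = TRUE, prob = w)
    for (j in seq_len(n_mut)) {
      hap[exposure[[seg[j]]]$leaves, j] <- 1L
    }
    pos <- sort(runif(n_mut, 1, region_length))
    # drop mutations fixed in the sample (root-edge artifacts cannot occur
    # here, but guard anyway) and order columns by position
    hap <- hap[, order(pos), drop = FALSE]
    pos <- sort(pos)
  } else {
    pos <- numeric(0)
  }
  rownames(hap) <- paste0("h", seq_len(n))
  list(haplotypes = hap, positions = pos, tmrca = tmrca)
}
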