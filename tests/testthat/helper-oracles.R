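# Independent oracles, deliberately coded differently from the package
# implementations they check.

# likelihood-ratio LOD of the single-marker regression, via lm()
lr_lod_oracle <- function(g, y) {
  ok <- is.finite(g) & is.finite(y)
  g <- g[ok]; y <- y[ok]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(resid(lm(y ~ g))^2)
  (n / 2) * log10(rss0 / rss1)
}

# single-pass Tajima's D over a complete 0/1 haplotype matrix: pairwise
# differences accumulated pair by pair, constants recomputed inline
tajima_oracle <- function(hap) {
  n <- nrow(hap)
  seg <- apply(hap, 2, function(s) length(unique(s)) == 2L)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  h <- hap[, seg, drop = FALSE]
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(h[i, ] != h[j, ])
  }
  pi <- tot / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# brute-force sliding-window LD pruner mirroring the documented rule,
# written as an explicit walk over a per-chromosome index queue
ld_prune_oracle <- function(vm, r2_max, window_size, step) {
  dos <- vm$dosage
  p <- colMeans(dos, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  alive <- rep(TRUE, ncol(dos))
  for (ch in unique(vm$map$chrom)) {
    idx <- which(vm$map$chrom == ch)
    s <- 1L
    while (s <= max(length(idx) - 1L, 1L)) {
      win <- idx[seq(s, min(s + window_size - 1L, length(idx)))]
      win <- win[alive[win]]
      if (length(win) >= 2) {
        for (i in seq_len(length(win) - 1L)) {
          for (j in seq(i + 1L, length(win))) {
            a <- win[i]; b <- win[j]
            if (!alive[a]) break
            if (!alive[b]) next
            r <- suppressWarnings(cor(dos[, a], dos[, b],
                                      use = "pairwise.complete.obs"))
            if (!is.na(r) && r^2 > r2_max) {
              if (maf[a] < maf[b]) alive[a] <- FALSE else alive[b] <- FALSE
            }
          }
        }
      }
      if (s + step > max(length(idx) - 1L, 1L)) break
      s <- s + step
    }
  }
  vm$map$variant[alive]
}

# build a variant matrix whose Hamming distances realize a given tree
# exactly: each edge of the (rooted, bifurcating) tree contributes
# `len` unique sites carried by all leaves below it
tree_to_variants <- function(tree) {
  n <- length(tree$tip.label)
  cols <- list()
  for (e in seq_len(nrow(tree$edge))) {
    len <- round(tree$edge.length[e])
    if (len == 0) next
    below <- phangorn::Descendants(tree, tree$edge[e, 2], "tips")[[1]]
    col <- rep(0L, n)
    col[below] <- 1L
    cols <- c(cols, replicate(len, col, simplify = FALSE))
  }
  m <- do.call(cbind, cols)
  rownames(m) <- tree$tip.label
  m
}

rand_cross_small <- function(n = 60, mpc = 20, seed = 1) {
  simulate_cross(n_strains = n, n_chrom = 3, markers_per_chrom = mpc,
                 seed = seed)
}
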