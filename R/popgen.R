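#' Tajima's (1989) constants for a sample of n sequences
#'
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1), and the derived
#' `b1, b2, c1, c2, e1, e2` used in the variance of D.
#'
#' @param n number of sampled haplotypes (>= 2).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# S, pi and D for one haplotype block (columns = sites, 0/1, complete)
.tajima_block <- function(hap) {
  n <- nrow(hap)
  if (ncol(hap) == 0L) {
    return(list(S = 0L, pi = 0, D = NA_real_))
  }
  ones <- colSums(hap)
  seg <- ones > 0 & ones < n
  S <- sum(seg)
  if (S == 0L) return(list(S = 0L, pi = 0, D = NA_real_))
  k1 <- ones[seg]
  pi <- sum(k1 * (n - k1)) / (n * (n - 1) / 2)
  cn <- tajima_constants(n)
  vd <- cn$e1 * S + cn$e2 * S * (S - 1)
  D <- (pi - S / cn$a1) / sqrt(vd)
  list(S = S, pi = pi, D = D)
}

#' Sliding-window Tajima's D
#'
#' Computes `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` in physical
#' windows across a region: windows of `window` bp advance by `step` bp,
#' left-aligned at the region start and right-truncated at its end.
#' Windows with no segregating sites yield a missing D (not 0). Sites
#' with any missing call are excluded (with a message). The study
#' configuration is 10 kb windows sliding by 1 kb.
#'
#' @param haplotypes a [variant_matrix], or a plain 0/1 matrix (strains x
#'   sites) accompanied by `positions`.
#' @param region region string `"chrom:start-end"` or list from
#'   [parse_region]; required for a [variant_matrix], optional otherwise
#'   (defaults to the span of the positions).
#' @param positions site positions in bp (only when `haplotypes` is a
#'   plain matrix).
#' @param window,step window size and slide in bp (defaults 10000, 1000).
#' @return data.frame with `chrom`, `start`, `end`, `n_sites`, `S`, `pi`,
#'   `D`.
#' @export
tajimas_d_windows <- function(haplotypes, region = NULL, positions = NULL,
                              window = 10000, step = 1000) {
  if (inherits(haplotypes, "variant_matrix")) {
    if (is.null(region)) stop("region required for a variant_matrix")
    reg <- if (is.character(region)) parse_region(region) else region
    on_reg <- haplotypes$map$chrom == reg$chrom &
      haplotypes$map$pos >= reg$start & haplotypes$map$pos <= reg$end
    hap <- haplotypes$dosage[, on_reg, drop = FALSE]
    pos <- haplotypes$map$pos[on_reg]
    chrom <- reg$chrom
  } else {
    hap <- haplotypes
    pos <- positions %||% seq_len(ncol(hap))
    if (is.null(region)) {
      reg <- list(chrom = "region", start = min(pos, 1), end = max(pos))
    } else {
      reg <- if (is.character(region)) parse_region(region) else region
    }
    chrom <- reg$chrom
  }
  stopifnot(nrow(hap) >= 4)
  if (anyNA(hap)) {
    drop <- colSums(is.na(hap)) > 0
    message(sum(drop), " site(s) with missing calls excluded")
    hap <- hap[, !drop, drop = FALSE]
    pos <- pos[!drop]
  }
  starts <- seq(reg$start, reg$end, by = step)
  starts <- starts[starts <= reg$end]
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1, reg$end)
    in_w <- pos >= s & pos <= e
    tb <- .tajima_block(hap[, in_w, drop = FALSE])
    data.frame(chrom = chrom, start = s, end = e, n_sites = sum(in_w),
               S = tb$S, pi = tb$pi, D = tb$D, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tajima's D for a whole region (single window)
#'
#' @inheritParams tajimas_d_windows
#' @return list with `S`, `pi`, `D`.
#' @export
tajimas_d <- function(haplotypes) {
  hap <- if (inherits(haplotypes, "variant_matrix")) haplotypes$dosage
  else haplotypes
  stopifnot(nrow(hap) >= 4)
  if (anyNA(hap)) hap <- hap[, colSums(is.na(hap)) == 0, drop = FALSE]
  .tajima_block(hap)
}

#' Neighbor-joining strain tree from a variant matrix
#'
#' Pairwise distances are the proportion of differing calls over shared
#' non-missing sites (Hamming proportion; for equal-length variant
#' strings this equals an alignment-based p-distance). The tree is built
#' by standard neighbor joining and midpoint rooted. Negative branch
#' lengths produced by NJ are clamped to zero with the deficit
#' transferred to the sibling edge, preserving the path length through
#' their parent.
#'
#' @param vm a [variant_matrix] (optionally already restricted to a
#'   region), or a plain 0/1 matrix strains x sites.
#' @param region optional region string to subset a [variant_matrix].
#' @return a midpoint-rooted `phylo` object (see [ape::read.tree]);
#'   write it with [ape::write.tree].
#' @export
nj_tree <- function(vm, region = NULL) {
  if (inherits(vm, "variant_matrix")) {
    dos <- vm$dosage
    if (!is.null(region)) {
      reg <- if (is.character(region)) parse_region(region) else region
      on_reg <- vm$map$chrom == reg$chrom & vm$map$pos >= reg$start &
        vm$map$pos <= reg$end
      dos <- dos[, on_reg, drop = FALSE]
    }
  } else {
    dos <- vm
  }
  n <- nrow(dos)
  if (n < 3) stop("need >= 3 strains")
  D <- matrix(0, n, n, dimnames = list(rownames(dos), rownames(dos)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(dos[i, ]) & !is.na(dos[j, ])
      if (!any(shared)) stop("strains ", rownames(dos)[i], " and ",
                             rownames(dos)[j], " share no genotyped sites")
      D[i, j] <- D[j, i] <- mean(dos[i, shared] != dos[j, shared])
    }
  }
  tr <- ape::nj(as.dist(D))
  tr <- .fix_negative_edges(tr)
  tr <- phangorn::midpoint(tr)
  # midpoint arithmetic can leave -0-scale dust on an edge
  tr$edge.length[tr$edge.length < 0 & tr$edge.length > -1e-12] <- 0
  tr
}

# clamp negative NJ edges to 0, moving the deficit onto the sibling edge
.fix_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- max(tr$edge.length[sibs[1]] + deficit, 0)
    }
  }
  tr
}
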