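#' @name trait_table
#' @title Per-well trait tables
#'
#' @description
#' The sorter pipeline carries a data.frame of per-well traits through five
#' stages, in order: `raw` -> `assay_regressed` -> `pruned` ->
#' `control_regressed` -> `unit_normalized`. The current stage is stored in
#' the `"stage"` attribute and checked at each transition. Trait columns
#' are `median.TOF`, `median.EXT`, `median.norm.EXT` and `norm.n`.
NULL

.trait_cols <- c("median.TOF", "median.EXT", "median.norm.EXT", "norm.n")
.stage_order <- c("raw", "assay_regressed", "pruned", "control_regressed",
                  "unit_normalized")

.set_stage <- function(tab, stage) {
  attr(tab, "stage") <- stage
  class(tab) <- unique(c("trait_table", class(tab)))
  tab
}

#' Stage of a trait table
#' @param tab a trait table.
#' @return the processing-stage label.
#' @export
table_stage <- function(tab) attr(tab, "stage")

#' Label a data.frame as a trait table at a given stage
#'
#' For assembling trait tables from external sources (or fixtures) at a
#' known processing stage.
#'
#' @param df data.frame keyed by (strain, assay, well, condition) with
#'   trait columns.
#' @param stage one of `raw`, `assay_regressed`, `pruned`,
#'   `control_regressed`, `unit_normalized`.
#' @return the trait table.
#' @export
as_trait_table <- function(df, stage = "raw") {
  stopifnot(stage %in% .stage_order)
  .set_stage(df, stage)
}

.check_stage <- function(tab, expected) {
  st <- table_stage(tab)
  if (is.null(st) || !st %in% expected) {
    stop("trait table at stage '", st %||% "<none>", "', expected ",
         paste(expected, collapse = " or "))
  }
  invisible(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize per-animal sorter records into per-well traits
#'
#' Collapses animal-level length (TOF) and optical density (EXT) records to
#' the four per-well traits: `median.TOF`, `median.EXT`, `median.norm.EXT`
#' (the median of per-animal EXT/TOF ratios, so that one oversized animal
#' cannot distort the density-per-length summary) and `norm.n` (animals per
#' well divided by the number of parents originally sorted, an approximate
#' brood size).
#'
#' Records with non-positive TOF are rejected with a warning; wells present
#' in `records` with no surviving animals yield a row with `n_animals = 0`
#' and missing trait values.
#'
#' @param records data.frame with columns `strain`, `assay`, `plate`,
#'   `well`, `condition`, `tof` (> 0), `ext` (>= 0).
#' @param parents_sorted parents sorted per well: a single count (> 0)
#'   recycled to every well, or a data.frame with columns `well` and
#'   `parents_sorted`.
#' @return a `raw`-stage trait table keyed by
#'   (strain, assay, plate, well, condition).
#' @export
summarize_wells <- function(records, parents_sorted = 3) {
  need <- c("strain", "assay", "plate", "well", "condition", "tof", "ext")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !is.finite(records$tof) | records$tof <= 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive TOF rejected")
    records <- records[!bad, , drop = FALSE]
  }
  key <- c("strain", "assay", "plate", "well", "condition")
  grp <- interaction(records[key], drop = TRUE, lex.order = TRUE)
  first <- records[!duplicated(grp), key, drop = FALSE]
  first <- first[order(unique(grp)), , drop = FALSE]
  agg <- function(f) {
    as.numeric(tapply(seq_len(nrow(records)), grp, f))
  }
  out <- first
  out$n_animals <- agg(length)
  out$median.TOF <- agg(function(i) median(records$tof[i]))
  out$median.EXT <- agg(function(i) median(records$ext[i]))
  out$median.norm.EXT <- agg(function(i)
    median(records$ext[i] / records$tof[i]))
  if (is.data.frame(parents_sorted)) {
    ps <- parents_sorted$parents_sorted[match(out$well, parents_sorted$well)]
    if (anyNA(ps)) stop("parents_sorted missing for some wells")
  } else {
    ps <- rep_len(parents_sorted, nrow(out))
  }
  if (any(ps <= 0)) stop("parents_sorted must be > 0")
  out$parents_sorted <- ps
  out$norm.n <- out$n_animals / ps
  rownames(out) <- NULL
  .set_stage(out, "raw")
}

#' Remove among-assay variation by fixed-effect regression
#'
#' Replaces each trait with the residuals of a linear model of the trait on
#' the assay label, so systematic day-to-day differences among assay runs
#' do not masquerade as strain effects. With a single assay level this is
#' plain mean-centering; an assay level with one well gets residual 0.
#'
#' @param tab a `raw`-stage trait table.
#' @return an `assay_regressed` trait table.
#' @export
regress_assay <- function(tab) {
  .check_stage(tab, "raw")
  for (tr in intersect(.trait_cols, names(tab))) {
    v <- tab[[tr]]
    ok <- is.finite(v)
    if (sum(ok) == 0) next
    a <- factor(tab$assay[ok])
    res <- v
    res[ok] <- v[ok] - ave(v[ok], a)
    singles <- names(which(table(a) == 1))
    if (length(singles)) {
      message("assay level(s) with a single well get residual 0: ",
              paste(singles, collapse = ", "))
    }
    tab[[tr]] <- res
  }
  .set_stage(tab, "assay_regressed")
}

#' Prune outlier wells
#'
#' Two policies, per trait, removing whole rows (a well flagged on any
#' trait is dropped):
#' \describe{
#'   \item{`sd`}{for highly replicated designs: within each
#'     (condition, strain) group, wells beyond two standard deviations of
#'     the group mean are removed. Groups with fewer than 3 wells are
#'     skipped.}
#'   \item{`bamf`}{for low-replication designs: within each condition
#'     (across strains), fences are `Q1 - 2*IQR` and `Q3 + 2*IQR`
#'     (type-7 quantiles). Wells outside the fences are removed only when
#'     fewer than 5% of the distinct strains have any well outside;
#'     otherwise the spread is treated as real strain variation and nothing
#'     is removed for that trait/condition.}
#' }
#' Bounds are computed once from the full group and applied in a single
#' pass (no re-estimation after removal).
#'
#' @param tab an `assay_regressed` trait table.
#' @param method `"sd"` or `"bamf"`.
#' @param strain_frac_max the bamf strain-fraction exemption (default 0.05).
#' @return a `pruned` trait table; removed rows are recorded in the
#'   `"removed"` attribute with the trait that flagged them.
#' @export
prune_wells <- function(tab, method = c("bamf", "sd"),
                        strain_frac_max = 0.05) {
  method <- match.arg(method)
  .check_stage(tab, "assay_regressed")
  traits <- intersect(.trait_cols, names(tab))
  drop_flag <- matrix(FALSE, nrow(tab), length(traits),
                      dimnames = list(NULL, traits))
  if (method == "sd") {
    grp <- interaction(tab$condition, tab$strain, drop = TRUE)
    for (g in levels(grp)) {
      ix <- which(grp == g)
      if (length(ix) < 3) {
        message("group '", g, "' has < 3 wells; sd pruning skipped")
        next
      }
      for (tr in traits) {
        v <- tab[[tr]][ix]
        m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
        if (!is.finite(s) || s == 0) next
        drop_flag[ix, tr] <- is.finite(v) & abs(v - m) > 2 * s
      }
    }
  } else {
    for (cond in unique(tab$condition)) {
      ix <- which(tab$condition == cond)
      if (length(ix) < 3) {
        message("condition '", cond, "' has < 3 wells; bamf pruning skipped")
        next
      }
      for (tr in traits) {
        v <- tab[[tr]][ix]
        q <- quantile(v, c(0.25, 0.75), na.rm = TRUE, type = 7)
        iqr <- q[2] - q[1]
        out <- is.finite(v) & (v < q[1] - 2 * iqr | v > q[2] + 2 * iqr)
        strains <- tab$strain[ix]
        frac_out <- length(unique(strains[out])) / length(unique(strains))
        if (frac_out >= strain_frac_max) {
          message("trait ", tr, ", condition '", cond, "': ",
                  round(100 * frac_out, 1),
                  "% of strains outside fences; no removal")
          next
        }
        drop_flag[ix, tr] <- out
      }
    }
  }
  drop <- rowSums(drop_flag) > 0
  removed <- tab[drop, , drop = FALSE]
  if (nrow(removed)) {
    removed$flagged_trait <- apply(drop_flag[drop, , drop = FALSE], 1,
                                   function(z) paste(traits[z], collapse = ";"))
  }
  out <- .set_stage(tab[!drop, , drop = FALSE], "pruned")
  attr(out, "removed") <- removed
  out
}

#' Regress drug wells on per-strain control means
#'
#' For each trait, fits the drug-condition values on the strain's mean
#' control (water) value across all strains with a single linear model and
#' returns the residuals; these residuals are the drug-response phenotype
#' used by all downstream mapping. Strains absent from the control table
#' are dropped with a warning.
#'
#' @param drug_tab,control_tab `pruned`-stage trait tables for the drug and
#'   control conditions.
#' @return a `control_regressed` trait table with the drug rows.
#' @export
regress_control <- function(drug_tab, control_tab) {
  .check_stage(drug_tab, "pruned")
  .check_stage(control_tab, "pruned")
  missing_strains <- setdiff(drug_tab$strain, control_tab$strain)
  if (length(missing_strains)) {
    warning("strain(s) missing from control dropped: ",
            paste(missing_strains, collapse = ", "))
    drug_tab <- drug_tab[!drug_tab$strain %in% missing_strains, ,
                         drop = FALSE]
  }
  for (tr in intersect(.trait_cols, names(drug_tab))) {
    ctrl_mean <- tapply(control_tab[[tr]], control_tab$strain, mean,
                        na.rm = TRUE)
    x <- as.numeric(ctrl_mean[drug_tab$strain])
    y <- drug_tab[[tr]]
    ok <- is.finite(x) & is.finite(y)
    res <- rep(NA_real_, length(y))
    if (sum(ok) >= 2 && sd(x[ok]) > 0) {
      fit <- lm(y[ok] ~ x[ok])
      res[ok] <- residuals(fit)
    } else if (sum(ok) >= 1) {
      res[ok] <- y[ok] - mean(y[ok])  # constant control: intercept only
    }
    drug_tab[[tr]] <- res
  }
  .set_stage(drug_tab, "control_regressed")
}

#' Scale a trait vector to the unit interval
#'
#' Affine map sending the smallest value to 0 and the largest to 1 (used
#' for plotting-style comparisons of residual traits).
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return rescaled vector in `[0, 1]`.
#' @export
normalize_unit <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) stop("constant vector: unit scaling undefined")
  (values - min(v)) / (max(v) - min(v))
}

#' Select the dose that best separates strains
#'
#' At each candidate dose, decomposes each trait one-way by strain and
#' forms the ratio of between-strain to within-strain mean squares; the
#' returned dose maximizes the mean of this ratio over traits, i.e. it
#' maximizes between-strain variation while minimizing within-strain
#' variation. A dose with zero within-strain variance in every trait gets
#' ratio `+Inf` with a warning.
#'
#' @param tab data.frame with columns `strain`, `dose` and trait columns.
#' @param traits trait columns to use (default: the four standard traits
#'   present in `tab`).
#' @return the selected dose (same type as `tab$dose`), with the per-dose
#'   mean ratios in the `"ratios"` attribute.
#' @export
select_dose <- function(tab, traits = intersect(.trait_cols, names(tab))) {
  stopifnot(all(c("strain", "dose") %in% names(tab)), length(traits) >= 1)
  doses <- unique(tab$dose)
  if (length(doses) == 1L) return(doses)
  ratio <- setNames(numeric(length(doses)), as.character(doses))
  for (d in seq_along(doses)) {
    sub <- tab[tab$dose == doses[d], , drop = FALSE]
    rs <- vapply(traits, function(tr) {
      v <- sub[[tr]]; s <- factor(sub$strain)
      ok <- is.finite(v)
      if (nlevels(droplevels(s[ok])) < 2) return(NA_real_)
      a <- anova(lm(v[ok] ~ droplevels(s[ok])))
      msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
      if (msw == 0) Inf else msb / msw
    }, numeric(1))
    if (all(is.infinite(rs[!is.na(rs)]))) {
      warning("dose ", doses[d], ": zero within-strain variance; ratio +Inf")
    }
    ratio[d] <- mean(rs, na.rm = TRUE)
  }
  best <- doses[which.max(ratio)]
  attr(best, "ratios") <- ratio
  best
}
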