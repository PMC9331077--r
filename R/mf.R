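# Clonality-aware mutation-frequency estimation, stratified summaries, dose
# contrasts and genomic-feature association tests.
#
# The per-bp mutation frequency (MF) is the number of unique somatic
# mutations divided by the number of duplex base pairs sequenced. Identical
# calls observed in more than one duplex molecule of the same sample are
# clonal expansions of a single mutational event: they count once for MF and
# are tallied separately for the clone-inclusive MF.

#' Deduplicate clonally expanded mutations
#'
#' Collapses records sharing the uniqueness key
#' `(sample_id, chrom, pos, ref, alt)` into one record whose multiplicity is
#' the summed molecule count. The same variant seen in two different samples
#' is never collapsed.
#'
#' @param mutations Mutation `data.frame`.
#' @return List with `unique` (deduplicated records, multiplicity preserved)
#'   and `clonal_extra` (total molecules minus unique mutations).
#' @export
#' @examples
#' m <- data.frame(sample_id = "s1", chrom = "chr1", pos = c(5, 5, 5, 9),
#'                 ref = "C", alt = "A", multiplicity = 1L)
#' deduplicate(m)$clonal_extra # 2
deduplicate <- function(mutations) {
  if (nrow(mutations) == 0L) {
    return(list(unique = mutations, clonal_extra = 0L))
  }
  if (is.null(mutations$multiplicity)) mutations$multiplicity <- 1L
  key <- paste(mutations$sample_id, mutations$chrom, mutations$pos,
               mutations$ref, mutations$alt, sep = "\r")
  mult <- tapply(mutations$multiplicity, key, sum)
  first <- !duplicated(key)
  uniq <- mutations[first, , drop = FALSE]
  uniq$multiplicity <- as.integer(mult[key[first]])
  rownames(uniq) <- NULL
  list(
    unique = uniq,
    clonal_extra = as.integer(sum(uniq$multiplicity) - nrow(uniq))
  )
}

# Resolve a grouping specification to metadata/panel columns.
resolve_groupby <- function(by) {
  alias <- c(cohort = "cohort", dose = "dose", sample = "sample_id",
             sample_id = "sample_id", target = "target",
             region_class = "region_class", chromatin = "chromatin",
             group = "group")
  unknown <- setdiff(by, names(alias))
  if (length(unknown) > 0L) {
    stop_fmt("unknown grouping scope(s): %s", paste(unknown, collapse = ", "))
  }
  unname(alias[by])
}

#' Compute mutation frequencies
#'
#' Aggregates deduplicated mutation counts and duplex depth over the
#' requested scope and reports per-bp MF and clone-inclusive MF
#' (multiplicity-summed). Group MF pools counts over pooled bp (exact under
#' unequal depths), and the across-sample SD of per-sample MFs is attached
#' for scopes coarser than a single sample.
#'
#' @param mutations Mutation `data.frame` (deduplicated; see
#'   [deduplicate()]).
#' @param depths Depth `data.frame` (`sample_id`, `target`, `duplex_bp`).
#' @param metadata Sample metadata (`sample_id`, `dose`, ...), required for
#'   dose scopes.
#' @param panel A `ds_panel`, required for target-annotation scopes.
#' @param by Grouping scope: `"cohort"`, `"dose"`, `"sample"`, `"target"`,
#'   `"region_class"`, `"chromatin"`, or a vector of several, e.g.
#'   `c("dose", "region_class")`.
#' @return A `data.frame` of MF estimates, one row per group.
#' @export
compute_mf <- function(mutations, depths, metadata = NULL, panel = NULL,
                       by = "cohort") {
  cols <- resolve_groupby(by)
  dd <- depths
  mm <- mutations
  mm$.n <- 1L
  if (!is.null(metadata)) {
    mi <- match(mm$sample_id, metadata$sample_id)
    di <- match(dd$sample_id, metadata$sample_id)
    mm$dose <- metadata$dose[mi]
    dd$dose <- metadata$dose[di]
    mm$group <- metadata$group[mi]
    dd$group <- metadata$group[di]
  }
  if (!is.null(panel)) {
    mi <- match(mm$target, panel$name)
    di <- match(dd$target, panel$name)
    for (cc in c("region_class", "chromatin")) {
      mm[[cc]] <- panel[[cc]][mi]
      dd[[cc]] <- panel[[cc]][di]
    }
  }
  mm$cohort <- "cohort"
  dd$cohort <- "cohort"
  missing <- setdiff(cols, union(names(mm), names(dd)))
  if (length(missing) > 0L) {
    stop_fmt("grouping column(s) unavailable (supply metadata/panel): %s",
             paste(missing, collapse = ", "))
  }
  mm$sample <- mm$sample_id
  dd$sample <- dd$sample_id

  # groups are the combinations realized in the depth grid
  dkchr <- do.call(paste, c(dd[cols], list(sep = "\r")))
  groups <- dd[!duplicated(dkchr), cols, drop = FALSE]
  groups <- groups[do.call(order, groups), , drop = FALSE]
  keys <- do.call(paste, c(groups[cols], list(sep = "\r")))

  mkchr <- do.call(paste, c(mm[cols], list(sep = "\r")))
  orphan <- !(mkchr %in% keys)
  if (any(orphan)) {
    stop_fmt("%d mutation(s) fall in groups absent from the depth table", sum(orphan))
  }
  fk <- factor(dkchr, levels = keys)
  fm <- factor(mkchr, levels = keys)
  bp <- tapply(dd$duplex_bp, fk, sum)
  n_mut <- tapply(mm$.n, fm, sum)
  n_clonal <- tapply(mm$multiplicity, fm, sum)
  n_mut[is.na(n_mut)] <- 0
  n_clonal[is.na(n_clonal)] <- 0

  if (any(bp == 0)) {
    stop_fmt("group '%s' has zero duplex bp",
             gsub("\r", "/", keys[which(bp == 0)[1]]))
  }

  out <- groups
  out$n_mutations <- as.integer(n_mut)
  out$n_mutations_clonal <- as.integer(n_clonal)
  out$duplex_bp <- as.numeric(bp)
  out$mf <- out$n_mutations / out$duplex_bp
  out$mf_clonal <- out$n_mutations_clonal / out$duplex_bp

  # across-sample SD for scopes above the sample level
  if (!("sample_id" %in% cols)) {
    per_sample <- compute_mf(mutations, depths, metadata = metadata,
                             panel = panel, by = unique(c(by, "sample")))
    pcols <- cols
    skey <- do.call(paste, c(per_sample[pcols], list(sep = "\r")))
    sds <- tapply(per_sample$mf, factor(skey, levels = keys), stats::sd)
    out$sd <- as.numeric(sds)
  } else {
    out$sd <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Fold change in mutation frequency
#'
#' @param mf_dose MF at the dose of interest.
#' @param mf_control MF in the control group (must be positive).
#' @return `mf_dose / mf_control`.
#' @export
#' @examples
#' fold_change(10.4e-7, 1.3e-7) # 8
fold_change <- function(mf_dose, mf_control) {
  if (any(mf_control <= 0)) stop_fmt("control MF must be positive")
  mf_dose / mf_control
}

#' Percent reduction in mutation frequency
#'
#' @param mf_reference Reference MF (must be positive).
#' @param mf_reduced Reduced MF.
#' @return `100 * (mf_reference - mf_reduced) / mf_reference`.
#' @export
#' @examples
#' percent_reduction(1.35e-7, 1.04e-7) # ~23%
percent_reduction <- function(mf_reference, mf_reduced) {
  if (any(mf_reference <= 0)) stop_fmt("reference MF must be positive")
  100 * (mf_reference - mf_reduced) / mf_reference
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p-values ascending, sets
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotonicity by a
#' running maximum, caps at 1 and returns the adjusted values in the original
#' order.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values, same order as `p`.
#' @export
#' @examples
#' holm_sidak(c(0.01, 0.04))
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  # -expm1(k * log1p(-p)) = 1 - (1 - p)^k without underflow for tiny p
  adj <- -expm1((m - seq_len(m) + 1) * log1p(-p[ord]))
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Aggregate mutations/depths to per-animal (optionally per-stratum) counts.
per_animal_counts <- function(mutations, depths, metadata, panel = NULL,
                              stratum = NULL) {
  by <- c("dose", "sample")
  if (!is.null(stratum)) by <- c(by, stratum)
  est <- compute_mf(mutations, depths, metadata = metadata, panel = panel,
                    by = by)
  names(est)[names(est) == "sample_id"] <- "sample_id"
  est
}

#' Binomial dose-response model with Wald contrasts
#'
#' Fits a logistic-link binomial GLM of unique mutation counts out of duplex
#' bp on dose (as a factor) to per-animal aggregates and reports the Wald z
#' contrast of every dose against the control (lowest) dose, with
#' Holm-Sidak-adjusted p-values. When `stratum` is given the model is fitted
#' within each stratum independently and the adjustment is applied within
#' each stratum independently. If a dose group has zero mutations a 0.5
#' mutation / 1 bp continuity count is added to it (with a warning).
#'
#' @param mutations,depths,metadata,panel As in [compute_mf()].
#' @param stratum Optional stratifying annotation (`"region_class"`,
#'   `"chromatin"`, `"target"`).
#' @param dispersion `"binomial"` for plain Wald SEs or `"quasibinomial"` to
#'   scale them by the estimated dispersion.
#' @param clonal Use clone-inclusive counts instead of unique counts.
#' @return A `data.frame` of dose contrasts: `stratum`, `dose_a` (control),
#'   `dose_b`, `estimate` (log-odds difference), `wald_z`, `p_raw`,
#'   `p_adjusted`.
#' @export
fit_binomial_dose_model <- function(mutations, depths, metadata, panel = NULL,
                                    stratum = NULL,
                                    dispersion = c("binomial", "quasibinomial"),
                                    clonal = FALSE) {
  dispersion <- match.arg(dispersion)
  est <- per_animal_counts(mutations, depths, metadata, panel, stratum)
  est$count <- if (clonal) est$n_mutations_clonal else est$n_mutations
  strata <- if (is.null(stratum)) list(all = est) else split(est, est[[stratum]])
  out <- lapply(names(strata), function(sname) {
    dat <- strata[[sname]]
    dat <- contrast_continuity(dat)
    dat$dose_f <- factor(dat$dose)
    fam <- if (dispersion == "binomial") stats::binomial() else stats::quasibinomial()
    fit <- suppressWarnings(stats::glm(
      cbind(count, duplex_bp - count) ~ dose_f, family = fam, data = dat
    ))
    sm <- summary(fit)$coefficients
    dose_levels <- levels(dat$dose_f)
    rows <- paste0("dose_f", dose_levels[-1])
    est_b <- sm[rows, 1]
    se_b <- sm[rows, 2]
    z <- est_b / se_b
    # identical groups give an exactly-zero contrast: force p = 1
    p <- ifelse(abs(est_b) < 1e-12, 1, 2 * stats::pnorm(-abs(z)))
    data.frame(
      stratum = sname,
      dose_a = as.numeric(dose_levels[1]),
      dose_b = as.numeric(dose_levels[-1]),
      estimate = unname(est_b),
      wald_z = unname(ifelse(abs(est_b) < 1e-12, 0, z)),
      p_raw = unname(p),
      p_adjusted = holm_sidak(unname(p)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Continuity handling for complete-separation groups (all-zero counts).
contrast_continuity <- function(dat) {
  totals <- tapply(dat$count, dat$dose, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0L) {
    warn_fmt("dose group(s) with zero mutations (%s): adding 0.5 continuity count",
             paste(zero, collapse = ", "))
    for (z in zero) {
      i <- which(dat$dose == as.numeric(z))[1]
      dat$count[i] <- dat$count[i] + 0.5
      dat$duplex_bp[i] <- dat$duplex_bp[i] + 1
    }
  }
  dat
}

#' GC-content association test
#'
#' Discretizes targets into two GC groups at `gc_threshold` (default: the
#' panel mean), fits a binomial GLM of per-animal per-target counts on dose
#' plus GC group, and reports the Type II Wald chi-square for the GC-group
#' term.
#'
#' @param mutations,depths,metadata,panel As in [compute_mf()].
#' @param gc_threshold GC fraction splitting the panel into low/high groups.
#' @return List with `chi_square`, `df`, `p`, `gc_threshold` and the group
#'   sizes.
#' @export
gc_group_test <- function(mutations, depths, metadata, panel,
                          gc_threshold = NULL) {
  if (any(is.na(panel$gc_fraction))) {
    stop_fmt("panel lacks gc_fraction annotations")
  }
  gc_threshold <- gc_threshold %||% mean(panel$gc_fraction)
  gc_group <- ifelse(panel$gc_fraction < gc_threshold, "low", "high")
  if (length(unique(gc_group)) < 2L) {
    stop_fmt("all targets fall into one GC group at threshold %.3f", gc_threshold)
  }
  est <- compute_mf(mutations, depths, metadata = metadata, panel = panel,
                    by = c("dose", "sample", "target"))
  est$gc_group <- factor(gc_group[match(est$target, panel$name)],
                         levels = c("low", "high"))
  est$dose_f <- factor(est$dose)
  fit <- suppressWarnings(stats::glm(
    cbind(n_mutations, duplex_bp - n_mutations) ~ dose_f + gc_group,
    family = stats::binomial(), data = est
  ))
  an <- car::Anova(fit, type = 2, test.statistic = "Wald")
  i <- match("gc_group", rownames(an))
  list(
    chi_square = an[i, "Chisq"],
    df = an[i, "Df"],
    p = an[i, "Pr(>Chisq)"],
    gc_threshold = gc_threshold,
    n_low = sum(gc_group == "low"),
    n_high = sum(gc_group == "high")
  )
}
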