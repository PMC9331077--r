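# 6-class and 96-channel mutation spectra, between-group spectrum tests and
# CpG-site mutation proportions.

#' Build a 96-channel trinucleotide spectrum
#'
#' Counts deduplicated SNVs per pyrimidine-normalized trinucleotide channel.
#' Non-SNV records are ignored (they are reported by [build_spectrum6()]).
#'
#' @param mutations Deduplicated mutation `data.frame` whose SNVs carry
#'   `tri_context`.
#' @param normalization `"counts"`, `"proportion"` (sums to 1), `"per_bp"`
#'   (divide by `duplex_bp`), or `"per_context_bp"` (divide each channel by
#'   its context abundance times depth-per-site; requires `tri_abundance`).
#' @param duplex_bp Total duplex bp for the scope (needed for `per_bp` and
#'   `per_context_bp`).
#' @param tri_abundance Named 32-vector of pyrimidine-context trinucleotide
#'   site counts (e.g. a column-sum over targets of
#'   [panel_tri_abundance()]); needed for `per_context_bp`.
#' @return A named numeric 96-vector of class `spectrum96` with attribute
#'   `normalization`.
#' @export
build_spectrum96 <- function(mutations,
                             normalization = c("counts", "proportion",
                                               "per_bp", "per_context_bp"),
                             duplex_bp = NULL, tri_abundance = NULL) {
  normalization <- match.arg(normalization)
  channels <- sbs_channels()
  snv <- mutations[mutations$var_class == "SNV", , drop = FALSE]
  if (nrow(snv) > 0L && anyNA(snv$tri_context)) {
    stop_fmt("%d SNV(s) lack a trinucleotide context", sum(is.na(snv$tri_context)))
  }
  ch <- if (nrow(snv) > 0L) {
    pyrimidine_channel(snv$ref, snv$alt, restore_ref_context(snv))
  } else character(0)
  counts <- table(factor(ch, levels = channels))
  out <- as.numeric(counts)
  names(out) <- channels
  total <- sum(out)
  if (normalization == "proportion") {
    if (total == 0) stop_fmt("cannot form proportions from an empty spectrum")
    out <- out / total
  } else if (normalization == "per_bp") {
    if (is.null(duplex_bp)) stop_fmt("per_bp normalization requires `duplex_bp`")
    out <- out / duplex_bp
  } else if (normalization == "per_context_bp") {
    if (is.null(tri_abundance)) {
      stop_fmt("per_context_bp normalization requires `tri_abundance`")
    }
    if (is.null(duplex_bp)) {
      stop_fmt("per_context_bp normalization requires `duplex_bp`")
    }
    total_sites <- sum(tri_abundance)
    depth_per_site <- duplex_bp / total_sites
    ab <- tri_abundance[channel_context(channels)]
    out <- out / (as.numeric(ab) * depth_per_site)
  }
  structure(out, class = "spectrum96", normalization = normalization)
}

# The stored tri_context is pyrimidine-normalized; recover the context on the
# reference strand (central base == ref) for channel assignment.
restore_ref_context <- function(snv) {
  ctx <- snv$tri_context
  flip <- substr(ctx, 2L, 2L) != snv$ref
  ctx[flip] <- revcomp3(ctx[flip])
  ctx
}

#' Build a 6-class substitution spectrum
#'
#' Marginalizes the 96-channel spectrum over flanking bases into the six
#' pyrimidine substitution classes and tallies insertions, deletions and
#' MNVs separately.
#'
#' @param mutations Deduplicated mutation `data.frame`.
#' @param duplex_bp Optional total duplex bp; when given, per-bp frequencies
#'   are attached.
#' @return A list of class `spectrum6` with `counts` (named 9-vector: six
#'   SNV classes, insertion, deletion, MNV), `proportions` (over all
#'   reported classes), `snv_proportions` (over the six SNV classes) and
#'   optionally `mf_per_class`.
#' @export
build_spectrum6 <- function(mutations, duplex_bp = NULL) {
  s96 <- build_spectrum96(mutations, normalization = "counts")
  cls <- channel_class(names(s96))
  snv_counts <- vapply(SBS_CLASSES, function(k) sum(s96[cls == k]), numeric(1))
  other <- c(
    insertion = sum(mutations$var_class == "insertion"),
    deletion = sum(mutations$var_class == "deletion"),
    MNV = sum(mutations$var_class == "MNV")
  )
  counts <- c(snv_counts, other)
  total <- sum(counts)
  out <- list(
    counts = counts,
    proportions = if (total > 0) counts / total else counts,
    snv_proportions = if (sum(snv_counts) > 0) snv_counts / sum(snv_counts) else snv_counts
  )
  if (!is.null(duplex_bp)) out$mf_per_class <- counts / duplex_bp
  structure(out, class = "spectrum6")
}

#' @export
print.spectrum6 <- function(x, ...) {
  cat("Substitution spectrum (6 classes + indel/MNV):\n")
  print(round(rbind(count = x$counts, proportion = x$proportions), 4))
  invisible(x)
}

#' Spectra for each group of samples
#'
#' Convenience wrapper pooling deduplicated mutations within each level of a
#' metadata column (dose by default) and building one spectrum per group.
#'
#' @param mutations Deduplicated mutation `data.frame`.
#' @param metadata Sample metadata.
#' @param by Metadata column defining the groups.
#' @param ... Passed to [build_spectrum96()].
#' @return Matrix, groups x 96 channels.
#' @export
group_spectra <- function(mutations, metadata, by = "dose", ...) {
  g <- metadata[[by]][match(mutations$sample_id, metadata$sample_id)]
  levels_ <- sort(unique(metadata[[by]]))
  out <- t(vapply(levels_, function(lv) {
    as.numeric(build_spectrum96(mutations[g == lv, , drop = FALSE], ...))
  }, numeric(96L)))
  rownames(out) <- as.character(levels_)
  colnames(out) <- sbs_channels()
  out
}

#' Per-sample spectra
#'
#' One spectrum row per sample; samples with no SNVs yield all-zero rows
#' (`counts`) or an error (`proportion`).
#'
#' @inheritParams group_spectra
#' @param samples Sample ids (default: all in `metadata`).
#' @return Matrix, samples x 96 channels.
#' @export
sample_spectra <- function(mutations, metadata, samples = metadata$sample_id, ...) {
  out <- t(vapply(samples, function(s) {
    as.numeric(build_spectrum96(mutations[mutations$sample_id == s, , drop = FALSE], ...))
  }, numeric(96L)))
  rownames(out) <- samples
  colnames(out) <- sbs_channels()
  out
}

#' Between-group spectrum homogeneity test
#'
#' Tests whether mutation-class composition differs between groups using a
#' Monte Carlo chi-square on the groups x classes contingency table with
#' fixed row totals, followed by per-class 2x2 comparisons (class vs rest,
#' group vs control) whose p-values are Holm-Sidak-adjusted across classes
#' within each group. All-zero classes are dropped with a message.
#'
#' @param counts Matrix of counts, groups x classes, with row names; the
#'   control group is `control` (default: first row).
#' @param control Row name of the control group.
#' @param B Number of Monte Carlo replicates.
#' @param seed Seed for the Monte Carlo draw.
#' @return List with `statistic`, `p_overall`, and `per_class` (a
#'   `data.frame` of per-class follow-ups).
#' @export
spectrum_contingency_test <- function(counts, control = rownames(counts)[1],
                                      B = 9999, seed = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop_fmt("need at least two groups")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (any(rowSums(counts) == 0)) {
    stop_fmt("group '%s' has zero total mutations",
             rownames(counts)[which(rowSums(counts) == 0)[1]])
  }
  drop <- colSums(counts) == 0
  if (any(drop)) {
    message(sprintf("dropping all-zero class(es): %s",
                    paste(colnames(counts)[drop], collapse = ", ")))
    counts <- counts[, !drop, drop = FALSE]
  }
  overall <- with_seed(seed, suppressWarnings(
    stats::chisq.test(counts, simulate.p.value = TRUE, B = B)
  ))
  groups <- setdiff(rownames(counts), control)
  per_class <- do.call(rbind, lapply(groups, function(g) {
    ps <- vapply(seq_len(ncol(counts)), function(j) {
      tab <- rbind(
        c(counts[g, j], sum(counts[g, -j])),
        c(counts[control, j], sum(counts[control, -j]))
      )
      suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
    }, numeric(1))
    ps[is.na(ps)] <- 1
    data.frame(
      group = g, class = colnames(counts),
      p_raw = ps, p_adjusted = holm_sidak(ps),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_class) <- NULL
  list(
    statistic = unname(overall$statistic),
    p_overall = overall$p.value,
    per_class = per_class
  )
}

#' Fraction of panel CpG sites that are mutated
#'
#' A CpG site counts as mutated when at least one deduplicated mutation in
#' scope hits the C of either strand of the CG dinucleotide; each site is
#' counted once no matter how many samples or mutations hit it.
#'
#' @param mutations Deduplicated mutation `data.frame` (subset to the scope
#'   of interest beforehand, e.g. one dose group).
#' @param panel A `ds_panel` with sequences (the CpG inventory).
#' @return List with `fraction`, `n_mutated` and `n_sites`.
#' @export
cpg_mutated_fraction <- function(mutations, panel) {
  sites <- panel_cpg_sites(panel)
  n_sites <- sum(lengths(sites))
  if (n_sites == 0L) stop_fmt("panel contains no CpG sites")
  hit <- character(0)
  idx <- match(mutations$target, panel$name)
  local <- mutations$pos - panel$start[idx] # 1-based within target
  for (t in unique(mutations$target)) {
    st <- sites[[t]]
    sel <- mutations$target == t
    lp <- local[sel]
    ref <- mutations$ref[sel]
    # C of the plus strand is at the site position; the minus-strand C (a G
    # on the plus strand) is at site position + 1
    site_of <- ifelse(substr(ref, 1L, 1L) == "C" & lp %in% st, lp,
               ifelse(substr(ref, 1L, 1L) == "G" & (lp - 1L) %in% st, lp - 1L,
                      NA_integer_))
    site_of <- site_of[!is.na(site_of)]
    if (length(site_of) > 0L) hit <- c(hit, paste(t, site_of))
  }
  n_mut <- length(unique(hit))
  list(fraction = n_mut / n_sites, n_mutated = n_mut, n_sites = n_sites)
}
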