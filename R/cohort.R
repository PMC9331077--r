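# Synthetic duplex-sequencing cohort generator.
#
# The generator emulates the downstream structure of an in vivo mutagenesis
# dose-response experiment: per-sample per-target duplex depth, Poisson
# unique-mutation counts proportional to depth and a dose-specific mutation
# frequency (modulated by genic/intergenic status and chromatin state),
# trinucleotide channels drawn from a dose-weighted mixture of a background
# and an exposure spectrum, positions drawn uniformly among in-target sites
# matching each channel's context, geometric clonal expansion multiplicities,
# and single-base-pair indel/MNV events.

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic cohort generator. Per-dose
#' parameters (`dose_mf`, `genic_reduction`, `exposure_weight`, `clone_prob`)
#' accept a scalar (recycled), an unnamed vector with one value per dose, or
#' a vector named by dose.
#'
#' @param doses Dose levels, mg/kg/day.
#' @param n_per_dose Animals per dose group.
#' @param panel A `ds_panel` with sequences.
#' @param depth_mean Mean total duplex bp per sample.
#' @param depth_cv Coefficient of variation of per-target depth.
#' @param base_mf Background mutation frequency per duplex bp.
#' @param dose_mf Mean panel-wide mutation frequency per bp at each dose.
#' @param genic_reduction Fractional MF reduction in genic targets, per dose.
#' @param heterochromatin_multiplier MF multiplier for heterochromatic
#'   targets (>= 1).
#' @param control_spectrum 96-channel background spectrum (sums to 1).
#' @param exposure_spectrum 96-channel exposure spectrum (sums to 1).
#' @param exposure_weight Mixture weight of the exposure spectrum per dose,
#'   in `[0, 1]`.
#' @param clone_prob Probability that a mutation is clonally expanded, per
#'   dose.
#' @param clone_size_mean Mean number of extra duplex molecules per clonally
#'   expanded mutation (>= 1).
#' @param indel_fraction Proportion of events that are not SNVs.
#' @param seed Integer seed governing all randomness.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(doses, n_per_dose, panel,
                          depth_mean, depth_cv,
                          base_mf, dose_mf,
                          genic_reduction = 0,
                          heterochromatin_multiplier = 1,
                          control_spectrum,
                          exposure_spectrum,
                          exposure_weight = 0,
                          clone_prob = 0,
                          clone_size_mean = 2,
                          indel_fraction = 0,
                          seed = 1L) {
  cfg <- list(
    doses = as.numeric(doses),
    n_per_dose = as.integer(n_per_dose),
    panel = panel,
    depth_mean = depth_mean,
    depth_cv = depth_cv,
    base_mf = base_mf,
    dose_mf = per_dose(dose_mf, doses, "dose_mf"),
    genic_reduction = per_dose(genic_reduction, doses, "genic_reduction"),
    heterochromatin_multiplier = heterochromatin_multiplier,
    control_spectrum = control_spectrum,
    exposure_spectrum = exposure_spectrum,
    exposure_weight = per_dose(exposure_weight, doses, "exposure_weight"),
    clone_prob = per_dose(clone_prob, doses, "clone_prob"),
    clone_size_mean = clone_size_mean,
    indel_fraction = indel_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate (and re-normalize) a cohort configuration
#'
#' Checks every invariant of a [cohort_config()] and returns the
#' configuration with its per-dose fields re-normalized, so that
#' configurations edited after construction stay consistent.
#'
#' @param cfg A `cohort_config`.
#' @return The validated configuration, invisibly.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg$panel, "ds_panel"), nrow(cfg$panel) > 0L)
  panel_sequences(cfg$panel) # errors if absent
  # re-normalize per-dose fields so configs edited after construction remain
  # consistent (scalars recycle, unnamed vectors pair with doses in order)
  for (nm in c("dose_mf", "genic_reduction", "exposure_weight", "clone_prob")) {
    cfg[[nm]] <- per_dose(cfg[[nm]], cfg$doses, nm)
  }
  if (cfg$n_per_dose < 1L) stop_fmt("n_per_dose must be >= 1")
  if (cfg$depth_mean <= 0 || cfg$depth_cv < 0) stop_fmt("invalid depth parameters")
  if (any(cfg$dose_mf <= 0)) stop_fmt("dose_mf must be positive")
  pos <- cfg$doses > 0
  if (any(cfg$dose_mf[pos] < cfg$base_mf)) {
    stop_fmt("base_mf must not exceed dose_mf at positive doses")
  }
  for (nm in c("control_spectrum", "exposure_spectrum")) {
    s <- cfg[[nm]]
    if (length(s) != 96L || any(s < 0) || abs(sum(s) - 1) > 1e-6) {
      stop_fmt("`%s` must be 96 non-negative proportions summing to 1", nm)
    }
    if (!is.null(names(s)) && !identical(names(s), sbs_channels())) {
      stop_fmt("`%s` must be in canonical channel order", nm)
    }
  }
  if (any(cfg$exposure_weight < 0 | cfg$exposure_weight > 1)) {
    stop_fmt("exposure_weight must lie in [0, 1]")
  }
  if (any(cfg$genic_reduction < 0 | cfg$genic_reduction >= 1)) {
    stop_fmt("genic_reduction must lie in [0, 1)")
  }
  if (cfg$heterochromatin_multiplier < 1) {
    stop_fmt("heterochromatin_multiplier must be >= 1")
  }
  if (any(cfg$clone_prob < 0 | cfg$clone_prob > 1)) {
    stop_fmt("clone_prob must lie in [0, 1]")
  }
  if (cfg$clone_size_mean < 1) stop_fmt("clone_size_mean must be >= 1")
  if (cfg$indel_fraction < 0 || cfg$indel_fraction >= 1) {
    stop_fmt("indel_fraction must lie in [0, 1)")
  }
  invisible(cfg)
}
# NB: callers that keep using the config after validation should take the
# returned (re-normalized) object.

# 6-class -> 96-channel expansion, uniform over the 16 flank contexts of each
# class unless per-channel overrides are given (named by channel).
expand_spectrum6 <- function(class6, overrides = NULL) {
  stopifnot(length(class6) == 6L)
  channels <- sbs_channels()
  cls <- channel_class(channels)
  out <- stats::setNames(rep(0, 96L), channels)
  for (k in seq_along(SBS_CLASSES)) {
    idx <- cls == SBS_CLASSES[k]
    out[idx] <- class6[k] / 16
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), channels)
    if (length(bad) > 0L) stop_fmt("unknown channel(s): %s", paste(bad, collapse = ", "))
    for (ch in names(overrides)) {
      k <- channel_class(ch)
      others <- cls == k & channels != ch & !(channels %in% names(overrides))
      # keep the class total fixed by re-spreading the residual mass
      delta <- overrides[[ch]] - out[ch]
      out[ch] <- overrides[[ch]]
      out[others] <- out[others] - delta / sum(others)
    }
    if (any(out < 0)) stop_fmt("channel overrides drove a proportion below zero")
  }
  out
}

#' Default benzo(a)pyrene-calibrated cohort configuration
#'
#' Returns the generator configuration emulating a 28-day oral BaP
#' dose-response study read out by a 20-target duplex panel in bone marrow:
#' four dose groups (0, 12.5, 25, 50 mg/kg/day) of six animals, ~850 million
#' duplex bp per sample, panel-mean mutation frequencies of 1.3, 3.3, 6.8 and
#' 10.4 x 1e-7 per bp, a 23% (background) and 42% (exposed) genic-vs-
#' intergenic MF reduction, a 1.3x heterochromatin multiplier, and a
#' C:G>A:T-dominated exposure spectrum. The exposure mixture weight at each
#' dose equals the excess-MF fraction `(dose_mf - base_mf) / dose_mf`, and
#' the exposure spectrum is solved so that the expected pooled high-dose
#' spectrum has 61% C>A, 14% C>G and 11% C>T among SNVs, with the channels
#' `C[C>A]A`, `C[C>A]C` and `G[C>A]C` at 4.23%, 10.3% and 4.00%, against a
#' background of 32% / 22% / 16%.
#'
#' @param seed Integer seed (default 20220728).
#' @return A `cohort_config`.
#' @export
#' @examples
#' cfg <- default_bap_config()
#' round(cfg$dose_mf["50"] / cfg$dose_mf["0"], 1) # 8-fold at the top dose
default_bap_config <- function(seed = 20220728L) {
  doses <- c(0, 12.5, 25, 50)
  dose_mf <- c(1.3, 3.3, 6.8, 10.4) * 1e-7
  base_mf <- dose_mf[1]
  w <- pmax(0, (dose_mf - base_mf) / dose_mf)
  w_hi <- w[length(w)]

  # background 6-class proportions among SNVs
  control6 <- c("C>A" = 0.32, "C>G" = 0.22, "C>T" = 0.16,
                "T>A" = 0.10, "T>C" = 0.10, "T>G" = 0.10)
  # observed 6-class proportions at the top dose
  observed6_hi <- c("C>A" = 0.61, "C>G" = 0.14, "C>T" = 0.11,
                    "T>A" = 0.14 / 3, "T>C" = 0.14 / 3, "T>G" = 0.14 / 3)
  # exposure process spectrum solved from the mixture identity
  exposure6 <- (observed6_hi - (1 - w_hi) * control6) / w_hi
  if (any(exposure6 < 0)) stop_fmt("inconsistent spectrum calibration")

  control_spectrum <- expand_spectrum6(control6)
  # per-channel high-dose calibration for the three discriminant channels and
  # a mild CpG-context excess (ACG/GCG), solved back to the exposure process
  observed_ch_hi <- c("C[C>A]A" = 0.0423, "C[C>A]C" = 0.1030, "G[C>A]C" = 0.0400)
  exposure_overrides <- (observed_ch_hi - (1 - w_hi) * control6["C>A"] / 16) / w_hi
  exposure_overrides <- c(exposure_overrides,
                          "A[C>A]G" = 0.045, "G[C>A]G" = 0.045)
  exposure_spectrum <- expand_spectrum6(exposure6, overrides = exposure_overrides)

  cohort_config(
    doses = doses,
    n_per_dose = 6L,
    panel = default_panel(),
    depth_mean = 8.5e8,
    depth_cv = 0.05,
    base_mf = base_mf,
    dose_mf = dose_mf,
    genic_reduction = c(0.23, 0.42, 0.42, 0.42),
    heterochromatin_multiplier = 1.3,
    control_spectrum = control_spectrum,
    exposure_spectrum = exposure_spectrum,
    exposure_weight = w,
    clone_prob = c(0.02, 0.04, 0.06, 0.10),
    clone_size_mean = 2.5,
    indel_fraction = 0.07,
    seed = seed
  )
}

# Per-target MF multipliers, renormalized (equal target weights) so that the
# expected panel-wide MF equals the configured dose mean.
target_modifiers <- function(panel, genic_reduction, hetero_multiplier) {
  m <- rep(1, nrow(panel))
  m[panel$region_class == "genic"] <- 1 - genic_reduction
  m[panel$chromatin == "heterochromatin"] <-
    m[panel$chromatin == "heterochromatin"] * hetero_multiplier
  w <- (panel$end - panel$start) / sum(panel$end - panel$start)
  m / sum(m * w)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (metadata, per-sample per-target duplex depths, and
#' mutation records) from a `cohort_config`. Fully reproducible given the
#' seed; per-sample randomness uses substreams derived deterministically from
#' it, so cohorts are byte-identical across runs.
#'
#' @param config A `cohort_config`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A `synthetic_cohort` list with elements `metadata`, `depths`,
#'   `mutations` and `truth` (the config used).
#' @export
#' @examples
#' cfg <- default_bap_config()
#' cfg$n_per_dose <- 2L; cfg$depth_mean <- 5e7
#' coh <- generate_cohort(cfg, seed = 7)
#' head(coh$mutations)
generate_cohort <- function(config, seed = NULL) {
  config <- validate_cohort_config(config)
  seed <- as.integer(seed %||% config$seed)
  panel <- config$panel
  seqs <- panel_sequences(panel)
  ctx_index <- lapply(seqs, target_context_positions)
  channels <- sbs_channels()
  ctx_of_channel <- channel_context(channels)

  dose_key <- format_dose(config$doses)
  metadata <- do.call(rbind, lapply(seq_along(config$doses), function(d) {
    data.frame(
      sample_id = sprintf("d%s_a%d", dose_key[d], seq_len(config$n_per_dose)),
      dose = config$doses[d],
      group = paste0("d", dose_key[d]),
      stringsAsFactors = FALSE
    )
  }))

  depth_mu <- config$depth_mean / nrow(panel)
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  meanlog <- log(depth_mu) - sdlog^2 / 2

  depths_list <- vector("list", nrow(metadata))
  muts_list <- vector("list", nrow(metadata))

  for (s in seq_len(nrow(metadata))) {
    smeta <- metadata[s, ]
    dkey <- format_dose(smeta$dose)
    mf_dose <- config$dose_mf[[dkey]]
    mods <- target_modifiers(panel, config$genic_reduction[[dkey]],
                             config$heterochromatin_multiplier)
    w <- config$exposure_weight[[dkey]]
    mix <- (1 - w) * config$control_spectrum + w * config$exposure_spectrum
    cp <- config$clone_prob[[dkey]]

    sample_out <- with_seed(child_seed(seed, s), {
      depth <- round(stats::rlnorm(nrow(panel), meanlog, sdlog))
      n_mut <- stats::rpois(nrow(panel), mf_dose * mods * depth)
      recs <- vector("list", nrow(panel))
      for (t in seq_len(nrow(panel))) {
        n <- n_mut[t]
        if (n == 0L) next
        recs[[t]] <- draw_target_mutations(
          n, panel[t, ], seqs[[t]], ctx_index[[t]], mix, channels,
          ctx_of_channel, config$indel_fraction
        )
      }
      recs <- do.call(rbind, recs)
      if (!is.null(recs) && nrow(recs) > 0L) {
        recs$sample_id <- smeta$sample_id
        # enforce within-sample uniqueness of (pos, ref, alt) draws
        key <- paste(recs$chrom, recs$pos, recs$ref, recs$alt)
        recs <- recs[!duplicated(key), , drop = FALSE]
        expanded <- stats::runif(nrow(recs)) < cp
        extra <- integer(nrow(recs))
        if (any(expanded)) {
          p <- 1 / config$clone_size_mean
          extra[expanded] <- 1L + stats::rgeom(sum(expanded), p)
        }
        recs$multiplicity <- 1L + extra
      }
      list(depth = depth, recs = recs)
    })

    depths_list[[s]] <- data.frame(
      sample_id = smeta$sample_id, target = panel$name,
      duplex_bp = sample_out$depth, stringsAsFactors = FALSE
    )
    muts_list[[s]] <- sample_out$recs
  }

  mutations <- do.call(rbind, Filter(Negate(is.null), muts_list))
  if (is.null(mutations)) {
    mutations <- data.frame(
      sample_id = character(0), target = character(0), chrom = character(0),
      pos = numeric(0), ref = character(0), alt = character(0),
      var_class = character(0), multiplicity = integer(0),
      tri_context = character(0), stringsAsFactors = FALSE
    )
  } else {
    cols <- c("sample_id", "target", "chrom", "pos", "ref", "alt",
              "var_class", "multiplicity", "tri_context")
    mutations <- mutations[, cols]
    rownames(mutations) <- NULL
  }

  out <- list(
    metadata = metadata,
    depths = do.call(rbind, depths_list),
    mutations = mutations,
    truth = config
  )
  rownames(out$depths) <- NULL
  class(out) <- "synthetic_cohort"
  out
}

# Draw `n` mutation records within one target.
draw_target_mutations <- function(n, target, seq, ctx_pos, mix, channels,
                                  ctx_of_channel, indel_fraction) {
  L <- nchar(seq)
  is_snv <- stats::runif(n) >= indel_fraction
  n_snv <- sum(is_snv)
  recs <- vector("list", 2L)

  if (n_snv > 0L) {
    ch_idx <- sample.int(96L, n_snv, replace = TRUE, prob = mix)
    avail <- lengths(ctx_pos)[ctx_of_channel] > 0L
    retry <- which(!avail[ch_idx])
    guard <- 0L
    while (length(retry) > 0L && guard < 100L) {
      ch_idx[retry] <- sample.int(96L, length(retry), replace = TRUE, prob = mix)
      retry <- retry[!avail[ch_idx[retry]]]
      guard <- guard + 1L
    }
    if (length(retry) > 0L) {
      stop_fmt("target '%s' lacks sites for every requested context", target$name)
    }
    # positions drawn without replacement within each context so that a
    # sample cannot carry two identical "unique" mutations
    pos_local <- numeric(n_snv)
    for (ctx in unique(ctx_of_channel[ch_idx])) {
      sel <- which(ctx_of_channel[ch_idx] == ctx)
      p <- ctx_pos[[ctx]]
      if (length(sel) <= length(p)) {
        pos_local[sel] <- p[sample.int(length(p), length(sel))]
      } else {
        pos_local[sel] <- p[sample.int(length(p), length(sel), replace = TRUE)]
      }
    }
    ref <- substring(seq, pos_local, pos_local)
    ch <- channels[ch_idx]
    # channel alleles are on the pyrimidine strand; flip at purine sites
    alt_pyr <- substr(ch, 5L, 5L)
    purine <- ref %in% c("A", "G")
    alt <- ifelse(purine, complement_base(alt_pyr), alt_pyr)
    recs[[1]] <- data.frame(
      target = target$name, chrom = target$chrom,
      pos = target$start + pos_local,
      ref = ref, alt = alt, var_class = "SNV",
      tri_context = channel_context(ch),
      stringsAsFactors = FALSE
    )
  }

  n_other <- n - n_snv
  if (n_other > 0L) {
    kind <- sample(c("insertion", "deletion", "MNV"), n_other, replace = TRUE,
                   prob = c(0.425, 0.425, 0.15))
    pos_local <- sample.int(L - 2L, n_other, replace = TRUE) + 1L
    ref1 <- substring(seq, pos_local, pos_local)
    ref2 <- substring(seq, pos_local, pos_local + 1L)
    ins_base <- sample(DNA_BASES, n_other, replace = TRUE)
    mnv_alt <- vapply(seq_len(n_other), function(i) {
      paste(vapply(strsplit(ref2[i], "")[[1]], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1)), collapse = "")
    }, character(1))
    ref <- ifelse(kind == "deletion", ref2, ifelse(kind == "MNV", ref2, ref1))
    alt <- ifelse(kind == "deletion", ref1,
                  ifelse(kind == "MNV", mnv_alt, paste0(ref1, ins_base)))
    recs[[2]] <- data.frame(
      target = target$name, chrom = target$chrom,
      pos = target$start + pos_local,
      ref = ref, alt = alt, var_class = kind,
      tri_context = NA_character_,
      stringsAsFactors = FALSE
    )
  }

  do.call(rbind, Filter(Negate(is.null), recs))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic duplex cohort: %d samples (%d dose groups), %d mutation records, %s duplex bp\n",
    nrow(x$metadata), length(unique(x$metadata$dose)), nrow(x$mutations),
    format(sum(x$depths$duplex_bp), big.mark = ",")
  ))
  invisible(x)
}
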