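# Mutagenesis panel: a set of genomic target intervals with genic/intergenic,
# chromatin and GC annotations. Coordinates are BED-style 0-based half-open in
# files; internal mutation positions are 1-based (VCF convention), so a target
# covers 1-based positions (start + 1) .. end.

#' Construct a mutagenesis panel
#'
#' @param name Unique target labels.
#' @param chrom Chromosome labels.
#' @param start 0-based inclusive start coordinates.
#' @param end 0-based exclusive end coordinates.
#' @param region_class `"genic"` or `"intergenic"` per target.
#' @param chromatin `"euchromatin"` or `"heterochromatin"` per target.
#' @param gc_fraction GC fraction in `[0, 1]` per target.
#' @param expression_level Non-negative expression (RPKM) or `NA`.
#' @param sequence Optional named character vector of target sequences
#'   (A/C/G/T), one per target, each of length `end - start`. Required for
#'   synthetic cohort generation, per-context normalization and CpG
#'   inventories.
#' @return A `data.frame` of class `ds_panel`, sorted by `(chrom, start)`,
#'   with the sequences (if any) in attribute `"sequences"`.
#' @export
panel_targets <- function(name, chrom, start, end,
                          region_class = "intergenic",
                          chromatin = "euchromatin",
                          gc_fraction = NA_real_,
                          expression_level = NA_real_,
                          sequence = NULL) {
  n <- length(name)
  df <- data.frame(
    name = as.character(name),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    region_class = rep_len(as.character(region_class), n),
    chromatin = rep_len(as.character(chromatin), n),
    gc_fraction = rep_len(as.numeric(gc_fraction), n),
    expression_level = rep_len(as.numeric(expression_level), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$name)) {
    stop_fmt("duplicate target names: %s",
             paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L) {
    stop_fmt("target '%s': end must be greater than start", df$name[bad[1]])
  }
  if (any(!is.na(df$gc_fraction) & (df$gc_fraction < 0 | df$gc_fraction > 1))) {
    stop_fmt("gc_fraction must lie in [0, 1]")
  }
  if (!all(df$region_class %in% c("genic", "intergenic"))) {
    stop_fmt("region_class must be 'genic' or 'intergenic'")
  }
  if (!all(df$chromatin %in% c("euchromatin", "heterochromatin"))) {
    stop_fmt("chromatin must be 'euchromatin' or 'heterochromatin'")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # overlap check within chromosome (sorted by start)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop_fmt("overlapping targets on %s", ch)
    }
  }
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (is.null(names(sequence))) {
      stop_fmt("`sequence` must be named by target")
    }
    missing <- setdiff(df$name, names(sequence))
    if (length(missing) > 0L) {
      stop_fmt("`sequence` missing for target(s): %s", paste(missing, collapse = ", "))
    }
    len_ok <- nchar(sequence[df$name]) == (df$end - df$start)
    if (!all(len_ok)) {
      stop_fmt("sequence length must equal target width (first offender: %s)",
               df$name[!len_ok][1])
    }
    attr(df, "sequences") <- sequence[df$name]
  }
  class(df) <- c("ds_panel", "data.frame")
  df
}

panel_sequences <- function(panel) {
  seqs <- attr(panel, "sequences")
  if (is.null(seqs)) {
    stop_fmt("this panel carries no target sequences; supply them via `sequence =` or `fasta =`")
  }
  seqs
}

#' @export
print.ds_panel <- function(x, ...) {
  cat(sprintf(
    "Mutagenesis panel: %d targets, %s bp total (%d genic / %d intergenic, %d heterochromatic)%s\n",
    nrow(x), format(sum(x$end - x$start), big.mark = ","),
    sum(x$region_class == "genic"), sum(x$region_class == "intergenic"),
    sum(x$chromatin == "heterochromatin"),
    if (is.null(attr(x, "sequences"))) "" else ", with sequences"
  ))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("... %d more targets\n", nrow(x) - 8L))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Default 20-target panel
# ---------------------------------------------------------------------------

# Fixed annotation table for the default panel: twenty ~2.4 kb autosomal
# targets (two on chromosome 1), 9 genic / 11 intergenic, 7 heterochromatic,
# GC content balanced around its mean with at most ~20% relative spread.
default_panel_annotation <- function() {
  name <- c("chr1.1", "chr1.2", paste0("chr", 2:19))
  chrom <- c("chr1", "chr1", paste0("chr", 2:19))
  genic <- c("chr3", "chr4", "chr5", "chr7", "chr9", "chr12", "chr13",
             "chr15", "chr18")
  hetero <- c("chr2", "chr5", "chr8", "chr11", "chr13", "chr14", "chr16")
  # deterministic GC ladder, mean 0.429, assigned in a fixed interleaved order
  gc <- seq(0.385, 0.473, length.out = 20L)
  ord <- c(7L, 14L, 3L, 18L, 10L, 1L, 16L, 5L, 12L, 20L,
           8L, 2L, 15L, 9L, 19L, 4L, 11L, 17L, 6L, 13L)
  data.frame(
    name = name,
    chrom = chrom,
    start = 10e6 + c(0, 5e6, seq_len(18L) * 1e6),
    end = 10e6 + c(0, 5e6, seq_len(18L) * 1e6) + 2400,
    region_class = ifelse(name %in% genic, "genic", "intergenic"),
    chromatin = ifelse(name %in% hetero, "heterochromatin", "euchromatin"),
    gc_fraction = gc[ord],
    expression_level = ifelse(name %in% genic,
                              round(2^seq(1, 6, length.out = 9L), 1), NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Default synthetic mutagenesis panel
#'
#' A deterministic 20-target panel (~2.4 kb per target, two targets on
#' chromosome 1, the rest on chromosomes 2-19) with 9 genic and 11 intergenic
#' targets, 7 targets in inferred heterochromatin, and GC content spread
#' around a mean of 42.9%. Target sequences are generated from a fixed
#' internal seed (independent of the user's RNG stream), so the panel is
#' byte-identical across sessions; the realized GC fraction of each sequence
#' is stored as the target's `gc_fraction`.
#'
#' @return A `ds_panel` with attached sequences.
#' @export
#' @examples
#' p <- default_panel()
#' table(p$region_class)
default_panel <- function() {
  ann <- default_panel_annotation()
  seqs <- with_seed(104729L, {
    vapply(seq_len(nrow(ann)), function(i) {
      gc <- ann$gc_fraction[i]
      prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(DNA_BASES, ann$end[i] - ann$start[i], replace = TRUE,
                   prob = prob), collapse = "")
    }, character(1))
  })
  names(seqs) <- ann$name
  gc_real <- vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  panel_targets(
    name = ann$name, chrom = ann$chrom, start = ann$start, end = ann$end,
    region_class = ann$region_class, chromatin = ann$chromatin,
    gc_fraction = round(gc_real, 4), expression_level = ann$expression_level,
    sequence = seqs
  )
}

# ---------------------------------------------------------------------------
# Sequence-derived inventories
# ---------------------------------------------------------------------------

# Positions (1-based within target) of each pyrimidine trinucleotide context.
# Returns a list mapping the 32 contexts to integer position vectors.
target_context_positions <- function(seq) {
  L <- nchar(seq)
  pos <- 2:(L - 1L)
  ctx <- substring(seq, pos - 1L, pos + 1L)
  ctx <- pyr_context(ctx)
  split(pos, factor(ctx, levels = sbs_contexts()))
}

#' Trinucleotide abundance of panel targets
#'
#' Counts, for each target, how many interior positions carry each of the 32
#' pyrimidine-context trinucleotides (purine-centred positions are counted
#' under their reverse complement).
#'
#' @param panel A `ds_panel` with sequences.
#' @return Integer matrix, targets x 32 contexts.
#' @export
panel_tri_abundance <- function(panel) {
  seqs <- panel_sequences(panel)
  out <- t(vapply(seqs, function(s) {
    lengths(target_context_positions(s))
  }, integer(32L)))
  colnames(out) <- sbs_contexts()
  rownames(out) <- panel$name
  out
}

#' CpG site inventory of panel targets
#'
#' A CpG site is a CG dinucleotide, counted once per dinucleotide (not per
#' strand). Returns the 1-based position of the C of each site, per target.
#'
#' @param panel A `ds_panel` with sequences.
#' @return Named list of integer vectors.
#' @export
panel_cpg_sites <- function(panel) {
  seqs <- panel_sequences(panel)
  lapply(seqs, function(s) {
    L <- nchar(s)
    p <- seq_len(L - 1L)
    p[substring(s, p, p) == "C" & substring(s, p + 1L, p + 1L) == "G"]
  })
}

# ---------------------------------------------------------------------------
# BED-like I/O
# ---------------------------------------------------------------------------

#' Read a panel definition from a BED-like file
#'
#' The file must be tab-separated with at least 4 columns (chrom, start, end,
#' name; BED 0-based half-open) and may carry up to four extra annotation
#' columns in order: region_class, chromatin, gc_fraction, expression_level.
#' Lines starting with `#` or `track` are skipped.
#'
#' @param path Path to the BED-like file.
#' @param fasta Optional FASTA file of target sequences named by target.
#' @return A `ds_panel`.
#' @export
read_panel <- function(path, fasta = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop_fmt("%s: no panel records", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop_fmt("%s line %d: expected at least 4 tab-separated columns",
             path, line_no[which(nf < 4L)[1]])
  }
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop_fmt("%s line %d: malformed coordinates", path, line_no[bad[1]])
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    stop_fmt("%s line %d: end must be greater than start", path, line_no[bad[1]])
  }
  sequence <- NULL
  if (!is.null(fasta)) {
    sequence <- read_fasta(fasta)
  }
  panel_targets(
    name = get(4L), chrom = get(1L), start = start, end = end,
    region_class = ifelse(is.na(get(5L)), "intergenic", get(5L)),
    chromatin = ifelse(is.na(get(6L)), "euchromatin", get(6L)),
    gc_fraction = suppressWarnings(as.numeric(get(7L))),
    expression_level = suppressWarnings(as.numeric(get(8L))),
    sequence = sequence
  )
}

#' Write a panel to a BED-like file
#'
#' @param panel A `ds_panel`.
#' @param path Output path.
#' @param fasta Optional path; when given and the panel has sequences, they
#'   are written there as FASTA.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, fasta = NULL) {
  df <- as.data.frame(panel)
  out <- df[, c("chrom", "start", "end", "name", "region_class", "chromatin",
                "gc_fraction", "expression_level")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(fasta)) {
    seqs <- panel_sequences(panel)
    con <- file(fasta, "w")
    on.exit(close(con))
    for (nm in names(seqs)) {
      writeLines(c(paste0(">", nm), seqs[[nm]]), con)
    }
  }
  invisible(path)
}

# Minimal FASTA reader (plain text, possibly wrapped lines).
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_fmt("%s: not a FASTA file", path)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- names_
  toupper(seqs)
}
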