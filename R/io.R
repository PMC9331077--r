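# Readers and writers for mutation calls, duplex depth tables, sample
# metadata and signature catalogs.
#
# Dialects:
#  * mutations (TSV): columns sample_id, chrom, pos (1-based), ref, alt,
#    multiplicity (optional, default 1). var_class and tri_context are
#    derived; target is assigned from the panel.
#  * mutations (VCF v4.x): one sample's calls per file unless the optional
#    INFO key `SAMPLE` is present; multiplicity read from an INFO key
#    (default `AC`), absent key => 1.
#  * depths (TSV): sample_id, target, duplex_bp.
#  * metadata (TSV): sample_id, dose, group (group optional).
#  * signature catalog (TSV): first column the 96 channel labels, one column
#    per signature.

#' Classify a variant from its ref/alt alleles
#'
#' @param ref,alt Allele strings.
#' @return One of `"SNV"`, `"insertion"`, `"deletion"`, `"MNV"`.
#' @export
variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  out <- ifelse(nr == 1L & na == 1L, "SNV",
         ifelse(na > nr, "insertion",
         ifelse(na < nr, "deletion", "MNV")))
  out
}

# Assign each call to the unique containing target. 1-based position p is in
# target t iff t$start < p <= t$end. Calls outside every target are dropped
# with a warning; multi-base calls spanning a target boundary are an error.
assign_targets <- function(chrom, pos, ref, panel) {
  n <- length(pos)
  target <- rep(NA_character_, n)
  known <- chrom %in% panel$chrom
  if (any(!known)) {
    stop_fmt("unknown chromosome(s) in calls: %s",
             paste(unique(chrom[!known]), collapse = ", "))
  }
  for (i in seq_len(nrow(panel))) {
    hit <- chrom == panel$chrom[i] & pos > panel$start[i] & pos <= panel$end[i]
    if (any(hit)) {
      end_pos <- pos + pmax(nchar(ref) - 1L, 0L)
      spans <- hit & end_pos > panel$end[i]
      if (any(spans)) {
        stop_fmt("call at %s:%d spans the boundary of target '%s'",
                 chrom[which(spans)[1]], pos[which(spans)[1]], panel$name[i])
      }
      target[hit] <- panel$name[i]
    }
  }
  target
}

finalize_mutations <- function(df, panel) {
  df$target <- assign_targets(df$chrom, df$pos, df$ref, panel)
  dropped <- sum(is.na(df$target))
  if (dropped > 0L) {
    warn_fmt("dropped %d call(s) outside every panel target", dropped)
    df <- df[!is.na(df$target), , drop = FALSE]
  }
  df$var_class <- variant_class(df$ref, df$alt)
  if (any(df$ref == df$alt)) stop_fmt("ref and alt must differ")
  if (any(df$multiplicity < 1L)) stop_fmt("multiplicity must be >= 1")
  # trinucleotide context from panel sequences when available
  seqs <- attr(panel, "sequences")
  df$tri_context <- NA_character_
  if (!is.null(seqs)) {
    snv <- df$var_class == "SNV"
    if (any(snv)) {
      idx <- match(df$target, panel$name)
      local <- df$pos - panel$start[idx] # 1-based within target
      ok <- snv & local >= 2L & local <= (panel$end[idx] - panel$start[idx] - 1L)
      ctx <- substring(seqs[df$target[ok]], local[ok] - 1L, local[ok] + 1L)
      mism <- substr(ctx, 2L, 2L) != df$ref[ok]
      if (any(mism)) {
        stop_fmt("reference allele mismatch with panel sequence at %s:%d",
                 df$chrom[ok][mism][1], df$pos[ok][mism][1])
      }
      df$tri_context[ok] <- pyr_context(ctx)
    }
  }
  cols <- c("sample_id", "target", "chrom", "pos", "ref", "alt", "var_class",
            "multiplicity", "tri_context")
  df <- df[, cols]
  rownames(df) <- NULL
  df
}

#' Read somatic mutation calls
#'
#' Reads a tabular (TSV) or VCF call list, assigns every call to its unique
#' containing panel target (calls outside all targets are dropped with a
#' warning), classifies variants, and annotates SNVs with their
#' pyrimidine-normalized trinucleotide context when the panel carries
#' sequences.
#'
#' @param path Path to a `.vcf` or TSV file.
#' @param panel A `ds_panel`.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param multiplicity_field INFO key holding the duplex-molecule count for
#'   VCF input (absent key means 1).
#' @return A mutation `data.frame` with columns `sample_id`, `target`,
#'   `chrom`, `pos`, `ref`, `alt`, `var_class`, `multiplicity`,
#'   `tri_context`.
#' @export
read_mutations <- function(path, panel, format = c("auto", "tsv", "vcf"),
                           multiplicity_field = "AC") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    info_get <- function(key) {
      vcfR::extract.info(v, element = key)
    }
    mult <- suppressWarnings(as.integer(info_get(multiplicity_field)))
    mult[is.na(mult)] <- 1L
    sample_id <- info_get("SAMPLE")
    if (all(is.na(sample_id))) {
      sample_id <- rep(sub("\\.vcf(\\.gz)?$", "", basename(path),
                           ignore.case = TRUE), nrow(fix))
    }
    df <- data.frame(
      sample_id = sample_id,
      chrom = fix$CHROM,
      pos = as.numeric(fix$POS),
      ref = toupper(fix$REF),
      alt = toupper(fix$ALT),
      multiplicity = mult,
      stringsAsFactors = FALSE
    )
  } else {
    # read everything as character first: an all-"T" allele column must not
    # collapse to logical
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("sample_id", "chrom", "pos", "ref", "alt")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L) {
      stop_fmt("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
    }
    df$pos <- as.numeric(df$pos)
    df$multiplicity <- if (is.null(df$multiplicity)) 1L else as.integer(df$multiplicity)
    df$ref <- toupper(df$ref)
    df$alt <- toupper(df$alt)
  }
  finalize_mutations(df, panel)
}

#' Write mutation calls
#'
#' `write_mutations` writes the documented TSV dialect; `write_mutations_vcf`
#' writes a minimal VCF v4.2 with `SAMPLE` and `AC` (multiplicity) INFO keys.
#'
#' @param mutations Mutation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutations
#' @export
write_mutations_vcf <- function(mutations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Duplex molecules carrying the variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(mutations) > 0L) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSAMPLE=%s;AC=%d",
                    mutations$chrom, as.integer(mutations$pos), mutations$ref,
                    mutations$alt, mutations$sample_id,
                    as.integer(mutations$multiplicity))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read or write a duplex depth table
#'
#' Depth tables map every (sample, target) pair to the number of duplex base
#' pairs sequenced. `read_depths` checks completeness over the cohort x panel
#' grid when `metadata`/`panel` are given.
#'
#' @param path TSV with columns `sample_id`, `target`, `duplex_bp`.
#' @param metadata Optional sample metadata for completeness checking.
#' @param panel Optional `ds_panel` for completeness checking.
#' @return A depth `data.frame`.
#' @export
read_depths <- function(path, metadata = NULL, panel = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "duplex_bp")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_fmt("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (any(df$duplex_bp < 0)) stop_fmt("duplex_bp must be non-negative")
  if (!is.null(metadata) && !is.null(panel)) {
    grid <- expand.grid(sample_id = metadata$sample_id, target = panel$name,
                        stringsAsFactors = FALSE)
    have <- paste(df$sample_id, df$target)
    lack <- !(paste(grid$sample_id, grid$target) %in% have)
    if (any(lack)) {
      stop_fmt("depth table incomplete: missing %d (sample, target) cell(s)", sum(lack))
    }
  }
  df
}

#' @rdname read_depths
#' @param depths Depth `data.frame` to write.
#' @export
write_depths <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write sample metadata
#'
#' @param path TSV with columns `sample_id`, `dose` (mg/kg/day) and
#'   optionally `group`.
#' @return Metadata `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "dose"), names(df))
  if (length(missing) > 0L) {
    stop_fmt("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop_fmt("sample_id must be unique")
  if (any(df$dose < 0)) stop_fmt("dose must be non-negative")
  if (is.null(df$group)) df$group <- paste0("d", format_dose(df$dose))
  df
}

#' @rdname read_metadata
#' @param metadata Metadata `data.frame` to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature catalog
#'
#' Reads a TSV whose first column holds the 96 channel labels and whose
#' remaining columns each hold one signature. Rows are reordered into
#' canonical channel order; signatures off unit sum by no more than `1e-3`
#' are renormalized, larger deviations are an error.
#'
#' @param path Path to the catalog TSV.
#' @return A `signature_catalog`: numeric matrix (signatures x 96) whose rows
#'   sum to 1.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  signature_catalog(t(mat), channels = labels)
}

#' Construct a signature catalog from a matrix
#'
#' @param mat Numeric matrix, signatures x 96 (rows named by signature).
#' @param channels Channel labels for the columns (any order; reordered to
#'   canonical).
#' @return A `signature_catalog`.
#' @export
signature_catalog <- function(mat, channels = colnames(mat)) {
  canon <- sbs_channels()
  if (ncol(mat) != 96L) {
    stop_fmt("a signature catalog must have exactly 96 channels, got %d", ncol(mat))
  }
  if (is.null(channels)) channels <- canon
  if (length(channels) != 96L) {
    stop_fmt("need 96 channel labels, got %d", length(channels))
  }
  if (anyDuplicated(channels)) stop_fmt("duplicate channel labels")
  missing <- setdiff(canon, channels)
  if (length(missing) > 0L) {
    stop_fmt("catalog channel labels do not match the canonical set (e.g. missing %s)",
             missing[1])
  }
  mat <- mat[, match(canon, channels), drop = FALSE]
  colnames(mat) <- canon
  if (any(mat < 0)) stop_fmt("signature proportions must be non-negative")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-3)) {
    bad <- which(abs(rs - 1) > 1e-3)[1]
    stop_fmt("signature '%s' sums to %.4g, not 1",
             rownames(mat)[bad] %||% as.character(bad), rs[bad])
  }
  mat <- sweep(mat, 1L, rs, "/")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("S", seq_len(nrow(mat)))
  class(mat) <- c("signature_catalog", class(mat))
  mat
}

#' @rdname read_signature_catalog
#' @param catalog A `signature_catalog` to write.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(channel = colnames(catalog), t(unclass(catalog)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
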