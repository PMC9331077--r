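# 96-channel single-base-substitution machinery.
#
# All spectra use the COSMIC convention: substitutions are reported on the
# strand carrying the pyrimidine reference base, giving 6 substitution classes
# (C>A, C>G, C>T, T>A, T>C, T>G), each expanded by the 4 x 4 flanking bases
# into 96 trinucleotide channels, ordered by class, then 5' base, then 3' base.

DNA_BASES <- c("A", "C", "G", "T")

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel labels
#'
#' Channel labels in canonical COSMIC order: six pyrimidine substitution
#' classes (C>A, C>G, C>T, T>A, T>C, T>G), each expanded over the sixteen
#' 5'/3' flanking-base combinations in alphabetical order, e.g. `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  out <- character(0)
  for (cls in SBS_CLASSES) {
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        out <- c(out, paste0(p5, "[", cls, "]", p3))
      }
    }
  }
  out
}

#' Pyrimidine-context trinucleotides
#'
#' The 32 trinucleotides with a central pyrimidine (C or T), in the order in
#' which they appear as channel contexts.
#'
#' @return Character vector of length 32.
#' @export
sbs_contexts <- function() {
  out <- character(0)
  for (mid in c("C", "T")) {
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        out <- c(out, paste0(p5, mid, p3))
      }
    }
  }
  out
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Reverse complement of trinucleotide strings (vectorised over 3-mers).
revcomp3 <- function(x) {
  paste0(
    complement_base(substr(x, 3L, 3L)),
    complement_base(substr(x, 2L, 2L)),
    complement_base(substr(x, 1L, 1L))
  )
}

# Context of a channel label, e.g. "A[C>A]G" -> "ACG".
channel_context <- function(channel) {
  paste0(substr(channel, 1L, 1L), substr(channel, 3L, 3L), substr(channel, 7L, 7L))
}

# Substitution class of a channel label, e.g. "A[C>A]G" -> "C>A".
channel_class <- function(channel) {
  substr(channel, 3L, 5L)
}

#' Pyrimidine-normalized substitution channel
#'
#' Maps a single-base substitution with its trinucleotide context onto the
#' canonical pyrimidine-strand channel. Purine reference bases are
#' reverse-complemented (together with the alternate base and the context)
#' before labelling, so `G>T` in context `AGC` and `C>A` in context `GCT`
#' yield the same channel.
#'
#' @param ref Reference base(s), one of A/C/G/T (vectorised).
#' @param alt Alternate base(s), one of A/C/G/T.
#' @param context Trinucleotide context(s) whose central base equals `ref`.
#' @return Character vector of channel labels such as `"G[C>A]T"`.
#' @export
#' @examples
#' pyrimidine_channel("C", "A", "ACA")
#' pyrimidine_channel("G", "T", "AGC") # reverse-complemented to G[C>A]T
pyrimidine_channel <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))
  if (any(nchar(context) != 3L)) {
    stop_fmt("`context` must be trinucleotides")
  }
  ok_base <- function(x) x %in% DNA_BASES
  if (!all(ok_base(ref)) || !all(ok_base(alt)) ||
      !all(strsplit(paste(context, collapse = ""), "")[[1]] %in% DNA_BASES)) {
    stop_fmt("ambiguous or non-ACGT base in ref/alt/context")
  }
  if (any(substr(context, 2L, 2L) != ref)) {
    stop_fmt("central base of `context` must equal `ref`")
  }
  if (any(ref == alt)) {
    stop_fmt("`ref` and `alt` must differ")
  }
  purine <- ref %in% c("A", "G")
  ref[purine] <- complement_base(ref[purine])
  alt[purine] <- complement_base(alt[purine])
  context[purine] <- revcomp3(context[purine])
  paste0(
    substr(context, 1L, 1L), "[", ref, ">", alt, "]", substr(context, 3L, 3L)
  )
}

# Normalize a trinucleotide to its pyrimidine-strand representation.
pyr_context <- function(context) {
  context <- toupper(context)
  purine <- substr(context, 2L, 2L) %in% c("A", "G")
  context[purine] <- revcomp3(context[purine])
  context
}
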