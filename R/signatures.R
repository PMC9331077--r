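# Cosine-similarity matching of observed trinucleotide spectra against a
# signature catalog.

#' Cosine similarity
#'
#' @param a,b Equal-length numeric vectors with nonzero norm.
#' @return `sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`.
#' @export
#' @examples
#' cosine_similarity(c(1, 2, 3), c(3, 2, 1)) # 10/14
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_fmt("zero-norm vector in cosine similarity")
  sum(a * b) / (na * nb)
}

#' Match a spectrum against a signature catalog
#'
#' Computes the cosine similarity of the query spectrum against every
#' signature and ranks them (descending). Ties are broken by catalog order
#' and flagged.
#'
#' @param spectrum Named 96-vector (counts or proportions; cosine is
#'   scale-free, but the query is converted to proportions for reporting).
#' @param catalog A `signature_catalog` (see [signature_catalog()]).
#' @return A `similarity_report` list: `query_proportions`, `ranking`
#'   (`data.frame` of signature/cosine), `best_match`, `ties`.
#' @export
match_catalog <- function(spectrum, catalog) {
  canon <- sbs_channels()
  if (!is.null(names(spectrum))) {
    if (!setequal(names(spectrum), canon)) {
      bad <- c(setdiff(names(spectrum), canon), setdiff(canon, names(spectrum)))
      stop_fmt("spectrum channel labels do not match the catalog: %s",
               paste(utils::head(bad, 3L), collapse = ", "))
    }
    spectrum <- spectrum[canon]
  } else if (length(spectrum) != 96L) {
    stop_fmt("spectrum must have 96 channels")
  }
  q <- as.numeric(spectrum)
  if (sum(q) <= 0) stop_fmt("spectrum must have positive total")
  q <- q / sum(q)
  cos <- vapply(seq_len(nrow(catalog)), function(i) {
    cosine_similarity(q, as.numeric(catalog[i, ]))
  }, numeric(1))
  names(cos) <- rownames(catalog)
  ord <- order(-cos, seq_along(cos)) # ties broken by catalog order
  ranking <- data.frame(
    signature = names(cos)[ord],
    cosine = unname(cos[ord]),
    stringsAsFactors = FALSE
  )
  ties <- ranking$signature[abs(ranking$cosine - ranking$cosine[1]) < 1e-12]
  structure(
    list(
      query_proportions = stats::setNames(q, canon),
      ranking = ranking,
      best_match = ranking$signature[1],
      ties = if (length(ties) > 1L) ties else character(0)
    ),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Best match: %s (cosine %.4f)\n", x$best_match, x$ranking$cosine[1]))
  print(utils::head(x$ranking, 5L))
  invisible(x)
}

#' Bundled synthetic signature catalog
#'
#' A deterministic five-signature catalog built in code (no external
#' download): a flat signature, a C>A-transversion-rich signature of the
#' kind produced by bulky-adduct mutagens, a CpG-deamination C>T signature,
#' a T>C-rich signature and a C>G-rich signature. Intended for tests and
#' examples; it is synthetic and is not the COSMIC catalog.
#'
#' @return A `signature_catalog` (5 x 96).
#' @export
synthetic_signature_catalog <- function() {
  channels <- sbs_channels()
  cls <- channel_class(channels)
  ctx <- channel_context(channels)
  flat <- rep(1 / 96, 96L)
  weight <- function(class_weights, boost = NULL) {
    v <- stats::setNames(class_weights[cls] / 16, channels)
    if (!is.null(boost)) {
      v[names(boost)] <- v[names(boost)] * boost
    }
    v / sum(v)
  }
  ca_rich <- weight(
    c("C>A" = 0.70, "C>G" = 0.10, "C>T" = 0.08, "T>A" = 0.04, "T>C" = 0.04,
      "T>G" = 0.04),
    boost = stats::setNames(c(3, 5, 3), c("C[C>A]A", "C[C>A]C", "G[C>A]C"))
  )
  cpg_ct <- {
    v <- c("C>A" = 0.05, "C>G" = 0.05, "C>T" = 0.70, "T>A" = 0.07,
           "T>C" = 0.07, "T>G" = 0.06)[cls] / 16
    is_cpg_ct <- cls == "C>T" & substr(ctx, 3L, 3L) == "G"
    v[is_cpg_ct] <- v[is_cpg_ct] * 8
    stats::setNames(v / sum(v), channels)
  }
  tc_rich <- weight(c("C>A" = 0.05, "C>G" = 0.05, "C>T" = 0.10, "T>A" = 0.08,
                      "T>C" = 0.64, "T>G" = 0.08))
  cg_rich <- weight(c("C>A" = 0.08, "C>G" = 0.62, "C>T" = 0.12, "T>A" = 0.06,
                      "T>C" = 0.06, "T>G" = 0.06))
  mat <- rbind(SYN1_flat = flat, SYN2_bulky_CA = ca_rich, SYN3_cpg_CT = cpg_ct,
               SYN4_TC = tc_rich, SYN5_CG = cg_rich)
  colnames(mat) <- channels
  signature_catalog(mat)
}
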