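# Shared fixtures, built in code.

# Scaled-down study configuration: identical rates/spectra to the default,
# shallower sequencing so structural tests stay fast.
small_config <- function(depth_mean = 5e7, n_per_dose = 6L) {
  cfg <- default_bap_config()
  cfg$depth_mean <- depth_mean
  cfg$n_per_dose <- as.integer(n_per_dose)
  cfg
}

# A minimal two-target panel with known sequences for hand-checkable tests.
tiny_panel <- function() {
  seqs <- c(
    t1 = paste(rep("ACGT", 25L), collapse = ""), # 100 bp
    t2 = paste(rep("CCGG", 25L), collapse = "")
  )
  panel_targets(
    name = c("t1", "t2"), chrom = c("chr1", "chr2"),
    start = c(100, 200), end = c(200, 300),
    region_class = c("genic", "intergenic"),
    chromatin = c("euchromatin", "heterochromatin"),
    gc_fraction = c(0.5, 1.0),
    sequence = seqs
  )
}

# Hand-built mutation table (already unique per sample).
tiny_mutations <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s2"),
    target = c("t1", "t1", "t2"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(105, 110, 205),
    ref = c("C", "G", "C"),
    alt = c("A", "T", "T"),
    var_class = "SNV",
    multiplicity = c(1L, 3L, 1L),
    tri_context = c("ACG", "GCT", "CCG"),
    stringsAsFactors = FALSE
  )
}

tiny_depths <- function() {
  expand.grid(sample_id = c("s1", "s2"), target = c("t1", "t2"),
              stringsAsFactors = FALSE) |>
    transform(duplex_bp = 1e7)
}

tiny_metadata <- function() {
  data.frame(sample_id = c("s1", "s2"), dose = c(0, 50),
             group = c("d0", "d50"), stringsAsFactors = FALSE)
}
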