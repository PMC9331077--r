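test_that("the default panel matches the study design", {
  p <- default_panel()
  expect_equal(nrow(p), 20L)
  expect_equal(sum(p$region_class == "genic"), 9L)
  expect_equal(sum(p$region_class == "intergenic"), 11L)
  expect_equal(sum(p$chromatin == "heterochromatin"), 7L)
  expect_true(all(p$end - p$start == 2400))
  expect_equal(mean(p$gc_fraction), 0.429, tolerance = 0.01)
  # deterministic: two builds are identical, and independent of the RNG state
  set.seed(999)
  expect_identical(default_panel(), p)
  ab <- panel_tri_abundance(p)
  expect_true(all(rowSums(ab) == 2398))
})

test_that("panel BED round trip preserves records and errors are located", {
  p <- default_panel()
  bed <- withr::local_tempfile(fileext = ".bed")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_panel(p, bed, fasta = fa)
  p2 <- read_panel(bed, fasta = fa)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  expect_identical(attr(p2, "sequences"), attr(p, "sequences"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\ta", "chr2\t500\t400\tb"), bad)
  expect_error(read_panel(bad), "line 2")
  writeLines(c("chr1\t100\t200\ta", "chr1\t150\t250\tb"), bad)
  expect_error(read_panel(bad), "overlap")
  writeLines(c("chr1\t100\t200\ta", "chr1\t300\t400\ta"), bad)
  expect_error(read_panel(bad), "duplicate")
})

test_that("mutation calls are assigned to targets with boundary conventions", {
  p <- tiny_panel()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  # BED start 100 => first in-target 1-based position is 101; position 200 is
  # the last one in; 201 is out
  df <- data.frame(sample_id = "s1", chrom = c("chr1", "chr1", "chr1"),
                   pos = c(101, 200, 201), ref = "A", alt = "G")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(m <- read_mutations(tsv, p), "dropped 1")
  expect_equal(nrow(m), 2L)
  expect_true(all(m$target == "t1"))
  expect_true(all(m$multiplicity == 1L))
})

test_that("VCF round trip preserves sample, multiplicity and alleles", {
  cfg <- small_config(depth_mean = 2e7, n_per_dose = 2L)
  coh <- generate_cohort(cfg, seed = 3)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_mutations_vcf(coh$mutations, vcf)
  back <- read_mutations(vcf, cfg$panel)
  ord <- function(d) d[order(d$sample_id, d$chrom, d$pos, d$alt), ]
  a <- ord(coh$mutations); b <- ord(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b$sample_id, a$sample_id)
  expect_equal(b$pos, a$pos)
  expect_equal(b$multiplicity, a$multiplicity)
  expect_equal(b$var_class, a$var_class)
  # contexts recomputed from panel sequences agree with generated ones
  expect_equal(b$tri_context[b$var_class == "SNV"],
               a$tri_context[a$var_class == "SNV"])
})

test_that("tabular mutation, depth and metadata round trips are lossless", {
  cfg <- small_config(depth_mean = 2e7, n_per_dose = 2L)
  coh <- generate_cohort(cfg, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mutations(coh$mutations, tsv)
  back <- read_mutations(tsv, cfg$panel)
  expect_equal(back, coh$mutations)

  dts <- withr::local_tempfile(fileext = ".tsv")
  write_depths(coh$depths, dts)
  expect_equal(read_depths(dts, coh$metadata, cfg$panel), coh$depths)

  mts <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(coh$metadata, mts)
  expect_equal(read_metadata(mts), coh$metadata)
})

test_that("signature catalogs validate, renormalize and reorder", {
  cat96 <- synthetic_signature_catalog()
  expect_equal(dim(cat96), c(5L, 96L))
  expect_equal(unname(rowSums(cat96)), rep(1, 5), tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_catalog(cat96, path)
  back <- read_signature_catalog(path)
  expect_equal(unclass(back), unclass(cat96), tolerance = 1e-9)

  # shuffled channel rows parse to the identical catalog
  df <- read.delim(path, check.names = FALSE)
  set.seed(1)
  df <- df[sample.int(nrow(df)), ]
  shuf <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, shuf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_signature_catalog(shuf), back)

  # a column summing to 0.5 is rejected; slight drift is renormalized
  bad <- as.data.frame(t(unclass(cat96)))
  bad[[1]] <- bad[[1]] * 0.5
  bfile <- withr::local_tempfile(fileext = ".tsv")
  write.table(cbind(channel = rownames(bad), bad), bfile, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(bfile), "sums to")
  expect_error(
    signature_catalog(matrix(1 / 95, 2, 95)),
    "96 channels"
  )
})
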