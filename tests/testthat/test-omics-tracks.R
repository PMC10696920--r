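track_layout <- function() {
  genome_layout(tibble::tibble(name = c("chr1", "chr2"),
                               length = c(100000L, 40000L)),
                resolution = 10000)
}

write_bg <- function(df) {
  path <- withr::local_tempfile(fileext = ".bedgraph",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  path
}

test_that("bedGraph bins map one-to-one onto beads", {
  lay <- track_layout()
  k <- 0:9
  path <- write_bg(tibble::tibble(chrom = "chr1", start = k * 10000,
                                  end = (k + 1) * 10000, value = k + 1))
  tr <- read_bedgraph(path, lay)
  v <- tidy(tr)
  expect_equal(v$value[v$chrom == 1], as.numeric(1:10))
  expect_true(all(is.na(v$value[v$chrom == 2])))  # untiled -> missing

  # a gap in the tiling leaves one missing bead
  path2 <- write_bg(tibble::tibble(chrom = "chr1", start = c(0, 20000),
                                   end = c(10000, 30000), value = c(5, 7)))
  v2 <- tidy(read_bedgraph(path2, lay))
  expect_true(is.na(v2$value[2]))
  expect_equal(v2$value[c(1, 3)], c(5, 7))
})

test_that("bedGraph at the wrong bin width is rejected", {
  lay <- track_layout()
  path <- write_bg(tibble::tibble(chrom = "chr1", start = c(0, 5000),
                                  end = c(5000, 10000), value = c(1, 2)))
  expect_error(read_bedgraph(path, lay), "bin width mismatch")
  path2 <- write_bg(tibble::tibble(chrom = "chrX", start = 0, end = 10000,
                                   value = 1))
  expect_error(read_bedgraph(path2, lay), "unknown chromosome")
  path3 <- write_bg(tibble::tibble(chrom = "chr1", start = c(0, 0),
                                   end = c(10000, 10000), value = c(1, 2)))
  expect_error(read_bedgraph(path3, lay), "overlapping")
})

test_that("thresholding follows the binarize-at-80 and floor-at-20 semantics", {
  lay <- single_chrom_layout(3, resolution = 10)
  bin <- threshold_track(hic_track(lay, c(100, 80, 79)), "binarize", 80)
  expect_equal(tidy(bin)$value, c(1, 1, 0))
  flo <- threshold_track(hic_track(lay, c(19, 20, 35)), "floor", 20)
  expect_equal(tidy(flo)$value, c(0, 20, 35))
  zero <- hic_track(lay, c(0, 0, 0))
  expect_equal(tidy(threshold_track(zero, "binarize", 80))$value, c(0, 0, 0))
  expect_equal(tidy(threshold_track(zero, "floor", 20))$value, c(0, 0, 0))
  # missing stays missing; binarized output re-binarizes to itself
  na <- threshold_track(hic_track(lay, c(100, NA, 10)), "binarize", 80)
  expect_equal(tidy(na)$value, c(1, NA, 0))
  expect_equal(tidy(threshold_track(na, "binarize", 1))$value, c(1, NA, 0))
})

test_that("painting fills B-values without touching geometry", {
  lay <- single_chrom_layout(5, resolution = 10000)
  m <- annotate_chromosomes(structure_model(lay, helix_coords(5)))
  tr <- hic_track(lay, c(1, NA, 3, 4, 5))
  p <- paint_model(m, tr)
  expect_equal(p$beads$bvalue, c(1, 0, 3, 4, 5))
  expect_equal(p$beads[, c("x", "y", "z", "status")],
               m$beads[, c("x", "y", "z", "status")])

  other <- single_chrom_layout(5, resolution = 5000)
  expect_error(paint_model(m, hic_track(other, rep(1, 5))), "resolution")

  # round-trip through the PDB B-factor column to 2 decimals
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, path)
  back <- read_pdb(path, layout = lay)
  expect_equal(tidy(back)$bvalue, c(1, 0, 3, 4, 5), tolerance = 0.01)
})

test_that("synthetic tracks round-trip and binarize back to their regions", {
  lay <- track_layout()
  regions <- tibble::tibble(chrom = 1, start = 30000, end = 60000)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  tr <- make_track(lay, regions, high = 100, low = 0, noise_sd = 0,
                   path = path)
  v <- tidy(tr)$value
  enriched <- which(v == 100)
  expect_equal(enriched, 4:6)  # bins ]30,40], ]40,50], ]50,60] kb
  expect_equal(tidy(read_bedgraph(path, lay))$value, v)
  bin <- threshold_track(tr, "binarize", 80)
  expect_equal(which(tidy(bin)$value == 1), enriched)
})
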