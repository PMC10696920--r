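two_chrom_model <- function() {
  lay <- genome_layout(tibble::tibble(name = c("chrI", "chrII"),
                                      length = c(50L, 30L)),
                       resolution = 10)
  coords <- cbind(seq_len(8), c(1, 2, 1, 2, 1, 2, 1, 2), 0)
  annotate_chromosomes(structure_model(lay, coords))
}

test_that("PDB records carry the chromosome annotation scheme", {
  m <- two_chrom_model()
  m$beads$bvalue[2] <- 80
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  lines <- readLines(path)
  at <- lines[startsWith(lines, "ATOM")]
  expect_length(at, 8)
  expect_equal(substr(at, 22, 22), c(rep("A", 5), rep("B", 3)))
  expect_equal(trimws(substr(at, 18, 20)), c(rep("C01", 5), rep("C02", 3)))
  expect_equal(as.integer(substr(at, 23, 26)), c(rep(1L, 5), rep(2L, 3)))
  expect_equal(substr(at[2], 61, 66), " 80.00")
  expect_equal(sum(startsWith(lines, "TER")), 2)
  expect_equal(tail(lines, 1), "END")
  # fixed-column widths: every coordinate field is exactly 8 chars
  expect_true(all(nchar(at) == 78))
  expect_true(all(grepl("^ *-?[0-9]+\\.[0-9]{3}$",
                        c(substr(at, 31, 38), substr(at, 39, 46),
                          substr(at, 47, 54)))))
})

test_that("PDB write -> read -> write is byte-identical", {
  m <- two_chrom_model()
  m$beads$bvalue <- c(0, 80, 12.3, 0, 5, 0, 999, 1)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, p1)
  back <- read_pdb(p1, layout = m$layout)
  write_pdb(back, p2)
  expect_identical(readLines(p2), readLines(p1))
  # coordinates survive to 3 decimals (after the uniform max-100 scaling)
  sc <- 100 / max(abs(as.matrix(m$beads[, c("x", "y", "z")])))
  expect_equal(as.matrix(tidy(back)[, c("x", "y", "z")]),
               unname(as.matrix(m$beads[, c("x", "y", "z")])) * sc,
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(tidy(back)$bvalue, m$beads$bvalue, tolerance = 0.01)
  expect_equal(tidy(back)$chrom, m$beads$chrom)
})

test_that("read_pdb agrees with an independent PDB parser", {
  skip_if_not_installed("bio3d")
  m <- two_chrom_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  ours <- read_pdb(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(as.matrix(tidy(ours)[, c("x", "y", "z")]),
               as.matrix(ref$atom[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  expect_equal(tidy(ours)$chain, ref$atom$chain)
})

test_that("chromosome number follows the residue seq, not chain order", {
  m <- two_chrom_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  lines <- readLines(path)
  swap <- lines  # chains out of alphabet order (column 22 only)
  substr(swap, 22, 22) <- chartr("AB", "ZY", substr(swap, 22, 22))
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(swap, path2)
  back <- read_pdb(path2)
  expect_equal(tidy(back)$chrom, c(rep(1L, 5), rep(2L, 3)))
})

test_that("malformed PDB input is rejected with a line number", {
  m <- two_chrom_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  lines <- readLines(path)
  lines[3] <- substr(lines[3], 1, 40)
  writeLines(lines, path)
  expect_error(read_pdb(path), "truncated ATOM record at line 3")
  writeLines(c("MODEL     1", "ENDMDL", "MODEL     2"), path)
  expect_error(read_pdb(path), "multi-MODEL")
})

test_that("G3D export lists placed beads with 0-based starts", {
  lay <- single_chrom_layout(10, resolution = 10000)
  m <- annotate_chromosomes(structure_model(lay, helix_coords(10)))
  path <- withr::local_tempfile(fileext = ".g3d")
  write_g3d(m, path)
  lines <- readLines(path)
  expect_length(lines, 11)  # header + 10 beads
  expect_match(lines[1], "resolution=10000")
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(first[1], "chr1")
  expect_equal(first[2], "0")  # bead 1 <-> ]0, 10000] starts at 0

  m$beads[4, c("x", "y", "z")] <- NA_real_
  m$beads$status[4] <- "discarded"
  write_g3d(m, path)
  expect_length(readLines(path), 10)  # discarded bead absent
})
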