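# Fixtures are generated in code; nothing is read from disk except what a
# test itself writes to a tempfile.

# Helix tight enough that round(beta * d^-3) stays positive across turns,
# so the contact graph carries cross-turn constraints.
helix_coords <- function(n = 100, radius = 2.2, beads_per_turn = 10,
                         rise = 0.35) {
  k <- seq_len(n) - 1
  theta <- 2 * pi * k / beads_per_turn
  cbind(radius * cos(theta), radius * sin(theta), rise * k)
}

single_chrom_layout <- function(n, resolution = 1) {
  genome_layout(tibble::tibble(name = "chr1",
                               length = as.integer(n * resolution)),
                resolution = resolution)
}

helix_model <- function(n = 100, ...) {
  structure_model(single_chrom_layout(n), helix_coords(n, ...))
}

# straight unit-spaced chain along x
line_model <- function(n, resolution = 1) {
  structure_model(single_chrom_layout(n, resolution),
                  cbind(seq_len(n) - 1, 0, 0))
}

radius_of_gyration <- function(model) {
  p <- as.matrix(tidy(model)[, c("x", "y", "z")])
  p <- p[stats::complete.cases(p), , drop = FALSE]
  sqrt(mean(rowSums(scale(p, scale = FALSE)^2)))
}

write_tmp_fasta <- function(seqs, names = paste0("chr", seq_along(seqs))) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(unlist(purrr::map2(names, seqs, function(n, s) {
    c(paste0(">", n), gsub("(.{60})", "\\1\n", s))
  })), path)
  path
}
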