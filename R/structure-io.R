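#' Write a bead model as an annotated PDB file
#'
#' One `ATOM` record per coordinate-bearing bead, in global order: serial
#' is the running index, atom name `CA`, residue name `C01`, `C02`, ... for
#' the chromosome, chain id `A`, `B`, ... and the chromosome number in the
#' residue sequence field, so any molecular viewer can colour chromosomes
#' immediately. The bead B-value is written to the B-factor column (clipped
#' to `[0, 999.99]`). A `TER` record closes each chromosome and `END` the
#' file. Coordinates are scaled by a single uniform (shape-preserving)
#' factor; the default policy makes the maximum absolute coordinate 100.0,
#' which keeps the fixed `%8.3f` columns representable and makes the writer
#' canonical (write - read - write is byte-identical).
#'
#' @param model An annotated `structure_model` (see
#'   [annotate_chromosomes()]).
#' @param path Output file path.
#' @param scale_policy `"max100"` (default) or `"none"`.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, scale_policy = c("max100", "none")) {
  stopifnot(inherits(model, "structure_model"))
  scale_policy <- match.arg(scale_policy)
  b <- model$beads[placed(model), ]
  if (nrow(b) == 0) abort("model has no coordinate-bearing beads")
  if (anyNA(b$chain) || anyNA(b$resname)) {
    abort("model is not annotated; run annotate_chromosomes() first")
  }
  if (max(b$chrom) > 62) abort("more than 62 chromosomes")
  xyz <- as.matrix(b[, c("x", "y", "z")])
  if (scale_policy == "max100") {
    mx <- max(abs(xyz))
    if (mx > 0) xyz <- xyz * (100 / mx)
  }
  bf <- pmin(pmax(ifelse(is.na(b$bvalue), 0, b$bvalue), 0), 999.99)
  lines <- character(0)
  serial <- 0L
  for (c in unique(b$chrom)) {
    sel <- which(b$chrom == c)
    at <- sprintf(
      "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      serial + seq_along(sel), b$resname[sel][1], b$chain[sel][1], c,
      xyz[sel, 1], xyz[sel, 2], xyz[sel, 3], 1, bf[sel]
    )
    serial <- serial + length(sel)
    serial <- serial + 1L
    ter <- sprintf("TER   %5d      %-3s %s%4d",
                   serial, b$resname[sel][1], b$chain[sel][1], c)
    lines <- c(lines, at, ter)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a bead model from a PDB file
#'
#' Accepts the dialect written by [write_pdb()] or any single-model PDB of
#' point beads. Beads are ordered by atom serial; the chromosome number is
#' taken from the residue sequence field (precedence over the chain
#' letter), and the B-factor column becomes the bead B-value.
#'
#' @param path Path to a PDB file.
#' @param layout Optional `genome_layout` to attach; when absent a minimal
#'   layout is reconstructed from the bead counts (resolution 1).
#' @return A `structure_model`.
#' @export
read_pdb <- function(path, layout = NULL) {
  raw <- readLines(path)
  if (sum(startsWith(raw, "MODEL")) > 1) {
    abort("multi-MODEL PDB files are not supported")
  }
  idx <- which(startsWith(raw, "ATOM  "))
  if (length(idx) == 0) abort("no ATOM records")
  short <- idx[nchar(raw[idx]) < 66]
  if (length(short)) {
    abort(paste0("truncated ATOM record at line ", short[1]))
  }
  at <- raw[idx]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      abort(paste0("malformed ATOM record at line ",
                   idx[which(is.na(v))[1]]))
    }
    v
  }
  serial <- num(substr(at, 7, 11))
  resname <- trimws(substr(at, 18, 20))
  chain <- substr(at, 22, 22)
  resseq <- num(substr(at, 23, 26))
  x <- num(substr(at, 31, 38))
  y <- num(substr(at, 39, 46))
  z <- num(substr(at, 47, 54))
  bf <- num(substr(at, 61, 66))
  ord <- order(serial)
  chrom <- as.integer(resseq[ord])
  df <- tibble(chrom = chrom, chain = chain[ord], resname = resname[ord],
               x = x[ord], y = y[ord], z = z[ord], bvalue = bf[ord])
  if (is.null(layout)) {
    counts <- as.integer(table(factor(df$chrom, levels = sort(unique(df$chrom)))))
    nm <- sprintf("chr%d", sort(unique(df$chrom)))
    layout <- genome_layout(tibble(name = nm, length = counts),
                            resolution = 1)
  }
  n <- n_beads(layout)
  if (n != nrow(df)) {
    # beads missing from the file (e.g. discarded) stay coordinate-less
    model <- structure_model(layout)
    model$beads$status <- "discarded"
    per <- beads_per_chromosome(layout)
    pos <- unlist(lapply(seq_along(per), function(c) {
      k <- sum(df$chrom == c)
      if (k) global_index(layout, c, seq_len(k)) else integer(0)
    }))
    model$beads[pos, c("x", "y", "z")] <-
      df[, c("x", "y", "z")]
    model$beads$bvalue[pos] <- df$bvalue
    model$beads$status[pos] <- "inferred"
  } else {
    model <- structure_model(layout, as.matrix(df[, c("x", "y", "z")]))
    model$beads$bvalue <- df$bvalue
  }
  annotate_chromosomes(model)
}

#' Write a bead model in a G3D-style tab-separated dialect
#'
#' A self-describing text export for genome-structure viewers: a one-line
#' header carrying the resolution, then one record per coordinate-bearing
#' bead with the chromosome name, the 0-based genomic start of the bead's
#' interval, and x, y, z.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_g3d <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$layout$resolution
  b <- model$beads[placed(model), ]
  lines <- c(
    sprintf("##g3d\tresolution=%d", res),
    sprintf("%s\t%d\t%g\t%g\t%g", b$chrom_name, b$start, b$x, b$y, b$z)
  )
  writeLines(lines, path)
  invisible(path)
}
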