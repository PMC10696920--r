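#' Genome layouts: chromosomes, resolution and the bead coordinate system
#'
#' A `genome_layout` holds the ordered chromosomes of a genome and, once a
#' resolution has been set with [make_layout()], the mapping between genomic
#' intervals and beads. Bead numbering is 1-based with left-open intervals:
#' bead `k` of a chromosome covers `](k-1)*res, k*res]` in base pairs,
#' clipped to the chromosome length, so bead 1 covers `]0, res]`. The global
#' bead index concatenates chromosomes in FASTA order.
#'
#' @param chromosomes A data frame with columns `name`, `length` and
#'   optionally `sequence`.
#' @param resolution Bead size in base pairs, or `NULL` when unset.
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, resolution = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  if (!"sequence" %in% names(chromosomes)) chromosomes$sequence <- NA_character_
  if (nrow(chromosomes) == 0) abort("genome has no chromosomes")
  if (anyDuplicated(chromosomes$name)) {
    abort(paste0("duplicate chromosome name: ",
                 chromosomes$name[duplicated(chromosomes$name)][1]))
  }
  if (any(!nzchar(chromosomes$name))) abort("empty chromosome name")
  if (any(chromosomes$length < 1)) abort("chromosome length must be positive")
  ok <- is.na(chromosomes$sequence) |
    nchar(chromosomes$sequence) == chromosomes$length
  if (!all(ok)) abort("sequence length does not match declared length")
  layout <- structure(
    list(chromosomes = chromosomes, resolution = NULL, beads = NULL),
    class = "genome_layout"
  )
  if (!is.null(resolution)) layout <- make_layout(layout, resolution)
  layout
}

valid_dna <- function(x) {
  !grepl("[^ACGTNacgtn]", x)
}

#' Load a genome from a FASTA file
#'
#' Reads a (non-mitochondrial) reference genome. Records are kept in file
#' order, sequences are retained with their case, and the alphabet is
#' restricted to `A,C,G,T,N` upper or lower case.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `genome_layout` with no resolution set.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) abort(paste0("no such file: ", fasta_path))
  recs <- seqinr::read.fasta(fasta_path, as.string = TRUE, seqonly = FALSE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) abort("empty FASTA file")
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  bad <- !valid_dna(seqs)
  if (any(bad)) {
    abort(paste0("non-nucleotide characters in record '", names(recs)[bad][1],
                 "' (allowed: A,C,G,T,N upper or lower case)"))
  }
  genome_layout(tibble(
    name = names(recs),
    length = unname(nchar(seqs)),
    sequence = unname(seqs)
  ))
}

#' Write a genome back to FASTA
#'
#' Sequences are wrapped at 60 columns, the conventional width for corrected
#' reference genomes.
#'
#' @param genome A `genome_layout` whose chromosomes carry sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_layout"))
  chroms <- genome$chromosomes
  if (anyNA(chroms$sequence)) abort("genome has no sequences to write")
  seqinr::write.fasta(
    sequences = as.list(chroms$sequence),
    names = chroms$name,
    file.out = path,
    as.string = TRUE,
    nbchar = 60
  )
  invisible(path)
}

#' Fix the model resolution of a genome layout
#'
#' Computes the bead table: each chromosome gets `ceiling(length/resolution)`
#' beads; the last bead may cover a partial interval (it is kept rather than
#' dropped, so no sequence is silently lost).
#'
#' @param genome A `genome_layout`.
#' @param resolution Bead size in base pairs (>= 1).
#' @return A `genome_layout` with `resolution` and a `beads` tibble holding
#'   `chrom` (number), `chrom_name`, `local`, `global`, `start`, `end`
#'   (0-based start, 1-based inclusive end of the covered interval).
#' @export
make_layout <- function(genome, resolution) {
  stopifnot(inherits(genome, "genome_layout"))
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 1) abort("resolution must be >= 1")
  chroms <- genome$chromosomes
  if (all(resolution > chroms$length)) {
    abort("resolution larger than every chromosome")
  }
  per <- as.integer(ceiling(chroms$length / resolution))
  beads <- purrr::map_dfr(seq_len(nrow(chroms)), function(c) {
    k <- seq_len(per[c])
    tibble(
      chrom = c,
      chrom_name = chroms$name[c],
      local = k,
      start = (k - 1L) * resolution,
      end = pmin(k * resolution, chroms$length[c])
    )
  })
  beads$global <- seq_len(nrow(beads))
  genome$resolution <- resolution
  genome$beads <- beads[, c("chrom", "chrom_name", "local", "global",
                            "start", "end")]
  genome
}

n_beads <- function(layout) {
  if (is.null(layout$beads)) abort("layout has no resolution set")
  nrow(layout$beads)
}

beads_per_chromosome <- function(layout) {
  tab <- table(layout$beads$chrom)
  as.integer(tab[order(as.integer(names(tab)))])
}

global_index <- function(layout, chrom, local) {
  offs <- c(0L, cumsum(beads_per_chromosome(layout)))
  offs[chrom] + local
}

local_index <- function(layout, global) {
  b <- layout$beads
  list(chrom = b$chrom[global], local = b$local[global])
}

#' Reverse-complement a DNA string
#'
#' Case is preserved and `N` maps to `N`; used when correcting inverted
#' assembly segments.
#'
#' @param sequence A DNA string over `A,C,G,T,N` (lowercase allowed).
#' @return The reverse complement.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!valid_dna(sequence)) abort("invalid character in DNA sequence")
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x$chromosomes), " chromosome(s), total ",
      sum(x$chromosomes$length), " bp\n", sep = "")
  if (!is.null(x$resolution)) {
    cat("resolution: ", x$resolution, " bp; ", n_beads(x), " beads\n", sep = "")
  } else {
    cat("resolution: unset\n")
  }
  invisible(x)
}

#' @method tidy genome_layout
#' @export
tidy.genome_layout <- function(x, ...) {
  if (is.null(x$beads)) {
    x$chromosomes[, c("name", "length")]
  } else {
    x$beads
  }
}
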