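#' Contact matrices
#'
#' A `contact_matrix` stores the symmetric, non-negative binned Hi-C counts
#' \eqn{x_{ij}} in sparse upper-triangle canonical form (`i <= j`), indexed
#' by global bead indices of a [genome_layout()].
#'
#' @param layout A `genome_layout` with resolution set.
#' @param pairs A data frame with columns `i`, `j`, `count`. Entries may be
#'   given in either orientation; they are canonicalised to `i <= j`.
#'   Conflicting duplicate entries are an error.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(layout, pairs) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- n_beads(layout)
  pairs <- as_tibble(pairs)[, c("i", "j", "count")]
  if (nrow(pairs) > 0) {
    if (any(pairs$count < 0)) abort("negative contact count")
    if (any(pairs$i < 1 | pairs$i > n | pairs$j < 1 | pairs$j > n)) {
      abort("bead index out of layout bounds")
    }
    ii <- pmin(pairs$i, pairs$j)
    jj <- pmax(pairs$i, pairs$j)
    pairs$i <- ii
    pairs$j <- jj
    key <- paste(pairs$i, pairs$j)
    if (anyDuplicated(key)) {
      agg <- dplyr::distinct(pairs, .data$i, .data$j, .data$count)
      if (anyDuplicated(paste(agg$i, agg$j))) {
        abort("conflicting duplicate entries for a bead pair")
      }
      pairs <- agg
    }
    pairs <- dplyr::arrange(pairs[pairs$count > 0, ], .data$i, .data$j)
  }
  structure(list(layout = layout, pairs = pairs), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", n_beads(x$layout), " beads, ", nrow(x$pairs),
      " non-zero pairs, total count ", sum(x$pairs$count), "\n", sep = "")
  invisible(x)
}

#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) x$pairs

#' Dense representation of a contact matrix
#'
#' @param matrix A `contact_matrix`.
#' @return A base `n x n` symmetric matrix (suitable only for small `n`).
#' @export
as_dense <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  n <- n_beads(matrix$layout)
  m <- base::matrix(0, n, n)
  p <- matrix$pairs
  m[cbind(p$i, p$j)] <- p$count
  m[cbind(p$j, p$i)] <- p$count
  m
}

#' Read a sparse triplet contact matrix (HiC-Pro dialect)
#'
#' The BED file defines bins as 0-based half-open intervals with a 1-based
#' bin id in the fourth column; the matrix file has whitespace-separated
#' rows `binA binB count`. File bin `[k*res, (k+1)*res)` maps to bead `k+1`.
#'
#' @param matrix_path Path to the triplet matrix file.
#' @param bed_path Path to the bin-definition BED file.
#' @param layout A `genome_layout` at the matrix resolution.
#' @return A `contact_matrix`.
#' @export
read_triplet <- function(matrix_path, bed_path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  res <- layout$resolution
  bed <- readr::read_tsv(bed_path, col_names = c("chrom", "start", "end", "bin"),
                         col_types = "ciii", progress = FALSE)
  chroms <- layout$chromosomes
  unknown <- setdiff(bed$chrom, chroms$name)
  if (length(unknown)) abort(paste0("unknown chromosome in BED: ", unknown[1]))
  if (any(bed$start %% res != 0)) {
    abort("BED bin start not aligned with layout resolution")
  }
  len <- chroms$length[match(bed$chrom, chroms$name)]
  exp_end <- pmin(bed$start + res, len)
  if (any(bed$end != exp_end)) {
    abort("BED bin end inconsistent with layout resolution")
  }
  chrom_no <- match(bed$chrom, chroms$name)
  glob <- global_index(layout, chrom_no, bed$start %/% res + 1L)
  bin_map <- rep(NA_integer_, max(bed$bin))
  bin_map[bed$bin] <- glob
  dat <- tryCatch(
    readr::read_table(matrix_path,
                      col_names = c("binA", "binB", "count"),
                      col_types = "iin", progress = FALSE),
    error = function(e) tibble(binA = integer(), binB = integer(),
                               count = numeric())
  )
  if (nrow(dat) > 0) {
    if (any(dat$count < 0)) abort("negative count in matrix file")
    out_of_bed <- dat$binA > length(bin_map) | dat$binB > length(bin_map) |
      is.na(bin_map[dat$binA]) | is.na(bin_map[dat$binB])
    if (any(out_of_bed)) {
      abort("matrix row references a bin id absent from the BED file")
    }
    pairs <- tibble(i = bin_map[dat$binA], j = bin_map[dat$binB],
                    count = dat$count)
  } else {
    pairs <- tibble(i = integer(), j = integer(), count = numeric())
  }
  contact_matrix(layout, pairs)
}

#' Write a contact matrix as sparse triplet + BED
#'
#' The upper triangle (`i <= j`, zero entries omitted) is written to
#' `matrix_path`, and the full bin definition to `bed_path`, in the dialect
#' read by [read_triplet()].
#'
#' @param matrix A `contact_matrix`.
#' @param matrix_path,bed_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_triplet <- function(matrix, matrix_path, bed_path) {
  stopifnot(inherits(matrix, "contact_matrix"))
  b <- matrix$layout$beads
  bed <- tibble(chrom = b$chrom_name, start = b$start, end = b$end,
                bin = b$global)
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  p <- matrix$pairs
  lines <- if (nrow(p) == 0) character(0) else {
    sprintf(ifelse(p$count == round(p$count), "%d\t%d\t%d", "%d\t%d\t%g"),
            p$i, p$j, p$count)
  }
  writeLines(lines, matrix_path)
  invisible(matrix_path)
}

#' Inject Poisson shot noise into a contact matrix
#'
#' Builds the noisy counts \eqn{y_{ij} = x_{ij} + e_{ij}} with
#' \eqn{e_{ij} \sim Poisson(\lambda)} drawn once per unordered pair of beads
#' (the diagonal included by default) and mirrored, so the result stays
#' symmetric. Poisson sampling of read counts is the standard model of shot
#' noise in sequencing data.
#'
#' @param matrix A `contact_matrix` (raw counts; a warning is issued when
#'   counts are non-integer, i.e. look normalised).
#' @param lambda Poisson mean, `>= 0`.
#' @param seed Integer seed; equal seeds give bit-identical noise.
#' @param include_diagonal Add noise to `i == i` pairs as well (default
#'   `TRUE`).
#' @return A `contact_matrix` with additional class `noisy_contact_matrix`
#'   and fields `lambda`, `seed`, `n_pairs` (number of unordered pairs the
#'   noise was drawn over) and `noise` (tibble of the non-zero `e_ij`).
#' @export
inject_shot_noise <- function(matrix, lambda, seed,
                              include_diagonal = TRUE) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (lambda < 0) abort("lambda must be >= 0")
  if (any(matrix$pairs$count != round(matrix$pairs$count))) {
    warn("non-integer counts: matrix looks normalised; shot noise is meant for raw counts")
  }
  n <- n_beads(matrix$layout)
  ut <- which(upper.tri(diag(n), diag = include_diagonal), arr.ind = TRUE)
  ii <- ut[, 1]
  jj <- ut[, 2]
  e <- withr::with_seed(as.integer(seed), rpois(length(ii), lambda))
  x <- as_dense(matrix)
  y <- x[cbind(ii, jj)] + e
  out <- contact_matrix(matrix$layout, tibble(i = ii, j = jj, count = y))
  out$lambda <- lambda
  out$seed <- as.integer(seed)
  out$n_pairs <- length(ii)
  nz <- e > 0
  out$noise <- tibble(i = ii[nz], j = jj[nz], e = e[nz])
  class(out) <- c("noisy_contact_matrix", class(out))
  out
}

#' Contact-map heatmap
#'
#' @param object A `contact_matrix`.
#' @param log_counts Plot `log10(1 + count)` (default) or raw counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, log_counts = TRUE, ...) {
  p <- dplyr::bind_rows(object$pairs,
                        dplyr::rename(object$pairs, i = "j", j = "i"))
  p <- dplyr::distinct(p)
  if (log_counts) p$count <- log10(1 + p$count)
  ggplot2::ggplot(p, ggplot2::aes(.data$i, .data$j, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bead", y = "bead",
                  fill = if (log_counts) "log10(1+count)" else "count")
}
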