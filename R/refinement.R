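#' Interpolate interior missing beads
#'
#' Each interior run of coordinate-less beads is filled from three
#' independent 1-D monotone piecewise-cubic Hermite interpolants (PCHIP;
#' one per axis) over bead local index, with knots at the chromosome's
#' coordinate-bearing beads. The scheme is shape-preserving: it is exact on
#' affine data and never overshoots the knot range. Runs touching a
#' chromosome end are never extrapolated: those beads are discarded.
#'
#' @param model A `structure_model`.
#' @return A refined `structure_model`; filled beads have status
#'   `interpolated`, terminal missing beads `discarded`. A chromosome with
#'   fewer than 2 placed beads has all its beads discarded, with a warning.
#' @export
interpolate_missing <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  b <- model$beads
  for (c in unique(b$chrom)) {
    rows <- which(b$chrom == c)
    has <- stats::complete.cases(b[rows, c("x", "y", "z")]) &
      !(b$status[rows] %in% c("discarded", "filtered"))
    if (sum(has) < 2) {
      if (!all(b$status[rows] == "discarded")) {
        warn(paste0("chromosome ", c,
                    " has fewer than 2 placed beads: all discarded"))
      }
      b[rows, c("x", "y", "z")] <- NA_real_
      b$status[rows] <- "discarded"
      next
    }
    knots <- b$local[rows][has]
    lo <- min(knots)
    hi <- max(knots)
    miss <- which(!has)
    for (axis in c("x", "y", "z")) {
      yk <- b[[axis]][rows][has]
      inner <- miss[b$local[rows][miss] > lo & b$local[rows][miss] < hi]
      if (length(inner)) {
        b[rows[inner], axis] <- pracma::pchip(knots, yk,
                                              b$local[rows][inner])
      }
    }
    inner <- miss[b$local[rows][miss] > lo & b$local[rows][miss] < hi]
    outer <- setdiff(miss, inner)
    b$status[rows[inner]] <- "interpolated"
    b$status[rows[outer]] <- "discarded"
    b[rows[outer], c("x", "y", "z")] <- NA_real_
  }
  model$beads <- b
  model
}

#' Filter geometrically aberrant beads
#'
#' A bead is an outlier when its Euclidean distance to *every*
#' coordinate-bearing sequence neighbour exceeds the threshold (a bead far
#' from one neighbour but close to the other is kept). The threshold is a
#' multiple of the chromosome's median adjacent-bead distance by default,
#' or an absolute distance. Filtered beads lose their coordinates; interior
#' gaps so created are then re-interpolated.
#'
#' @param model A `structure_model`.
#' @param threshold Positive threshold value (default 10).
#' @param type `"multiple"` of the chromosome median adjacent distance, or
#'   `"absolute"` model units.
#' @param reinterpolate Re-run [interpolate_missing()] afterwards (default
#'   `TRUE`).
#' @return A `structure_model`.
#' @export
filter_outliers <- function(model, threshold = 10,
                            type = c("multiple", "absolute"),
                            reinterpolate = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  type <- match.arg(type)
  if (threshold <= 0) abort("threshold must be positive")
  b <- model$beads
  for (c in unique(b$chrom)) {
    rows <- which(b$chrom == c)
    has <- which(stats::complete.cases(b[rows, c("x", "y", "z")]))
    if (length(has) < 2) next
    p <- as.matrix(b[rows[has], c("x", "y", "z")])
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2))
    cut <- if (type == "multiple") threshold * median(seg) else threshold
    if (!is.finite(cut)) next
    k <- length(has)
    prev_far <- c(TRUE, seg > cut)   # no left neighbour counts as far
    next_far <- c(seg > cut, TRUE)
    out <- prev_far & next_far
    # a lone end bead with its only neighbour in range is kept
    out[1] <- seg[1] > cut
    out[k] <- seg[k - 1] > cut
    if (any(out)) {
      b[rows[has[out]], c("x", "y", "z")] <- NA_real_
      b$status[rows[has[out]]] <- "filtered"
    }
  }
  model$beads <- b
  if (reinterpolate) model <- interpolate_missing(model)
  model
}

#' Annotate beads with chromosome number, chain and residue name
#'
#' Chromosome 1 gets chain `A` and residue name `C01`, chromosome 2 chain
#' `B` and `C02`, and so on; chains extend `A-Z` then `a-z` (62
#' chromosomes at most). The chromosome number itself is carried in the PDB
#' residue sequence field by [write_pdb()].
#'
#' @param model A `structure_model`.
#' @return The annotated model. Idempotent.
#' @export
annotate_chromosomes <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  alphabet <- c(LETTERS, letters)
  nc <- max(model$beads$chrom)
  if (nc > length(alphabet)) {
    abort("more than 62 chromosomes: chain alphabet exhausted")
  }
  model$beads$chain <- alphabet[model$beads$chrom]
  model$beads$resname <- sprintf("C%02d", model$beads$chrom)
  model
}

#' Full refinement pass
#'
#' Applies, in order: outlier filtering, interpolation of interior missing
#' beads (with terminal discards), and chromosome annotation. Filtering
#' precedes interpolation so that aberrant beads are replaced by
#' interpolated positions, leaving no coordinate holes except at chromosome
#' ends.
#'
#' @inheritParams filter_outliers
#' @return A refined, annotated `structure_model`.
#' @export
refine_model <- function(model, threshold = 10,
                         type = c("multiple", "absolute")) {
  model <- filter_outliers(model, threshold, type, reinterpolate = FALSE)
  model <- interpolate_missing(model)
  annotate_chromosomes(model)
}
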