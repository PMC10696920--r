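#' Per-bin omics tracks
#'
#' A `hic_track` carries one quantitative value (e.g. normalised ChIP-seq
#' coverage) per bead position of a [genome_layout()]. Its resolution must
#' equal the model resolution it will paint: each bin corresponds to one
#' bead.
#'
#' @param layout A `genome_layout` with resolution set.
#' @param values Numeric vector, one value per bead in global order
#'   (`NA` = missing).
#' @return An object of class `hic_track`.
#' @export
hic_track <- function(layout, values) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- n_beads(layout)
  if (length(values) != n) abort("one value per bead required")
  v <- layout$beads[, c("chrom", "chrom_name", "local", "global")]
  v$value <- as.numeric(values)
  structure(list(layout = layout, values = v), class = "hic_track")
}

#' @export
print.hic_track <- function(x, ...) {
  cat("<hic_track> ", nrow(x$values), " bins at ", x$layout$resolution,
      " bp; ", sum(is.na(x$values$value)), " missing\n", sep = "")
  invisible(x)
}

#' @method tidy hic_track
#' @export
tidy.hic_track <- function(x, ...) x$values

#' Read a bedGraph track at the model resolution
#'
#' UCSC dialect: 4 columns (chrom, start, end, value), 0-based half-open.
#' Intervals must tile chromosomes at exactly the layout resolution (the
#' trailing bin may be clipped to the chromosome length); file bin
#' `[k*res, (k+1)*res)` maps to bead `k+1`. Beads not covered by any
#' interval get a missing value.
#'
#' @param path Path to a bedGraph file.
#' @param layout A `genome_layout` at the track resolution.
#' @return A `hic_track`.
#' @export
read_bedgraph <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  res <- layout$resolution
  bg <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", comment = "#", progress = FALSE)
  chroms <- layout$chromosomes
  unknown <- setdiff(bg$chrom, chroms$name)
  if (length(unknown)) {
    abort(paste0("unknown chromosome in bedGraph: ", unknown[1]))
  }
  len <- chroms$length[match(bg$chrom, chroms$name)]
  exp_end <- pmin(bg$start + res, len)
  if (any(bg$start %% res != 0) || any(bg$end != exp_end)) {
    abort(paste0("bin width mismatch: bedGraph bins must equal the model ",
                 "resolution (", res, " bp)"))
  }
  chrom_no <- match(bg$chrom, chroms$name)
  glob <- global_index(layout, chrom_no, bg$start %/% res + 1L)
  if (anyDuplicated(glob)) abort("overlapping intervals in bedGraph")
  values <- rep(NA_real_, n_beads(layout))
  values[glob] <- bg$value
  hic_track(layout, values)
}

#' Write a track as bedGraph
#'
#' @param track A `hic_track`.
#' @param path Output file path. Missing values are omitted.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "hic_track"))
  b <- track$layout$beads
  v <- track$values$value
  keep <- !is.na(v)
  readr::write_tsv(
    tibble(chrom = b$chrom_name[keep], start = b$start[keep],
           end = b$end[keep], value = v[keep]),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Threshold a track for visualisation
#'
#' `binarize` turns the signal into 0/1 at the cutoff (value >= cutoff
#' maps to 1), e.g. to highlight high-residency cohesin anchor regions at a
#' cutoff of 80 normalised counts. `floor` zeroes values below the cutoff
#' and keeps the rest, e.g. discarding values below 20 counts while keeping
#' the signal continuous. Missing values stay missing; geometry is never
#' touched.
#'
#' @param track A `hic_track`.
#' @param mode `"binarize"` or `"floor"`.
#' @param cutoff Threshold value.
#' @return A `hic_track`.
#' @export
threshold_track <- function(track, mode = c("binarize", "floor"), cutoff) {
  stopifnot(inherits(track, "hic_track"))
  mode <- match.arg(mode)
  v <- track$values$value
  v <- switch(mode,
    binarize = ifelse(v >= cutoff, 1, 0),
    floor = ifelse(v < cutoff, 0, v)
  )
  hic_track(track$layout, v)
}

#' Paint a model with a track
#'
#' Sets each bead's B-value to the track value of its bin (missing values
#' become 0.0), so a subsequent [write_pdb()] carries the signal in the
#' B-factor field. Coordinates and statuses are never altered.
#'
#' @param model A `structure_model`.
#' @param track A `hic_track` on the same layout/resolution.
#' @return A painted `structure_model`.
#' @export
paint_model <- function(model, track) {
  stopifnot(inherits(model, "structure_model"), inherits(track, "hic_track"))
  if (!identical(track$layout$resolution, model$layout$resolution) ||
      nrow(track$values) != nrow(model$beads)) {
    abort("track resolution/layout does not match the model")
  }
  v <- track$values$value
  model$beads$bvalue <- ifelse(is.na(v), 0, v)
  model
}

#' Track profile plot
#'
#' @param object A `hic_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hic_track
#' @export
autoplot.hic_track <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(.data$local, .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom_name), scales = "free_x") +
    ggplot2::labs(x = "bin", y = "signal")
}
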