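#' Adjacent-bead distance profile
#'
#' Euclidean distances between beads with successive sequence numbers,
#' restricted to consecutive coordinate-bearing beads, per chromosome. On a
#' correctly assembled genome the profile is smooth; an inverted assembly
#' segment shows up as two isolated spikes at its junctions, because the
#' spatial chaining of beads disagrees with the sequence numbering there.
#'
#' @param model A refined `structure_model`.
#' @return A tibble of class `adjacency_profile` with columns `chrom`,
#'   `chrom_name`, `k` (lower bead local index of the pair) and `dist`.
#' @export
adjacency_profile <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  b <- model$beads
  out <- purrr::map_dfr(unique(b$chrom), function(c) {
    rows <- which(b$chrom == c)
    has <- stats::complete.cases(b[rows, c("x", "y", "z")])
    if (sum(has) < 2) abort(paste0("chromosome ", c,
                                   " has fewer than 2 placed beads"))
    loc <- b$local[rows][has]
    p <- as.matrix(b[rows[has], c("x", "y", "z")])
    consec <- which(diff(loc) == 1L)
    tibble(
      chrom = c,
      chrom_name = b$chrom_name[rows][1],
      k = loc[consec],
      dist = sqrt(rowSums((p[consec + 1, , drop = FALSE] -
                             p[consec, , drop = FALSE])^2))
    )
  })
  class(out) <- c("adjacency_profile", class(out))
  out
}

#' @method autoplot adjacency_profile
#' @export
autoplot.adjacency_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$k, .data$dist)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom_name), scales = "free_x") +
    ggplot2::labs(x = "bead index (lower of the adjacent pair)",
                  y = "Euclidean distance between successive beads")
}

reverse_segment_coords <- function(model, chrom, from, to) {
  rows <- which(model$beads$chrom == chrom &
                  model$beads$local >= from & model$beads$local <= to)
  cols <- c("x", "y", "z", "status")
  model$beads[rows, cols] <- model$beads[rev(rows), cols]
  model
}

#' Detect assembly inversions from a 3D model
#'
#' Flags adjacent-bead pairs whose distance exceeds `tau` times the
#' chromosome's median adjacent distance, pairs flagged junctions greedily
#' left to right, and for each candidate pair of junctions `(i, i+1)` and
#' `(j, j+1)` tentatively reverses the bead order on the segment
#' `[i+1, j]`. The candidate is accepted iff both junction distances fall
#' to `tau` times the median or below afterwards. An odd flagged junction
#' left unpaired is reported (`accepted = FALSE`, kind `"unpaired"`): it
#' indicates an anomaly this method does not correct (e.g. a
#' translocation).
#'
#' @param model A refined `structure_model`.
#' @param tau Threshold multiple of the median adjacent distance (> 1;
#'   default 5).
#' @return A tibble of class `inversion_report`: one row per candidate,
#'   with the chromosome, junction indices `i` and `j` (lower bead of each
#'   flagged pair), the inverted bead segment `[seg_from, seg_to]`, its
#'   genomic interval, pre- and post-correction junction distances, and
#'   `accepted`. Empty when nothing is flagged.
#' @export
detect_inversions <- function(model, tau = 5) {
  stopifnot(inherits(model, "structure_model"))
  if (tau <= 1) abort("tau must be > 1")
  prof <- adjacency_profile(model)
  res <- model$layout$resolution
  out <- purrr::map_dfr(unique(prof$chrom), function(c) {
    pc <- prof[prof$chrom == c, ]
    med <- median(pc$dist)
    cut <- tau * med
    flagged <- pc$k[pc$dist > cut]
    if (length(flagged) == 0) return(NULL)
    rows <- NULL
    f <- flagged
    while (length(f) >= 2) {
      i <- f[1]
      j <- f[2]
      f <- f[-(1:2)]
      cand <- reverse_segment_coords(model, c, i + 1L, j)
      pi_ <- pc$dist[pc$k == i]
      pj_ <- pc$dist[pc$k == j]
      pcand <- adjacency_profile(cand)
      pcand <- pcand[pcand$chrom == c, ]
      post_i <- pcand$dist[pcand$k == i]
      post_j <- pcand$dist[pcand$k == j]
      ok <- length(post_i) == 1 && length(post_j) == 1 &&
        post_i <= cut && post_j <= cut
      rows <- dplyr::bind_rows(rows, tibble(
        chrom = c, chrom_name = pc$chrom_name[1],
        i = i, j = j, seg_from = i + 1L, seg_to = j,
        start = i * res,
        end = min(j * res,
                  model$layout$chromosomes$length[c]),
        pre_dist_i = pi_, pre_dist_j = pj_,
        post_dist_i = post_i, post_dist_j = post_j,
        median_adjacent = med, tau = tau,
        kind = "inversion", accepted = ok
      ))
    }
    if (length(f) == 1) {
      rows <- dplyr::bind_rows(rows, tibble(
        chrom = c, chrom_name = pc$chrom_name[1],
        i = f, j = NA_integer_, seg_from = NA_integer_,
        seg_to = NA_integer_, start = NA_integer_, end = NA_integer_,
        pre_dist_i = pc$dist[pc$k == f], pre_dist_j = NA_real_,
        post_dist_i = NA_real_, post_dist_j = NA_real_,
        median_adjacent = med, tau = tau,
        kind = "unpaired", accepted = FALSE
      ))
    }
    rows
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(
      chrom = integer(), chrom_name = character(), i = integer(),
      j = integer(), seg_from = integer(), seg_to = integer(),
      start = integer(), end = integer(), pre_dist_i = numeric(),
      pre_dist_j = numeric(), post_dist_i = numeric(),
      post_dist_j = numeric(), median_adjacent = numeric(),
      tau = numeric(), kind = character(), accepted = logical()
    )
  }
  class(out) <- c("inversion_report", class(out))
  out
}

#' Apply an accepted inversion correction
#'
#' Reverse-complements the genomic interval spanned by the inverted bead
#' segment in the genome sequence, and reverses the bead labels on the
#' segment in the model (the spatial coordinates are untouched; their
#' assignment to sequence indices is permuted back). Applying the same
#' correction twice restores the original genome and model exactly.
#'
#' @param genome A `genome_layout` with sequences loaded.
#' @param model The `structure_model` the report was computed on.
#' @param report A single accepted row of an `inversion_report` (or a
#'   report whose accepted rows are applied in order).
#' @return A list with elements `genome` and `model`, corrected.
#' @export
apply_correction <- function(genome, model, report) {
  stopifnot(inherits(genome, "genome_layout"),
            inherits(model, "structure_model"))
  rows <- report[report$accepted %in% TRUE, ]
  if (nrow(rows) == 0) abort("report contains no accepted inversion")
  res <- model$layout$resolution
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    seq_ <- genome$chromosomes$sequence[r$chrom]
    if (is.na(seq_)) abort("genome sequence absent")
    from_bp <- (r$seg_from - 1L) * res + 1L
    to_bp <- min(r$seg_to * res, nchar(seq_))
    segment <- substr(seq_, from_bp, to_bp)
    substr(seq_, from_bp, to_bp) <- reverse_complement(segment)
    genome$chromosomes$sequence[r$chrom] <- seq_
    model <- reverse_segment_coords(model, r$chrom, r$seg_from, r$seg_to)
  }
  list(genome = genome, model = model)
}

#' Iterated inversion detect-and-correct
#'
#' Runs [detect_inversions()] and [apply_correction()] until no accepted
#' inversion remains (at most `max_rounds` rounds), handling multiple
#' inversions on one genome.
#'
#' @inheritParams detect_inversions
#' @param genome A `genome_layout` with sequences.
#' @param max_rounds Maximum detect/correct rounds (default 5).
#' @return A list with `genome`, `model` and `reports` (all rounds,
#'   row-bound).
#' @export
correct_assembly <- function(genome, model, tau = 5, max_rounds = 5) {
  reports <- NULL
  for (round in seq_len(max_rounds)) {
    rep_ <- detect_inversions(model, tau)
    reports <- dplyr::bind_rows(reports, rep_)
    if (!any(rep_$accepted)) break
    fixed <- apply_correction(genome, model, rep_)
    genome <- fixed$genome
    model <- fixed$model
  }
  list(genome = genome, model = model, reports = reports)
}
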