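#' Specification of a synthetic Rabl-like genome structure
#'
#' The generator emulates the hallmark features of fungal nuclear
#' architecture: centromeres clustered at one pole, telomeres pointing
#' toward the opposite side (the Rabl "clothespin" arrangement), coiled
#' chromosome arms, and angularly separated chromosome territories. The
#' default genome is 3 chromosomes of 1.0/0.8/0.6 Mb at 10 kb resolution
#' (60-100 beads each): large enough to exhibit the Rabl features, small
#' enough for seconds-scale inference.
#'
#' @param chrom_lengths Chromosome lengths in bp.
#' @param resolution Bead size in bp.
#' @param centromere_pos Centromere positions in bp (default 40% of each
#'   length).
#' @param cluster_radius Radius of the centromere cluster around the pole
#'   (model units; adjacent beads are ~1 unit apart).
#' @param pole_offset Axial reach of the arms toward the telomere pole, as
#'   the per-bead axial step (model units).
#' @param coil_radius Helix radius of the coiled arms.
#' @param beads_per_turn Beads per helix turn (sets the coil pitch).
#' @param territory_spread Lateral spread of chromosome axes (controls
#'   territory separation).
#' @param jitter_sd Gaussian positional jitter (model units).
#' @param seed Integer seed.
#' @return A list of class `rabl_spec`.
#' @export
rabl_spec <- function(chrom_lengths = c(1e6, 8e5, 6e5),
                      resolution = 1e4,
                      centromere_pos = 0.4 * chrom_lengths,
                      cluster_radius = 2.5,
                      pole_offset = 0.35,
                      coil_radius = 0.8,
                      beads_per_turn = 10,
                      territory_spread = 0.35,
                      jitter_sd = 0.05,
                      seed = 42) {
  if (any(centromere_pos <= 0 | centromere_pos >= chrom_lengths)) {
    abort("centromere position must lie within the chromosome")
  }
  if (cluster_radius <= 0 || pole_offset <= 0 || coil_radius <= 0) {
    abort("geometric parameters must be positive")
  }
  if (any(resolution > chrom_lengths)) {
    abort("resolution incompatible with chromosome lengths")
  }
  structure(list(chrom_lengths = chrom_lengths, resolution = resolution,
                 centromere_pos = centromere_pos,
                 cluster_radius = cluster_radius, pole_offset = pole_offset,
                 coil_radius = coil_radius, beads_per_turn = beads_per_turn,
                 territory_spread = territory_spread, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "rabl_spec")
}

#' Generate a Rabl-like bead structure
#'
#' Per chromosome, a continuous bead curve: both arms run from a point
#' near the centromere pole (the origin) toward the opposite telomere pole
#' as helices around a chromosome-specific tilted axis, with a phase
#' offset between the arms. Chromosomes are offset angularly, giving
#' separate territories. Deterministic given the spec's seed.
#'
#' @param spec An [rabl_spec()].
#' @return A `structure_model` (all beads status `inferred`) on a layout
#'   with chromosomes named `chr1`, `chr2`, ...
#' @export
make_rabl_structure <- function(spec = rabl_spec()) {
  stopifnot(inherits(spec, "rabl_spec"))
  C <- length(spec$chrom_lengths)
  layout <- genome_layout(
    tibble(name = sprintf("chr%d", seq_len(C)),
           length = as.integer(spec$chrom_lengths)),
    resolution = spec$resolution
  )
  per <- beads_per_chromosome(layout)
  coords <- base::matrix(NA_real_, n_beads(layout), 3)
  for (c in seq_len(C)) {
    m <- per[c]
    kc <- max(1L, min(m - 1L,
                      as.integer(ceiling(spec$centromere_pos[c] /
                                           spec$resolution))))
    theta <- 2 * pi * (c - 1) / C
    p0 <- c(spec$cluster_radius / 2 * cos(theta),
            spec$cluster_radius / 2 * sin(theta), 0)
    u <- c(spec$territory_spread * cos(theta),
           spec$territory_spread * sin(theta), 1)
    u <- u / sqrt(sum(u^2))
    e1 <- c(-sin(theta), cos(theta), 0)
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    arm_bead <- function(t, phase) {
      phi <- 2 * pi * t / spec$beads_per_turn + phase + theta
      p0 + t * spec$pole_offset * u +
        spec$coil_radius * (cos(phi) * e1 + sin(phi) * e2)
    }
    # arm 1: beads kc..1 walk outward from the centromere
    for (k in seq_len(kc)) {
      g <- global_index(layout, c, k)
      coords[g, ] <- arm_bead(kc - k, 0)
    }
    # arm 2: beads kc+1..m, axially offset half a step and phase-shifted
    # so the two arms interleave (folded against each other) without a
    # spacing spike at the centromere junction
    for (k in seq(kc + 1L, m)) {
      g <- global_index(layout, c, k)
      coords[g, ] <- arm_bead(k - kc - 0.5, 0.8)
    }
  }
  coords <- coords + withr::with_seed(
    spec$seed,
    base::matrix(rnorm(length(coords), sd = spec$jitter_sd), ncol = 3)
  )
  model <- structure_model(layout, coords)
  annotate_chromosomes(model)
}

#' Random genome sequences for a layout
#'
#' Uniform random A/C/G/T sequences matching the given chromosome lengths;
#' used when a fixture needs actual sequence (e.g. inversion planting and
#' correction).
#'
#' @param layout A `genome_layout` (sequences are replaced).
#' @param seed Integer seed.
#' @return The layout with sequences filled in.
#' @export
random_genome <- function(layout, seed = 42) {
  stopifnot(inherits(layout, "genome_layout"))
  withr::with_seed(as.integer(seed), {
    layout$chromosomes$sequence <- vapply(
      layout$chromosomes$length,
      function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                        collapse = ""),
      character(1)
    )
  })
  layout
}

#' Simulate contact counts from a structure
#'
#' The generative counterpart of the inference model: expected counts
#' \eqn{\mu_{ij} = \beta d_{ij}^{\alpha}} over all pairs of placed beads,
#' realised as `round(mu)` (`"none"`), Poisson draws (`"poisson"`) or
#' negative binomial draws (`"nb"`, dispersion `params$r`). Symmetric and
#' reproducible.
#'
#' @param model A `structure_model` with coordinates for all beads used.
#' @param params An [nb_params()].
#' @param noise `"none"`, `"poisson"` or `"nb"`.
#' @param seed Integer seed (used for the stochastic modes).
#' @return A `contact_matrix` on the model's layout.
#' @export
counts_from_structure <- function(model, params = nb_params(beta = 100),
                                  noise = c("none", "poisson", "nb"),
                                  seed = 42) {
  stopifnot(inherits(model, "structure_model"))
  noise <- match.arg(noise)
  idx <- which(placed(model))
  p <- coords_matrix(model)[idx, , drop = FALSE]
  n <- length(idx)
  ut <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ii <- ut[, 1]
  jj <- ut[, 2]
  d <- pair_distances(p, ii, jj)
  if (any(d == 0)) abort("coincident beads")
  mu <- params$beta * d^params$alpha
  counts <- switch(noise,
    none = round(mu),
    poisson = withr::with_seed(as.integer(seed), rpois(length(mu), mu)),
    nb = withr::with_seed(as.integer(seed),
                          stats::rnbinom(length(mu), size = params$r,
                                         mu = mu))
  )
  contact_matrix(model$layout,
                 tibble(i = idx[ii], j = idx[jj], count = counts))
}

#' Plant an assembly inversion into a genome and model
#'
#' Produces the configuration in which sequence numbering disagrees with
#' spatial chaining: the segment's genomic interval is reverse-complemented
#' in the genome sequence, and the model's bead labels on the segment are
#' reversed (the geometry is untouched). [apply_correction()] round-trips
#' this exactly.
#'
#' @param genome A `genome_layout` with sequences (see [random_genome()]).
#' @param model A `structure_model` on the same layout.
#' @param chromosome Chromosome number.
#' @param segment Bead interval `c(from, to)` in local indices, strictly
#'   interior to the chromosome and of length >= 2.
#' @return A list with the mis-assembled `genome` and mislabelled `model`.
#' @export
plant_inversion <- function(genome, model, chromosome, segment) {
  stopifnot(inherits(genome, "genome_layout"),
            inherits(model, "structure_model"))
  from <- segment[1]
  to <- segment[2]
  nb <- sum(model$beads$chrom == chromosome)
  if (from <= 1 || to >= nb) abort("segment touches chromosome ends")
  if (to - from + 1 < 2) abort("segment must span at least 2 beads")
  res <- model$layout$resolution
  seq_ <- genome$chromosomes$sequence[chromosome]
  if (is.na(seq_)) abort("genome sequence absent")
  from_bp <- (from - 1L) * res + 1L
  to_bp <- min(to * res, nchar(seq_))
  substr(seq_, from_bp, to_bp) <-
    reverse_complement(substr(seq_, from_bp, to_bp))
  genome$chromosomes$sequence[chromosome] <- seq_
  model <- reverse_segment_coords(model, chromosome, from, to)
  list(genome = genome, model = model)
}

#' Generate a two-level omics track
#'
#' Emulates ChIP-seq enrichment (e.g. a histone mark accumulating in
#' centromeric or sub-telomeric bins): `high` signal in bins overlapping
#' the enriched regions, `low` elsewhere, plus Gaussian noise truncated at
#' zero (the consumed quantity is normalised coverage, not raw counts).
#'
#' @param layout A `genome_layout` with resolution set.
#' @param enriched_regions Data frame with columns `chrom` (number),
#'   `start`, `end` (0-based half-open bp intervals).
#' @param high,low Signal levels (non-negative).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param path Optional bedGraph output path.
#' @return A `hic_track`.
#' @export
make_track <- function(layout, enriched_regions, high = 100, low = 0,
                       noise_sd = 0, seed = 42, path = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (high < 0 || low < 0) abort("levels must be non-negative")
  er <- as_tibble(enriched_regions)
  b <- layout$beads
  lens <- layout$chromosomes$length
  if (any(er$start < 0 | er$end > lens[er$chrom])) {
    abort("enriched region outside chromosome")
  }
  enriched <- rep(FALSE, nrow(b))
  for (k in seq_len(nrow(er))) {
    enriched <- enriched | (b$chrom == er$chrom[k] &
                              b$start < er$end[k] & b$end > er$start[k])
  }
  v <- ifelse(enriched, high, low)
  if (noise_sd > 0) {
    v <- pmax(0, v + withr::with_seed(as.integer(seed),
                                      rnorm(length(v), sd = noise_sd)))
  }
  track <- hic_track(layout, v)
  if (!is.null(path)) write_bedgraph(track, path)
  track
}
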