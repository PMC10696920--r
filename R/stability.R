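#' Optimal superposition RMSD between two bead models
#'
#' Least-squares (Kabsch) superposition over the beads that carry
#' coordinates in both models: centring, optimal rotation, optionally the
#' reflection branch (taking the smaller RMSD) and optionally a uniform
#' scale. Both options default to on because inferred structures are
#' defined only up to a similarity transform (orientation, chirality and
#' scale trade off against the model parameters). With scaling on, `other`
#' is scaled onto `reference` (documented asymmetry); with scaling off the
#' measure is symmetric.
#'
#' @param reference,other `structure_model`s sharing a layout.
#' @param allow_scaling Fit a uniform scale (default `TRUE`).
#' @param allow_reflection Allow an improper rotation (default `TRUE`).
#' @return A list with `rmsd`, `rotation` (3x3), `scale`, and the common
#'   bead count `n`.
#' @export
superpose_rmsd <- function(reference, other, allow_scaling = TRUE,
                           allow_reflection = TRUE) {
  stopifnot(inherits(reference, "structure_model"),
            inherits(other, "structure_model"))
  common <- placed(reference) & placed(other)
  if (sum(common) < 3) abort("fewer than 3 common beads")
  X <- coords_matrix(reference)[common, , drop = FALSE]
  Y <- coords_matrix(other)[common, , drop = FALSE]
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  branch <- function(reflect) {
    sign3 <- if (reflect) c(1, 1, -1) else c(1, 1, 1)
    R <- s$u %*% diag(sign3) %*% t(s$v)
    trace <- sum(s$d * sign3)
    sc <- if (allow_scaling) trace / sum(Yc * Yc) else 1
    fit <- sc * Yc %*% R
    list(rmsd = sqrt(mean(rowSums((fit - Xc)^2))), rotation = R, scale = sc)
  }
  det_plain <- det(s$u %*% t(s$v))
  if (allow_reflection) {
    a <- branch(FALSE)
    b <- branch(TRUE)
    best <- if (a$rmsd <= b$rmsd) a else b
  } else {
    best <- branch(det_plain < 0)  # force a proper rotation
  }
  c(best, list(n = sum(common)))
}

#' Configuration of the shot-noise stability experiment
#'
#' The default grid spans 23 noise intensities, `0.1` then `5, 10, ...,
#' 110`, with 50 replicates each (1150 cells in total). Per-cell noise
#' seeds are derived deterministically from `base_seed`, the position of
#' lambda in the grid and the replicate index, so results are independent
#' of scheduling order; the inference seed is identical across cells so
#' RMSD differences reflect noise, not initialisation.
#'
#' @param lambda_grid Poisson intensities (all `>= 0`).
#' @param replicates Replicates per intensity (>= 1).
#' @param base_seed Integer master seed.
#' @param fit A [fit_config()] shared by all cells.
#' @param outlier_threshold Refinement outlier threshold (multiple of the
#'   median adjacent distance).
#' @param allow_scaling,allow_reflection Superposition options (see
#'   [superpose_rmsd()]).
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(lambda_grid = c(0.1, seq(5, 110, by = 5)),
                         replicates = 50, base_seed = 1,
                         fit = fit_config(), outlier_threshold = 10,
                         allow_scaling = TRUE, allow_reflection = TRUE) {
  if (any(lambda_grid < 0)) abort("lambda must be >= 0")
  if (replicates < 1) abort("replicates must be >= 1")
  structure(list(lambda_grid = lambda_grid, replicates = replicates,
                 base_seed = as.integer(base_seed), fit = fit,
                 outlier_threshold = outlier_threshold,
                 allow_scaling = allow_scaling,
                 allow_reflection = allow_reflection),
            class = "noise_config")
}

#' Enumerate the cells of a noise experiment
#'
#' @param config A [noise_config()].
#' @return A tibble with one row per (lambda, replicate) cell and its
#'   derived noise seed.
#' @export
noise_design <- function(config) {
  stopifnot(inherits(config, "noise_config"))
  grid <- tidyr::expand_grid(
    lambda_index = seq_along(config$lambda_grid),
    replicate = seq_len(config$replicates)
  )
  grid$lambda <- config$lambda_grid[grid$lambda_index]
  grid$seed <- as.integer(
    (as.numeric(config$base_seed) * 1000003 +
       grid$lambda_index * 1009 + grid$replicate) %% 2147483647
  )
  grid[, c("lambda_index", "lambda", "replicate", "seed")]
}

#' Poisson shot-noise stability experiment
#'
#' Fits and refines a reference structure from the raw matrix, then for
#' each (lambda, replicate) cell injects symmetric Poisson noise
#' (`y_ij = x_ij + e_ij`), re-fits, and records the RMSD to the reference
#' after optimal superposition: globally, and per chromosome with each
#' chromosome superposed independently. Inference failures in a cell are
#' recorded (`rmsd = NA` with the error message), not fatal.
#'
#' @param matrix A `contact_matrix` of raw counts.
#' @param config A [noise_config()].
#' @return A tibble of class `rmsd_records`, long format: `lambda`,
#'   `replicate`, `seed`, `scope` (`"global"` or the chromosome name) and
#'   `rmsd`.
#' @export
run_noise_experiment <- function(matrix, config = noise_config()) {
  stopifnot(inherits(matrix, "contact_matrix"))
  refit <- function(mat) {
    refine_model(fit_structure(mat, config$fit),
                 threshold = config$outlier_threshold)
  }
  reference <- refit(matrix)
  chroms <- unique(reference$beads$chrom)
  chrom_names <- reference$beads$chrom_name[match(chroms,
                                                  reference$beads$chrom)]
  subset_chrom <- function(model, c) {
    keep <- model$beads$chrom == c
    model$beads[!keep, c("x", "y", "z")] <- NA_real_
    model
  }
  design <- noise_design(config)
  rows <- purrr::map_dfr(seq_len(nrow(design)), function(r) {
    cell <- design[r, ]
    base <- cell[, c("lambda", "replicate", "seed")]
    result <- tryCatch({
      noisy <- inject_shot_noise(matrix, cell$lambda, cell$seed)
      m <- refit(noisy)
      g <- superpose_rmsd(reference, m, config$allow_scaling,
                          config$allow_reflection)$rmsd
      per <- vapply(chroms, function(c) {
        tryCatch(
          superpose_rmsd(subset_chrom(reference, c), subset_chrom(m, c),
                         config$allow_scaling,
                         config$allow_reflection)$rmsd,
          error = function(e) NA_real_
        )
      }, numeric(1))
      tibble(base, scope = c("global", chrom_names),
             rmsd = c(g, per), note = NA_character_)
    }, error = function(e) {
      tibble(base, scope = "global", rmsd = NA_real_,
             note = conditionMessage(e))
    })
    result
  })
  class(rows) <- c("rmsd_records", class(rows))
  rows
}

#' Summarise RMSD records per noise intensity
#'
#' @param records An `rmsd_records` tibble from [run_noise_experiment()].
#' @param path Optional TSV output path.
#' @return A tibble with, per scope and lambda: `n`, `q1`, `median`, `q3`.
#' @export
summarize_rmsd <- function(records, path = NULL) {
  if (nrow(records) == 0) abort("no records to summarise")
  out <- records %>%
    dplyr::filter(!is.na(.data$rmsd)) %>%
    group_by(.data$scope, .data$lambda) %>%
    summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$rmsd, 0.25),
      median = median(.data$rmsd),
      q3 = stats::quantile(.data$rmsd, 0.75),
      .groups = "drop"
    ) %>%
    arrange(.data$scope != "global", .data$scope, .data$lambda)
  class(out) <- c("rmsd_summary", class(out))
  if (!is.null(path)) readr::write_tsv(out, path, progress = FALSE)
  out
}

#' @method autoplot rmsd_summary
#' @export
autoplot.rmsd_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lambda, .data$median,
                                       colour = .data$scope)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q1, ymax = .data$q3,
                                      fill = .data$scope),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = "RMSD (model units)")
}
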