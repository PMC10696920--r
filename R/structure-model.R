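#' 3D bead structure models
#'
#' A `structure_model` holds one bead per bin of a [genome_layout()], in
#' global (sequence) order, with 3D coordinates in arbitrary model units, a
#' status and a B-value carrying optional omics signal. Statuses:
#' `inferred` (placed by the fit), `interpolated` (filled by refinement),
#' `discarded` (terminal missing bead), `filtered` (geometric outlier),
#' `missing` (no coordinates yet, resolved by refinement).
#'
#' @param layout A `genome_layout` with resolution set.
#' @param coords Optional `n x 3` matrix of coordinates (rows may be `NA`).
#' @param status Optional character vector of per-bead statuses.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(layout, coords = NULL, status = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- n_beads(layout)
  beads <- layout$beads
  if (is.null(coords)) {
    coords <- base::matrix(NA_real_, n, 3)
  }
  stopifnot(nrow(coords) == n, ncol(coords) == 3)
  if (is.null(status)) {
    status <- ifelse(stats::complete.cases(coords), "inferred", "missing")
  }
  beads$x <- coords[, 1]
  beads$y <- coords[, 2]
  beads$z <- coords[, 3]
  beads$status <- status
  beads$bvalue <- 0
  beads$chain <- NA_character_
  beads$resname <- NA_character_
  structure(
    list(layout = layout, beads = beads, params = NULL,
         loglik = NA_real_, iterations = 0L, loglik_trace = numeric(0)),
    class = "structure_model"
  )
}

coords_matrix <- function(model) {
  as.matrix(model$beads[, c("x", "y", "z")])
}

placed <- function(model) {
  stats::complete.cases(model$beads[, c("x", "y", "z")])
}

#' @export
print.structure_model <- function(x, ...) {
  tab <- table(x$beads$status)
  cat("<structure_model> ", nrow(x$beads), " beads (",
      paste(names(tab), as.integer(tab), sep = ":", collapse = ", "),
      ")\n", sep = "")
  if (!is.na(x$loglik)) {
    cat("log-likelihood ", format(x$loglik), " after ", x$iterations,
        " iteration(s)\n", sep = "")
  }
  invisible(x)
}

#' @describeIn structure_model Per-bead tibble view of a model.
#' @param x A `structure_model`.
#' @param ... Unused.
#' @method tidy structure_model
#' @export
tidy.structure_model <- function(x, ...) x$beads

#' @describeIn structure_model One-row fit summary.
#' @method glance structure_model
#' @export
glance.structure_model <- function(x, ...) {
  tibble(
    n_beads = nrow(x$beads),
    n_placed = sum(placed(x)),
    loglik = x$loglik,
    iterations = x$iterations,
    alpha = if (is.null(x$params)) NA_real_ else x$params$alpha,
    beta = if (is.null(x$params)) NA_real_ else x$params$beta,
    dispersion = if (is.null(x$params)) NA_real_ else x$params$r
  )
}

#' 2D projection plot of a structure model
#'
#' @param object A `structure_model`.
#' @param ... Unused.
#' @return A ggplot object (x/y projection, coloured by chromosome).
#' @method autoplot structure_model
#' @export
autoplot.structure_model <- function(object, ...) {
  b <- object$beads[placed(object), ]
  ggplot2::ggplot(b, ggplot2::aes(.data$x, .data$y,
                                  colour = factor(.data$chrom))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "chromosome")
}
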