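#' Negative-binomial count-to-distance model parameters
#'
#' Contact counts between beads `i` and `j` are modelled as negative
#' binomial with mean \eqn{\mu_{ij} = \beta d_{ij}^{\alpha}} and dispersion
#' `r` (variance \eqn{\mu + \mu^2/r}, the convention of count models in
#' sequencing statistics; `r -> Inf` recovers Poisson). `alpha < 0` is the
#' contact-distance decay exponent, fixed at -3 by default.
#'
#' @param alpha Count-distance exponent (< 0).
#' @param beta Scale (> 0).
#' @param r Dispersion (> 0).
#' @return An object of class `nb_params`.
#' @export
nb_params <- function(alpha = -3, beta = 1, r = 100) {
  if (alpha >= 0) abort("alpha must be < 0")
  if (beta <= 0) abort("beta must be > 0")
  if (r <= 0) abort("r must be > 0")
  structure(list(alpha = alpha, beta = beta, r = r), class = "nb_params")
}

#' Convert contact counts into wish distances
#'
#' Distance-based initialisation: \eqn{d_{ij} = c_{ij}^{1/\alpha}} for
#' observed pairs (`c > 0`); zero-count pairs are absent (unknown, not
#' infinite). By default distances are rescaled so the median adjacent-bead
#' wish distance is 1, fixing the arbitrary model unit.
#'
#' @param matrix A `contact_matrix`.
#' @param alpha Decay exponent (< 0).
#' @param rescale Rescale to unit median adjacent distance (default `TRUE`).
#' @return A tibble `i, j, wish` with attribute `scale` (the divisor used).
#' @export
counts_to_wish_distances <- function(matrix, alpha = -3, rescale = TRUE) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (alpha >= 0) abort("alpha must be < 0")
  p <- matrix$pairs[matrix$pairs$count > 0 & matrix$pairs$i != matrix$pairs$j, ]
  wish <- tibble(i = p$i, j = p$j, wish = p$count^(1 / alpha))
  scale <- 1
  if (rescale && nrow(wish) > 0) {
    chrom <- matrix$layout$beads$chrom
    adj <- wish$j == wish$i + 1L & chrom[wish$i] == chrom[wish$j]
    if (any(adj)) scale <- median(wish$wish[adj])
    wish$wish <- wish$wish / scale
  }
  attr(wish, "scale") <- scale
  wish
}

# Signed incidence of the pair list: npairs x n, +1 at i, -1 at j.
# Gradients of pairwise objectives are then t(B) %*% per-pair vectors.
pair_incidence <- function(i, j, n) {
  m <- length(i)
  Matrix::sparseMatrix(
    i = c(seq_len(m), seq_len(m)),
    j = c(i, j),
    x = c(rep(1, m), rep(-1, m)),
    dims = c(m, n)
  )
}

pair_distances <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Weighted-stress MDS initialisation
#'
#' Embeds beads in 3D from a sparse map of wish distances: per connected
#' component, shortest-path completion of the distance graph, classical
#' scaling, then gradient refinement of the stress over observed pairs only
#' (unobserved pairs have weight 0). Components are placed apart along the
#' x axis. Deterministic given `seed` (used only to break exact coincidences).
#'
#' @param wish Tibble `i, j, wish` as from [counts_to_wish_distances()].
#' @param n Number of beads to embed (indices in `wish` are `1..n`).
#' @param seed Integer seed.
#' @return An `n x 3` coordinate matrix.
#' @export
mds_init <- function(wish, n, seed = 42) {
  if (n < 2) abort("need at least 2 beads")
  g <- igraph::graph_from_data_frame(
    data.frame(from = wish$i, to = wish$j, weight = wish$wish),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- igraph::components(g)
  coords <- base::matrix(0, n, 3)
  offset <- 0
  gap <- if (nrow(wish)) median(wish$wish) else 1
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    m <- length(members)
    if (m == 1) {
      xyz <- base::matrix(0, 1, 3)
    } else {
      sub <- igraph::induced_subgraph(g, members)
      D <- igraph::distances(sub)
      xyz <- suppressWarnings(stats::cmdscale(D, k = min(3, m - 1)))
      if (ncol(xyz) < 3) {
        xyz <- cbind(xyz, base::matrix(0, m, 3 - ncol(xyz)))
      }
      sel <- wish$i %in% members
      ii <- match(wish$i[sel], members)
      jj <- match(wish$j[sel], members)
      ww <- wish$wish[sel]
      B <- pair_incidence(ii, jj, m)
      stress_fn <- function(par) {
        p <- base::matrix(par, m, 3)
        d <- pair_distances(p, ii, jj)
        sum((d - ww)^2)
      }
      stress_gr <- function(par) {
        p <- base::matrix(par, m, 3)
        diff <- p[ii, , drop = FALSE] - p[jj, , drop = FALSE]
        d <- sqrt(rowSums(diff * diff))
        w <- 2 * (d - ww) / pmax(d, 1e-12)
        as.vector(Matrix::crossprod(B, diff * w))
      }
      opt <- optim(as.vector(xyz), stress_fn, stress_gr,
                   method = "L-BFGS-B", control = list(maxit = 300))
      xyz <- base::matrix(opt$par, m, 3)
    }
    xyz[, 1] <- xyz[, 1] - min(xyz[, 1]) + offset
    offset <- max(xyz[, 1]) + 3 * gap
    coords[members, ] <- xyz
  }
  dup <- duplicated(round(coords, 12)) & duplicated(coords)
  if (any(dup)) {
    jit <- withr::with_seed(as.integer(seed),
                            base::matrix(rnorm(3 * sum(dup), sd = 1e-4 * gap),
                                         ncol = 3))
    coords[dup, ] <- coords[dup, , drop = FALSE] + jit
  }
  coords
}

nb_ll_terms <- function(count, mu, r) {
  if (r >= 1e10) {
    # Poisson limit; the exact NB expression loses precision in
    # lgamma(count + r) - lgamma(r) at this magnitude
    count * log(mu) - mu - lgamma(count + 1)
  } else {
    lgamma(count + r) - lgamma(r) - lgamma(count + 1) -
      r * log1p(mu / r) + count * (log(mu) - log(r + mu))
  }
}

#' Negative binomial log-likelihood of coordinates
#'
#' Sums, over observed unordered pairs (`i < j` with the pair present in
#' the matrix), the log NB probability of the count at mean
#' \eqn{\mu_{ij} = \beta \|p_i - p_j\|^{\alpha}}. A distance floor keeps the
#' value finite for coincident beads.
#'
#' @param matrix A `contact_matrix`.
#' @param coords `n x 3` coordinate matrix (finite for all beads involved
#'   in observed pairs).
#' @param params An [nb_params()] object.
#' @param dist_floor Minimum distance used in the mean (default 0, i.e. no
#'   floor).
#' @return The scalar log-likelihood.
#' @export
nb_loglik <- function(matrix, coords, params, dist_floor = 0) {
  p <- matrix$pairs[matrix$pairs$i != matrix$pairs$j, ]
  if (nrow(p) == 0) return(0)
  d <- pmax(pair_distances(coords, p$i, p$j), dist_floor)
  mu <- params$beta * d^params$alpha
  sum(nb_ll_terms(p$count, mu, params$r))
}

#' Closed-form scale and moment dispersion estimates
#'
#' Given coordinates, `beta` is the Poisson maximum-likelihood closed form
#' \eqn{\sum c_{ij} / \sum d_{ij}^{\alpha}} over observed pairs, and the
#' dispersion `r` comes from the method of moments on Pearson residuals,
#' clamped to `[1e-2, 1e12]`.
#'
#' @inheritParams nb_loglik
#' @param alpha Fixed decay exponent.
#' @return An [nb_params()] object.
#' @export
estimate_nb_params <- function(matrix, coords, alpha = -3) {
  p <- matrix$pairs[matrix$pairs$i != matrix$pairs$j, ]
  if (nrow(p) < 2) abort("need at least 2 observed pairs")
  if (all(p$count == 0)) abort("all counts are zero")
  d <- pair_distances(coords, p$i, p$j)
  da <- d^alpha
  beta <- sum(p$count) / sum(da)
  mu <- beta * da
  denom <- sum((p$count - mu)^2 - mu)
  r <- if (denom <= 0) 1e12 else sum(mu^2) / denom
  nb_params(alpha = alpha,
            beta = beta,
            r = min(max(r, 1e-2), 1e12))
}

#' Inference settings for [fit_structure()]
#'
#' @param alpha Decay exponent, fixed during the fit.
#' @param beta Fixed scale, or `NULL` to re-estimate each iteration.
#' @param dispersion_mode `"estimate"` (method of moments each iteration)
#'   or `"fixed"`.
#' @param dispersion Dispersion value used when `dispersion_mode = "fixed"`
#'   (default `1e12`, effectively Poisson).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum coordinate-update iterations in total.
#' @param inner_iter L-BFGS iterations per parameter refresh.
#' @param seed Seed for the MDS initialisation.
#' @param zeros_informative Treat zero-count pairs between fitted beads as
#'   observed NB zeros (default `FALSE`, which keeps the cost proportional
#'   to the number of non-zero entries).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(alpha = -3, beta = NULL,
                       dispersion_mode = c("estimate", "fixed"),
                       dispersion = 1e12, tol = 1e-6, max_iter = 500,
                       inner_iter = 50, seed = 42,
                       zeros_informative = FALSE) {
  dispersion_mode <- match.arg(dispersion_mode)
  if (alpha >= 0) abort("alpha must be < 0")
  structure(list(alpha = alpha, beta = beta,
                 dispersion_mode = dispersion_mode, dispersion = dispersion,
                 tol = tol, max_iter = max_iter, inner_iter = inner_iter,
                 seed = seed, zeros_informative = zeros_informative),
            class = "fit_config")
}

#' Fit a 3D structure to a contact matrix
#'
#' Maximises the negative binomial log-likelihood of bead coordinates by
#' alternating L-BFGS coordinate updates with closed-form `beta` and moment
#' `r` re-estimation, starting from [mds_init()]. Parameter updates are
#' accepted only when they do not decrease the likelihood, so the traced
#' likelihood is non-decreasing. Beads whose bin has zero marginal count
#' are excluded from the likelihood and left without coordinates (statuses
#' resolved later by refinement). A disconnected contact graph is fitted
#' per component, with components placed apart and a warning.
#'
#' @param matrix A non-empty `contact_matrix`.
#' @param config A [fit_config()].
#' @return A `structure_model` carrying the fitted coordinates, the final
#'   `nb_params`, `loglik`, `iterations` and the per-iteration
#'   `loglik_trace`.
#' @export
fit_structure <- function(matrix, config = fit_config()) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (nrow(matrix$pairs) == 0) abort("empty contact matrix")
  n <- n_beads(matrix$layout)
  if (n < 2) abort("need at least 2 beads")
  obs <- matrix$pairs[matrix$pairs$i != matrix$pairs$j &
                        matrix$pairs$count > 0, ]
  active <- sort(unique(c(obs$i, obs$j)))
  m <- length(active)
  if (m < 2) abort("fewer than 2 beads with observed contacts")
  map <- rep(NA_integer_, n)
  map[active] <- seq_len(m)

  wish_full <- counts_to_wish_distances(matrix, config$alpha)
  wish <- tibble(i = map[wish_full$i], j = map[wish_full$j],
                 wish = wish_full$wish)
  ncomp <- igraph::components(igraph::graph_from_data_frame(
    data.frame(from = wish$i, to = wish$j), directed = FALSE,
    vertices = data.frame(name = seq_len(m))
  ))$no
  if (ncomp > 1) {
    warn(paste0("contact graph has ", ncomp,
                " components; fitted per component and placed apart"))
  }
  coords <- mds_init(wish, m, config$seed)
  eps <- 1e-6 * median(wish$wish)

  ii <- map[obs$i]
  jj <- map[obs$j]
  cc <- obs$count
  if (config$zeros_informative) {
    all_ut <- which(upper.tri(diag(m)), arr.ind = TRUE)
    key_obs <- paste(pmin(ii, jj), pmax(ii, jj))
    key_all <- paste(all_ut[, 1], all_ut[, 2])
    zero <- !(key_all %in% key_obs)
    ii <- c(ii, all_ut[zero, 1])
    jj <- c(jj, all_ut[zero, 2])
    cc <- c(cc, rep(0, sum(zero)))
  }
  B <- pair_incidence(ii, jj, m)

  est_params <- function(crd) {
    d <- pmax(pair_distances(crd, ii, jj), eps)
    da <- d^config$alpha
    beta <- if (is.null(config$beta)) sum(cc) / sum(da) else config$beta
    mu <- beta * da
    if (config$dispersion_mode == "fixed") {
      r <- config$dispersion
    } else {
      denom <- sum((cc - mu)^2 - mu)
      r <- if (denom <= 0) 1e12 else min(max(sum(mu^2) / denom, 1e-2), 1e12)
    }
    nb_params(alpha = config$alpha, beta = beta, r = r)
  }
  ll_of <- function(crd, par) {
    d <- pmax(pair_distances(crd, ii, jj), eps)
    mu <- par$beta * d^par$alpha
    sum(nb_ll_terms(cc, mu, par$r))
  }
  params <- est_params(coords)

  negll <- function(v) {
    -ll_of(base::matrix(v, m, 3), params)
  }
  neggr <- function(v) {
    crd <- base::matrix(v, m, 3)
    diff <- crd[ii, , drop = FALSE] - crd[jj, , drop = FALSE]
    d <- sqrt(rowSums(diff * diff))
    df <- pmax(d, eps)
    mu <- params$beta * df^params$alpha
    dll_dmu <- cc / mu - (cc + params$r) / (params$r + mu)
    w <- dll_dmu * params$beta * params$alpha * df^(params$alpha - 2)
    w[d < eps] <- 0  # flat inside the floor
    -as.vector(Matrix::crossprod(B, diff * w))
  }

  ll <- ll_of(coords, params)
  trace <- ll
  iters <- 0L
  while (iters < config$max_iter) {
    step <- min(config$inner_iter, config$max_iter - iters)
    opt <- optim(as.vector(coords), negll, neggr, method = "L-BFGS-B",
                 control = list(maxit = step))
    cand <- base::matrix(opt$par, m, 3)
    if (-opt$value >= ll) {
      coords <- cand
      ll <- -opt$value
    }
    iters <- iters + step
    prop <- est_params(coords)
    ll_prop <- ll_of(coords, prop)
    if (ll_prop >= ll) {  # backtracking: keep old params on decrease
      params <- prop
      ll <- ll_prop
    }
    trace <- c(trace, ll)
    last <- trace[length(trace) - 1]
    if (abs(ll - last) <= config$tol * (abs(last) + 1e-8)) break
  }

  full <- base::matrix(NA_real_, n, 3)
  full[active, ] <- coords
  model <- structure_model(matrix$layout, full)
  model$params <- params
  model$loglik <- ll
  model$iterations <- iters
  model$loglik_trace <- trace
  model
}
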