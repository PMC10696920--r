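test_that("wish distances follow the power law and the zero convention", {
  lay <- single_chrom_layout(4)
  m <- contact_matrix(lay, tibble::tibble(i = c(1, 2), j = c(2, 4),
                                          count = c(8, 1)))
  w <- counts_to_wish_distances(m, alpha = -3, rescale = FALSE)
  expect_equal(w$wish[w$i == 1 & w$j == 2], 8^(-1 / 3))  # = 0.5
  expect_equal(w$wish[w$i == 2 & w$j == 4], 1)
  expect_false(any(w$i == 1 & w$j == 3))  # zero count -> absent
  expect_error(counts_to_wish_distances(m, alpha = 1), "alpha")

  wr <- counts_to_wish_distances(m, alpha = -3)
  adj <- wr$wish[wr$i == 1 & wr$j == 2]
  expect_equal(adj, 1)  # only adjacent observed pair defines the unit
})

test_that("mds_init embeds exact metric data and is deterministic", {
  # 4 points on a line at 0,1,2,3: all pairwise distances observed
  wish <- tibble::tibble(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4),
                         wish = c(1, 2, 3, 1, 2, 1))
  xyz <- mds_init(wish, 4, seed = 1)
  d <- as.matrix(dist(xyz))
  stress <- sum((d[cbind(wish$i, wish$j)] - wish$wish)^2)
  expect_lt(stress, 1e-8)
  # collinearity: rank of centred coordinates is 1
  sv <- svd(scale(xyz, scale = FALSE))$d
  expect_lt(sv[2], 1e-6)
  expect_identical(mds_init(wish, 4, seed = 1), xyz)

  two <- mds_init(tibble::tibble(i = 1, j = 2, wish = 2), 2, seed = 1)
  expect_equal(sqrt(sum((two[1, ] - two[2, ])^2)), 2, tolerance = 1e-6)
  expect_error(mds_init(wish, 1), "at least 2")
})

test_that("NB log-likelihood matches a direct pmf oracle and its limits", {
  lay <- single_chrom_layout(3)
  m <- contact_matrix(lay, tibble::tibble(i = c(1, 1, 2), j = c(2, 3, 3),
                                          count = c(7, 2, 11)))
  coords <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.9, 1.1, 0))
  par <- nb_params(alpha = -3, beta = 9, r = 4)
  d <- as.matrix(dist(coords))
  mu <- par$beta * d[cbind(c(1, 1, 2), c(2, 3, 3))]^par$alpha
  oracle <- sum(dnbinom(c(7, 2, 11), size = par$r, mu = mu, log = TRUE))
  expect_equal(nb_loglik(m, coords, par), oracle, tolerance = 1e-12)

  # Poisson limit
  par_p <- nb_params(alpha = -3, beta = 9, r = 1e12)
  oracle_p <- sum(dpois(c(7, 2, 11), mu, log = TRUE))
  expect_equal(nb_loglik(m, coords, par_p), oracle_p, tolerance = 1e-4)

  # rigid motions leave the value unchanged
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- coords %*% R + rep(1, 3) %o% c(5, -2, 3)
  expect_equal(nb_loglik(m, moved, par), nb_loglik(m, coords, par),
               tolerance = 1e-9)
})

test_that("closed-form beta is exact and homogeneous; moment r is sane", {
  lay <- single_chrom_layout(20)
  set.seed(2)
  coords <- helix_coords(20)
  ut <- which(upper.tri(diag(20)), arr.ind = TRUE)
  d <- sqrt(rowSums((coords[ut[, 1], ] - coords[ut[, 2], ])^2))
  m1 <- contact_matrix(lay, tibble::tibble(i = ut[, 1], j = ut[, 2],
                                           count = d^-3))
  p1 <- estimate_nb_params(m1, coords, alpha = -3)
  expect_equal(p1$beta, 1, tolerance = 1e-9)
  m100 <- contact_matrix(lay, tibble::tibble(i = ut[, 1], j = ut[, 2],
                                             count = 100 * d^-3))
  expect_equal(estimate_nb_params(m100, coords, alpha = -3)$beta, 100,
               tolerance = 1e-9)
})

test_that("moment dispersion recovers a known generator within factor 2", {
  model <- helix_model(200)
  cm <- counts_from_structure(model, nb_params(alpha = -3, beta = 200, r = 10),
                              noise = "nb", seed = 8)
  est <- estimate_nb_params(cm, helix_coords(200), alpha = -3)
  expect_gt(est$r, 5)
  expect_lt(est$r, 20)
})

test_that("two-bead fit reaches the closed-form distance", {
  lay <- single_chrom_layout(2)
  m <- contact_matrix(lay, tibble::tibble(i = 1, j = 2, count = 8))
  fit <- fit_structure(m, fit_config(alpha = -3, beta = 8,
                                     dispersion_mode = "fixed"))
  p <- as.matrix(tidy(fit)[, c("x", "y", "z")])
  expect_equal(sqrt(sum((p[1, ] - p[2, ])^2)), 1, tolerance = 1e-6)
})

test_that("fit recovers a planted helix and ascends monotonically", {
  truth <- helix_model(100)
  cm <- counts_from_structure(truth, nb_params(alpha = -3, beta = 100))
  fit <- fit_structure(cm)
  expect_false(is.unsorted(fit$loglik_trace))
  expect_gte(fit$loglik, fit$loglik_trace[1])
  r <- superpose_rmsd(truth, fit)$rmsd
  expect_lt(r / radius_of_gyration(truth), 0.05)

  # determinism under a fixed seed
  fit2 <- fit_structure(cm)
  expect_identical(tidy(fit2), tidy(fit))
})

test_that("inferred distances anticorrelate with counts on clean data", {
  truth <- helix_model(60)
  cm <- counts_from_structure(truth, nb_params(alpha = -3, beta = 1000))
  fit <- fit_structure(cm)
  p <- tidy(cm)
  pc <- as.matrix(tidy(fit)[, c("x", "y", "z")])
  d <- sqrt(rowSums((pc[p$i, ] - pc[p$j, ])^2))
  expect_lte(cor(d, p$count, method = "spearman"), -0.95)
})

test_that("zero-marginal beads stay unplaced and components split apart", {
  lay <- single_chrom_layout(7)
  # beads 1:3 and 5:7 form two components; bead 4 has no contacts
  pairs <- tibble::tibble(i = c(1, 2, 5, 6), j = c(2, 3, 6, 7),
                          count = c(10, 10, 10, 10))
  m <- contact_matrix(lay, pairs)
  expect_warning(fit <- fit_structure(m), "components")
  b <- tidy(fit)
  expect_equal(b$status[4], "missing")
  expect_true(all(is.na(b$x[4])))
  expect_true(all(!is.na(b$x[c(1:3, 5:7)])))
})

test_that("Poisson-limit NB fit matches a fixed-huge-dispersion fit", {
  truth <- helix_model(40)
  cm <- counts_from_structure(truth, nb_params(alpha = -3, beta = 80),
                              noise = "poisson", seed = 3)
  f_fix <- fit_structure(cm, fit_config(dispersion_mode = "fixed",
                                        dispersion = 1e12))
  f_est <- fit_structure(cm, fit_config(dispersion_mode = "estimate"))
  r <- superpose_rmsd(f_fix, f_est)$rmsd
  expect_lt(r / radius_of_gyration(f_fix), 0.05)
})
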