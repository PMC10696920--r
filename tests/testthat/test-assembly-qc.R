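test_that("adjacency profile lists successive-bead distances in order", {
  m <- line_model(10)
  ap <- adjacency_profile(m)
  expect_equal(nrow(ap), 9)
  expect_equal(ap$k, 1:9)
  expect_equal(ap$dist, rep(1, 9))

  m$beads[4, c("x", "y", "z")] <- NA_real_
  ap2 <- adjacency_profile(m)
  expect_equal(ap2$k, setdiff(1:9, 3:4))  # pairs touching bead 4 dropped
})

test_that("a planted reversal spikes exactly at its junctions", {
  g <- random_genome(single_chrom_layout(20, resolution = 100), seed = 2)
  m <- line_model(20, resolution = 100)
  pl <- plant_inversion(g, m, 1, c(8, 12))
  ap <- adjacency_profile(pl$model)
  med <- median(ap$dist)
  spikes <- ap$k[ap$dist > 3 * med]
  expect_equal(spikes, c(7L, 12L))
})

test_that("detection recovers a planted segment, matching brute force", {
  truth <- helix_model(20)
  g <- random_genome(truth$layout, seed = 3)
  pl <- plant_inversion(g, truth, 1, c(8, 12))
  rep_ <- detect_inversions(pl$model, tau = 3)
  expect_equal(nrow(rep_), 1)
  expect_true(rep_$accepted)
  expect_equal(c(rep_$seg_from, rep_$seg_to), c(8L, 12L))

  # oracle: exhaustive search over all (from, to) reversals for the one
  # minimising total chain path length
  coords <- as.matrix(tidy(pl$model)[, c("x", "y", "z")])
  path_len <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  best <- c(NA, NA)
  best_len <- path_len(coords)
  for (from in 2:19) {
    for (to in (from + 1):19) {
      p <- coords
      p[from:to, ] <- p[to:from, ]
      if (path_len(p) < best_len) {
        best_len <- path_len(p)
        best <- c(from, to)
      }
    }
  }
  expect_equal(best, c(8, 12))

  clean <- detect_inversions(truth, tau = 3)
  expect_equal(nrow(clean), 0)
})

test_that("detection tolerates the full tau range on smooth chains", {
  spec <- rabl_spec(chrom_lengths = 3e5, resolution = 1e4, seed = 5)
  truth <- make_rabl_structure(spec)  # 30 beads, spacing CV < 0.2
  ap <- adjacency_profile(truth)
  expect_lt(sd(ap$dist) / mean(ap$dist), 0.2)
  g <- random_genome(truth$layout, seed = 5)
  pl <- plant_inversion(g, truth, 1, c(14, 28))
  for (tau in c(2, 5, 8)) {
    rep_ <- detect_inversions(pl$model, tau = tau)
    acc <- rep_[rep_$accepted, ]
    expect_equal(c(acc$seg_from, acc$seg_to), c(14L, 28L))
  }
})

test_that("correction restores sequence and labels; double reversal is identity", {
  lay <- single_chrom_layout(20, resolution = 100)
  g <- random_genome(lay, seed = 4)
  m <- structure_model(lay, helix_coords(20))
  pl <- plant_inversion(g, m, 1, c(8, 12))
  expect_false(identical(pl$genome$chromosomes$sequence,
                         g$chromosomes$sequence))
  # the planted reversal reverse-complements the spanned interval
  seg <- substr(g$chromosomes$sequence, 701, 1200)
  expect_equal(substr(pl$genome$chromosomes$sequence, 701, 1200),
               reverse_complement(seg))

  rep_ <- detect_inversions(pl$model, tau = 3)
  fixed <- apply_correction(pl$genome, pl$model, rep_)
  expect_identical(fixed$genome$chromosomes$sequence,
                   g$chromosomes$sequence)
  expect_equal(fixed$model$beads, m$beads)
  expect_equal(nrow(detect_inversions(fixed$model, tau = 3)), 0)

  # path length never increases after an accepted correction
  plen <- function(mod) {
    p <- as.matrix(tidy(mod)[, c("x", "y", "z")])
    sum(sqrt(rowSums(diff(p)^2)))
  }
  expect_lte(plen(fixed$model), plen(pl$model))

  expect_error(apply_correction(g, m, detect_inversions(m, tau = 3)),
               "no accepted inversion")
})

test_that("iterated correction resolves two separate inversions", {
  spec <- rabl_spec(chrom_lengths = 6e5, resolution = 1e4, seed = 6)
  truth <- make_rabl_structure(spec)  # 60 beads
  g <- random_genome(truth$layout, seed = 6)
  p1 <- plant_inversion(g, truth, 1, c(5, 20))
  p2 <- plant_inversion(p1$genome, p1$model, 1, c(30, 55))
  out <- correct_assembly(p2$genome, p2$model, tau = 5)
  expect_identical(out$genome$chromosomes$sequence,
                   g$chromosomes$sequence)
  expect_equal(out$model$beads, truth$beads)
})
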