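test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(6)
  P <- matrix(rnorm(36), 12, 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-12)
  th <- 1.2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% R, 2, c(4, -2, 9), "+")
  sup <- kabsch_superpose(P, Q)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # transformed coordinates really land on the reference
  moved <- sweep(P %*% sup$rotation, 2, sup$translation, "+")
  expect_equal(moved, Q, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3 fit atoms")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("Kabsch finds the brute-force rotation-grid minimum", {
  # 4-point asymmetric set vs a perturbed copy; oracle scans a dense
  # grid of rotations (z-y-z Euler angles) with centroids aligned
  P <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0), c(0.5, 0.3, 2.2))
  set.seed(10)
  Q <- P + matrix(rnorm(12, sd = 0.15), 4, 3)
  got <- kabsch_superpose(P, Q)$rmsd
  pc <- sweep(P, 2, colMeans(P)); qc <- sweep(Q, 2, colMeans(Q))
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  obj <- function(ang) {
    R <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
    sqrt(mean(rowSums((pc %*% R - qc)^2)))
  }
  best <- Inf
  best_ang <- c(0, 0, 0)
  step <- pi / 30
  for (a in seq(0, 2 * pi - step, by = step)) {
    for (b in seq(0, pi, by = step)) {
      for (cc in seq(0, 2 * pi - step, by = step)) {
        v <- obj(c(a, b, cc))
        if (v < best) {
          best <- v
          best_ang <- c(a, b, cc)
        }
      }
    }
  }
  # polish the best grid cell with a derivative-free local search
  best <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14))$value
  expect_lt(abs(got - best), 1e-3)
  expect_lte(got, best + 1e-9)  # analytic optimum can't be worse
})

test_that("residue pairing matches by number and atom name, dropping gaps", {
  a <- build_ideal_helix(8)
  b <- build_ideal_helix(8)
  pr <- pair_residues(a, b)
  expect_equal(pr$n_matched, 40)
  expect_equal(pr$n_dropped, 0)
  # backbone-only pairing gives 4 atoms per residue
  pr_bb <- pair_residues(a, b, atom_names = c("N", "CA", "C", "O"))
  expect_equal(pr_bb$n_matched, 32)
  # drop one residue from b
  keep <- b$topology$atoms$residue_number != 4
  atoms <- b$topology$atoms[keep, ]
  atoms$atom_index <- NULL
  b2 <- list(topology = topology(atoms), frame = b$frame[keep, ])
  pr2 <- pair_residues(a, b2)
  expect_equal(pr2$n_matched, 35)
  expect_equal(pr2$n_dropped, 5)
  expect_error(pair_residues(a, b, sel = selection(chain = "Z")), "empty|common")
})

test_that("RMSD matrices are symmetric pseudo-metrics on rigid copies", {
  base <- build_ideal_helix(8)
  th <- 0.8
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- list(topology = base$topology,
                frame = sweep(base$frame %*% R, 2, c(7, 1, -2), "+"))
  set.seed(3)
  wiggled <- list(topology = base$topology,
                  frame = base$frame + matrix(rnorm(nrow(base$frame) * 3,
                                                    sd = 0.4),
                                              ncol = 3))
  m <- rmsd_matrix(list(A = base, B = wiggled, C = moved))
  expect_equal(diag(unclass(m)), c(A = 0, B = 0, C = 0))
  expect_equal(unclass(m), t(unclass(m)))
  expect_lt(m["A", "C"], 1e-6)                      # congruent pair
  expect_equal(m["A", "B"], m["C", "B"], tolerance = 1e-6)
  expect_gt(m["A", "B"], 0)
  # duplicated structures give an all-zero matrix
  m0 <- rmsd_matrix(list(X = base, Y = base))
  expect_true(all(unclass(m0) < 1e-12))
  expect_error(rmsd_matrix(list(base)), "2 structures")
})

test_that("off-diagonal RMSD grows with perturbation magnitude", {
  base <- build_ideal_helix(8)
  mean_offdiag <- vapply(c(0.1, 0.3, 0.6), function(sig) {
    set.seed(40)
    perturbed <- lapply(1:3, function(i) {
      list(topology = base$topology,
           frame = base$frame + matrix(rnorm(nrow(base$frame) * 3, sd = sig),
                                       ncol = 3))
    })
    m <- unclass(rmsd_matrix(perturbed))
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_true(all(diff(mean_offdiag) > 0))
})

test_that("classical MDS reproduces exactly embeddable geometries", {
  # equilateral triangle, side 1
  d <- matrix(1, 3, 3) - diag(3)
  emb <- mds_embed(d)
  expect_equal(as.numeric(dist(unclass(emb)[, 1:2])), rep(1, 3),
               tolerance = 1e-9)
  # collinear metric embeds on one axis
  d3 <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  emb3 <- mds_embed(d3)
  expect_lt(max(abs(unclass(emb3)[, 2])), 1e-9)
  # random 2D point clouds are recovered up to rigid motion
  set.seed(14)
  pts <- matrix(runif(20), 10, 2)
  dm <- as.matrix(dist(pts))
  emb10 <- mds_embed(dm)
  expect_equal(as.matrix(dist(unclass(emb10)[, 1:2])), dm,
               tolerance = 1e-9, ignore_attr = TRUE)
  # centred output, deterministic sign, zero matrix allowed
  expect_equal(colMeans(unclass(emb10)[, 1:2]), c(dim1 = 0, dim2 = 0),
               tolerance = 1e-9)
  z <- mds_embed(matrix(0, 3, 3))
  expect_true(all(abs(unclass(z)) < 1e-12))
  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the MDS implementation agrees with stats::cmdscale", {
  set.seed(15)
  pts <- matrix(rnorm(24), 8, 3)
  dm <- as.matrix(dist(pts))
  ours <- unclass(mds_embed(dm))[, 1:2]
  ref <- stats::cmdscale(dm, k = 2)
  # same configuration up to per-axis sign
  for (k in 1:2) {
    agree <- max(abs(ours[, k] - ref[, k]))
    flipped <- max(abs(ours[, k] + ref[, k]))
    expect_lt(min(agree, flipped), 1e-9)
  }
})
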