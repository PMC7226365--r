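test_that("isolated-sphere SASA matches the analytic area within 1%", {
  tr <- fixture_atoms(matrix(0, 1, 3), radii = 1.9)
  s <- sasa_frame(get_frame(tr, 1), 1, 1, radii = 1.9)
  analytic <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(s - analytic) / analytic, 0.01)
})

test_that("a fully buried atom has zero SASA", {
  fr <- rbind(c(0, 0, 0), c(0, 0, 0.1))
  expect_equal(sasa_frame(fr, 2, 1:2, radii = c(3, 1)), 0)
})

test_that("cluster SASA agrees with a high-density brute-force recomputation", {
  set.seed(13)
  pos <- matrix(rnorm(18, sd = 2), 6, 3)
  radii <- runif(6, 1.2, 1.9)
  probe <- 1.4
  fast <- sasa_frame(pos, 1:6, 1:6, radii, probe, n_points = 960)
  # independent brute force at 1e5 points per atom, plain double loop
  slow <- 0
  dense <- {
    i <- seq_len(1e5) - 0.5
    ph <- acos(1 - 2 * i / 1e5)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
  }
  for (a in 1:6) {
    ra <- radii[a] + probe
    pts <- sweep(dense * ra, 2, pos[a, ], "+")
    outside <- rep(TRUE, nrow(pts))
    for (j in setdiff(1:6, a)) {
      rj <- radii[j] + probe
      outside <- outside &
        rowSums(sweep(pts, 2, pos[j, ])^2) > rj^2
    }
    slow <- slow + mean(outside) * 4 * pi * ra^2
  }
  expect_lt(abs(fast - slow) / slow, 0.02)
})

test_that("SASA is additive over well-separated clusters and monotone under burial", {
  c1 <- rbind(c(0, 0, 0), c(2, 0, 0))
  c2 <- rbind(c(100, 0, 0), c(102, 0, 0))
  r <- rep(1.6, 2)
  both <- sasa_frame(rbind(c1, c2), 1:4, 1:4, rep(1.6, 4))
  alone <- sasa_frame(c1, 1:2, 1:2, r) + sasa_frame(c2, 1:2, 1:2, r)
  expect_equal(both, alone, tolerance = 1e-9)
  # adding a context atom never increases exposed area
  fr <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  s_bare <- sasa_frame(fr[1, , drop = FALSE], 1, 1, 1.6)
  s_ctx <- sasa_frame(fr, 1, 1:2, c(1.6, 1.6))
  expect_lt(s_ctx, s_bare)
})

test_that("SASA series tracks portal widening and is frame-equivariant", {
  widths <- seq(4, 14, length.out = 25)
  sch <- aperture_schedule(widths, noise_sigma = 0.05, seed = 9)
  tr <- build_portal_trajectory(6, sch, n_frames = 25)
  raw <- sasa_series(tr, selection(), n_points = 240)
  expect_s3_class(raw, "time_series")
  expect_equal(raw$units, "A^2")
  sm <- savgol_smooth(raw, window = 11, degree = 3)
  # buried area shrinks as the portal opens: smoothed series tracks the
  # widening schedule (rank correlation; sampling noise flattens the tail
  # once the helices separate)
  expect_gt(cor(sm$values, widths, method = "spearman"), 0.9)
  expect_gt(sm$values[25], sm$values[1])
  # static trajectory gives a constant series
  st <- build_portal_trajectory(6, aperture_schedule(rep(10, 4)))
  ss <- sasa_series(st, selection(), n_points = 240)
  expect_equal(diff(range(ss$values)), 0)
  # frame reversal reverses the series
  tr_rev <- trajectory(tr$topology, tr$coords[, , 25:1, drop = FALSE])
  rev_series <- sasa_series(tr_rev, selection(), n_points = 240)
  expect_equal(rev_series$values, rev(raw$values))
})

test_that("Savitzky-Golay reproduces cubic signals and damps noise", {
  x <- seq(0, 5, length.out = 300)
  y <- 1 - 2 * x + 0.3 * x^2 - 0.05 * x^3
  sm <- savgol_smooth(y, window = 51, degree = 3)
  interior <- 26:275
  expect_lt(max(abs((sm[interior] - y[interior]) / y[interior])), 1e-8)
  # constant series unchanged everywhere (edges included)
  expect_equal(savgol_smooth(rep(3.5, 120), 51, 3), rep(3.5, 120))
  # variance of white noise strictly reduced
  set.seed(31)
  noise <- rnorm(500)
  expect_lt(var(savgol_smooth(noise, 51, 3)), var(noise))
  # argument validation
  expect_error(savgol_smooth(noise, 50, 3), "odd")
  expect_error(savgol_smooth(noise, 501, 3), "length")
  expect_error(savgol_smooth(noise, 5, 7), "degree")
  # metadata flags
  ts <- time_series(noise, 0.04, "x", "A^2")
  out <- savgol_smooth(ts)
  expect_true(out$smoothed)
  expect_equal(out$window, 51)
  expect_equal(out$degree, 3)
  expect_length(out$values, length(noise))
  expect_equal(out$units, "A^2")
})

test_that("hydrogen-bond counting follows distance and angle criteria", {
  # ideal collinear N-H...O at 2.9 A donor-acceptor
  atoms <- data.frame(
    atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_name = c("ALA", "ALA", "HOH"), residue_number = c(1, 1, 2),
    chain_id = "A", vdw_radius = c(1.55, 1.2, 1.52))
  top <- topology(atoms)
  fr <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  tr <- trajectory(top, fr)
  don <- selection(atom_names = "N")
  acc <- selection(atom_names = "O")
  expect_equal(hbond_count_series(tr, don, acc)$values, 1)
  # same geometry stretched past the cutoff
  fr2 <- fr
  fr2[3, 1] <- 4.5
  expect_equal(hbond_count_series(trajectory(top, fr2), don, acc)$values, 0)
  # bent geometry below the angle cutoff
  fr3 <- fr
  fr3[3, ] <- c(1, 2.4, 0)   # D..A 2.6 A but angle ~100 degrees
  expect_equal(hbond_count_series(trajectory(top, fr3), don, acc)$values, 0)
})

test_that("multi-donor frames match brute-force triple enumeration", {
  set.seed(17)
  nd <- 3; na_ <- 2
  atoms <- data.frame(
    atom_name = c(paste0("N", 1:nd), paste0("H", 1:nd), paste0("O", 1:na_)),
    element = c(rep("N", nd), rep("H", nd), rep("O", na_)),
    residue_name = "UNK",
    residue_number = c(1:nd, 1:nd, nd + (1:na_)),
    chain_id = "A", vdw_radius = 1.5)
  top <- topology(atoms)
  dpos <- matrix(runif(nd * 3, 0, 5), nd)
  hpos <- dpos + matrix(rnorm(nd * 3, sd = 0.55), nd)  # ~1 A from donors
  hpos <- dpos + (hpos - dpos) / sqrt(rowSums((hpos - dpos)^2))
  apos <- matrix(runif(na_ * 3, 0, 5), na_)
  tr <- trajectory(top, rbind(dpos, hpos, apos))
  got <- hbond_count_series(tr, selection(atom_names = paste0("N", 1:nd)),
                            selection(atom_names = paste0("O", 1:na_)))
  # brute force over all (D, H, A) triples
  want <- 0L
  for (d in 1:nd) {
    for (a in 1:na_) {
      rda <- sqrt(sum((apos[a, ] - dpos[d, ])^2))
      if (rda > 3.5) next
      v1 <- dpos[d, ] - hpos[d, ]
      v2 <- apos[a, ] - hpos[d, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang >= 140) want <- want + 1L
    }
  }
  expect_equal(got$values, as.numeric(want))
})
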