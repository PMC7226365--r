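test_that("amide hydrogens are placed anti to the preceding carbonyl", {
  hx <- build_ideal_helix(6)
  top <- hx$topology; fr <- hx$frame
  hs <- place_amide_hydrogens(top, fr)
  # residue 1 has no preceding carbonyl
  expect_true(1 %in% hs$flagged)
  expect_true(all(is.na(hs$h_xyz[1, ])))
  # analytic position for residue 2: N2 + unit(C1 - O1)
  a <- top$atoms
  at <- function(name, res) fr[a$atom_name == name & a$residue_number == res, ]
  expected <- at("N", 2) +
    (at("C", 1) - at("O", 1)) / sqrt(sum((at("C", 1) - at("O", 1))^2))
  expect_equal(hs$h_xyz[2, ], expected, tolerance = 1e-6)
  # H sits 1.0 A from N
  expect_equal(sqrt(sum((hs$h_xyz[2, ] - at("N", 2))^2)), 1, tolerance = 1e-9)
})

test_that("chain breaks suppress hydrogen placement", {
  hx <- build_ideal_helix(6)
  fr <- hx$frame
  a <- hx$topology$atoms
  # push residues 4-6 far away: residue 4's N is then > 2.5 A from C(3)
  fr[a$residue_number >= 4, ] <- fr[a$residue_number >= 4, ] + 50
  hs <- place_amide_hydrogens(hx$topology, fr)
  expect_true(4 %in% hs$flagged)
  expect_false(5 %in% hs$flagged)
})

test_that("the hydrogen-bond energy formula behaves as expected", {
  # constructed near-linear N-H...O=C at r(OH) ~ 2 A: bonded
  n <- c(0, 0, 0); h <- c(1, 0, 0); o <- c(3.0, 0, 0); cc <- c(4.23, 0, 0)
  e <- ks_energy(n, h, cc, o)
  expect_lt(e, -0.5)
  # explicit formula evaluation on the same geometry
  expect_equal(e, 0.084 * 332 * (1 / 3 + 1 / 3.23 - 1 / 2 - 1 / 4.23),
               tolerance = 1e-12)
  # distant pair: energy ~ 0
  expect_lt(abs(ks_energy(n, h, cc + 15, o + 15)), 0.1)
  # the formula is directional: swapping roles changes the energy
  e_swap <- ks_energy(o, o + c(0, 1, 0), n, h)
  expect_false(isTRUE(all.equal(e, e_swap)))
  # clash guard
  expect_equal(ks_energy(n, h, n + 0.1, o), Inf)
})

test_that("an ideal helix is assigned one contiguous helical block", {
  hx <- build_ideal_helix(20)
  flags <- assign_helix(hx$topology, hx$frame)
  runs <- rle(flags)
  expect_equal(sum(runs$values), 1)            # exactly one helical run
  expect_gt(sum(flags), 12)                    # covers most of the chain
  # rotation/translation invariance
  th <- 0.6
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  fr2 <- sweep(hx$frame %*% R, 2, c(11, -4, 3), "+")
  expect_identical(assign_helix(hx$topology, fr2), flags)
})

test_that("an extended chain has no helical residues", {
  ext <- build_ideal_helix(12, phi = 180, psi = 180)
  expect_false(any(assign_helix(ext$topology, ext$frame)))
  # degrading phi/psi by >= 40 degrees from ideal destroys the assignment
  off <- build_ideal_helix(12, phi = -57 + 45, psi = -47 + 45)
  expect_equal(sum(assign_helix(off$topology, off$frame)), 0)
})

test_that("helix-linker-helix gives two segments with the linker as hinge", {
  h1 <- build_ideal_helix(10, resno_start = 101)
  # extended 3-residue linker + second helix, chained by continuing
  # residue numbering; build as one synthetic flag vector over a region
  flags <- c(rep(TRUE, 10), rep(FALSE, 3), rep(TRUE, 9))
  resno <- 101:122
  seg <- segment_helices(data.frame(residue_number = resno, helical = flags),
                         region = c(101, 122))
  expect_equal(nrow(seg$segments), 2)
  expect_equal(unname(seg$segments[1, ]), c(101, 110))
  expect_equal(unname(seg$segments[2, ]), c(114, 122))
  expect_equal(seg$hinges, c(111, 112, 113))
  # geometric version: two ideal helices placed far apart on one chain
  a1 <- h1
  a2 <- build_ideal_helix(9, resno_start = 114)
  sep_frame <- sweep(a2$frame, 2, c(100, 0, 0), "+")
  atoms <- rbind(a1$topology$atoms, a2$topology$atoms)
  atoms$atom_index <- NULL
  top <- topology(atoms)
  fr <- rbind(a1$frame, sep_frame)
  gflags <- assign_helix(top, fr)
  gseg <- segment_helices(gflags, top, region = c(101, 122))
  expect_equal(nrow(gseg$segments), 2)
})

test_that("segmentation text round-trips the published table format", {
  flags <- data.frame(
    residue_number = 139:182,
    helical = (139:182) %in% c(139:150, 153:177))
  seg <- segment_helices(flags, region = c(139, 182))
  expect_equal(seg$text, "139‒150 + 153‒177")
  expect_equal(seg$hinges, c(151, 152))
  back <- parse_segments(seg$text)
  expect_equal(back, matrix(c(139, 153, 150, 177), 2))
  # plain hyphens parse too
  expect_equal(parse_segments("139-150 + 153-177"), back)
  # three-segment pattern
  flags3 <- data.frame(
    residue_number = 139:182,
    helical = (139:182) %in% c(139:150, 152:176, 179:181))
  seg3 <- segment_helices(flags3, region = c(139, 182))
  expect_equal(nrow(seg3$segments), 3)
  expect_equal(seg3$text, "139‒150 + 152‒176 + 179‒181")
  expect_equal(seg3$hinges, c(151, 177, 178))
  # all-helical region: one segment, no hinge
  all_h <- segment_helices(data.frame(residue_number = 60:88,
                                      helical = TRUE),
                           region = c(60, 88))
  expect_equal(nrow(all_h$segments), 1)
  expect_length(all_h$hinges, 0)
  expect_equal(all_h$text, "60‒88")
})

test_that("segments, hinges and flanks partition the region", {
  set.seed(4)
  resno <- 1:40
  flags <- data.frame(residue_number = resno,
                      helical = runif(40) > 0.4)
  seg <- segment_helices(flags, region = c(1, 40))
  in_seg <- unlist(apply(seg$segments, 1, function(s) s[1]:s[2]))
  expect_setequal(in_seg, resno[flags$helical])
  # hinges are non-helical and strictly interior
  expect_true(all(!flags$helical[match(seg$hinges, resno)]))
  if (nrow(seg$segments) >= 1) {
    expect_true(all(seg$hinges > min(seg$segments) &
                    seg$hinges < max(seg$segments)))
  }
})

test_that("external helix assignments can be ingested", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("residue_number,ss", "139,H", "140,H", "141,C", "142,H"), f)
  tab <- read_helix_assignment(f)
  expect_equal(tab$helical, c(TRUE, TRUE, FALSE, TRUE))
  seg <- segment_helices(tab, region = c(139, 142))
  expect_equal(nrow(seg$segments), 2)
})
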