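# Model and map I/O, geometry primitives, chain fragmentation.

test_that("kabsch superposition matches an independent oracle and recovers
           applied rigid motions", {
  set.seed(1)
  for (rep in 1:10) {
    x <- matrix(rnorm(30), ncol = 3)
    tr <- rigid(rotvec_to_matrix(rnorm(3)), rnorm(3, sd = 5))
    y <- apply_rigid(tr, x)
    fit <- kabsch(x, y)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(fit$R, tr$R, tolerance = 1e-9)
    # noisy case: residual must agree with the bio3d superposition
    yn <- y + matrix(rnorm(30, sd = 0.3), ncol = 3)
    expect_equal(kabsch(x, yn)$rmsd, bio3d_rmsd(x, yn), tolerance = 1e-6)
  }
})

test_that("fractional/Cartesian transforms compose to identity for random
           valid cells", {
  set.seed(2)
  for (rep in 1:20) {
    cell <- c(runif(3, 10, 80), runif(3, 70, 110))
    cm <- cell_matrices(cell)
    pts <- matrix(rnorm(150, sd = 20), ncol = 3)
    back <- (pts %*% t(cm$frac)) %*% t(cm$orth)
    expect_lt(max(abs(back - pts)), 1e-9)
  }
})

test_that("structures survive PDB and mmCIF round trips with equal atom
           inventories", {
  d <- make_duplex("GAUCG", "A_RNA")
  for (ext in c(".pdb", ".cif")) {
    f <- withr::local_tempfile(fileext = ext)
    write_structure(d, f)
    s <- read_structure(f)
    expect_length(s$chains, 2)
    expect_length(all_residues(s), 10)
    orig <- all_residues(d)
    back <- all_residues(s)
    expect_equal(lapply(back, `[[`, "atom_names"),
                 lapply(orig, `[[`, "atom_names"))
    expect_lt(max(abs(do.call(rbind, lapply(back, `[[`, "xyz")) -
                        do.call(rbind, lapply(orig, `[[`, "xyz")))), 1e-3)
  }
})

test_that("a single G.C pair is read as one chain of two residues, and a
           protein-only file yields zero nucleic chains", {
  d <- make_duplex("G", "A_RNA")
  # both residues in one chain
  ch <- new_chain("A", c(d$chains[[1]]$residues,
                         lapply(d$chains[[2]]$residues, function(r) {
                           r$seqid <- 2L; r$chain_id <- "A"; r
                         })), kind = "RNA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(new_structure(list(ch)), f)
  s <- read_structure(f)
  expect_length(s$chains, 1)
  expect_length(s$chains[[1]]$residues, 2)

  prot <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.152  -4.899  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      12.974   7.980  -5.772  1.00  0.00           O",
    "END"), prot)
  expect_length(read_structure(prot)$chains, 0)
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("chain_fragments follows bonded connectivity, not numbering", {
  d <- make_duplex("GAUCGAUCGAUCGAUCGAUC", "A_RNA",
                   include_complement = FALSE)
  ch <- d$chains[[1]]
  fr <- chain_fragments(ch)
  expect_length(fr, 1)
  expect_equal(fr[[1]]$length, 20)

  # translate residues 10..20 en bloc: break after 9 -> fragments 9 and 11
  ch_broken <- ch
  for (i in 10:20) ch_broken$residues[[i]]$xyz <-
      ch_broken$residues[[i]]$xyz + 20
  fr2 <- chain_fragments(ch_broken)
  expect_equal(unname(vapply(fr2, `[[`, 0L, "length")), c(9L, 11L))

  # a single displaced residue is isolated on both sides
  ch_one <- ch
  ch_one$residues[[10]]$xyz <- ch_one$residues[[10]]$xyz + 20
  expect_equal(unname(vapply(chain_fragments(ch_one), `[[`, 0L, "length")),
               c(9L, 1L, 10L))

  # renumbering gap with intact geometry stays one fragment
  ch_gap <- ch
  for (i in 11:20) ch_gap$residues[[i]]$seqid <- ch_gap$residues[[i]]$seqid + 50L
  fr3 <- chain_fragments(ch_gap)
  expect_length(fr3, 1)

  # fragments partition the chain
  expect_equal(sum(vapply(fr2, `[[`, 0L, "length")), length(ch$residues))
})

test_that("CCP4 maps round-trip and permuted axis order does not change
           interpolated values", {
  d <- make_duplex("GAUC", "A_RNA")
  map <- simulate_map(d, 3.0, noise_sd = 0.1, seed = 3)
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4_map(map, f)
  m2 <- read_ccp4_map(f)
  expect_lt(max(abs(m2$values - map$values)), 1e-5 * max(abs(map$values)))

  fp <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4_map(map, fp, axis_order = c("Z", "X", "Y"))
  m3 <- read_ccp4_map(fp)
  set.seed(4)
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  expect_equal(interpolate_density(m2, pts), interpolate_density(m3, pts),
               tolerance = 1e-6)

  trunc <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(readBin(f, "raw", 500), trunc)
  expect_error(read_ccp4_map(trunc), "too small|truncated")
  garbage <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(as.raw(rep(7, 2000)), garbage)
  expect_error(read_ccp4_map(garbage))
})

test_that("trilinear interpolation reproduces node values, linear ramps and
           periodicity", {
  vals <- array(0, c(4, 4, 4))
  vals[] <- slice.index(vals, 1)  # linear ramp along x
  m <- new_density_map(vals, cell = c(4, 4, 4, 90, 90, 90), periodic = TRUE)
  # node (2,1,1) sits at cartesian (1, 0, 0), value 2
  expect_equal(interpolate_density(m, c(1, 0, 0)), 2)
  # midpoint between nodes 2 and 3 on the ramp
  expect_equal(interpolate_density(m, c(1.5, 0, 0)), 2.5)
  # periodicity: one full cell along x
  expect_equal(interpolate_density(m, c(0.3, 1, 1)),
               interpolate_density(m, c(4.3, 1, 1)), tolerance = 1e-12)
  # non-periodic out-of-bounds is zero
  m$periodic <- FALSE
  expect_equal(interpolate_density(m, c(40, 0, 0)), 0)
})

test_that("MTZ synthesis reproduces closed-form Fourier components", {
  cell <- c(20, 30, 40, 90, 90, 90)
  V <- 20 * 30 * 40
  # DC term only: constant map F000 / V
  f1 <- withr::local_tempfile(fileext = ".mtz")
  write_gemmi_mtz(f1, cell, rbind(c(0, 0, 0, 100, 0)))
  m1 <- map_from_mtz(f1)
  expect_equal(range(m1$values), rep(100 / V, 2), tolerance = 1e-6)

  # single (1,0,0) reflection, amplitude A, phase 0: 2A cos(2 pi x) / V
  f2 <- withr::local_tempfile(fileext = ".mtz")
  write_gemmi_mtz(f2, cell, rbind(c(1, 0, 0, 50, 0)))
  m2 <- map_from_mtz(f2, oversample = 12)
  expect_equal(interpolate_density(m2, c(0, 0, 0)), 2 * 50 / V,
               tolerance = 1e-6)
  # at x = 1/4 fractional the cosine vanishes
  expect_lt(abs(interpolate_density(m2, c(5, 0, 0))), 1e-9)
  expect_equal(interpolate_density(m2, c(10, 0, 0)), -2 * 50 / V,
               tolerance = 1e-6)

  expect_error(map_from_mtz(f2, amp_label = "NOPE"), "FWT")
})

test_that("map -> structure factors -> map round trip correlates > 0.999", {
  d <- make_duplex("GAUCGA", "A_RNA")
  map <- simulate_map(d, 3.0, grid_spacing = 1.0)
  # forward transform (test-side oracle), keep all coefficients
  G <- fft(map$values)
  dims <- dim(map$values)
  hkl <- as.matrix(expand.grid(h = 0:(dims[1] - 1), k = 0:(dims[2] - 1),
                               l = 0:(dims[3] - 1)))
  # bring indices to signed convention and keep a unique Friedel half
  hs <- hkl
  for (i in 1:3) {
    w <- hs[, i] > dims[i] / 2
    hs[w, i] <- hs[w, i] - dims[i]
  }
  keep <- hs[, 1] > 0 | (hs[, 1] == 0 & hs[, 2] > 0) |
    (hs[, 1] == 0 & hs[, 2] == 0 & hs[, 3] >= 0)
  # drop Nyquist rows (their Friedel mate coincides)
  keep <- keep & hs[, 1] != -dims[1] / 2 & hs[, 2] != -dims[2] / 2 &
    hs[, 3] != -dims[3] / 2
  vals <- G[cbind(hkl[keep, 1] + 1, hkl[keep, 2] + 1, hkl[keep, 3] + 1)]
  cellV <- prod(map$cell[1:3])
  # R's forward FFT computes F(-h) up to scale under the crystallographic
  # convention rho(x) = (1/V) sum F(h) exp(-2 pi i h.x); negate the phase
  tab <- cbind(hs[keep, , drop = FALSE], Mod(vals) * cellV / prod(dims),
               -Arg(vals) * 180 / pi)
  f <- withr::local_tempfile(fileext = ".mtz")
  write_gemmi_mtz(f, map$cell, tab)
  m2 <- map_from_mtz(f, oversample = 10)
  # compare on the original grid points
  fr <- as.matrix(expand.grid(x = (0:(dims[1] - 1)) / dims[1],
                              y = (0:(dims[2] - 1)) / dims[2],
                              z = (0:(dims[3] - 1)) / dims[3]))
  xyz <- fr %*% t(cell_matrices(map$cell)$orth)
  v2 <- interpolate_density(m2, xyz)
  expect_gt(cor(as.numeric(map$values[cbind(fr[, 1] * dims[1] + 1,
                                            fr[, 2] * dims[2] + 1,
                                            fr[, 3] * dims[3] + 1)]), v2),
            0.999)
})
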