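test_that("the phase-encode matrix has the DFT structure with R_m rows", {
  grid <- c(4, 4, 2)
  s0 <- pe_scheme(rbind(c(0, 0, 0)), 1L, c(240, 240, 200), grid)
  pe0 <- build_pe_matrix(s0, grid)
  expect_equal(as.vector(pe0), rep(1 + 0i, prod(grid)))

  s <- pe_scheme(rbind(c(1, -1, 0), c(1, -1, 0) + c(0, 0, 1)),
                 c(1L, 2L), c(240, 240, 200), grid)
  pe <- build_pe_matrix(s, grid)
  s1 <- pe_scheme(rbind(c(1, -1, 0) + c(0, 0, 1)), 1L,
                  c(240, 240, 200), grid)
  expect_equal(pe[2, ], 2 * build_pe_matrix(s1, grid)[1, ],
               tolerance = 1e-12)

  # full integer scheme, R = 1: columns orthogonal with squared norm M
  su <- make_aw_scheme(grid, 1, weighting = "uniform")
  peu <- build_pe_matrix(su, grid)
  gram <- Conj(t(peu)) %*% peu
  expect_equal(gram, diag(prod(grid)) * prod(grid) + 0i, tolerance = 1e-9)
})

test_that("compartment compression matches brute-force column sums", {
  # two half-FOV compartments on an 8-voxel 1D grid, encodes k in {0, 1}
  grid <- c(8, 1, 1)
  fov <- c(240, 1, 1)
  lab <- array(c(rep(1L, 4), rep(2L, 4)), dim = grid)
  mask <- compartment_mask(lab, fov, c(left = 1L, right = 2L))
  s <- pe_scheme(rbind(c(0, 0, 0), c(1, 0, 0)), c(1L, 1L), fov, grid)
  pe <- build_pe_matrix(s, grid)
  op <- compress_compartments(pe, mask, s)
  x <- (0:7 - 4) / 8
  brute <- cbind(
    c(mean(exp(-2i * pi * 0 * x[1:4])), mean(exp(-2i * pi * 1 * x[1:4]))),
    c(mean(exp(-2i * pi * 0 * x[5:8])), mean(exp(-2i * pi * 1 * x[5:8])))
  )
  expect_equal(op$encoding_matrix, brute, tolerance = 1e-12)

  # one compartment covering everything, k = 0 only: scalar R
  mask1 <- compartment_mask(array(1L, dim = grid), fov, c(all = 1L))
  s0 <- pe_scheme(rbind(c(0, 0, 0)), 3L, fov, grid)
  op1 <- compress_compartments(build_pe_matrix(s0, grid), mask1, s0)
  expect_equal(op1$encoding_matrix[1, 1], 3 + 0i)

  expect_error(
    compartment_mask(lab, fov, c(left = 1L, right = 2L, ghost = 9L)),
    "ghost"
  )
})

test_that("SLAM recovers homogeneous compartment spectra exactly", {
  ph <- homog_phantom()
  mask <- as_compartment_mask(ph)
  s <- make_aw_scheme(c(8, 16, 8), 4)
  kd <- forward_encode(ph, s, n_time = 32)
  op <- slam_operator(s, mask)
  expect_lt(max(abs(op$pinv %*% op$encoding_matrix - diag(3))), 1e-8)
  rec <- slam_reconstruct(kd, op)
  gt <- gt_compartment_fids(ph, 32, kd$dwell_s)
  expect_lt(max(rel_err_rows(rec$time_signals, gt)), 1e-8)

  # all-zero data give all-zero spectra
  kz <- kspace_data(s, array(0 + 0i, dim = c(1, nrow(s), 8)), kd$dwell_s)
  expect_equal(max(Mod(slam_reconstruct(kz, op)$spectra)), 0)

  # doubling every R_m and re-simulating leaves the reconstruction unchanged
  s2 <- pe_scheme(slamslim:::scheme_k_matrix(s), s$repeats * 2L,
                  attr(s, "fov_mm"), attr(s, "matrix_shape"))
  kd2 <- forward_encode(ph, s2, n_time = 32)
  rec2 <- slam_reconstruct(kd2, slam_operator(s2, mask))
  expect_equal(rec2$time_signals, rec$time_signals, tolerance = 1e-10)
})

test_that("SLAM exactness holds over randomized phantoms and schemes", {
  set.seed(4)
  for (i in 1:4) {
    grid <- c(sample(4:6, 1), sample(4:8, 1), sample(3:5, 1))
    # three contiguous slabs along a random axis (spatially coherent
    # compartments, as SLAM assumes)
    ax <- sample(1:3, 1)
    cuts <- sort(sample(seq_len(grid[ax] - 1), 2))
    idx_along <- slice.index(array(0L, dim = grid), ax)
    lab <- array(0L, dim = grid)
    lab[idx_along > cuts[1]] <- 1L
    lab[idx_along > cuts[2]] <- 2L
    ph <- homog_phantom(c(8, 16, 8))  # resonance tables only
    ph$grid_shape <- grid
    ph$label_map <- lab
    ph$delta_f_map <- array(0, dim = grid)
    ph$phase_map <- array(0, dim = grid)
    ph$density_map <- array(1, dim = grid)
    ph$b1_tx_map <- array(1, dim = grid)
    mask <- compartment_mask(lab, ph$fov_mm,
                             c(other = 0L, chest_wall = 1L, heart = 2L))
    m_prime <- sample(6:12, 1)
    # full-FOV slabs only couple to encodes with zero k on the in-plane
    # axes, so guarantee three informative encodes along every axis
    k <- unique(rbind(
      diag(3), -diag(3), c(0, 0, 0),
      cbind(sample(-2:2, m_prime, TRUE), sample(-2:2, m_prime, TRUE),
            sample(-1:1, m_prime, TRUE))
    ))
    s <- pe_scheme(k, sample(1:4, nrow(k), TRUE), ph$fov_mm, grid)
    op <- slam_operator(s, mask)
    kd <- forward_encode(ph, s, n_time = 16)
    rec <- slam_reconstruct(kd, op)
    gt <- gt_compartment_fids(ph, 16, kd$dwell_s)
    expect_lt(max(rel_err_rows(rec$time_signals, gt)), 1e-8)
  }
})

test_that("the SLIM encoding matrix evaluates the closed-form integrals", {
  grid <- c(8, 1, 1)
  fov <- c(240, 1, 1)
  lab <- array(c(rep(1L, 7), 2L), dim = grid)
  mask <- compartment_mask(lab, fov, c(bulk = 1L, point = 2L))
  s <- pe_scheme(rbind(c(0, 0, 0), c(1, 0, 0)), c(2L, 3L), fov, grid)

  opt <- build_g_matrix(s, mask, normalization = "total")
  # k = 0 row: R * compartment volume
  expect_equal(opt$encoding_matrix[1, ], c(2 * 7 / 8, 2 * 1 / 8) + 0i,
               tolerance = 1e-12)
  # single-voxel compartment at k = 1: |g| = R w sinc(kw), phase -2pi k x
  g <- opt$encoding_matrix[2, 2]
  w <- 1 / 8
  xc <- (7 - 4) / 8
  expect_equal(Mod(g), 3 * w * slamslim:::sinc(w), tolerance = 1e-12)
  expect_equal(Arg(g), Arg(exp(-2i * pi * xc)), tolerance = 1e-12)

  opm <- build_g_matrix(s, mask)
  expect_equal(opm$encoding_matrix[1, ], c(2, 2) + 0i, tolerance = 1e-12)

  # compartment spanning the full FOV along x: g = 0 for integer k != 0
  mask_full <- compartment_mask(array(1L, dim = grid), fov, c(all = 1L))
  opf <- build_g_matrix(s, mask_full)
  expect_lt(Mod(opf$encoding_matrix[2, 1]), 1e-12)
})

test_that("SLIM reconstruction solves the compartment system", {
  ph <- homog_phantom()
  mask <- as_compartment_mask(ph)
  s <- make_central_scheme(c(8, 16, 8), c(4, 4, 4), 6)
  op <- build_g_matrix(s, mask)
  expect_lt(max(abs(op$pinv %*% op$encoding_matrix - diag(3))), 1e-8)

  kz <- kspace_data(s, array(0 + 0i, dim = c(1, 64, 8)), 1 / 6000)
  expect_equal(max(Mod(slim_reconstruct(kz, op)$spectra)), 0)

  # C = 1 whole-FOV compartment, k = 0 encode only: the per-voxel-mean
  # spectrum equals the mean of all voxel FIDs
  grid <- c(4, 4, 2)
  ph2 <- homog_phantom(grid, extra = list(trim_base_slices = FALSE))
  ph2$label_map <- array(2L, dim = grid)
  ph2$density_map <- array(1, dim = grid)
  mask1 <- compartment_mask(ph2$label_map, ph2$fov_mm, c(heart = 2L))
  s0 <- pe_scheme(rbind(c(0, 0, 0)), 1L, ph2$fov_mm, grid)
  kd <- forward_encode(ph2, s0, n_time = 16)
  rec <- slim_reconstruct(kd, build_g_matrix(s0, mask1))
  mean_fid <- colMeans(slamslim:::phantom_fid_matrix(ph2, 16, kd$dwell_s))
  expect_equal(rec$time_signals[1, ], mean_fid, tolerance = 1e-10)
})

test_that("SLAM and SLIM agree as the voxel width shrinks", {
  set.seed(13)
  diffs <- sapply(c(64, 128), function(n) {
    grid <- c(n, n, 1)
    fov <- c(240, 240, 1)
    lab <- array(0L, dim = grid)
    xc <- voxel_centers(grid)
    inside <- (xc[, 1] / 0.3)^2 + (xc[, 2] / 0.25)^2 <= 1
    lab[array(inside, dim = grid)] <- 1L
    mask <- compartment_mask(lab, fov, c(bg = 0L, blob = 1L))
    k <- as.matrix(expand.grid(kx = -2:1, ky = -2:1, kz = 0))
    s <- pe_scheme(k, rep(1L, nrow(k)), fov, grid)
    kd_dummy <- array(0 + 0i, dim = c(1, nrow(k), 4))
    kd_dummy[1, , ] <- matrix(rnorm(nrow(k) * 4) +
                                1i * rnorm(nrow(k) * 4), nrow(k), 4)
    kd <- kspace_data(s, kd_dummy, 1e-4)
    a <- slam_reconstruct(kd, slam_operator(s, mask))$time_signals
    b <- slim_reconstruct(kd, build_g_matrix(s, mask))$time_signals
    max(Mod(a - b)) / max(Mod(a))
  })
  expect_lt(diffs[2], 1e-3)
  expect_lt(diffs[2], diffs[1])
})

test_that("FT-MRS reconstruction is the apodized inverse DFT", {
  grid <- c(4, 4, 2)
  fov <- c(240, 240, 200)
  ph <- homog_phantom(grid, extra = list(trim_base_slices = FALSE))
  d <- array(0, dim = grid)
  j0 <- c(2, 3, 1)
  d[j0[1], j0[2], j0[3]] <- 1
  ph$density_map <- d
  ph$label_map <- array(2L, dim = grid)  # single compartment everywhere

  su <- make_aw_scheme(grid, 1, weighting = "uniform", fov_mm = fov)
  kd <- forward_encode(ph, su, n_time = 8)
  vs <- ft_mrs_reconstruct(kd)
  amp <- Mod(vs$fids[, 1])
  lin0 <- (j0[3] - 1) * 16 + (j0[2] - 1) * 4 + j0[1]
  expect_equal(which.max(amp), lin0)
  expect_lt(max(amp[-lin0]) / amp[lin0], 1e-10)

  # AW weights act as apodization: nonzero sidelobes at the window's PSF
  sa <- make_aw_scheme(grid, 4, weighting = "hamming", fov_mm = fov,
                       drop_zero = FALSE)
  kda <- forward_encode(ph, sa, n_time = 8)
  vsa <- ft_mrs_reconstruct(kda)
  ampa <- Mod(vsa$fids[, 1])
  expect_gt(max(ampa[-lin0]) / ampa[lin0], 1e-6)
  psf <- ft_psf(sa, j0)
  expect_equal(ampa / ampa[lin0], Mod(psf$values)[cbind(
    rep(1:4, 8), rep(rep(1:4, each = 4), 2), rep(1:2, each = 16))],
    tolerance = 1e-9)

  # DC identity: the voxel sum equals the k = 0 sample
  expect_equal(colSums(vs$fids),
               kd$data[1, which(su$kx == 0 & su$ky == 0 & su$kz == 0), ],
               tolerance = 1e-10)

  sf <- pe_scheme(rbind(c(0.5, 0, 0)), 1L, fov, grid)
  kdf <- kspace_data(sf, array(0 + 0i, dim = c(1, 1, 4)), 1e-4)
  expect_error(ft_mrs_reconstruct(kdf), "fractional")
})

test_that("whitened SVD coil combination has matched-filter behavior", {
  dwell <- 1 / 6000
  sch <- make_central_scheme(c(8, 16, 8), c(2, 2, 2), 1)
  tv <- (0:127) * dwell
  sig <- exp((2i * pi * 100 - pi * 300) * tv)  # decayed well before the tail

  # single channel: identity pass-through
  d1 <- array(0 + 0i, dim = c(1, 8, 128))
  d1[1, , ] <- matrix(sig, 8, 128, byrow = TRUE)
  kd1 <- kspace_data(sch, d1, dwell)
  expect_identical(wsvd_combine(kd1)$data, d1)

  # channels (s, 0): output proportional to s
  d2 <- array(0 + 0i, dim = c(2, 8, 128))
  d2[1, , ] <- matrix(sig, 8, 128, byrow = TRUE)
  kd2 <- kspace_data(sch, d2, dwell)
  comb <- wsvd_combine(kd2, noise_cov = diag(2) + 0i)
  ratio <- comb$data[1, , ] / d2[1, , ]
  expect_lt(max(Mod(ratio - ratio[1, 1])), 1e-9)

  expect_error(
    wsvd_combine(kd2, noise_cov = matrix(c(1, 0, 0, -1), 2) + 0i),
    "positive-definite"
  )

  # two equal-signal channels with equal independent noise: SNR gain ~ sqrt(2)
  set.seed(7)
  gains <- replicate(40, {
    d <- array(0 + 0i, dim = c(2, 8, 128))
    for (ch in 1:2) {
      d[ch, , ] <- matrix(sig, 8, 128, byrow = TRUE) +
        matrix(complex(real = rnorm(8 * 128, sd = 0.1),
                       imaginary = rnorm(8 * 128, sd = 0.1)), 8, 128)
    }
    kd <- kspace_data(sch, d, dwell)
    cb <- wsvd_combine(kd, noise_cov = diag(2) + 0i)
    tail_idx <- 100:128
    snr1 <- Mod(d[1, 1, 1]) / sd(c(Re(d[1, , tail_idx]),
                                   Im(d[1, , tail_idx])))
    snrc <- Mod(cb$data[1, 1, 1]) / sd(c(Re(cb$data[1, , tail_idx]),
                                         Im(cb$data[1, , tail_idx])))
    snrc / snr1
  })
  expect_equal(mean(gains), sqrt(2), tolerance = 0.05)
})

test_that("reconstructed noise matches the closed-form operator gain", {
  ph <- homog_phantom()
  mask <- as_compartment_mask(ph)
  s <- make_aw_scheme(c(8, 16, 8), 4)
  op <- slam_operator(s, mask)
  gain <- operator_noise_gain(op)
  sigma <- 0.5
  set.seed(21)
  n_mc <- 300
  draws <- sapply(seq_len(n_mc), function(i) {
    noise <- complex(
      real = rnorm(nrow(s) * 2, sd = sigma * sqrt(s$repeats)),
      imaginary = rnorm(nrow(s) * 2, sd = sigma * sqrt(s$repeats))
    )
    d <- array(matrix(noise, nrow(s), 2), dim = c(1, nrow(s), 2))
    rec <- slam_reconstruct(kspace_data(s, d, 1e-4), op)
    c(Re(rec$time_signals), Im(rec$time_signals))
  })
  emp_c <- sapply(1:3, function(c) {
    sd(c(draws[seq(c, 12, by = 3), ]))
  })
  expect_equal(emp_c, sigma * gain, tolerance = 0.05)
})
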