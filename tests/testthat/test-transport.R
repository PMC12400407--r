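test_that("MSD handles stationary, ballistic and Brownian motion", {
  box <- box_geometry(50)
  n <- 5; nf <- 21
  still <- array(rep(matrix(runif(n * 3) * 10, n, 3), nf), c(n, 3, nf))
  tr <- make_trajectory(still, 0:(nf - 1), rep("A", n), box, unwrapped = still)
  msd <- compute_msd(tr)
  expect_true(all(msd$msd == 0))

  # ballistic: r = v t -> MSD = v^2 t^2, poor linear fit flagged via R^2 shape
  v <- c(0.3, 0, 0)
  bal <- array(0, c(1, 3, nf))
  for (f in 1:nf) bal[1, , f] <- v * (f - 1)
  trb <- make_trajectory(bal, 0:(nf - 1), "A", box, unwrapped = bal)
  msdb <- compute_msd(trb)
  expect_equal(msdb$msd, 0.09 * msdb$lag^2, tolerance = 1e-12)
  fitb <- einstein_diffusion(msdb)
  expect_gt(abs(fitb$intercept), 1e-3) # nonlinearity leaks into the intercept

  trd <- gen_brownian_ensemble(800, c(A = 0.05), dt = 1, n_steps = 200,
                               seed = 3)
  d <- einstein_diffusion(compute_msd(trd, origin_stride = 5))
  expect_equal(d$D, 0.05, tolerance = 0.05)
})

test_that("MSD is invariant under global translation", {
  tr <- gen_brownian_ensemble(50, c(A = 0.02), n_steps = 50, seed = 8)
  msd1 <- compute_msd(tr)
  tr2 <- tr
  tr2$unwrapped <- tr$unwrapped + 5.5
  msd2 <- compute_msd(tr2)
  expect_equal(msd1$msd, msd2$msd, tolerance = 1e-10)
})

test_that("minimum-image unwrapping reconstructs true displacements", {
  tr <- gen_brownian_ensemble(100, c(A = 0.05), dt = 1, n_steps = 100,
                              box = box_geometry(8), seed = 9)
  wrapped_only <- tr
  wrapped_only$unwrapped <- NULL
  rec <- unwrap_trajectory(wrapped_only)
  disp_true <- tr$unwrapped[, , 101] - tr$unwrapped[, , 1]
  disp_rec <- rec$unwrapped[, , 101] - rec$unwrapped[, , 1]
  expect_equal(disp_rec, disp_true, tolerance = 1e-9)
})

test_that("einstein_diffusion is exact on lines and absorbs intercepts", {
  msd <- data.frame(lag = 0:20, msd = 0.3 * (0:20))
  expect_equal(einstein_diffusion(msd)$D, 0.05, tolerance = 1e-12)
  msd2 <- data.frame(lag = 0:20, msd = 1.7 + 0.3 * (0:20))
  expect_equal(einstein_diffusion(msd2)$D, 0.05, tolerance = 1e-12)
  expect_error(einstein_diffusion(msd, window = c(0.5, 0.1)), "increasing")
  expect_error(einstein_diffusion(data.frame(lag = c(0, 1), msd = c(0, 1))),
               "fewer than 2 lags")
})

test_that("the +/-2 SE interval has near-nominal coverage", {
  hits <- vapply(1:100, function(s) {
    tr <- gen_brownian_ensemble(40, c(A = 0.05), dt = 1, n_steps = 60,
                                seed = 1000 + s)
    d <- einstein_diffusion(compute_msd(tr, origin_stride = 5))
    abs(d$D - 0.05) <= 2 * d$se
  }, logical(1))
  expect_gte(mean(hits), 0.88) # ~95% nominal, binomial noise at 100 repeats
})

test_that("D recovery is unbiased across magnitudes", {
  for (D0 in c(0.001, 0.01, 0.1)) {
    est <- vapply(1:30, function(s) {
      tr <- gen_brownian_ensemble(60, c(A = D0), dt = 1, n_steps = 60,
                                  seed = 200 * D0 * 1000 + s)
      einstein_diffusion(compute_msd(tr, origin_stride = 5))$D
    }, numeric(1))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - D0), 2 * se + 0.002 * D0)
  }
})

test_that("finite-size extrapolation is exact on noise-free lines", {
  N <- c(10^4, 20^4, 30^4)
  pts <- data.frame(N = N, D = 5 - 2 * N^(-1 / 3))
  fit <- finite_size_extrapolate(pts)
  expect_equal(fit$D_inf, 5, tolerance = 1e-10)
  expect_equal(fit$slope, -2, tolerance = 1e-10)

  flat <- data.frame(N = N, D = rep(3.3, 3))
  fitf <- finite_size_extrapolate(flat)
  expect_equal(fitf$D_inf, 3.3, tolerance = 1e-12)
  expect_equal(fitf$slope, 0, tolerance = 1e-10)

  expect_error(finite_size_extrapolate(data.frame(N = c(100, 100),
                                                  D = c(1, 2))),
               "at least 2 distinct")
})

test_that("noisy finite-size fits recover the intercept without bias", {
  N <- c(10^4, 20^4, 30^4)
  ints <- vapply(1:500, function(s) {
    set.seed(s)
    D <- 5 - 2 * N^(-1 / 3) + rnorm(3, sd = 0.05)
    finite_size_extrapolate(data.frame(N = N, D = D))$D_inf
  }, numeric(1))
  se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - 5), 2 * se)
})

test_that("local-phase classification matches ground truth and the oracle", {
  fp <- build_random_config(c(HexA = 1), 80, density = 3, min_dist = 0,
                            seed = 1)
  pa <- classify_local_phase(fp, 1.2)
  expect_true(all(pa$label == "HexA-rich"))

  box <- box_geometry(6, 6, 12)
  fr <- build_slab_config(c(HexA = 0.45, IMID = 0.45, water = 0.10), 500, box,
                          slab_species = c("IMID", "water"),
                          slab_fraction = 0.5, seed = 2)
  pa2 <- classify_local_phase(fr, 1.2)
  z <- fr$coords[match(pa2$mol_id, fr$mol_id), 3]
  deep_imid <- fr$species[match(pa2$mol_id, fr$mol_id)] == "IMID" &
    z > 1.2 & z < 6 - 1.2
  deep_hexa <- fr$species[match(pa2$mol_id, fr$mol_id)] == "HexA" &
    z > 6 + 1.2 & z < 12 - 1.2
  expect_gt(mean(pa2$label[deep_imid] == "IMID-rich"), 0.95)
  expect_gt(mean(pa2$label[deep_hexa] == "HexA-rich"), 0.95)

  # neighbourhood census equals the all-pairs oracle
  fr3 <- build_random_config(c(HexA = 0.4, IMID = 0.4, water = 0.2), 60,
                             density = 2, min_dist = 0, seed = 3)
  cen <- molecule_centers(fr3)
  sp_levels <- sort(unique(cen$species))
  got <- desmix:::neighbor_species_counts_cpp(
    cen$centers, match(cen$species, sp_levels) - 1L, length(sp_levels),
    fr3$box$L, 1.2)
  colnames(got) <- sp_levels
  expect_identical(got, oracle_neighbor_counts(cen$centers, cen$species,
                                               fr3$box, 1.2))

  expect_error(classify_local_phase(fp, radius = 100), "half the shortest")
})

test_that("per-phase diffusion is survivor-bias free", {
  tr <- gen_brownian_ensemble(400, c(A = 1), dt = 1, n_steps = 120, seed = 4,
                              compartments = list(D = c(0.01, 0.05),
                                                  fractions = c(0.5, 0.5),
                                                  rate = 0))
  pp <- per_phase_diffusion(tr, origin_stride = 10)
  expect_equal(pp[["1"]]$D, 0.01, tolerance = 0.10)
  expect_equal(pp[["2"]]$D, 0.05, tolerance = 0.10)

  # fast exchange: both phase-of-origin estimates converge to the population
  # average (the phases are dynamically indistinguishable)
  trx <- gen_brownian_ensemble(400, c(A = 1), dt = 1, n_steps = 120, seed = 5,
                               compartments = list(D = c(0.01, 0.05),
                                                   fractions = c(0.5, 0.5),
                                                   rate = 0.5))
  ppx <- per_phase_diffusion(trx, origin_stride = 10)
  dpop <- einstein_diffusion(compute_msd(trx, origin_stride = 10))
  expect_equal(ppx[["1"]]$D, dpop$D, tolerance = 0.10)
  expect_equal(ppx[["2"]]$D, dpop$D, tolerance = 0.10)

  # the survivor-only variant is visibly biased low on the same fixture:
  # regression guard that the default is the unbiased grouping
  pps <- per_phase_diffusion(trx, origin_stride = 10, survivors_only = TRUE)
  expect_lt(pps[["1"]]$D, 0.8 * ppx[["1"]]$D)
})

test_that("pair-count-weighted per-phase MSDs reconstruct the population MSD", {
  tr <- gen_brownian_ensemble(200, c(A = 1), dt = 1, n_steps = 60, seed = 6,
                              compartments = list(D = c(0.02, 0.08),
                                                  fractions = c(0.3, 0.7),
                                                  rate = 0.1))
  pp <- per_phase_diffusion(tr, origin_stride = 4)
  mall <- compute_msd(tr, origin_stride = 4)
  m1 <- pp[["1"]]$msd; m2 <- pp[["2"]]$msd
  wavg <- (m1$msd * m1$n_pairs + m2$msd * m2$n_pairs) /
    (m1$n_pairs + m2$n_pairs)
  expect_equal(wavg[-1], mall$msd[-1], tolerance = 1e-10)
})
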