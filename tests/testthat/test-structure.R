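test_that("density profiles conserve counts and resolve slabs", {
  box <- box_geometry(6, 6, 12)
  fr <- build_slab_config(c(A = 0.5, B = 0.5), 600, box, slab_species = "B",
                          slab_fraction = 0.5, seed = 1)
  prof <- partial_density_profile(fr, bin_width = 0.5)
  expect_equal(sum(attr(prof, "counts")), 600) # mass conservation, exact
  # plateau inside the slab, near-zero outside
  inside <- prof$center < 5
  outside <- prof$center > 7
  expect_gt(mean(prof$B[inside]), 10 * mean(prof$B[outside] + 1e-12))
  # normalized variant peaks at 1
  expect_equal(max(prof$B_norm), 1)
  # integral of number density recovers the molecule count
  vol_bin <- attr(prof, "bin_width") * 6 * 6
  expect_equal(sum(prof$B) * vol_bin, sum(fr$species == "B"))

  # homogeneous fluid: flat profile
  frh <- build_random_config(c(A = 1), 4000, box = box_geometry(5, 5, 10),
                             min_dist = 0, seed = 2)
  profh <- partial_density_profile(frh, bin_width = 1)
  expect_lt(max(profh$A) / min(profh$A), 1.2)

  expect_error(partial_density_profile(fr, bin_width = 20), "exceeds")
})

test_that("per-frame alignment keeps drifting slab profiles sharp", {
  box <- box_geometry(5, 5, 10)
  n <- 800
  nf <- 8
  set.seed(3)
  z0 <- c(runif(n / 2) * 5, 5 + runif(n / 2) * 5) # B slab at z < 5
  species <- rep(c("B", "A"), each = n / 2)
  co <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    co[, 1, f] <- runif(n) * 5
    co[, 2, f] <- runif(n) * 5
    co[, 3, f] <- (z0 + (f - 1) * 1.25) %% 10 # drift covers a full period
  }
  tr <- make_trajectory(co, 0:(nf - 1), species, box)
  aligned <- partial_density_profile(tr, bin_width = 0.5, align = "B")
  raw <- partial_density_profile(tr, bin_width = 0.5, align = FALSE)
  # drift washes the unaligned profile out; alignment keeps the contrast
  contrast <- function(p) max(p$B) / mean(p$B)
  expect_gt(contrast(aligned), 1.8)
  expect_lt(contrast(raw), 1.2)
  # aligned profile keeps an empty region outside the slab; raw does not
  expect_lt(min(aligned$B), 0.05 * max(aligned$B))
  expect_gt(min(raw$B), 0.5 * mean(raw$B))
})

test_that("RDF is flat for ideal gases and localises frozen pairs", {
  fr <- build_random_config(c(A = 1), 700, density = 2, min_dist = 0, seed = 5)
  g <- compute_rdf(fr, c("A", "A"), dr = 0.1)
  expect_true(all(abs(g$g[g$r > 0.3] - 1) < 0.15))
  expect_lt(abs(mean(g$g[g$r > 0.3]) - 1), 0.02)

  # self-consistency: integral of rho g(r) 4 pi r^2 dr recovers N - 1
  rho <- 700 / prod(fr$box$L)
  n_rec <- sum(rho * g$g * 4 * pi * g$r^2 * 0.1)
  n_ideal <- rho * 4 / 3 * pi * max(g$r + 0.05)^3
  expect_equal(n_rec / n_ideal, 1, tolerance = 0.02)

  frz <- make_frame(rbind(c(1, 1, 1), c(2, 1, 1)), c("A", "A"),
                    box_geometry(8))
  g2 <- compute_rdf(frz, c("A", "A"), dr = 0.02)
  hit <- which(attr(g2, "counts") > 0)
  expect_length(hit, 1)
  expect_true(g2$r[hit] > 0.98 && g2$r[hit] < 1.02)

  expect_error(compute_rdf(frz, c("A", "A"), r_max = 10), "half the shortest")
})

test_that("RDF histograms equal an all-pairs brute-force count", {
  fr <- build_random_config(c(A = 0.6, B = 0.4), 250, density = 2,
                            min_dist = 0, seed = 6)
  for (pair in list(c("A", "A"), c("A", "B"))) {
    g <- compute_rdf(fr, pair, r_max = 2, dr = 0.1)
    # oracle: direct double loop over minimum-image distances
    ia <- which(fr$species == pair[1])
    ib <- which(fr$species == pair[2])
    dists <- c()
    for (i in ia) {
      js <- if (pair[1] == pair[2]) ib[ib > i] else ib
      if (length(js) == 0) next
      d <- minimum_image(sweep(fr$coords[js, , drop = FALSE], 2,
                               fr$coords[i, ]), fr$box)
      dists <- c(dists, sqrt(rowSums(d^2)))
    }
    oracle <- as.numeric(table(cut(dists[dists < 2], seq(0, 2, 0.1),
                                   right = FALSE)))
    expect_equal(as.numeric(attr(g, "counts")), oracle)
  }
})

test_that("self-clustering fixtures show preferential self-interaction", {
  box <- box_geometry(10)
  fr <- build_slab_config(c(A = 0.5, B = 0.5), 600, box, slab_species = "B",
                          slab_fraction = 0.5, seed = 7)
  r1 <- 0.8 # first-shell scale of the fixture
  gaa <- compute_rdf(fr, c("A", "A"), r_max = 2, dr = 0.2)
  gbb <- compute_rdf(fr, c("B", "B"), r_max = 2, dr = 0.2)
  gab <- compute_rdf(fr, c("A", "B"), r_max = 2, dr = 0.2)
  k <- which.min(abs(gaa$r - r1))
  expect_gt(gaa$g[k], gab$g[k])
  expect_gt(gbb$g[k], gab$g[k])
})

test_that("pollutant fractions agree between region definitions", {
  box <- box_geometry(6, 6, 12)
  frm <- build_slab_config(c(A = 0.5, B = 0.5), 2000, box,
                           slab_species = "B", slab_fraction = 0.5,
                           misplaced_fraction = 0.2, min_dist = 0, seed = 8)
  # ground-truth interval region
  pp <- pollutant_fraction(frm, "B", region = attr(frm, "slab_bounds"))
  expect_equal(pp$fraction_outside, 20.0, tolerance = 1e-9)
  # all inside
  fr0 <- build_slab_config(c(A = 0.5, B = 0.5), 400, box, slab_species = "B",
                           slab_fraction = 0.5, seed = 9)
  pp0 <- pollutant_fraction(fr0, "B", region = attr(fr0, "slab_bounds"))
  expect_equal(pp0$fraction_outside, 0)

  # profile-threshold region agrees within 5 percentage points
  prof <- partial_density_profile(frm, bin_width = 0.5)
  reg <- phase_region_from_profile(prof, "B")
  pp2 <- pollutant_fraction(frm, "B", region = reg)
  expect_lt(abs(pp2$fraction_outside - pp$fraction_outside), 5)

  # local-composition labels agree too on this sharp interface
  pa <- classify_local_phase(frm, radius = 1.2,
                             groups = list("A-rich" = "A", "B-rich" = "B"),
                             exclude = character(0))
  pp3 <- pollutant_fraction(frm, "B", labels = pa, home_phase = "B-rich")
  expect_lt(abs(pp3$fraction_outside - pp$fraction_outside), 5)

  # no density contrast -> explicit failure
  frh <- build_random_config(c(A = 1), 500, density = 2, min_dist = 0,
                             seed = 10)
  profh <- partial_density_profile(frh, bin_width = 1)
  expect_error(phase_region_from_profile(profh, "A"), "no density contrast")
})
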