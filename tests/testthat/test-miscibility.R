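test_that("contacts follow the pair-distance definition", {
  box <- box_geometry(10)
  near <- make_frame(rbind(c(1, 1, 1), c(1.5, 1, 1)), c("HexA", "IMID"), box)
  far <- make_frame(rbind(c(1, 1, 1), c(1.7, 1, 1)), c("HexA", "IMID"), box)
  expect_equal(count_contacts(near, 0.6)$counts["HexA", "IMID"], 1)
  expect_equal(count_contacts(far, 0.6)$counts["HexA", "IMID"], 0)

  # periodic image: 0.5 nm across the boundary
  wrap <- make_frame(rbind(c(0.2, 1, 1), c(9.7, 1, 1)), c("HexA", "IMID"), box)
  expect_equal(count_contacts(wrap, 0.6)$counts["HexA", "IMID"], 1)

  # demixed slabs with a vacuum gap wider than the cutoff: no cross contacts
  gap <- make_frame(rbind(cbind(runif(20), runif(20), runif(20) * 2),
                          cbind(runif(20), runif(20), 4 + runif(20) * 2)),
                    rep(c("HexA", "IMID"), each = 20), box)
  expect_equal(count_contacts(gap, 0.6)$counts["HexA", "IMID"], 0)

  expect_error(count_contacts(near, 6), "half the shortest box edge")
})

test_that("cell-list counts equal the brute-force oracle on random fixtures", {
  for (s in 1:8) {
    fr <- build_random_config(c(HexA = 0.4, IMID = 0.4, water = 0.2),
                              80 + 15 * s, density = 2 + 0.3 * s,
                              min_dist = 0, seed = s)
    cell <- count_contacts(fr, 0.6, method = "cell")$counts
    brute <- count_contacts(fr, 0.6, method = "brute")$counts
    expect_identical(cell, brute)
    expect_identical(cell, oracle_contact_counts(fr, 0.6))
  }
})

test_that("multi-bead molecules count once per molecule pair", {
  box <- box_geometry(10)
  # two 2-bead molecules with both bead pairs within cutoff: still 1 contact
  fr <- make_frame(rbind(c(1, 1, 1), c(1.3, 1, 1), c(1.6, 1, 1), c(1.9, 1, 1)),
                   c("HexA", "HexA", "IMID", "IMID"), box,
                   mol_id = c(1, 1, 2, 2))
  expect_equal(count_contacts(fr, 0.6, mode = "molecule")$counts["HexA", "IMID"], 1)
  # bead mode counts bead pairs on distinct molecules
  expect_gt(count_contacts(fr, 0.6, mode = "bead")$counts["HexA", "IMID"], 1)
  expect_identical(count_contacts(fr, 0.6)$counts, oracle_contact_counts(fr, 0.6))
})

test_that("counts are invariant under rigid motion and relabeling", {
  fr <- build_random_config(c(HexA = 0.5, IMID = 0.5), 120, density = 3,
                            min_dist = 0, seed = 5)
  base <- count_contacts(fr, 0.6)$counts
  shifted <- make_frame(sweep(fr$coords, 2, c(1.3, -2.1, 0.7), `+`),
                        fr$species, fr$box, fr$mol_id)
  expect_identical(count_contacts(shifted, 0.6)$counts, base)
  # permuting particles within a species leaves species-pair counts unchanged
  perm <- sample(nrow(fr$coords))
  relab <- make_frame(fr$coords[perm, ], fr$species[perm], fr$box,
                      fr$mol_id[perm])
  expect_identical(count_contacts(relab, 0.6)$counts, base)
})

test_that("the metric is scale-consistent under periodic replication", {
  fr <- build_random_config(c(HexA = 0.5, IMID = 0.5), 100, density = 3,
                            min_dist = 0, seed = 6)
  m1 <- mixing_metric(count_contacts(fr, 0.6))
  m2 <- mixing_metric(count_contacts(replicate_frame(fr), 0.6))
  expect_lt(abs(m2 - m1) / m1, 0.01)
})

test_that("mixing metric computes the contact percentage and flags zero denominators", {
  rep0 <- structure(list(counts = matrix(c(0, 30, 30, 70), 2, 2,
                                         dimnames = list(c("HexA", "IMID"),
                                                         c("HexA", "IMID"))),
                         cutoff = 0.6, mode = "molecule", n_molecules = 100),
                    class = "contact_report")
  expect_equal(mixing_metric(rep0), 30.0)

  rep1 <- rep0
  rep1$counts["HexA", "IMID"] <- rep1$counts["IMID", "HexA"] <- 0
  expect_equal(mixing_metric(rep1), 0)

  rep2 <- rep0
  rep2$counts[] <- 0
  expect_warning(m <- mixing_metric(rep2), "undefined")
  expect_true(is.na(m))
})

test_that("ideal random equimolar mixtures match the analytic expectation", {
  # E[metric] = 100 * 2 N_H / (2 N_H + N_I - 1) for uniform placement:
  # cross pairs N_H*N_I and self pairs N_I(N_I-1)/2 share one contact
  # probability p, which cancels.
  n_h <- n_i <- 100
  expected <- 100 * 2 * n_h / (2 * n_h + n_i - 1)
  vals <- vapply(1:50, function(s) {
    fr <- build_random_config(c(HexA = 0.5, IMID = 0.5), n_h + n_i,
                              box = box_geometry(6.3), min_dist = 0, seed = s)
    mixing_metric(count_contacts(fr, 0.6))
  }, numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * sem + 0.5)
})

test_that("classification follows the miscibility bands with an explicit gap", {
  expect_equal(classify_mixing(55), "mixed")
  expect_equal(classify_mixing(40), "partially_mixed")
  expect_equal(classify_mixing(20), "almost_biphasic")
  expect_equal(classify_mixing(47), "intermediate")
  # band edges: 50 is not mixed, 45 is still partially mixed, 30 included
  expect_equal(classify_mixing(c(50, 45, 30, 29.999, 50.001)),
               c("intermediate", "partially_mixed", "partially_mixed",
                 "almost_biphasic", "mixed"))
  expect_error(classify_mixing(120), "within")
  expect_error(classify_mixing(-5), "within")
})

test_that("slab demixing lowers the metric monotonically", {
  box <- box_geometry(8, 8, 8)
  vals <- vapply(c(0, 0.5, 1), function(f) {
    # move a fraction f of IMID into an exclusive slab
    set.seed(40)
    n <- 300
    fr <- build_random_config(c(HexA = 0.5, IMID = 0.5), n, box = box,
                              min_dist = 0, seed = 40)
    im <- which(fr$species == "IMID")
    mv <- im[seq_len(round(f * length(im)))]
    coords <- fr$coords
    coords[mv, 3] <- runif(length(mv)) * 2      # slab z < 2
    others <- setdiff(seq_len(n), mv)
    coords[others, 3] <- 2 + runif(length(others)) * 6
    m <- make_frame(coords, fr$species, box, fr$mol_id)
    mixing_metric(count_contacts(m, 0.6))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("miscibility_scan aggregates replicas into labelled cells", {
  box <- box_geometry(6, 6, 12)
  slab_traj <- function(seed) {
    fr <- build_slab_config(c(HexA = 0.45, IMID = 0.45, water = 0.10), 300,
                            box, slab_species = c("IMID", "water"),
                            slab_fraction = 0.4, seed = seed)
    make_trajectory(array(rep(fr$coords, 2), c(nrow(fr$coords), 3, 2)),
                    c(0, 1), fr$species, box)
  }
  mixed_traj <- function(seed) {
    fr <- build_random_config(c(HexA = 0.45, IMID = 0.45, water = 0.10), 300,
                              density = 3, min_dist = 0, seed = seed)
    make_trajectory(array(rep(fr$coords, 2), c(nrow(fr$coords), 3, 2)),
                    c(0, 1), fr$species, fr$box)
  }
  cells <- list(
    list(chi_imid = 0.45, temperature = 270,
         trajectories = list(slab_traj(1), slab_traj(2))),
    list(chi_imid = 0.45, temperature = 330,
         trajectories = list(mixed_traj(3), mixed_traj(4)))
  )
  tab <- miscibility_scan(cells, cutoff = 0.6, discard = 0)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$class[1], "almost_biphasic")
  expect_equal(tab$class[2], "mixed")
  expect_true(all(tab$sd_pct >= 0))
  expect_error(miscibility_scan(list(list(chi_imid = 1, temperature = 1,
                                          trajectories = list()))),
               "at least one trajectory")
})
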