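test_that("crossover detection takes block-boundary midpoints", {
  markers <- tibble::tibble(
    pos = c(seq(1, 1e6, length.out = 600), seq(1.001e6, 2e6, length.out = 600)),
    origin = rep(c("GP", "GM"), each = 600))
  bp <- detect_crossovers(markers, min_block = 500)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$breakpoint, (1e6 + 1.001e6) / 2)
  expect_equal(bp$left_origin, "GP")
  expect_equal(bp$right_origin, "GM")
})

test_that("single-origin tracks and short runs produce no breakpoints", {
  mono <- tibble::tibble(pos = 1:2000, origin = "GP")
  expect_equal(nrow(detect_crossovers(mono, min_block = 500)), 0)
  # a short flip inside one block is masked, and the flanks re-merge
  flick <- tibble::tibble(
    pos = 1:2000,
    origin = c(rep("GP", 900), rep("GM", 50), rep("GP", 1050)))
  expect_equal(nrow(detect_crossovers(flick, min_block = 500)), 0)
  # but a genuine block boundary survives the same masking
  real <- tibble::tibble(
    pos = 1:2000,
    origin = c(rep("GP", 900), rep("GM", 50), rep("GP", 50), rep("GM", 1000)))
  bp <- detect_crossovers(real, min_block = 500)
  expect_equal(nrow(bp), 1)
})

test_that("noiseless simulated tracks are recovered exactly", {
  true_xo <- c(30e6, 55e6, 80e6)
  mk <- simulate_marker_track(1e8, 40000, true_xo, seed = 4)
  bp <- detect_crossovers(mk, min_block = 500)
  expect_equal(nrow(bp), length(true_xo))
  # each true crossover lies inside its flanking-marker interval
  expect_true(all(bp$left_end <= true_xo & true_xo <= bp$right_start))
  # count is within 1 of truth even with sparse label noise
  noisy <- simulate_marker_track(1e8, 40000, true_xo, error_rate = 0.001,
                                 seed = 5)
  bp_n <- detect_crossovers(noisy, min_block = 500)
  expect_lte(abs(nrow(bp_n) - 3), 1)
})

test_that("grouped tracks are detected per trio and chromosome", {
  mk <- function(tid, ctg, xo) {
    dplyr::mutate(simulate_marker_track(1e7, 3000, xo),
                  trio_id = tid, contig = ctg)
  }
  set.seed(10)
  tracks <- dplyr::bind_rows(mk("T1", "chr1", 5e6), mk("T1", "chr2", numeric()),
                             mk("T2", "chr1", c(2e6, 8e6)))
  bp <- detect_crossovers(tracks, min_block = 300)
  tab <- dplyr::count(bp, trio_id)
  expect_equal(tab$n[tab$trio_id == "T1"], 1)
  expect_equal(tab$n[tab$trio_id == "T2"], 2)
})

test_that("proximity expectation is trio-matched and saturates safely", {
  empty <- dnm_crossover_proximity(
    tibble::tibble(trio_id = "T1", contig = "chr1", pos = 100),
    tibble::tibble(trio_id = character(), contig = character(),
                   breakpoint = numeric()),
    genome_size = 2.28e9)
  expect_equal(empty$observed_near, 0)
  expect_equal(empty$expected_near, 0)

  one <- dnm_crossover_proximity(
    tibble::tibble(trio_id = "T1", contig = "chr1", pos = 5e6),
    tibble::tibble(trio_id = "T1", contig = "chr1", breakpoint = 5e6 + 300),
    genome_size = 2.28e9)
  expect_equal(one$observed_near, 1)

  expect_error(dnm_crossover_proximity(
    tibble::tibble(trio_id = "T1", contig = "chr1", pos = 1),
    tibble::tibble(trio_id = rep("T1", 60), contig = "chr1",
                   breakpoint = seq(1e6, 6e7, length.out = 60)),
    window_bp = 1e4, genome_size = 1e6), "saturate")
})

test_that("cohort-scale proximity expectation reproduces ~1.3", {
  # 390 trios with ~21.3 DNMs and ~18.3 crossovers each, 10-kb window,
  # 2.28-Gb autosomal genome
  set.seed(17)
  n_dnm <- rpois(390, 21.3)
  n_bp <- rpois(390, 18.3)
  dnms <- tibble::tibble(
    trio_id = rep(sprintf("T%03d", 1:390), n_dnm), contig = "chr1",
    pos = runif(sum(n_dnm), 1, 2.28e9))
  bps <- tibble::tibble(
    trio_id = rep(sprintf("T%03d", 1:390), n_bp), contig = "chr1",
    breakpoint = runif(sum(n_bp), 1, 2.28e9))
  prox <- dnm_crossover_proximity(dnms, bps, window_bp = 1e4,
                                  genome_size = 2.28e9)
  manual <- sum(n_dnm * n_bp * 2e4 / 2.28e9)
  expect_equal(prox$expected_near, manual, tolerance = 1e-12)
  expect_equal(prox$expected_near, 1.3, tolerance = 0.1)
  expect_true(prox$p >= 0 && prox$p <= 1)
})

test_that("branch ratios pair identical topologies and reject mismatches", {
  tt <- demo_carnivore_timetree()
  same <- branch_ratios(tt, tt)
  expect_true(all(abs(same$ratios$ratio - 1) < 1e-12))

  # one branch scaled by 2.21
  scaled <- tt
  clades <- canidnm:::edge_clades(tt)
  idx <- clades$edge[clades$clade == "awd|dog"]
  scaled$edge.length[idx] <- scaled$edge.length[idx] * 2.21
  rp <- branch_ratios(scaled, tt)
  expect_equal(rp$ratios$ratio[rp$ratios$clade == "awd|dog"], 2.21)
  expect_true(all(abs(rp$ratios$ratio[rp$ratios$clade != "awd|dog"] - 1)
                  < 1e-12))

  # common rescaling leaves ratios unchanged
  h2 <- scaled; h2$edge.length <- h2$edge.length * 3.7
  a2 <- tt; a2$edge.length <- a2$edge.length * 3.7
  expect_equal(branch_ratios(h2, a2)$ratios$ratio, rp$ratios$ratio)

  other <- ape::read.tree(text = "(cat:52,((ursus:12,fox:12):31,(dog:6,awd:6):37):9);")
  expect_error(branch_ratios(other, tt), "mismatch")
  expect_error(branch_ratios(ape::read.tree(text = "(a:1,b:1);"), tt),
               "tip sets")
})

test_that("loss-time solver inverts the mixture in its limit cases", {
  tt <- demo_carnivore_timetree()
  roles <- demo_branch_roles()
  solve_at <- function(loss) {
    sim <- simulate_ratioed_phylogeny(tt, r0 = 1, r1 = 2.21, loss_time = loss,
                                      noise_sd = 0)
    estimate_loss_time(branch_ratios(sim$tree_hmr, sim$tree_auto), tt, roles,
                       n_resamples = 10, noise_sd = 0, seed = 1)
  }
  # full effect on the transition branch: loss at its oldest point (43 My)
  expect_equal(solve_at(43)$loss_time_mya, 43, tolerance = 1e-9)
  # mixture midpoint: loss at the branch midpoint
  expect_equal(solve_at((12 + 43) / 2)$loss_time_mya, (12 + 43) / 2,
               tolerance = 1e-9)
})

test_that("loss-time estimation round-trips the simulator at zero noise", {
  tt <- demo_carnivore_timetree()
  roles <- demo_branch_roles()
  for (loss in c(15.2, 26.9, 37.3, 41.8)) {
    sim <- simulate_ratioed_phylogeny(tt, r0 = 1, r1 = 2.21, loss_time = loss,
                                      noise_sd = 0)
    est <- estimate_loss_time(branch_ratios(sim$tree_hmr, sim$tree_auto), tt,
                              roles, n_resamples = 5, noise_sd = 0, seed = 1)
    expect_equal(est$loss_time_mya, loss, tolerance = 1e-9)
  }
})

test_that("loss-time estimate is invariant to rescaling both trees", {
  tt <- demo_carnivore_timetree()
  sim <- simulate_ratioed_phylogeny(tt, loss_time = 37.3, noise_sd = 0.01,
                                    seed = 3)
  est1 <- estimate_loss_time(branch_ratios(sim$tree_hmr, sim$tree_auto), tt,
                             demo_branch_roles(), n_resamples = 50, seed = 2)
  h <- sim$tree_hmr; h$edge.length <- h$edge.length * 10
  a <- sim$tree_auto; a$edge.length <- a$edge.length * 10
  est2 <- estimate_loss_time(branch_ratios(h, a), tt, demo_branch_roles(),
                             n_resamples = 50, seed = 2)
  expect_equal(est1$loss_time_mya, est2$loss_time_mya, tolerance = 1e-9)
  expect_equal(est1$ci_low, est2$ci_low, tolerance = 1e-9)
})

test_that("loss-time estimation under noise brackets the configured loss", {
  tt <- demo_carnivore_timetree()
  sim <- simulate_ratioed_phylogeny(tt, loss_time = 37.3, noise_sd = 0.005,
                                    seed = 11)
  est <- estimate_loss_time(branch_ratios(sim$tree_hmr, sim$tree_auto), tt,
                            demo_branch_roles(), n_resamples = 400,
                            noise_sd = 0.005, seed = 12)
  expect_lt(abs(est$loss_time_mya - 37.3), 2)
  expect_true(est$ci_low <= est$loss_time_mya &&
                est$loss_time_mya <= est$ci_high)
  expect_true(est$ci_low >= est$t_young && est$ci_high <= est$t_old)
})

test_that("degenerate ratio configurations are rejected or clamped", {
  tt <- demo_carnivore_timetree()
  same <- branch_ratios(tt, tt)
  expect_error(estimate_loss_time(same, tt, demo_branch_roles(),
                                  n_resamples = 5, seed = 1),
               "no rate shift")
  # r_obs above r1: clamped with flag
  sim <- simulate_ratioed_phylogeny(tt, r0 = 1, r1 = 2, loss_time = 43,
                                    noise_sd = 0)
  h <- sim$tree_hmr
  cl <- canidnm:::edge_clades(tt)
  idx <- cl$edge[cl$clade == "awd|dog|fox"]
  h$edge.length[idx] <- h$edge.length[idx] * 1.5
  est <- estimate_loss_time(branch_ratios(h, sim$tree_auto), tt,
                            demo_branch_roles(), n_resamples = 5,
                            noise_sd = 0, seed = 1)
  expect_true(est$clamped)
  expect_equal(est$loss_time_mya, 43)
})
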