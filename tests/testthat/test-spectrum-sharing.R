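test_that("spectrum tables are complete, normalised and order-invariant", {
  co <- small_cohort()
  sp <- spectrum_table(co$dnms, cohort = "a")
  expect_equal(nrow(sp), 7)
  expect_equal(sum(sp$fraction), 1, tolerance = 1e-12)
  shuffled <- co$dnms[sample.int(nrow(co$dnms)), ]
  expect_equal(spectrum_table(shuffled)$fraction, sp$fraction)
  # region restriction
  sp_hmr <- spectrum_table(co$dnms, region = "HMR_CGI")
  expect_equal(sum(sp_hmr$count), sum(co$dnms$in_hmr_cgi))
})

test_that("Fisher class tests match the hypergeometric enumeration oracle", {
  ft <- cross_species_class_test(c(x = 10, y = 90), c(x = 20, y = 80),
                                 n_tests = 8)
  expect_equal(ft$p[1], fisher_p_oracle(10, 90, 20, 80), tolerance = 1e-9)
  # exhaustive small-table sweep
  for (a in c(0, 1, 3, 7)) for (b in c(1, 4, 9)) {
    for (cc in c(0, 2, 6)) for (d in c(1, 5, 10)) {
      if (a + cc == 0) next
      got <- cross_species_class_test(c(k = a, o = b), c(k = cc, o = d))$p[1]
      expect_equal(got, fisher_p_oracle(a, b, cc, d), tolerance = 1e-9,
                   info = paste(a, b, cc, d))
    }
  }
})

test_that("class-test significance uses the Bonferroni-of-8 threshold", {
  ft <- cross_species_class_test(c(x = 10, y = 90), c(x = 20, y = 80),
                                 n_tests = 8)
  expect_equal(ft$bonferroni_threshold[1], 0.00625)
  expect_equal(ft$significant, ft$p < 0.00625)
  expect_false(0.007 < ft$bonferroni_threshold[1])
  expect_true(0.006 < ft$bonferroni_threshold[1])
  # identical spectra: odds ratio 1, never significant
  same <- cross_species_class_test(c(x = 50, y = 50), c(x = 50, y = 50))
  expect_equal(same$odds_ratio, c(1, 1), tolerance = 1e-6)
  expect_false(any(same$significant))
  # class absent from both cohorts
  absent <- cross_species_class_test(c(x = 0, y = 50), c(x = 0, y = 60))
  expect_equal(absent$p[1], 1)
  expect_false(absent$or_defined[1])
})

test_that("paternal-age class trends fit a weighted line over age bins", {
  flat <- tibble::tibble(
    mutation_class = rep(c("C>T", "T>C"), 300),
    paternal_age_years = rep(2:7, each = 100))
  tr <- paternal_age_class_trend(flat, "C>T")
  expect_equal(tr$slope, 0, tolerance = 1e-12)

  two <- tibble::tibble(
    mutation_class = c(rep("C>T", 30), rep("T>C", 70),
                       rep("C>T", 60), rep("T>C", 40)),
    paternal_age_years = rep(c(2, 8), each = 100))
  tr2 <- paternal_age_class_trend(two, "C>T")
  expect_equal(tr2$slope, (0.6 - 0.3) / 6, tolerance = 1e-12)

  set.seed(21)
  ages <- sample(2:9, 4000, replace = TRUE)
  p_ct <- 0.30 - 0.015 * ages
  dec <- tibble::tibble(
    mutation_class = ifelse(runif(4000) < p_ct, "CpG>TpG", "T>C"),
    paternal_age_years = ages)
  tr3 <- paternal_age_class_trend(dec, "CpG>TpG")
  expect_lt(tr3$slope, 0)
  expect_lt(tr3$p, 0.05)
})

test_that("shared-mutation grouping resolves sibling relations", {
  trios <- dplyr::bind_rows(
    toy_trio("T1"), toy_trio("T2"), toy_trio("T3"), toy_trio("T4"))
  trios$sire_id <- c("S1", "S1", "S1", "S9")
  trios$dam_id <- c("D1", "D1", "D2", "D9")
  mk <- function(trio, pos, alt = "T") {
    tibble::tibble(trio_id = trio, contig = "chr1", pos = pos, alt = alt,
                   phase = "unphased")
  }
  dnms <- dplyr::bind_rows(
    mk("T1", 100), mk("T2", 100), mk("T3", 100),   # T1,T2 full; T3 half-sib
    mk("T1", 200), mk("T2", 200),                  # full-sib pair
    mk("T1", 300), mk("T4", 300),                  # no shared parent
    mk("T1", 400), mk("T2", 450),                  # singletons
    mk("T1", 500, "G"), mk("T2", 500, "A")         # same pos, different alt
  )
  sm <- find_shared_mutations(dnms, trios)
  expect_equal(nrow(sm$groups), 3)
  g100 <- sm$groups[sm$groups$pos == 100, ]
  expect_equal(g100$n_members, 3)
  expect_equal(g100$relation, "half_sib") # T3 shares only the sire
  expect_equal(sm$groups$relation[sm$groups$pos == 200], "full_sib")
  expect_equal(sm$groups$relation[sm$groups$pos == 300],
               "RECURRENT_UNRELATED")
  expect_equal(sm$n_shared_groups, 2)

  none <- find_shared_mutations(dplyr::bind_rows(mk("T1", 1), mk("T2", 2)),
                                trios)
  expect_equal(nrow(none$groups), 0)
})

test_that("simulated early mutations surface as full-sib shared groups", {
  cfg <- simulation_config(n_trios = 200, shared_fraction = 0.02, seed = 61)
  co <- simulate_cohort(cfg, region_map = default_region_map(scale = 0.05))
  sm <- find_shared_mutations(co$dnms, co$trios)
  truth_groups <- dplyr::n_distinct(stats::na.omit(co$dnms$shared_group_id))
  expect_equal(sm$n_shared_groups, truth_groups)
  expect_true(all(sm$groups$relation == "full_sib"))
})

test_that("shared-fraction bootstrap is exact in degenerate cases and seeded", {
  trios <- dplyr::bind_rows(toy_trio("T1"), toy_trio("T2"))
  trios$sire_id <- "S"
  trios$dam_id <- "D"
  both <- dplyr::bind_rows(
    tibble::tibble(trio_id = "T1", contig = "chr1", pos = c(10, 20), alt = "T"),
    tibble::tibble(trio_id = "T2", contig = "chr1", pos = c(10, 20), alt = "T"))
  all_shared <- shared_fraction_bootstrap(both, trios, n_boot = 100, seed = 1)
  expect_equal(all_shared$fraction, 1)
  expect_equal(all_shared$ci_low, 1)
  expect_equal(all_shared$ci_high, 1)
  a <- shared_fraction_bootstrap(both, trios, n_boot = 100, seed = 5)
  b <- shared_fraction_bootstrap(both, trios, n_boot = 100, seed = 5)
  expect_identical(a, b)
  expect_error(shared_fraction_bootstrap(both, toy_trio("T9"), seed = 1),
               "full-sibling")
})

test_that("the estimator recovers the configured sibling-shared fraction", {
  # single-cohort estimates are noisy (shared counts are correlated within a
  # litter), so the recovery property is assessed as bias over replicate
  # cohorts plus CI behaviour
  rm <- default_region_map(scale = 0.02)
  target <- 0.0045
  ests <- purrr::map(1:10, function(i) {
    co <- simulate_cohort(simulation_config(seed = 500 + i), rm)
    shared_fraction_bootstrap(co$dnms, co$trios, n_boot = 200, seed = i)
  }) |> purrr::list_rbind()
  expect_lt(abs(mean(ests$fraction) / target - 1), 0.25)
  covered <- mean(ests$ci_low <= target & target <= ests$ci_high)
  expect_gte(covered, 0.6)
  expect_true(all(ests$fraction >= 0 & ests$fraction <= 1))
})

test_that("hypermutator flagging finds a tenfold outlier and nothing in nulls", {
  counts <- tibble::tibble(trio_id = sprintf("T%03d", 1:50),
                           n_dnm = c(rep(21:25, length.out = 49), 214))
  fl <- flag_hypermutators(counts)
  expect_true(fl$flagged[fl$n_dnm == 214])
  expect_equal(fl$fold[fl$n_dnm == 214], 214 / 23, tolerance = 0.05)
  expect_false(any(fl$flagged[fl$n_dnm != 214]))
  at_median <- fl[fl$n_dnm == 23, ][1, ]
  expect_equal(at_median$fold, 1.0)

  # type-I error under a homogeneous Poisson cohort
  set.seed(99)
  any_flag <- vapply(1:100, function(i) {
    d <- tibble::tibble(trio_id = as.character(1:60), n_dnm = rpois(60, 21))
    any(flag_hypermutators(d)$flagged)
  }, TRUE)
  expect_lte(mean(any_flag), 0.08)
  expect_error(flag_hypermutators(tibble::tibble(trio_id = as.character(1:10),
                                                 n_dnm = rep(0L, 10))),
               "median")
})

test_that("phase balance test equals exact binomial enumeration", {
  expect_equal(phase_balance_test(5, 5), 1)
  expect_equal(phase_balance_test(0, 20), 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(phase_balance_test(11, 12),
               binom_p_oracle(12, 23, 0.5), tolerance = 1e-9)
  expect_equal(phase_balance_test(11, 12, expected_paternal_fraction = 0.7505),
               binom_p_oracle(12, 23, 0.7505), tolerance = 1e-9)
  expect_error(phase_balance_test(0, 0), "no phased")
})
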