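test_that("the canonical autosomal DNM passes and single violations are coded", {
  rm <- toy_region_map()
  trio <- toy_trio()
  v <- apply_dnm_filters(toy_site(), trio, rm)
  expect_true(v$pass)
  expect_equal(v$failed, "")

  v2 <- apply_dnm_filters(toy_site(ad_alt_sire = 2), trio, rm)
  expect_false(v2$pass)
  expect_equal(v2$failed, "PARENT_ALT_READS")

  v3 <- apply_dnm_filters(toy_site(gt_dam = "0/1"), trio, rm)
  expect_equal(v3$failed, "GT_PATTERN")

  v4 <- apply_dnm_filters(toy_site(gq_offspring = 39), trio, rm)
  expect_equal(v4$failed, "GQ")

  v5 <- apply_dnm_filters(toy_site(ref = "CT", alt = "C"), trio, rm)
  expect_true(grepl("NOT_SNV", v5$failed))
})

test_that("boundary strictness follows the stated inequalities", {
  rm <- toy_region_map()
  trio <- toy_trio() # mean depth 43.3 for every member
  # GQ >= 40 inclusive
  expect_true(apply_dnm_filters(toy_site(gq_offspring = 40), trio, rm)$pass)
  # DP >= 12 inclusive, but mean-relative bounds strict: with mean 20,
  # DP = 12 satisfies 10 < 12 < 40 (parents kept near their own mean)
  s12 <- toy_site(dp_offspring = 12, ad_ref_offspring = 6,
                  ad_alt_offspring = 6, gq_offspring = 60,
                  dp_sire = 25, dp_dam = 25)
  expect_true(apply_dnm_filters(s12, toy_trio(depth = 20), rm)$pass)
  # with mean 24 the lower strict bound is 12, so DP = 12 fails
  expect_equal(apply_dnm_filters(s12, toy_trio(depth = 24), rm)$failed,
               "DEPTH")
  # allele balance strict at both ends (AB exactly 0.25 / 0.75 fail)
  expect_equal(apply_dnm_filters(
    toy_site(ad_ref_offspring = 30, ad_alt_offspring = 10), trio, rm)$failed,
    "ALLELE_BALANCE")
  expect_equal(apply_dnm_filters(
    toy_site(ad_ref_offspring = 10, ad_alt_offspring = 30), trio, rm)$failed,
    "ALLELE_BALANCE")
  expect_true(apply_dnm_filters(
    toy_site(ad_ref_offspring = 29, ad_alt_offspring = 11), trio, rm)$pass)
})

test_that("male-offspring X-unique sites use halved depths, inverted balance", {
  rm <- toy_region_map()
  trio <- toy_trio(offspring_sex = "M", depth = 24)
  # X-unique (outside the 68 kb PAR), DP 7 with mean 24: halved thresholds
  # are DP >= 6, DP > 6, DP < 24; AB must exceed 0.75
  x_site <- toy_site(contig = "chrX", pos = 2e5, gt_offspring = "1/1",
                     dp_offspring = 7, dp_sire = 7, dp_dam = 7,
                     ad_ref_offspring = 0, ad_alt_offspring = 7,
                     ad_ref_sire = 7, ad_ref_dam = 7, gq_offspring = 70)
  v <- apply_dnm_filters(x_site, trio, rm)
  expect_true(v$pass)
  # DP 6 violates the strict halved mean-relative bound (6 > 6 is false)
  expect_equal(apply_dnm_filters(
    dplyr::mutate(x_site, dp_offspring = 6, ad_alt_offspring = 6),
    trio, rm)$failed, "DEPTH")
  # balanced het evidence fails the male-X allele-balance rule
  expect_false(apply_dnm_filters(
    dplyr::mutate(x_site, ad_ref_offspring = 3, ad_alt_offspring = 4),
    trio, rm)$pass)
  # the same site in a female offspring follows the autosomal rules
  vf <- apply_dnm_filters(
    dplyr::mutate(x_site, gt_offspring = "0/1", dp_offspring = 24,
                  dp_sire = 24, dp_dam = 24, ad_ref_offspring = 12,
                  ad_alt_offspring = 12),
    toy_trio(offspring_sex = "F", depth = 24), rm)
  expect_true(vf$pass)
  # PAR sites are autosomal for all thresholds even in males
  par_site <- toy_site(contig = "chrX", pos = 100)
  expect_true(apply_dnm_filters(par_site, trio, rm)$pass)
})

test_that("missing evidence fails closed with a single code", {
  v <- apply_dnm_filters(toy_site(ad_alt_sire = NA), toy_trio(),
                         toy_region_map())
  expect_false(v$pass)
  expect_equal(v$failed, "MISSING_EVIDENCE")
})

test_that("verdicts report every violated rule regardless of order", {
  bad <- toy_site(gt_offspring = "1/1", gq_offspring = 10,
                  ad_alt_sire = 3, dp_dam = 5)
  v <- apply_dnm_filters(bad, toy_trio(), toy_region_map())
  codes <- strsplit(v$failed, ",")[[1]]
  expect_setequal(codes, c("GT_PATTERN", "PARENT_ALT_READS", "GQ", "DEPTH"))
})

test_that("read-level post-check counts incorrect reads and offspring balance", {
  mk <- function(off_alt, off_ref, off_other = 0, sire_nonref = 0,
                 dam_nonref = 0) {
    tibble::tibble(
      sample_role = c(rep("offspring", off_alt + off_ref + off_other),
                      rep("sire", 20), rep("dam", 20)),
      allele = c(rep("alt", off_alt), rep("ref", off_ref),
                 rep("other", off_other),
                 rep(c("alt", "ref"), c(sire_nonref, 20 - sire_nonref)),
                 rep(c("alt", "ref"), c(dam_nonref, 20 - dam_nonref)))
    )
  }
  expect_true(read_check(mk(12, 18))$pass)              # AB 0.40
  expect_false(read_check(mk(12, 18, sire_nonref = 2))$pass)
  expect_true(read_check(mk(12, 18, sire_nonref = 1))$pass)
  expect_false(read_check(mk(5, 25))$pass)              # AB 0.167
  # inclusive bounds at read level
  expect_true(read_check(mk(10, 30))$pass)              # AB exactly 0.25
  # offspring read carrying neither allele counts as incorrect
  expect_false(read_check(mk(12, 18, off_other = 2))$pass)
  # no offspring reads: fail closed
  expect_false(read_check(tibble::tibble(sample_role = "sire",
                                         allele = "ref"))$pass)
})

test_that("callable sizes scale by sex and region", {
  rm <- region_map(contigs = data.frame(name = c("chr1", "chrX"),
                                        length = c(3000, 2000)),
                   par = data.frame(contig = "chrX", start = 0, end = 500))
  mk_sites <- function(contig, pos) {
    tibble::tibble(contig = contig, pos = pos, gt_sire = "0/0",
                   gt_dam = "0/0", dp_offspring = 40, dp_sire = 40,
                   dp_dam = 40)
  }
  x_sites <- mk_sites("chrX", 501:1500) # 1000 X-unique sites
  prof_m <- compute_callable_profile(x_sites, toy_trio(offspring_sex = "M"), rm)
  expect_equal(prof_m$callable_size[prof_m$region == "X_UNIQUE"], 1000)
  prof_f <- compute_callable_profile(x_sites, toy_trio(offspring_sex = "F"), rm)
  expect_equal(prof_f$callable_size[prof_f$region == "X_UNIQUE"], 2000)

  a_sites <- mk_sites("chr1", 1:1000)
  prof_a <- compute_callable_profile(a_sites, toy_trio(offspring_sex = "M"), rm)
  expect_equal(prof_a$callable_size[prof_a$region == "AUTOSOME"], 2000)
  expect_equal(prof_a$callable_fraction[1], 1.0)

  # depth failures and het parents reduce the callable count
  mixed <- dplyr::mutate(a_sites,
                         gt_sire = ifelse(pos <= 100, "0/1", "0/0"),
                         dp_dam = ifelse(pos > 900, 5, 40))
  prof_mix <- compute_callable_profile(mixed, toy_trio(), rm)
  expect_equal(prof_mix$callable_sites[prof_mix$region == "AUTOSOME"], 800)

  expect_error(compute_callable_profile(mk_sites("chr9", 1), toy_trio(), rm),
               "absent")
})

test_that("filters recover simulation truth exactly on noiseless evidence", {
  co <- small_cohort()
  ids <- co$trios$trio_id[1:4]
  verdicts <- purrr::map(ids, function(tid) {
    truth <- trio_truth_sites(co, tid, n_negative = 60)
    ev <- simulate_site_evidence(truth, noise = FALSE, depth_mean = 43)
    v <- apply_dnm_filters(ev, co$trios, co$region_map)
    dplyr::mutate(v, is_dnm = truth$is_dnm)
  }) |> purrr::list_rbind()
  expect_equal(mean(verdicts$pass[verdicts$is_dnm]), 1.0)
  expect_equal(sum(verdicts$pass[!verdicts$is_dnm]), 0)
})

test_that("low-depth trios are excluded cohort-wide", {
  trios <- dplyr::bind_rows(toy_trio("T1"), toy_trio("T2", depth = 20))
  expect_message(kept <- exclude_low_depth_trios(trios), "1 trio")
  expect_equal(kept$trio_id, "T1")
})

test_that("mendelian QC reports the explainable fraction", {
  sites <- dplyr::bind_rows(
    toy_site(gt_offspring = "0/1", gt_sire = "0/1"),
    toy_site(gt_offspring = "0/1", gt_dam = "0/1"),
    toy_site(gt_offspring = "0/1"),                      # true DNM pattern
    toy_site(gt_offspring = "0/0")
  )
  qc <- mendelian_qc(sites)
  expect_equal(qc$n_nonref, 3)
  expect_equal(qc$fraction, 2 / 3)
})
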