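# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-scale default cohort (study conditions)
full_cohort <- function() {
  cached("full_cohort", simulate_cohort(simulation_config(seed = 101)))
}

# small, fast cohort on a scaled-down genome
small_cohort <- function() {
  cached("small_cohort", {
    simulate_cohort(simulation_config(n_trios = 60, seed = 202),
                    region_map = default_region_map(scale = 0.05))
  })
}

# minimal two-contig region map for hand-built sites
toy_region_map <- function() {
  region_map(
    contigs = data.frame(name = c("chr1", "chrX"),
                         length = c(1e6, 5e5)),
    par = data.frame(contig = "chrX", start = 0, end = 68000),
    cgi = data.frame(contig = "chr1", start = c(100, 5000),
                     end = c(200, 5400)),
    hmr_cgi = data.frame(contig = "chr1", start = 100, end = 150)
  )
}

# one hand-built candidate site with sensible defaults, overridable
toy_site <- function(...) {
  site <- tibble::tibble(
    site_id = "s1", trio_id = "T1", contig = "chr1", pos = 1000,
    ref = "C", alt = "T", context3 = "ACA", filter = "PASS",
    gt_offspring = "0/1", gt_sire = "0/0", gt_dam = "0/0",
    gq_offspring = 45, gq_sire = 60, gq_dam = 60,
    dp_offspring = 40, dp_sire = 40, dp_dam = 40,
    ad_ref_offspring = 20, ad_alt_offspring = 20,
    ad_ref_sire = 40, ad_alt_sire = 0,
    ad_ref_dam = 39, ad_alt_dam = 1
  )
  over <- list(...)
  for (nm in names(over)) site[[nm]] <- over[[nm]]
  site
}

toy_trio <- function(trio_id = "T1", offspring_sex = "F", depth = 43.3) {
  tibble::tibble(
    trio_id = trio_id, offspring_id = paste0(trio_id, "_o"),
    sire_id = paste0(trio_id, "_s"), dam_id = paste0(trio_id, "_d"),
    offspring_sex = offspring_sex, paternal_age_years = 4.5,
    maternal_age_years = 4, breed = "beagle", size_class = "small",
    depth_offspring = depth, depth_sire = depth, depth_dam = depth,
    litter_id = paste0(trio_id, "_L"), pedigree_id = paste0(trio_id, "_P")
  )
}

# independent two-sided Fisher p oracle: hypergeometric enumeration
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent two-sided binomial p oracle: pmf enumeration
binom_p_oracle <- function(x, n, p) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}
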