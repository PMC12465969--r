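# Mutation-rate estimation: pooled and bootstrap rates, composition-corrected
# per-class rates, X/autosome and PAR expectations, and the
# recombination-mutagenesis accounting for hypomethylated CpG islands.

#' Pooled per-generation mutation rate
#'
#' The rate per base pair per generation is the number of DNMs divided by the
#' summed callable size (the callable size already carries the x2 diploid /
#' x1 hemizygous scaling, so no further factor is applied here).
#'
#' @param n_dnm Total DNM count.
#' @param callable_size_sum Summed callable size (bp), > 0.
#' @return Rate in mutations per bp per generation.
#' @examples
#' mutation_rate(21, 4.3e9)
#' @export
mutation_rate <- function(n_dnm, callable_size_sum) {
  if (any(callable_size_sum <= 0)) abort("callable_size_sum must be > 0")
  n_dnm / callable_size_sum
}

#' Bootstrap a pooled mutation rate over trios
#'
#' Resamples trios with replacement; each round's rate is the ratio of summed
#' DNM counts to summed callable sizes over the resampled trios (pooled
#' ratio-of-sums, matching the cohort estimator). The 95% CI is the 2.5%/97.5%
#' percentile of the bootstrap distribution.
#'
#' @param data Tibble with one row per trio.
#' @param n_boot Bootstrap rounds (default 10000; < 100 warns).
#' @param seed Integer seed (mandatory, for reproducibility).
#' @param dnm_col,size_col Column names of per-trio DNM counts and callable
#'   sizes.
#' @param region Optional label stored on the estimate.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble of class `rate_estimate`: `region`, `rate`,
#'   `ci_low`, `ci_high`, `n_trios`, `n_boot`, `seed`.
#' @export
bootstrap_rate <- function(data, n_boot = 10000, seed, dnm_col = "n_dnm",
                           size_col = "callable_size", region = NA_character_,
                           conf = 0.95) {
  if (missing(seed)) abort("seed is required")
  if (n_boot < 100) warn("n_boot < 100: percentile CI will be unstable")
  if (nrow(data) < 2) abort("need >= 2 trios to bootstrap")
  y <- data[[dnm_col]]
  s <- data[[size_col]]
  if (any(s <= 0)) abort("callable sizes must be > 0")
  set.seed(seed)
  n <- length(y)
  rates <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    sum(y[idx]) / sum(s[idx])
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(quantile(rates, c(a, 1 - a), names = FALSE))
  out <- tibble(region = region, rate = sum(y) / sum(s),
                ci_low = ci[1], ci_high = ci[2],
                n_trios = n, n_boot = n_boot, seed = seed)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Regional bootstrap rates
#'
#' Runs [bootstrap_rate()] for each region category, pairing per-trio DNM
#' counts in the region with the per-trio regional callable sizes.
#'
#' @param dnms DNM tibble with `trio_id`, `primary`, `in_cgi`, `in_hmr_cgi`.
#' @param callable Per-trio x region callable tibble (`trio_id`, `region`,
#'   `callable_size`).
#' @param regions Region labels to estimate (default all six).
#' @inheritParams bootstrap_rate
#' @return `rate_estimate` tibble, one row per region.
#' @export
regional_rates <- function(dnms, callable, regions = REGION_LABELS,
                           n_boot = 10000, seed) {
  if (missing(seed)) abort("seed is required")
  per_region <- lapply(seq_along(regions), function(i) {
    reg <- regions[i]
    in_reg <- switch(reg,
      CGI = dnms$in_cgi, HMR_CGI = dnms$in_hmr_cgi,
      NONHMR_CGI = dnms$in_cgi & !dnms$in_hmr_cgi,
      dnms$primary == reg)
    counts <- dnms[in_reg, ] %>% count(.data$trio_id, name = "n_dnm")
    d <- callable %>%
      filter(.data$region == reg) %>%
      left_join(counts, by = "trio_id") %>%
      mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L))
    bootstrap_rate(d, n_boot = n_boot, seed = seed + i, region = reg)
  })
  bind_rows(per_region)
}

# mutational opportunity fraction for a class given a composition row
opportunity_fraction <- function(mutation_class, comp_row) {
  case_when(
    mutation_class == "CpG>TpG" ~ comp_row$frac_cpg,
    substr(mutation_class, 1, 1) == "C" ~ comp_row$frac_cg,
    TRUE ~ comp_row$frac_at
  )
}

#' Composition-corrected per-class mutation rates
#'
#' For each region x mutation class, the rate denominator is the callable
#' size scaled by the fraction of sites offering that class's mutational
#' opportunity: A/T sites for T>* classes, non-CpG C/G sites for C>* classes,
#' and CpG-dinucleotide sites for CpG>TpG. Bootstrap as in
#' [bootstrap_rate()]; the composition scaling is applied inside every round.
#'
#' @param dnms DNM tibble with `trio_id`, `mutation_class` and region flags.
#' @param callable Per-trio x region callable tibble.
#' @param composition A [composition_table()].
#' @param regions Regions to estimate.
#' @inheritParams bootstrap_rate
#' @return `rate_estimate` tibble with one row per region x class; classes
#'   with zero opportunity and zero observed DNMs are reported as absent.
#' @export
composition_corrected_rates <- function(dnms, callable, composition,
                                        regions = unique(composition$region),
                                        n_boot = 10000, seed) {
  if (missing(seed)) abort("seed is required")
  out <- list()
  k <- 0
  for (reg in regions) {
    comp_row <- composition[composition$region == reg, ]
    if (nrow(comp_row) != 1) abort(paste("no composition row for", reg))
    in_reg <- switch(reg,
      CGI = dnms$in_cgi, HMR_CGI = dnms$in_hmr_cgi,
      NONHMR_CGI = dnms$in_cgi & !dnms$in_hmr_cgi,
      dnms$primary == reg)
    reg_dnms <- dnms[in_reg, ]
    cal <- filter(callable, .data$region == reg)
    for (cls in MUTATION_CLASSES) {
      k <- k + 1
      frac <- opportunity_fraction(cls, comp_row)
      n_cls <- sum(reg_dnms$mutation_class == cls)
      if (frac == 0) {
        if (n_cls > 0) {
          abort(sprintf("class %s observed in %s but opportunity is zero",
                        cls, reg))
        }
        next
      }
      counts <- reg_dnms %>%
        filter(.data$mutation_class == cls) %>%
        count(.data$trio_id, name = "n_dnm")
      d <- cal %>%
        left_join(counts, by = "trio_id") %>%
        mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L),
               callable_size = .data$callable_size * frac)
      est <- bootstrap_rate(d, n_boot = n_boot, seed = seed + k, region = reg)
      est$mutation_class <- cls
      out[[length(out) + 1]] <- est
    }
  }
  bind_rows(out)
}

#' Expected X-to-autosome mutation rate ratio
#'
#' Under a male-to-female mutation ratio `alpha`, the X chromosome (spending
#' one third of its time in males, two thirds in females) is expected to
#' mutate at `2(2 + alpha) / (3(1 + alpha))` times the autosomal rate. The
#' expression decreases monotonically from 4/3 (alpha -> 0) through 1
#' (alpha = 1) to 2/3 (alpha -> Inf).
#'
#' @param alpha Male-to-female mutation ratio, > 0.
#' @return Expected X/autosome rate ratio.
#' @examples
#' expected_x_autosome_ratio(3.01) # ~0.83
#' @export
expected_x_autosome_ratio <- function(alpha) {
  if (any(alpha <= 0)) abort("alpha must be > 0")
  2 * (2 + alpha) / (3 * (1 + alpha))
}

#' Paternal fraction and male-to-female ratio from phased counts
#'
#' @param n_paternal,n_maternal Phased DNM counts (>= 0, sum > 0).
#' @return One-row tibble with `paternal_fraction`, `alpha`, and
#'   `alpha_infinite` (flag set when no maternal DNMs were observed).
#' @examples
#' phased_sex_ratio(1941, 645) # paternal fraction 0.7505, alpha ~3.01
#' @export
phased_sex_ratio <- function(n_paternal, n_maternal) {
  stopifnot(n_paternal >= 0, n_maternal >= 0)
  if (n_paternal + n_maternal == 0) abort("no phased DNMs")
  tibble(paternal_fraction = n_paternal / (n_paternal + n_maternal),
         alpha = if (n_maternal == 0) Inf else n_paternal / n_maternal,
         alpha_infinite = n_maternal == 0)
}

#' PAR recombination rates implied by the obligate male crossover
#'
#' One obligate crossover per male meiosis confined to the pseudoautosomal
#' region implies a male recombination rate of `map_length / par_length`
#' (100 cM over the PAR span); with the female rate taken at the genome-wide
#' scale, the sex-averaged rate is the mean of the two.
#'
#' @param par_length_mb PAR length in Mb, > 0.
#' @param obligate_map_length_cM Male map length of the PAR (default 100 cM).
#' @param female_rate_cM_per_Mb Female rate (default 1 cM/Mb).
#' @return One-row tibble with `male`, `female`, `sex_averaged` (cM/Mb).
#' @examples
#' par_recombination_rates(6.8) # male 14.7, sex-averaged 7.85
#' @export
par_recombination_rates <- function(par_length_mb,
                                    obligate_map_length_cM = 100,
                                    female_rate_cM_per_Mb = 1) {
  if (par_length_mb <= 0) abort("par_length_mb must be > 0")
  male <- obligate_map_length_cM / par_length_mb
  tibble(male = male, female = female_rate_cM_per_Mb,
         sex_averaged = (male + female_rate_cM_per_Mb) / 2)
}

#' Mutagenic-effect accounting for recombination in hypomethylated CGIs
#'
#' Given the observed count of DNMs in hypomethylated CpG islands and the
#' composition-corrected fold enrichment, the expected count without
#' recombination is `observed / fold`; the excess, the per-trio excess, and
#' the excess as a fraction of all mutations quantify the mutagenic effect of
#' recombination. Significance is a one-sided Poisson tail probability of the
#' observed count at the expected mean.
#'
#' @param observed_in_hmr Observed DNM count in HMR-CGIs.
#' @param corrected_fold Composition-corrected fold enrichment (> 0; a fold
#'   below 1 warns but the arithmetic is still valid).
#' @param n_trios Number of trios contributing.
#' @param mean_dnm_per_trio Cohort mean DNMs per trio.
#' @return One-row tibble with `expected_count`, `excess_total`,
#'   `excess_per_trio`, `fraction_of_all_mutations`, `enrichment_p`.
#' @examples
#' recombination_mutagenesis(117, 2.34, 389, 21.31)
#' @export
recombination_mutagenesis <- function(observed_in_hmr, corrected_fold,
                                      n_trios, mean_dnm_per_trio) {
  if (corrected_fold <= 0 || n_trios <= 0) {
    abort("fold and n_trios must be > 0")
  }
  if (corrected_fold < 1) warn("fold < 1: region is depleted, not enriched")
  expected <- observed_in_hmr / corrected_fold
  excess <- observed_in_hmr - expected
  per_trio <- excess / n_trios
  tibble(
    expected_count = expected,
    excess_total = excess,
    excess_per_trio = per_trio,
    fraction_of_all_mutations = per_trio / mean_dnm_per_trio,
    enrichment_p = ppois(observed_in_hmr - 1, expected, lower.tail = FALSE)
  )
}
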