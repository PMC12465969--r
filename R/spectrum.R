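# Mutational-spectrum tables, cross-cohort class tests, and the
# paternal-age trend in class fractions.

#' Tabulate a seven-class mutational spectrum
#'
#' @param dnms DNM tibble with a `mutation_class` column.
#' @param cohort Optional cohort label.
#' @param region Optional restriction: one of the region labels (e.g.
#'   `"CGI"`), applied via the DNM region flags.
#' @return Tibble of class `spectrum_table` with `mutation_class`, `count`,
#'   `fraction` (all 7 classes present; fractions sum to 1 when any DNMs).
#' @export
spectrum_table <- function(dnms, cohort = NA_character_, region = NULL) {
  if (!is.null(region)) {
    in_reg <- switch(region,
      CGI = dnms$in_cgi, HMR_CGI = dnms$in_hmr_cgi,
      NONHMR_CGI = dnms$in_cgi & !dnms$in_hmr_cgi,
      dnms$primary == region)
    dnms <- dnms[in_reg, ]
  }
  counts <- table(factor(dnms$mutation_class, levels = MUTATION_CLASSES))
  total <- sum(counts)
  out <- tibble(
    cohort = cohort,
    mutation_class = MUTATION_CLASSES,
    count = as.integer(counts),
    fraction = if (total > 0) as.integer(counts) / total else 0
  )
  class(out) <- c("spectrum_table", class(out))
  out
}

#' Cross-cohort mutational-class tests
#'
#' For each class, builds the 2x2 table (in-class vs not, cohort A vs B) and
#' applies a two-sided Fisher's exact test. Significance is assessed at the
#' Bonferroni-corrected threshold `0.05 / n_classes` (default 8 classes: the
#' seven spectrum classes plus, when supplied, a CGI-membership class).
#'
#' @param counts_a,counts_b Named count vectors per class (same names).
#' @param n_tests Number of tests for the Bonferroni threshold (default the
#'   number of shared classes, conventionally 8).
#' @return Tibble per class: `odds_ratio`, `p`, `significant` (at
#'   `p < 0.05 / n_tests`), `or_defined`.
#' @export
cross_species_class_test <- function(counts_a, counts_b,
                                     n_tests = length(counts_a)) {
  stopifnot(setequal(names(counts_a), names(counts_b)),
            sum(counts_a) > 0, sum(counts_b) > 0)
  counts_b <- counts_b[names(counts_a)]
  thr <- 0.05 / n_tests
  rows <- lapply(names(counts_a), function(cls) {
    a_in <- counts_a[[cls]]
    b_in <- counts_b[[cls]]
    a_out <- sum(counts_a) - a_in
    b_out <- sum(counts_b) - b_in
    if (a_in + b_in == 0) {
      return(tibble(mutation_class = cls, odds_ratio = NA_real_, p = 1,
                    significant = FALSE, or_defined = FALSE))
    }
    ft <- fisher.test(matrix(c(a_in, a_out, b_in, b_out), 2))
    tibble(mutation_class = cls, odds_ratio = unname(ft$estimate),
           p = ft$p.value, significant = ft$p.value < thr, or_defined = TRUE)
  })
  mutate(bind_rows(rows), bonferroni_threshold = thr)
}

#' Paternal-age trend of a mutational-class fraction
#'
#' Regresses the per-paternal-age-bin fraction of DNMs in `class` on paternal
#' age by weighted least squares, with the total DNM count per bin as the
#' weight. Bins with zero totals are dropped with a warning.
#'
#' @param dnms DNM tibble with `mutation_class` and `paternal_age_years`.
#' @param class Mutation class of interest.
#' @param digits Age-binning precision in years (default 0: whole years).
#' @return One-row tibble with `slope` (fraction/year), `p`, `n_bins`.
#' @export
paternal_age_class_trend <- function(dnms, class, digits = 0) {
  bins <- dnms %>%
    mutate(age_bin = round(.data$paternal_age_years, digits)) %>%
    group_by(.data$age_bin) %>%
    summarise(total = n(),
              frac = mean(.data$mutation_class == .env$class),
              .groups = "drop")
  empty <- bins$total == 0
  if (any(empty)) {
    warn("dropping age bins with zero totals")
    bins <- bins[!empty, ]
  }
  if (nrow(bins) < 2) abort("need >= 2 age bins with observations")
  f <- lm(frac ~ age_bin, data = bins, weights = bins$total)
  co <- summary(f)$coefficients
  tibble(slope = co["age_bin", "Estimate"],
         p = if (nrow(bins) > 2) co["age_bin", "Pr(>|t|)"] else NA_real_,
         n_bins = nrow(bins))
}

#' Binomial test of parental-phase balance
#'
#' Two-sided exact binomial test of the paternal count against an expected
#' paternal fraction (default 0.5, the early-embryonic null under which
#' mutations accrue equally in both sexes).
#'
#' @param n_maternal,n_paternal Phased counts (>= 0, total > 0).
#' @param expected_paternal_fraction Null paternal fraction.
#' @return Two-sided exact p-value.
#' @export
phase_balance_test <- function(n_maternal, n_paternal,
                               expected_paternal_fraction = 0.5) {
  stopifnot(n_maternal >= 0, n_paternal >= 0)
  if (n_maternal + n_paternal == 0) abort("no phased mutations")
  binom.test(n_paternal, n_paternal + n_maternal,
             p = expected_paternal_fraction)$p.value
}

#' Plot a mutational spectrum
#'
#' @param spectra One or more [spectrum_table()] rows (bind rows of several
#'   cohorts to compare).
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectra) {
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = factor(.data$mutation_class,
                                          levels = MUTATION_CLASSES),
                               y = .data$fraction, fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of DNMs", fill = NULL) +
    ggplot2::theme_minimal()
}
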