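# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: litter-structured pedigrees, phased per-parent
# DNM counts that rise linearly with parental age on the rate scale, a
# seven-class mutational spectrum, enrichment of mutations in hypomethylated
# CpG islands, and early-embryonic mutations duplicated across littermates.

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions the package targets: a 390-trio cohort
#' with a haploid autosomal callable genome of 2.18 Gb, paternal/maternal age
#' effects of 3.25e-10 and 9.64e-11 mutations/bp/year, intercepts chosen so
#' the expected cohort mean is ~21.3 DNMs per trio with 75.05% of mutations
#' paternal at the mean parental ages, a 2.34-fold mutation-rate enrichment in
#' hypomethylated CpG islands, a 0.45% sibling-shared (early-embryonic)
#' mutation fraction, a 31.11% phasing rate, and 43.3x mean sequencing depth.
#'
#' @param n_trios Number of trios.
#' @param b1p,b1m Paternal/maternal age effect (mutations/bp/year, haploid).
#' @param b0p,b0m Regression intercepts (mutations/bp at age 0 on the model
#'   scale; not a biological "birth" rate).
#' @param g_haploid Haploid autosomal callable size (bp) used as per-parent
#'   exposure.
#' @param spectrum Named probabilities over the 7 mutation classes (sum 1).
#' @param hmr_fold Mutation-rate fold enrichment in HMR-CGI regions (>= 1).
#' @param shared_fraction Target pairwise sibling-shared mutation fraction.
#' @param phased_fraction Probability a DNM's parental origin is resolved by
#'   read-backed phasing.
#' @param mean_litter Mean litter size (litters are 1 + Poisson(mean - 1)).
#' @param age_p_mean,age_p_sd,age_m_mean,age_m_sd Gamma age distributions
#'   (years) for sire/dam age at conception, truncated at 1 year.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); `depth_dispersion = Inf` gives constant depth.
#' @param callable_fraction_mean,callable_fraction_sd Per-trio callable genome
#'   fraction model.
#' @param size_class_probs Probabilities of small/intermediate/large breeds.
#' @param b1p_by_class Optional named vector of class-specific paternal
#'   slopes overriding `b1p` (names small/intermediate/large).
#' @param seed Integer seed recorded in every output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_trios = 390,
    b1p = 3.25e-10, b1m = 9.64e-11,
    b0p = 5.88e-9, b0m = 2.06e-9,
    g_haploid = 2.18e9,
    spectrum = c("C>A" = 0.08, "C>G" = 0.09, "C>T" = 0.25, "CpG>TpG" = 0.24,
                 "T>A" = 0.06, "T>C" = 0.18, "T>G" = 0.10),
    hmr_fold = 2.34,
    shared_fraction = 0.0045,
    phased_fraction = 0.3111,
    mean_litter = 2.4,
    age_p_mean = 4.5, age_p_sd = 2.5,
    age_m_mean = 4.0, age_m_sd = 2.0,
    depth_mean = 43.3, depth_dispersion = 40,
    callable_fraction_mean = 0.9652, callable_fraction_sd = 5e-4,
    size_class_probs = c(small = 0.4, intermediate = 0.3, large = 0.3),
    b1p_by_class = NULL,
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_trios >= 1, g_haploid > 0, depth_mean >= 1)
  if (any(c(b1p, b1m, b0p, b0m) < 0)) abort("rates must be >= 0")
  if (!setequal(names(spectrum), MUTATION_CLASSES)) {
    abort("spectrum must be named with the 7 mutation classes")
  }
  if (abs(sum(spectrum) - 1) > 1e-12) abort("spectrum must sum to 1")
  if (hmr_fold < 1) abort("hmr_fold must be >= 1")
  if (shared_fraction < 0 || shared_fraction >= 1) {
    abort("shared_fraction must be in [0, 1)")
  }
  # the implied private Poisson means must stay nonnegative
  f_early <- 2 * shared_fraction / (1 + shared_fraction)
  mu_min <- min(b0p, b0m) * g_haploid
  if (f_early > 0 && mu_min < 0) abort("negative implied Poisson mean")
  class(cfg) <- "simulation_config"
  cfg
}

#' Synthetic dog-like genome region map
#'
#' Four autosomes totalling 2.28 Gb plus an X chromosome of 124 Mb with a
#' 6.8 Mb PAR; hypomethylated CpG islands span 30.68 Mb and methylated
#' (non-HMR) CpG islands 36.82 Mb of the autosomes, laid out as regularly
#' spaced islands. `scale` shrinks every contig and interval proportionally
#' for fast tests.
#'
#' @param scale Multiplicative size factor in (0, 1].
#' @return A [region_map()].
#' @export
default_region_map <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  auto_len <- round(570e6 * scale)
  x_len <- round(124e6 * scale)
  par_len <- round(6.8e6 * scale)
  contigs <- tibble(
    name = c(paste0("chr", 1:4), "chrX"),
    length = c(rep(auto_len, 4), x_len)
  )
  # regularly spaced islands: per autosome, HMR islands then non-HMR islands
  n_isl <- 500
  isl_hmr <- round(30.68e6 * scale / (4 * n_isl))
  isl_non <- round(36.82e6 * scale / (4 * n_isl))
  pitch <- floor(auto_len / n_isl)
  starts <- (seq_len(n_isl) - 1) * pitch
  cgi <- bind_rows(lapply(paste0("chr", 1:4), function(ctg) {
    tibble(contig = ctg,
           start = c(starts, starts + isl_hmr + 1000),
           end = c(starts + isl_hmr, starts + isl_hmr + 1000 + isl_non))
  }))
  hmr <- filter(cgi, .data$end - .data$start == isl_hmr &
                  (.data$start %% pitch) == 0)
  region_map(contigs,
             par = tibble(contig = "chrX", start = 0, end = par_len),
             cgi = cgi, hmr_cgi = hmr, x_contig = "chrX")
}

# sample n positions uniformly within a merged interval set (1-based out)
sample_positions <- function(iv, n) {
  if (n == 0) return(tibble(contig = character(), pos = numeric()))
  w <- iv$end - iv$start
  idx <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  tibble(contig = iv$contig[idx],
         pos = floor(iv$start[idx] + runif(n) * w[idx]) + 1)
}

# draw ref/alt/context consistent with a mutation class, random strand
draw_alleles <- function(classes) {
  n <- length(classes)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyr_ref <- if_else(substr(classes, 1, 1) == "C", "C", "T")
  pyr_alt <- dplyr::case_match(classes,
    "C>A" ~ "A", "C>G" ~ "G", "C>T" ~ "T", "CpG>TpG" ~ "T",
    "T>A" ~ "A", "T>C" ~ "C", "T>G" ~ "G")
  left <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  right <- character(n)
  is_cpg <- classes == "CpG>TpG"
  is_ct <- classes == "C>T"
  right[is_cpg] <- "G"
  right[is_ct] <- sample(c("A", "C", "T"), sum(is_ct), replace = TRUE)
  other <- !is_cpg & !is_ct
  right[other] <- sample(c("A", "C", "G", "T"), sum(other), replace = TRUE)
  ctx <- paste0(left, pyr_ref, right)
  flip <- runif(n) < 0.5
  revcomp <- function(s) {
    vapply(strsplit(s, ""), function(b) paste(rev(unname(comp[b])), collapse = ""), "")
  }
  tibble(
    ref = if_else(flip, unname(comp[pyr_ref]), pyr_ref),
    alt = if_else(flip, unname(comp[pyr_alt]), pyr_alt),
    context3 = if_else(flip, revcomp(ctx), ctx)
  )
}

#' Simulate a trio cohort with ground-truth de novo mutations
#'
#' Generates a litter-structured pedigree, per-parent phased mutation counts
#' `Poisson((b0 + b1 * age) * g_haploid)`, mutation positions placed uniformly
#' across the autosomes except for an `hmr_fold` oversampling of HMR-CGI
#' islands, mutation classes from the configured spectrum with
#' strand-consistent alleles and contexts, early-embryonic mutations
#' duplicated across littermates (parent of origin balanced 1:1), read-backed
#' phasing labels, and per-trio callable profiles.
#'
#' @param config A [simulation_config()].
#' @param region_map Optional [region_map()]; defaults to
#'   [default_region_map()] at full scale.
#' @return A list of class `dnm_cohort` with elements `trios`, `dnms`,
#'   `callable` (per trio x region callable sites/sizes), `region_map`,
#'   `config` and `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), region_map = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(region_map)) region_map <- default_region_map()
  set.seed(config$seed)

  # -- pedigree: litters of full siblings, one breed/size class per litter --
  sizes <- character(0); litter_sizes <- integer(0)
  while (sum(litter_sizes) < config$n_trios) {
    litter_sizes <- c(litter_sizes, 1L + rpois(1, config$mean_litter - 1))
  }
  classes <- names(config$size_class_probs)
  litters <- tibble(
    litter_id = sprintf("L%03d", seq_along(litter_sizes)),
    n_off = litter_sizes,
    size_class = sample(classes, length(litter_sizes), replace = TRUE,
                        prob = config$size_class_probs),
    paternal_age_years = pmax(1, rgamma(length(litter_sizes),
      shape = (config$age_p_mean / config$age_p_sd)^2,
      rate = config$age_p_mean / config$age_p_sd^2)),
    maternal_age_years = pmax(1, rgamma(length(litter_sizes),
      shape = (config$age_m_mean / config$age_m_sd)^2,
      rate = config$age_m_mean / config$age_m_sd^2))
  )
  litters$breed <- paste0("breed_", match(litters$size_class, classes),
                          "_", (seq_len(nrow(litters)) %% 12) + 1)
  trios <- litters %>%
    tidyr::uncount(.data$n_off, .id = "sib") %>%
    slice(seq_len(config$n_trios)) %>%
    mutate(
      trio_id = sprintf("T%04d", row_number()),
      offspring_id = paste0(.data$litter_id, "_o", .data$sib),
      sire_id = paste0(.data$litter_id, "_sire"),
      dam_id = paste0(.data$litter_id, "_dam"),
      offspring_sex = sample(c("M", "F"), n(), replace = TRUE),
      pedigree_id = .data$litter_id,
      depth_offspring = depth_draw(n(), config),
      depth_sire = depth_draw(n(), config),
      depth_dam = depth_draw(n(), config)
    ) %>%
    select(all_of(PED_COLUMNS))

  # -- per-trio true phased counts (identity-scale linear in age) ----------
  G <- config$g_haploid
  b1p <- config$b1p
  if (!is.null(config$b1p_by_class)) {
    b1p <- unname(config$b1p_by_class[trios_size(trios)])
  }
  mu_p <- (config$b0p + b1p * trios$paternal_age_years) * G
  mu_m <- (config$b0m + config$b1m * trios$maternal_age_years) * G
  if (any(mu_p < 0 | mu_m < 0)) abort("negative implied Poisson mean")

  f_early <- 2 * config$shared_fraction / (1 + config$shared_fraction)
  mu_tot <- mu_p + mu_m
  mu_early <- f_early * mu_tot # shared across the litter, drawn once
  mu_p_priv <- pmax(0, mu_p - mu_early / 2)
  mu_m_priv <- pmax(0, mu_m - mu_early / 2)

  n_p <- rpois(nrow(trios), mu_p_priv)
  n_m <- rpois(nrow(trios), mu_m_priv)

  # litter-level early mutations, parent of origin balanced 1:1
  first_sib <- !duplicated(trios$litter_id)
  n_early_litter <- setNames(rpois(sum(first_sib), mu_early[first_sib]),
                             trios$litter_id[first_sib])

  auto_iv <- merge_intervals(
    region_map$intervals[region_map$intervals$label == "AUTOSOME", ])
  hmr_iv <- region_map$intervals[region_map$intervals$label == "HMR_CGI", ]
  rest_iv <- interval_setdiff(auto_iv, hmr_iv)
  span_hmr <- interval_total_span(hmr_iv)
  span_rest <- interval_total_span(rest_iv)

  place_dnms <- function(k) {
    if (k == 0) {
      return(tibble(contig = character(), pos = numeric()))
    }
    in_hmr <- runif(k) < (config$hmr_fold * span_hmr) /
      (config$hmr_fold * span_hmr + span_rest)
    bind_rows(sample_positions(hmr_iv, sum(in_hmr)),
              sample_positions(rest_iv, sum(!in_hmr)))
  }

  make_rows <- function(trio_ids, phase_true, early, group) {
    k <- length(trio_ids)
    if (k == 0) return(NULL)
    pos <- place_dnms(k)
    cls <- sample(names(config$spectrum), k, replace = TRUE,
                  prob = config$spectrum)
    al <- draw_alleles(cls)
    tibble(trio_id = trio_ids, contig = pos$contig, pos = pos$pos,
           ref = al$ref, alt = al$alt, context3 = al$context3,
           mutation_class = cls, phase_true = phase_true, early = early,
           shared_group_id = group)
  }

  private <- bind_rows(
    make_rows(rep(trios$trio_id, n_p), "paternal", FALSE, NA_character_),
    make_rows(rep(trios$trio_id, n_m), "maternal", FALSE, NA_character_)
  )

  early_rows <- purrr::imap(n_early_litter[n_early_litter > 0], function(k, lid) {
    proto <- make_rows(rep("proto", k),
                       sample(c("paternal", "maternal"), k, replace = TRUE),
                       TRUE, paste0(lid, "_e", seq_len(k)))
    members <- trios$trio_id[trios$litter_id == lid]
    bind_rows(lapply(members, function(tid) mutate(proto, trio_id = tid)))
  }) %>% list_rbind()

  dnms <- bind_rows(private, early_rows)
  if (nrow(dnms) > 0) {
    reg <- region_lookup(region_map, dnms$contig, dnms$pos, one_based = TRUE)
    phased <- runif(nrow(dnms)) < config$phased_fraction
    dnms <- dnms %>%
      mutate(primary = reg$primary, in_cgi = reg$in_cgi,
             in_hmr_cgi = reg$in_hmr_cgi,
             phase = if_else(phased, .data$phase_true, "unphased")) %>%
      # shared early mutations must be flagged as shared only when the litter
      # actually has >= 2 sequenced siblings
      group_by(.data$shared_group_id) %>%
      mutate(shared_group_id = if_else(
        !is.na(.data$shared_group_id) & n() >= 2, .data$shared_group_id,
        NA_character_)) %>%
      ungroup() %>%
      arrange(.data$trio_id, .data$contig, .data$pos)
  }

  callable <- simulate_callable(trios, region_map, config)

  structure(list(trios = trios, dnms = dnms, callable = callable,
                 region_map = region_map, config = config,
                 seed = config$seed),
            class = "dnm_cohort")
}

trios_size <- function(trios) trios$size_class

depth_draw <- function(n, config) {
  if (is.infinite(config$depth_dispersion)) {
    return(rep(config$depth_mean, n))
  }
  pmax(1, rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion))
}

# per-trio callable sites per region, scaled to callable sizes. Regional
# spans are anchored to the configured haploid callable size so that the
# exposures downstream models use are consistent with the Poisson means the
# counts were drawn from, whatever the region map's physical scale.
simulate_callable <- function(trios, region_map, config) {
  spans <- region_map$intervals %>%
    group_by(region = .data$label) %>%
    summarise(span = sum(.data$end - .data$start), .groups = "drop")
  span_auto <- spans$span[spans$region == "AUTOSOME"]
  anchor <- config$g_haploid / config$callable_fraction_mean / span_auto
  spans$span <- spans$span * anchor
  frac <- pmin(1, pmax(0, rnorm(nrow(trios), config$callable_fraction_mean,
                                config$callable_fraction_sd)))
  tidyr::crossing(trio_id = trios$trio_id, region = spans$region) %>%
    left_join(spans, by = "region") %>%
    left_join(tibble(trio_id = trios$trio_id,
                     offspring_sex = trios$offspring_sex,
                     callable_fraction = frac), by = "trio_id") %>%
    mutate(callable_sites = round(.data$span * .data$callable_fraction),
           callable_size = .data$callable_sites *
             if_else(.data$region == "X_UNIQUE" & .data$offspring_sex == "M",
                     1, 2)) %>%
    select("trio_id", "region", "callable_sites", "callable_size",
           "callable_fraction")
}

#' @export
print.dnm_cohort <- function(x, ...) {
  cat(sprintf("<dnm_cohort> %d trios, %d DNMs (seed %d)\n",
              nrow(x$trios), nrow(x$dnms), x$seed))
  invisible(x)
}
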