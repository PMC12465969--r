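# End-to-end orchestration on synthetic or user-supplied cohorts, with seeds,
# stage toggles, and a JSON/TSV report bundle.

#' Pipeline configuration
#'
#' Centralises every threshold and seed of the pipeline; defaults are the
#' values the analysis is calibrated to (GQ >= 40, DP >= 12, allele balance
#' 0.25-0.75, 24x minimum mean depth, 10000/1000 bootstrap rounds, 10 kb
#' proximity window). The configuration is echoed into the report for
#' provenance.
#'
#' @param sim A [simulation_config()] for the synthetic cohort stage.
#' @param stages Named logical toggles: `cohort`, `rates`, `age_models`,
#'   `spectrum`, `sharing`, `crossovers`, `prdm9`.
#' @param gq_min,dp_min,ab_low,ab_high,min_mean_depth Filter thresholds.
#' @param n_boot_rates,n_boot_sharing Bootstrap rounds.
#' @param window_bp DNM-crossover proximity window.
#' @param n_markers_per_chrom,crossovers_per_meiosis Synthetic marker-track
#'   density and expected autosomal crossovers per meiosis.
#' @param phylo List of PRDM9-clock settings (`r0`, `r1`, `loss_time`,
#'   `noise_sd`, `n_resamples`).
#' @param seed Master seed; stage seeds are derived as small offsets.
#' @param out_dir Optional output directory for the report bundle.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c(cohort = TRUE, rates = TRUE,
                                       age_models = TRUE, spectrum = TRUE,
                                       sharing = TRUE, crossovers = TRUE,
                                       prdm9 = TRUE),
                            gq_min = 40, dp_min = 12, ab_low = 0.25,
                            ab_high = 0.75, min_mean_depth = 24,
                            n_boot_rates = 10000, n_boot_sharing = 1000,
                            window_bp = 10000,
                            n_markers_per_chrom = 20000,
                            crossovers_per_meiosis = 18.3,
                            phylo = list(r0 = 1, r1 = 2.21, loss_time = 37.3,
                                         noise_sd = 0.005, n_resamples = 1000),
                            seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Cohort-level summary table
#'
#' Mean DNMs per trio with a CI (normal approximation on the per-trio mean by
#' default, exact Poisson on the total as an alternative), the phased
#' fraction, the paternal fraction of phased DNMs with the implied
#' male-to-female ratio, and the mean callable genome fraction.
#'
#' @param dnms DNM tibble (with `phase` when phased fractions are wanted).
#' @param trios Trio table (nonempty).
#' @param callable Optional per-trio callable tibble with
#'   `callable_fraction`.
#' @param ci_method `"normal"` (default) or `"poisson"`.
#' @param conf Confidence level.
#' @return One-row summary tibble.
#' @export
cohort_summary <- function(dnms, trios, callable = NULL,
                           ci_method = c("normal", "poisson"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (nrow(trios) == 0) abort("empty cohort")
  counts <- trios %>%
    left_join(count(dnms, .data$trio_id, name = "n_dnm"), by = "trio_id") %>%
    mutate(n_dnm = tidyr::replace_na(.data$n_dnm, 0L))
  n <- nrow(counts)
  m <- mean(counts$n_dnm)
  z <- qnorm(1 - (1 - conf) / 2)
  degenerate <- n < 2 || sd(counts$n_dnm) == 0
  ci <- if (ci_method == "normal") {
    if (degenerate) c(m, m) else m + c(-1, 1) * z * sd(counts$n_dnm) / sqrt(n)
  } else {
    tot <- sum(counts$n_dnm)
    c(stats::qgamma((1 - conf) / 2, tot), stats::qgamma(1 - (1 - conf) / 2,
                                                        tot + 1)) / n
  }
  phased <- if ("phase" %in% names(dnms)) sum(dnms$phase != "unphased") else NA
  n_pat <- if ("phase" %in% names(dnms)) sum(dnms$phase == "paternal") else NA
  alpha <- if (!is.na(phased) && phased > 0 && phased - n_pat > 0) {
    n_pat / (phased - n_pat)
  } else {
    NA_real_
  }
  tibble(
    n_trios = n, n_dnm = sum(counts$n_dnm), mean_dnm_per_trio = m,
    ci_low = ci[1], ci_high = ci[2], ci_method = ci_method,
    ci_degenerate = degenerate,
    phased_fraction = if (nrow(dnms) > 0) phased / nrow(dnms) else NA_real_,
    paternal_fraction = if (!is.na(phased) && phased > 0) n_pat / phased
                        else NA_real_,
    alpha = alpha,
    mean_callable_fraction = if (!is.null(callable) &&
                                 "callable_fraction" %in% names(callable)) {
      mean(distinct(callable, .data$trio_id, .data$callable_fraction)$callable_fraction)
    } else {
      NA_real_
    }
  )
}

#' Run the analysis pipeline end to end
#'
#' Executes the toggled stages on a synthetic cohort: cohort generation,
#' regional bootstrap rates, phased parental-age models, spectrum and
#' sharing summaries, hypermutator flagging, crossover detection with DNM
#' proximity, and the PRDM9 loss clock. Later stages that need the cohort
#' refuse to run when the `cohort` stage is toggled off. The run is
#' idempotent given its seeds; when `out_dir` is set, a JSON report and TSV
#' tables are written there.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_report` with one element per executed
#'   stage plus `config_echo`, `seeds` and `timings` (seconds).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  needs_cohort <- c("rates", "age_models", "spectrum", "sharing", "crossovers")
  if (!isTRUE(st[["cohort"]]) && any(unlist(st[needs_cohort]))) {
    abort(paste("stages", paste(needs_cohort[unlist(st[needs_cohort])],
                                collapse = ", "),
                "require the cohort stage to be enabled"))
  }
  report <- list()
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s (completed: %s)", name,
                    conditionMessage(e),
                    paste(names(report), collapse = ", ")))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  cohort <- NULL
  if (isTRUE(st[["cohort"]])) {
    cohort <- tick("cohort", simulate_cohort(config$sim))
    trios <- exclude_low_depth_trios(cohort$trios, config$min_mean_depth)
    dnms <- semi_join(cohort$dnms, trios, by = "trio_id")
    callable <- semi_join(cohort$callable, trios, by = "trio_id")
    report$cohort <- cohort_summary(dnms, trios, callable)
  }
  if (isTRUE(st[["rates"]])) {
    report$rates <- tick("rates", regional_rates(
      dnms, callable, n_boot = config$n_boot_rates, seed = config$seed + 10))
  }
  if (isTRUE(st[["age_models"]])) {
    report$age_models <- tick("age_models", {
      pc <- phased_counts(dnms, trios, callable)
      fp <- fit_phased_age_model(pc, "paternal")
      fm <- fit_phased_age_model(pc, "maternal")
      list(paternal = glance(fp), maternal = glance(fm),
           coef = bind_rows(mutate(tidy(fp), sex = "paternal"),
                            mutate(tidy(fm), sex = "maternal")),
           yearly = yearly_rate(fp, fm,
                                mean_ages = c(
                                  paternal = mean(trios$paternal_age_years),
                                  maternal = mean(trios$maternal_age_years)),
                                g_diploid = 2 * config$sim$g_haploid))
    })
  }
  if (isTRUE(st[["spectrum"]])) {
    report$spectrum <- tick("spectrum", spectrum_table(dnms, cohort = "synthetic"))
  }
  if (isTRUE(st[["sharing"]])) {
    report$sharing <- tick("sharing", {
      shared <- find_shared_mutations(dnms, trios)
      frac <- shared_fraction_bootstrap(dnms, trios,
                                        n_boot = config$n_boot_sharing,
                                        seed = config$seed + 20)
      hyper <- flag_hypermutators(
        count(dnms, .data$trio_id, name = "n_dnm"))
      list(shared_groups = shared$groups, fraction = frac,
           hypermutators = filter(hyper, .data$flagged))
    })
  }
  if (isTRUE(st[["crossovers"]])) {
    report$crossovers <- tick("crossovers", {
      set.seed(config$seed + 30)
      auto <- filter(cohort$region_map$contigs,
                     .data$name != cohort$region_map$x_contig)
      genome_size <- sum(auto$length)
      per_chrom <- config$crossovers_per_meiosis / nrow(auto)
      tracks <- tidyr::crossing(trio_id = trios$trio_id,
                                contig = auto$name) %>%
        mutate(n_xo = rpois(n(), per_chrom))
      bps <- purrr::pmap(list(tracks$trio_id, tracks$contig, tracks$n_xo),
        function(tid, ctg, k) {
          len <- auto$length[auto$name == ctg]
          mk <- simulate_marker_track(len, config$n_markers_per_chrom,
                                      runif(k, 1, len))
          mutate(detect_crossovers(mk), trio_id = tid, contig = ctg)
        }) %>% list_rbind()
      prox <- dnm_crossover_proximity(
        filter(dnms, .data$primary == "AUTOSOME"), bps,
        window_bp = config$window_bp, genome_size = genome_size)
      list(n_breakpoints = nrow(bps), proximity = prox)
    })
  }
  if (isTRUE(st[["prdm9"]])) {
    report$prdm9 <- tick("prdm9", {
      tt <- demo_carnivore_timetree()
      sim <- simulate_ratioed_phylogeny(
        tt, r0 = config$phylo$r0, r1 = config$phylo$r1,
        loss_time = config$phylo$loss_time,
        noise_sd = config$phylo$noise_sd, seed = config$seed + 40)
      rp <- branch_ratios(sim$tree_hmr, sim$tree_auto)
      est <- estimate_loss_time(rp, tt, demo_branch_roles(),
                                n_resamples = config$phylo$n_resamples,
                                noise_sd = config$phylo$noise_sd,
                                seed = config$seed + 41)
      list(ratios = rp$ratios,
           estimate = tibble(loss_time_mya = est$loss_time_mya,
                             ci_low = est$ci_low, ci_high = est$ci_high,
                             r0 = est$r0, r1 = est$r1, r_obs = est$r_obs))
    })
  }

  report$seeds <- config$seed
  report$timings <- timings
  report$config_echo <- config[setdiff(names(config), "sim")]
  report$config_echo$sim <- unclass(config$sim)
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writable <- report[setdiff(names(report), "config_echo")]
    write_results(purrr::map(writable, report_jsonable),
                  file.path(config$out_dir, "report.json"), "json")
    if (!is.null(report$rates)) {
      write_results(report$rates, file.path(config$out_dir, "rates.tsv"))
    }
    if (!is.null(report$spectrum)) {
      write_results(report$spectrum, file.path(config$out_dir, "spectrum.tsv"))
    }
  }
  report
}

report_jsonable <- function(x) {
  if (inherits(x, "dnm_cohort")) {
    return(list(n_trios = nrow(x$trios), n_dnms = nrow(x$dnms), seed = x$seed))
  }
  x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> stages:",
      paste(setdiff(names(x), c("seeds", "timings", "config_echo")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Plot regional rate estimates
#' @param rates A `rate_estimate` tibble (e.g. from [regional_rates()]).
#' @return A ggplot.
#' @export
plot_rate_estimates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$region, y = .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "mutations / bp / generation") +
    ggplot2::theme_minimal()
}

#' Plot an age-model fit over its data
#' @param object A `dnm_age_fit`.
#' @param ... Unused.
#' @return A ggplot of per-trio rates against age with the fitted line.
#' @method autoplot dnm_age_fit
#' @export
autoplot.dnm_age_fit <- function(object, ...) {
  d <- mutate(object$data, rate = .data$count / .data$exposure)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(intercept = object$b0, slope = object$b1,
                         colour = "firebrick") +
    ggplot2::labs(x = "parental age at conception (years)",
                  y = "phased mutations / bp",
                  title = paste(object$sex, "age model")) +
    ggplot2::theme_minimal()
}
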