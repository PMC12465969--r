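# Phased parental-age models: identity-link Poisson regression of per-parent
# DNM counts on parental age at conception, fit by constrained maximum
# likelihood or random-walk Metropolis MCMC, with McFadden's pseudo-R2,
# binomial downsampling, breed-size strata, and line predictions.

# log-likelihood of counts ~ Poisson((b0 + b1*age) * exposure); -Inf barrier
# when a fitted mean is non-positive with a positive count
poisson_identity_loglik <- function(b0, b1, counts, ages, exposure) {
  mu <- (b0 + b1 * ages) * exposure
  if (any(mu < 0) || any(mu == 0 & counts > 0)) return(-Inf)
  sum(dpois(counts, mu, log = TRUE))
}

#' Build per-trio phased count data for age modelling
#'
#' Tallies phased paternal and maternal DNM counts per trio and attaches the
#' exposure used in phased regressions: the trio's haploid autosomal callable
#' size (half the diploid callable size). Unphased DNMs are excluded. Because
#' read-backed phasing resolves only a fraction of DNMs, phased counts are a
#' thinned Poisson sample; with `phase_correction = "cohort"` (default) the
#' exposure is additionally multiplied by the cohort-wide phased fraction, so
#' the fitted slope and intercept are on the full per-parent rate scale
#' rather than the phased-subset scale. Use `"none"` to model the phased
#' counts as-is.
#'
#' @param dnms DNM tibble with `trio_id` and `phase`
#'   (`"paternal"`/`"maternal"`/`"unphased"`).
#' @param trios Trio table.
#' @param callable Per-trio x region callable tibble (AUTOSOME rows used).
#' @param phase_correction `"cohort"` or `"none"`.
#' @return Trio tibble with `n_paternal`, `n_maternal`, `exposure`.
#' @export
phased_counts <- function(dnms, trios, callable,
                          phase_correction = c("cohort", "none")) {
  phase_correction <- match.arg(phase_correction)
  phased_frac <- if (phase_correction == "cohort" && nrow(dnms) > 0) {
    mean(dnms$phase != "unphased")
  } else {
    1
  }
  if (phased_frac == 0) abort("no phased DNMs in cohort")
  counts <- dnms %>%
    filter(.data$phase != "unphased") %>%
    count(.data$trio_id, .data$phase) %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  expo <- callable %>%
    filter(.data$region == "AUTOSOME") %>%
    mutate(exposure = .data$callable_size / 2 * phased_frac) %>%
    select("trio_id", "exposure")
  trios %>%
    left_join(counts, by = "trio_id") %>%
    left_join(expo, by = "trio_id") %>%
    mutate(n_paternal = tidyr::replace_na(.data[["n_paternal"]], 0L),
           n_maternal = tidyr::replace_na(.data[["n_maternal"]], 0L))
}

#' Fit an identity-link Poisson parental-age model
#'
#' Models phased per-parent DNM counts as
#' `count ~ Poisson((b0 + b1 * age) * exposure)` with additive per-year
#' effects on the rate scale (matching how age effects are reported, in
#' mutations/bp/year). `method = "ML"` maximises the likelihood under
#' nonnegativity constraints with a barrier against non-positive fitted
#' means; `method = "Bayes"` runs random-walk Metropolis with half-normal
#' priors (scale 10x a crude moment estimate) across 4 chains and reports
#' posterior means with highest-density intervals and split-R-hat.
#'
#' @param data Tibble with one row per trio; see `count_col`, `age_col`,
#'   `exposure_col`.
#' @param sex `"paternal"` or `"maternal"`; picks the default columns
#'   `n_paternal`/`paternal_age_years` or the maternal pair.
#' @param method `"ML"` (default) or `"Bayes"`.
#' @param count_col,age_col,exposure_col Column overrides.
#' @param conf Interval level (default 0.95).
#' @param n_iter,n_warmup,n_chains MCMC controls (Bayes only).
#' @param seed Sampler seed (Bayes only).
#' @return Object of class `dnm_age_fit` with elements `b0`, `b1` (rate
#'   scale), `ci` (2 x 2), `vcov`, `ll_model`, `ll_null`, `mcfadden`,
#'   `n_trios`, `sex`, `method`, `boundary`, and for Bayes `draws`, `rhat`.
#' @export
fit_phased_age_model <- function(data, sex = c("paternal", "maternal"),
                                 method = c("ML", "Bayes"),
                                 count_col = NULL, age_col = NULL,
                                 exposure_col = "exposure", conf = 0.95,
                                 n_iter = 2000, n_warmup = 1000,
                                 n_chains = 4, seed = 1L) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  count_col <- count_col %||% paste0("n_", sex)
  age_col <- age_col %||% paste0(sex, "_age_years")
  y <- data[[count_col]]
  age <- data[[age_col]]
  E <- data[[exposure_col]]
  stopifnot(length(y) >= 10, all(E > 0), all(is.finite(age)))
  if (sd(age) == 0) abort("zero age variance: slope is unidentifiable")

  # work on the per-Gb scale for conditioning
  S <- 1e9
  nll <- function(th) {
    ll <- poisson_identity_loglik(th[1] / S, th[2] / S, y, age, E)
    if (!is.finite(ll)) 1e12 else -ll
  }
  # crude moment estimates used for starts and prior scales
  r <- y / E
  b1_mom <- max(1e-12, stats::cov(r, age) / stats::var(age))
  b0_mom <- max(1e-12, mean(r) - b1_mom * mean(age))

  ll_null <- {
    mu0 <- mean(y)
    if (mu0 == 0) 0 else sum(dpois(y, mu0 * E / mean(E), log = TRUE))
  }

  if (all(y == 0)) {
    fit <- list(b0 = 0, b1 = 0, ci = rbind(b0 = c(0, 0), b1 = c(0, 0)),
                vcov = matrix(0, 2, 2), ll_model = 0, ll_null = 0,
                boundary = TRUE, method = method)
  } else if (method == "ML") {
    opt <- optim(c(b0_mom, b1_mom) * S, nll, method = "L-BFGS-B",
                 lower = c(0, 0), hessian = TRUE)
    se <- tryCatch(sqrt(diag(solve(opt$hessian))) / S,
                   error = function(e) c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - conf) / 2)
    est <- opt$par / S
    ci <- rbind(b0 = pmax(0, est[1] + c(-1, 1) * z * se[1]),
                b1 = pmax(0, est[2] + c(-1, 1) * z * se[2]))
    fit <- list(b0 = est[1], b1 = est[2], ci = ci,
                vcov = tryCatch(solve(opt$hessian) / S^2,
                                error = function(e) matrix(NA, 2, 2)),
                ll_model = -opt$value, ll_null = ll_null,
                boundary = any(opt$par == 0), method = "ML")
  } else {
    fit <- fit_bayes_rwm(y, age, E, b0_mom, b1_mom, conf = conf,
                         n_iter = n_iter, n_warmup = n_warmup,
                         n_chains = n_chains, seed = seed)
    fit$ll_model <- poisson_identity_loglik(fit$b0, fit$b1, y, age, E)
    fit$ll_null <- ll_null
  }
  fit$mcfadden <- if (fit$ll_null == 0) NA_real_ else 1 - fit$ll_model / fit$ll_null
  fit$n_trios <- length(y)
  fit$sex <- sex
  fit$conf <- conf
  fit$exposure_convention <- "haploid autosomal callable size per trio"
  fit$data <- tibble(count = y, age = age, exposure = E)
  structure(fit, class = "dnm_age_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random-walk Metropolis with half-normal priors on (b0, b1)
fit_bayes_rwm <- function(y, age, E, b0_mom, b1_mom, conf, n_iter, n_warmup,
                          n_chains, seed) {
  S <- 1e9
  prior_scale <- c(b0_mom, b1_mom) * S * 10
  log_post <- function(th) {
    if (any(th < 0)) return(-Inf)
    ll <- poisson_identity_loglik(th[1] / S, th[2] / S, y, age, E)
    ll + sum(dnorm(th, 0, prior_scale, log = TRUE))
  }
  set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(ch) {
    step <- pmax(prior_scale / 50, 1e-6)
    scale_mult <- 1
    chol_prop <- diag(step)
    th <- abs(rnorm(2, c(b0_mom, b1_mom) * S, prior_scale / 10))
    lp <- log_post(th)
    draws <- matrix(NA_real_, n_iter, 2)
    for (i in seq_len(n_iter)) {
      prop <- th + scale_mult * as.numeric(chol_prop %*% rnorm(2))
      lp_prop <- log_post(prop)
      accepted <- log(runif(1)) < lp_prop - lp
      if (accepted) {
        th <- prop
        lp <- lp_prop
      }
      draws[i, ] <- th
      if (i <= n_warmup) {
        # Robbins-Monro adaptation towards ~30% acceptance, and a
        # covariance-shaped proposal from the second half of warmup on
        # (b0 and b1 are strongly anti-correlated under the identity link)
        scale_mult <- scale_mult * exp((accepted - 0.3) / 30)
        if (i == ceiling(n_warmup / 2)) {
          emp <- stats::cov(draws[ceiling(i / 2):i, , drop = FALSE])
          ch_try <- tryCatch(chol(emp * 2.4^2 / 2), error = function(e) NULL)
          if (!is.null(ch_try)) {
            chol_prop <- t(ch_try)
            scale_mult <- 1
          }
        }
      }
    }
    draws[(n_warmup + 1):n_iter, , drop = FALSE]
  })
  rhat <- vapply(1:2, function(j) {
    split_rhat(lapply(chains, function(d) d[, j])) }, 0)
  if (any(rhat >= 1.01, na.rm = TRUE)) {
    warn(sprintf("MCMC not converged (max split-Rhat %.3f)", max(rhat)))
  }
  draws <- do.call(rbind, chains) / S
  a <- (1 - conf) / 2
  list(b0 = mean(draws[, 1]), b1 = mean(draws[, 2]),
       ci = rbind(b0 = hdi(draws[, 1], conf), b1 = hdi(draws[, 2], conf)),
       vcov = stats::cov(draws), draws = draws, rhat = rhat,
       boundary = FALSE, method = "Bayes", seed = seed)
}

split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- floor(length(x) / 2)
    list(x[seq_len(n)], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

hdi <- function(x, conf = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1, floor(conf * n))
  widths <- x[(k + 1):n] - x[seq_len(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' McFadden's pseudo-R-squared of an age-model fit
#'
#' `1 - ll_model / ll_null`, where the null is the intercept-only Poisson
#' model on the same counts and exposures.
#'
#' @param fit A `dnm_age_fit`.
#' @return McFadden's R2 in `[0, 1)`.
#' @export
mcfadden_r2 <- function(fit) {
  stopifnot(inherits(fit, "dnm_age_fit"))
  if (is.na(fit$ll_null) || fit$ll_null == 0) {
    abort("null log-likelihood is zero; McFadden's R2 undefined")
  }
  1 - fit$ll_model / fit$ll_null
}

#' Downsample counts binomially and refit the age model
#'
#' Thins each trio's count with `Binomial(count, q)` where
#' `q = target_total / sum(counts)`, matching the target total in
#' expectation, then refits. Poisson thinning scales both slope and intercept
#' by `q` in expectation.
#'
#' @param data Per-trio count data (see [fit_phased_age_model()]).
#' @param target_total Target total DNM count (<= available).
#' @param seed Thinning seed.
#' @param ... Passed to [fit_phased_age_model()].
#' @inheritParams fit_phased_age_model
#' @return A `dnm_age_fit` on the thinned counts, with a `thinning` element.
#' @export
downsample_and_refit <- function(data, target_total, seed,
                                 sex = c("paternal", "maternal"),
                                 count_col = NULL, ...) {
  sex <- match.arg(sex)
  count_col <- count_col %||% paste0("n_", sex)
  total <- sum(data[[count_col]])
  if (target_total > total) abort("target_total exceeds available DNMs")
  q <- target_total / total
  set.seed(seed)
  data[[count_col]] <- rbinom(nrow(data), data[[count_col]], q)
  fit <- fit_phased_age_model(data, sex = sex, count_col = count_col, ...)
  fit$thinning <- list(q = q, target_total = target_total, seed = seed)
  fit
}

#' Fit the age model separately per breed-size class
#'
#' @param data Per-trio count data with a `size_class` column.
#' @param classes Classes to fit (others are dropped; empty classes are
#'   omitted with a warning).
#' @param min_trios Minimum trios per class (default 10).
#' @param ... Passed to [fit_phased_age_model()].
#' @return List of class `dnm_age_fit_by_class`: `per_class` (named list of
#'   fits) and `pooled` (single fit on all rows).
#' @export
fit_by_size_class <- function(data,
                              classes = c("small", "intermediate", "large"),
                              min_trios = 10, ...) {
  per_class <- list()
  for (cl in classes) {
    sub <- data[data$size_class == cl, ]
    if (nrow(sub) == 0) {
      warn(paste("size class", cl, "is empty; omitted"))
      next
    }
    if (nrow(sub) < min_trios) {
      warn(paste("size class", cl, "has <", min_trios, "trios; omitted"))
      next
    }
    per_class[[cl]] <- fit_phased_age_model(sub, ...)
  }
  pooled <- fit_phased_age_model(data[data$size_class %in% classes, ], ...)
  structure(list(per_class = per_class, pooled = pooled),
            class = "dnm_age_fit_by_class")
}

#' Predict the mutation rate at a given age
#'
#' Evaluates `b0 + b1 * age` (mutations/bp on the model's exposure scale)
#' with an interval propagated from the parameter covariance. Negative
#' predictions are reported truncated at zero with a flag.
#'
#' @param fit A `dnm_age_fit`.
#' @param age_years Age(s) in years.
#' @param max_age Extrapolation guard: ages beyond this warn (default 1.5x
#'   the largest observed age).
#' @return Tibble with `age_years`, `rate`, `ci_low`, `ci_high`, `truncated`.
#' @export
predict_rate_at_age <- function(fit, age_years, max_age = NULL) {
  stopifnot(inherits(fit, "dnm_age_fit"))
  max_age <- max_age %||% (1.5 * max(fit$data$age))
  if (any(age_years > max_age)) {
    warn("prediction beyond the extrapolation guard")
  }
  raw <- fit$b0 + fit$b1 * age_years
  v <- vapply(age_years, function(a) {
    x <- c(1, a)
    as.numeric(t(x) %*% fit$vcov %*% x)
  }, 0)
  z <- qnorm(1 - (1 - (fit$conf %||% 0.95)) / 2)
  se <- sqrt(pmax(v, 0))
  tibble(age_years = age_years, rate = pmax(0, raw),
         ci_low = pmax(0, raw - z * se), ci_high = pmax(0, raw + z * se),
         truncated = raw < 0)
}

#' Yearly germline mutation rate from paired parental fits
#'
#' The per-generation rate cannot be converted exactly into a yearly rate
#' without a generational model, so two documented approximations are
#' reported: `interval` divides the per-generation per-bp rate at the mean
#' parental ages by the mean generation interval; `slope_sum` uses only the
#' age effects, `(b1p * Ep + b1m * Em) / (2 * g_diploid)` per year.
#'
#' @param fit_paternal,fit_maternal `dnm_age_fit` objects.
#' @param mean_ages Named numeric: `paternal`, `maternal` mean ages (years).
#' @param g_diploid Diploid callable genome size (bp).
#' @param exposure_p,exposure_m Haploid exposures (default `g_diploid / 2`).
#' @return Tibble with `method` (`interval`, `slope_sum`) and
#'   `yearly_rate` (mutations/bp/year).
#' @export
yearly_rate <- function(fit_paternal, fit_maternal,
                        mean_ages = c(paternal = 4.5, maternal = 4.0),
                        g_diploid = 4.36e9,
                        exposure_p = g_diploid / 2,
                        exposure_m = g_diploid / 2) {
  interval <- mean(mean_ages)
  if (interval <= 0) abort("generation interval must be > 0")
  mu_p <- (fit_paternal$b0 + fit_paternal$b1 * mean_ages[["paternal"]]) *
    exposure_p
  mu_m <- (fit_maternal$b0 + fit_maternal$b1 * mean_ages[["maternal"]]) *
    exposure_m
  per_gen <- (mu_p + mu_m) / g_diploid
  slope_sum <- (fit_paternal$b1 * exposure_p + fit_maternal$b1 * exposure_m) /
    (2 * g_diploid)
  tibble(method = c("interval", "slope_sum"),
         yearly_rate = c(per_gen / interval, slope_sum))
}

# -- broom-style methods -----------------------------------------------------

#' @export
print.dnm_age_fit <- function(x, ...) {
  cat(sprintf("<dnm_age_fit> %s, %s: b0 = %.3e, b1 = %.3e /bp/yr (n = %d)\n",
              x$sex, x$method, x$b0, x$b1, x$n_trios))
  invisible(x)
}

#' Tidy an age-model fit
#' @param x A `dnm_age_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy dnm_age_fit
#' @export
tidy.dnm_age_fit <- function(x, ...) {
  tibble(term = c("intercept", "age_effect"),
         estimate = c(x$b0, x$b1),
         conf.low = x$ci[, 1], conf.high = x$ci[, 2])
}

#' One-row model summary of an age-model fit
#' @param x A `dnm_age_fit`.
#' @param ... Unused.
#' @return Tibble with log-likelihoods, McFadden's R2, n, method.
#' @method glance dnm_age_fit
#' @export
glance.dnm_age_fit <- function(x, ...) {
  tibble(logLik = x$ll_model, logLik_null = x$ll_null,
         mcfadden_r2 = x$mcfadden, n_trios = x$n_trios,
         sex = x$sex, method = x$method, boundary = x$boundary)
}

#' @method tidy dnm_age_fit_by_class
#' @export
tidy.dnm_age_fit_by_class <- function(x, ...) {
  bind_rows(
    list_rbind(purrr::imap(x$per_class,
                           function(f, cl) mutate(tidy(f), size_class = cl))),
    mutate(tidy(x$pooled), size_class = "pooled")
  )
}
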