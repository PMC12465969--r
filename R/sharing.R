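# Sibling-shared mutation analysis and hypermutation flagging.

#' Group DNMs shared across offspring
#'
#' Groups DNMs observed in more than one offspring by (contig, position,
#' alternate allele) — the allele must match so coincidental positional
#' collisions do not join a group. Members of a group are labelled full
#' siblings (both parents shared) or half siblings (one parent shared);
#' groups whose members share no parent are flagged `RECURRENT_UNRELATED`
#' and excluded from sharing fractions.
#'
#' @param dnms DNM tibble with `trio_id`, `contig`, `pos`, `alt`, and
#'   optionally `phase`.
#' @param trios Trio table resolving `trio_id` to `sire_id`/`dam_id`.
#' @return List of class `shared_mutation_summary`: `groups` (one row per
#'   shared group: members, size, relation, phases), `n_unique` (unique
#'   mutations in the cohort), `n_shared_groups`, and the group-size table.
#' @export
find_shared_mutations <- function(dnms, trios) {
  keyed <- dnms %>%
    left_join(select(trios, "trio_id", "sire_id", "dam_id"), by = "trio_id") %>%
    mutate(key = paste(.data$contig, .data$pos, .data$alt, sep = ":"))
  groups <- keyed %>%
    group_by(.data$key) %>%
    filter(dplyr::n_distinct(.data$trio_id) >= 2) %>%
    summarise(
      contig = .data$contig[1], pos = .data$pos[1], alt = .data$alt[1],
      members = list(sort(unique(.data$trio_id))),
      n_members = dplyr::n_distinct(.data$trio_id),
      relation = dplyr::case_when(
        dplyr::n_distinct(.data$sire_id) == 1 &
          dplyr::n_distinct(.data$dam_id) == 1 ~ "full_sib",
        dplyr::n_distinct(.data$sire_id) == 1 |
          dplyr::n_distinct(.data$dam_id) == 1 ~ "half_sib",
        TRUE ~ "RECURRENT_UNRELATED"),
      phases = list(if ("phase" %in% names(keyed)) unique(.data$phase)
                    else character()),
      .groups = "drop"
    )
  n_unique <- dplyr::n_distinct(keyed$key)
  structure(list(groups = groups, n_unique = n_unique,
                 n_shared_groups = sum(groups$relation != "RECURRENT_UNRELATED"),
                 size_table = table(groups$n_members[
                   groups$relation != "RECURRENT_UNRELATED"])),
            class = "shared_mutation_summary")
}

#' @export
print.shared_mutation_summary <- function(x, ...) {
  cat(sprintf("<shared_mutation_summary> %d shared groups among %d unique mutations\n",
              x$n_shared_groups, x$n_unique))
  invisible(x)
}

# all full-sibling trio pairs implied by a trio table
full_sib_pairs <- function(trios) {
  trios %>%
    inner_join(trios, by = c("sire_id", "dam_id"),
               suffix = c("_1", "_2"), relationship = "many-to-many") %>%
    filter(.data$trio_id_1 < .data$trio_id_2) %>%
    select("trio_id_1", "trio_id_2", "sire_id", "dam_id")
}

#' Bootstrap the full-sibling shared-mutation fraction
#'
#' For every full-sibling pair, counts the mutations shared between the two
#' offspring (matching contig, position and allele) and the unique mutations
#' of the pair. The pooled fraction is total shared over total unique across
#' all pairs; triple sharing contributes to every constituent pair. The CI is
#' a percentile bootstrap over pairs (default 1000 rounds). Half-sib sharing
#' is excluded.
#'
#' @param dnms DNM tibble.
#' @param trios Trio table.
#' @param n_boot Bootstrap rounds (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return One-row tibble: `fraction`, `ci_low`, `ci_high`, `n_pairs`,
#'   `n_shared`, `n_unique`, `n_boot`, `seed`.
#' @export
shared_fraction_bootstrap <- function(dnms, trios, n_boot = 1000, seed,
                                      conf = 0.95) {
  if (missing(seed)) abort("seed is required")
  pairs <- full_sib_pairs(trios)
  if (nrow(pairs) == 0) abort("no full-sibling pairs in the pedigree")
  keyed <- mutate(dnms, key = paste(.data$contig, .data$pos, .data$alt,
                                    sep = ":"))
  per_pair <- purrr::pmap(
    list(pairs$trio_id_1, pairs$trio_id_2),
    function(t1, t2) {
      k1 <- unique(keyed$key[keyed$trio_id == t1])
      k2 <- unique(keyed$key[keyed$trio_id == t2])
      tibble(n_shared = length(intersect(k1, k2)),
             n_unique = length(union(k1, k2)))
    }
  ) %>% list_rbind()
  frac <- function(d) sum(d$n_shared) / sum(d$n_unique)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    frac(per_pair[sample.int(nrow(per_pair), replace = TRUE), ])
  }, 0)
  a <- (1 - conf) / 2
  ci <- unname(quantile(boots, c(a, 1 - a)))
  tibble(fraction = frac(per_pair), ci_low = ci[1], ci_high = ci[2],
         n_pairs = nrow(per_pair), n_shared = sum(per_pair$n_shared),
         n_unique = sum(per_pair$n_unique), n_boot = n_boot, seed = seed)
}

#' Flag hypermutated trios
#'
#' Computes each trio's fold excess over the cohort median DNM count
#' (excluding the trio itself) and flags trios whose count is improbably
#' large under a Poisson at the cohort mean: upper-tail probability,
#' Bonferroni-adjusted across trios, below `alpha`. Flagged trios are
#' conventionally excluded from downstream rate and age analyses.
#'
#' @param counts Tibble with `trio_id` and `n_dnm` (>= 10 trios).
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with `trio_id`, `n_dnm`, `fold`, `p_adjusted`, `flagged`.
#' @export
flag_hypermutators <- function(counts, alpha = 0.05) {
  stopifnot(nrow(counts) >= 10)
  n <- nrow(counts)
  med_excl <- vapply(seq_len(n), function(i) median(counts$n_dnm[-i]), 0)
  if (any(med_excl == 0)) abort("cohort median DNM count is zero")
  cohort_mean <- vapply(seq_len(n), function(i) mean(counts$n_dnm[-i]), 0)
  p <- ppois(counts$n_dnm - 1, cohort_mean, lower.tail = FALSE)
  p_adj <- pmin(1, p * n)
  tibble(trio_id = counts$trio_id, n_dnm = counts$n_dnm,
         fold = counts$n_dnm / med_excl, p_adjusted = p_adj,
         flagged = p_adj < alpha)
}
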