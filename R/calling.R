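# Trio DNM filter cascade, read-level post-check, and callable-site /
# callable-size accounting.

FILTER_RULES <- c("GT_PATTERN", "PARENT_ALT_READS", "GQ", "DEPTH",
                  "ALLELE_BALANCE", "NOT_SNV", "MISSING_EVIDENCE")

#' Apply the trio de novo mutation filter cascade
#'
#' Evaluates, per candidate site, the full rule set for accepting a de novo
#' SNV: offspring heterozygous (0/1) with both parents homozygous reference
#' (0/0); at most one alternate-allele read in each parent; offspring genotype
#' quality GQ >= 40; every sample's depth at least 12 and strictly between
#' half and twice that individual's mean autosomal depth; offspring allele
#' balance strictly between 0.25 and 0.75; single-nucleotide changes only.
#' At X-unique sites of male offspring the depth thresholds are halved, the
#' allele balance must instead exceed 0.75, and the offspring genotype may be
#' 0/1 or 1/1 (hemizygous calls are emitted as homozygous by joint callers).
#' PAR sites are treated as autosomal. All rules are evaluated for every site,
#' so the verdict is independent of rule order.
#'
#' @param sites Candidate-site tibble (layout of [read_trio_vcf()] /
#'   [simulate_site_evidence()]) with a `trio_id` column.
#' @param trios Trio table (see [validate_trios()]) supplying offspring sex
#'   and per-individual mean depths.
#' @param region_map A [region_map()] used to flag PAR / X-unique sites.
#' @param gq_min,dp_min,ab_low,ab_high Threshold defaults per the cascade.
#' @param gq_all_samples Apply the GQ rule to parents as well as offspring.
#' @return Verdict tibble: one row per site with `site_id`, `trio_id`,
#'   `pass`, and `failed` (comma-joined rule codes, empty when passing).
#' @export
apply_dnm_filters <- function(sites, trios, region_map,
                              gq_min = 40, dp_min = 12,
                              ab_low = 0.25, ab_high = 0.75,
                              gq_all_samples = FALSE) {
  stopifnot("trio_id" %in% names(sites))
  d <- sites %>%
    left_join(select(trios, "trio_id", "offspring_sex", "depth_offspring",
                     "depth_sire", "depth_dam"),
              by = "trio_id")
  if (anyNA(d$offspring_sex)) abort("sites reference trios absent from `trios`")
  reg <- region_lookup(region_map, d$contig, d$pos, one_based = TRUE)
  male_x <- reg$primary == "X_UNIQUE" & d$offspring_sex == "M"
  halve <- if_else(male_x, 0.5, 1)

  ev_cols <- c("gt_offspring", "gt_sire", "gt_dam", "gq_offspring",
               "dp_offspring", "dp_sire", "dp_dam",
               "ad_ref_offspring", "ad_alt_offspring",
               "ad_alt_sire", "ad_alt_dam")
  missing_ev <- !complete.cases(d[, ev_cols])

  gt_ok <- d$gt_sire == "0/0" & d$gt_dam == "0/0" &
    (d$gt_offspring == "0/1" | (male_x & d$gt_offspring == "1/1"))
  parent_ok <- d$ad_alt_sire <= 1 & d$ad_alt_dam <= 1
  gq_ok <- d$gq_offspring >= gq_min
  if (gq_all_samples) gq_ok <- gq_ok & d$gq_sire >= gq_min & d$gq_dam >= gq_min
  dep_one <- function(dp, ind) {
    dp >= dp_min * halve & dp > 0.5 * ind * halve & dp < 2 * ind * halve
  }
  depth_ok <- dep_one(d$dp_offspring, d$depth_offspring) &
    dep_one(d$dp_sire, d$depth_sire) & dep_one(d$dp_dam, d$depth_dam)
  ab <- d$ad_alt_offspring / (d$ad_ref_offspring + d$ad_alt_offspring)
  ab_ok <- if_else(male_x, ab > ab_high, ab > ab_low & ab < ab_high)
  snv_ok <- grepl("^[ACGT]$", d$ref) & grepl("^[ACGT]$", d$alt) &
    d$ref != d$alt

  fails <- cbind(
    GT_PATTERN = !gt_ok, PARENT_ALT_READS = !parent_ok, GQ = !gq_ok,
    DEPTH = !depth_ok, ALLELE_BALANCE = !ab_ok, NOT_SNV = !snv_ok
  )
  fails[is.na(fails)] <- FALSE
  fails <- cbind(fails, MISSING_EVIDENCE = missing_ev)
  # fail-closed: with missing evidence only MISSING_EVIDENCE is reported
  fails[missing_ev, colnames(fails) != "MISSING_EVIDENCE"] <- FALSE
  failed <- apply(fails, 1, function(f) paste(colnames(fails)[f], collapse = ","))
  tibble(site_id = d$site_id, trio_id = d$trio_id,
         pass = !rowSums(fails) > 0, failed = failed,
         allele_balance = ab, primary = reg$primary)
}

#' Read-level post-check of a candidate DNM
#'
#' Mirrors a manual pile-up inspection: at most one "incorrect" read is
#' allowed across the trio, where an incorrect read is a parental read
#' carrying a non-reference allele or an offspring read carrying neither the
#' reference nor the candidate alternate allele. The offspring's read-level
#' allele balance must additionally lie within `[ab_low, ab_high]`
#' (inclusive). Sites with no offspring reads fail closed.
#'
#' @param reads Tibble of per-read allele assignments for one site with
#'   columns `sample_role` (`"offspring"`, `"sire"`, `"dam"`) and `allele`
#'   (`"ref"`, `"alt"`, `"other"`).
#' @param max_incorrect Maximum tolerated incorrect reads (default 1).
#' @param ab_low,ab_high Inclusive offspring allele-balance bounds.
#' @return One-row tibble with `pass`, `n_incorrect`, `allele_balance`.
#' @export
read_check <- function(reads, max_incorrect = 1, ab_low = 0.25,
                       ab_high = 0.75) {
  stopifnot(all(reads$sample_role %in% c("offspring", "sire", "dam")),
            all(reads$allele %in% c("ref", "alt", "other")))
  parent <- reads$sample_role != "offspring"
  n_incorrect <- sum(parent & reads$allele != "ref") +
    sum(!parent & reads$allele == "other")
  off <- reads[!parent, ]
  n_alt <- sum(off$allele == "alt")
  n_ref <- sum(off$allele == "ref")
  ab <- if (n_alt + n_ref > 0) n_alt / (n_alt + n_ref) else NA_real_
  pass <- nrow(off) > 0 && n_incorrect <= max_incorrect &&
    !is.na(ab) && ab >= ab_low && ab <= ab_high
  tibble(pass = pass, n_incorrect = n_incorrect, allele_balance = ab)
}

#' Compute a trio's callable profile from per-site summaries
#'
#' A position is callable when both parents are homozygous reference and all
#' three samples pass the depth rule used for DNM calling (thresholds halved
#' at X-unique sites of male offspring). Counts are tallied per region
#' category and scaled into callable sizes: twice the callable sites
#' everywhere except X-unique sites of male offspring, which count once.
#'
#' @param sites Per-position tibble with `contig`, `pos` (1-based),
#'   `gt_sire`, `gt_dam`, `dp_offspring`, `dp_sire`, `dp_dam`.
#' @param trio One-row trio record (sex and mean depths).
#' @param region_map A [region_map()]; every contig in `sites` must exist.
#' @param dp_min Minimum depth (default 12).
#' @return Tibble with one row per region category: `callable_sites`,
#'   `callable_size`, plus a `callable_fraction` attribute-free column giving
#'   callable primary sites over total sites examined.
#' @export
compute_callable_profile <- function(sites, trio, region_map, dp_min = 12) {
  stopifnot(nrow(trio) == 1)
  bad <- setdiff(unique(sites$contig), region_map$contigs$name)
  if (length(bad) > 0) {
    abort(paste("contigs absent from region map:", paste(bad, collapse = ", ")))
  }
  reg <- region_lookup(region_map, sites$contig, sites$pos, one_based = TRUE)
  male_x <- reg$primary == "X_UNIQUE" & trio$offspring_sex == "M"
  halve <- if_else(male_x, 0.5, 1)
  dep_one <- function(dp, ind) dp >= dp_min * halve & dp < 2 * ind * halve
  callable <- sites$gt_sire == "0/0" & sites$gt_dam == "0/0" &
    dep_one(sites$dp_offspring, trio$depth_offspring) &
    dep_one(sites$dp_sire, trio$depth_sire) &
    dep_one(sites$dp_dam, trio$depth_dam)
  callable[is.na(callable)] <- FALSE

  scale <- if_else(male_x, 1, 2)
  tab <- tibble(primary = reg$primary, in_cgi = reg$in_cgi,
                in_hmr = reg$in_hmr_cgi, callable = callable, scale = scale)
  one <- function(sel, label) {
    tibble(trio_id = trio$trio_id, region = label,
           callable_sites = sum(tab$callable[sel]),
           callable_size = sum((tab$callable * tab$scale)[sel]))
  }
  prof <- bind_rows(
    one(tab$primary == "AUTOSOME", "AUTOSOME"),
    one(tab$primary == "PAR", "PAR"),
    one(tab$primary == "X_UNIQUE", "X_UNIQUE"),
    one(tab$in_cgi, "CGI"),
    one(tab$in_hmr, "HMR_CGI"),
    one(tab$in_cgi & !tab$in_hmr, "NONHMR_CGI")
  )
  prof$callable_fraction <- sum(callable) / nrow(sites)
  prof
}

#' Exclude trios with low mean sequencing depth
#'
#' Cohort-wide pre-filter: trios where any member's mean autosomal depth is
#' below `min_depth` (default 24x) are removed before DNM calling.
#'
#' @param trios Trio table.
#' @param min_depth Minimum per-individual mean depth.
#' @return Filtered trio tibble (message reports how many were dropped).
#' @export
exclude_low_depth_trios <- function(trios, min_depth = 24) {
  keep <- trios$depth_offspring >= min_depth & trios$depth_sire >= min_depth &
    trios$depth_dam >= min_depth
  if (any(!keep)) {
    message(sprintf("excluding %d trio(s) with mean depth < %gx",
                    sum(!keep), min_depth))
  }
  trios[keep, ]
}

#' Mendelian-consistency QC for a trio
#'
#' Reports the fraction of non-reference offspring genotypes explainable by
#' Mendelian transmission from the parents, as a parentage sanity check. This
#' is a QC report, not a hard gate.
#'
#' @param sites Candidate-site tibble with `gt_offspring`, `gt_sire`, `gt_dam`.
#' @return One-row tibble with `n_nonref`, `n_consistent`, `fraction`.
#' @export
mendelian_qc <- function(sites) {
  has_alt <- function(gt) grepl("1", gt, fixed = TRUE)
  nonref <- has_alt(sites$gt_offspring)
  consistent <- nonref & (has_alt(sites$gt_sire) | has_alt(sites$gt_dam))
  tibble(n_nonref = sum(nonref, na.rm = TRUE),
         n_consistent = sum(consistent, na.rm = TRUE),
         fraction = sum(consistent, na.rm = TRUE) /
           max(1, sum(nonref, na.rm = TRUE)))
}

#' Call de novo mutations from candidate sites
#'
#' Convenience wrapper: applies [apply_dnm_filters()], keeps passing sites,
#' classifies them into the seven-class spectrum and attaches region flags.
#'
#' @inheritParams apply_dnm_filters
#' @return DNM tibble with `trio_id`, `contig`, `pos`, `ref`, `alt`,
#'   `mutation_class`, `primary`, `in_cgi`, `in_hmr_cgi`.
#' @export
call_dnms <- function(sites, trios, region_map, ...) {
  verdict <- apply_dnm_filters(sites, trios, region_map, ...)
  keep <- sites[verdict$pass, ]
  if (nrow(keep) == 0) {
    return(tibble(trio_id = character(), contig = character(), pos = numeric(),
                  ref = character(), alt = character(),
                  mutation_class = character(), primary = character(),
                  in_cgi = logical(), in_hmr_cgi = logical()))
  }
  reg <- region_lookup(region_map, keep$contig, keep$pos, one_based = TRUE)
  keep %>%
    mutate(mutation_class = classify_mutation(.data$context3, .data$ref,
                                              .data$alt),
           primary = reg$primary, in_cgi = reg$in_cgi,
           in_hmr_cgi = reg$in_hmr_cgi) %>%
    select("trio_id", "contig", "pos", "ref", "alt", "mutation_class",
           "primary", "in_cgi", "in_hmr_cgi")
  }
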