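# Readers and writers for the tabular interfaces: PED-like pedigree TSVs,
# per-trio VCF genotype evidence (via vcfR), and TSV/JSON result tables.

PED_COLUMNS <- c(
  "trio_id", "offspring_id", "sire_id", "dam_id", "offspring_sex",
  "paternal_age_years", "maternal_age_years", "breed", "size_class",
  "depth_offspring", "depth_sire", "depth_dam", "litter_id", "pedigree_id"
)

#' Read a PED-like pedigree/trio table
#'
#' A tab-separated table with one row per trio, extending the classic PED
#' layout with ages at conception (years), breed, FCI size class and mean
#' autosomal sequencing depth per individual.
#'
#' @param path TSV path with the columns listed in `canidnm:::PED_COLUMNS`.
#' @return Tibble of validated trio records.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      trio_id = "c", offspring_id = "c", sire_id = "c", dam_id = "c",
      offspring_sex = "c", breed = "c", size_class = "c", litter_id = "c",
      pedigree_id = "c", .default = readr::col_guess()
    ))
  validate_trios(ped)
}

#' Validate a trio table
#'
#' Checks the invariants of trio records: unique trio ids, sexes coded M/F,
#' strictly positive finite ages and mean depths.
#'
#' @param trios Data frame of trio records.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_trios <- function(trios) {
  trios <- as_tibble(trios)
  missing <- setdiff(PED_COLUMNS, names(trios))
  if (length(missing) > 0) {
    abort(paste("pedigree table missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(trios$trio_id)) abort("trio_id must be unique")
  if (!all(trios$offspring_sex %in% c("M", "F"))) {
    abort("offspring_sex must be coded M/F")
  }
  ages <- c(trios$paternal_age_years, trios$maternal_age_years)
  if (!all(is.finite(ages)) || any(ages <= 0)) {
    abort("parental ages must be strictly positive and finite")
  }
  depths <- c(trios$depth_offspring, trios$depth_sire, trios$depth_dam)
  if (any(!is.finite(depths) | depths <= 0)) abort("mean depths must be > 0")
  trios
}

#' Write a pedigree/trio table
#' @param trios Trio tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(trios, path) {
  readr::write_tsv(validate_trios(trios), path)
  invisible(path)
}

#' Read trio genotype evidence from a VCF
#'
#' Extracts per-sample GT, GQ, DP and allele depths (AD) for the three trio
#' members from a VCF 4.x file and returns one row per site with offspring /
#' sire / dam columns. Multi-allelic sites are decomposed into bi-allelic
#' candidates, one row per alternate allele. Positions are kept 1-based as in
#' the VCF; region lookups convert internally.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param offspring_id,sire_id,dam_id Sample names in the VCF.
#' @param pass_only Drop records whose FILTER is neither `PASS` nor `.`.
#' @return Tibble of candidate sites with columns `contig`, `pos`, `ref`,
#'   `alt`, `context3` (from the INFO field `CTX` when present, else `NA`),
#'   `filter`, and per-role `gt_*`, `gq_*`, `dp_*`, `ad_ref_*`, `ad_alt_*`.
#' @export
read_trio_vcf <- function(path, offspring_id, sire_id, dam_id,
                          pass_only = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx) # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    abort("VCF contains no records")
  }
  samples <- colnames(v@gt)[-1]
  roles <- c(offspring = offspring_id, sire = sire_id, dam = dam_id)
  if (!all(roles %in% samples)) {
    abort(paste("samples not in VCF:",
                paste(setdiff(roles, samples), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")

  info <- vcfR::getINFO(v)
  ctx <- ifelse(grepl("(^|;)CTX=", info), sub(".*CTX=([^;]+).*", "\\1", info),
                NA_character_)
  ctx[!grepl("^[ACGTacgt]{3}$", ctx)] <- NA_character_

  base <- tibble(
    contig = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt_field = fix$ALT,
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    context3 = ctx
  )
  for (role in names(roles)) {
    s <- roles[[role]]
    base[[paste0("gt_", role)]] <- unname(gt[, s])
    base[[paste0("gq_", role)]] <- unname(gq[, s])
    base[[paste0("dp_", role)]] <- unname(dp[, s])
    base[[paste0("ad_", role)]] <- unname(ad[, s])
  }
  if (pass_only) base <- filter(base, .data$filter %in% c("PASS", "."))

  # decompose multi-allelics: one bi-allelic candidate row per alt
  base <- base %>%
    mutate(.alts = strsplit(.data$alt_field, ",", fixed = TRUE),
           .n_alt = lengths(.data$.alts)) %>%
    tidyr::unnest(cols = ".alts") %>%
    group_by(.data$contig, .data$pos) %>%
    mutate(.alt_idx = row_number()) %>%
    ungroup() %>%
    rename(alt = ".alts")

  split_ad <- function(ad_str, idx) {
    parts <- strsplit(ifelse(is.na(ad_str), "", ad_str), ",", fixed = TRUE)
    ref_d <- suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 1) p[1] else NA_character_, "")))
    alt_d <- suppressWarnings(as.numeric(map2_dbl(parts, idx, function(p, i)
      if (length(p) >= i + 1) as.numeric(p[i + 1]) else NA_real_)))
    list(ref = ref_d, alt = alt_d)
  }
  for (role in c("offspring", "sire", "dam")) {
    ads <- split_ad(base[[paste0("ad_", role)]], base$.alt_idx)
    base[[paste0("ad_ref_", role)]] <- ads$ref
    base[[paste0("ad_alt_", role)]] <- ads$alt
    # normalise GT for the decomposed alt: alleles equal to this alt -> 1,
    # other non-ref alleles -> 2 (so the 0/1-vs-0/0 pattern test stays exact)
    g <- base[[paste0("gt_", role)]]
    base[[paste0("gt_", role)]] <- normalise_gt(g, base$.alt_idx)
  }
  base %>%
    select(-"alt_field", -".n_alt", -".alt_idx",
           -"ad_offspring", -"ad_sire", -"ad_dam") %>%
    mutate(site_id = paste0(.data$contig, ":", .data$pos, ":", .data$ref, ">",
                            .data$alt)) %>%
    select("site_id", dplyr::everything())
}

normalise_gt <- function(gt, alt_idx) {
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    if (is.na(gt[i])) { out[i] <- NA_character_; next }
    alleles <- strsplit(gt[i], "[/|]")[[1]]
    mapped <- vapply(alleles, function(a) {
      if (a == ".") return(".")
      ai <- suppressWarnings(as.integer(a))
      if (is.na(ai) || ai == 0) "0" else if (ai == alt_idx[i]) "1" else "2"
    }, "")
    out[i] <- paste(sort(mapped), collapse = "/")
  }
  out
}

#' Write result tables to TSV or JSON
#'
#' Round-trip safe: numeric values are serialised with full precision so a
#' re-read reproduces them to at least 12 significant digits.
#'
#' @param tables A data frame, or a named list of data frames / lists.
#' @param path Output path.
#' @param format `"tsv"` (single data frame only) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    stopifnot(is.data.frame(tables))
    num <- vapply(tables, is.numeric, TRUE)
    out <- tables
    out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
    readr::write_tsv(as_tibble(out), path)
  } else {
    jsonlite::write_json(tables, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}
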