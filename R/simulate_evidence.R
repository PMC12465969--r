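# Per-site genotype evidence simulator: turns true trio genotypes into
# VCF-writable candidate sites with read-depth and allele-balance noise.

#' Simulate per-sample genotype evidence for candidate sites
#'
#' For each true-genotype row, draws per-sample read depths from a negative
#' binomial (or constant depth when `noise = FALSE`), allele depths from a
#' Binomial(DP, 0.5) for heterozygotes (exact DP/2 split when noiseless),
#' stray alternate reads in homozygous-reference samples at `error_rate` per
#' read, and a genotype-quality score that decreases with genotype ambiguity.
#'
#' @param truth Tibble with columns `trio_id`, `contig`, `pos`, `ref`, `alt`,
#'   `context3` and per-role true genotypes `gt_offspring`, `gt_sire`,
#'   `gt_dam` (`"0/0"`, `"0/1"`, `"1/1"`).
#' @param depth_mean,depth_dispersion Negative-binomial depth model.
#' @param error_rate Per-read probability of a stray alternate read in a
#'   hom-ref sample (0 when `noise = FALSE`).
#' @param noise Set `FALSE` for deterministic, noiseless evidence.
#' @param seed Optional integer seed.
#' @return Candidate-site tibble in the layout of [read_trio_vcf()].
#' @export
simulate_site_evidence <- function(truth, depth_mean = 43.3,
                                   depth_dispersion = 40,
                                   error_rate = 0.002, noise = TRUE,
                                   seed = NULL) {
  stopifnot(depth_mean >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  out <- as_tibble(truth)
  for (role in c("offspring", "sire", "dam")) {
    gt <- out[[paste0("gt_", role)]]
    dp <- if (noise) {
      pmax(1, rnbinom(n, mu = depth_mean, size = depth_dispersion))
    } else {
      rep(round(depth_mean), n)
    }
    n_alt <- integer(n)
    het <- gt == "0/1"
    hom_alt <- gt == "1/1"
    hom_ref <- gt == "0/0"
    if (noise) {
      n_alt[het] <- rbinom(sum(het), dp[het], 0.5)
      n_alt[hom_ref] <- rbinom(sum(hom_ref), dp[hom_ref], error_rate)
    } else {
      n_alt[het] <- round(dp[het] / 2)
      n_alt[hom_ref] <- 0L
    }
    n_alt[hom_alt] <- dp[hom_alt]
    # GQ heuristic: confident when the minor-allele support is deep (het) or
    # alternate support is absent (hom-ref)
    gq <- integer(n)
    gq[het] <- pmin(99, 10 * pmin(n_alt[het], dp[het] - n_alt[het]))
    gq[hom_ref] <- pmin(99, pmax(0, 2 * dp[hom_ref] - 30 * n_alt[hom_ref]))
    gq[hom_alt] <- pmin(99, 2 * dp[hom_alt])
    out[[paste0("dp_", role)]] <- as.numeric(dp)
    out[[paste0("gq_", role)]] <- as.numeric(gq)
    out[[paste0("ad_ref_", role)]] <- as.numeric(dp - n_alt)
    out[[paste0("ad_alt_", role)]] <- as.numeric(n_alt)
  }
  out %>%
    mutate(filter = "PASS",
           site_id = paste0(.data$contig, ":", .data$pos, ":", .data$ref,
                            ">", .data$alt)) %>%
    select("site_id", dplyr::everything())
}

#' True-genotype rows for a trio's DNMs plus inherited negative sites
#'
#' Builds the truth table consumed by [simulate_site_evidence()]: every DNM of
#' the trio as an offspring-het / parents-hom-ref site, plus `n_negative`
#' inherited polymorphic sites where one parent is heterozygous (which the
#' filter cascade must reject).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param trio_id Trio to extract.
#' @param n_negative Number of inherited (non-DNM) sites to add.
#' @return Truth tibble for [simulate_site_evidence()].
#' @export
trio_truth_sites <- function(cohort, trio_id, n_negative = 0) {
  dn <- filter(cohort$dnms, .data$trio_id == .env$trio_id)
  pos_sites <- tibble(
    trio_id = trio_id, contig = dn$contig, pos = dn$pos, ref = dn$ref,
    alt = dn$alt, context3 = dn$context3,
    gt_offspring = "0/1", gt_sire = "0/0", gt_dam = "0/0", is_dnm = TRUE
  )
  if (n_negative > 0) {
    auto_iv <- merge_intervals(cohort$region_map$intervals[
      cohort$region_map$intervals$label == "AUTOSOME", ])
    pos <- sample_positions(auto_iv, n_negative)
    cls <- sample(MUTATION_CLASSES, n_negative, replace = TRUE)
    al <- draw_alleles(cls)
    het_parent <- sample(c("sire", "dam"), n_negative, replace = TRUE)
    transmitted <- runif(n_negative) < 0.5
    neg <- tibble(
      trio_id = trio_id, contig = pos$contig, pos = pos$pos, ref = al$ref,
      alt = al$alt, context3 = al$context3,
      gt_offspring = if_else(transmitted, "0/1", "0/0"),
      gt_sire = if_else(het_parent == "sire", "0/1", "0/0"),
      gt_dam = if_else(het_parent == "dam", "0/1", "0/0"),
      is_dnm = FALSE
    )
    pos_sites <- bind_rows(pos_sites, neg)
  }
  arrange(pos_sites, .data$contig, .data$pos)
}

#' Write candidate sites as a minimal VCF 4.2 file
#'
#' Emits a plain-text VCF with GT:GQ:DP:AD per sample and the reference
#' context triplet in the INFO field `CTX`, readable by [read_trio_vcf()] (or
#' any VCF 4.x reader). Output is byte-deterministic given its input.
#'
#' @param sites Candidate-site tibble (one trio).
#' @param path Output path.
#' @param sample_names Names for offspring, sire, dam columns.
#' @param contigs Optional contig table (`name`, `length`) for the header.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(sites, path,
                           sample_names = c("offspring", "sire", "dam"),
                           contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=canidnm-simulator",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference triplet context\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">"
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", contigs$name,
                          as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample_names), collapse = "\t"))
  fmt <- function(role) {
    sprintf("%s:%d:%d:%d,%d", sites[[paste0("gt_", role)]],
            as.integer(sites[[paste0("gq_", role)]]),
            as.integer(sites[[paste0("dp_", role)]]),
            as.integer(sites[[paste0("ad_ref_", role)]]),
            as.integer(sites[[paste0("ad_alt_", role)]]))
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tCTX=%s\tGT:GQ:DP:AD\t%s\t%s\t%s",
                  sites$contig, as.integer(sites$pos), sites$ref, sites$alt,
                  ifelse(is.na(sites$filter), "PASS", sites$filter),
                  ifelse(is.na(sites$context3), "NNN", sites$context3),
                  fmt("offspring"), fmt("sire"), fmt("dam"))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
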