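# Genome region model: contigs, labelled interval sets, and per-position
# category lookup. Coordinates are 0-based half-open internally; VCF-style
# 1-based positions are converted at the boundary.

REGION_LABELS <- c("AUTOSOME", "PAR", "X_UNIQUE", "CGI", "HMR_CGI", "NONHMR_CGI")
MUTATION_CLASSES <- c("C>A", "C>G", "C>T", "CpG>TpG", "T>A", "T>C", "T>G")

#' Build a genome region map
#'
#' Assembles the six-category region model used throughout the package:
#' autosomes, the pseudoautosomal region (PAR) and the X-unique remainder of
#' the X chromosome, CpG islands (CGI), sperm-hypomethylated CpG islands
#' (HMR_CGI) and their complement within CGIs (NONHMR_CGI, computed as the set
#' difference CGI minus HMR_CGI).
#'
#' @param contigs Data frame with columns `name` and `length` (bp); the X
#'   chromosome is identified by `x_contig`.
#' @param par,cgi,hmr_cgi Data frames of intervals with columns `contig`,
#'   `start`, `end` (0-based half-open), or `NULL` for none.
#' @param x_contig Name of the X contig; every other contig is autosomal.
#' @return An object of class `region_map`: a list with `contigs`, a tibble of
#'   merged labelled `intervals`, and `x_contig`.
#' @examples
#' rm <- region_map(
#'   contigs = data.frame(name = c("chr1", "chrX"), length = c(1e6, 5e5)),
#'   par = data.frame(contig = "chrX", start = 0, end = 68000)
#' )
#' region_lookup(rm, "chrX", 5)
#' @export
region_map <- function(contigs, par = NULL, cgi = NULL, hmr_cgi = NULL,
                       x_contig = intersect(c("chrX", "X"), contigs$name)[1]) {
  contigs <- as_tibble(contigs)[, c("name", "length")]
  stopifnot(!anyDuplicated(contigs$name), all(contigs$length > 0))
  if (is.na(x_contig)) x_contig <- NA_character_

  check_iv <- function(iv, what) {
    if (is.null(iv) || nrow(iv) == 0) {
      return(tibble(contig = character(), start = numeric(), end = numeric()))
    }
    iv <- as_tibble(iv)[, c("contig", "start", "end")]
    bad <- !iv$contig %in% contigs$name
    if (any(bad)) {
      abort(sprintf("%s: unknown contig '%s' (line %d)", what,
                    iv$contig[bad][1], which(bad)[1]))
    }
    len <- contigs$length[match(iv$contig, contigs$name)]
    over <- iv$end > len | iv$start < 0 | iv$start >= iv$end
    if (any(over)) {
      abort(sprintf("%s: interval outside contig bounds at line %d", what,
                    which(over)[1]))
    }
    iv
  }

  par <- check_iv(par, "PAR")
  if (nrow(par) > 0 && (is.na(x_contig) || any(par$contig != x_contig))) {
    abort("PAR intervals must lie on the X contig")
  }
  cgi <- merge_intervals(check_iv(cgi, "CGI"))
  hmr <- merge_intervals(check_iv(hmr_cgi, "HMR_CGI"))
  if (nrow(hmr) > 0 && nrow(interval_setdiff(hmr, cgi)) > 0) {
    abort("HMR_CGI intervals must be contained in CGI intervals")
  }
  par <- merge_intervals(par)
  nonhmr <- interval_setdiff(cgi, hmr)

  # X_UNIQUE is the X contig minus the PAR; autosomes are whole contigs.
  x_unique <- if (!is.na(x_contig)) {
    interval_setdiff(
      tibble(contig = x_contig, start = 0,
             end = contigs$length[contigs$name == x_contig]),
      par
    )
  } else {
    tibble(contig = character(), start = numeric(), end = numeric())
  }
  auto <- contigs %>%
    filter(is.na(x_contig) | .data$name != x_contig) %>%
    mutate(contig = .data$name, start = 0, end = .data$length) %>%
    select("contig", "start", "end")

  intervals <- bind_rows(
    mutate(auto, label = "AUTOSOME"),
    mutate(par, label = "PAR"),
    mutate(x_unique, label = "X_UNIQUE"),
    mutate(cgi, label = "CGI"),
    mutate(hmr, label = "HMR_CGI"),
    mutate(nonhmr, label = "NONHMR_CGI")
  )
  structure(list(contigs = contigs, intervals = as_tibble(intervals),
                 x_contig = x_contig),
            class = "region_map")
}

#' Read a genome region map from BED files
#'
#' @param bed_paths Named list of BED file paths (0-based half-open) with any
#'   of the names `par`, `cgi`, `hmr_cgi`; missing entries mean "no intervals".
#' @param contig_table Data frame with columns `name`, `length`.
#' @inheritParams region_map
#' @return A [region_map()] object.
#' @export
read_region_map <- function(bed_paths, contig_table,
                            x_contig = intersect(c("chrX", "X"),
                                                 contig_table$name)[1]) {
  get <- function(nm) if (!is.null(bed_paths[[nm]])) read_bed(bed_paths[[nm]])
  region_map(contig_table, par = get("par"), cgi = get("cgi"),
             hmr_cgi = get("hmr_cgi"), x_contig = x_contig)
}

#' Read a BED file of intervals
#'
#' Only the first three columns (contig, start, end; 0-based half-open) are
#' used; track/browser lines are skipped.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    contig = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)),
    end = as.numeric(vapply(parts, `[`, "", 3))
  )
}

#' Write intervals to a BED file
#' @param intervals Tibble with `contig`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  readr::write_tsv(intervals[, c("contig", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

# -- internal interval arithmetic (IRanges-backed) ---------------------------

as_iranges <- function(iv) {
  IRanges::IRanges(start = as.integer(iv$start) + 1L, end = as.integer(iv$end))
}

from_iranges <- function(ir, contig) {
  tibble(contig = contig, start = IRanges::start(ir) - 1,
         end = as.numeric(IRanges::end(ir)))
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv %>%
    group_by(.data$contig) %>%
    dplyr::group_modify(function(d, key) {
      from_iranges(IRanges::reduce(as_iranges(d)), key$contig)[, c("start", "end")]
    }) %>%
    ungroup() %>%
    arrange(.data$contig, .data$start)
}

interval_setdiff <- function(a, b) {
  if (nrow(a) == 0) return(a)
  out <- lapply(unique(a$contig), function(ctg) {
    ia <- as_iranges(a[a$contig == ctg, ])
    ib <- as_iranges(b[b$contig == ctg, , drop = FALSE])
    from_iranges(IRanges::setdiff(ia, ib), ctg)
  })
  arrange(bind_rows(out), .data$contig, .data$start)
}

interval_total_span <- function(iv) {
  if (nrow(iv) == 0) return(0)
  sum(merge_intervals(iv)$end - merge_intervals(iv)$start)
}

in_intervals <- function(contig, pos0, iv) {
  # pos0: 0-based position; iv assumed merged
  if (nrow(iv) == 0) return(rep(FALSE, length(pos0)))
  out <- rep(FALSE, length(pos0))
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    sub <- iv[iv$contig == ctg, , drop = FALSE]
    if (nrow(sub) == 0) next
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = as.integer(pos0[sel]) + 1L, width = 1L),
      as_iranges(sub)
    )
    out[sel] <- hit
  }
  out
}

#' Look up the region category of genomic positions
#'
#' Every position maps to exactly one primary category with precedence
#' PAR > X_UNIQUE > AUTOSOME, plus independent CGI / HMR-CGI membership flags.
#'
#' @param map A [region_map()].
#' @param contig,pos Character and numeric vectors (recycled); `pos` is
#'   0-based by default.
#' @param one_based Set `TRUE` if `pos` is 1-based (e.g. straight from a VCF).
#' @return Tibble with `primary`, `in_cgi`, `in_hmr_cgi`, `in_nonhmr_cgi`.
#' @export
region_lookup <- function(map, contig, pos, one_based = FALSE) {
  stopifnot(inherits(map, "region_map"))
  n <- max(length(contig), length(pos))
  contig <- rep_len(as.character(contig), n)
  pos0 <- rep_len(as.numeric(pos), n) - if (one_based) 1 else 0
  bad <- !contig %in% map$contigs$name
  if (any(bad)) abort(sprintf("unknown contig '%s'", contig[bad][1]))
  iv <- function(lab) map$intervals[map$intervals$label == lab, ]
  is_par <- in_intervals(contig, pos0, iv("PAR"))
  is_xu <- in_intervals(contig, pos0, iv("X_UNIQUE"))
  primary <- if_else(is_par, "PAR", if_else(is_xu, "X_UNIQUE", "AUTOSOME"))
  in_hmr <- in_intervals(contig, pos0, iv("HMR_CGI"))
  in_cgi <- in_intervals(contig, pos0, iv("CGI")) | in_hmr
  tibble(primary = primary, in_cgi = in_cgi, in_hmr_cgi = in_hmr,
         in_nonhmr_cgi = in_cgi & !in_hmr)
}

#' Classify single-nucleotide changes into the seven-class mutational spectrum
#'
#' Classes are strand-collapsed to the pyrimidine strand: C>A, C>G, C>T,
#' CpG>TpG, T>A, T>C, T>G. A C>T change whose pyrimidine-strand context has a
#' 3' G (equivalently a G>A change with a 5' C) is a CpG>TpG transition; the
#' CpG context is recognised on either strand so the classification is
#' invariant under reverse complementation.
#'
#' @param context3 Reference triplet centred on the mutated base (characters
#'   from ACGT).
#' @param ref,alt Reference and alternate alleles (single bases, `alt != ref`,
#'   `ref` must equal the centre of `context3`).
#' @return Character vector of classes, one of
#'   `c("C>A","C>G","C>T","CpG>TpG","T>A","T>C","T>G")`.
#' @examples
#' classify_mutation("ACG", "C", "T") # CpG>TpG
#' classify_mutation("ATA", "A", "G") # T>C (strand collapse of A>G)
#' @export
classify_mutation <- function(context3, ref, alt) {
  n <- max(length(context3), length(ref), length(alt))
  context3 <- toupper(rep_len(context3, n))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  ok <- grepl("^[ACGT]{3}$", context3) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("non-ACGT characters in context/alleles")
  if (any(ref == alt)) abort("ref must differ from alt")
  if (any(substr(context3, 2, 2) != ref)) {
    abort("centre of context3 must equal ref")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyr <- ref %in% c("C", "T")
  p_ref <- if_else(pyr, ref, unname(comp[ref]))
  p_alt <- if_else(pyr, alt, unname(comp[alt]))
  next_base <- if_else(pyr, substr(context3, 3, 3),
                       unname(comp[substr(context3, 1, 1)]))
  cls <- paste0(p_ref, ">", p_alt)
  if_else(cls == "C>T" & next_base == "G", "CpG>TpG", cls)
}

#' Nucleotide composition of region categories
#'
#' Tabulates, for each region category of a [region_map()], the fraction of
#' A/T sites, of C/G sites outside CpG dinucleotides, and of sites inside CpG
#' dinucleotides. These fractions scale callable sizes into per-class
#' mutational opportunities (see [composition_corrected_rates()]).
#'
#' @param region Character vector of region labels.
#' @param frac_at,frac_cg,frac_cpg Fractions summing to 1 within each region.
#' @return A tibble of class `composition_table`.
#' @export
composition_table <- function(region, frac_at, frac_cg, frac_cpg) {
  tab <- tibble(region = region, frac_at = frac_at, frac_cg = frac_cg,
                frac_cpg = frac_cpg)
  tot <- tab$frac_at + tab$frac_cg + tab$frac_cpg
  if (any(abs(tot - 1) > 1e-9)) abort("composition fractions must sum to 1")
  class(tab) <- c("composition_table", class(tab))
  tab
}
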