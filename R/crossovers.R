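# Crossover breakpoint detection from phased informative-marker tracks, and
# DNM-breakpoint proximity with a trio-matched expectation.

#' Detect crossover breakpoints from a phased marker track
#'
#' Markers carry grandparental-origin labels along one chromosome of one
#' parental side. Runs of identical origin shorter than `min_block`
#' consecutive markers are masked as noise (they neither form blocks nor
#' generate breakpoints); adjacent surviving blocks of different origin yield
#' a breakpoint at the midpoint between the last marker of the left block and
#' the first marker of the right block.
#'
#' @param markers Tibble with `pos` (sorted) and `origin` (two labels);
#'   optional grouping columns `trio_id`, `contig`, `parent_side` are carried
#'   through and detected per group.
#' @param min_block Minimum consecutive markers per valid block (default 500).
#' @return Tibble of breakpoints: grouping columns, `breakpoint`, `left_end`,
#'   `right_start`, `left_origin`, `right_origin`.
#' @export
detect_crossovers <- function(markers, min_block = 500) {
  grp <- intersect(c("trio_id", "contig", "parent_side"), names(markers))
  one_track <- function(d, key) {
    d <- arrange(d, .data$pos)
    r <- rle(d$origin)
    keep <- r$lengths >= min_block
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    blocks <- tibble(origin = r$values[keep],
                     first = starts[keep], last = ends[keep])
    if (nrow(blocks) < 2) {
      return(tibble(breakpoint = numeric(), left_end = numeric(),
                    right_start = numeric(), left_origin = character(),
                    right_origin = character()))
    }
    # merge adjacent same-origin blocks that survive masking
    merged <- blocks[1, ]
    for (i in seq_len(nrow(blocks))[-1]) {
      j <- nrow(merged)
      if (blocks$origin[i] == merged$origin[j]) {
        merged$last[j] <- blocks$last[i]
      } else {
        merged <- bind_rows(merged, blocks[i, ])
      }
    }
    if (nrow(merged) < 2) {
      return(tibble(breakpoint = numeric(), left_end = numeric(),
                    right_start = numeric(), left_origin = character(),
                    right_origin = character()))
    }
    i <- seq_len(nrow(merged) - 1)
    left_end <- d$pos[merged$last[i]]
    right_start <- d$pos[merged$first[i + 1]]
    tibble(breakpoint = (left_end + right_start) / 2,
           left_end = left_end, right_start = right_start,
           left_origin = merged$origin[i],
           right_origin = merged$origin[i + 1])
  }
  if (length(grp) == 0) return(one_track(markers))
  markers %>%
    group_by(across(all_of(grp))) %>%
    dplyr::group_modify(one_track) %>%
    ungroup()
}

#' Simulate a phased informative-marker track
#'
#' Places `n_markers` markers uniformly along a chromosome and assigns
#' grandparental origins that switch at the given true crossover positions.
#'
#' @param chrom_length Chromosome length (bp).
#' @param n_markers Number of informative markers.
#' @param crossovers Numeric vector of true crossover positions (bp).
#' @param error_rate Per-marker probability of a flipped origin label.
#' @param seed Optional seed.
#' @return Tibble with `pos`, `origin` (`"GP"`/`"GM"`).
#' @export
simulate_marker_track <- function(chrom_length, n_markers, crossovers,
                                  error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(runif(n_markers, 1, chrom_length))
  phase <- (findInterval(pos, sort(crossovers)) %% 2) == 0
  if (error_rate > 0) phase <- xor(phase, runif(n_markers) < error_rate)
  tibble(pos = pos, origin = if_else(phase, "GP", "GM"))
}

#' DNM proximity to crossover breakpoints
#'
#' Counts DNMs lying within `window_bp` of a breakpoint detected in the same
#' trio (and contig), and compares against the trio-matched expectation under
#' uniform placement: for each trio, its DNM count times the fraction of the
#' genome covered by its breakpoint windows, summed over trios. A
#' cohort-pooled expectation (all DNMs against the pooled window fraction) is
#' reported alongside for transparency. Significance is a one-sided Poisson
#' tail at the trio-matched expectation.
#'
#' @param dnms Tibble with `trio_id`, `contig`, `pos`.
#' @param breakpoints Tibble with `trio_id`, `contig`, `breakpoint`.
#' @param window_bp Window half-width (default 10000).
#' @param genome_size Autosomal genome size (bp).
#' @return One-row tibble: `observed_near`, `expected_near`,
#'   `expected_pooled`, `p`.
#' @export
dnm_crossover_proximity <- function(dnms, breakpoints, window_bp = 10000,
                                    genome_size) {
  max_bp <- if (nrow(breakpoints) == 0) 0 else
    max(table(breakpoints$trio_id))
  if (genome_size <= 2 * window_bp * max_bp) {
    abort("genome_size too small: breakpoint windows saturate the genome")
  }
  hits <- dnms %>%
    inner_join(breakpoints, by = c("trio_id", "contig"),
               relationship = "many-to-many") %>%
    filter(abs(.data$pos - .data$breakpoint) <= window_bp) %>%
    distinct(.data$trio_id, .data$contig, .data$pos)
  per_trio <- dnms %>%
    count(.data$trio_id, name = "n_dnm") %>%
    left_join(count(breakpoints, .data$trio_id, name = "n_bp"),
              by = "trio_id") %>%
    mutate(n_bp = tidyr::replace_na(.data$n_bp, 0L))
  expected <- sum(per_trio$n_dnm * per_trio$n_bp * 2 * window_bp / genome_size)
  expected_pooled <- sum(per_trio$n_dnm) *
    (sum(per_trio$n_bp) / max(1, nrow(per_trio))) * 2 * window_bp / genome_size
  obs <- nrow(hits)
  p <- if (expected == 0) as.numeric(obs == 0) else
    ppois(obs - 1, expected, lower.tail = FALSE)
  tibble(observed_near = obs, expected_near = expected,
         expected_pooled = expected_pooled, p = p)
}
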