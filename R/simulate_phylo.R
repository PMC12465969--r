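# Paired-phylogeny simulator: autosomal and HMR-CGI trees with a
# recombination-regime rate-ratio shift on one branch.

#' Simulate paired autosome / HMR-CGI phylogenies with a rate-ratio shift
#'
#' Starting from a time-calibrated species tree, generates an autosomal tree
#' (branch length = time span x `auto_rate`) and an HMR-CGI tree whose branch
#' lengths equal the autosomal lengths times a rate ratio: `r0` on branches
#' where PRDM9-directed recombination is intact, `r1` on branches descending
#' from the loss, and the time-weighted mixture
#' `(r1 * (t - T_young) + r0 * (T_old - t)) / (T_old - T_young)` on the
#' transition branch where the loss occurs at time `t = loss_time`.
#' Multiplicative lognormal noise (sdlog `noise_sd`) is applied independently
#' to each branch of each tree; `noise_sd = 0` is exact.
#'
#' @param time_tree Ultrametric `ape::phylo`, ages in My.
#' @param r0,r1 Pre-loss and post-loss HMR/autosome rate ratios.
#' @param loss_time Loss time (Mya) inside the transition branch's age span.
#' @param transition_clade Tip labels subtended by the transition branch.
#' @param noise_sd Lognormal sdlog of branch-length noise.
#' @param auto_rate Autosomal substitution rate (subst/site/My).
#' @param seed Optional seed.
#' @return List with `tree_auto`, `tree_hmr` (both `ape::phylo`) and the
#'   per-edge `true_ratio` vector.
#' @export
simulate_ratioed_phylogeny <- function(time_tree, r0 = 1, r1 = 2.21,
                                       loss_time,
                                       transition_clade = c("dog", "awd", "fox"),
                                       noise_sd = 0, auto_rate = 0.002,
                                       seed = NULL) {
  stopifnot(inherits(time_tree, "phylo"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(loss_time)) {
    # loss never occurs: every branch keeps the baseline ratio
    tree_auto <- time_tree
    tree_auto$edge.length <- time_tree$edge.length * auto_rate *
      rlnorm(length(time_tree$edge.length), 0, noise_sd)
    tree_hmr <- tree_auto
    tree_hmr$edge.length <- tree_auto$edge.length * r0 *
      rlnorm(length(time_tree$edge.length), 0, noise_sd)
    return(list(tree_auto = tree_auto, tree_hmr = tree_hmr,
                true_ratio = rep(r0, length(time_tree$edge.length))))
  }
  ages <- node_ages(time_tree)
  clades <- edge_clades(time_tree)
  tkey <- clade_key(transition_clade)
  te <- clades[clades$clade == tkey, ]
  if (nrow(te) != 1) abort("transition clade not found in time tree")
  t_young <- ages[te$child]
  t_old <- t_young + te$length
  if (loss_time < t_young || loss_time > t_old) {
    abort(sprintf("loss_time must lie within the transition branch span [%g, %g]",
                  t_young, t_old))
  }
  tset <- sort(transition_clade)
  ratio <- vapply(seq_len(nrow(clades)), function(e) {
    tips <- strsplit(clades$clade[e], "|", fixed = TRUE)[[1]]
    if (clades$clade[e] == tkey) {
      (r1 * (loss_time - t_young) + r0 * (t_old - loss_time)) /
        (t_old - t_young)
    } else if (all(tips %in% tset)) {
      r1
    } else {
      r0
    }
  }, 0)
  tree_auto <- time_tree
  tree_auto$edge.length <- time_tree$edge.length * auto_rate *
    rlnorm(nrow(clades), 0, noise_sd)
  tree_hmr <- time_tree
  tree_hmr$edge.length <- tree_auto$edge.length * ratio *
    rlnorm(nrow(clades), 0, noise_sd)
  list(tree_auto = tree_auto, tree_hmr = tree_hmr, true_ratio = ratio)
}
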