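#' Binary propensity tree
#'
#' The event-selection structure of the simulator: leaves hold the per-mRNA
#' propensity sums phi_i (plus one leaf for the pool-reaction group), every
#' internal node the sum of its two children, and the root the total
#' propensity Phi. Selecting the leaf eta with cumulative sum exceeding
#' r * Phi, and updating one leaf, both touch only one root-to-leaf path,
#' i.e. ceil(log2 n) + 1 nodes.
#'
#' These functions expose the same implementation the simulation engine
#' uses, for direct inspection and testing.
#'
#' @param phis nonnegative leaf values.
#' @return `phi_tree()` returns a tree object (`nodes`, `n_leaves`,
#'   `padded`).
#' @examples
#' tr <- phi_tree(c(2, 3, 5, 7))
#' phi_tree_root(tr)          # 17
#' phi_tree_select(tr, 0.6)
#' @export
phi_tree <- function(phis) {
  tr <- cpp_tree_build(as.numeric(phis))
  class(tr) <- "phi_tree"
  tr
}

#' @describeIn phi_tree total propensity Phi at the root.
#' @param tree a `phi_tree`.
#' @export
phi_tree_root <- function(tree) tree$nodes[2]

#' @describeIn phi_tree leaf values.
#' @export
phi_tree_leaves <- function(tree)
  tree$nodes[tree$padded + seq_len(tree$n_leaves)]

#' @describeIn phi_tree replace the value of leaf `leaf` (1-based) with
#'   `phi`, repairing the sums along its path. The returned tree carries a
#'   `touched` field: the number of nodes written.
#' @param leaf leaf index (1-based).
#' @param phi new leaf value (>= 0).
#' @export
phi_tree_update <- function(tree, leaf, phi) {
  tr <- cpp_tree_update(unclass(tree), as.integer(leaf), as.numeric(phi))
  class(tr) <- "phi_tree"
  tr
}

#' @describeIn phi_tree select the smallest leaf index eta whose cumulative
#'   sum exceeds `r` times the root total Phi.
#' @param r uniform variate in `[0, 1)`.
#' @export
phi_tree_select <- function(tree, r)
  cpp_tree_select(unclass(tree), as.numeric(r))

#' @export
print.phi_tree <- function(x, ...) {
  cat("Propensity tree:", x$n_leaves, "leaves (padded to", x$padded,
      "), root =", phi_tree_root(x), "\n")
  invisible(x)
}
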