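# Branch bookkeeping on the population phylogeny. Every branch partitions
# the populations into a descendant set (leaves below the branch) and an
# ancestral set (everything above it); the differentiation test scores
# every such partition.

#' Branch table of a rooted population tree
#'
#' One row per testable branch of a rooted phylogeny. Each branch
#' partitions the populations into the set descending from it and the
#' complementary ancestral set. The two branches leaving the root induce
#' the same partition (with the roles of the two sets swapped), so the one
#' with the larger descendant set is suppressed to avoid double counting.
#'
#' @param tree A rooted [ape::phylo].
#' @return A tibble with columns `branch` (id: the population name for
#'   leaf branches, `n<node>` for internal ones), `node` (child node
#'   number in `tree$edge`), `is_leaf`, `n_desc`, `descendants` and
#'   `ancestral` (list-columns of population labels).
#' @export
population_branches <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  tips <- tree$tip.label
  n_tip <- length(tips)
  root <- n_tip + 1L
  edge <- tree$edge
  # leaves below every node
  desc_of <- descendant_tips(tree)
  child <- edge[, 2]
  is_root_child <- edge[, 1] == root
  # among root children, suppress the one with the larger descendant set
  # (tie: the later one in edge order)
  drop <- rep(FALSE, nrow(edge))
  rc <- which(is_root_child)
  if (length(rc) >= 2) {
    sizes <- lengths(desc_of[child[rc]])
    ord <- order(sizes, seq_along(rc))
    drop[rc[ord[-1]]] <- TRUE
    if (length(rc) > 2) {
      warn("root has more than two children; only the smallest root partition is tested")
    }
  }
  keep <- which(!drop)
  nodes <- child[keep]
  desc <- desc_of[nodes]
  tibble::tibble(
    branch = ifelse(nodes <= n_tip, tips[nodes], paste0("n", nodes)),
    node = as.integer(nodes),
    is_leaf = nodes <= n_tip,
    n_desc = lengths(desc),
    descendants = desc,
    ancestral = lapply(desc, function(d) setdiff(tips, d))
  )
}

# List, indexed by node number, of the tip labels below each node.
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  out <- vector("list", n_tip + n_node)
  out[seq_len(n_tip)] <- as.list(tree$tip.label)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    out[[edge[i, 1]]] <- c(out[[edge[i, 1]]], out[[edge[i, 2]]])
  }
  out
}

# branch_a descends from branch_b iff its descendant set is a proper
# subset of branch_b's. Returns a logical matrix [i, j] = i descends from j.
branch_descent_matrix <- function(branches) {
  sets <- branches$descendants
  n <- length(sets)
  m <- matrix(FALSE, n, n, dimnames = list(branches$branch, branches$branch))
  sizes <- lengths(sets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && sizes[i] < sizes[j] && all(sets[[i]] %in% sets[[j]])) {
        m[i, j] <- TRUE
      }
    }
  }
  m
}
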