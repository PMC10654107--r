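# Tree construction/import and strict Robinson-Foulds co-phylogeny.

#' Neighbor-joining tree from a distance matrix
#'
#' Desk-scale tree builder (neighbor joining on a symmetric distance
#' matrix, negative branch lengths clamped to zero). Externally computed
#' maximum-likelihood trees can be imported as Newick with
#' [ape::read.tree()] and used everywhere a tree is accepted.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and
#'   dimnames.
#' @return An [ape::phylo] tree (unrooted).
#' @export
build_nj_tree <- function(distances) {
  d <- as.matrix(distances)
  assert_that(!is.null(rownames(d)), "distance matrix needs dimnames")
  assert_that(max(abs(d - t(d))) <= 1e-9, "distance matrix is not symmetric")
  assert_that(all(abs(diag(d)) <= 1e-12), "distance matrix diagonal must be 0")
  n <- nrow(d)
  assert_that(n >= 3, "need at least 3 taxa")
  if (n == 3) {
    # unique unrooted topology; three-point branch lengths
    ids <- rownames(d)
    b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    txt <- sprintf("(%s:%g,%s:%g,%s:%g);", ids[1], max(b[1], 0),
                   ids[2], max(b[2], 0), ids[3], max(b[3], 0))
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Pairwise evolutionary distances from an alignment
#'
#' Mean per-site mismatch fraction over columns where both rows are
#' ungapped; used to feed [build_nj_tree()] from a hallmark alignment.
#'
#' @param msa A `protein_msa` object.
#' @return Symmetric distance matrix.
#' @export
msa_distances <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != GAP_CHAR & m[j, ] != GAP_CHAR
    d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 1
  }
  d
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as the
# sorted member string of the side not containing the reference leaf.
#' @noRd
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n <- length(tips)
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- labels[p]
    size <- length(side)
    if (size < 2 || size > n - 2) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) < 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Strict Robinson-Foulds value between two trees
#'
#' Both trees are pruned to their shared leaves (suppressing degree-2
#' nodes); `rf` counts the leaf splits implied by only one of the trees
#' (symmetric difference of the non-trivial bipartition sets) and `srfv`
#' normalizes by the total split count of both trees, which equals
#' `2(n - 3)` for two fully resolved trees on `n` leaves. `srfv = 0` for
#' identical topologies, 1 for fully conflicting ones.
#'
#' @param tree_a,tree_b [ape::phylo] trees (leaf-labeled; >= 4 shared
#'   leaves required).
#' @param id_a,id_b Identifiers for reporting.
#' @return One-row tibble of class `srfv_result`: `tree_a`, `tree_b`,
#'   `shared_leaves`, `rf`, `srfv`.
#' @export
srfv <- function(tree_a, tree_b, id_a = "tree_a", id_b = "tree_b") {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  assert_that(length(shared) >= 4, "need >= 4 shared leaves")
  ta <- ape::keep.tip(tree_a, shared)
  tb <- ape::keep.tip(tree_b, shared)
  sa <- tree_splits(ta)
  sb <- tree_splits(tb)
  rf <- length(setdiff(sa, sb)) + length(setdiff(sb, sa))
  denom <- length(sa) + length(sb)
  out <- tibble::tibble(tree_a = id_a, tree_b = id_b,
                        shared_leaves = length(shared), rf = rf,
                        srfv = if (denom == 0) 0 else rf / denom)
  class(out) <- c("srfv_result", class(out))
  out
}

#' All-pairs strict Robinson-Foulds matrix
#'
#' @param trees Named list of [ape::phylo] trees.
#' @return Symmetric numeric matrix of sRFV values (diagonal 0).
#' @export
srfv_matrix <- function(trees) {
  ids <- names(trees)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- srfv(trees[[i]], trees[[j]],
                               ids[i], ids[j])$srfv
  }
  m
}
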