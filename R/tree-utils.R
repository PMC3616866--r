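# Internal helpers around ape's "phylo" representation.
#
# All inference code works on a flat index built once per tree: parent
# pointers, ordered child lists, depths and traversal orders over node ids
# 1..(Ntip + Nnode), with tips first (ape numbering).

#' @keywords internal
#' @noRd
tree_index <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  N <- nt + nn
  parent <- integer(N)
  children <- vector("list", N)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]
    b <- phy$edge[i, 2L]
    children[[a]] <- c(children[[a]], b)
    parent[b] <- a
  }
  root <- which(parent == 0L & seq_len(N) > nt)
  if (length(root) == 0L && nt == 1L) root <- 1L  # single-leaf tree
  label <- character(N)
  label[seq_len(nt)] <- phy$tip.label
  if (!is.null(phy$node.label)) label[nt + seq_len(nn)] <- phy$node.label

  depth <- integer(N)
  # preorder: parent always visited before child
  pre <- integer(N)
  stack <- root
  k <- 0L
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    pre[k] <- v
    if (v != root) depth[v] <- depth[parent[v]] + 1L
    kids <- children[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  pre <- pre[seq_len(k)]
  post <- rev(pre)

  list(phy = phy, n_tip = nt, n_node = N, root = root, parent = parent,
       children = children, label = label, depth = depth,
       preorder = pre, postorder = post)
}

# TRUE where node a is an ancestor of (or equal to) node b
#' @noRd
is_ancestor <- function(ix, a, b) {
  while (TRUE) {
    if (a == b) return(TRUE)
    if (ix$depth[b] <= ix$depth[a]) return(FALSE)
    b <- ix$parent[b]
  }
}

#' @noRd
lca_node <- function(ix, a, b) {
  while (a != b) {
    if (ix$depth[a] > ix$depth[b]) a <- ix$parent[a] else b <- ix$parent[b]
  }
  a
}

# other child of parent(x); NA for the root
#' @noRd
sibling_node <- function(ix, x) {
  p <- ix$parent[x]
  if (p == 0L) return(NA_integer_)
  kids <- ix$children[[p]]
  kids[kids != x]
}

# ancestors of x from x up to the root (inclusive)
#' @noRd
ancestors_incl <- function(ix, x) {
  out <- x
  while (ix$parent[x] != 0L) {
    x <- ix$parent[x]
    out <- c(out, x)
  }
  out
}

# Fill empty internal labels deterministically ("n<k>", k = internal node
# rank) and uniquify; used for species trees so every branch (identified by
# its child node) has a stable name.
#' @noRd
fill_internal_labels <- function(phy) {
  nn <- phy$Nnode
  nt <- length(phy$tip.label)
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", nn)
  empty <- !nzchar(lab)
  lab[empty] <- paste0("n", which(empty))
  lab <- make.unique(c(phy$tip.label, lab), sep = "_")[nt + seq_len(nn)]
  phy$node.label <- lab
  phy
}

#' @noRd
assert_binary <- function(ix, what = "tree") {
  for (v in seq_len(ix$n_node)) {
    k <- length(ix$children[[v]])
    # degenerate single-gene family: a unary root over exactly one leaf
    if (k == 1L && v == ix$root && ix$n_tip == 1L) next
    if (k != 0L && k != 2L) {
      lab <- if (nzchar(ix$label[v])) ix$label[v] else paste0("#", v)
      stop(sprintf(
        "%s is not strictly binary: node %s has %d children (polytomies %s)",
        what, lab, k,
        "must be resolved explicitly, e.g. with resolve_polytomies()"),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}
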