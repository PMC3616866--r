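#' Duplication-loss parsimony reconciliation by LCA mapping
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of the species of its descendant genes, labels each internal
#' gene node as a duplication or a speciation, and places every implied gene
#' loss on the specific species-tree branch where the lineage is absent.
#' The LCA mapping attains the minimum duplication + loss count over all
#' reconciliations (standard duplication-loss parsimony, as popularized by
#' Notung-style analyses).
#'
#' For a gene edge (v, c) whose endpoints map d species-tree edges apart, the
#' edge contributes d losses when v is a duplication and d - 1 when v is a
#' speciation; each loss sits on the branch into the off-path daughter of a
#' species node traversed by the edge.
#'
#' @param family A `"family_data"` object from [bind_family()].
#' @return An object of class `"reconciliation"` with elements
#'   \describe{
#'     \item{M}{integer vector, species-tree node id for every gene node}
#'     \item{event}{`"duplication"`/`"speciation"` for internal gene nodes,
#'       `"leaf"` for tips}
#'     \item{losses}{data.frame, one row per loss: `species_branch` (label of
#'       the child species node identifying the branch), `gene_parent`,
#'       `gene_child` (gene node ids of the contributing edge)}
#'     \item{dup_count, loss_count}{event totals}
#'   }
#' @examples
#' fd <- bind_family("(a1,(a2,b1));", "(A,B);",
#'                   data.frame(gene_id = c("a1", "a2", "b1"),
#'                              species_id = c("A", "A", "B"),
#'                              architecture = "SPLIT"))
#' reconcile(fd)
#' @seealso [infer_states()], [branch_ledger()], [date_event()]
#' @export
reconcile <- function(family) {
  stopifnot(inherits(family, "family_data"))
  gi <- family$gi
  si <- family$si
  N <- gi$n_node
  M <- integer(N)
  event <- rep(NA_character_, N)

  for (v in gi$postorder) {
    kids <- gi$children[[v]]
    if (!length(kids)) {
      M[v] <- family$species_of[[gi$label[v]]]
      event[v] <- "leaf"
    } else if (length(kids) == 1L) {
      # unary root of a single-gene family: not an event
      M[v] <- M[kids[1L]]
      event[v] <- "unary"
    } else {
      M[v] <- lca_node(si, M[kids[1L]], M[kids[2L]])
      event[v] <- if (M[v] == M[kids[1L]] || M[v] == M[kids[2L]])
        "duplication" else "speciation"
    }
  }

  loss_branch <- integer(0)
  loss_gp <- integer(0)
  loss_gc <- integer(0)
  for (c0 in seq_len(N)) {
    v <- gi$parent[c0]
    if (v == 0L) next
    d <- si$depth[M[c0]] - si$depth[M[v]]
    k <- if (event[v] == "duplication") d else d - 1L
    if (k <= 0L) next
    # climb from M(c) towards M(v); off-path daughters are the losses
    x <- M[c0]
    for (i in seq_len(k)) {
      loss_branch <- c(loss_branch, sibling_node(si, x))
      loss_gp <- c(loss_gp, v)
      loss_gc <- c(loss_gc, c0)
      x <- si$parent[x]
    }
  }
  losses <- data.frame(
    species_branch = si$label[loss_branch],
    gene_parent = loss_gp, gene_child = loss_gc,
    stringsAsFactors = FALSE)

  structure(list(M = M, event = event, losses = losses,
                 dup_count = sum(event == "duplication", na.rm = TRUE),
                 loss_count = nrow(losses),
                 family = family),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf(
    "Reconciliation: %d gene leaves on %d species; %d duplications, %d losses\n",
    x$family$gi$n_tip, x$family$si$n_tip, x$dup_count, x$loss_count))
  invisible(x)
}

#' Date a reconciled gene-tree node onto the species tree
#'
#' Dating is categorical: a duplication mapping to species node s happened on
#' the species branch entering s (for s the species root, on the "stem", a
#' virtual branch above the root — "in the common ancestor" of all sampled
#' species); a speciation node is dated exactly to its species node, not to a
#' branch.
#'
#' @param reconciliation A `"reconciliation"` object.
#' @param node Gene-tree node id (integer) or leaf label.
#' @return A list with `kind` (`"branch"` for duplications/leaves,
#'   `"node"` for speciations), and `species` (the species-node label;
#'   `"stem"` for the pre-root branch).
#' @export
date_event <- function(reconciliation, node) {
  rec <- reconciliation
  gi <- rec$family$gi
  si <- rec$family$si
  if (is.character(node)) {
    node <- match(node, gi$label)
    if (is.na(node)) stop("unknown gene node label", call. = FALSE)
  }
  s <- rec$M[node]
  if (rec$event[node] == "speciation")
    return(list(kind = "node", species = si$label[s]))
  list(kind = "branch", species = branch_name(si, s))
}

# branch into species node s, named by its child node; stem above the root
#' @noRd
branch_name <- function(si, s) {
  if (s == si$root) "stem" else si$label[s]
}

#' Render a reconciled gene tree as annotated newick
#'
#' Internal nodes are labelled `D` (duplication) or `S` (speciation), a
#' conventional rendering of reconciled trees.
#'
#' @param reconciliation A `"reconciliation"` object.
#' @return A newick string.
#' @export
reconciled_newick <- function(reconciliation) {
  rec <- reconciliation
  phy <- rec$family$gene_tree
  nt <- length(phy$tip.label)
  ev <- rec$event[(nt + 1L):rec$family$gi$n_node]
  phy$node.label <- ifelse(ev == "duplication", "D", "S")
  write_newick(phy)
}
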