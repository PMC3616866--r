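#' Number of gene lineages crossing a speciation
#'
#' Counts the gene lineages present at an internal species-tree node s: gene
#' edges (p, c) — including a virtual edge above the gene root — such that p
#' predates the speciation at s (maps strictly above s, or to s as a
#' duplication, since a duplication mapped to s happened on the branch into
#' s) and c does not (maps to s as a speciation, or strictly below s).
#' This is the "common ancestor" count whose branch-wise arithmetic
#' count(s) = count(parent) + gains - losses the ledger enforces.
#'
#' @param reconciliation A `"reconciliation"`.
#' @param species Internal species-tree node, by label or node id.
#' @return Integer count.
#' @export
ancestor_count <- function(reconciliation, species) {
  rec <- reconciliation
  si <- rec$family$si
  s <- resolve_species_node(si, species)
  if (!length(si$children[[s]]))
    stop("ancestor counts are defined at speciations; '", si$label[s],
         "' is a terminal species", call. = FALSE)
  length(crossing_edges(rec, s)$child)
}

#' @noRd
parent_labels <- function(si, nodes) {
  vapply(nodes, function(s)
    if (s == si$root) NA_character_ else si$label[si$parent[s]],
    NA_character_)
}

#' @noRd
resolve_species_node <- function(si, species) {
  if (is.character(species)) {
    s <- match(species, si$label)
    if (is.na(s)) stop("unknown species-tree node: ", species, call. = FALSE)
    return(s)
  }
  s <- as.integer(species)
  if (is.na(s) || s < 1L || s > si$n_node)
    stop("species node id out of range", call. = FALSE)
  s
}

# gene edges crossing the speciation at internal species node s;
# parent 0 encodes the virtual edge above the gene root
#' @noRd
crossing_edges <- function(rec, s) {
  gi <- rec$family$gi
  si <- rec$family$si
  M <- rec$M
  strictly_below <- function(x) x != s && is_ancestor(si, s, x)
  predates <- function(p) {
    x <- M[p]
    (x != s && is_ancestor(si, x, s)) ||
      (x == s && rec$event[p] == "duplication")
  }
  ends_at_or_below <- function(c0) {
    x <- M[c0]
    (x == s && rec$event[c0] != "duplication") || strictly_below(x)
  }
  parent <- integer(0)
  child <- integer(0)
  # virtual root edge: the family enters from the stem, so it crosses every
  # speciation at or above the gene root's mapping
  r <- gi$root
  if (is_ancestor(si, s, M[r]) && ends_at_or_below(r)) {
    parent <- 0L
    child <- r
  }
  for (c0 in seq_len(gi$n_node)) {
    p <- gi$parent[c0]
    if (p == 0L) next
    if (predates(p) && ends_at_or_below(c0)) {
      parent <- c(parent, p)
      child <- c(child, c0)
    }
  }
  list(parent = parent, child = child)
}

# architecture class of each crossing at s: the state changes on an edge are
# dated to the branch into M(child), so a crossing is already in the child
# state iff the child maps exactly to s
#' @noRd
crossing_classes <- function(rec, s, state) {
  cr <- crossing_edges(rec, s)
  vapply(seq_along(cr$child), function(i) {
    c0 <- cr$child[i]
    p <- cr$parent[i]
    if (rec$M[c0] == s || p == 0L) state[c0] else state[p]
  }, "")
}

#' Per-branch evolutionary ledger
#'
#' Builds the full bookkeeping table of the reconciled, architecture-labelled
#' family: for every species-tree branch (identified by its child node; the
#' root row is the pre-root "stem") the duplications (gains), losses, fusion
#' and fission events dated to it, split by architecture class, and the
#' lineage count at the child node (ancestor count at speciations, extant
#' gene count at terminal species).
#'
#' Both bookkeeping identities are verified as an internal audit and any
#' violation is an error, never a silently returned table:
#' \itemize{
#'   \item `count(s) = count(parent(s)) + gains - losses` on every branch;
#'   \item class-wise, FUSED additionally changes by `+fusions - fissions`
#'     (SPLIT symmetrically).
#' }
#'
#' When the gene root maps below the species root, the family is carried as a
#' single stem lineage through the earlier speciations and one implied loss
#' is placed on each off-path branch (these implied losses appear only here,
#' not in `reconciliation$loss_count`).
#'
#' @param reconciliation A `"reconciliation"`.
#' @param assignment The matching `"arch_assignment"`.
#' @return A data.frame of class `"branch_ledger"`, one row per species node
#'   in species-tree preorder, with columns `node`, `parent`, `terminal`,
#'   `gains`, `losses`, `fusions`, `fissions`, `gains_fused`, `gains_split`,
#'   `losses_fused`, `losses_split`, `count`, `count_fused`, `count_split`.
#' @export
branch_ledger <- function(reconciliation, assignment) {
  rec <- reconciliation
  stopifnot(inherits(rec, "reconciliation"),
            inherits(assignment, "arch_assignment"))
  gi <- rec$family$gi
  si <- rec$family$si
  state <- assignment$state
  nodes <- si$preorder
  n <- length(nodes)
  led <- data.frame(
    node = si$label[nodes],
    parent = parent_labels(si, nodes),
    terminal = vapply(nodes, function(s) !length(si$children[[s]]), TRUE),
    gains = 0L, losses = 0L, fusions = 0L, fissions = 0L,
    gains_fused = 0L, gains_split = 0L,
    losses_fused = 0L, losses_split = 0L,
    count = 0L, count_fused = 0L, count_split = 0L,
    stringsAsFactors = FALSE)
  rowid <- function(s) match(s, nodes)

  # gains: duplications dated to the branch entering their mapped node
  for (v in seq_len(gi$n_node)) {
    if (is.na(rec$event[v]) || rec$event[v] != "duplication") next
    i <- rowid(rec$M[v])
    led$gains[i] <- led$gains[i] + 1L
    cls <- if (state[v] == "FUSED") "gains_fused" else "gains_split"
    led[[cls]][i] <- led[[cls]][i] + 1L
  }

  # losses, classed by the state of the gene edge's parent end
  if (nrow(rec$losses)) {
    for (k in seq_len(nrow(rec$losses))) {
      i <- rowid(match(rec$losses$species_branch[k], si$label))
      led$losses[i] <- led$losses[i] + 1L
      cls <- if (state[rec$losses$gene_parent[k]] == "FUSED")
        "losses_fused" else "losses_split"
      led[[cls]][i] <- led[[cls]][i] + 1L
    }
  }
  # implied stem-path losses when the gene root maps below the species root
  x <- rec$M[gi$root]
  root_state <- state[gi$root]
  while (x != si$root) {
    sib <- sibling_node(si, x)
    i <- rowid(sib)
    led$losses[i] <- led$losses[i] + 1L
    cls <- if (root_state == "FUSED") "losses_fused" else "losses_split"
    led[[cls]][i] <- led[[cls]][i] + 1L
    x <- si$parent[x]
  }

  # fusion/fission events dated by call_events
  ev <- assignment$events
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      s <- if (ev$species_branch[k] == "stem") si$root
           else match(ev$species_branch[k], si$label)
      i <- rowid(s)
      col <- if (ev$kind[k] == "fusion") "fusions" else "fissions"
      led[[col]][i] <- led[[col]][i] + 1L
    }
  }

  # lineage counts at nodes
  for (j in seq_len(n)) {
    s <- nodes[j]
    if (led$terminal[j]) {
      here <- which(rec$family$species_of == s)
      led$count[j] <- length(here)
      led$count_fused[j] <- sum(rec$family$arch_of[here] == "FUSED")
      led$count_split[j] <- sum(rec$family$arch_of[here] == "SPLIT")
    } else {
      cls <- crossing_classes(rec, s, state)
      led$count[j] <- length(cls)
      led$count_fused[j] <- sum(cls == "FUSED")
      led$count_split[j] <- sum(cls == "SPLIT")
    }
  }

  audit_ledger(led, root_state)
  class(led) <- c("branch_ledger", "data.frame")
  led
}

#' @noRd
audit_ledger <- function(led, root_state) {
  for (j in seq_len(nrow(led))) {
    if (is.na(led$parent[j])) {
      above <- 1L
      above_f <- as.integer(root_state == "FUSED")
    } else {
      i <- match(led$parent[j], led$node)
      above <- led$count[i]
      above_f <- led$count_fused[i]
    }
    above_s <- above - above_f
    ok_total <- led$count[j] == above + led$gains[j] - led$losses[j]
    ok_fused <- led$count_fused[j] ==
      above_f + led$gains_fused[j] - led$losses_fused[j] +
      led$fusions[j] - led$fissions[j]
    ok_split <- led$count_split[j] ==
      above_s + led$gains_split[j] - led$losses_split[j] -
      led$fusions[j] + led$fissions[j]
    if (!(ok_total && ok_fused && ok_split) ||
        any(unlist(led[j, c("count", "count_fused", "count_split")]) < 0L))
      stop("internal audit failure: bookkeeping identity violated on the ",
           "branch into '", led$node[j], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.branch_ledger <- function(x, ...) {
  cat("Branch ledger (", nrow(x), " species branches):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Genome-size-normalized family expansion ratio
#'
#' Ratio of per-genome gene-family densities,
#' `(count_a / genome_size_a) / (count_ref / genome_size_ref)`: how many
#' times larger the family is in genome a than in the reference, after
#' normalizing by genome size. Genome sizes must be user-supplied (any
#' common unit; the ratio is invariant under rescaling both by the same
#' factor).
#'
#' @param count_a,count_ref Gene counts (the reference count must be > 0).
#' @param genome_size_a,genome_size_ref Positive genome sizes.
#' @return Numeric ratio.
#' @examples
#' expansion_ratio(129, 7, 389, 480)  # rice vs moss, Mb assembly sizes
#' @export
expansion_ratio <- function(count_a, count_ref, genome_size_a,
                            genome_size_ref) {
  if (!is.numeric(genome_size_a) || !is.numeric(genome_size_ref) ||
      genome_size_a <= 0 || genome_size_ref <= 0)
    stop("genome sizes must be positive", call. = FALSE)
  if (count_ref <= 0)
    stop("reference count must be positive", call. = FALSE)
  (count_a / genome_size_a) / (count_ref / genome_size_ref)
}
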