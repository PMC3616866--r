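#' Event cost model
#'
#' Unit costs for every event class, following the equal-cost convention:
#' duplication, loss, speciation, fusion and fission all default to 1, so a
#' node at which both a fusion (or fission) and a duplication (or speciation)
#' occur carries a total cost of 2.
#'
#' Under a fixed reconciliation the duplication/speciation/loss part of the
#' cost is a constant; ancestral-state optimization only ever trades
#' `fusion` against `fission`. The full sum is still reported so the
#' per-node accounting stays visible.
#'
#' @param dup,loss,speciation,fusion,fission Non-negative event costs.
#' @return An object of class `"fuserec_costs"`.
#' @export
fuserec_costs <- function(dup = 1, loss = 1, speciation = 1,
                          fusion = 1, fission = 1) {
  x <- list(dup = dup, loss = loss, speciation = speciation,
            fusion = fusion, fission = fission)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("cost '", nm, "' must be a single non-negative number",
           call. = FALSE)
  }
  structure(x, class = "fuserec_costs")
}

#' @export
print.fuserec_costs <- function(x, ...) {
  cat("Event costs:",
      paste(names(x), unlist(x), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

ARCH_STATES <- c("SPLIT", "FUSED")

# transition cost matrix rows = parent state, cols = child state
#' @noRd
trans_matrix <- function(costs) {
  matrix(c(0, costs$fission, costs$fusion, 0), 2L, 2L,
         dimnames = list(ARCH_STATES, ARCH_STATES))
}

#' Infer minimum-cost ancestral architectures
#'
#' Reconstructs the FUSED/SPLIT architecture of every ancestral node of a
#' reconciled gene tree by exact weighted two-state parsimony (Sankoff
#' dynamic programming): an upward pass accumulates, for each node and each
#' state, the minimum cost of its subtree given edge transition costs
#' (`fusion` for SPLIT to FUSED, `fission` for FUSED to SPLIT); a downward
#' pass then selects states. The returned assignment is guaranteed to attain
#' the minimum total cost over all possible ancestral-state maps under the
#' given reconciliation.
#'
#' Ties are broken deterministically and configurably: at the root by
#' `root_pref` (default SPLIT, on the rationale that kinase-only split
#' proteins are the ancestral architecture and fusions, not fissions, create
#' composite receptor kinases); below the root a tied node inherits its
#' parent's selected state (minimizing spurious boundaries) unless
#' `child_tie` forces a state.
#'
#' @param reconciliation A `"reconciliation"` object from [reconcile()].
#' @param costs A [fuserec_costs()] object.
#' @param root_pref State preferred at the root on a cost tie:
#'   `"SPLIT"` or `"FUSED"`.
#' @param child_tie `"parent"` (default: inherit the parent state on a tie)
#'   or a fixed state `"SPLIT"`/`"FUSED"`.
#' @return An object of class `"arch_assignment"`:
#'   \describe{
#'     \item{state}{character vector over gene nodes}
#'     \item{events}{data.frame of called fusion/fission events
#'       (`kind`, `gene_node`, `gene_label`, `species_branch`), sorted by
#'       species-tree preorder then gene node id}
#'     \item{transition_cost, base_cost, total_cost}{cost decomposition;
#'       `base_cost` covers duplications, speciations and losses}
#'   }
#' @examples
#' fd <- bind_family("(((g1,g2),g3),g4);", "(A,B);",
#'                   data.frame(gene_id = paste0("g", 1:4),
#'                              species_id = c("A", "B", "A", "B"),
#'                              architecture = c("FUSED", "FUSED",
#'                                               "SPLIT", "SPLIT")))
#' infer_states(reconcile(fd))
#' @export
infer_states <- function(reconciliation, costs = fuserec_costs(),
                         root_pref = c("SPLIT", "FUSED"),
                         child_tie = c("parent", "SPLIT", "FUSED")) {
  rec <- reconciliation
  stopifnot(inherits(rec, "reconciliation"))
  if (!inherits(costs, "fuserec_costs")) costs <- do.call(fuserec_costs, costs)
  root_pref <- match.arg(root_pref)
  child_tie <- match.arg(child_tie)
  gi <- rec$family$gi
  N <- gi$n_node
  tr <- trans_matrix(costs)

  up <- matrix(Inf, N, 2L)  # cols follow ARCH_STATES
  for (v in gi$postorder) {
    kids <- gi$children[[v]]
    if (!length(kids)) {
      st <- rec$family$arch_of[[gi$label[v]]]
      if (is.null(st) || is.na(st))
        stop("missing architecture state for leaf ", gi$label[v],
             call. = FALSE)
      up[v, match(st, ARCH_STATES)] <- 0
    } else {
      for (s in 1:2)
        up[v, s] <- sum(vapply(
          kids, function(k) min(tr[s, ] + up[k, ]), 0))
    }
  }

  state_i <- integer(N)
  pick_tie <- function(cands, parent_state) {
    if (length(cands) == 1L) return(cands)
    if (child_tie == "parent") {
      if (parent_state %in% cands) return(parent_state)
      return(match("SPLIT", ARCH_STATES))  # residual tie
    }
    match(child_tie, ARCH_STATES)
  }
  r <- gi$root
  root_cands <- which(up[r, ] == min(up[r, ]))
  state_i[r] <- if (length(root_cands) == 1L) root_cands else
    match(root_pref, ARCH_STATES)
  for (v in gi$preorder) {
    if (v == r) next
    p <- gi$parent[v]
    w <- tr[state_i[p], ] + up[v, ]
    state_i[v] <- pick_tie(which(w == min(w)), state_i[p])
  }
  state <- ARCH_STATES[state_i]

  assignment <- structure(
    list(state = state, transition_cost = min(up[r, ]),
         reconciliation = rec, costs = costs,
         root_pref = root_pref, child_tie = child_tie),
    class = "arch_assignment")
  assignment$events <- call_events(assignment)
  assignment$base_cost <-
    costs$dup * rec$dup_count +
    costs$speciation * sum(rec$event == "speciation", na.rm = TRUE) +
    costs$loss * rec$loss_count
  assignment$total_cost <- assignment$base_cost + assignment$transition_cost
  # audit: the DP optimum must equal a first-principles recount
  audit <- assignment_cost(assignment$state, rec, costs)
  if (abs(audit - assignment$total_cost) > 1e-9)
    stop("internal audit failure: recomputed cost ", audit,
         " != DP cost ", assignment$total_cost, call. = FALSE)
  assignment
}

#' Call and date fusion/fission events from a state assignment
#'
#' A fusion is called on every gene-tree edge whose parent is SPLIT and
#' child FUSED (a fission for the reverse), attached to the child node — the
#' earliest ancestor showing the new architecture — and dated to the species
#' branch entering that node's species mapping (the stem for the species
#' root), the same categorical convention as [date_event()].
#'
#' @param assignment An `"arch_assignment"` (its stored reconciliation is
#'   used).
#' @return data.frame of events sorted by species-tree preorder then gene
#'   node id: `kind` (`"fusion"`/`"fission"`), `gene_node`, `gene_label`,
#'   `species_branch`.
#' @export
call_events <- function(assignment) {
  rec <- assignment$reconciliation
  gi <- rec$family$gi
  si <- rec$family$si
  state <- assignment$state
  kind <- character(0)
  node <- integer(0)
  for (c0 in seq_len(gi$n_node)) {
    p <- gi$parent[c0]
    if (p == 0L) next
    if (state[p] == state[c0]) next
    kind <- c(kind, if (state[c0] == "FUSED") "fusion" else "fission")
    node <- c(node, c0)
  }
  branch <- vapply(node, function(v) branch_name(si, rec$M[v]), "")
  # species-tree preorder rank; the stem precedes everything
  prank <- match(rec$M[node], si$preorder)
  prank[branch == "stem"] <- 0L
  o <- order(prank, node)
  data.frame(kind = kind[o], gene_node = node[o],
             gene_label = gi$label[node[o]],
             species_branch = branch[o], stringsAsFactors = FALSE)
}

#' Recompute the total cost of a state assignment from first principles
#'
#' Independent auditor for [infer_states()]: walks every gene-tree edge and
#' node, summing duplication/speciation/loss base costs and fusion/fission
#' transition costs for an arbitrary (not necessarily optimal) state map.
#'
#' @param state Character vector of `"FUSED"`/`"SPLIT"` over gene-tree nodes
#'   (ape numbering), or an `"arch_assignment"`.
#' @param reconciliation A `"reconciliation"`.
#' @param costs A [fuserec_costs()] object.
#' @return The total cost (numeric scalar).
#' @export
assignment_cost <- function(state, reconciliation, costs = fuserec_costs()) {
  if (inherits(state, "arch_assignment")) state <- state$state
  rec <- reconciliation
  gi <- rec$family$gi
  if (length(state) != gi$n_node)
    stop("state vector length does not match the gene tree", call. = FALSE)
  for (v in seq_len(gi$n_node)) {
    if (length(gi$children[[v]])) next
    if (state[v] != rec$family$arch_of[[gi$label[v]]])
      stop("assignment contradicts the annotated state of leaf ",
           gi$label[v], call. = FALSE)
  }
  tr <- trans_matrix(costs)
  total <- costs$dup * rec$dup_count +
    costs$speciation * sum(rec$event == "speciation", na.rm = TRUE) +
    costs$loss * rec$loss_count
  for (c0 in seq_len(gi$n_node)) {
    p <- gi$parent[c0]
    if (p == 0L) next
    total <- total + tr[state[p], state[c0]]
  }
  total
}

#' @export
print.arch_assignment <- function(x, ...) {
  ev <- table(factor(x$events$kind, c("fusion", "fission")))
  cat(sprintf(
    "Ancestral architectures: root %s; %d fusion(s), %d fission(s); total cost %g\n",
    x$state[x$reconciliation$family$gi$root], ev[["fusion"]],
    ev[["fission"]], x$total_cost))
  invisible(x)
}
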