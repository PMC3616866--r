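#' Fit the joint duplication-loss / fusion-fission model to a gene family
#'
#' One-call pipeline: binds and validates the inputs ([bind_family()]),
#' reconciles the gene tree against the species tree by duplication-loss
#' parsimony ([reconcile()]), reconstructs minimum-cost ancestral
#' architectures and calls dated fusion/fission events ([infer_states()]),
#' and assembles the audited per-branch ledger ([branch_ledger()]).
#'
#' @param gene_tree,species_tree Rooted binary trees: `"phylo"` objects,
#'   newick strings, or file paths.
#' @param annotations Leaf annotation table (data.frame or TSV path) with
#'   columns `gene_id`, `species_id`, `architecture`.
#' @param costs A [fuserec_costs()] cost model.
#' @param root_pref,child_tie Tie-break policy, see [infer_states()].
#' @return An object of class `"fuserec"` with elements `family`,
#'   `reconciliation`, `assignment`, `events` (the dated fusion/fission
#'   table), `ledger`, `costs` and `call`.
#' @examples
#' fam <- srlk_coarse_family()
#' fit <- fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
#' fit
#' summary(fit)
#' @export
fuserec <- function(gene_tree, species_tree, annotations,
                    costs = fuserec_costs(),
                    root_pref = c("SPLIT", "FUSED"),
                    child_tie = c("parent", "SPLIT", "FUSED")) {
  fd <- bind_family(gene_tree, species_tree, annotations)
  rec <- reconcile(fd)
  asg <- infer_states(rec, costs = costs,
                      root_pref = match.arg(root_pref),
                      child_tie = match.arg(child_tie))
  led <- branch_ledger(rec, asg)
  structure(list(family = fd, reconciliation = rec, assignment = asg,
                 events = asg$events, ledger = led, costs = asg$costs,
                 call = match.call()),
            class = "fuserec")
}

#' @export
print.fuserec <- function(x, ...) {
  fd <- x$family
  nf <- sum(x$events$kind == "fusion")
  ns <- sum(x$events$kind == "fission")
  cat("Gene-family reconciliation with architecture inference\n")
  cat(sprintf("  %d genes over %d species (%d FUSED, %d SPLIT leaves)\n",
              fd$gi$n_tip, fd$si$n_tip,
              sum(fd$arch_of == "FUSED"), sum(fd$arch_of == "SPLIT")))
  cat(sprintf("  duplications: %d   losses: %d   fusions: %d   fissions: %d\n",
              x$reconciliation$dup_count, x$reconciliation$loss_count,
              nf, ns))
  cat(sprintf("  total parsimony cost: %g\n", x$assignment$total_cost))
  invisible(x)
}

#' @export
summary.fuserec <- function(object, ...) {
  structure(list(fit = object), class = "summary.fuserec")
}

#' @export
print.summary.fuserec <- function(x, ...) {
  print(x$fit)
  ev <- x$fit$events
  if (nrow(ev)) {
    cat("\nDated fusion/fission events (species branch = child node; ",
        "'stem' = above the species root):\n", sep = "")
    print.data.frame(ev, row.names = FALSE)
  } else {
    cat("\nNo fusion or fission events called.\n")
  }
  cat("\n")
  print(x$fit$ledger)
  invisible(x)
}

#' Plot a fitted gene family
#'
#' Draws the gene tree with tips coloured by architecture (FUSED filled,
#' SPLIT open), duplication nodes marked with squares and fusion/fission
#' edges flagged.
#'
#' @param x A `"fuserec"` fit.
#' @param cex Character expansion for tip labels.
#' @param ... Passed on to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.fuserec <- function(x, cex = 0.7, ...) {
  fd <- x$family
  phy <- fd$gene_tree
  st <- x$assignment$state
  nt <- fd$gi$n_tip
  ape::plot.phylo(phy, cex = cex, no.margin = TRUE, ...)
  tipcol <- ifelse(st[seq_len(nt)] == "FUSED", "black", "white")
  ape::tiplabels(pch = 21, bg = tipcol, cex = 0.9)
  dup <- which(x$reconciliation$event == "duplication")
  if (length(dup))
    ape::nodelabels(node = dup, pch = 15, col = "firebrick", cex = 0.8)
  if (nrow(x$events))
    ape::nodelabels(node = x$events$gene_node,
                    pch = ifelse(x$events$kind == "fusion", 24, 25),
                    bg = "gold", cex = 1)
  invisible(x)
}

#' Export a fit as JSON-ready report structures
#'
#' @param fit A `"fuserec"` fit.
#' @return A list (node maps, event labels, per-branch losses, states,
#'   events, ledger, costs) directly serializable with jsonlite.
#' @export
fit_report <- function(fit) {
  rec <- fit$reconciliation
  gi <- rec$family$gi
  si <- rec$family$si
  node_id <- ifelse(nzchar(gi$label), gi$label,
                    paste0("#", seq_len(gi$n_node)))
  list(
    n_genes = gi$n_tip,
    species = si$phy$tip.label,
    mapping = stats::setNames(as.list(si$label[rec$M]), node_id),
    event = stats::setNames(as.list(rec$event), node_id),
    state = stats::setNames(as.list(fit$assignment$state), node_id),
    dup_count = rec$dup_count,
    loss_count = rec$loss_count,
    losses_per_branch = as.list(table(rec$losses$species_branch)),
    events = fit$events,
    total_cost = fit$assignment$total_cost,
    costs = unclass(fit$costs),
    ledger = as.data.frame(fit$ledger))
}
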