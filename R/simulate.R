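#' Simulation parameters for a birth-death gene family
#'
#' Defines a continuous-time Markov gene-family process along a dated
#' species tree: per lineage and per unit branch length, duplication at rate
#' `rate_dup` (copies the lineage in place), loss at `rate_loss` (terminates
#' it), fusion at `rate_fusion` (flips a SPLIT lineage to FUSED) and fission
#' at `rate_fission` (FUSED to SPLIT). At every speciation each surviving
#' lineage is copied into both daughter branches. Event waiting times are
#' exponential (Gillespie), so simultaneous events have probability zero.
#'
#' @param species_tree Rooted binary `"phylo"` species tree with
#'   non-negative branch lengths (time units).
#' @param rate_dup,rate_loss,rate_fusion,rate_fission Non-negative rates per
#'   lineage per unit time.
#' @param n_root_lineages Number of independent lineages at the species
#'   root (joined into a single binary gene root by stem nodes, which the
#'   truth log records as `n_root_lineages - 1` stem duplications).
#' @param root_state `"SPLIT"` (default) or `"FUSED"`, recycled across root
#'   lineages; or a vector of length `n_root_lineages`.
#' @param seed Integer; fully determines the simulation output.
#' @return An object of class `"sim_params"`.
#' @seealso [simulate_family()], [srlk_species_tree()]
#' @export
sim_params <- function(species_tree, rate_dup = 0.2, rate_loss = 0.1,
                       rate_fusion = 0.05, rate_fission = 0.02,
                       n_root_lineages = 1L, root_state = "SPLIT",
                       seed = 1L) {
  species_tree <- as_tree(species_tree)
  species_tree <- fill_internal_labels(species_tree)
  si <- tree_index(species_tree)
  assert_binary(si, "species tree")
  if (is.null(species_tree$edge.length))
    stop("species tree needs branch lengths (time units)", call. = FALSE)
  if (any(species_tree$edge.length < 0))
    stop("negative branch length in species tree", call. = FALSE)
  rates <- c(rate_dup = rate_dup, rate_loss = rate_loss,
             rate_fusion = rate_fusion, rate_fission = rate_fission)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be finite and non-negative", call. = FALSE)
  n_root_lineages <- as.integer(n_root_lineages)
  if (is.na(n_root_lineages) || n_root_lineages < 1L)
    stop("n_root_lineages must be a positive integer", call. = FALSE)
  root_state <- toupper(root_state)
  if (!all(root_state %in% ARCH_STATES))
    stop("root_state must be FUSED or SPLIT", call. = FALSE)
  root_state <- rep_len(root_state, n_root_lineages)
  structure(list(species_tree = species_tree, si = si,
                 rate_dup = rate_dup, rate_loss = rate_loss,
                 rate_fusion = rate_fusion, rate_fission = rate_fission,
                 n_root_lineages = n_root_lineages, root_state = root_state,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a gene family with ground truth
#'
#' Runs the process described in [sim_params()] and returns the surviving
#' gene tree, its leaf annotations (in the exact formats [bind_family()]
#' consumes), the complete event log (including events inside fully extinct
#' subtrees, which reconciliation can at best infer as losses) and the
#' ground-truth per-branch ledger, which satisfies the same bookkeeping
#' identities as [branch_ledger()] by construction.
#'
#' @param params A `"sim_params"` object.
#' @return An object of class `"sim_family"`:
#'   \describe{
#'     \item{gene_tree}{`"phylo"` over surviving genes, or `NULL` when the
#'       whole family went extinct (then `empty` is `TRUE`)}
#'     \item{annotations}{data.frame `gene_id`, `species_id`,
#'       `architecture`}
#'     \item{truth}{event log data.frame: `kind`
#'       (duplication/loss/fusion/fission), `species_branch` (child-node
#'       label; `"stem"` above the root), `time` (since the branch start),
#'       `state` (lineage architecture immediately after the event)}
#'     \item{true_ledger}{ground-truth `"branch_ledger"`-shaped table}
#'     \item{params}{the input parameters}
#'   }
#' @examples
#' fam <- simulate_family(sim_params(srlk_species_tree(), seed = 7))
#' fam
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  si <- params$si
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$gene_n <- 0L
  env$leaves <- list()   # gene_id -> list(species, state)
  env$cross <- matrix(0L, si$n_node, 2L,
                      dimnames = list(NULL, ARCH_STATES))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)

  blen <- branch_length_of(si)
  log_event <- function(kind, branch, time, state) {
    env$log[[length(env$log) + 1L]] <-
      list(kind = kind, species_branch = branch, time = time, state = state)
  }

  # evolve one lineage from time t0 on the branch entering species node sp;
  # returns a nested list: kind leaf/lost/dup/spec
  evolve <- function(state, sp, t0) {
    len <- blen[sp]
    t <- t0
    repeat {
      flip_rate <- if (state == "SPLIT") params$rate_fusion
                   else params$rate_fission
      r <- c(params$rate_dup, params$rate_loss, flip_rate)
      tot <- sum(r)
      dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
      if (t + dt >= len) break
      t <- t + dt
      ev <- sample.int(3L, 1L, prob = r)
      if (ev == 1L) {
        log_event("duplication", si$label[sp], t, state)
        return(list(kind = "dup",
                    children = list(evolve(state, sp, t),
                                    evolve(state, sp, t))))
      } else if (ev == 2L) {
        log_event("loss", si$label[sp], t, state)
        return(list(kind = "lost"))
      } else {
        state <- if (state == "SPLIT") "FUSED" else "SPLIT"
        log_event(if (state == "FUSED") "fusion" else "fission",
                  si$label[sp], t, state)
      }
    }
    kids <- si$children[[sp]]
    if (!length(kids)) {
      env$gene_n <- env$gene_n + 1L
      id <- paste0(si$label[sp], "_g", env$gene_n)
      env$leaves[[id]] <- list(species = si$label[sp], state = state)
      return(list(kind = "leaf", label = id))
    }
    env$cross[sp, state] <- env$cross[sp, state] + 1L
    list(kind = "spec",
         children = list(evolve(state, kids[1L], 0),
                         evolve(state, kids[2L], 0)))
  }

  roots <- vector("list", params$n_root_lineages)
  for (i in seq_len(params$n_root_lineages)) {
    st <- params$root_state[i]
    env$cross[si$root, st] <- env$cross[si$root, st] + 1L
    kids <- si$children[[si$root]]
    roots[[i]] <- list(kind = "spec",
                       children = list(evolve(st, kids[1L], 0),
                                       evolve(st, kids[2L], 0)))
  }
  # join multiple root lineages with stem duplications (ladder)
  if (length(roots) > 1L) {
    for (i in seq_along(roots)[-1L])
      log_event("duplication", "stem", 0, params$root_state[i])
    tree0 <- Reduce(function(a, b) list(kind = "dup", children = list(a, b)),
                    roots)
  } else {
    tree0 <- roots[[1L]]
  }

  pruned <- prune_lineage(tree0)
  truth <- do.call(rbind, lapply(env$log, function(e)
    data.frame(kind = e$kind, species_branch = e$species_branch,
               time = e$time, state = e$state, stringsAsFactors = FALSE)))
  if (is.null(truth))
    truth <- data.frame(kind = character(0), species_branch = character(0),
                        time = numeric(0), state = character(0),
                        stringsAsFactors = FALSE)

  ids <- names(env$leaves)
  annotations <- data.frame(
    gene_id = ids,
    species_id = vapply(env$leaves, `[[`, "", "species"),
    architecture = vapply(env$leaves, `[[`, "", "state"),
    row.names = NULL, stringsAsFactors = FALSE)

  gene_tree <- NULL
  empty <- is.null(pruned)
  if (!empty && pruned$kind == "leaf") {
    # single survivor: degenerate one-leaf tree under a unary root
    gene_tree <- read_newick(
      text = paste0("(", quote_for_newick(pruned$label), ");"))
  } else if (!empty) {
    gene_tree <- read_newick(text = paste0(lineage_newick(pruned), ";"))
  }

  true_ledger <- true_ledger_from(params, truth, annotations, env$cross)

  structure(list(gene_tree = gene_tree, annotations = annotations,
                 truth = truth, true_ledger = true_ledger,
                 params = params, empty = empty),
            class = "sim_family")
}

#' @noRd
branch_length_of <- function(si) {
  phy <- si$phy
  blen <- numeric(si$n_node)
  for (i in seq_len(nrow(phy$edge)))
    blen[phy$edge[i, 2L]] <- phy$edge.length[i]
  blen
}

#' @noRd
prune_lineage <- function(node) {
  if (node$kind == "leaf") return(node)
  if (node$kind == "lost") return(NULL)
  kids <- Filter(Negate(is.null), lapply(node$children, prune_lineage))
  if (!length(kids)) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  node$children <- kids
  node
}

#' @noRd
lineage_newick <- function(node) {
  if (node$kind == "leaf") return(quote_for_newick(node$label))
  sprintf("(%s,%s)", lineage_newick(node$children[[1L]]),
          lineage_newick(node$children[[2L]]))
}

# ground-truth ledger from the event log and crossing counts
#' @noRd
true_ledger_from <- function(params, truth, annotations, cross) {
  si <- params$si
  nodes <- si$preorder
  led <- data.frame(
    node = si$label[nodes],
    parent = parent_labels(si, nodes),
    terminal = vapply(nodes, function(s) !length(si$children[[s]]), TRUE),
    gains = 0L, losses = 0L, fusions = 0L, fissions = 0L,
    gains_fused = 0L, gains_split = 0L,
    losses_fused = 0L, losses_split = 0L,
    count = 0L, count_fused = 0L, count_split = 0L,
    stringsAsFactors = FALSE)
  rowid <- function(branch) {
    if (branch == "stem") match(si$label[si$root], led$node)
    else match(branch, led$node)
  }
  if (nrow(truth)) for (k in seq_len(nrow(truth))) {
    i <- rowid(truth$species_branch[k])
    kind <- truth$kind[k]
    st <- truth$state[k]
    if (kind == "duplication") {
      led$gains[i] <- led$gains[i] + 1L
      cls <- if (st == "FUSED") "gains_fused" else "gains_split"
      led[[cls]][i] <- led[[cls]][i] + 1L
    } else if (kind == "loss") {
      led$losses[i] <- led$losses[i] + 1L
      cls <- if (st == "FUSED") "losses_fused" else "losses_split"
      led[[cls]][i] <- led[[cls]][i] + 1L
    } else if (kind == "fusion") {
      led$fusions[i] <- led$fusions[i] + 1L
    } else {
      led$fissions[i] <- led$fissions[i] + 1L
    }
  }
  for (j in seq_len(nrow(led))) {
    s <- nodes[j]
    if (led$terminal[j]) {
      here <- annotations$species_id == led$node[j]
      led$count[j] <- sum(here)
      led$count_fused[j] <- sum(annotations$architecture[here] == "FUSED")
      led$count_split[j] <- sum(annotations$architecture[here] == "SPLIT")
    } else {
      led$count[j] <- sum(cross[s, ])
      led$count_fused[j] <- cross[s, "FUSED"]
      led$count_split[j] <- cross[s, "SPLIT"]
    }
  }
  # the origin lineage (before any stem join) carries the first root state
  audit_ledger(led, params$root_state[1L])
  class(led) <- c("branch_ledger", "data.frame")
  led
}

#' @export
print.sim_family <- function(x, ...) {
  if (x$empty) {
    cat("Simulated gene family: extinct (no surviving lineages)\n")
  } else {
    cat(sprintf(
      "Simulated gene family: %d surviving genes (%d FUSED, %d SPLIT); %d true events\n",
      nrow(x$annotations), sum(x$annotations$architecture == "FUSED"),
      sum(x$annotations$architecture == "SPLIT"), nrow(x$truth)))
  }
  invisible(x)
}

#' Compare inferred events against simulation ground truth
#'
#' Matches inferred fusion/fission events to the truth log by kind and
#' species branch (multiset matching) and summarizes duplication/loss count
#' errors. A precision or recall whose denominator is zero (no inferred, or
#' no true, events of that kind) is reported as `NA`, not 0.
#'
#' @param sim A `"sim_family"`.
#' @param fit A `"fuserec"` fit of the same family (see [fuserec()]), or a
#'   list with elements `reconciliation` and `assignment`.
#' @return A list: `fusion_precision`, `fusion_recall`, `fission_precision`,
#'   `fission_recall`, `dup_count_error`, `loss_count_error` (inferred minus
#'   true; non-positive whenever parsimony behaves as an under-count).
#' @export
recovery_report <- function(sim, fit) {
  stopifnot(inherits(sim, "sim_family"))
  rec <- fit$reconciliation
  asg <- fit$assignment
  if (is.null(rec) || is.null(asg))
    stop("fit must carry a reconciliation and an assignment", call. = FALSE)
  if (!sim$empty &&
      !setequal(rec$family$gene_tree$tip.label, sim$annotations$gene_id))
    stop("fit and simulation describe different families", call. = FALSE)

  pr <- function(kind) {
    true_b <- sim$truth$species_branch[sim$truth$kind == kind]
    inf_b <- asg$events$species_branch[asg$events$kind == kind]
    matched <- 0L
    pool <- true_b
    for (b in inf_b) {
      hit <- match(b, pool)
      if (!is.na(hit)) {
        matched <- matched + 1L
        pool <- pool[-hit]
      }
    }
    c(precision = if (length(inf_b)) matched / length(inf_b) else NA_real_,
      recall = if (length(true_b)) matched / length(true_b) else NA_real_)
  }
  fu <- pr("fusion")
  fi <- pr("fission")
  list(fusion_precision = fu[["precision"]],
       fusion_recall = fu[["recall"]],
       fission_precision = fi[["precision"]],
       fission_recall = fi[["recall"]],
       dup_count_error =
         rec$dup_count - sum(sim$truth$kind == "duplication"),
       loss_count_error =
         rec$loss_count - sum(sim$truth$kind == "loss"))
}
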