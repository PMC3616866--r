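# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's algorithms: the
# reconciliation oracle enumerates every valid gene-to-species map and
# scores it from the event definitions; the architecture oracle enumerates
# every ancestral state vector.  Both are exponential and only run on the
# small instances the tests build.

# random rooted binary topology over the given (distinct) labels,
# built by sequential random joins
random_topology <- function(labels) {
  units <- as.list(labels)
  while (length(units) > 1L) {
    i <- sample.int(length(units), 2L)
    a <- min(i)
    b <- max(i)
    units[[a]] <- sprintf("(%s,%s)", units[[a]], units[[b]])
    units[[b]] <- NULL
  }
  paste0(units[[1L]], ";")
}

# random bound family: n_genes leaves over a random species tree
random_family <- function(n_genes, n_species, states = c("FUSED", "SPLIT")) {
  sp <- paste0("S", seq_len(n_species))
  sp_tree <- random_topology(sp)
  genes <- sprintf("x%02d", seq_len(n_genes))
  ann <- data.frame(gene_id = genes,
                    species_id = sample(sp, n_genes, replace = TRUE),
                    architecture = sample(states, n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  bind_family(random_topology(genes), sp_tree, ann)
}

# --- duplication-loss oracle -------------------------------------------

# exhaustive minimum of dup + loss over every valid reconciliation map
brute_dl_min <- function(fd) {
  gi <- fd$gi
  si <- fd$si
  M <- integer(gi$n_node)
  for (v in gi$postorder)
    if (!length(gi$children[[v]])) M[v] <- fd$species_of[[gi$label[v]]]
  internals <- gi$postorder[vapply(gi$postorder,
                                   function(v) length(gi$children[[v]]) > 0L,
                                   TRUE)]
  anc_chain <- function(x) {
    out <- x
    while (si$parent[x] != 0L) {
      x <- si$parent[x]
      out <- c(out, x)
    }
    out
  }
  lca <- function(a, b) {
    while (a != b)
      if (si$depth[a] > si$depth[b]) a <- si$parent[a] else b <- si$parent[b]
    a
  }
  map_cost <- function(M) {
    dups <- 0L
    losses <- 0L
    for (v in internals) {
      kids <- gi$children[[v]]
      # a speciation at s is only valid when the children descend through
      # s's two daughter branches, i.e. s is exactly the children's LCA
      # and distinct from both child images; anything else is a duplication
      is_dup <- M[v] == M[kids[1L]] || M[v] == M[kids[2L]] ||
        M[v] != lca(M[kids[1L]], M[kids[2L]])
      if (is_dup) dups <- dups + 1L
      for (k in kids) {
        d <- si$depth[M[k]] - si$depth[M[v]]
        losses <- losses + d - (!is_dup)
      }
    }
    dups + losses
  }
  best <- Inf
  recurse <- function(k) {
    if (k > length(internals)) {
      best <<- min(best, map_cost(M))
      return(invisible())
    }
    v <- internals[k]
    kids <- gi$children[[v]]
    for (cand in anc_chain(lca(M[kids[1L]], M[kids[2L]]))) {
      M[v] <<- cand
      recurse(k + 1L)
    }
  }
  recurse(1L)
  best
}

# --- ancestral-architecture oracle -------------------------------------

# exhaustive minimum transition cost over all 2^I internal state vectors
brute_arch_min <- function(fd, costs = fuserec_costs()) {
  gi <- fd$gi
  states <- c("SPLIT", "FUSED")
  tr <- matrix(c(0, costs$fission, costs$fusion, 0), 2L, 2L,
               dimnames = list(states, states))
  internals <- which(vapply(seq_len(gi$n_node),
                            function(v) length(gi$children[[v]]) > 0L, TRUE))
  st <- character(gi$n_node)
  for (v in seq_len(gi$n_node))
    if (!length(gi$children[[v]])) st[v] <- fd$arch_of[[gi$label[v]]]
  edges <- which(gi$parent != 0L)
  best <- Inf
  n_int <- length(internals)
  for (mask in 0:(2^n_int - 1L)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(n_int) - 1L), 1L)
    st[internals] <- states[bits + 1L]
    cost <- 0
    for (c0 in edges) cost <- cost + tr[st[gi$parent[c0]], st[c0]]
    best <- min(best, cost)
  }
  best
}

# coarse study-structure fixture used across files
coarse_fit <- function(...) {
  fam <- srlk_coarse_family(...)
  fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
}

# recompute both bookkeeping identities of a ledger table from its columns
ledger_identity_ok <- function(led, origin_fused) {
  for (j in seq_len(nrow(led))) {
    if (is.na(led$parent[j])) {
      above <- 1L
      above_f <- as.integer(origin_fused)
    } else {
      i <- match(led$parent[j], led$node)
      above <- led$count[i]
      above_f <- led$count_fused[i]
    }
    if (led$count[j] != above + led$gains[j] - led$losses[j]) return(FALSE)
    if (led$count_fused[j] != above_f + led$gains_fused[j] -
        led$losses_fused[j] + led$fusions[j] - led$fissions[j]) return(FALSE)
    if (led$count_split[j] != (above - above_f) + led$gains_split[j] -
        led$losses_split[j] - led$fusions[j] + led$fissions[j]) return(FALSE)
    if (any(unlist(led[j, c("count", "count_fused", "count_split")]) < 0L))
      return(FALSE)
  }
  TRUE
}
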