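ann2 <- function(ids, sp, arch = "SPLIT")
  data.frame(gene_id = ids, species_id = sp, architecture = arch,
             stringsAsFactors = FALSE)

test_that("LCA mapping and event labels on hand-checked families", {
  # congruent single-copy family: root is the AB speciation
  fd <- bind_family("(a1,b1);", "(A,B);", ann2(c("a1", "b1"), c("A", "B")))
  rec <- reconcile(fd)
  r <- fd$gi$root
  expect_equal(fd$si$label[rec$M[r]], "n1")
  expect_equal(rec$event[r], "speciation")
  expect_equal(rec$dup_count, 0L)
  expect_equal(rec$loss_count, 0L)

  # two copies of the species tree: one duplication at the root, no losses
  fd <- bind_family("((a1,b1),(a2,b2));", "(A,B);",
                    ann2(c("a1", "b1", "a2", "b2"), c("A", "B", "A", "B")))
  rec <- reconcile(fd)
  ev <- rec$event[!is.na(rec$event) & rec$event != "leaf"]
  expect_equal(rec$dup_count, 1L)
  expect_equal(rec$event[fd$gi$root], "duplication")
  expect_equal(sum(ev == "speciation"), 2L)
  expect_equal(rec$loss_count, 0L)

  # unbalanced copy: duplication at the root plus one loss, placed on the
  # branch where the duplicate's descendant is absent (B)
  fd <- bind_family("(a1,(a2,b1));", "(A,B);",
                    ann2(c("a1", "a2", "b1"), c("A", "A", "B")))
  rec <- reconcile(fd)
  expect_equal(rec$dup_count, 1L)
  expect_equal(rec$event[fd$gi$root], "duplication")
  expect_equal(rec$loss_count, 1L)
  expect_equal(rec$losses$species_branch, "B")

  # deeper species tree: loss of the second B copy under a duplication
  fd <- bind_family("((a1,b1),(a2,c1));", "((A,B)ab,C);",
                    ann2(c("a1", "b1", "a2", "c1"), c("A", "B", "A", "C")))
  rec <- reconcile(fd)
  expect_equal(rec$dup_count, 1L)
  expect_true("B" %in% rec$losses$species_branch)
})

test_that("reconciliation cost equals the exhaustive minimum (small random)", {
  set.seed(101)
  for (i in 1:40) {
    fd <- random_family(sample(3:7, 1), sample(2:4, 1))
    rec <- reconcile(fd)
    expect_equal(rec$dup_count + rec$loss_count, brute_dl_min(fd))
  }
})

test_that("LCA mapping is monotone along the gene tree", {
  set.seed(7)
  for (i in 1:20) {
    fd <- random_family(8, 4)
    rec <- reconcile(fd)
    gi <- fd$gi
    si <- fd$si
    for (v in seq_len(gi$n_node)) {
      p <- gi$parent[v]
      if (p == 0L) next
      expect_true(fuserec:::is_ancestor(si, rec$M[p], rec$M[v]))
    }
  }
})

test_that("grafting a same-species gene copy adds exactly one duplication", {
  # adding a leaf of a *new* species can complete a speciation pattern and
  # remove a loss, so the cost is not monotone in arbitrary leaf additions;
  # a same-species sister copy, however, adds exactly its duplication
  set.seed(202)
  for (rep in 1:15) {
    n_sp <- sample(2:4, 1)
    sp <- paste0("S", seq_len(n_sp))
    sp_tree <- random_topology(sp)
    labs <- sprintf("x%02d", 1:9)
    spmap <- sample(sp, 9, replace = TRUE)
    txt <- sprintf("(%s,%s);", labs[1], labs[2])
    prev_cost <- NULL
    for (k in 3:9) {
      ann <- ann2(labs[1:(k - 1)], spmap[1:(k - 1)])
      rec <- reconcile(bind_family(txt, sp_tree, ann))
      cost <- rec$dup_count + rec$loss_count
      if (!is.null(prev_cost)) expect_equal(cost, prev_cost + 1L)
      prev_cost <- cost
      # graft the next leaf as a same-species sister of an existing leaf
      at <- sample(labs[1:(k - 1)], 1)
      spmap[k] <- spmap[match(at, labs)]
      txt <- sub(at, sprintf("(%s,%s)", at, labs[k]), txt, fixed = TRUE)
    }
  }
})

test_that("a new-species leaf can lower the cost by completing a speciation", {
  ann <- ann2(c("a1", "c1"), c("A", "C"))
  rec_small <- reconcile(bind_family("(a1,c1);", "((A,B),C);", ann))
  expect_equal(rec_small$dup_count + rec_small$loss_count, 1L)
  ann3 <- ann2(c("a1", "b1", "c1"), c("A", "B", "C"))
  rec_big <- reconcile(bind_family("((a1,b1),c1);", "((A,B),C);", ann3))
  expect_equal(rec_big$dup_count + rec_big$loss_count, 0L)
})

test_that("events are dated categorically onto species branches", {
  # duplication mapping to a terminal species -> that terminal branch
  fd <- bind_family("((p1,p2),b1);", "(Pt,B);",
                    ann2(c("p1", "p2", "b1"), c("Pt", "Pt", "B")))
  rec <- reconcile(fd)
  dup_node <- which(rec$event == "duplication")
  expect_length(dup_node, 1L)
  d <- date_event(rec, dup_node)
  expect_equal(d, list(kind = "branch", species = "Pt"))

  # duplication mapping to the species root -> the root stem
  fd <- bind_family("((a1,b1),(a2,b2));", "(A,B);",
                    ann2(c("a1", "b1", "a2", "b2"), c("A", "B", "A", "B")))
  rec <- reconcile(fd)
  expect_equal(date_event(rec, fd$gi$root)$species, "stem")

  # speciation nodes are dated to the species node itself, not a branch
  spec_node <- which(rec$event == "speciation")[1]
  expect_equal(date_event(rec, spec_node)$kind, "node")
})

test_that("reconciled newick renders duplication/speciation labels", {
  fd <- bind_family("((a1,b1),(a2,b2));", "(A,B);",
                    ann2(c("a1", "b1", "a2", "b2"), c("A", "B", "A", "B")))
  s <- reconciled_newick(reconcile(fd))
  expect_match(s, "D;$")   # root duplication is the last label
  expect_match(s, "\\)S")
})
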