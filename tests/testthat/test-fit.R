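test_that("the one-call fit wires all stages together", {
  fam <- srlk_coarse_family()
  fit <- fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
  expect_s3_class(fit, "fuserec")
  expect_s3_class(fit$ledger, "branch_ledger")
  expect_identical(fit$events, fit$assignment$events)
  expect_output(print(fit), "duplications")
  expect_output(print(summary(fit)), "Dated fusion/fission events")
  rep <- fit_report(fit)
  expect_equal(rep$n_genes, length(fam$gene_tree$tip.label))
  expect_equal(rep$total_cost, fit$assignment$total_cost)
  # report is JSON-serializable
  expect_silent(jsonlite::toJSON(rep, auto_unbox = TRUE))
})

test_that("plot method draws without error", {
  fam <- srlk_coarse_family(n_basal = 3, per_species = 1)
  fit <- fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("cli: simulate/reconcile/infer/summarize chain runs and audits", {
  out <- file.path(tempfile("cli"), "run")
  status <- cli_main(c("all", "--paper-like", "--seed", "11",
                       "--out", out, "--quiet"))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "gene_tree.nwk")))
  expect_true(file.exists(file.path(out, "truth.tsv")))
  expect_true(file.exists(file.path(out, "reconciliation.json")))
  expect_true(file.exists(file.path(out, "events.tsv")))
  expect_true(file.exists(file.path(out, "ledger.tsv")))
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_true(summ$dup_count >= 0)
})

test_that("cli: fixed seed reruns reproduce reports byte-identically", {
  o1 <- tempfile("a")
  o2 <- tempfile("b")
  for (o in c(o1, o2))
    expect_identical(cli_main(c("all", "--paper-like", "--seed", "7",
                                "--out", o, "--quiet")), 0L)
  for (f in c("gene_tree.nwk", "annotations.tsv", "truth.tsv",
              "reconciliation.json", "events.tsv", "ledger.tsv",
              "summary.json"))
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)))
})

test_that("cli: the coarse fixture summarizes to 2 fusions, 0 fissions", {
  fam <- srlk_coarse_family()
  out <- tempfile("coarse")
  dir.create(out, recursive = TRUE)
  gt <- file.path(out, "gene.nwk")
  sp <- file.path(out, "species.nwk")
  an <- file.path(out, "ann.tsv")
  write_newick(fam$gene_tree, gt)
  write_newick(fam$species_tree, sp)
  write.table(fam$annotations, an, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_identical(cli_main(c("infer", "--gene-tree", gt,
                              "--species-tree", sp, "--annotations", an,
                              "--out", out, "--quiet")), 0L)
  expect_identical(cli_main(c("summarize", "--gene-tree", gt,
                              "--species-tree", sp, "--annotations", an,
                              "--out", out, "--quiet")), 0L)
  summ <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(summ$fusion_count, 2L)
  expect_equal(summ$fission_count, 0L)
})

test_that("cli: usage errors exit nonzero without touching files", {
  expect_identical(cli_main(character(0)), 2L)
  expect_identical(cli_main("frobnicate"), 2L)
  expect_identical(cli_main(c("simulate", "--out", tempfile())), 2L)
  expect_identical(
    suppressMessages(cli_main(c("reconcile", "--gene-tree", "missing.nwk",
                                "--species-tree", "missing.nwk",
                                "--annotations", "missing.tsv",
                                "--out", tempfile()))), 1L)
})

test_that("alternate cost models and tie-breaks reach the cli surface", {
  fam <- srlk_coarse_family(n_basal = 2, per_species = 1)
  out <- tempfile("costs")
  dir.create(out)
  gt <- file.path(out, "gene.nwk")
  sp <- file.path(out, "species.nwk")
  an <- file.path(out, "ann.tsv")
  write_newick(fam$gene_tree, gt)
  write_newick(fam$species_tree, sp)
  write.table(fam$annotations, an, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_identical(cli_main(c("infer", "--gene-tree", gt,
                              "--species-tree", sp, "--annotations", an,
                              "--cost-fusion", "10", "--tie-break",
                              "fused-root", "--out", out, "--quiet")), 0L)
  arch <- jsonlite::read_json(file.path(out, "architecture.json"))
  expect_equal(arch$costs$fusion, 10)
})
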