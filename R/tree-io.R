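#' Read a rooted tree from newick text or a file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Square-bracket
#' comments are stripped (outside quoted labels), single-quoted labels are
#' unquoted, and malformed input fails with the character position of the
#' first offending parenthesis. Leaf labels must be unique and non-empty;
#' child order, branch lengths and internal labels are preserved.
#'
#' @param text A newick string (exactly one tree).
#' @param file Path to a newick file; exactly one of `text`/`file`.
#' @return An object of class `"phylo"` (see [ape::read.tree()]).
#' @examples
#' tr <- read_newick("((A:1,B:2)n1:3,C:4);")
#' tr$tip.label
#' @seealso [write_newick()], [bind_family()]
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- strip_newick_comments(text)
  check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy))
    stop("newick parse error: ape could not read the tree", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("expected exactly one tree, found ", length(phy), call. = FALSE)
    phy <- phy[[1L]]
  }
  phy$tip.label <- unquote_label(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote_label(phy$node.label)
  if (any(!nzchar(phy$tip.label)))
    stop("empty leaf label in newick input", call. = FALSE)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  phy
}

# drop [...] comments, respecting single-quoted labels
#' @noRd
strip_newick_comments <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  in_q <- FALSE
  in_c <- FALSE
  for (c0 in ch) {
    if (in_c) {
      if (c0 == "]") in_c <- FALSE
      next
    }
    if (c0 == "'") in_q <- !in_q
    if (!in_q && c0 == "[") {
      in_c <- TRUE
      next
    }
    out <- c(out, c0)
  }
  if (in_c) stop("newick parse error: unterminated [comment]", call. = FALSE)
  if (in_q) stop("newick parse error: unterminated quoted label", call. = FALSE)
  paste(out, collapse = "")
}

#' @noRd
check_newick_syntax <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  in_q <- FALSE
  for (i in seq_along(ch)) {
    c0 <- ch[i]
    if (c0 == "'") in_q <- !in_q
    if (in_q) next
    if (c0 == "(") depth <- depth + 1L
    if (c0 == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at position %d: unmatched ')'", i),
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop(sprintf("newick parse error at position %d: %d unclosed '('",
                 length(ch), depth), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("newick parse error at position %d: missing ';'",
                 length(ch)), call. = FALSE)
  invisible(TRUE)
}

#' @noRd
unquote_label <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L), fixed = TRUE)
  x
}

#' Write a tree as a newick string
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(t))` reproduces
#' topology, labels and branch lengths (to printed precision).
#'
#' @param tree A `"phylo"` tree.
#' @param file Optional path; when given the string is also written there.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a gene-leaf annotation table
#'
#' Reads the tab-separated three-column table binding each gene-tree leaf to
#' its species and to its protein architecture state: `FUSED` for composite
#' receptor kinases (extracellular domain + kinase, e.g. SRLKs) and `SPLIT`
#' for kinase-only cytoplasmic proteins (e.g. SRLCKs).
#'
#' @param file Path to a TSV with header `gene_id  species_id  architecture`,
#'   or a data.frame with those columns.
#' @return A data.frame with columns `gene_id`, `species_id`, `architecture`
#'   (values `"FUSED"`/`"SPLIT"`).
#' @export
read_annotations <- function(file) {
  ann <- if (is.data.frame(file)) {
    file
  } else {
    utils::read.delim(file, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
  }
  need <- c("gene_id", "species_id", "architecture")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ann <- ann[, need]
  ann$gene_id <- as.character(ann$gene_id)
  ann$species_id <- as.character(ann$species_id)
  ann$architecture <- toupper(as.character(ann$architecture))
  bad <- setdiff(unique(ann$architecture), c("FUSED", "SPLIT"))
  if (length(bad))
    stop("unknown architecture token(s): ", paste(bad, collapse = ", "),
         " (expected FUSED or SPLIT)", call. = FALSE)
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s) in annotation table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  rownames(ann) <- NULL
  ann
}

#' Bind a gene tree, a species tree and leaf annotations
#'
#' Validates the triple that the reconciliation and architecture-inference
#' steps assume: both trees rooted and strictly binary, unique leaf labels,
#' every gene leaf annotated with a known species and an architecture state.
#' Polytomies are rejected, never resolved implicitly (use
#' [resolve_polytomies()] first if you accept a deterministic resolution).
#'
#' @param gene_tree,species_tree `"phylo"` trees (or newick strings / file
#'   paths, passed through [read_newick()]).
#' @param annotations Annotation table (path or data.frame), see
#'   [read_annotations()].
#' @return An object of class `"family_data"`: the validated triple plus
#'   precomputed node indices.
#' @examples
#' fd <- bind_family("((a1,a2),b1);", "(A,B);",
#'                   data.frame(gene_id = c("a1", "a2", "b1"),
#'                              species_id = c("A", "A", "B"),
#'                              architecture = c("FUSED", "FUSED", "SPLIT")))
#' fd
#' @export
bind_family <- function(gene_tree, species_tree, annotations) {
  gene_tree <- as_tree(gene_tree)
  species_tree <- as_tree(species_tree)
  ann <- read_annotations(annotations)

  species_tree <- fill_internal_labels(species_tree)
  si <- tree_index(species_tree)
  assert_binary(si, "species tree")
  gi <- tree_index(gene_tree)
  assert_binary(gi, "gene tree")

  gleaves <- gene_tree$tip.label
  unann <- setdiff(gleaves, ann$gene_id)
  if (length(unann))
    stop("gene leaf without annotation: ", paste(unann, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(ann$gene_id, gleaves)
  if (length(extra))
    stop("annotation for unknown gene leaf: ", paste(extra, collapse = ", "),
         call. = FALSE)
  unknown_sp <- setdiff(unique(ann$species_id), species_tree$tip.label)
  if (length(unknown_sp))
    stop("annotation references species absent from the species tree: ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)

  ord <- match(gleaves, ann$gene_id)
  species_of <- match(ann$species_id[ord], species_tree$tip.label)
  arch_of <- ann$architecture[ord]
  names(species_of) <- names(arch_of) <- gleaves

  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 annotations = ann[ord, , drop = FALSE],
                 gi = gi, si = si,
                 species_of = species_of, arch_of = arch_of),
            class = "family_data")
}

#' @noRd
as_tree <- function(x) {
  if (inherits(x, "phylo")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x) && !grepl("[();]", x)) return(read_newick(file = x))
    return(read_newick(text = x))
  }
  stop("expected a 'phylo' tree, a newick string, or a file path",
       call. = FALSE)
}

#' @export
print.family_data <- function(x, ...) {
  cat(sprintf(
    "Bound gene family: %d genes (%d FUSED, %d SPLIT) over %d species\n",
    length(x$gene_tree$tip.label),
    sum(x$arch_of == "FUSED"), sum(x$arch_of == "SPLIT"),
    length(x$species_tree$tip.label)))
  invisible(x)
}

#' Resolve polytomies deterministically
#'
#' Left-ladderizes every multifurcation (the first two children are joined,
#' then the next child, and so on), giving a reproducible strictly binary
#' tree. Inference functions never call this implicitly.
#'
#' @param tree A `"phylo"` tree.
#' @return A binary `"phylo"` tree.
#' @export
resolve_polytomies <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ix <- tree_index(tree)
  build <- function(v) {
    kids <- ix$children[[v]]
    if (!length(kids)) return(quote_for_newick(ix$label[v]))
    parts <- vapply(kids, build, "")
    s <- parts[1L]
    if (length(parts) > 1L) {
      for (k in 2L:length(parts)) {
        s <- if (k == 2L) sprintf("(%s,%s)", s, parts[k])
             else sprintf("(%s,%s)", s, parts[k])
      }
    }
    if (nzchar(ix$label[v]) && length(parts) > 1L)
      s <- paste0(s, quote_for_newick(ix$label[v]))
    s
  }
  read_newick(text = paste0(build(ix$root), ";"))
}

#' @noRd
quote_for_newick <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.|-]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad], fixed = TRUE), "'")
  x
}
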