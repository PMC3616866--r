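#' Five-species land-plant species tree
#'
#' The rooted species tree of the five sequenced land-plant genomes used in
#' the SRLK analyses: poplar (Populus trichocarpa), Arabidopsis
#' (Arabidopsis thaliana), rice (Oryza sativa), spikemoss (Selaginella
#' moellendorffii) and moss (Physcomitrella patens). Internal nodes carry
#' the conventional labels E (eudicots), A (angiosperms), V (vascular
#' plants) and L (land plants).
#'
#' With `dated = TRUE`, branch lengths are in units of 100 million years,
#' from literature divergence times: land plants ~450 My, vascular plants
#' ~420 My, angiosperm crown ~140 My, poplar/Arabidopsis split ~100 My.
#' Inference is topology-only; the lengths matter only to the simulator.
#'
#' @param dated Attach branch lengths (default `TRUE`).
#' @return A `"phylo"` tree.
#' @export
srlk_species_tree <- function(dated = TRUE) {
  if (dated) {
    txt <- paste0(
      "((((Populus_trichocarpa:1.0,Arabidopsis_thaliana:1.0)E:0.4,",
      "Oryza_sativa:1.4)A:2.8,Selaginella_moellendorffii:4.2)V:0.3,",
      "Physcomitrella_patens:4.5)L;")
  } else {
    txt <- paste0(
      "((((Populus_trichocarpa,Arabidopsis_thaliana)E,",
      "Oryza_sativa)A,Selaginella_moellendorffii)V,",
      "Physcomitrella_patens)L;")
  }
  read_newick(text = txt)
}

#' Coarse SRLK/SRLCK family encoding the reported group structure
#'
#' Builds a small rooted gene family reproducing, at desk scale, the group
#' structure of the kinase-domain tree of land-plant S-domain kinases: a
#' basal stratum of split cytoplasmic kinases (RLCKs) arranged as a ladder,
#' then a sister pair of clades — one entirely FUSED (standing for the major
#' SRLK group) and one SPLIT clade (the SRLCK group) containing a nested
#' FUSED cherry of two moss genes. Both large clades span all five species,
#' so the fused clade's ancestor maps to the species root. Run through
#' [fuserec()] this structure yields exactly two fusion events and no
#' fission: a major fusion on the stem of land plants and a minor fusion on
#' the terminal moss branch.
#'
#' @param n_basal Number of basal SPLIT lineages (default 17, the reported
#'   basal RLCK count).
#' @param per_species Leaves per species inside each of the two big clades
#'   (default 2; sizes do not change the event calls).
#' @return A list with `gene_tree`, `species_tree` and `annotations`,
#'   ready for [fuserec()] or [bind_family()].
#' @examples
#' fam <- srlk_coarse_family()
#' fit <- fuserec(fam$gene_tree, fam$species_tree, fam$annotations)
#' fit$events
#' @export
srlk_coarse_family <- function(n_basal = 17L, per_species = 2L) {
  sp <- c("Populus_trichocarpa", "Arabidopsis_thaliana", "Oryza_sativa",
          "Selaginella_moellendorffii", "Physcomitrella_patens")
  gene_id <- character(0)
  species_id <- character(0)
  architecture <- character(0)
  add <- function(id, s, a) {
    gene_id <<- c(gene_id, id)
    species_id <<- c(species_id, s)
    architecture <<- c(architecture, a)
    id
  }
  ladder <- function(ids) Reduce(function(a, b) sprintf("(%s,%s)", a, b), ids)

  # major fused clade: per_species SRLKs from every species
  fused <- unlist(lapply(sp, function(s)
    vapply(seq_len(per_species), function(i)
      add(sprintf("srlk_%s_%d", abbrev_sp(s), i), s, "FUSED"), "")))
  # split clade: SRLCKs from every species plus the fused moss cherry
  split1 <- unlist(lapply(sp, function(s)
    vapply(seq_len(per_species), function(i)
      add(sprintf("srlck_%s_%d", abbrev_sp(s), i), s, "SPLIT"), "")))
  cherry <- sprintf("(%s,%s)",
                    add("srlk_Pp_moss1", "Physcomitrella_patens", "FUSED"),
                    add("srlk_Pp_moss2", "Physcomitrella_patens", "FUSED"))
  split_clade <- ladder(c(split1, cherry))
  core <- sprintf("(%s,%s)", ladder(fused), split_clade)
  # basal split lineages wrap the core as a ladder, species cycling
  for (i in seq_len(n_basal)) {
    s <- sp[((i - 1L) %% length(sp)) + 1L]
    core <- sprintf("(%s,%s)",
                    add(sprintf("rlck_basal_%d", i), s, "SPLIT"), core)
  }
  list(gene_tree = read_newick(text = paste0(core, ";")),
       species_tree = srlk_species_tree(),
       annotations = data.frame(gene_id = gene_id, species_id = species_id,
                                architecture = architecture,
                                stringsAsFactors = FALSE))
}

#' @noRd
abbrev_sp <- function(s) {
  parts <- strsplit(s, "_", fixed = TRUE)[[1L]]
  paste0(toupper(substr(parts[1L], 1L, 1L)), substr(parts[2L], 1L, 1L))
}

#' Paper-like simulation preset
#'
#' Simulation parameters on the dated five-species tree tuned so a typical
#' draw resembles the SRLK family's shape: a sizeable FUSED clade born from
#' an early fusion, a persisting SPLIT stratum, and rare fissions. Intended
#' for demos and exploration, not for any quantitative claim.
#'
#' @param seed Integer seed.
#' @return A `"sim_params"` object.
#' @export
sim_params_paperlike <- function(seed = 1L) {
  sim_params(srlk_species_tree(), rate_dup = 0.35, rate_loss = 0.12,
             rate_fusion = 0.08, rate_fission = 0.005,
             n_root_lineages = 3L, root_state = "SPLIT", seed = seed)
}
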