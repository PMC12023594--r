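#' Run configuration for reduced-graph series analysis
#'
#' Bundles the tunable parameters of the whole pipeline. The defaults are the
#' operating point used throughout the package: a graph-Tanimoto similarity
#' threshold of 0.5 for near-neighbour lists and a minimum RG core size of
#' five nodes. The hydrogen-bond acceptor/donor SMARTS defaults are the
#' standard pharmacophoric definitions: acceptors are neutral non-carbon,
#' non-halogen atoms excluding aromatic o/s/trisubstituted n and hypervalent
#' N/P/S; donors are non-carbon atoms bearing at least one hydrogen.
#'
#' @param similarity_threshold Tanimoto threshold in \[0, 1\] used to build
#'   near-neighbour lists during core extraction.
#' @param min_core_size Minimum number of nodes in an RG core (integer >= 2).
#' @param hba_smarts SMARTS pattern matched per atom for acceptor character.
#' @param hbd_smarts SMARTS pattern matched per atom for donor character.
#' @return A list of class `rg_config`.
#' @examples
#' cfg <- rg_config(similarity_threshold = 0.7, min_core_size = 4)
#' @export
rg_config <- function(similarity_threshold = 0.5,
                      min_core_size = 5L,
                      hba_smarts = "[$([!#6;+0]);!$([F,Cl,Br,I]);!$([o,s,nX3]);!$([Nv5,Pv5,Sv4,Sv6])]",
                      hbd_smarts = "[!#6;!H0]") {
  stopifnot(
    is.numeric(similarity_threshold), length(similarity_threshold) == 1,
    similarity_threshold >= 0, similarity_threshold <= 1,
    is.numeric(min_core_size), length(min_core_size) == 1, min_core_size >= 2,
    is.character(hba_smarts), is.character(hbd_smarts)
  )
  structure(list(
    similarity_threshold = as.numeric(similarity_threshold),
    min_core_size = as.integer(min_core_size),
    hba_smarts = hba_smarts,
    hbd_smarts = hbd_smarts
  ), class = "rg_config")
}

# Table of node labels: two-letter element codes usable in SMILES grammar.
rg_label_table <- function() {
  data.frame(
    structural_class = rep(c("acyclic", "aromatic_ring", "aliphatic_ring"), each = 4),
    hbond_class = rep(c("inert", "HBA", "HBD", "HBA_HBD"), times = 3),
    label = c("Li", "Ga", "Gd", "Ge",
              "No", "Na", "Nd", "Ne",
              "Co", "Ca", "Cd", "Ce"),
    stringsAsFactors = FALSE
  )
}

rg_node_label <- function(structural_class, hbond_class) {
  if (structural_class == "complex") return("Hg")
  tab <- rg_label_table()
  hit <- tab$label[tab$structural_class == structural_class &
                     tab$hbond_class == hbond_class]
  if (length(hit) != 1)
    stop("no label for (", structural_class, ", ", hbond_class, ")", call. = FALSE)
  hit
}
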