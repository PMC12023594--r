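# Programmatic test-series generators: small lead-optimisation-style series
# written around a fixed scaffold with enumerated substituents, so the
# expected core and membership are known by construction.

#' Generate a substituted scaffold series
#'
#' Enumerates `scaffold_smiles` x `substituents`, splicing each substituent
#' SMILES fragment at the `{R}` marker. The reduced graph of the scaffold
#' (marker replaced by a hydrogen) is the expected series core provided the
#' substituents only extend the molecule beyond it. Substituents that give
#' an invalid structure are skipped with a warning.
#'
#' @param scaffold_smiles SMILES containing the literal marker `{R}` once.
#' @param substituents Character vector of substituent SMILES fragments
#'   (use `"[H]"` for hydrogen); ring-closure digits 2+ to avoid clashing
#'   with the scaffold.
#' @param activities Numeric pIC50 vector recycled over the substituents, or
#'   NULL to draw plausible values (normal around 7) under `seed`.
#' @param seed Integer seed for generated activities.
#' @param name Series name, used to form compound ids.
#' @return list(name, records, expected_core_smarts, expected_member_count,
#'   expected_rg_smiles): `records` is a tibble usable by [rg_run()].
#' @examples
#' \dontrun{
#' fx <- make_series("NC(=O)c1ccc({R})cc1", c("Cl", "Br", "F", "C(F)(F)F"))
#' }
#' @export
make_series <- function(scaffold_smiles, substituents, activities = NULL,
                        seed = 1L, name = "series") {
  stopifnot(grepl("{R}", scaffold_smiles, fixed = TRUE),
            length(substituents) > 0)
  if (is.null(activities)) {
    set.seed(seed)
    activities <- round(stats::rnorm(length(substituents), mean = 7, sd = 0.8), 2)
  }
  activities <- rep_len(activities, length(substituents))
  smiles <- vapply(substituents, function(s) {
    sub("{R}", s, scaffold_smiles, fixed = TRUE)
  }, character(1), USE.NAMES = FALSE)
  records <- tibble::tibble(
    compound_id = sprintf("%s_%02d", name, seq_along(smiles)),
    smiles = smiles,
    pic50 = activities
  )
  percs <- perceive_molecules(records$smiles)
  ok <- vapply(percs, function(p) is.null(p$error), logical(1))
  for (i in which(!ok)) {
    warning("dropping ", records$compound_id[i], ": ", percs[[i]]$error,
            call. = FALSE)
  }
  records <- records[ok, , drop = FALSE]

  scaffold_rg <- assemble_rg(sub("{R}", "[H]", scaffold_smiles, fixed = TRUE),
                             paste0(name, "_scaffold"))
  rgs <- build_rgs(records)
  list(
    name = name,
    records = records,
    expected_core_smarts = scaffold_rg$rg_smiles,
    expected_member_count = nrow(records),
    expected_rg_smiles = vapply(rgs, `[[`, character(1), "rg_smiles")
  )
}

#' The demonstration series used by the command-line `demo` mode
#'
#' A six-molecule chloro-phenyl acetamide series varied at the amide
#' nitrogen: the shared four-node scaffold (complex halogen, aromatic ring,
#' methylene linker, amide) is the expected core, and the substituents add
#' zero to two further nodes so pairwise similarities span both sides of the
#' default 0.5 threshold's neighbourhood structure.
#'
#' @inheritParams make_series
#' @return As [make_series()].
#' @export
make_series_demo <- function(seed = 1L) {
  make_series(
    "O=C(N{R})Cc1ccc(Cl)cc1",
    c("[H]", "C", "CC", "c2ccccc2", "C2CCCCC2", "Cc2ccccc2"),
    seed = seed, name = "demo"
  )
}

#' An ambiguity fixture with known ground-truth mapping
#'
#' Three uniquely mapping molecules (phenylacetamides with varied ring
#' halogens) plus one molecule carrying both an acetamide arm (two bonds
#' from ring to carbonyl) and a propanoic-acid arm (three bonds): both arms
#' present the same acyclic HBA-HBD node to the core, giving two candidate
#' mappings distinguishable only by their node topological distance maps.
#' Every uniquely mapped molecule places the carbonyl two bonds from the
#' ring, so the resolved mapping must pick the acetamide arm.
#'
#' @param seed Integer seed for the activities.
#' @return list(records, core, ambiguous_id, expected_core_smarts,
#'   expected_ring_to_ge_distance): `core` is the shared three-node RG core
#'   (acyclic HBA-HBD, inert linker, aromatic ring) as an `rg_core`.
#' @export
make_ambiguous_pair_series <- function(seed = 1L) {
  set.seed(seed)
  records <- tibble::tibble(
    compound_id = c("amb_01", "amb_02", "amb_03", "amb_amb"),
    smiles = c(
      "NC(=O)Cc1ccc(Cl)cc1",
      "NC(=O)Cc1ccc(Br)cc1",
      "NC(=O)Cc1ccc(F)cc1",
      "NC(=O)Cc1ccc(CCC(=O)O)cc1"
    ),
    pic50 = round(stats::rnorm(4, 7, 0.5), 2)
  )
  core_graph <- rg_graph(c("Ge", "Li", "No"),
                         rbind(c(1, 2, 1), c(2, 3, 1)))
  list(
    records = records,
    core = new_rg_core(1L, core_graph, character(0)),
    ambiguous_id = "amb_amb",
    expected_core_smarts = rg_graph_smiles(core_graph),
    expected_ring_to_ge_distance = 2L
  )
}
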