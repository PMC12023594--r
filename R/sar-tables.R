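# Markush-style SAR summaries: per-node substructure tables with activity
# statistics, combined-substructure core tables, pie-chart metadata, the
# core-overlap matrix and the dataset summary.

core_assignment <- function(assignments, core_id) {
  for (a in assignments) if (a$core_id == core_id) return(a)
  stop("no assignment for core ", core_id, call. = FALSE)
}

#' Per-node substructure annotation of an RG core
#'
#' For each core node, the molecules assigned to the core are grouped by the
#' substructure (canonical fragment SMILES with wildcard attachment points)
#' their mapped RG node represents; each group reports its molecule count
#' and the median, mean and sample standard deviation of pIC50 (single
#' molecule groups report NA standard deviation). Groups are sorted by
#' descending count, ties alphabetically by substructure.
#'
#' @param core An `rg_core`.
#' @param assignments An `rg_assignments` object.
#' @param rgs The named list of `reduced_graph` objects.
#' @return A tibble with columns `core_id`, `node_index`, `label`,
#'   `substructure_smarts`, `count`, `pic50_median`, `pic50_mean`,
#'   `pic50_std`.
#' @export
annotate_core <- function(core, assignments, rgs) {
  a <- core_assignment(assignments, core$core_id)
  k <- rg_n_nodes(core$graph)
  rows <- list()
  for (node in seq_len(k)) {
    subs <- vapply(a$member_ids, function(id) {
      rg <- rgs[[id]]
      rg$substructure[a$mappings[[id]]$mapping[node]]
    }, character(1))
    pic <- vapply(a$member_ids, function(id) rgs[[id]]$pic50, numeric(1))
    for (s in unique(subs)) {
      v <- pic[subs == s]
      rows[[length(rows) + 1]] <- tibble::tibble(
        core_id = core$core_id,
        node_index = node,
        label = core$graph$labels[node],
        substructure_smarts = s,
        count = length(v),
        pic50_median = stats::median(v),
        pic50_mean = mean(v),
        pic50_std = if (length(v) > 1) stats::sd(v) else NA_real_
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$node_index, -out$count, out$substructure_smarts), ]
}

#' Combined-substructure table of an RG core
#'
#' One row per unique tuple of per-node substructures; the combined
#' substructure is the connected fragment covering all core-mapped atoms of
#' a representative molecule, with wildcard atoms marking positions where
#' members extend beyond the core. Row counts partition the core's members.
#'
#' @inheritParams annotate_core
#' @return A tibble with one column per core node (`node_<i>_<label>`), plus
#'   `combined_substructure` and `molecule_count`.
#' @export
build_core_table <- function(core, assignments, rgs) {
  a <- core_assignment(assignments, core$core_id)
  k <- rg_n_nodes(core$graph)
  tuples <- vapply(a$member_ids, function(id) {
    rg <- rgs[[id]]
    paste(rg$substructure[a$mappings[[id]]$mapping], collapse = "\r")
  }, character(1))
  rows <- list()
  for (tp in unique(tuples)) {
    ids <- a$member_ids[tuples == tp]
    rep_id <- ids[1]
    rg <- rgs[[rep_id]]
    mapping <- a$mappings[[rep_id]]$mapping
    combined <- extract_fragments(rg$smiles,
                                  list(sort(unlist(rg$atom_indices[mapping]))))
    row <- as.list(strsplit(tp, "\r", fixed = TRUE)[[1]])
    names(row) <- sprintf("node_%d_%s", seq_len(k), core$graph$labels)
    row$combined_substructure <- combined
    row$molecule_count <- length(ids)
    rows[[length(rows) + 1]] <- tibble::as_tibble(row)
  }
  out <- do.call(rbind, rows)
  out[order(-out$molecule_count, out$combined_substructure), ]
}

#' Pie-chart metadata for the nodes of an RG core
#'
#' Node size is the number of distinct substructures it represents; segment
#' fractions are substructure frequencies over the core's member count and
#' sum to one per node.
#'
#' @param core An `rg_core`.
#' @param annotation Output of [annotate_core()] for that core.
#' @return A list, one entry per core node:
#'   list(node_index, label, size, segments = tibble(substructure, count,
#'   fraction)).
#' @export
pie_metadata <- function(core, annotation) {
  member_count <- sum(annotation$count[annotation$node_index == 1])
  lapply(seq_len(rg_n_nodes(core$graph)), function(node) {
    seg <- annotation[annotation$node_index == node, ]
    list(
      node_index = node,
      label = core$graph$labels[node],
      size = nrow(seg),
      segments = tibble::tibble(
        substructure = seg$substructure_smarts,
        count = seg$count,
        fraction = seg$count / member_count
      )
    )
  })
}

#' Core-overlap matrix
#'
#' Entry (i, j) counts the molecules assigned to both core i and core j; the
#' diagonal holds the core member counts.
#'
#' @param assignments An `rg_assignments` object.
#' @return A symmetric integer matrix with cores as rows and columns.
#' @export
overlap_matrix <- function(assignments) {
  n <- length(assignments)
  ids <- lapply(assignments, `[[`, "member_ids")
  m <- matrix(0L, n, n,
              dimnames = list(paste0("core_", vapply(assignments, `[[`, integer(1), "core_id")),
                              paste0("core_", vapply(assignments, `[[`, integer(1), "core_id"))))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(ids[[i]], ids[[j]]))
    }
  }
  m
}

#' Dataset-level reduced-graph summary
#'
#' @param records The cleaned dataset tibble.
#' @param rgs The list of `reduced_graph` objects built from it.
#' @return A one-row tibble: number of molecules, mean heavy atoms per
#'   molecule, number of unique RGs (canonical RG-SMILES equality), mean
#'   nodes per RG, and mean nodes per unique RG.
#' @export
dataset_summary <- function(records, rgs) {
  if (length(rgs) == 0) {
    return(tibble::tibble(n_molecules = 0L, mean_heavy_atoms = NA_real_,
                          n_unique_rgs = 0L, mean_nodes_per_rg = NA_real_,
                          mean_nodes_per_unique_rg = NA_real_))
  }
  nodes <- vapply(rgs, function(r) length(r$labels), integer(1))
  smiles <- vapply(rgs, `[[`, character(1), "rg_smiles")
  uniq <- !duplicated(smiles)
  tibble::tibble(
    n_molecules = length(rgs),
    mean_heavy_atoms = mean(vapply(rgs, `[[`, numeric(1), "n_atoms")),
    n_unique_rgs = sum(uniq),
    mean_nodes_per_rg = mean(nodes),
    mean_nodes_per_unique_rg = mean(nodes[uniq])
  )
}
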