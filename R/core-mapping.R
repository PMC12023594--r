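# Second-pass assignment of molecules to cores and resolution of ambiguous
# correspondences via topological distance maps.

# all-pairs through-bond distances between heavy atoms of the molecule
atom_distances <- function(rg) {
  g <- igraph::make_empty_graph(n = rg$n_atoms, directed = FALSE)
  if (nrow(rg$bonds) > 0) {
    g <- igraph::add_edges(g, t(rg$bonds[, c("a", "b"), drop = FALSE]))
  }
  igraph::distances(g)
}

#' Enumerate mappings of a molecule onto an RG core
#'
#' All label- and edge-multiplicity-preserving induced embeddings of the core
#' graph into the molecule's reduced graph. Embeddings that differ only by a
#' core automorphism over the same set of molecule nodes collapse to a single
#' canonical mapping; the result is sorted by the mapped atom image so the
#' candidate order is independent of enumeration order.
#'
#' @param rg A `reduced_graph`.
#' @param core An `rg_core` (or bare `rg_graph`).
#' @return A list of integer vectors (core node -> molecule RG node); empty
#'   if the molecule does not contain the core.
#' @export
enumerate_mappings <- function(rg, core) {
  emb <- rg_embeddings(as_rg_graph(core), as_rg_graph(rg))
  if (length(emb) == 0) return(list())
  image_key <- vapply(emb, function(m) paste(sort(m), collapse = ","), character(1))
  corr_key <- vapply(emb, function(m) paste(m, collapse = ","), character(1))
  keep <- vapply(split(seq_along(emb), image_key), function(idx) {
    idx[order(corr_key[idx])[1]]
  }, integer(1))
  emb <- emb[sort(keep)]
  atom_key <- vapply(emb, function(m) {
    paste(sprintf("%05d", sort(unlist(rg$atom_indices[m]))), collapse = ",")
  }, character(1))
  emb[order(atom_key)]
}

#' Node topological distance map of a mapping
#'
#' For every unordered pair of core nodes, the shortest through-bond distance
#' in the molecule between the two mapped atom sets (minimum over atom pairs,
#' one atom from each node).
#'
#' @param rg A `reduced_graph`.
#' @param mapping Integer vector from [enumerate_mappings()].
#' @param dmat Optional precomputed atom distance matrix.
#' @return Named integer vector, names `"i-j"` with i < j over core node
#'   indices; empty for a single-node core.
#' @export
node_distance_map <- function(rg, mapping, dmat = NULL) {
  k <- length(mapping)
  if (k < 2) return(stats::setNames(integer(0), character(0)))
  if (is.null(dmat)) dmat <- atom_distances(rg)
  out <- integer(0)
  nms <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ai <- rg$atom_indices[[mapping[i]]]
      aj <- rg$atom_indices[[mapping[j]]]
      out <- c(out, as.integer(min(dmat[ai, aj])))
      nms <- c(nms, paste0(i, "-", j))
    }
  }
  stats::setNames(out, nms)
}

#' Substituent topological distance map of a mapping
#'
#' Substitution sites are the first atoms outside the core image that are
#' bonded to a core-image atom. For each core node the through-bond distances
#' from the node (nearest atom) to every site are listed, sorted ascending.
#'
#' @inheritParams node_distance_map
#' @return A list, one sorted integer vector per core node (list length =
#'   core size; vector length = number of substitution sites).
#' @export
substituent_distance_map <- function(rg, mapping, dmat = NULL) {
  if (is.null(dmat)) dmat <- atom_distances(rg)
  core_atoms <- sort(unlist(rg$atom_indices[mapping]))
  sites <- integer(0)
  if (nrow(rg$bonds) > 0) {
    # external atoms adjacent to any core-image atom
    adj_ext <- c(rg$bonds[rg$bonds[, "a"] %in% core_atoms &
                            !(rg$bonds[, "b"] %in% core_atoms), "b"],
                 rg$bonds[rg$bonds[, "b"] %in% core_atoms &
                            !(rg$bonds[, "a"] %in% core_atoms), "a"])
    sites <- sort(unique(as.integer(adj_ext)))
  }
  lapply(seq_along(mapping), function(i) {
    ai <- rg$atom_indices[[mapping[i]]]
    if (length(sites) == 0) return(integer(0))
    sort(vapply(sites, function(s) as.integer(min(dmat[ai, s])), integer(1)))
  })
}

serialise_node_map <- function(m) paste(names(m), m, sep = ":", collapse = ";")
serialise_sub_map <- function(m) {
  paste(vapply(m, function(v) paste(v, collapse = ","), character(1)),
        collapse = ";")
}

#' Aggregate reference distance maps over uniquely mapped molecules
#'
#' Identical maps are collapsed with a frequency count; a map seen for the
#' first time is appended.
#'
#' @param maps List of maps (node maps or substituent maps).
#' @param serialise Serialisation function defining map identity.
#' @return list(list(map, count), ...) in first-seen order.
#' @export
aggregate_reference_maps <- function(maps, serialise = serialise_node_map) {
  refs <- list()
  index <- character(0)
  for (m in maps) {
    key <- serialise(m)
    hit <- match(key, index)
    if (is.na(hit)) {
      refs[[length(refs) + 1]] <- list(map = m, count = 1L)
      index <- c(index, key)
    } else {
      refs[[hit]]$count <- refs[[hit]]$count + 1L
    }
  }
  refs
}

#' Resolve an ambiguous mapping against reference distance maps
#'
#' Cascade: (1) if exactly one candidate's node distance map matches a
#' reference map, use it; (2) among several matching candidates, the one
#' whose matched reference has the highest count; (3, 4) the same two rules
#' on substituent distance maps; (5) deterministic fallback: the candidate
#' with the lexicographically smallest mapped atom image. The stage that
#' decided is recorded.
#'
#' @param rg A `reduced_graph`.
#' @param candidates List of candidate mappings (>= 2) from
#'   [enumerate_mappings()].
#' @param node_refs,sub_refs Reference maps from [aggregate_reference_maps()].
#' @return list(mapping, stage) with stage one of `node_map`,
#'   `node_map_frequency`, `substituent_map`, `substituent_map_frequency`,
#'   `fallback`.
#' @export
resolve_mapping <- function(rg, candidates, node_refs, sub_refs) {
  stopifnot(length(candidates) >= 2)
  dmat <- atom_distances(rg)

  stage_pick <- function(cands, refs, maps_for, serialise, stage_unique, stage_freq) {
    keys <- vapply(refs, function(r) serialise(r$map), character(1))
    counts <- vapply(refs, `[[`, integer(1), "count")
    cand_keys <- vapply(cands, function(cm) serialise(maps_for(cm)), character(1))
    hit <- match(cand_keys, keys)
    matching <- which(!is.na(hit))
    if (length(matching) == 1) {
      return(list(done = TRUE, mapping = cands[[matching]], stage = stage_unique))
    }
    if (length(matching) > 1) {
      cnt <- counts[hit[matching]]
      top <- matching[cnt == max(cnt)]
      if (length(top) == 1) {
        return(list(done = TRUE, mapping = cands[[top]], stage = stage_freq))
      }
      return(list(done = FALSE, survivors = cands[top]))
    }
    list(done = FALSE, survivors = cands)
  }

  res <- stage_pick(candidates, node_refs,
                    function(cm) node_distance_map(rg, cm, dmat),
                    serialise_node_map, "node_map", "node_map_frequency")
  if (res$done) return(list(mapping = res$mapping, stage = res$stage))

  res <- stage_pick(res$survivors, sub_refs,
                    function(cm) substituent_distance_map(rg, cm, dmat),
                    serialise_sub_map, "substituent_map", "substituent_map_frequency")
  if (res$done) return(list(mapping = res$mapping, stage = res$stage))

  # fallback: smallest mapped atom image (candidates are pre-sorted that way)
  list(mapping = res$survivors[[1]], stage = "fallback")
}

#' Assign every molecule to every core it contains
#'
#' Two phases per core: first all molecules with exactly one mapping are
#' registered and their node/substituent distance maps aggregated into the
#' core's reference maps; then each ambiguously mapped molecule is resolved
#' against those (frozen) references. A molecule appears under every core
#' whose graph its RG contains.
#'
#' @param rgs Named list of `reduced_graph` objects (dataset order).
#' @param cores List of `rg_core` objects from [extract_cores()].
#' @return An object of class `rg_assignments`: a list with one entry per
#'   core, each holding `core_id`, `member_ids` and `mappings` (named by
#'   compound id: list(mapping, ambiguous, stage)).
#' @export
assign_all <- function(rgs, cores) {
  out <- lapply(cores, function(core) {
    cand <- lapply(rgs, enumerate_mappings, core = core)
    nmap <- vapply(cand, length, integer(1))
    members <- which(nmap > 0)

    unique_idx <- members[nmap[members] == 1]
    node_maps <- list(); sub_maps <- list()
    mappings <- list()
    for (i in unique_idx) {
      rg <- rgs[[i]]
      dmat <- atom_distances(rg)
      m <- cand[[i]][[1]]
      node_maps[[length(node_maps) + 1]] <- node_distance_map(rg, m, dmat)
      sub_maps[[length(sub_maps) + 1]] <- substituent_distance_map(rg, m, dmat)
      mappings[[rg$compound_id]] <- list(mapping = m, ambiguous = FALSE,
                                         stage = "unique")
    }
    node_refs <- aggregate_reference_maps(node_maps, serialise_node_map)
    sub_refs <- aggregate_reference_maps(sub_maps, serialise_sub_map)

    for (i in members[nmap[members] > 1]) {
      rg <- rgs[[i]]
      res <- resolve_mapping(rg, cand[[i]], node_refs, sub_refs)
      mappings[[rg$compound_id]] <- list(mapping = res$mapping, ambiguous = TRUE,
                                         stage = res$stage)
    }
    member_ids <- vapply(rgs[members], `[[`, character(1), "compound_id")
    list(core_id = core$core_id, member_ids = member_ids,
         mappings = mappings[member_ids])
  })
  structure(out, class = "rg_assignments")
}

#' @export
print.rg_assignments <- function(x, ...) {
  cat("<rg_assignments> ", length(x), " cores; members: ",
      paste(vapply(x, function(a) length(a$member_ids), integer(1)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
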