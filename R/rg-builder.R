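# Reduced-graph construction: collapse a molecule into typed nodes (rings,
# H-bonding groups, complex atoms, inert linkers) joined by edges that follow
# the bonds of the original structure.

HALOGEN_Z <- c(9L, 17L, 35L, 53L, 85L)

#' Per-atom hydrogen-bond donor/acceptor flags
#'
#' Each heavy atom is matched independently against the configured HBA and
#' HBD SMARTS; an atom matching both carries both flags (HBA-HBD character).
#'
#' @param perception A perception record from [perceive_molecules()].
#' @return list(is_hba, is_hbd): logical vectors over the molecule's atoms.
#' @export
perceive_functional_groups <- function(perception) {
  n <- perception$n_atoms
  is_hba <- seq_len(n) %in% perception$hba_atoms
  is_hbd <- seq_len(n) %in% perception$hbd_atoms
  list(is_hba = is_hba, is_hbd = is_hbd)
}

hb_class <- function(has_hba, has_hbd) {
  if (has_hba && has_hbd) "HBA_HBD"
  else if (has_hba) "HBA"
  else if (has_hbd) "HBD"
  else "inert"
}

#' Ring perception for RG construction
#'
#' One descriptor per SSSR ring: its atom set, aromaticity (all ring bonds
#' aromatic) and hydrogen-bonding class derived from the donor/acceptor flags
#' of the ring atoms. Rings are sorted by (size, atom indices) so downstream
#' processing is independent of the toolkit's ring enumeration order.
#'
#' @param perception A perception record.
#' @param fg Output of [perceive_functional_groups()].
#' @return A list of `list(atoms, aromatic, hbond_class)` descriptors.
#' @export
perceive_rings <- function(perception, fg) {
  rings <- lapply(perception$rings, function(r) {
    atoms <- sort(as.integer(r$atoms))
    list(
      atoms = atoms,
      aromatic = isTRUE(r$aromatic),
      hbond_class = hb_class(any(fg$is_hba[atoms]), any(fg$is_hbd[atoms]))
    )
  })
  if (length(rings) == 0) return(rings)
  keys <- vapply(rings, function(r) {
    sprintf("%03d|%s", length(r$atoms), paste(sprintf("%04d", r$atoms), collapse = ","))
  }, character(1))
  rings[order(keys)]
}

bond_matrix <- function(perception) {
  if (length(perception$bonds) == 0)
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order"))))
  do.call(rbind, lapply(perception$bonds, function(b) c(a = b$a, b = b$b, order = b$order)))
}

# connected components of an atom subset under the molecule's bonds
atom_components <- function(atoms, bonds) {
  if (length(atoms) == 0) return(list())
  comp <- as.list(atoms)
  names(comp) <- atoms
  parent <- stats::setNames(as.character(atoms), atoms)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      a <- as.character(bonds[k, "a"]); b <- as.character(bonds[k, "b"])
      if (a %in% names(parent) && b %in% names(parent)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[[ra]] <- rb
      }
    }
  }
  roots <- vapply(as.character(atoms), find, character(1))
  unname(lapply(split(atoms, roots), function(x) sort(unname(x))))
}

new_node <- function(structural_class, hbond_class, atoms) {
  list(structural_class = structural_class, hbond_class = hbond_class,
       atoms = sort(unname(as.integer(atoms))))
}

#' Build the pre-merge node partition of a molecule
#'
#' Assignment precedence: (1) one node per SSSR ring (an atom shared between
#' fused rings goes to the first ring in the deterministic ring order); (2)
#' connected groups of acyclic donor/acceptor-flagged atoms become acyclic
#' HBA/HBD/HBA-HBD nodes; (3) remaining acyclic heteroatoms (halogens
#' included) and acyclic carbons with three or more heavy neighbours become
#' complex nodes, grouped when adjacent; (4) whatever acyclic atoms remain
#' form acyclic inert nodes. Every heavy atom lands in exactly one node.
#'
#' @param perception A perception record.
#' @param fg Donor/acceptor flags.
#' @param rings Output of [perceive_rings()].
#' @return list(nodes, ring_ids): nodes are `list(structural_class,
#'   hbond_class, atoms)`; `ring_ids[k]` gives the index into `rings` for the
#'   k-th node when that node is a ring, NA otherwise.
#' @export
build_raw_nodes <- function(perception, fg, rings) {
  n <- perception$n_atoms
  bonds <- bond_matrix(perception)
  atoms <- perception$atoms
  assigned <- logical(n)
  nodes <- list()
  ring_ids <- integer(0)

  for (ri in seq_along(rings)) {
    r <- rings[[ri]]
    own <- r$atoms[!assigned[r$atoms]]
    if (length(own) == 0) next   # ring fully covered by earlier fused rings
    assigned[own] <- TRUE
    nodes[[length(nodes) + 1]] <- new_node(
      if (r$aromatic) "aromatic_ring" else "aliphatic_ring",
      r$hbond_class, own
    )
    ring_ids[length(nodes)] <- ri
  }

  acyclic <- which(!assigned)
  flagged <- acyclic[fg$is_hba[acyclic] | fg$is_hbd[acyclic]]
  for (grp in atom_components(flagged, bonds)) {
    nodes[[length(nodes) + 1]] <- new_node(
      "acyclic", hb_class(any(fg$is_hba[grp]), any(fg$is_hbd[grp])), grp
    )
    ring_ids[length(nodes)] <- NA_integer_
    assigned[grp] <- TRUE
  }

  acyclic <- which(!assigned)
  is_complex <- vapply(acyclic, function(i) {
    a <- atoms[[i]]
    a$atomic_num != 6L || a$degree >= 3L
  }, logical(1))
  for (grp in atom_components(acyclic[is_complex], bonds)) {
    nodes[[length(nodes) + 1]] <- new_node("complex", NA_character_, grp)
    ring_ids[length(nodes)] <- NA_integer_
    assigned[grp] <- TRUE
  }

  for (grp in atom_components(which(!assigned), bonds)) {
    nodes[[length(nodes) + 1]] <- new_node("acyclic", "inert", grp)
    ring_ids[length(nodes)] <- NA_integer_
    assigned[grp] <- TRUE
  }
  list(nodes = nodes, ring_ids = ring_ids)
}

# remove atoms from a node, splitting it into connected components if needed
remove_atoms_from_node <- function(nodes, ring_ids, idx, atoms_out, bonds) {
  left <- setdiff(nodes[[idx]]$atoms, atoms_out)
  cls <- nodes[[idx]]
  if (length(left) == 0) {
    nodes[[idx]] <- NULL
    ring_ids <- ring_ids[-idx]
  } else {
    comps <- atom_components(left, bonds)
    nodes[[idx]]$atoms <- comps[[1]]
    for (extra in comps[-1]) {
      nodes[[length(nodes) + 1]] <- new_node(cls$structural_class, cls$hbond_class, extra)
      ring_ids[length(nodes)] <- NA_integer_
    }
  }
  list(nodes = nodes, ring_ids = ring_ids)
}

node_of_atom <- function(nodes, atom) {
  for (k in seq_along(nodes)) if (atom %in% nodes[[k]]$atoms) return(k)
  NA_integer_
}

#' Apply the carbonyl and acyl-halide special rules
#'
#' (a) An acyclic carbonyl carbon joins the acceptor node of its doubly
#' bonded oxygen, so C=O behaves as one HBA-bearing group; when the carbonyl
#' carbon sits in a ring the exocyclic oxygen stays as its own acyclic HBA
#' node. (b) An acyclic halogen adjacent to an acyclic HBA node is absorbed
#' into that node, so e.g. an acyl chloride collapses to a single node.
#'
#' @inheritParams build_raw_nodes
#' @param raw Output of [build_raw_nodes()].
#' @return Updated list(nodes, ring_ids).
#' @export
apply_special_rules <- function(perception, fg, raw) {
  nodes <- raw$nodes
  ring_ids <- raw$ring_ids
  bonds <- bond_matrix(perception)
  atoms <- perception$atoms
  in_ring <- vapply(atoms, function(a) isTRUE(a$in_ring), logical(1))
  znum <- vapply(atoms, function(a) a$atomic_num, numeric(1))

  # (a) acyclic carbonyl carbon joins the oxygen's acceptor node
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      if (bonds[k, "order"] != 2) next
      a <- unname(bonds[k, "a"]); b <- unname(bonds[k, "b"])
      if (znum[a] == 8 && znum[b] == 6) { o <- a; cc <- b }
      else if (znum[b] == 8 && znum[a] == 6) { o <- b; cc <- a }
      else next
      if (in_ring[o] || in_ring[cc]) next
      o_node <- node_of_atom(nodes, o)
      c_node <- node_of_atom(nodes, cc)
      if (o_node == c_node) next
      if (!(nodes[[o_node]]$structural_class == "acyclic" &&
            nodes[[o_node]]$hbond_class %in% c("HBA", "HBA_HBD"))) next
      upd <- remove_atoms_from_node(nodes, ring_ids, c_node, cc, bonds)
      nodes <- upd$nodes; ring_ids <- upd$ring_ids
      o_node <- node_of_atom(nodes, o)   # indices may have shifted
      nodes[[o_node]]$atoms <- sort(c(nodes[[o_node]]$atoms, cc))
    }
  }

  # (b) acyclic halogen adjacent to an acyclic HBA node is absorbed
  repeat {
    moved <- FALSE
    for (k in seq_len(max(nrow(bonds), 0))) {
      a <- unname(bonds[k, "a"]); b <- unname(bonds[k, "b"])
      hal <- if (znum[a] %in% HALOGEN_Z && !in_ring[a]) a
             else if (znum[b] %in% HALOGEN_Z && !in_ring[b]) b
             else next
      other <- if (hal == a) b else a
      hal_node <- node_of_atom(nodes, hal)
      tgt <- node_of_atom(nodes, other)
      if (hal_node == tgt) next
      if (!(nodes[[tgt]]$structural_class == "acyclic" &&
            nodes[[tgt]]$hbond_class == "HBA")) next
      upd <- remove_atoms_from_node(nodes, ring_ids, hal_node, hal, bonds)
      nodes <- upd$nodes; ring_ids <- upd$ring_ids
      tgt <- node_of_atom(nodes, other)
      nodes[[tgt]]$atoms <- sort(c(nodes[[tgt]]$atoms, hal))
      moved <- TRUE
      break
    }
    if (!moved) break
  }
  list(nodes = nodes, ring_ids = ring_ids)
}

#' Merge adjoining acyclic nodes to a fixed point
#'
#' Three rules, applied in order until none fires: adjacent acyclic nodes of
#' the same (structural, H-bonding) type combine; an acyclic HBA or HBD node
#' adjacent to an acyclic HBA-HBD node is subsumed by it; an acyclic inert
#' node adjacent to a complex node is absorbed into the complex node. Ring
#' nodes never merge, preserving the ring count of the molecule.
#'
#' @inheritParams apply_special_rules
#' @param staged Output of [apply_special_rules()].
#' @return Updated list(nodes, ring_ids).
#' @export
merge_nodes <- function(perception, staged) {
  nodes <- staged$nodes
  ring_ids <- staged$ring_ids
  bonds <- bond_matrix(perception)

  adjacent <- function(n1, n2) {
    if (nrow(bonds) == 0) return(FALSE)
    any((bonds[, "a"] %in% n1$atoms & bonds[, "b"] %in% n2$atoms) |
        (bonds[, "b"] %in% n1$atoms & bonds[, "a"] %in% n2$atoms))
  }
  is_ring <- function(nd) nd$structural_class %in% c("aromatic_ring", "aliphatic_ring")

  do_merge <- function(into, from) {
    nodes[[into]]$atoms <<- sort(c(nodes[[into]]$atoms, nodes[[from]]$atoms))
    nodes[[from]] <<- NULL
    ring_ids <<- ring_ids[-from]
  }

  repeat {
    fired <- FALSE
    pairs <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
    for (rule in 1:3) {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        ni <- nodes[[i]]; nj <- nodes[[j]]
        if (is_ring(ni) || is_ring(nj)) next
        if (!adjacent(ni, nj)) next
        if (rule == 1 &&
            identical(ni$structural_class, nj$structural_class) &&
            identical(ni$hbond_class, nj$hbond_class)) {
          do_merge(i, j); fired <- TRUE; break
        }
        if (rule == 2 && ni$structural_class == "acyclic" &&
            nj$structural_class == "acyclic") {
          if (ni$hbond_class == "HBA_HBD" && nj$hbond_class %in% c("HBA", "HBD")) {
            do_merge(i, j); fired <- TRUE; break
          }
          if (nj$hbond_class == "HBA_HBD" && ni$hbond_class %in% c("HBA", "HBD")) {
            do_merge(j, i); fired <- TRUE; break
          }
        }
        if (rule == 3) {
          if (ni$structural_class == "complex" &&
              nj$structural_class == "acyclic" && nj$hbond_class == "inert") {
            do_merge(i, j); fired <- TRUE; break
          }
          if (nj$structural_class == "complex" &&
              ni$structural_class == "acyclic" && ni$hbond_class == "inert") {
            do_merge(j, i); fired <- TRUE; break
          }
        }
      }
      if (fired) break
    }
    if (!fired) break
  }
  list(nodes = nodes, ring_ids = ring_ids)
}

#' Assemble the reduced graph of one molecule
#'
#' Runs the full workflow: donor/acceptor perception, SSSR ring perception,
#' raw node partition, carbonyl/halogen special rules, node merging, edge
#' construction (nodes joined by at least one bond; two ring nodes whose SSSR
#' rings share two or more atoms are fused and joined with multiplicity 2),
#' substructure annotation and canonical RG-SMILES serialisation.
#'
#' @param smiles Input SMILES (cleaned internally: largest fragment,
#'   neutralised, canonicalised).
#' @param compound_id Identifier carried on the result.
#' @param pic50 Activity value carried on the result (may be NA).
#' @param config An [rg_config()].
#' @param perception Optional pre-computed perception record (batch callers).
#' @return An object of class `reduced_graph`.
#' @examples
#' \dontrun{
#' rg <- assemble_rg("Cc1ccccc1", "toluene")
#' rg$rg_smiles   # "[Li][No]"
#' }
#' @export
assemble_rg <- function(smiles, compound_id = NA_character_, pic50 = NA_real_,
                        config = rg_config(), perception = NULL) {
  if (is.null(perception)) perception <- perceive_molecules(smiles, config)[[1]]
  if (!is.null(perception$error))
    stop("cannot build RG for ", compound_id, ": ", perception$error, call. = FALSE)

  fg <- perceive_functional_groups(perception)
  rings <- perceive_rings(perception, fg)
  raw <- build_raw_nodes(perception, fg, rings)
  staged <- apply_special_rules(perception, fg, raw)
  merged <- merge_nodes(perception, staged)

  nodes <- merged$nodes
  ring_ids <- merged$ring_ids
  ord <- order(vapply(nodes, function(nd) min(nd$atoms), numeric(1)))
  nodes <- nodes[ord]
  ring_ids <- ring_ids[ord]

  n <- length(nodes)
  labels <- vapply(nodes, function(nd) {
    rg_node_label(nd$structural_class, nd$hbond_class)
  }, character(1))

  # edges: bonds crossing node boundaries; fused SSSR rings get multiplicity 2
  bonds <- bond_matrix(perception)
  node_of <- integer(perception$n_atoms)
  for (k in seq_len(n)) node_of[nodes[[k]]$atoms] <- k
  edge_set <- list()
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      ni <- node_of[bonds[k, "a"]]; nj <- node_of[bonds[k, "b"]]
      if (ni != nj) edge_set[[paste(min(ni, nj), max(ni, nj))]] <- c(min(ni, nj), max(ni, nj), 1L)
    }
  }
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p >= q || is.na(ring_ids[p]) || is.na(ring_ids[q])) next
      shared <- length(intersect(rings[[ring_ids[p]]]$atoms, rings[[ring_ids[q]]]$atoms))
      if (shared >= 2) edge_set[[paste(p, q)]] <- c(p, q, 2L)
    }
  }
  edges <- if (length(edge_set) > 0) do.call(rbind, unname(edge_set)) else NULL

  g <- rg_graph(labels, edges)
  atom_sets <- lapply(nodes, `[[`, "atoms")
  substructure <- extract_fragments(perception$smiles, atom_sets)

  structure(list(
    compound_id = compound_id,
    smiles = perception$smiles,
    pic50 = pic50,
    labels = labels,
    structural_class = vapply(nodes, `[[`, character(1), "structural_class"),
    hbond_class = vapply(nodes, function(nd) {
      if (is.na(nd$hbond_class)) NA_character_ else nd$hbond_class
    }, character(1)),
    atom_indices = atom_sets,
    substructure = substructure,
    edges = g$edges,
    rg_smiles = rg_graph_smiles(g),
    n_atoms = perception$n_atoms,
    bonds = bonds
  ), class = "reduced_graph")
}

#' Build reduced graphs for a whole dataset
#'
#' Batched variant of [assemble_rg()]: one backend perception call for all
#' molecules. Records whose SMILES cannot be processed are dropped with a
#' warning.
#'
#' @param records A data frame with columns `compound_id`, `smiles`, `pic50`
#'   (as returned by [read_dataset()] / [clean_dataset()]).
#' @param config An [rg_config()].
#' @return A named list of `reduced_graph` objects, in record order.
#' @export
build_rgs <- function(records, config = rg_config()) {
  percs <- perceive_molecules(records$smiles, config)
  out <- list()
  for (i in seq_len(nrow(records))) {
    if (!is.null(percs[[i]]$error)) {
      warning("skipping ", records$compound_id[i], ": ", percs[[i]]$error,
              call. = FALSE)
      next
    }
    out[[records$compound_id[i]]] <- assemble_rg(
      records$smiles[i], records$compound_id[i], records$pic50[i],
      config, perception = percs[[i]]
    )
  }
  out
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat("<reduced_graph> ", x$compound_id, ": ", x$rg_smiles,
      " (", length(x$labels), " nodes over ", x$n_atoms, " atoms)\n", sep = "")
  invisible(x)
}

# bare labelled graph of a reduced graph, rg_core, or rg_graph
as_rg_graph <- function(x) {
  if (inherits(x, "rg_graph")) return(x)
  if (inherits(x, "rg_core")) return(x$graph)
  rg_graph(x$labels, x$edges)
}
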