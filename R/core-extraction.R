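# RG core extraction: iterative maximum-common-subgraph series detection
# driven by graph-Tanimoto near-neighbour lists.

.mcs_cache <- new.env(parent = emptyenv())

# MCS memoised by the unordered pair of canonical codes; the result graph is
# order-independent because ties are broken canonically.
rg_mcs_cached <- function(a, b) {
  ga <- as_rg_graph(a); gb <- as_rg_graph(b)
  ca <- rg_code(ga); cb <- rg_code(gb)
  key <- paste(sort(c(ca, cb)), collapse = "\r")
  if (exists(key, envir = .mcs_cache, inherits = FALSE)) {
    hit <- get(key, envir = .mcs_cache, inherits = FALSE)
    return(hit)
  }
  res <- rg_mcs(ga, gb)
  out <- list(graph = res$graph, size = res$size)
  assign(key, out, envir = .mcs_cache)
  out
}

#' Graph Tanimoto similarity between two reduced graphs
#'
#' T = MCS / (A + B - MCS), where A and B are the node counts of the two RGs
#' and MCS the node count of their maximum common connected subgraph (exact
#' node-label and edge-multiplicity matching).
#'
#' @param a,b `reduced_graph` or `rg_graph` objects.
#' @return list(A, B, mcs_size, tanimoto).
#' @examples
#' \dontrun{
#' tanimoto(assemble_rg("Cc1ccccc1"), assemble_rg("CCc1ccccc1"))$tanimoto  # 1
#' }
#' @export
tanimoto <- function(a, b) {
  ga <- as_rg_graph(a); gb <- as_rg_graph(b)
  A <- rg_n_nodes(ga); B <- rg_n_nodes(gb)
  if (A == 0 && B == 0) stop("Tanimoto undefined for two empty graphs", call. = FALSE)
  m <- rg_mcs_cached(ga, gb)$size
  list(A = A, B = B, mcs_size = m, tanimoto = m / (A + B - m))
}

#' Near-neighbour lists over a set of reduced graphs
#'
#' For every RG, all other RGs with Tanimoto similarity at or above the
#' threshold, sorted by descending similarity; ties keep input order, so the
#' list tail is the most distant neighbour.
#'
#' @param rgs List of `reduced_graph` objects.
#' @param threshold Similarity threshold in \[0, 1\].
#' @return A list (one element per RG, named by compound id) of integer
#'   vectors indexing `rgs`, each with a `similarity` attribute.
#' @export
neighbour_lists <- function(rgs, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  n <- length(rgs)
  sims <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        t <- tanimoto(rgs[[i]], rgs[[j]])$tanimoto
        sims[i, j] <- t; sims[j, i] <- t
      }
    }
  }
  out <- lapply(seq_len(n), function(i) {
    idx <- setdiff(which(sims[i, ] >= threshold), i)
    idx <- idx[order(-sims[i, idx])]        # stable: ties keep input order
    attr(idx, "similarity") <- sims[i, idx]
    idx
  })
  names(out) <- vapply(rgs, function(r) as.character(r$compound_id), character(1))
  out
}

#' Initial candidate MCS for a centroid
#'
#' Walks the centroid's neighbours starting from the most distant one and
#' returns the first MCS with at least `min_size` nodes. If no neighbour
#' yields one, the largest MCS seen over all neighbours is returned and
#' flagged as sub-minimal.
#'
#' @param centroid A `reduced_graph`.
#' @param neighbours Integer vector of neighbour indices, descending
#'   similarity (as one element of [neighbour_lists()]).
#' @param rgs The full RG list the indices refer to.
#' @param min_size Minimum core size.
#' @return list(graph, consumed = neighbour index, sub_minimal = logical).
#' @export
find_candidate_mcs <- function(centroid, neighbours, rgs, min_size) {
  if (length(neighbours) == 0)
    stop("find_candidate_mcs requires a non-empty neighbour list", call. = FALSE)
  best <- NULL
  for (j in rev(as.integer(neighbours))) {        # most distant first
    m <- rg_mcs_cached(centroid, rgs[[j]])
    if (m$size >= min_size) {
      return(list(graph = m$graph, consumed = j, sub_minimal = FALSE))
    }
    if (is.null(best) || m$size > best$size) {
      best <- list(graph = m$graph, size = m$size, consumed = j)
    }
  }
  list(graph = best$graph, consumed = best$consumed, sub_minimal = TRUE)
}

new_rg_core <- function(core_id, graph, member_ids, sub_minimal = FALSE) {
  structure(list(
    core_id = core_id,
    graph = graph,
    core_smarts = rg_graph_smiles(graph),
    member_ids = member_ids,
    sub_minimal = sub_minimal
  ), class = "rg_core")
}

#' @export
print.rg_core <- function(x, ...) {
  cat("<rg_core ", x$core_id, "> ", x$core_smarts, " (",
      length(x$member_ids), " members", if (x$sub_minimal) ", sub-minimal",
      ")\n", sep = "")
  invisible(x)
}

#' Extract RG cores from a dataset of reduced graphs
#'
#' Iterative series detection: (1) near-neighbour lists at the similarity
#' threshold; (2) the listed molecule with the most remaining neighbours
#' becomes the centroid (ties: earliest input order); (3) an initial
#' candidate MCS is taken against the centroid's most distant qualifying
#' neighbour, removing both molecules; (4) every remaining RG in list order
#' either contains the candidate (associate and remove) or proposes a
#' refined MCS, accepted only when it is a subgraph of the current candidate
#' and still at least `min_core_size` nodes, in which case all previous
#' members are re-associated; (5) the surviving candidate becomes an RG
#' core; (6) repeat until every molecule is associated. A centroid with no
#' remaining neighbours becomes a singleton core consisting of its whole RG.
#'
#' @param rgs A list of `reduced_graph` objects (dataset order).
#' @param config An [rg_config()] supplying `similarity_threshold` and
#'   `min_core_size`.
#' @return A list of `rg_core` objects in creation order.
#' @export
extract_cores <- function(rgs, config = rg_config()) {
  stopifnot(length(rgs) >= 1)
  n <- length(rgs)
  nbl <- neighbour_lists(rgs, config$similarity_threshold)
  ids <- unname(vapply(rgs, function(r) as.character(r$compound_id), character(1)))
  remaining <- rep(TRUE, n)
  cores <- list()

  while (any(remaining)) {
    working <- which(remaining)
    counts <- vapply(working, function(i) sum(remaining[nbl[[i]]]), integer(1))
    centroid <- working[which.max(counts)]   # first max = earliest input order
    nbrs <- nbl[[centroid]][remaining[nbl[[centroid]]]]

    if (length(nbrs) == 0) {
      core_graph <- as_rg_graph(rgs[[centroid]])
      remaining[centroid] <- FALSE
      cores[[length(cores) + 1]] <- new_rg_core(
        length(cores) + 1L, core_graph, ids[centroid],
        sub_minimal = rg_n_nodes(core_graph) < config$min_core_size
      )
      next
    }

    fc <- find_candidate_mcs(rgs[[centroid]], nbrs, rgs, config$min_core_size)
    candidate <- fc$graph
    sub_minimal <- fc$sub_minimal
    members <- c(centroid, fc$consumed)
    remaining[members] <- FALSE

    for (j in which(remaining)) {
      rg_j <- as_rg_graph(rgs[[j]])
      if (rg_contains(rg_j, candidate)) {
        members <- c(members, j)
        remaining[j] <- FALSE
      } else {
        m <- rg_mcs_cached(rg_j, candidate)
        if (m$size >= config$min_core_size && rg_contains(candidate, m$graph)) {
          candidate <- m$graph
          members <- c(members, j)
          remaining[j] <- FALSE
        }
      }
    }
    cores[[length(cores) + 1]] <- new_rg_core(
      length(cores) + 1L, candidate, ids[members], sub_minimal = sub_minimal
    )
  }
  cores
}

#' Core counts over a grid of thresholds and minimum sizes
#'
#' Convenience sweep reproducing the usual parameter-sensitivity table.
#'
#' @param rgs List of `reduced_graph` objects.
#' @param thresholds,min_sizes Numeric vectors of parameter values.
#' @return A tibble with columns `similarity_threshold`, `min_core_size`,
#'   `n_cores`.
#' @export
core_count_sweep <- function(rgs, thresholds = seq(0.1, 0.9, by = 0.1),
                             min_sizes = 2:7) {
  grid <- expand.grid(similarity_threshold = thresholds,
                      min_core_size = min_sizes)
  grid$n_cores <- vapply(seq_len(nrow(grid)), function(k) {
    cfg <- rg_config(similarity_threshold = grid$similarity_threshold[k],
                     min_core_size = grid$min_core_size[k])
    length(extract_cores(rgs, cfg))
  }, integer(1))
  tibble::as_tibble(grid)
}
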