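# Labelled-multigraph machinery for reduced graphs: canonical codes, the
# RG-SMILES serialisation, induced subgraph embeddings and the exact maximum
# common connected induced subgraph (MCS) used for series detection.
#
# A bare RG graph is a list(labels = character n, edges = integer matrix with
# columns i, j, mult). Edge multiplicity 2 marks fused-ring node pairs.

#' Construct a bare RG graph
#'
#' @param labels Character vector of node labels (two-letter element codes).
#' @param edges Integer matrix with columns `i`, `j`, `mult`, or a zero-row
#'   matrix / NULL for an edgeless graph.
#' @return An object of class `rg_graph`.
#' @export
rg_graph <- function(labels, edges = NULL) {
  labels <- as.character(labels)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(integer(0), ncol = 3, dimnames = list(NULL, c("i", "j", "mult")))
  } else {
    edges <- matrix(as.integer(edges), ncol = 3,
                    dimnames = list(NULL, c("i", "j", "mult")))
    if (any(edges[, 1:2] < 1) || any(edges[, 1:2] > length(labels)))
      stop("edge endpoint out of range", call. = FALSE)
  }
  structure(list(labels = labels, edges = edges), class = "rg_graph")
}

#' @export
print.rg_graph <- function(x, ...) {
  cat("<rg_graph> ", length(x$labels), " nodes, ", nrow(x$edges), " edges: ",
      rg_graph_smiles(x), "\n", sep = "")
  invisible(x)
}

rg_n_nodes <- function(g) length(g$labels)

# symmetric multiplicity matrix (0 = no edge)
rg_adj <- function(g) {
  n <- rg_n_nodes(g)
  adj <- matrix(0L, n, n)
  if (nrow(g$edges) > 0) {
    adj[g$edges[, 1:2, drop = FALSE]] <- g$edges[, 3]
    adj[g$edges[, 2:1, drop = FALSE]] <- g$edges[, 3]
  }
  adj
}

rg_is_connected <- function(g) {
  n <- rg_n_nodes(g)
  if (n <= 1) return(TRUE)
  adj <- rg_adj(g)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# induced subgraph on a node subset, preserving multiplicities
rg_induced <- function(g, nodes) {
  nodes <- as.integer(nodes)
  adj <- rg_adj(g)
  sub <- adj[nodes, nodes, drop = FALSE]
  el <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
  edges <- if (nrow(el) > 0) {
    cbind(el[, 1], el[, 2], sub[el])
  } else NULL
  rg_graph(g$labels[nodes], edges)
}

# --- canonical form ---------------------------------------------------------

# Weisfeiler-Lehman refinement; colour ranks are isomorphism-invariant because
# they derive from sorted signature strings.
wl_colours <- function(labels, adj) {
  n <- length(labels)
  if (n == 0) return(integer(0))
  col <- match(labels, sort(unique(labels)))
  for (iter in seq_len(n)) {
    sig <- vapply(seq_len(n), function(i) {
      nb <- which(adj[i, ] > 0)
      paste(col[i],
            paste(sort(sprintf("%03d:%d", col[nb], adj[i, nb])), collapse = ","),
            sep = "|")
    }, character(1))
    new <- match(sig, sort(unique(sig)))
    if (identical(new, col)) break
    col <- new
  }
  col
}

#' Canonical node ordering and code of an RG graph
#'
#' Branch-and-bound search for the lexicographically smallest row code
#' (label plus back-references to already-placed neighbours), with
#' Weisfeiler-Lehman colours collapsing equivalent branch candidates. Two
#' RG graphs are isomorphic (labels and edge multiplicities) iff their codes
#' are equal.
#'
#' @param g An `rg_graph`.
#' @return list(order = integer permutation, code = character scalar).
#' @keywords internal
rg_canonical <- function(g) {
  n <- rg_n_nodes(g)
  if (n == 0) return(list(order = integer(0), code = ""))
  adj <- rg_adj(g)
  labels <- g$labels
  col <- wl_colours(labels, adj)
  best <- new.env(parent = emptyenv())
  best$code <- NULL
  best$order <- NULL

  row_code <- function(v, placed) {
    nb <- which(adj[v, ] > 0)
    pos <- match(nb, placed)
    sel <- !is.na(pos)
    paste(labels[v],
          paste(sort(sprintf("%02d:%d", pos[sel], adj[v, nb[sel]])), collapse = ","),
          sep = "|")
  }

  recurse <- function(placed, codes) {
    k <- length(placed)
    if (k == n) {
      code <- paste(codes, collapse = ";")
      if (is.null(best$code) || code < best$code) {
        best$code <- code
        best$order <- placed
      }
      return(invisible(NULL))
    }
    rest <- setdiff(seq_len(n), placed)
    if (k > 0) {
      attached <- rest[vapply(rest, function(v) any(adj[v, placed] > 0), logical(1))]
      if (length(attached) > 0) rest <- attached
    }
    rows <- vapply(rest, row_code, character(1), placed = placed)
    minrow <- min(rows)
    seen <- character(0)
    for (v in rest[rows == minrow]) {
      key <- paste(minrow, col[v])
      if (key %in% seen) next
      seen <- c(seen, key)
      recurse(c(placed, v), c(codes, minrow))
    }
    invisible(NULL)
  }
  recurse(integer(0), character(0))
  list(order = best$order, code = best$code)
}

rg_code <- function(g) rg_canonical(g)$code

rg_isomorphic <- function(a, b) {
  length(a$labels) == length(b$labels) &&
    nrow(a$edges) == nrow(b$edges) &&
    identical(rg_code(a), rg_code(b))
}

# --- RG-SMILES serialisation ------------------------------------------------

#' Write an RG graph as an RG-SMILES string
#'
#' Nodes become bracket atoms over the two-letter label alphabet; branches and
#' ring closures follow SMILES grammar. A fused-ring double edge is encoded as
#' the tree bond plus one extra ring-closure pair between the same two nodes
#' (SMILES grammar cannot express parallel edges directly); the edge list
#' remains authoritative and the parser restores multiplicity 2.
#'
#' @param g An `rg_graph`.
#' @param canonical Use the canonical node ordering (default) so that
#'   isomorphic graphs serialise identically.
#' @return A character scalar such as `"[Ge][Li][No]([Hg])[Hg]"`.
#' @export
rg_graph_smiles <- function(g, canonical = TRUE) {
  n <- rg_n_nodes(g)
  if (n == 0) return("")
  order <- if (canonical) rg_canonical(g)$order else seq_len(n)
  adj <- rg_adj(g)
  pos <- integer(n)
  pos[order] <- seq_len(n)

  visited <- logical(n)
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  closures <- vector("list", n)        # closure digit tokens per node
  counter <- 0L
  used <- matrix(FALSE, n, n)          # tree edges already consumed

  token <- function(num) if (num < 10) as.character(num) else sprintf("%%%02d", num)

  dfs_order <- integer(0)
  stack <- order[1]
  visited[order[1]] <- TRUE
  # iterative DFS respecting canonical rank for child order
  dfs <- function(v) {
    dfs_order <<- c(dfs_order, v)
    nbs <- which(adj[v, ] > 0)
    nbs <- nbs[order(pos[nbs])]
    for (u in nbs) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        parent[u] <<- v
        used[v, u] <<- TRUE; used[u, v] <<- TRUE
        children[[v]] <<- c(children[[v]], u)
        # fused double edge on a tree bond: add one closure pair
        if (adj[v, u] == 2) {
          counter <<- counter + 1L
          closures[[v]] <<- c(closures[[v]], token(counter))
          closures[[u]] <<- c(closures[[u]], token(counter))
        }
        dfs(u)
      } else if (u != parent[v] && !used[v, u]) {
        used[v, u] <<- TRUE; used[u, v] <<- TRUE
        reps <- adj[v, u]               # back edge: one closure per multiplicity
        for (r in seq_len(reps)) {
          counter <<- counter + 1L
          closures[[v]] <<- c(closures[[v]], token(counter))
          closures[[u]] <<- c(closures[[u]], token(counter))
        }
      }
    }
  }
  dfs(order[1])

  emit <- function(v) {
    s <- paste0("[", g$labels[v], "]", paste(closures[[v]], collapse = ""))
    kids <- children[[v]]
    if (length(kids) > 0) {
      for (u in kids[-length(kids)]) s <- paste0(s, "(", emit(u), ")")
      s <- paste0(s, emit(kids[length(kids)]))
    }
    s
  }
  emit(order[1])
}

#' Parse an RG-SMILES string back into an RG graph
#'
#' @param s An RG-SMILES string produced by [rg_graph_smiles()].
#' @return An `rg_graph`. A repeated bond between the same node pair (adjacent
#'   bond plus ring closure) is folded into one edge of multiplicity 2.
#' @export
parse_rg_smiles <- function(s) {
  if (!nzchar(s)) return(rg_graph(character(0)))
  tokens <- regmatches(s, gregexpr("\\[[A-Za-z]+\\]|%[0-9]{2}|[0-9()]", s))[[1]]
  if (paste(tokens, collapse = "") != s)
    stop("cannot parse RG-SMILES: ", s, call. = FALSE)
  labels <- character(0)
  edges <- list()
  stack <- integer(0)
  prev <- NA_integer_
  open <- list()   # closure number -> node index
  add_bond <- function(a, b) {
    edges[[length(edges) + 1]] <<- c(min(a, b), max(a, b))
  }
  for (tk in tokens) {
    if (startsWith(tk, "[")) {
      labels <- c(labels, substr(tk, 2, nchar(tk) - 1))
      cur <- length(labels)
      if (!is.na(prev)) add_bond(prev, cur)
      prev <- cur
    } else if (tk == "(") {
      stack <- c(stack, prev)
    } else if (tk == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else {
      num <- if (startsWith(tk, "%")) substr(tk, 2, 3) else tk
      if (!is.null(open[[num]])) {
        add_bond(open[[num]], prev)
        open[[num]] <- NULL
      } else {
        open[[num]] <- prev
      }
    }
  }
  if (length(edges) == 0) return(rg_graph(labels))
  em <- do.call(rbind, edges)
  key <- paste(em[, 1], em[, 2])
  mult <- table(key)[unique(key)]
  uniq <- em[!duplicated(key), , drop = FALSE]
  rg_graph(labels, cbind(uniq, pmin(as.integer(mult), 2L)))
}

# --- induced subgraph embeddings --------------------------------------------

#' Enumerate induced label-preserving embeddings of one RG graph in another
#'
#' Backtracking search for injective maps from `pattern` nodes to `target`
#' nodes preserving labels and, for every node pair, the exact edge
#' multiplicity (including absence). With `first_only = TRUE` stops at the
#' first embedding (containment test).
#'
#' @return A list of integer vectors (pattern node i -> target node map[i]);
#'   empty list if the pattern does not embed.
#' @keywords internal
rg_embeddings <- function(pattern, target, first_only = FALSE) {
  np <- rg_n_nodes(pattern)
  nt <- rg_n_nodes(target)
  if (np == 0 || np > nt) return(list())
  padj <- rg_adj(pattern)
  tadj <- rg_adj(target)

  # BFS order over the pattern so each node after the first touches a placed one
  ordv <- integer(0)
  seen <- logical(np)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    ordv <- c(ordv, v)
    nb <- which(padj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) ordv <- c(ordv, which(!seen))   # disconnected pattern

  results <- list()
  map <- rep(NA_integer_, np)
  used <- logical(nt)
  recurse <- function(k) {
    if (k > np) {
      results[[length(results) + 1]] <<- map
      return(first_only)
    }
    p <- ordv[k]
    earlier <- ordv[seq_len(k - 1)]
    for (t in which(!used & target$labels == pattern$labels[p])) {
      ok <- TRUE
      for (e in earlier) {
        if (padj[p, e] != tadj[t, map[e]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[p] <<- t; used[t] <<- TRUE
      done <- recurse(k + 1)
      map[p] <<- NA_integer_; used[t] <<- FALSE
      if (isTRUE(done)) return(TRUE)
    }
    FALSE
  }
  recurse(1L)
  results
}

rg_contains <- function(big, small) {
  length(rg_embeddings(small, big, first_only = TRUE)) > 0
}

# --- maximum common connected induced subgraph ------------------------------

#' Maximum common connected subgraph of two RG graphs
#'
#' Exact search via the modular product graph: vertices are label-compatible
#' node pairs, edges join pairs whose adjacency status (edge multiplicity,
#' including absence) agrees in both graphs. Maximal cliques then correspond
#' to maximal common induced subgraphs; the largest connected component over
#' all maximal cliques is the connected MCS. Ties are broken by the canonical
#' code of the common subgraph so the result is deterministic.
#'
#' @param a,b `rg_graph` objects (or reduced graphs; the `labels`/`edges`
#'   fields are used).
#' @return list(graph = `rg_graph` (possibly empty), size, map_a, map_b) where
#'   `map_a[i]`/`map_b[i]` give the nodes of `a`/`b` realising common node i.
#' @export
rg_mcs <- function(a, b) {
  a <- rg_graph(a$labels, a$edges)
  b <- rg_graph(b$labels, b$edges)
  na <- rg_n_nodes(a); nb <- rg_n_nodes(b)
  empty <- list(graph = rg_graph(character(0)), size = 0L,
                map_a = integer(0), map_b = integer(0))
  if (na == 0 || nb == 0) return(empty)
  pairs <- which(outer(a$labels, b$labels, "=="), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(empty)
  aadj <- rg_adj(a); badj <- rg_adj(b)
  m <- nrow(pairs)
  # compatibility edges between product vertices
  el <- list()
  for (p in seq_len(m - 1)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    for (q in (p + 1):m) {
      k <- pairs[q, 1]; l <- pairs[q, 2]
      if (i != k && j != l && aadj[i, k] == badj[j, l]) {
        el[[length(el) + 1]] <- c(p, q)
      }
    }
  }
  if (length(el) == 0) {
    # best common subgraph is a single node; deterministic pick by label
    best_p <- order(a$labels[pairs[, 1]], pairs[, 1], pairs[, 2])[1]
    return(list(graph = rg_graph(a$labels[pairs[best_p, 1]]), size = 1L,
                map_a = pairs[best_p, 1], map_b = pairs[best_p, 2]))
  }
  pg <- igraph::make_empty_graph(n = m, directed = FALSE)
  pg <- igraph::add_edges(pg, t(do.call(rbind, el)))
  cliques <- igraph::max_cliques(pg)

  best <- NULL
  best_code <- NULL
  for (cl in cliques) {
    sel <- pairs[as.integer(cl), , drop = FALSE]
    anodes <- sel[, 1]
    sub <- aadj[anodes, anodes, drop = FALSE]
    # connected components of the common subgraph
    ng <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
    comp <- igraph::components(ng)
    for (cid in seq_len(comp$no)) {
      members <- which(comp$membership == cid)
      sz <- length(members)
      if (!is.null(best) && sz < best$size) next
      cand_a <- anodes[members]
      cand_b <- sel[members, 2]
      graph <- rg_induced(a, cand_a)
      code <- rg_code(graph)
      if (is.null(best) || sz > best$size ||
          (sz == best$size && code < best_code)) {
        best <- list(graph = graph, size = as.integer(sz),
                     map_a = cand_a, map_b = cand_b)
        best_code <- code
      }
    }
  }
  if (is.null(best)) empty else best
}
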