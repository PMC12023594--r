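# Brute-force oracles, independent of the clique-based MCS implementation:
# subset enumeration plus naive recursive embedding search.

oracle_adj <- function(g) {
  n <- length(g$labels)
  adj <- matrix(0L, n, n)
  if (nrow(g$edges) > 0) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1]; j <- g$edges[k, 2]; m <- g$edges[k, 3]
      adj[i, j] <- m; adj[j, i] <- m
    }
  }
  adj
}

oracle_connected <- function(nodes, adj) {
  if (length(nodes) <= 1) return(TRUE)
  seen <- nodes[1]
  repeat {
    grow <- setdiff(nodes[colSums(adj[seen, nodes, drop = FALSE] > 0) > 0], seen)
    if (length(grow) == 0) break
    seen <- c(seen, grow)
  }
  length(seen) == length(nodes)
}

# does the induced subgraph of `a` on `nodes` embed (induced, label- and
# multiplicity-exact) into b? naive recursion over all assignments
oracle_embeds <- function(a, nodes, b, adja = oracle_adj(a), adjb = oracle_adj(b)) {
  k <- length(nodes)
  nb <- length(b$labels)
  recurse <- function(pos, map) {
    if (pos > k) return(TRUE)
    p <- nodes[pos]
    for (t in seq_len(nb)) {
      if (t %in% map) next
      if (b$labels[t] != a$labels[p]) next
      ok <- TRUE
      if (pos > 1) {
        for (q in seq_len(pos - 1)) {
          if (adja[p, nodes[q]] != adjb[t, map[q]]) { ok <- FALSE; break }
        }
      }
      if (ok && recurse(pos + 1, c(map, t))) return(TRUE)
    }
    FALSE
  }
  recurse(1, integer(0))
}

# maximum connected common induced subgraph size by exhaustive enumeration
oracle_mcs_size <- function(a, b) {
  if (length(a$labels) > length(b$labels)) { tmp <- a; a <- b; b <- tmp }
  na <- length(a$labels)
  adja <- oracle_adj(a); adjb <- oracle_adj(b)
  best <- 0L
  for (size in rev(seq_len(na))) {
    if (size <= best) break
    for (nodes in utils::combn(na, size, simplify = FALSE)) {
      if (!oracle_connected(nodes, adja)) next
      if (oracle_embeds(a, nodes, b, adja, adjb)) { best <- size; break }
    }
    if (best == size) break
  }
  best
}
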