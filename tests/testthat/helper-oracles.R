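# Independent reference implementations and offline test doubles.

# Exhaustive propagation oracle: for a directed edge list, return every
# ordered kept-node pair (u, w), u != w, joined by a path whose interior
# nodes are all non-kept and of length >= 1 interior node.  Recursive DFS
# over non-kept interiors, independent of the package's BFS.
oracle_propagated_pairs <- function(edges, nodes, kept) {
  succ <- lapply(stats::setNames(nodes, nodes),
                 function(v) unique(edges$to[edges$from == v]))
  is_kept <- nodes %in% kept
  names(is_kept) <- nodes
  pairs <- character()
  walk <- function(u, x, seen) {
    # x is a non-kept interior node on a path from u
    for (y in succ[[x]]) {
      if (is_kept[[y]]) {
        if (y != u) pairs <<- c(pairs, paste(u, y, sep = "\r"))
      } else if (!y %in% seen) {
        walk(u, y, c(seen, y))
      }
    }
  }
  for (u in nodes[is_kept]) {
    for (x in succ[[u]]) {
      if (!is_kept[[x]]) walk(u, x, x)
    }
  }
  sort(unique(pairs))
}

# CPp pairs actually produced by the package on the same inputs.
package_propagated_pairs <- function(edges, nodes, kept) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$from, to = edges$to,
               rel_type = rep_len("PPrel", nrow(edges)),
               rel_value = rep_len("-->", nrow(edges)),
               rel_name = rep_len("activation", nrow(edges)),
               provenance = rep_len("original", nrow(edges)),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  g2 <- propagate_non_genes(g, function(nms) nms %in% kept)
  ed <- igraph::as_data_frame(g2, what = "edges")
  ed <- ed[ed$rel_type == "CPp", , drop = FALSE]
  sort(unique(paste(ed$from, ed$to, sep = "\r")))
}

# Random directed graph with a random kept/non-kept split, for the
# propagation equivalence property.
random_keep_graph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  n_edges <- sample.int(max(1L, n_nodes * 2L), 1L)
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  edges <- data.frame(from = from[keep], to = to[keep],
                      stringsAsFactors = FALSE)
  kept <- sample(nodes, max(1L, rbinom(1L, n_nodes, 0.5)))
  list(edges = edges, nodes = nodes, kept = kept)
}

# All set partitions of a character vector (Bell number growth; n <= 7).
all_partitions <- function(items) {
  if (length(items) == 0L) return(list(list()))
  first <- items[1]
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    out[[length(out) + 1L]] <- c(list(first), p)
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

# Matrix-form modularity oracle:
# Q = (1/2m) * sum_ij [A_ij - gamma * k_i k_j / (2m)] * delta(c_i, c_j)
# on the undirected simple graph of an edge_set.
matrix_modularity <- function(E, P, gamma = 1) {
  nodes <- edge_set_nodes(E)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in unclass(E)) {
    uv <- strsplit(e, "|", fixed = TRUE)[[1]]
    A[uv[1], uv[2]] <- A[uv[1], uv[2]] + 1
    A[uv[2], uv[1]] <- A[uv[2], uv[1]] + 1
  }
  m <- length(E)
  k <- rowSums(A)
  comm <- rep(seq_along(P), lengths(P))
  names(comm) <- unlist(P)
  same <- outer(comm[nodes], comm[nodes], "==")
  sum((A - gamma * outer(k, k) / (2 * m)) * same) / (2 * m)
}

# A fake HTTP transport serving canned responses and counting requests.
canned_transport <- function(responses) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  counter$urls <- character()
  f <- function(u) {
    counter$n <- counter$n + 1L
    counter$urls <- c(counter$urls, u)
    for (pat in names(responses)) {
      if (grepl(pat, u, fixed = TRUE)) return(responses[[pat]])
    }
    stop("no canned response for ", u)
  }
  attr(f, "counter") <- counter
  f
}

# A small pathway with a two-member group bound to an external gene.
make_group_fixture <- function() {
  act <- data.frame(name = "activation", value = "-->",
                    stringsAsFactors = FALSE)
  entries <- list(
    list(id = 1L, name = "hsa:100", type = "gene", x = 80L, y = 80L),
    list(id = 2L, name = "hsa:200", type = "gene", x = 160L, y = 80L),
    list(id = 3L, name = "hsa:300", type = "gene", x = 240L, y = 80L),
    list(id = 7L, name = "undefined", type = "group", x = 120L, y = 80L,
         components = c(1L, 2L))
  )
  relations <- list(
    list(entry1 = 7L, entry2 = 3L, type = "PPrel", subtypes = act)
  )
  make_kgml(fixture_spec(org = "hsa", number = "99902",
                         title = "group fixture",
                         entries = entries, relations = relations))
}

pair_df <- function(...) {
  v <- c(...)
  if (length(v) == 0L)
    return(data.frame(entry1 = character(), entry2 = character(),
                      stringsAsFactors = FALSE))
  data.frame(entry1 = v[seq(1, length(v), 2)],
             entry2 = v[seq(2, length(v), 2)],
             stringsAsFactors = FALSE)
}
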