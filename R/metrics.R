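# Evaluation metrics for comparing parse variants: per-pathway edge
# difference against a reference graph, and partition modularity
# Q = sum_c [ L_c/m - gamma * (k_c / 2m)^2 ]  over communities c,
# with m total edges, L_c intra-community edges, k_c total degree in c.

#' Undirected edge set of a network table
#'
#' Canonicalizes a table (or any two-column edge data frame) into a set of
#' unordered node pairs: self-pairs are excluded, direction is dropped and
#' duplicates removed.  Modifiers are kept or stripped as requested, so
#' unique and plain parses can be compared as parsed.
#'
#' @param x A `network_table` or data frame with columns `entry1`, `entry2`.
#' @param strip Strip terminal entry-id modifiers before pairing.
#' @return Sorted character vector of class `"edge_set"`; each element is
#'   `"a|b"` with `a < b`.
#' @export
edge_set <- function(x, strip = FALSE) {
  a <- x$entry1; b <- x$entry2
  if (strip) { a <- strip_modifier(a); b <- strip_modifier(b) }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  structure(sort(unique(paste(lo, hi, sep = "|"))), class = "edge_set")
}

#' Nodes spanned by an edge set
#' @param E An `edge_set`.
#' @return Sorted character vector of node names.
#' @export
edge_set_nodes <- function(E) {
  sort(unique(unlist(strsplit(unclass(E), "|", fixed = TRUE))))
}

#' Per-pathway difference between two edge sets
#'
#' The number of edges present in the query set `A` but absent from the
#' reference set `B`, divided by the number of pathways compared:
#' `|A \ B| / n`.
#'
#' @param A Query `edge_set` (or plain character vector of canonical pairs).
#' @param B Reference `edge_set`.
#' @param n Number of pathways used, >= 1.
#' @return A non-negative number.
#' @export
per_pathway_difference <- function(A, B, n) {
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer", call. = FALSE)
  length(setdiff(unclass(A), unclass(B))) / n
}

#' Modularity of a partition
#'
#' Evaluates `Q = sum_c [ L_c/m - gamma * (k_c/(2m))^2 ]` on an undirected,
#' unweighted edge set, where `m` is the total edge count, `L_c` the number
#' of intra-community edges of community `c`, `k_c` the summed degree of its
#' nodes and `gamma` the resolution parameter (default 1).  A single
#' community containing the whole graph scores exactly 0.
#'
#' @param E An `edge_set` with at least one edge.
#' @param P A partition: list of disjoint character vectors jointly covering
#'   the nodes of `E` (extra isolated nodes are allowed in `P`).
#' @param gamma Resolution parameter.
#' @return Q, a number in `[-1, 1]`.
#' @export
partition_modularity <- function(E, P, gamma = 1) {
  m <- length(E)
  if (m < 1L) stop("modularity is undefined for an edgeless graph",
                   call. = FALSE)
  members <- unlist(P)
  if (anyDuplicated(members))
    stop("partition communities are not disjoint", call. = FALSE)
  nodes <- edge_set_nodes(E)
  if (!all(nodes %in% members))
    stop("partition does not cover the node set", call. = FALSE)
  comm <- rep(seq_along(P), lengths(P))
  names(comm) <- members

  ends <- strsplit(unclass(E), "|", fixed = TRUE)
  u <- vapply(ends, `[[`, "", 1L)
  w <- vapply(ends, `[[`, "", 2L)
  cu <- comm[u]; cw <- comm[w]
  Q <- 0
  for (ci in seq_along(P)) {
    L_c <- sum(cu == ci & cw == ci)
    k_c <- sum(cu == ci) + sum(cw == ci)
    Q <- Q + L_c / m - gamma * (k_c / (2 * m))^2
  }
  Q
}

#' Greedy-modularity community detection
#'
#' Fast greedy agglomerative maximization of modularity (resolution 1),
#' delegated to `igraph::cluster_fast_greedy` on the simplified undirected
#' graph of the edge set.
#'
#' @param E An `edge_set`.
#' @return A partition: list of character vectors of node names.
#' @export
greedy_partition <- function(E) {
  ends <- strsplit(unclass(E), "|", fixed = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(ends, `[[`, "", 1L),
               to = vapply(ends, `[[`, "", 2L),
               stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::cluster_fast_greedy(g)
  unname(lapply(igraph::groups(cl), as.character))
}

#' Compare modularity of unique vs plain parses
#'
#' For each (unique, plain) pair of network tables, runs a community
#' detector on both undirected graphs and records the modularity of the
#' chosen partitions and their difference.  Modifiers are kept on the
#' unique graph and absent on the plain graph, exactly as parsed.
#' Edgeless pathways are skipped with a log message.
#'
#' @param pairs List of `list(unique = <network_table>, plain =
#'   <network_table>)` pairs.
#' @param detector Partition function `edge_set -> list of node sets`
#'   (default [greedy_partition()]; any external detector with the same
#'   signature can be injected).
#' @param gamma Resolution parameter for scoring.
#' @return Data frame with one row per pathway: `pathway_id`, `m_unique`,
#'   `m_plain`, `q_unique`, `q_plain`, `delta` (= q_unique - q_plain).
#' @export
compare_unique_modularity <- function(pairs, detector = greedy_partition,
                                      gamma = 1) {
  out <- list()
  for (pr in pairs) {
    tu <- pr$unique; tp <- pr$plain
    Eu <- edge_set(tu); Ep <- edge_set(tp)
    if (length(Eu) == 0L || length(Ep) == 0L) {
      .log_msg("pathway %s is edgeless; skipped",
               attr(tu, "pathway_id") %||% "?")
      next
    }
    qu <- partition_modularity(Eu, detector(Eu), gamma)
    qp <- partition_modularity(Ep, detector(Ep), gamma)
    out[[length(out) + 1L]] <- data.frame(
      pathway_id = attr(tu, "pathway_id") %||% NA_character_,
      m_unique = length(Eu), m_plain = length(Ep),
      q_unique = qu, q_plain = qp, delta = qu - qp,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(pathway_id = character(), m_unique = integer(),
                      m_plain = integer(), q_unique = numeric(),
                      q_plain = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a modularity comparison summary to TSV
#'
#' @param df Result of [compare_unique_modularity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modularity_summary <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
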