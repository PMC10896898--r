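# Conversion of a parsed pathway into mixed or gene-only edge-list networks.
#
# Node identity is (accession, entry id): the numeric KGML entry id is
# attached to every accession as a terminal modifier so that duplicated
# accessions occurring in different neighborhoods of the map stay distinct.
# Non-gene nodes are removed by shortest-path propagation AFTER the graph is
# built and BEFORE any modifier is stripped, which is what preserves the
# original topology.

#' Attach a terminal entry-id modifier to an accession
#'
#' @param accession Namespaced accession, e.g. `"cpd:C00035"`.
#' @param entry_id Non-negative integer KGML entry id.
#' @return `"<accession>-<entry_id>"`, e.g. `"cpd:C00035-92"`.
#' @export
attach_modifier <- function(accession, entry_id) {
  stopifnot(all(entry_id >= 0))
  paste0(accession, "-", as.integer(entry_id))
}

#' Strip a terminal entry-id modifier from a node identifier
#'
#' Removes one final `-<digits>` group if present; identifiers without a
#' modifier are returned unchanged.  Vectorized.
#'
#' @param node_id Node identifier(s), with or without modifier.
#' @return The bare accession(s).
#' @export
strip_modifier <- function(node_id) {
  sub("-[0-9]+$", "", node_id)
}

.has_modifier <- function(node_id) grepl("-[0-9]+$", node_id)

.empty_edge_df <- function() {
  data.frame(from = character(), to = character(), rel_type = character(),
             rel_value = character(), rel_name = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

.entry_nodes <- function(e) {
  if (e$entry_type == "group") return(paste0("group-", e$entry_id))
  accs <- unique(e$accessions)
  if (length(accs) == 0L) accs <- "undefined"
  attach_modifier(accs, e$entry_id)
}

#' Build the base directed graph of a pathway
#'
#' One node per (accession, entry id) pair — an entry listing k accessions
#' yields k nodes sharing the entry-id modifier — and one directed edge per
#' relation and accession pair, carrying the relation type and subtype.
#' Binding/association subtypes with glyph `"---"` are undirected in KGML
#' and yield an edge in both directions.  Group entries remain as
#' placeholder nodes for [expand_groups()]; entries whose name is
#' `"undefined"` become `undefined-<id>` placeholder nodes.
#'
#' @param p A [kgml_pathway()].
#' @return A directed `igraph` with vertex attributes `accession`,
#'   `entry_id`, `kind` and edge attributes `rel_type`, `rel_value`,
#'   `rel_name`, `provenance`.
#' @export
build_base_graph <- function(p) {
  stopifnot(inherits(p, "kgml_pathway"))
  vname <- vacc <- vkind <- character()
  vid <- integer()
  for (e in p$entries) {
    nn <- .entry_nodes(e)
    vname <- c(vname, nn)
    vacc <- c(vacc, strip_modifier(nn))
    vid <- c(vid, rep(e$entry_id, length(nn)))
    vkind <- c(vkind, rep(e$entry_type, length(nn)))
  }
  vdf <- data.frame(name = vname, accession = vacc, entry_id = vid,
                    kind = vkind, stringsAsFactors = FALSE)

  from <- to <- rtype <- rvalue <- rname <- character()
  for (r in p$relations) {
    n1 <- .entry_nodes(p$entries[[as.character(r$entry1_id)]])
    n2 <- .entry_nodes(p$entries[[as.character(r$entry2_id)]])
    st <- r$subtypes
    if (nrow(st) == 0L) st <- data.frame(name = "", value = "")
    for (i in seq_len(nrow(st))) {
      for (u in n1) for (w in n2) {
        if (u == w) next
        from <- c(from, u); to <- c(to, w)
        rtype <- c(rtype, r$relation_type)
        rvalue <- c(rvalue, st$value[i]); rname <- c(rname, st$name[i])
        if (identical(st$value[i], "---")) {
          # KGML encodes binding/association as undirected
          from <- c(from, w); to <- c(to, u)
          rtype <- c(rtype, r$relation_type)
          rvalue <- c(rvalue, st$value[i]); rname <- c(rname, st$name[i])
        }
      }
    }
  }
  edf <- data.frame(from = from, to = to, rel_type = rtype,
                    rel_value = rvalue, rel_name = rname,
                    provenance = rep("original", length(from)),
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

.resolve_group_members <- function(p, entry_id, stack = integer()) {
  if (entry_id %in% stack)
    stop("cyclic group membership involving entry ids: ",
         paste(c(stack, entry_id), collapse = ", "), call. = FALSE)
  e <- p$entries[[as.character(entry_id)]]
  if (is.null(e)) return(character())
  if (e$entry_type != "group") return(.entry_nodes(e))
  unique(unlist(lapply(e$components, .resolve_group_members,
                       p = p, stack = c(stack, entry_id))))
}

#' Expand group (complex) entries into their member nodes
#'
#' Each group placeholder is removed after every incident edge is re-attached
#' to each member node; pairwise "clique" edges (value `"Custom"`, name
#' `"clique"`) are added among the members of a group so complexes remain
#' internally connected.  Nested groups resolve recursively; groups with no
#' components are retained as placeholders (they transit like compounds
#' during propagation) and logged.
#'
#' @param g Graph from [build_base_graph()].
#' @param p The originating [kgml_pathway()].
#' @return The expanded graph.
#' @export
expand_groups <- function(g, p) {
  for (e in p$entries) {
    if (e$entry_type != "group") next
    gnode <- paste0("group-", e$entry_id)
    if (!gnode %in% igraph::V(g)$name) next
    if (length(e$components) == 0L) {
      .log_msg("group entry %d has no components; placeholder retained",
               e$entry_id)
      next
    }
    members <- .resolve_group_members(p, e$entry_id)
    members <- intersect(members, igraph::V(g)$name)

    ed <- igraph::as_data_frame(g, what = "edges")
    inc <- ed[ed$from == gnode | ed$to == gnode, , drop = FALSE]
    add <- .empty_edge_df()
    if (nrow(inc) > 0L) {
      for (i in seq_len(nrow(inc))) {
        row <- inc[i, ]
        if (row$from == gnode && row$to == gnode) next
        if (row$from == gnode) {
          tgt <- setdiff(members, row$to)
          if (length(tgt))
            add <- rbind(add, data.frame(
              from = tgt, to = row$to, rel_type = row$rel_type,
              rel_value = row$rel_value, rel_name = row$rel_name,
              provenance = row$provenance, stringsAsFactors = FALSE))
        } else {
          tgt <- setdiff(members, row$from)
          if (length(tgt))
            add <- rbind(add, data.frame(
              from = row$from, to = tgt, rel_type = row$rel_type,
              rel_value = row$rel_value, rel_name = row$rel_name,
              provenance = row$provenance, stringsAsFactors = FALSE))
        }
      }
    }
    if (length(members) >= 2L) {
      pr <- utils::combn(sort(members), 2L)
      add <- rbind(add, data.frame(
        from = pr[1, ], to = pr[2, ], rel_type = "clique",
        rel_value = "Custom", rel_name = "clique",
        provenance = "clique", stringsAsFactors = FALSE))
    }
    if (nrow(add) > 0L) {
      g <- igraph::add_edges(
        g, rbind(add$from, add$to),
        rel_type = add$rel_type, rel_value = add$rel_value,
        rel_name = add$rel_name, provenance = add$provenance)
    }
    g <- igraph::delete_vertices(g, gnode)
  }
  g
}

.keep_mask <- function(g, keep) {
  nms <- igraph::V(g)$name
  if (is.function(keep)) {
    k <- keep(nms)
  } else if (is.logical(keep)) {
    k <- keep
  } else {
    k <- nms %in% keep
  }
  stopifnot(length(k) == length(nms))
  k
}

#' Remove non-kept nodes by shortest-path propagation
#'
#' For every ordered pair (u, w) of kept nodes joined by a directed path
#' whose interior nodes are all non-kept, one edge u -> w with type
#' `"CPp"`, value `"Custom"`, name `"compound propagation"` is added; all
#' non-kept nodes are then deleted.  Self-loops arising from propagation are
#' discarded.  Where an original u -> w edge already exists the propagated
#' edge is merged away later by [aggregate_parallel_edges()] (original
#' metadata takes precedence).
#'
#' @param g Directed graph.
#' @param keep Character vector of node names to retain, a logical mask over
#'   vertices, or a predicate `function(names) -> logical`.
#' @return The propagated graph containing only kept nodes.
#' @export
propagate_non_genes <- function(g, keep) {
  k <- .keep_mask(g, keep)
  nms <- igraph::V(g)$name
  kept <- nms[k]
  nonkept <- nms[!k]
  if (length(nonkept) == 0L) return(g)

  adj <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
  succ <- lapply(adj, function(v) unique(names(v)))
  names(succ) <- nms
  is_kept <- stats::setNames(k, nms)

  new_from <- new_to <- character()
  for (u in kept) {
    frontier <- succ[[u]][!is_kept[succ[[u]]]]
    visited <- character()
    reached <- character()
    queue <- unique(frontier)
    while (length(queue)) {
      x <- queue[[1L]]; queue <- queue[-1L]
      if (x %in% visited) next
      visited <- c(visited, x)
      for (y in succ[[x]]) {
        if (is_kept[[y]]) reached <- c(reached, y)
        else if (!y %in% visited) queue <- c(queue, y)
      }
    }
    reached <- setdiff(unique(reached), u)
    if (length(reached)) {
      new_from <- c(new_from, rep(u, length(reached)))
      new_to <- c(new_to, reached)
    }
  }
  if (length(new_from)) {
    g <- igraph::add_edges(
      g, rbind(new_from, new_to),
      rel_type = "CPp", rel_value = "Custom",
      rel_name = "compound propagation",
      provenance = "compound_propagated")
  }
  igraph::delete_vertices(g, nonkept)
}

#' Collapse parallel edges into single annotated rows
#'
#' One row per ordered (entry1, entry2) pair.  Metadata of parallel original
#' edges is comma-joined in first-seen order; original rows take precedence
#' over clique rows, which take precedence over propagated (`CPp`) rows, so
#' a propagated duplicate of an original interaction contributes no
#' metadata.  Multiple propagated edges for one pair collapse to a single
#' `CPp` row.
#'
#' @param rows Data frame with columns `entry1`, `entry2`, `type`, `value`,
#'   `name`, `provenance`.
#' @return Data frame of the same shape with unique (entry1, entry2) pairs.
#' @export
aggregate_parallel_edges <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  rank <- c(original = 1L, clique = 2L, compound_propagated = 3L)
  key <- paste0(rows$entry1, "\r", rows$entry2)
  first <- !duplicated(key)
  out <- vector("list", sum(first))
  j <- 0L
  for (kk in key[first]) {
    grp <- rows[key == kk, , drop = FALSE]
    best <- min(rank[grp$provenance])
    grp <- grp[rank[grp$provenance] == best, , drop = FALSE]
    j <- j + 1L
    if (best > 1L) {
      out[[j]] <- grp[1L, , drop = FALSE]
    } else {
      out[[j]] <- data.frame(
        entry1 = grp$entry1[1L], entry2 = grp$entry2[1L],
        type = paste(grp$type, collapse = ", "),
        value = paste(grp$value, collapse = ","),
        name = paste(grp$name, collapse = ", "),
        provenance = "original", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.graph_rows <- function(g) {
  ed <- igraph::as_data_frame(g, what = "edges")
  data.frame(entry1 = ed$from, entry2 = ed$to, type = ed$rel_type,
             value = ed$rel_value, name = ed$rel_name,
             provenance = ed$provenance, stringsAsFactors = FALSE)
}

.apply_suffix_policy <- function(ids, mode, unique, org) {
  if (unique) return(ids)
  if (mode == "gene") return(strip_modifier(ids))
  # mixed, non-unique: strip modifiers from gene nodes only; compounds,
  # maps and other non-gene nodes keep theirs for differentiation
  is_gene <- startsWith(ids, paste0(org, ":"))
  ids[is_gene] <- strip_modifier(ids[is_gene])
  ids
}

.keep_predicate <- function(p, mode) {
  org_prefix <- paste0(p$org, ":")
  if (mode == "gene") {
    function(nms) startsWith(nms, org_prefix)
  } else {
    # mixed: keep everything with a real accession; transit group
    # placeholders and undefined entries
    function(nms) !startsWith(nms, "group-") & !startsWith(nms, "undefined")
  }
}

.finalize_rows <- function(rows, mode, unique, pathway_id) {
  rows <- rows[rows$entry1 != rows$entry2, , drop = FALSE]
  rows <- aggregate_parallel_edges(rows)
  if (nrow(rows)) {
    rows <- rows[order(rows$entry1, rows$entry2, method = "radix"), ,
                 drop = FALSE]
  }
  rownames(rows) <- NULL
  structure(rows, class = c("network_table", "data.frame"),
            pathway_id = pathway_id, mode = mode, unique = unique)
}

#' Build a network table from a parsed pathway
#'
#' The full pipeline: base graph with entry-id modifiers on every node, group
#' expansion, shortest-path propagation of non-kept nodes (all non-gene nodes
#' in gene mode; only group/undefined placeholders in mixed mode), modifier
#' policy, aggregation of parallel edges, and a deterministic lexicographic
#' sort.  Modifier policy: with `unique = TRUE` every node keeps its
#' modifier; `unique = FALSE` strips modifiers from every node in gene mode
#' and from gene nodes only in mixed mode.  Stripping happens strictly after
#' propagation, so duplicated compound accessions never bridge independent
#' neighborhoods.
#'
#' @param p A [kgml_pathway()].
#' @param mode `"gene"` for a gene-only network, `"mixed"` to retain
#'   compounds and linked pathway (map) nodes.
#' @param unique Keep entry-id terminal modifiers on output node ids.
#' @return A `network_table`: a data frame with columns `entry1`, `entry2`,
#'   `type`, `value`, `name`, `provenance` and attributes `pathway_id`,
#'   `mode`, `unique`.
#' @examples
#' p <- parse_kgml(make_shared_compound_scenario())
#' build_network(p, mode = "gene", unique = TRUE)
#' @export
build_network <- function(p, mode = c("gene", "mixed"), unique = FALSE) {
  mode <- match.arg(mode)
  pathway_id <- sub("^path:", "", p$name)
  if (mode == "gene") {
    n_gene <- sum(vapply(p$entries, function(e) e$entry_type == "gene",
                         logical(1)))
    if (n_gene == 0L) {
      warning(pathway_id, ": no gene entries; gene network is empty",
              call. = FALSE)
      return(.finalize_rows(
        data.frame(entry1 = character(), entry2 = character(),
                   type = character(), value = character(),
                   name = character(), provenance = character(),
                   stringsAsFactors = FALSE),
        mode, unique, pathway_id))
    }
  }
  g <- build_base_graph(p)
  g <- expand_groups(g, p)
  g <- propagate_non_genes(g, .keep_predicate(p, mode))
  rows <- .graph_rows(g)
  rows$entry1 <- .apply_suffix_policy(rows$entry1, mode, unique, p$org)
  rows$entry2 <- .apply_suffix_policy(rows$entry2, mode, unique, p$org)
  .finalize_rows(rows, mode, unique, pathway_id)
}

#' Emulate an accession-merging parser (gene mode)
#'
#' Strips entry-id modifiers from every node BEFORE propagation, so distinct
#' entries sharing an accession collapse into one node — the behavior of
#' conventional parsers.  Used as the comparison baseline for topology and
#' modularity analyses.
#'
#' @param p A [kgml_pathway()].
#' @return A `network_table` in gene mode without modifiers.
#' @export
naive_gene_network <- function(p) {
  pathway_id <- sub("^path:", "", p$name)
  g <- build_base_graph(p)
  g <- expand_groups(g, p)
  ed <- igraph::as_data_frame(g, what = "edges")
  vs <- unique(strip_modifier(igraph::V(g)$name))
  ed$from <- strip_modifier(ed$from)
  ed$to <- strip_modifier(ed$to)
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  g2 <- igraph::graph_from_data_frame(
    ed, directed = TRUE,
    vertices = data.frame(name = vs, stringsAsFactors = FALSE))
  org_prefix <- paste0(p$org, ":")
  g2 <- propagate_non_genes(g2, function(nms) startsWith(nms, org_prefix))
  rows <- .graph_rows(g2)
  .finalize_rows(rows, "gene", FALSE, pathway_id)
}

#' @export
print.network_table <- function(x, ...) {
  cat(sprintf("network table: %s, mode=%s, unique=%s, %d edge row(s)\n",
              attr(x, "pathway_id"), attr(x, "mode"),
              attr(x, "unique"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Node identifiers of a network table
#'
#' @param tbl A `network_table`.
#' @return Sorted character vector of distinct node identifiers.
#' @export
network_nodes <- function(tbl) {
  sort(unique(c(tbl$entry1, tbl$entry2)))
}

#' View a network table as an igraph
#'
#' @param tbl A `network_table`.
#' @param directed Build a directed graph (default) or undirected.
#' @return An `igraph` object.
#' @export
network_graph <- function(tbl, directed = TRUE) {
  igraph::graph_from_data_frame(
    data.frame(from = tbl$entry1, to = tbl$entry2, stringsAsFactors = FALSE),
    directed = directed)
}

#' Count weakly connected components of a network table
#'
#' @param tbl A `network_table`.
#' @return Integer component count (0 for an empty table).
#' @export
network_components <- function(tbl) {
  if (nrow(tbl) == 0L) return(0L)
  igraph::count_components(network_graph(tbl), mode = "weak")
}

#' Standard output filename for a network table
#'
#' @param pathway_id Pathway id, e.g. `"hsa04014"`.
#' @param mode `"gene"` or `"mixed"`.
#' @param unique Whether terminal modifiers are kept.
#' @return A filename such as `"hsa04014_genes_unique.tsv"`.
#' @export
network_filename <- function(pathway_id, mode, unique) {
  label <- if (mode == "gene") "genes" else "mixed"
  paste0(pathway_id, "_", label, if (unique) "_unique" else "", ".tsv")
}

#' Write a network table to TSV
#'
#' UTF-8, tab-separated, header `entry1 entry2 type value name`; the
#' internal provenance column is not written (it is recoverable from the
#' `name` column).
#'
#' @param tbl A `network_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(tbl, path) {
  df <- as.data.frame(tbl)[, c("entry1", "entry2", "type", "value", "name"),
                           drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("entry1\tentry2\ttype\tvalue\tname",
               if (nrow(df)) do.call(paste, c(df, sep = "\t"))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read a network table from TSV
#'
#' Provenance is inferred from the `name` column (`"compound propagation"`
#' and `"clique"` mark derived edges; everything else is original).
#'
#' @param path Path to a TSV written by [write_network()].
#' @param mode,unique,pathway_id Optional metadata to attach; `unique`
#'   defaults to whether any gene-like node carries a modifier.
#' @return A `network_table`.
#' @export
read_network <- function(path, mode = NULL, unique = NULL, pathway_id = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  stopifnot(identical(names(df)[1:5],
                      c("entry1", "entry2", "type", "value", "name")))
  df$provenance <- ifelse(
    df$name == "compound propagation", "compound_propagated",
    ifelse(df$name == "clique", "clique", "original"))
  if (is.null(pathway_id))
    pathway_id <- sub("_(genes|mixed)(_unique)?\\.tsv$", "", basename(path))
  if (is.null(mode))
    mode <- if (grepl("_mixed(_unique)?\\.tsv$", basename(path))) "mixed"
            else "gene"
  if (is.null(unique))
    unique <- grepl("_unique\\.tsv$", basename(path))
  structure(df, class = c("network_table", "data.frame"),
            pathway_id = pathway_id, mode = mode, unique = unique)
}
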