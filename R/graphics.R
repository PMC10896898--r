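# Export of the original KEGG canvas layout: node identifier -> (x, y).
# Coordinates are KEGG-native pixels, origin top-left with y growing
# DOWNWARD; negate y before plotting in the usual mathematical convention.

#' Extract node coordinates for a parse variant
#'
#' Maps every node that appears in `build_network(p, mode, unique)` — plus
#' kept nodes isolated after propagation, which the edge-list format cannot
#' express — to its entry's graphics center, using the same modifier policy
#' as the companion network table.  Entries without graphics are omitted
#' with a warning.
#'
#' @param p A [kgml_pathway()].
#' @param mode `"gene"` or `"mixed"`.
#' @param unique Keep entry-id terminal modifiers on keys.
#' @return A `graphics_map`: data frame with columns `node`, `x`, `y` and
#'   attributes `pathway_id`, `mode`, `unique`.
#' @export
extract_coordinates <- function(p, mode = c("gene", "mixed"),
                                unique = FALSE) {
  mode <- match.arg(mode)
  pathway_id <- sub("^path:", "", p$name)
  g <- build_base_graph(p)
  g <- expand_groups(g, p)
  k <- .keep_mask(g, .keep_predicate(p, mode))
  nms <- igraph::V(g)$name[k]
  eids <- igraph::V(g)$entry_id[k]

  node <- .apply_suffix_policy(nms, mode, unique, p$org)
  xs <- ys <- integer(length(node))
  has_gfx <- logical(length(node))
  for (i in seq_along(node)) {
    e <- p$entries[[as.character(eids[i])]]
    has_gfx[i] <- !is.na(e$graphics_x) && !is.na(e$graphics_y)
    if (has_gfx[i]) { xs[i] <- e$graphics_x; ys[i] <- e$graphics_y }
  }
  n_missing <- sum(!has_gfx)
  if (n_missing > 0L)
    warning(sprintf("%s: %d node(s) without graphics omitted from layout",
                    pathway_id, n_missing), call. = FALSE)
  df <- data.frame(node = node[has_gfx], x = xs[has_gfx], y = ys[has_gfx],
                   stringsAsFactors = FALSE)
  # stripped modifiers can collapse several entries onto one key; the
  # first (lowest entry id) coordinate wins
  df <- df[!duplicated(df$node), , drop = FALSE]
  df <- df[order(df$node, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L)
    warning(pathway_id, ": pathway has no graphics at all", call. = FALSE)
  structure(df, class = c("graphics_map", "data.frame"),
            pathway_id = pathway_id, mode = mode, unique = unique)
}

#' Standard output filename for a graphics map
#'
#' @param pathway_id Pathway id, e.g. `"hsa04014"`.
#' @param unique Whether terminal modifiers are kept.
#' @return A filename such as `"hsa04014_graphics_unique.txt"`.
#' @export
graphics_filename <- function(pathway_id, unique) {
  paste0(pathway_id, "_graphics", if (unique) "_unique" else "", ".txt")
}

#' Write a graphics map to a TSV text file
#'
#' Header `node x y`, one node per line, sorted by node identifier.
#'
#' @param gmap A `graphics_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphics <- function(gmap, path) {
  df <- as.data.frame(gmap)
  df <- df[order(df$node, method = "radix"), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("node\tx\ty",
               if (nrow(df)) paste(df$node, df$x, df$y, sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read a graphics map written by [write_graphics()]
#'
#' @param path Path to the TSV file.
#' @param mode,unique,pathway_id Optional metadata to attach.
#' @return A `graphics_map`.
#' @export
read_graphics <- function(path, mode = "gene", unique = NULL,
                          pathway_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer"))
  stopifnot(identical(names(df), c("node", "x", "y")))
  if (is.null(pathway_id))
    pathway_id <- sub("_graphics(_unique)?\\.txt$", "", basename(path))
  if (is.null(unique)) unique <- grepl("_unique\\.txt$", basename(path))
  structure(df, class = c("graphics_map", "data.frame"),
            pathway_id = pathway_id, mode = mode, unique = unique)
}

#' @export
print.graphics_map <- function(x, ...) {
  cat(sprintf("graphics map: %s, %d node(s) (KEGG canvas, y grows downward)\n",
              attr(x, "pathway_id"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10L))
  invisible(x)
}
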