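# Parsing of KGML (KEGG Markup Language) pathway documents into the
# in-memory pathway model used by the rest of the package.

.entry_types <- c("gene", "compound", "group", "map", "ortholog", "enzyme")
.relation_types <- c("PPrel", "PCrel", "ECrel", "GErel", "PErel", "maplink")

#' Construct a KGML entry record
#'
#' One `<entry>` element of a KGML document: a numeric per-pathway id, the
#' (possibly multiple) namespaced accessions from its whitespace-separated
#' `name` attribute, the entry type, optional canvas coordinates and an
#' optional display label.  Group entries carry the ids of their member
#' entries in `components`.
#'
#' @param entry_id Positive integer, the KGML `id` attribute.
#' @param accessions Character vector of namespaced accessions such as
#'   `"hsa:10000"`, `"cpd:C00165"` or `"path:hsa04014"`.  Empty for groups
#'   and for entries whose `name` attribute is `"undefined"`.
#' @param entry_type One of `"gene"`, `"compound"`, `"group"`, `"map"`,
#'   `"ortholog"`, `"enzyme"` or `"other"`.
#' @param graphics_x,graphics_y Integer pixel coordinates in KEGG canvas
#'   convention (origin top-left, y grows downward), or `NA` when absent.
#' @param label Display string from the `graphics` `name` attribute, or `NA`.
#' @param components Integer vector of member entry ids (groups only).
#' @return A list of class `"kgml_entry"`.
#' @export
kgml_entry <- function(entry_id, accessions = character(), entry_type = "other",
                       graphics_x = NA_integer_, graphics_y = NA_integer_,
                       label = NA_character_, components = integer()) {
  entry_id <- as.integer(entry_id)
  stopifnot(length(entry_id) == 1L, !is.na(entry_id), entry_id >= 0L)
  if (!entry_type %in% c(.entry_types, "other")) entry_type <- "other"
  structure(
    list(
      entry_id = entry_id,
      accessions = as.character(accessions),
      entry_type = entry_type,
      graphics_x = as.integer(graphics_x),
      graphics_y = as.integer(graphics_y),
      label = as.character(label),
      components = as.integer(components)
    ),
    class = "kgml_entry"
  )
}

#' Construct a KGML relation record
#'
#' @param entry1_id,entry2_id Entry ids of the relation endpoints.
#' @param relation_type KGML relation type (`"PPrel"`, `"PCrel"`, `"ECrel"`,
#'   `"GErel"`, `"PErel"`, `"maplink"`).
#' @param subtypes A data frame with columns `name` (e.g. `"activation"`)
#'   and `value` (the KGML glyph, e.g. `"-->"`, `"---"`, `"..>"`); may have
#'   zero rows.
#' @return A list of class `"kgml_relation"`.
#' @export
kgml_relation <- function(entry1_id, entry2_id, relation_type,
                          subtypes = data.frame(name = character(),
                                                value = character())) {
  structure(
    list(
      entry1_id = as.integer(entry1_id),
      entry2_id = as.integer(entry2_id),
      relation_type = as.character(relation_type),
      subtypes = data.frame(name = as.character(subtypes$name),
                            value = as.character(subtypes$value),
                            stringsAsFactors = FALSE)
    ),
    class = "kgml_relation"
  )
}

#' Construct a pathway object
#'
#' @param org KEGG organism code (e.g. `"hsa"`).
#' @param number Pathway number string (e.g. `"04014"`).
#' @param name Full pathway id (e.g. `"path:hsa04014"`).
#' @param title Human-readable pathway title.
#' @param entries Named list of [kgml_entry()] records, names are the entry
#'   ids as strings.
#' @param relations List of [kgml_relation()] records.
#' @return A list of class `"kgml_pathway"`.
#' @export
kgml_pathway <- function(org = "", number = "", name = "", title = "",
                         entries = list(), relations = list()) {
  structure(
    list(org = org, number = number, name = name, title = title,
         entries = entries, relations = relations),
    class = "kgml_pathway"
  )
}

#' @export
print.kgml_pathway <- function(x, ...) {
  cat(sprintf("KGML pathway %s (%s): %d entries, %d relations\n",
              x$name, x$title, length(x$entries), length(x$relations)))
  invisible(x)
}

.log_msg <- function(...) {
  if (isTRUE(getOption("kgmlnet.verbose", TRUE))) message(sprintf(...))
}

#' Parse KGML text into a pathway object
#'
#' Reads the `<entry>` and `<relation>` elements of a KGML document.
#' Multi-accession `name` attributes are split on whitespace; `graphics`
#' coordinates are captured when present; `<reaction>` elements are ignored
#' (relations carry the topology used here).  Relations referencing an
#' unknown entry id are dropped with a warning.
#'
#' @param xml_text A length-one character string of KGML, or an `xml2`
#'   document.
#' @return A [kgml_pathway()] object.
#' @seealso [parse_kgml_file()], [validate_pathway()]
#' @export
parse_kgml <- function(xml_text) {
  doc <- if (inherits(xml_text, "xml_document")) xml_text
         else xml2::read_xml(xml_text)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    stop("not a KGML document: root element is <", xml2::xml_name(root),
         ">, expected <pathway>", call. = FALSE)

  p <- kgml_pathway(
    org = xml2::xml_attr(root, "org"),
    number = xml2::xml_attr(root, "number"),
    name = xml2::xml_attr(root, "name"),
    title = xml2::xml_attr(root, "title")
  )
  if (is.na(p$title)) p$title <- ""

  for (node in xml2::xml_find_all(root, "entry")) {
    id <- as.integer(xml2::xml_attr(node, "id"))
    nm <- xml2::xml_attr(node, "name")
    type <- xml2::xml_attr(node, "type")
    if (is.na(type) || !type %in% .entry_types) type <- "other"
    accs <- if (is.na(nm) || identical(nm, "undefined")) character()
            else strsplit(trimws(nm), "\\s+")[[1]]
    gfx <- xml2::xml_find_first(node, "graphics")
    gx <- gy <- NA_integer_
    lbl <- NA_character_
    if (!inherits(gfx, "xml_missing")) {
      gx <- suppressWarnings(as.integer(round(as.numeric(xml2::xml_attr(gfx, "x")))))
      gy <- suppressWarnings(as.integer(round(as.numeric(xml2::xml_attr(gfx, "y")))))
      lbl <- xml2::xml_attr(gfx, "name")
    }
    comp <- as.integer(xml2::xml_attr(xml2::xml_find_all(node, "component"), "id"))
    p$entries[[as.character(id)]] <-
      kgml_entry(id, accs, type, gx, gy, lbl, comp)
  }

  n_dropped <- 0L
  for (node in xml2::xml_find_all(root, "relation")) {
    e1 <- as.integer(xml2::xml_attr(node, "entry1"))
    e2 <- as.integer(xml2::xml_attr(node, "entry2"))
    rtype <- xml2::xml_attr(node, "type")
    if (!as.character(e1) %in% names(p$entries) ||
        !as.character(e2) %in% names(p$entries)) {
      n_dropped <- n_dropped + 1L
      next
    }
    st <- xml2::xml_find_all(node, "subtype")
    subtypes <- data.frame(
      name = xml2::xml_attr(st, "name"),
      value = xml2::xml_attr(st, "value"),
      stringsAsFactors = FALSE
    )
    p$relations[[length(p$relations) + 1L]] <-
      kgml_relation(e1, e2, rtype, subtypes)
  }
  if (n_dropped > 0L)
    warning(sprintf("%s: dropped %d relation(s) referencing unknown entry ids",
                    p$name, n_dropped), call. = FALSE)
  attr(p, "dropped_relations") <- n_dropped
  p
}

#' Parse a KGML file from disk
#'
#' @param path Path to a `.xml` KGML file.
#' @return A [kgml_pathway()] object.
#' @export
parse_kgml_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_kgml(xml2::read_xml(path))
}

#' Check a parsed pathway for structural problems
#'
#' Reports dangling group component ids, empty accession lists on non-group
#' entries and missing graphics.  Never raises; a fully consistent pathway
#' yields a zero-row data frame.
#'
#' @param p A [kgml_pathway()] object.
#' @return A data frame with columns `severity` (`"error"` or `"warning"`),
#'   `ref` (entry id or relation index as string) and `message`.
#' @export
validate_pathway <- function(p) {
  stopifnot(inherits(p, "kgml_pathway"))
  sev <- ref <- msg <- character()
  add <- function(s, r, m) {
    sev <<- c(sev, s); ref <<- c(ref, r); msg <<- c(msg, m)
  }
  ids <- names(p$entries)
  for (e in p$entries) {
    rid <- as.character(e$entry_id)
    if (e$entry_type == "group") {
      bad <- setdiff(as.character(e$components), ids)
      if (length(bad))
        add("error", rid, paste0("group component id(s) not in pathway: ",
                                 paste(bad, collapse = ", ")))
      if (length(e$components) == 0L)
        add("warning", rid, "group entry has no components")
    } else if (length(e$accessions) == 0L) {
      add("warning", rid, "entry has no accessions (name is undefined)")
    }
    if (is.na(e$graphics_x) || is.na(e$graphics_y))
      add("warning", rid, "entry has no graphics coordinates")
  }
  for (i in seq_along(p$relations)) {
    r <- p$relations[[i]]
    if (!as.character(r$entry1_id) %in% ids ||
        !as.character(r$entry2_id) %in% ids)
      add("error", as.character(i), "relation endpoint not in pathway")
  }
  data.frame(severity = sev, ref = ref, message = msg,
             stringsAsFactors = FALSE)
}
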