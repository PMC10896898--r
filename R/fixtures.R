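# Synthetic KGML generators.  Every other module is testable offline by
# emitting valid KGML documents with controllable topology.

#' Describe a synthetic KGML document
#'
#' A fixture spec is the declarative input of [make_kgml()]: an organism
#' code, a list of entry specs and a list of relation specs.  Entry specs
#' are lists with elements `id`, `name` (whitespace-separated accessions or
#' `"undefined"`), `type`, optional `x`, `y`, `label` and `components`.
#' Relation specs are lists with `entry1`, `entry2`, `type` and an optional
#' `subtypes` data frame (columns `name`, `value`).
#'
#' @param org Organism code, e.g. `"hsa"`.
#' @param number Pathway number string.
#' @param title Pathway title.
#' @param entries List of entry specs.
#' @param relations List of relation specs.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(org = "hsa", number = "00001", title = "synthetic",
                         entries = list(), relations = list()) {
  ids <- vapply(entries, function(e) as.integer(e$id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate entry ids in fixture spec")
  for (e in entries) {
    comp <- e$components
    if (length(comp) && !all(comp %in% ids))
      stop("fixture spec: group ", e$id, " references unknown component id(s)")
  }
  for (r in relations) {
    if (!r$entry1 %in% ids || !r$entry2 %in% ids)
      stop("fixture spec: relation references unknown entry id")
  }
  structure(list(org = org, number = number, title = title,
                 entries = entries, relations = relations),
            class = "fixture_spec")
}

#' Serialize a fixture spec to KGML text
#'
#' Emits a well-formed KGML document that [parse_kgml()] round-trips.
#'
#' @param spec A [fixture_spec()].
#' @return A length-one character string of XML.
#' @export
make_kgml <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  doc <- xml2::xml_new_root(
    "pathway",
    name = paste0("path:", spec$org, spec$number),
    org = spec$org, number = spec$number, title = spec$title
  )
  for (e in spec$entries) {
    node <- xml2::xml_add_child(
      doc, "entry", id = as.character(e$id), name = e$name, type = e$type
    )
    if (!is.null(e$x) && !is.na(e$x)) {
      xml2::xml_add_child(
        node, "graphics",
        name = if (is.null(e$label) || is.na(e$label)) e$name else e$label,
        x = as.character(e$x), y = as.character(e$y),
        type = "rectangle", width = "46", height = "17"
      )
    }
    for (cid in e$components)
      xml2::xml_add_child(node, "component", id = as.character(cid))
  }
  for (r in spec$relations) {
    node <- xml2::xml_add_child(
      doc, "relation",
      entry1 = as.character(r$entry1), entry2 = as.character(r$entry2),
      type = r$type
    )
    st <- r$subtypes
    if (!is.null(st) && nrow(st) > 0L) {
      for (i in seq_len(nrow(st)))
        xml2::xml_add_child(node, "subtype",
                            name = st$name[i], value = st$value[i])
    }
  }
  as.character(doc)
}

#' Project a parsed pathway back onto a fixture spec
#'
#' Inverse of `parse_kgml(make_kgml(spec))` up to field equality; used for
#' serialization round-trip checks.
#'
#' @param p A [kgml_pathway()].
#' @return A [fixture_spec()].
#' @export
as_fixture_spec <- function(p) {
  stopifnot(inherits(p, "kgml_pathway"))
  entries <- lapply(unname(p$entries), function(e) {
    list(
      id = e$entry_id,
      name = if (length(e$accessions)) paste(e$accessions, collapse = " ")
             else "undefined",
      type = e$entry_type,
      x = e$graphics_x, y = e$graphics_y,
      label = e$label,
      components = e$components
    )
  })
  relations <- lapply(p$relations, function(r) {
    list(entry1 = r$entry1_id, entry2 = r$entry2_id,
         type = r$relation_type, subtypes = r$subtypes)
  })
  fixture_spec(org = p$org, number = p$number, title = p$title,
               entries = entries, relations = relations)
}

#' Serialize a parsed pathway to KGML text
#'
#' @param p A [kgml_pathway()].
#' @return KGML XML text.
#' @export
serialize_kgml <- function(p) make_kgml(as_fixture_spec(p))

.grid_xy <- function(i, per_row = 8L, spacing = 80L) {
  # deterministic grid layout, 80 px spacing
  i0 <- i - 1L
  c(x = spacing * (i0 %% per_row) + spacing,
    y = spacing * (i0 %/% per_row) + spacing)
}

.subtype_df <- function(name, value) {
  data.frame(name = name, value = value, stringsAsFactors = FALSE)
}

#' The shared-compound two-neighborhood scenario
#'
#' A minimal pathway in which the same compound accession (`cpd:C00165`,
#' diacylglycerol) appears as two distinct entries in two disconnected
#' neighborhoods, each bridging a different gene pair.  This is the smallest
#' instance of the failure mode where parsers that merge nodes by accession
#' fuse independent neighborhoods: a topology-aware gene-only parse yields
#' two connected components, a merge-by-accession parse yields one.
#'
#' @return KGML XML text.
#' @export
make_shared_compound_scenario <- function() {
  act <- .subtype_df("activation", "-->")
  entries <- list(
    list(id = 10L, name = "hsa:1111", type = "gene", x = 80L,  y = 80L),
    list(id = 11L, name = "hsa:2222", type = "gene", x = 240L, y = 80L),
    list(id = 12L, name = "cpd:C00165", type = "compound", x = 160L, y = 80L),
    list(id = 20L, name = "hsa:3333", type = "gene", x = 80L,  y = 320L),
    list(id = 21L, name = "hsa:4444", type = "gene", x = 240L, y = 320L),
    list(id = 22L, name = "cpd:C00165", type = "compound", x = 160L, y = 320L)
  )
  relations <- list(
    list(entry1 = 10L, entry2 = 12L, type = "PCrel", subtypes = act),
    list(entry1 = 12L, entry2 = 11L, type = "PCrel", subtypes = act),
    list(entry1 = 20L, entry2 = 22L, type = "PCrel", subtypes = act),
    list(entry1 = 22L, entry2 = 21L, type = "PCrel", subtypes = act)
  )
  make_kgml(fixture_spec(org = "hsa", number = "99901",
                         title = "shared compound scenario",
                         entries = entries, relations = relations))
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random synthetic pathway
#'
#' Builds several disconnected gene neighborhoods (random trees plus extra
#' within-neighborhood edges), scatters compounds that bridge gene pairs
#' inside a neighborhood, and plants duplicated hub accessions: each hub
#' accession is given one entry in each of two different neighborhoods, so
#' parsers that merge nodes by bare accession fuse those neighborhoods.
#' Output is deterministic for a fixed seed.
#'
#' @param n_genes Number of distinct (non-hub) gene entries, >= 1.
#' @param n_compounds Number of compound entries, >= 0.
#' @param n_duplicated_hubs Number of duplicated hub accessions, >= 0
#'   (each contributes two entries).
#' @param seed Integer seed.
#' @return KGML XML text.
#' @export
random_pathway <- function(n_genes = 12L, n_compounds = 4L,
                           n_duplicated_hubs = 2L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_compounds >= 0L, n_duplicated_hubs >= 0L)
  .with_seed(seed, {
    n_clusters <- max(2L, min(4L, n_genes %/% 3L))
    cluster_of <- sort(rep_len(seq_len(n_clusters), n_genes))
    entries <- list()
    relations <- list()
    next_id <- 1L
    act <- .subtype_df("activation", "-->")

    gene_ids <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      xy <- .grid_xy(next_id)
      entries[[length(entries) + 1L]] <- list(
        id = next_id, name = sprintf("hsa:%d", 1000L + i), type = "gene",
        x = xy[["x"]], y = xy[["y"]]
      )
      gene_ids[i] <- next_id
      next_id <- next_id + 1L
    }

    add_rel <- function(a, b) {
      relations[[length(relations) + 1L]] <<-
        list(entry1 = a, entry2 = b, type = "PPrel", subtypes = act)
    }

    # random spanning tree per cluster, plus a few extra edges
    for (cl in seq_len(n_clusters)) {
      members <- gene_ids[cluster_of == cl]
      if (length(members) >= 2L) {
        for (j in 2:length(members)) {
          parent <- members[sample.int(j - 1L, 1L)]
          add_rel(parent, members[j])
        }
        n_extra <- sample.int(max(1L, length(members) %/% 2L), 1L) - 1L
        for (k in seq_len(n_extra)) {
          pair <- sample(members, 2L)
          add_rel(pair[1L], pair[2L])
        }
      }
    }

    # compounds bridge two genes of one cluster: gene -> cpd -> gene
    for (i in seq_len(n_compounds)) {
      cl <- sample.int(n_clusters, 1L)
      members <- gene_ids[cluster_of == cl]
      xy <- .grid_xy(next_id)
      entries[[length(entries) + 1L]] <- list(
        id = next_id, name = sprintf("cpd:C%05d", 100L + i),
        type = "compound", x = xy[["x"]], y = xy[["y"]]
      )
      a <- sample(members, 1L)
      b <- sample(members, 1L)
      relations[[length(relations) + 1L]] <-
        list(entry1 = a, entry2 = next_id, type = "PCrel", subtypes = act)
      relations[[length(relations) + 1L]] <-
        list(entry1 = next_id, entry2 = b, type = "PCrel", subtypes = act)
      next_id <- next_id + 1L
    }

    # duplicated hubs: one entry in each of two distinct clusters
    for (h in seq_len(n_duplicated_hubs)) {
      hub_acc <- sprintf("hsa:%d", 9000L + h)
      cls <- sample.int(n_clusters, 2L)
      for (cl in cls) {
        members <- gene_ids[cluster_of == cl]
        xy <- .grid_xy(next_id)
        entries[[length(entries) + 1L]] <- list(
          id = next_id, name = hub_acc, type = "gene",
          x = xy[["x"]], y = xy[["y"]]
        )
        n_att <- min(length(members), sample(1:2, 1L))
        for (g in sample(members, n_att)) add_rel(g, next_id)
        next_id <- next_id + 1L
      }
    }

    make_kgml(fixture_spec(org = "hsa", number = "99900",
                           title = sprintf("random pathway seed %d", seed),
                           entries = entries, relations = relations))
  })
}
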