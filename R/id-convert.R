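# Rewriting of network tables and graphics maps from KEGG gene accessions
# to NCBI Entrez ("ncbi-geneid:") or UniProt ("up:") identifiers.
# Non-gene namespaces (cpd:, path:, gl:, ...) always pass through untouched.

.convert_ids <- function(ids, cmap, unique, org_prefixes = NULL) {
  mapping <- cmap$mapping
  is_nongene <- grepl("^(cpd|path|gl|dr|ko|ec|undefined)", ids)
  if (!unique) {
    suspicious <- !is_nongene & .has_modifier(ids)
    if (any(suspicious))
      stop("input contains terminal modifiers (e.g. \"", ids[suspicious][1L],
           "\") but unique = FALSE; re-run with the --unique flag",
           call. = FALSE)
  }
  out <- ids
  n_unmapped <- 0L
  for (i in seq_along(ids)) {
    if (is_nongene[i]) next
    acc <- ids[i]
    suffix <- ""
    if (unique && .has_modifier(acc)) {
      suffix <- regmatches(acc, regexpr("-[0-9]+$", acc))
      acc <- strip_modifier(acc)
    }
    tgt <- mapping[[acc]]
    if (is.null(tgt) || is.na(tgt)) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    out[i] <- paste0(tgt, suffix)
  }
  if (n_unmapped > 0L)
    .log_msg("%d accession(s) had no conversion and pass through unchanged",
             n_unmapped)
  out
}

#' Convert a network table to Entrez or UniProt identifiers
#'
#' Each gene node identifier is split into accession and (when
#' `unique = TRUE`) terminal modifier, the accession is mapped through
#' `cmap`, and the modifier is re-attached.  Unmapped accessions pass
#' through unchanged with a logged count; compound and pathway nodes are
#' never touched.  Row counts and all metadata columns are preserved
#' exactly.
#'
#' @param tbl A `network_table`.
#' @param cmap A `conv_map` from [fetch_conv_map()] or [conv_map()].
#' @param unique Must match how `tbl` was produced; a `FALSE` value on input
#'   that carries modifiers is an error.
#' @return A converted `network_table`.
#' @export
convert_table <- function(tbl, cmap, unique = attr(tbl, "unique")) {
  stopifnot(inherits(tbl, "network_table"), inherits(cmap, "conv_map"))
  if (is.null(unique)) unique <- FALSE
  out <- tbl
  out$entry1 <- .convert_ids(tbl$entry1, cmap, unique)
  out$entry2 <- .convert_ids(tbl$entry2, cmap, unique)
  out
}

#' Convert a graphics map to Entrez or UniProt identifiers
#'
#' Same contract as [convert_table()], applied to the `node` keys;
#' coordinates are preserved exactly.
#'
#' @param gmap A `graphics_map`.
#' @param cmap A `conv_map`.
#' @param unique Must match how `gmap` was produced.
#' @return A converted `graphics_map`.
#' @export
convert_graphics <- function(gmap, cmap, unique = attr(gmap, "unique")) {
  stopifnot(inherits(gmap, "graphics_map"), inherits(cmap, "conv_map"))
  if (is.null(unique)) unique <- FALSE
  out <- gmap
  out$node <- .convert_ids(gmap$node, cmap, unique)
  out
}
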