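# KEGG REST client.  Every operation takes an injectable `transport`
# function (url -> character text) so the full test suite runs with zero
# live HTTP calls; the default transport follows KEGG's fair-use guidance
# (rate-limited, 3 attempts with exponential backoff).

.client_state <- new.env(parent = emptyenv())

.kegg_base <- function() getOption("kgmlnet.base_url", "https://rest.kegg.jp")

#' The default HTTP transport
#'
#' Returns a function that GETs a URL and returns the response body as a
#' single string, sleeping between consecutive requests and retrying
#' transient failures with exponential backoff.
#'
#' @param rate_limit Minimum seconds between requests (default 0.34, i.e.
#'   under 3 requests per second).
#' @param retries Number of attempts before giving up.
#' @return A `function(url) -> character(1)`.
#' @export
default_transport <- function(rate_limit = getOption("kgmlnet.rate_limit", 0.34),
                              retries = 3L) {
  function(u) {
    last <- .client_state$last_request
    if (!is.null(last)) {
      wait <- rate_limit - as.numeric(Sys.time() - last, units = "secs")
      if (wait > 0) Sys.sleep(wait)
    }
    for (attempt in seq_len(retries)) {
      .client_state$last_request <- Sys.time()
      res <- tryCatch({
        con <- url(u, open = "rb")
        on.exit(close(con), add = TRUE)
        rawToChar(readBin(con, what = "raw", n = 50e6))
      }, error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (attempt < retries) Sys.sleep(0.5 * 2^(attempt - 1L))
      else stop("KEGG request failed after ", retries, " attempts: ",
                conditionMessage(res), call. = FALSE)
    }
  }
}

.get_lines <- function(url, transport) {
  txt <- transport(url)
  if (is.null(txt) || !nzchar(paste(txt, collapse = ""))) return(character())
  strsplit(paste(txt, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

#' List the pathways of an organism
#'
#' Queries the REST `list` endpoint and returns bare pathway identifiers
#' such as `"hsa04014"`.
#'
#' @param org_code KEGG organism code (3-4 letters, e.g. `"hsa"`).
#' @param transport HTTP transport function (see [default_transport()]).
#' @return Character vector of pathway ids; empty (with a warning) when the
#'   organism is unknown.
#' @export
list_pathways <- function(org_code, transport = default_transport()) {
  stopifnot(grepl("^[A-Za-z]{2,4}$", org_code))
  lines <- .get_lines(paste0(.kegg_base(), "/list/pathway/", org_code),
                      transport)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("no pathways listed for organism \"", org_code, "\"",
            call. = FALSE)
    return(character())
  }
  ids <- sub("\t.*$", "", lines)
  sub("^path:", "", ids)
}

#' Fetch the KGML document of a pathway, with on-disk caching
#'
#' Downloads `/get/<pathway>/kgml` once and stores it as
#' `<pathway_id>.xml` under `cache_dir`; later calls are served from disk
#' with no HTTP request.
#'
#' @param pathway_id Pathway id such as `"hsa04014"`.
#' @param cache_dir Cache directory; created if needed.  Defaults to the
#'   user cache dir for this package.
#' @param transport HTTP transport function.
#' @return The KGML text (invisibly also on disk).
#' @export
fetch_kgml <- function(pathway_id,
                       cache_dir = tools::R_user_dir("kgmlnet", "cache"),
                       transport = default_transport()) {
  stopifnot(grepl("^[A-Za-z]{2,4}[0-9]{5}$", pathway_id))
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cache_dir, paste0(pathway_id, ".xml"))
  if (file.exists(path))
    return(readChar(path, file.size(path), useBytes = TRUE))
  txt <- transport(paste0(.kegg_base(), "/get/", pathway_id, "/kgml"))
  if (is.null(txt) || !nzchar(txt))
    stop("pathway ", pathway_id, " has no KGML", call. = FALSE)
  writeChar(txt, path, eos = NULL, useBytes = TRUE)
  txt
}

#' Construct an identifier conversion map
#'
#' @param mapping Named character vector, namespaced KEGG accession ->
#'   namespaced target accession (e.g. `c("hsa:10000" = "ncbi-geneid:10000")`).
#' @param source_db Source database (organism code or `"cpd"`).
#' @param target_db `"ncbi-geneid"` or `"uniprot"`.
#' @return A list of class `"conv_map"` with a `mapping` environment-free
#'   named list for O(1) lookup.
#' @export
conv_map <- function(mapping = character(), source_db = "", target_db = "ncbi-geneid") {
  stopifnot(target_db %in% c("ncbi-geneid", "uniprot", ""))
  structure(list(mapping = as.list(mapping), source_db = source_db,
                 target_db = target_db),
            class = "conv_map")
}

#' @export
print.conv_map <- function(x, ...) {
  cat(sprintf("conversion map %s -> %s: %d entries\n",
              x$source_db, x$target_db, length(x$mapping)))
  invisible(x)
}

#' Fetch a KEGG identifier conversion table
#'
#' Parses the two-column tab-separated `/conv/<target>/<source>` response.
#' Malformed lines are skipped with a warning.
#'
#' @param source_db Organism code (e.g. `"hsa"`).
#' @param target_db `"ncbi-geneid"` or `"uniprot"`.
#' @param transport HTTP transport function.
#' @return A [conv_map()].
#' @export
fetch_conv_map <- function(source_db, target_db = c("ncbi-geneid", "uniprot"),
                           transport = default_transport()) {
  target_db <- match.arg(target_db)
  lines <- .get_lines(paste0(.kegg_base(), "/conv/", target_db, "/", source_db),
                      transport)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 2L
  if (any(!ok))
    warning(sum(!ok), " malformed conversion line(s) skipped", call. = FALSE)
  parts <- parts[ok]
  mapping <- stats::setNames(vapply(parts, `[[`, "", 2L),
                             vapply(parts, `[[`, "", 1L))
  conv_map(mapping, source_db, target_db)
}

#' Invert a conversion map
#'
#' @param cmap A [conv_map()].
#' @return A [conv_map()] mapping target -> source.
#' @export
invert_conv_map <- function(cmap) {
  m <- unlist(cmap$mapping)
  conv_map(stats::setNames(names(m), m), cmap$target_db, "")
}

.parse_name_field <- function(accession, field) {
  # genes: "SYM1, SYM2; description"  -> description after first semicolon
  # compounds / pathways: first semicolon-separated synonym
  if (grepl(";", field, fixed = TRUE)) {
    if (grepl("^(cpd|gl|path):", accession))
      trimws(strsplit(field, ";", fixed = TRUE)[[1]][1])
    else
      trimws(sub("^[^;]*;", "", field))
  } else trimws(field)
}

#' Fetch display names for accessions
#'
#' Batches requests to the REST `list` endpoint (10 accessions per call)
#' and returns one name per accession: for genes the description after the
#' symbol list, for compounds and pathways the first synonym.  Accessions
#' absent from the response are omitted.
#'
#' @param accessions Character vector of namespaced accessions.
#' @param transport HTTP transport function.
#' @param batch_size Accessions per request (KEGG allows up to 10).
#' @return Named character vector, accession -> name.
#' @export
fetch_names <- function(accessions, transport = default_transport(),
                        batch_size = 10L) {
  accessions <- unique(accessions)
  if (length(accessions) == 0L) return(stats::setNames(character(), character()))
  out <- character()
  for (chunk in split(accessions,
                      ceiling(seq_along(accessions) / batch_size))) {
    lines <- .get_lines(
      paste0(.kegg_base(), "/list/", paste(chunk, collapse = "+")), transport)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) next
      acc <- parts[1]
      # responses may drop the namespace prefix; restore it from the query
      if (!acc %in% chunk) {
        hit <- chunk[sub("^[^:]*:", "", chunk) == acc]
        if (length(hit) == 1L) acc <- hit else next
      }
      nm <- .parse_name_field(acc, parts[2])
      if (nzchar(nm)) out[acc] <- nm
    }
  }
  out
}
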