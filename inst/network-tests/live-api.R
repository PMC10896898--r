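# Live KEGG REST probes.  These hit the network and are therefore kept out
# of the default test suite; run them manually when connectivity is
# available:
#
#     Rscript inst/network-tests/live-api.R
#
# (or system.file("network-tests", "live-api.R", package = "kgmlnet") from
# an installed copy.)

library(kgmlnet)

stopifnot_msg <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE) else message("ok: ", msg)
}

ids <- list_pathways("hsa")
stopifnot_msg("hsa04014" %in% ids, "list_pathways(\"hsa\") contains hsa04014")

cache <- tempfile("kgml-cache-")
xml <- fetch_kgml("hsa04014", cache_dir = cache)
p <- parse_kgml(xml)
stopifnot_msg(identical(p$org, "hsa"), "hsa04014 KGML parses with org = hsa")
stopifnot_msg(length(p$entries) > 0, "hsa04014 has entries")

cm <- fetch_conv_map("hsa", "ncbi-geneid")
stopifnot_msg(identical(cm$mapping[["hsa:10000"]], "ncbi-geneid:10000"),
              "conv map sends hsa:10000 to ncbi-geneid:10000")

cm_up <- fetch_conv_map("hsa", "uniprot")
stopifnot_msg(startsWith(cm_up$mapping[["hsa:10000"]], "up:"),
              "uniprot conv map uses the up: namespace")

nm <- fetch_names("hsa:10000")
stopifnot_msg(identical(nm[["hsa:10000"]], "AKT serine/threonine kinase 3"),
              "hsa:10000 resolves to its gene description")

message("all live API probes passed")
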