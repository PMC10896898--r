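act <- data.frame(name = "activation", value = "-->",
                  stringsAsFactors = FALSE)

test_that("terminal modifiers attach and strip as an inverse pair", {
  expect_equal(attach_modifier("cpd:C00035", 92), "cpd:C00035-92")
  expect_equal(attach_modifier("hsa:10000", 23), "hsa:10000-23")
  expect_equal(attach_modifier("path:hsa04014", 0), "path:hsa04014-0")
  expect_equal(strip_modifier("hsa:10000-23"), "hsa:10000")
  expect_equal(strip_modifier("hsa:10000"), "hsa:10000")
  expect_equal(strip_modifier("cpd:C00165-198"), "cpd:C00165")
  accs <- c("hsa:1", "cpd:C00165", "path:hsa04014")
  expect_equal(strip_modifier(attach_modifier(accs, c(5, 10, 0))), accs)
})

test_that("base graph expands multi-accession entries Cartesian-style", {
  spec <- fixture_spec(entries = list(
    list(id = 5L, name = "hsa:1 hsa:2", type = "gene", x = 80L, y = 80L),
    list(id = 6L, name = "hsa:3", type = "gene", x = 160L, y = 80L)
  ), relations = list(
    list(entry1 = 5L, entry2 = 6L, type = "PPrel", subtypes = act)
  ))
  g <- build_base_graph(parse_kgml(make_kgml(spec)))
  expect_setequal(igraph::V(g)$name, c("hsa:1-5", "hsa:2-5", "hsa:3-6"))
  ed <- igraph::as_data_frame(g, "edges")
  expect_setequal(paste(ed$from, ed$to),
                  c("hsa:1-5 hsa:3-6", "hsa:2-5 hsa:3-6"))
  expect_true(all(ed$rel_type == "PPrel"))
})

test_that("a relationless pathway yields an edgeless node-per-accession graph", {
  spec <- fixture_spec(entries = list(
    list(id = 1L, name = "hsa:10 hsa:11", type = "gene", x = 80L, y = 80L)
  ))
  g <- build_base_graph(parse_kgml(make_kgml(spec)))
  expect_equal(igraph::gorder(g), 2)
  expect_equal(igraph::gsize(g), 0)
})

test_that("entries sharing an accession become distinct suffixed nodes", {
  spec <- fixture_spec(entries = list(
    list(id = 10L, name = "cpd:C00165", type = "compound", x = 80L, y = 80L),
    list(id = 20L, name = "cpd:C00165", type = "compound", x = 160L, y = 80L)
  ))
  g <- build_base_graph(parse_kgml(make_kgml(spec)))
  expect_setequal(igraph::V(g)$name, c("cpd:C00165-10", "cpd:C00165-20"))
})

test_that("binding/association '---' subtypes produce edges both ways", {
  spec <- fixture_spec(entries = list(
    list(id = 1L, name = "hsa:10", type = "gene", x = 80L, y = 80L),
    list(id = 2L, name = "hsa:20", type = "gene", x = 160L, y = 80L)
  ), relations = list(
    list(entry1 = 1L, entry2 = 2L, type = "PPrel",
         subtypes = data.frame(name = "binding/association", value = "---"))
  ))
  g <- build_base_graph(parse_kgml(make_kgml(spec)))
  ed <- igraph::as_data_frame(g, "edges")
  expect_setequal(paste(ed$from, ed$to),
                  c("hsa:10-1 hsa:20-2", "hsa:20-2 hsa:10-1"))
})

test_that("groups expand to member edges plus a clique annotation", {
  p <- parse_kgml(make_group_fixture())
  g <- expand_groups(build_base_graph(p), p)
  expect_false(any(startsWith(igraph::V(g)$name, "group-")))
  ed <- igraph::as_data_frame(g, "edges")
  orig <- ed[ed$provenance == "original", ]
  expect_setequal(paste(orig$from, orig$to),
                  c("hsa:100-1 hsa:300-3", "hsa:200-2 hsa:300-3"))
  cli <- ed[ed$provenance == "clique", ]
  expect_equal(nrow(cli), 1)
  expect_equal(cli$rel_value, "Custom")
  expect_equal(cli$rel_name, "clique")
  expect_setequal(c(cli$from, cli$to), c("hsa:100-1", "hsa:200-2"))
})

test_that("group expansion is identity on group-free graphs", {
  p <- parse_kgml(make_shared_compound_scenario())
  g <- build_base_graph(p)
  g2 <- expand_groups(g, p)
  expect_equal(igraph::as_data_frame(g2, "both"),
               igraph::as_data_frame(g, "both"))
})

test_that("one-member groups inherit edges without clique edges", {
  spec <- fixture_spec(entries = list(
    list(id = 1L, name = "hsa:10", type = "gene", x = 80L, y = 80L),
    list(id = 2L, name = "hsa:20", type = "gene", x = 160L, y = 80L),
    list(id = 3L, name = "undefined", type = "group", components = 1L)
  ), relations = list(
    list(entry1 = 3L, entry2 = 2L, type = "PPrel", subtypes = act)
  ))
  p <- parse_kgml(make_kgml(spec))
  g <- expand_groups(build_base_graph(p), p)
  ed <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ed), 1)
  expect_equal(paste(ed$from, ed$to), "hsa:10-1 hsa:20-2")
  expect_false(any(ed$provenance == "clique"))
})

test_that("cyclic group membership is rejected with the entry ids named", {
  spec <- fixture_spec(entries = list(
    list(id = 1L, name = "undefined", type = "group", components = 2L),
    list(id = 2L, name = "undefined", type = "group", components = 1L)
  ))
  p <- parse_kgml(make_kgml(spec))
  expect_error(expand_groups(build_base_graph(p), p), "cyclic.*1, 2")
})

test_that("a gene-compound-gene chain propagates to one annotated edge", {
  p <- parse_kgml(make_shared_compound_scenario())
  g <- expand_groups(build_base_graph(p), p)
  g2 <- propagate_non_genes(g, function(n) startsWith(n, "hsa:"))
  ed <- igraph::as_data_frame(g2, "edges")
  expect_setequal(igraph::V(g2)$name,
                  c("hsa:1111-10", "hsa:2222-11", "hsa:3333-20", "hsa:4444-21"))
  expect_setequal(paste(ed$from, ed$to),
                  c("hsa:1111-10 hsa:2222-11", "hsa:3333-20 hsa:4444-21"))
  expect_true(all(ed$rel_type == "CPp"))
  expect_true(all(ed$rel_value == "Custom"))
  expect_true(all(ed$rel_name == "compound propagation"))
})

test_that("propagation is identity on compound-free graphs", {
  spec <- fixture_spec(entries = list(
    list(id = 1L, name = "hsa:10", type = "gene", x = 80L, y = 80L),
    list(id = 2L, name = "hsa:20", type = "gene", x = 160L, y = 80L)
  ), relations = list(
    list(entry1 = 1L, entry2 = 2L, type = "PPrel", subtypes = act)
  ))
  g <- build_base_graph(parse_kgml(make_kgml(spec)))
  g2 <- propagate_non_genes(g, function(n) startsWith(n, "hsa:"))
  expect_equal(igraph::as_data_frame(g2, "both"),
               igraph::as_data_frame(g, "both"))
})

test_that("chained compounds with a branch propagate only along paths", {
  # g1 -> c1 -> c2 -> g2 and c1 -> g3: expect g1->g2 and g1->g3 only
  edges <- data.frame(from = c("g1", "c1", "c2", "c1"),
                      to = c("c1", "c2", "g2", "g3"),
                      stringsAsFactors = FALSE)
  nodes <- c("g1", "g2", "g3", "c1", "c2")
  kept <- c("g1", "g2", "g3")
  got <- package_propagated_pairs(edges, nodes, kept)
  expect_equal(got, sort(c("g1\rg2", "g1\rg3")))
  expect_equal(got, oracle_propagated_pairs(edges, nodes, kept))
})

test_that("propagation matches the exhaustive path oracle on random graphs", {
  for (seed in 1:60) {
    rg <- random_keep_graph(sample(4:12, 1), seed = seed)
    expect_equal(
      package_propagated_pairs(rg$edges, rg$nodes, rg$kept),
      oracle_propagated_pairs(rg$edges, rg$nodes, rg$kept),
      info = paste("seed", seed))
  }
})

test_that("parallel originals aggregate to comma-joined metadata", {
  rows <- data.frame(
    entry1 = c("A", "A"), entry2 = c("B", "B"),
    type = c("PPrel", "PPrel"), value = c("-->", "-->"),
    name = c("activation", "activation"),
    provenance = c("original", "original"), stringsAsFactors = FALSE)
  out <- aggregate_parallel_edges(rows)
  expect_equal(nrow(out), 1)
  expect_equal(out$type, "PPrel, PPrel")
  expect_equal(out$value, "-->,-->")
  expect_equal(out$name, "activation, activation")
})

test_that("aggregation keeps already-unique rows unchanged", {
  rows <- data.frame(
    entry1 = c("A", "B"), entry2 = c("B", "C"),
    type = "PPrel", value = "-->", name = "activation",
    provenance = "original", stringsAsFactors = FALSE)
  expect_equal(aggregate_parallel_edges(rows), rows)
})

test_that("original metadata wins over a propagated duplicate", {
  rows <- data.frame(
    entry1 = c("A", "A"), entry2 = c("B", "B"),
    type = c("PPrel", "CPp"), value = c("-->", "Custom"),
    name = c("activation", "compound propagation"),
    provenance = c("original", "compound_propagated"),
    stringsAsFactors = FALSE)
  out <- aggregate_parallel_edges(rows)
  expect_equal(nrow(out), 1)
  expect_equal(out$type, "PPrel")
  expect_equal(out$provenance, "original")
})

test_that("the four output variants have the documented node policies", {
  p <- parse_kgml(make_shared_compound_scenario())

  tu <- build_network(p, "gene", unique = TRUE)
  expect_equal(network_components(tu), 2)
  expect_true(all(grepl("-[0-9]+$", network_nodes(tu))))

  tp <- build_network(p, "gene", unique = FALSE)
  expect_equal(network_components(tp), 2)  # stripping happens after propagation
  expect_false(any(grepl("-[0-9]+$", network_nodes(tp))))

  mu <- build_network(p, "mixed", unique = TRUE)
  expect_true(all(grepl("-[0-9]+$", network_nodes(mu))))

  mp <- build_network(p, "mixed", unique = FALSE)
  nn <- network_nodes(mp)
  cpd <- nn[startsWith(nn, "cpd:")]
  gene <- nn[startsWith(nn, "hsa:")]
  expect_true(all(grepl("-[0-9]+$", cpd)))
  expect_false(any(grepl("-[0-9]+$", gene)))
  expect_setequal(cpd, c("cpd:C00165-12", "cpd:C00165-22"))
})

test_that("gene networks contain only organism-prefixed nodes", {
  for (seed in 1:5) {
    p <- parse_kgml(random_pathway(10, 4, 2, seed = seed))
    for (uq in c(TRUE, FALSE)) {
      nn <- network_nodes(build_network(p, "gene", unique = uq))
      expect_true(all(startsWith(nn, "hsa:")), info = paste("seed", seed))
    }
  }
})

test_that("an empty pathway yields an empty table with a warning", {
  p <- parse_kgml('<pathway name="path:hsa00001" org="hsa" number="00001"/>')
  expect_warning(tbl <- build_network(p, "gene"), "no gene entries")
  expect_equal(nrow(tbl), 0)
})

test_that("unique component count never drops below the naive emulation", {
  for (seed in 1:5) {
    p <- parse_kgml(random_pathway(12, 4, 2, seed = seed))
    expect_gte(network_components(build_network(p, "gene", unique = TRUE)),
               network_components(naive_gene_network(p)))
  }
  # strict on the two-neighborhood fixture
  p <- parse_kgml(make_shared_compound_scenario())
  expect_gt(network_components(build_network(p, "gene", unique = TRUE)),
            network_components(naive_gene_network(p)))
})

test_that("repeated builds produce byte-identical TSV output", {
  p <- parse_kgml(random_pathway(10, 4, 2, seed = 42))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(build_network(p, "mixed", unique = TRUE), f1)
  write_network(build_network(p, "mixed", unique = TRUE), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_gt(file.size(f1), 0)
})

test_that("network TSV files round-trip through write and read", {
  p <- parse_kgml(make_shared_compound_scenario())
  tbl <- build_network(p, "mixed", unique = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(tbl, f)
  back <- read_network(f, mode = "mixed", unique = FALSE,
                       pathway_id = attr(tbl, "pathway_id"))
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  header <- readLines(f, n = 1)
  expect_identical(header, "entry1\tentry2\ttype\tvalue\tname")
})
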