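test_that("edge-table construction parses GPRs and pathways", {
  tab <- tibble::tibble(
    reaction_id = c("R05940", "R2", "R3"),
    source = c("C19752", "C1", "C2"),
    target = c("C19753", "C2", "C3"),
    gpr = c("ST8SIA1", "A AND B", "(A AND B) OR C"),
    pathways = c("hsa00604", "hsa00600;hsa00601", "hsa00600")
  )
  g <- read_graph_table(tab)
  expect_s3_class(g, "metabolic_graph")
  expect_equal(nrow(g$edges), 3)
  expect_equal(gpr_class(g$edges$gpr[[1]]), "single")
  expect_equal(gpr_class(g$edges$gpr[[2]]), "AND")
  expect_equal(gpr_class(g$edges$gpr[[3]]), "nested")
  expect_equal(g$edges$pathways[[2]], c("hsa00600", "hsa00601"))
  expect_setequal(g$gene_universe, c("ST8SIA1", "A", "B", "C"))
})

test_that("duplicate (source, target) rows are rejected unless merged", {
  tab <- tibble::tibble(
    reaction_id = c("R1", "R2"),
    source = "C1", target = "C2",
    gpr = c("A", "B"), pathways = "p"
  )
  expect_error(metabolic_graph(tab), class = "rasnet_graph_error")
  g <- metabolic_graph(tab, merge_duplicates = TRUE)
  expect_equal(nrow(g$edges), 1)
  expect_equal(gpr_class(g$edges$gpr[[1]]), "OR")
  expect_setequal(g$edges$reaction_ids[[1]], c("R1", "R2"))
})

test_that("unparseable GPR errors with row number; self-loops rejected", {
  bad <- tibble::tibble(reaction_id = "R1", source = "C1", target = "C2",
                        gpr = "A AND", pathways = "p")
  expect_error(metabolic_graph(bad), regexp = "Row 1")
  loop <- tibble::tibble(reaction_id = "R1", source = "C1", target = "C1",
                         gpr = "A", pathways = "p")
  expect_error(metabolic_graph(loop), class = "rasnet_graph_error")
})

test_that("KGML parsing builds nodes, edges and reversibility", {
  f <- write_kgml(kgml_text("irreversible"))
  g <- parse_kgml(f)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$source, "C00001")
  expect_equal(g$edges$target, "C00002")
  # KGML gene lists become an OR rule
  expect_equal(gpr_class(g$edges$gpr[[1]]), "OR")
  expect_setequal(gpr_genes(g$edges$gpr[[1]]), c("111", "222"))

  g2 <- parse_kgml(write_kgml(kgml_text("reversible")))
  expect_equal(nrow(g2$edges), 2)
  expect_setequal(paste(g2$edges$source, g2$edges$target),
                  c("C00001 C00002", "C00002 C00001"))
})

test_that("KGML errors: malformed XML, unknown compound; GPR table override", {
  expect_error(parse_kgml(write_kgml("<pathway><broken")),
               class = "rasnet_parse_error")
  bad <- sub('name="cpd:C00001" type="compound"', 'name="cpd:C09999" type="compound"',
             kgml_text())
  expect_error(parse_kgml(write_kgml(bad)), class = "rasnet_structure_error")
  g <- parse_kgml(write_kgml(kgml_text()),
                  gpr_table = data.frame(reaction_id = "R00001",
                                         gpr = "G1 AND G2"))
  expect_equal(gpr_class(g$edges$gpr[[1]]), "AND")
})

test_that("remove_reactions drops edges, keeps nodes, warns on absent ids", {
  g <- toy_graph_fig3()
  g2 <- remove_reactions(g, c("R_ac", "R_bd"))
  expect_equal(nrow(g2$edges), 6)
  expect_equal(nrow(g2$nodes), 9)
  expect_warning(g3 <- remove_reactions(g, "R_nope"),
                 class = "rasnet_absent_reaction")
  expect_equal(g3$edges, g$edges)
  # idempotent and commuting over disjoint sets
  a <- remove_reactions(remove_reactions(g, "R_ac"), "R_ac") |> suppressWarnings()
  expect_equal(a$edges$edge_id, remove_reactions(g, "R_ac")$edges$edge_id)
  ab <- remove_reactions(remove_reactions(g, "R_ac"), "R_bd")
  ba <- remove_reactions(remove_reactions(g, "R_bd"), "R_ac")
  expect_equal(ab$edges$edge_id, ba$edges$edge_id)
})

test_that("graph_summary counts classes, partitions, and outside enzymes", {
  empty <- toy_graph_fig3()
  empty$edges <- empty$edges[0, ]
  empty$gene_universe <- character()
  s0 <- graph_summary(empty)
  expect_equal(s0$n_reactions, 0)
  expect_equal(s0$n_enzymes, 0)

  tab <- tibble::tibble(
    reaction_id = sprintf("R%d", 1:4),
    source = c("a", "b", "c", "d"),
    target = c("b", "c", "d", "e"),
    gpr = c("g1", "g1 AND g2", "g2 OR g3", "(g1 AND g2) OR g3"),
    pathways = "gsl"
  )
  g <- metabolic_graph(tab)
  s <- graph_summary(
    g, gsl_pathways = "gsl",
    gene_pathways = data.frame(
      gene = c("g1", "g1", "g2", "g3", "zz"),
      pathway = c("gsl", "other1", "gsl", "other2", "other3")
    )
  )
  expect_equal(s$n_reactions, 4)
  expect_equal(s$n_and, 1)
  expect_equal(s$n_or, 1)
  expect_equal(s$n_single, 1)
  expect_equal(s$n_nested, 1)
  expect_equal(s$n_and + s$n_or + s$n_single + s$n_nested, s$n_reactions)
  expect_equal(s$n_enzymes, 3)
  expect_equal(s$n_enzymes_outside, 2)  # g1 and g3, not zz (absent from graph)
})

test_that("graph table write/read round trip preserves structure", {
  g <- toy_graph_fig3()
  f <- tempfile(fileext = ".tsv")
  write_graph_table(g, f)
  g2 <- read_graph_table(f)
  expect_setequal(g2$nodes$id, g$nodes$id)
  expect_equal(g2$edges[, c("reaction_id", "source", "target")],
               g$edges[, c("reaction_id", "source", "target")])
  expect_equal(vapply(g2$edges$gpr, format, character(1)),
               vapply(g$edges$gpr, format, character(1)))
  # graphml export is parseable by igraph
  fg <- tempfile(fileext = ".graphml")
  write_graphml(g, fg)
  gi <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::gorder(gi), 9)
  expect_equal(igraph::gsize(gi), 8)
})
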