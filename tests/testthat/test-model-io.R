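# Model reading, validation, pools, round-trips.

make_toy6 <- function(dir) {
  write_tiny_model(
    dir,
    metabolites = list(a_c = "alpha", b_c = "beta", c_c = "gamma",
                       d_c = "delta", nad_c = "nad", nadh_c = "nadh"),
    reactions = list(
      bigg_reaction("R1", c(a_c = -1, nad_c = -1, b_c = 1, nadh_c = 1),
                    gene = "g001"),
      bigg_reaction("R2", c(b_c = -1, c_c = 1), gene = "g002", kegg = "R00002"),
      bigg_reaction("R3", c(c_c = -1, d_c = 1), gene = "g003", kegg = "R00003",
                    reversible = FALSE),
      bigg_reaction("R4", c(a_c = -1, d_c = 1), gene = "g004", kegg = "R00004")),
    smiles = c(a = "CC(C)O", b = "CC(=O)C", c = "CC(O)CO", d = "CCO"))
}

test_that("a toy BiGG-style model loads with correct counts and flags", {
  paths <- make_toy6(withr::local_tempdir())
  m <- load_model(paths$model, "bigg-json", paths$structures)
  expect_equal(nrow(m$metabolites), 6)
  expect_equal(nrow(m$reactions), 4)
  expect_false(m$metabolites$has_structure[m$metabolites$id == "nad_c"])
  expect_true(all(m$metabolites$has_structure[m$metabolites$id %in%
                                                c("a_c", "b_c", "c_c", "d_c")]))
  expect_false(m$reactions$reversible[m$reactions$id == "R3"])
  expect_true(m$reactions$reversible[m$reactions$id == "R1"])
})

test_that("an empty reaction list yields a valid, empty-reaction model", {
  paths <- write_tiny_model(withr::local_tempdir(),
                            metabolites = list(a_c = "alpha"),
                            reactions = list())
  m <- load_model(paths$model, "bigg-json")
  expect_equal(nrow(m$reactions), 0)
  expect_equal(nrow(m$metabolites), 1)
})

test_that("a reaction citing a missing metabolite errors naming it", {
  paths <- write_tiny_model(withr::local_tempdir(),
                            metabolites = list(a_c = "alpha"),
                            reactions = list(bigg_reaction("R1", c(a_c = -1, X = 1))))
  expect_error(load_model(paths$model, "bigg-json"), "X")
})

test_that("model serialization round-trips", {
  paths <- make_toy6(withr::local_tempdir())
  m <- load_model(paths$model, "bigg-json", paths$structures)
  out <- file.path(withr::local_tempdir(), "roundtrip.json")
  write_model(m, out)
  m2 <- load_model(out, "bigg-json", paths$structures)
  expect_identical(m$metabolites$id, m2$metabolites$id)
  expect_identical(m$reactions$id, m2$reactions$id)
  expect_identical(m$reactions$reversible, m2$reactions$reversible)
  expect_identical(m$reactions$stoich, m2$reactions$stoich)
  expect_identical(lapply(m$reactions$ec, as.character),
                   lapply(m2$reactions$ec, as.character))
})

test_that("the SBML subset loads an equivalent model", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
 <model id="toy">
  <listOfSpecies>
   <species id="a_c" name="alpha" compartment="c"/>
   <species id="b_c" name="beta" compartment="c"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: g001</p></body></notes>
    <annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
      xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
     <rdf:Description><bqbiol:is><rdf:Bag>
      <rdf:li rdf:resource="http://identifiers.org/ec-code/1.1.1.1"/>
      <rdf:li rdf:resource="http://identifiers.org/kegg.reaction/R00754"/>
     </rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>
    <listOfReactants><speciesReference species="a_c" stoichiometry="1"/></listOfReactants>
    <listOfProducts><speciesReference species="b_c" stoichiometry="1"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  f <- file.path(withr::local_tempdir(), "toy.xml")
  writeLines(sbml, f)
  m <- load_model(f, "sbml")
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 1)
  expect_false(m$reactions$reversible[1])
  expect_equal(m$reactions$ec[[1]], "1.1.1.1")
  expect_equal(m$reactions$kegg_reaction[[1]], "R00754")
  expect_equal(m$reactions$genes[[1]], "g001")
  expect_equal(unname(m$reactions$stoich[[1]][c("a_c", "b_c")]), c(-1, 1))
})

test_that("substrate pool selection uses a strict threshold and partitions", {
  paths <- make_toy6(withr::local_tempdir())
  m <- load_model(paths$model, "bigg-json", paths$structures)
  conc <- tibble::tibble(metabolite_id = c("a_c", "b_c", "c_c"),
                         concentration_uM = c(5, 0.5, 1.0))
  pool <- select_substrate_pool(m, conc, 1)
  expect_setequal(pool$high, "a")      # 1.0 is not "above 1"
  expect_true(all(c("b", "c", "d") %in% pool$remainder))
  # partition invariant: high and remainder cover all structure-bearing ids
  eligible <- unique(m$metabolites$base_id[m$metabolites$has_structure])
  expect_setequal(c(pool$high, pool$remainder), eligible)
  expect_length(intersect(pool$high, pool$remainder), 0)

  empty <- select_substrate_pool(m, conc[0, ], 1)
  expect_length(empty$high, 0)

  all_in <- select_substrate_pool(m, conc, 0)
  expect_setequal(all_in$high, c("a", "b", "c"))
})

test_that("concentration tables are validated", {
  d <- withr::local_tempdir()
  f <- file.path(d, "conc.tsv")
  writeLines("metabolite_id\tconcentration_uM\na_c\t-3", f)
  expect_error(read_concentrations(f), "negative")
  writeLines("metabolite_id\tconcentration_uM\na_c\t3\na_c\t4", f)
  expect_error(read_concentrations(f), "duplicate")
})
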