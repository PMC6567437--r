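# Site finding and operator application on new substrates.

# operator from a primary-alcohol oxidation on 1,2-propanediol
diol_oxidation_op <- function() {
  s <- smi("CC(O)CO")    # propane-1,2-diol
  p <- smi("CC(O)C=O")   # lactaldehyde
  pat <- extract_rdm(s, p, map_atoms(s, p))$patterns[[1]]
  rx <- tibble::tibble(id = "RX", ec = list("1.1.1.x"), genes = list("g001"),
                       kegg_reaction = list("R00001"), reversible = TRUE,
                       stoich = list(numeric(0)))
  emmr:::.make_operator(pat, s, p, "diol", "lald", rx[1, ], "forward")
}

test_that("find_sites distinguishes site classes and collapses symmetry", {
  op <- diol_oxidation_op()
  glycerol <- smi("OCC(O)CO")
  sites <- find_sites(op, glycerol)
  # two classes: the (automorphic) terminal carbinols collapse to one site,
  # the central carbinol is the other
  expect_length(sites, 2)

  # no reaction-center type present: no sites
  expect_length(find_sites(op, smi("CCCC")), 0)

  # the originating substrate contains the originating site
  s <- smi("CC(O)CO")
  expect_true(op$origin$site %in% find_sites(op, s))
})

test_that("operator application reproduces curated redox and kinase chemistry", {
  # glyoxylate-reductase-style carbonyl reduction applied to 2-oxoglutarate
  pyr <- smi("CC(=O)C(=O)O"); lac <- smi("CC(O)C(=O)O")
  pat <- extract_rdm(pyr, lac, map_atoms(pyr, lac))$patterns[[1]]
  rx <- tibble::tibble(id = "GRX", ec = list("1.1.1.79"), genes = list("b1033"),
                       kegg_reaction = list("R00717"), reversible = TRUE,
                       stoich = list(numeric(0)))
  op <- emmr:::.make_operator(pat, pyr, lac, "pyr", "lac", rx[1, ], "forward")
  og <- smi("OC(=O)CCC(=O)C(=O)O")
  keys <- vapply(find_sites(op, og), function(s) apply_operator(op, og, s)$key, "")
  expect_true(canonical_key(smi("OC(=O)CCC(O)C(=O)O")) %in% keys)

  # phosphoribulokinase-style phosphorylation round-trips on its own pair
  ru5p <- smi("OCC(=O)C(O)C(O)COP(=O)(O)O")
  rubp <- smi("OP(=O)(O)OCC(=O)C(O)C(O)COP(=O)(O)O")
  pat2 <- extract_rdm(ru5p, rubp, map_atoms(ru5p, rubp))$patterns[[1]]
  op2 <- emmr:::.make_operator(pat2, ru5p, rubp, "ru5p", "rubp", rx[1, ], "forward")
  res <- apply_operator(op2, ru5p, op2$origin$site)
  expect_identical(res$key, canonical_key(rubp))
})

test_that("applications that cannot be realized return NULL", {
  op <- diol_oxidation_op()
  g <- smi("CC(O)CO")
  # a site whose type does not match the key
  expect_null(apply_operator(op, g, which(g$atoms$element == "O")[1]))
})

test_that("enumeration recovers planted products, dedupes, and never emits the parent", {
  u <- generate_toy_universe(11, n_scaffolds = 6, n_reactions = 6,
                             promiscuity_rate = 0.1)
  tab <- build_operator_table(u$model)
  pool <- unique(u$model$metabolites$base_id[u$model$metabolites$has_structure])
  derivs <- enumerate_derivatives(tab, u$model, pool, u$known)
  # planted recovery at the enumeration level
  expect_true(all(paste(u$planted$substrate, u$planted$product_key) %in%
                    paste(derivs$parent, derivs$product_key)))
  # no derivative equals its parent
  expect_false(any(derivs$product_key == derivs$parent_key))
  # deduplication on (parent, product, provenance)
  sig <- paste(derivs$parent, derivs$product_key, derivs$ec, derivs$genes,
               derivs$kegg_reaction, derivs$direction)
  expect_false(anyDuplicated(sig) > 0)
  # determinism: a second run is identical
  derivs2 <- enumerate_derivatives(tab, u$model, pool, u$known)
  expect_identical(derivs[, setdiff(names(derivs), "graph")],
                   derivs2[, setdiff(names(derivs2), "graph")])
  # known-compound ids attached where the table covers the product
  expect_true(all(!is.na(derivs$known_id[derivs$product_key %in% names(u$known)])))

  # empty pool
  expect_equal(nrow(enumerate_derivatives(tab, u$model, character(0))), 0)
})

test_that("pool of originating substrates regenerates all originating products", {
  m <- alcohol_ketone_model(withr::local_tempdir())
  tab <- build_operator_table(m)
  derivs <- enumerate_derivatives(tab, m, c("ipa", "act"))
  for (op in tab$operators) {
    expect_true(op$origin$product_key %in% derivs$product_key)
  }
})
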