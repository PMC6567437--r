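# Atom mapping, RDM extraction, operator table construction.

test_that("MCS mapping matches the brute-force oracle on small pairs", {
  cases <- list(
    list(s = "CC(=O)C(=O)O", p = "CC(O)C(=O)O", expect = 5),  # pyruvate/lactate
    list(s = "CC(=O)O", p = "CC(=O)O", expect = 4),           # identical
    list(s = "C", p = "c1ccccc1", expect = 1))                # near-disjoint
  for (cs in cases) {
    s <- smi(cs$s); p <- smi(cs$p)
    m <- map_atoms(s, p)
    expect_equal(sum(!is.na(m$map)), oracle_mcs_size(s, p), label = cs$s)
    expect_equal(sum(!is.na(m$map)), cs$expect, label = cs$s)
    # injectivity and element preservation
    mapped <- m$map[!is.na(m$map)]
    expect_false(anyDuplicated(mapped) > 0)
    expect_identical(s$atoms$element[!is.na(m$map)], p$atoms$element[mapped])
  }
})

test_that("identical graphs map completely; pyruvate/lactate localizes to one carbon", {
  s <- smi("CC(=O)C(=O)O")
  m_id <- map_atoms(s, s)
  expect_length(m_id$lost, 0)
  expect_length(m_id$gained, 0)

  p <- smi("CC(O)C(=O)O")
  m <- map_atoms(s, p)
  expect_length(m$lost, 1)   # the carbonyl O
  expect_length(m$gained, 1) # the hydroxyl O
  expect_equal(s$atoms$element[m$lost], "O")
})

test_that("RDM extraction finds the single reaction center with correct D regions", {
  og <- smi("OC(=O)CCC(=O)C(=O)O")  # 2-oxoglutarate
  hg <- smi("OC(=O)CCC(O)C(=O)O")   # 2-hydroxyglutarate
  r <- extract_rdm(og, hg, map_atoms(og, hg))
  expect_false(r$multi_center)
  expect_length(r$patterns, 1)
  pat <- r$patterns[[1]]
  expect_equal(pat$r_substrate, "C.car")
  expect_equal(pat$r_product, "C.olc")
  expect_equal(pat$d_substrate, "O.car")
  expect_equal(pat$d_product, "O.hyd")

  # a molecule against itself yields no pattern
  same <- extract_rdm(og, og, map_atoms(og, og))
  expect_length(same$patterns, 0)
  expect_equal(same$reason, "identical")

  # differences at two distant carbons: flagged multi-center, no pattern
  diol <- smi("OCCCCO")
  dial <- smi("O=CCCC=O")
  r2 <- extract_rdm(diol, dial, map_atoms(diol, dial))
  expect_true(r2$multi_center)
  expect_length(r2$patterns, 0)
})

test_that("operator tables honor reversibility and skip degenerate pairs", {
  m_rev <- alcohol_ketone_model(withr::local_tempdir(), reversible = TRUE)
  t_rev <- build_operator_table(m_rev)
  expect_length(t_rev$operators, 2)
  expect_setequal(vapply(t_rev$operators, function(o) o$provenance$direction, ""),
                  c("forward", "reverse"))

  m_irr <- alcohol_ketone_model(withr::local_tempdir(), reversible = FALSE)
  expect_length(build_operator_table(m_irr)$operators, 1)

  # a model whose only pair is multi-center yields no operator, one skip
  paths <- write_tiny_model(
    withr::local_tempdir(),
    metabolites = list(diol_c = "diol", dial_c = "dial"),
    reactions = list(bigg_reaction("RX", c(diol_c = -1, dial_c = 1))),
    smiles = c(diol = "OCCCCO", dial = "O=CCCC=O"))
  t_mc <- build_operator_table(load_model(paths$model, "bigg-json", paths$structures))
  expect_length(t_mc$operators, 0)
  expect_equal(nrow(t_mc$skipped), 1)
  expect_match(t_mc$skipped$reason, "multi-center")
})

test_that("every operator round-trips on its originating pair, both directions", {
  m <- alcohol_ketone_model(withr::local_tempdir())
  tab <- build_operator_table(m)
  for (op in tab$operators) {
    sub <- m$structures[[op$origin$substrate_id]]
    res <- apply_operator(op, sub, op$origin$site)
    expect_identical(res$key, op$origin$product_key,
                     label = op$provenance$direction)
  }
})

test_that("operator count and keys are invariant under atom reordering", {
  base <- withr::local_tempdir()
  smiles <- c(ipa = "CC(C)O", act = "CC(=O)C")
  mk <- function(dir, smiles) {
    paths <- write_tiny_model(
      dir,
      metabolites = list(ipa_c = "isopropanol", act_c = "acetone"),
      reactions = list(bigg_reaction("ADH", c(ipa_c = -1, act_c = 1))),
      smiles = smiles)
    build_operator_table(load_model(paths$model, "bigg-json", paths$structures))
  }
  t1 <- mk(file.path(base, "a"), smiles)
  # same molecules written with a different atom order
  t2 <- mk(file.path(base, "b"), c(ipa = "OC(C)C", act = "O=C(C)C"))
  expect_equal(length(t1$operators), length(t2$operators))
  sig <- function(t) sort(vapply(t$operators, function(o)
    paste(o$key$r, paste(o$key$m, collapse = ","),
          paste(o$key$d, collapse = ","), o$value$r,
          paste(o$value$d, collapse = ","), o$provenance$direction), ""))
  expect_identical(sig(t1), sig(t2))
})

test_that("reactions without KEGG ids are skipped when required", {
  paths <- write_tiny_model(
    withr::local_tempdir(),
    metabolites = list(ipa_c = "isopropanol", act_c = "acetone"),
    reactions = list({
      r <- bigg_reaction("ADH", c(ipa_c = -1, act_c = 1))
      r$annotation$`kegg.reaction` <- list()
      r
    }),
    smiles = c(ipa = "CC(C)O", act = "CC(=O)C"))
  m <- load_model(paths$model, "bigg-json", paths$structures)
  expect_length(build_operator_table(m, require_kegg = TRUE)$operators, 0)
  expect_length(build_operator_table(m, require_kegg = FALSE)$operators, 2)
})
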