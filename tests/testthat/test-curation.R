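# Discard filters, cofactor completion, balance, decision tree.

test_that("discard filters apply in fixed order", {
  mk <- function(...) candidate_reaction("s", "p", ec = "1.1.1.1", ...)
  expect_equal(apply_discard_filters(mk(substrate_is_cofactor = TRUE)),
               "DISCARD(cofactor)")
  expect_equal(apply_discard_filters(mk()), "keep")
  expect_equal(apply_discard_filters(mk(multi_center = TRUE, feasible = FALSE)),
               "DISCARD(infeasible)")  # first rule wins
  expect_equal(apply_discard_filters(mk(multi_center = TRUE)),
               "DISCARD(multi-center)")
})

test_that("cofactor completion copies the template couple side for side", {
  # phosphoribosyltransferase couple: PRPP in, diphosphate out
  r <- complete_reaction("cytosine", "cmp",
                         list(sub_cofactors = c(prpp = 1),
                              prod_cofactors = c(diphosphate = 1)),
                         ec = "2.4.2.10", genes = "b3642")
  expect_equal(format_equation(r), "cytosine + prpp <=> cmp + diphosphate")
  expect_true(r$completed)

  # redox couple: the product side gains the oxidized cofactor
  r2 <- complete_reaction("2-oxoglutarate", "2-hydroxyglutarate",
                          list(sub_cofactors = c(nadph = 1, `h+` = 1),
                               prod_cofactors = c(`nadp+` = 1)),
                          ec = "1.1.1.79")
  expect_true(r2$stoich[["nadp+"]] > 0)
  expect_true(r2$stoich[["nadph"]] < 0)

  # no template: bare pair, flagged uncompleted
  r3 <- complete_reaction("a", "b")
  expect_equal(format_equation(r3), "a <=> b")
  expect_false(r3$completed)
})

test_that("reaction templates come from a reaction's cofactor participants", {
  m <- alcohol_ketone_model(withr::local_tempdir())
  t_fwd <- reaction_template(m$reactions[1, ], direction = "forward")
  expect_equal(t_fwd$sub_cofactors, c(nad = 1))
  expect_equal(t_fwd$prod_cofactors, c(nadh = 1))
  t_rev <- reaction_template(m$reactions[1, ], direction = "reverse")
  expect_equal(t_rev$sub_cofactors, c(nadh = 1))
  expect_equal(t_rev$prod_cofactors, c(nad = 1))
})

test_that("balance checking reports signed per-element deltas", {
  formulas <- list(
    bicarbonate = parse_formula("CHO3", -1),
    orthophosphate = parse_formula("H3O4P"),
    carboxyphosphate = parse_formula("CH3O6P"),
    h2o = parse_formula("H2O"),
    glucose = parse_formula("C6H12O6"),
    a = parse_formula("C2H4O2"))
  r <- complete_reaction("bicarbonate", "carboxyphosphate",
                         list(sub_cofactors = c(orthophosphate = 1),
                              prod_cofactors = c(h2o = 1)), ec = "3.6.1.7")
  b <- check_balance(r, formulas)
  expect_true(b$balanced)
  expect_length(b$deltas, 0)

  # A <=> A trivially balances
  r_id <- structure(list(stoich = c(a = -1, a2 = 1), ec = "x", genes = character(0),
                         direction = "reversible", completed = TRUE),
                    class = "curated_reaction")
  formulas$a2 <- formulas$a
  expect_true(check_balance(r_id, formulas)$balanced)

  # glucose <=> glucose + H2O: O off by one
  r_bad <- structure(list(stoich = c(glucose = -1, glucose2 = 1, h2o = 1),
                          ec = "x", genes = character(0),
                          direction = "reversible", completed = TRUE),
                     class = "curated_reaction")
  formulas$glucose2 <- formulas$glucose
  b_bad <- check_balance(r_bad, formulas)
  expect_false(b_bad$balanced)
  expect_equal(b_bad$deltas[["O"]], 1)

  # missing formula errors with the metabolite named
  r_miss <- structure(list(stoich = c(glucose = -1, mystery = 1), ec = "x",
                           genes = character(0), direction = "reversible",
                           completed = TRUE), class = "curated_reaction")
  expect_error(check_balance(r_miss, formulas), "mystery")
})

test_that("H/charge tolerance absorbs only water and protons, when enabled", {
  formulas <- list(glucose = parse_formula("C6H12O6"),
                   glucose2 = parse_formula("C6H12O6"),
                   h2o = parse_formula("H2O"))
  r <- structure(list(stoich = c(glucose = -1, glucose2 = 1, h2o = 1),
                      ec = "x", genes = character(0),
                      direction = "reversible", completed = TRUE),
                 class = "curated_reaction")
  expect_false(check_balance(r, formulas)$balanced)
  b <- check_balance(r, formulas, tolerate_h = TRUE)
  expect_true(b$balanced)
  expect_equal(b$added[["h2o"]], -1)  # water removed from the surplus side
})

test_that("the decision tree reproduces the documented example categories", {
  ref <- reference_index(
    model_metabolite_keys = c("cytosine", "cmp", "d-gluconate", "l-serine"),
    model_reactions = data.frame(substrate = "cytosine", product = "cmp",
                                 ec = "3.2.2.10", genes = "b2795"),
    organism_reactions = data.frame(substrate = "d-gluconate",
                                    product = "2-keto-d-gluconate",
                                    equation_sig = NA_character_))
  # parallel route under a different gene: C1
  c1 <- candidate_reaction("cytosine", "cmp", ec = "2.4.2.10", genes = "b3642")
  expect_equal(classify(c1, ref), "C1")
  # same enzyme: already in the model
  c_dup <- candidate_reaction("cytosine", "cmp", ec = "3.2.2.10", genes = "b2795")
  expect_equal(classify(c_dup, ref), "DISCARD(already-in-model)")
  # documented for the organism but missing from the model: C2
  c2 <- candidate_reaction("d-gluconate", "2-keto-d-gluconate", ec = "1.1.1.215")
  expect_equal(classify(c2, ref), "C2")
  # documented only elsewhere: C3
  ref3 <- reference_index(other_organism_reactions = data.frame(
    substrate = "l-histidine", product = "imidazol-5-yl-pyruvate"))
  c3 <- candidate_reaction("l-histidine", "imidazol-5-yl-pyruvate", ec = "1.4.1.4")
  expect_equal(classify(c3, ref3), "C3")
  # nowhere: C4
  c4 <- candidate_reaction("l-serine", "aminomalonate", ec = "1.1.1.23")
  expect_equal(classify(c4, ref), "C4")
})

test_that("the decision tree is total: every kept candidate gets exactly one label", {
  ref <- reference_index(
    model_metabolite_keys = c("a", "b"),
    model_reactions = data.frame(substrate = "a", product = "b",
                                 ec = "1.1.1.1", genes = "g1"),
    organism_reactions = data.frame(substrate = "c", product = "d",
                                    equation_sig = NA_character_),
    other_organism_reactions = data.frame(substrate = "e", product = "f"))
  labels <- c("C1", "C2", "C3", "C4", "DISCARD(already-in-model)")
  for (s in letters[1:6]) {
    for (p in letters[1:6]) {
      if (s == p) next
      for (g in c("g1", "g2")) {
        got <- classify(candidate_reaction(s, p, ec = "9.9.9.9", genes = g), ref)
        expect_length(got, 1)
        expect_true(got %in% labels, label = paste(s, p, g))
      }
    }
  }
})

test_that("summaries conserve counts and list only new-to-model metabolites", {
  ref <- reference_index(
    model_metabolite_keys = c("a", "b"),
    model_reactions = data.frame(substrate = "a", product = "b",
                                 ec = "1.1.1.1", genes = "g1"),
    organism_reactions = data.frame(substrate = "a", product = "c",
                                    equation_sig = NA_character_))
  cands <- list(
    candidate_reaction("a", "b", ec = "2.2.2.2", genes = "g9"),   # C1
    candidate_reaction("a", "c", ec = "3.3.3.3"),                 # C2
    candidate_reaction("a", "d", ec = "4.4.4.4"),                 # C4
    candidate_reaction("a", "e", ec = "5.5.5.5", feasible = FALSE))
  s <- summarize_categories(cands, ref)
  expect_equal(sum(s$counts), 3)
  expect_equal(unname(s$counts[c("C1", "C2", "C4")]), c(1L, 1L, 1L))
  expect_equal(sum(s$discarded), 1)
  expect_equal(nrow(s$table), sum(s$counts) + sum(s$discarded))
  # C1 adds no metabolites; discards add none
  expect_setequal(s$new_metabolites, c("c", "d"))

  empty <- summarize_categories(list(), ref)
  expect_equal(sum(empty$counts), 0)
})
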