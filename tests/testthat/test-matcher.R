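# Identity reconciliation by majority vote and derivative matching.

xr <- function(...) {
  rows <- list(...)
  xref_table(do.call(rbind, lapply(rows, function(r)
    data.frame(source = r[1], id = r[2], primary_id = r[3]))))
}

rec <- function(pubchem = NA, inchikey = NA, kegg = NA, cas = NA,
                chebi = NA, biocyc = NA) {
  list(db_id = "X", name = "x", pubchem = pubchem, inchikey = inchikey,
       kegg = kegg, cas = cas, chebi = chebi, biocyc = biocyc)
}

test_that("majority vote follows the retrieved ids over the declared one", {
  x <- xr(c("inchikey", "IK1", "P1"), c("kegg", "K1", "P1"), c("cas", "C1", "P1"))
  r <- reconcile_primary_id(rec(pubchem = "P2", inchikey = "IK1",
                                kegg = "K1", cas = "C1"), x)
  expect_equal(r$primary_id, "P1")
  expect_false(r$consistent)

  r2 <- reconcile_primary_id(rec(pubchem = "P1", inchikey = "IK1",
                                 kegg = "K1", cas = "C1"), x)
  expect_equal(r2$primary_id, "P1")
  expect_true(r2$consistent)
})

test_that("the declared id counts as one vote; 2-vs-1 resolves, no majority stays open", {
  x <- xr(c("inchikey", "IK1", "P1"), c("kegg", "K1", "P2"))
  r <- reconcile_primary_id(rec(pubchem = "P2", inchikey = "IK1", kegg = "K1"), x)
  expect_equal(r$primary_id, "P2")  # P2 gets kegg + declared = 2 of 3

  # 1-vs-1 tie: unresolved
  r2 <- reconcile_primary_id(rec(inchikey = "IK1", kegg = "K1"), x)
  expect_true(is.na(r2$primary_id))

  # nothing resolvable and nothing declared: unresolved
  r3 <- reconcile_primary_id(rec(), x)
  expect_true(is.na(r3$primary_id))
})

test_that("vote outcome matches a brute-force counter and ignores source order", {
  # exhaustive: up to 5 sources each voting for one of two ids or abstaining
  sources <- c("inchikey", "kegg", "cas", "chebi", "biocyc")
  set.seed(3)
  for (trial in 1:200) {
    votes <- sample(c("P1", "P2", NA), 5, replace = TRUE)
    declared <- sample(c("P1", "P2", NA), 1)
    rows <- lapply(which(!is.na(votes)), function(i)
      c(sources[i], paste0("id", i), votes[i]))
    x <- if (length(rows)) do.call(xr, rows) else xref_table(
      data.frame(source = character(0), id = character(0),
                 primary_id = character(0)))
    args <- stats::setNames(as.list(ifelse(is.na(votes), NA,
                                           paste0("id", 1:5))), sources)
    r <- do.call(rec, c(args, list(pubchem = declared)))
    got <- reconcile_primary_id(r, x)$primary_id
    cast <- c(votes[!is.na(votes)], declared[!is.na(declared)])
    expected <- if (!length(cast)) NA_character_ else {
      t <- table(cast)
      if (max(t) * 2 > sum(t)) names(t)[which.max(t)] else NA_character_
    }
    expect_identical(got, expected)
  }
})

test_that("derivative matching uses reconciled ids with a structure fallback", {
  derivs <- tibble::tibble(
    parent = paste0("m", 1:5), parent_key = paste0("pk", 1:5),
    ec = "1.1.1.1", genes = "g", kegg_reaction = "R", reaction_id = "RX",
    direction = "forward", site = 1L,
    product_key = paste0("key", 1:5),
    known_id = c("P1", "P2", NA, "P4", NA),
    already_in_model = FALSE, self_transformation = FALSE,
    graph = replicate(5, NULL, simplify = FALSE))
  records <- tibble::tibble(
    db_id = c("DB1", "DB2", "DB3"), name = c("one", "two", "three"),
    formula = NA_character_,
    pubchem = c("P1", "P2", "P9"),
    inchikey = c("IK1", "IK2", "IK9"), kegg = NA_character_,
    cas = NA_character_, chebi = NA_character_, biocyc = NA_character_,
    structure_key = c(NA, NA, "key3"))
  x <- xr(c("inchikey", "IK1", "P1"), c("inchikey", "IK2", "P0"),
          c("inchikey", "IK9", "P9"))
  rr <- reconcile_metabolome(records, x)
  # DB2 has a 1-vs-1 conflict: unresolved, excluded from matching
  expect_false(rr$resolved[rr$db_id == "DB2"])
  m <- match_derivatives(derivs, rr)
  expect_equal(nrow(m), 2)
  expect_setequal(m$matched_db_id, c("DB1", "DB3"))  # P1 by id, key3 by structure

  # empty metabolome
  expect_equal(nrow(match_derivatives(derivs, rr[0, ])), 0)

  # record order does not change the outcome
  m2 <- match_derivatives(derivs, rr[rev(seq_len(nrow(rr))), ])
  expect_identical(m[order(m$parent), ], m2[order(m2$parent), ])
})
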