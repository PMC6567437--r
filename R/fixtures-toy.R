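## Synthetic test universes with planted promiscuous activity.
##
## Molecules come from a small scaffold grammar -- carbon chains and rings
## decorated with hydroxyl, carbonyl, carboxyl, amino and phosphate groups --
## chosen so that every native reaction is a single-center edit. Native
## reactions draw from five template chemistries with chemically consistent
## cofactor couples, so every curated reaction is heavy-atom balanced by
## construction. Promiscuous products are planted by replaying real
## operators (extracted from the native reactions) on non-native substrates,
## inserting the products into the synthetic metabolome, and populating the
## reference index to realize a requested category mix.

.TOY_COFACTOR_FORMULAS <- c(
  nad = "C21H27N7O14P2", nadh = "C21H29N7O14P2",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2",
  nh3 = "H3N", h2o = "H2O", co2 = "CO2", h = "H",
  accoa = "C23H38N7O17P3S", coa = "C21H36N7O16P3S",
  pi = "H3O4P", ppi = "H4O7P2")

# reaction chemistries: predicate finds sites, transform edits the graph
.TOY_RXN_TYPES <- list(
  oxidation = list(
    ec_prefix = "1.1.1.", sub_cof = c(nad = 1), prod_cof = c(nadh = 1)),
  phosphorylation = list(
    ec_prefix = "2.7.1.", sub_cof = c(atp = 1), prod_cof = c(adp = 1)),
  amination = list(
    ec_prefix = "1.4.1.", sub_cof = c(nh3 = 1, nadh = 1),
    prod_cof = c(h2o = 1, nad = 1)),
  decarboxylation = list(
    ec_prefix = "4.1.1.", sub_cof = c(), prod_cof = c(co2 = 1)),
  acetylation = list(
    ec_prefix = "2.3.1.", sub_cof = c(accoa = 1), prod_cof = c(coa = 1))
)

.toy_sites <- function(g, type) {
  at <- g$atoms$atom_type
  switch(type,
    oxidation = which(at == "C.olc" & g$atoms$implicit_h >= 1 &
      vapply(seq_len(n_atoms(g)), function(i) {
        any(at[neighbors_of(g, i)] == "O.hyd")
      }, TRUE)),
    phosphorylation = which(at == "O.hyd" &
      vapply(seq_len(n_atoms(g)), function(i) {
        nb <- neighbors_of(g, i)
        length(nb) == 1 && g$atoms$element[nb] == "C"
      }, TRUE)),
    amination = which(at == "C.car"),
    decarboxylation = which(vapply(seq_len(n_atoms(g)), function(i) {
      # alpha carbon bearing a carboxyl branch (and keeping a carbon neighbor)
      if (g$atoms$element[i] != "C" || at[i] %in% c("C.cox", "C.car")) return(FALSE)
      nb <- neighbors_of(g, i)
      any(at[nb] == "C.cox") && sum(g$atoms$element[nb] == "C") >= 2
    }, TRUE)),
    acetylation = which(at == "N.am1" & g$atoms$implicit_h >= 2)
  )
}

.toy_transform <- function(g, type, site) {
  b <- g$bonds
  if (type == "oxidation") {
    nb <- neighbors_of(g, site)
    o <- nb[g$atoms$atom_type[nb] == "O.hyd"][1]
    hit <- (b$from == site & b$to == o) | (b$from == o & b$to == site)
    g$bonds$order[hit] <- 2
  } else if (type == "phosphorylation") {
    off <- n_atoms(g)
    g$atoms <- rbind(g$atoms, data.frame(
      element = c("P", "O", "O", "O"), charge = 0L,
      implicit_h = NA_integer_, atom_type = NA_character_))
    g$bonds <- rbind(g$bonds, data.frame(
      from = c(site, off + 1, off + 1, off + 1),
      to = c(off + 1, off + 2, off + 3, off + 4),
      order = c(1, 2, 1, 1)))
  } else if (type == "amination") {
    nb <- neighbors_of(g, site)
    o <- nb[g$atoms$atom_type[nb] == "O.car"][1]
    keep <- setdiff(seq_len(n_atoms(g)), o)
    site <- match(site, keep)
    g <- subgraph_of(g, keep)
    off <- n_atoms(g)
    g$atoms <- rbind(g$atoms, data.frame(
      element = "N", charge = 0L, implicit_h = NA_integer_,
      atom_type = NA_character_))
    g$bonds <- rbind(g$bonds, data.frame(from = site, to = off + 1, order = 1))
  } else if (type == "decarboxylation") {
    nb <- neighbors_of(g, site)
    cx <- nb[g$atoms$atom_type[nb] == "C.cox"][1]
    drop <- c(cx, neighbors_of(g, cx)[g$atoms$element[neighbors_of(g, cx)] == "O"])
    g <- subgraph_of(g, setdiff(seq_len(n_atoms(g)), drop))
  } else if (type == "acetylation") {
    off <- n_atoms(g)
    g$atoms <- rbind(g$atoms, data.frame(
      element = c("C", "O", "C"), charge = 0L,
      implicit_h = NA_integer_, atom_type = NA_character_))
    g$bonds <- rbind(g$bonds, data.frame(
      from = c(site, off + 1, off + 1), to = c(off + 1, off + 2, off + 3),
      order = c(1, 2, 1)))
  }
  rownames(g$atoms) <- NULL
  assign_atom_types(recompute_hydrogens(g))
}

# random decorated scaffold from the grammar
.toy_molecule <- function() {
  k <- sample(4:7, 1)
  ring <- k >= 5 && stats::runif(1) < 0.25
  bonds <- data.frame(from = seq_len(k - 1), to = 2:k, order = 1)
  if (ring) bonds <- rbind(bonds, data.frame(from = k, to = 1, order = 1))
  atoms <- data.frame(element = rep("C", k), charge = 0L,
                      implicit_h = NA_integer_, atom_type = NA_character_)
  g <- list(atoms = atoms, bonds = bonds)
  n_dec <- sample(1:3, 1)
  pos <- sample(seq_len(k), min(n_dec, k))
  for (p in pos) {
    dec <- sample(c("hydroxyl", "carbonyl", "carboxyl", "amino", "phosphate"), 1)
    off <- nrow(g$atoms)
    add_atoms <- switch(dec,
      hydroxyl = data.frame(element = "O"),
      carbonyl = data.frame(element = "O"),
      carboxyl = data.frame(element = c("C", "O", "O")),
      amino = data.frame(element = "N"),
      phosphate = data.frame(element = c("O", "P", "O", "O", "O")))
    add_atoms$charge <- 0L
    add_atoms$implicit_h <- NA_integer_
    add_atoms$atom_type <- NA_character_
    add_bonds <- switch(dec,
      hydroxyl = data.frame(from = p, to = off + 1, order = 1),
      carbonyl = data.frame(from = p, to = off + 1, order = 2),
      carboxyl = data.frame(from = c(p, off + 1, off + 1),
                            to = off + c(1, 2, 3), order = c(1, 2, 1)),
      amino = data.frame(from = p, to = off + 1, order = 1),
      phosphate = data.frame(from = c(p, off + 1, off + 2, off + 2, off + 2),
                             to = off + c(1, 2, 3, 4, 5),
                             order = c(1, 1, 2, 1, 1)))
    g2 <- list(atoms = rbind(g$atoms, add_atoms),
               bonds = rbind(g$bonds, add_bonds))
    ok <- tryCatch({
      recompute_hydrogens(structure(g2, class = "mol_graph")); TRUE
    }, error = function(e) FALSE)
    if (ok) g <- g2
  }
  assign_atom_types(recompute_hydrogens(structure(g, class = "mol_graph")))
}

#' Generate a synthetic test universe with planted promiscuity
#'
#' Deterministic under `seed`. Builds a metabolic model from the scaffold
#' grammar, extracts its operator table, replays operators on non-native
#' substrates to plant promiscuous products in the requested category mix,
#' and assembles the matching metabolome records, offline cross-reference
#' table, known-compound table, concentration table and reference index.
#' For a category-1 planting the parallel native route is added to the model
#' under a distinct gene, so the planted label follows from the reference
#' data alone.
#'
#' @param seed integer seed (single PRNG stream; global RNG state restored)
#' @param n_scaffolds number of seed metabolites drawn from the grammar
#' @param n_reactions number of native reactions
#' @param promiscuity_rate planted promiscuous products as a fraction of the
#'   `n_scaffolds * n_reactions` application opportunities (the default 0.2
#'   plants `round(0.2 * 10 * 10) = 20` products under the default sizes)
#' @param category_mix named numeric over C1..C4 summing to 1
#' @param threshold_uM concentration threshold the universe is built around
#' @return a `toy_universe`: list(model, conc, metabolome, xref, known,
#'   formulas, ref, planted, config)
#' @export
generate_toy_universe <- function(seed, n_scaffolds = 10, n_reactions = 10,
                                  promiscuity_rate = 0.2,
                                  category_mix = c(C1 = 0.25, C2 = 0.25,
                                                   C3 = 0.25, C4 = 0.25),
                                  threshold_uM = 1) {
  stopifnot(n_scaffolds > 0, n_reactions > 0, promiscuity_rate >= 0)
  if (abs(sum(category_mix) - 1) > 1e-8) stop("category_mix must sum to 1")
  mix <- stats::setNames(rep(0, 4), c("C1", "C2", "C3", "C4"))
  mix[names(category_mix)] <- category_mix

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  ## 1. scaffold metabolites
  structures <- list()
  keys <- character(0)
  tries <- 0
  while (length(structures) < n_scaffolds && tries < 50 * n_scaffolds) {
    tries <- tries + 1
    g <- .toy_molecule()
    k <- canonical_key(g)
    if (k %in% keys) next
    id <- sprintf("m%03d", length(structures) + 1L)
    structures[[id]] <- g
    keys <- c(keys, k)
  }

  ## 2. native reactions
  rxns <- list()
  add_reaction <- function(sub_id, prod_id, type, i, gene, ec) {
    spec <- .TOY_RXN_TYPES[[type]]
    st <- c(stats::setNames(-1, paste0(sub_id, "_c")),
            stats::setNames(1, paste0(prod_id, "_c")))
    if (length(spec$sub_cof)) st <- c(st, stats::setNames(
      -spec$sub_cof, paste0(names(spec$sub_cof), "_c")))
    if (length(spec$prod_cof)) st <- c(st, stats::setNames(
      spec$prod_cof, paste0(names(spec$prod_cof), "_c")))
    rxns[[length(rxns) + 1L]] <<- list(
      id = sprintf("RXN%03d", length(rxns) + 1L),
      ec = ec, genes = gene, kegg_reaction = sprintf("R9%04d", length(rxns) + 1L),
      reversible = stats::runif(1) > 0.2, stoich = st, type = type)
  }
  types <- rep(names(.TOY_RXN_TYPES), length.out = n_reactions)
  for (i in seq_len(n_reactions)) {
    type <- types[i]
    placed <- FALSE
    for (attempt in seq_len(40)) {
      sub_id <- sample(names(structures), 1)
      sites <- .toy_sites(structures[[sub_id]], type)
      if (!length(sites)) next
      site <- sites[sample(length(sites), 1)]
      prod <- tryCatch(.toy_transform(structures[[sub_id]], type, site),
                       error = function(e) NULL)
      if (is.null(prod)) next
      pk <- canonical_key(prod)
      if (identical(pk, keys[match(sub_id, names(structures))])) next
      prod_id <- if (pk %in% keys) names(structures)[match(pk, keys)] else {
        nid <- sprintf("m%03d", length(structures) + 1L)
        structures[[nid]] <- prod
        keys <- c(keys, pk)
        nid
      }
      dup <- any(vapply(rxns, function(r) {
        identical(names(r$stoich)[r$stoich < 0][1], paste0(sub_id, "_c")) &&
          identical(names(r$stoich)[r$stoich > 0][1], paste0(prod_id, "_c")) &&
          identical(r$type, type)
      }, TRUE))
      if (dup) next
      add_reaction(sub_id, prod_id, type, i,
                   gene = sprintf("g%03d", i), ec = paste0(.TOY_RXN_TYPES[[type]]$ec_prefix, 100 + i))
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  if (!length(rxns)) stop("could not place any native reaction")

  model <- .toy_model(structures, rxns)

  ## 3. operator table and candidate cross-applications
  ops <- build_operator_table(model)
  apps <- .cross_applications(ops, model)

  n_planted <- round(promiscuity_rate * n_scaffolds * n_reactions)
  want <- round(mix * n_planted)
  while (sum(want) < n_planted) want[which.max(mix)] <- want[which.max(mix)] + 1
  while (sum(want) > n_planted) want[which.max(want)] <- want[which.max(want)] - 1

  model_pairs <- .model_pair_table(model)

  ## planted products must be reachable from exactly one substrate across the
  ## whole application universe, so a metabolome hit pins down one reaction
  multi <- tapply(apps$substrate_key, apps$product_key,
                  function(s) length(unique(s)))
  unique_prod <- apps$product_key %in% names(multi)[multi == 1]

  is_c1 <- unique_prod & vapply(seq_len(nrow(apps)), function(i) {
    hit <- model_pairs$pair == pair_key(apps$substrate_key[i], apps$product_key[i])
    any(hit) && all(model_pairs$genes[hit] != apps$genes[i])
  }, TRUE)
  in_model_prod <- apps$product_key %in% keys
  eligible_c1 <- which(is_c1)
  eligible_new <- which(unique_prod & !in_model_prod &
    !(paste(apps$substrate_key, apps$product_key) %in%
        paste(model_pairs$sub, model_pairs$prod)))

  planted <- list()
  take <- function(pool, n) utils::head(pool, n)

  c1_direct <- take(eligible_c1, want[["C1"]])
  n_convert <- want[["C1"]] - length(c1_direct)
  needed_new <- n_convert + want[["C2"]] + want[["C3"]] + want[["C4"]]
  if (length(eligible_new) < needed_new) {
    stop("infeasible category mix: only ", length(eligible_new),
         " novel applications available, need ", needed_new)
  }
  pool_new <- eligible_new
  convert <- take(pool_new, n_convert); pool_new <- setdiff(pool_new, convert)

  ## C1 conversions: add the parallel native route under a fresh gene. The
  ## route's product enters the model structure-less (formula only), so it
  ## never spawns further applications of its own; its key and the pair are
  ## recorded directly in the reference index.
  extra_mets <- list()
  parallel_entries <- list()
  for (i in convert) {
    sub_id <- apps$parent[i]
    pk <- apps$product_key[i]
    prod_id <- sprintf("x%03d", length(extra_mets) + 1L)
    extra_mets[[prod_id]] <- format_formula(formula_of(apps$graph[[i]]))
    tmpl <- .op_template(ops$operators[[apps$op_idx[i]]], model)
    st <- c(stats::setNames(-1, paste0(sub_id, "_c")),
            stats::setNames(1, paste0(prod_id, "_c")))
    if (length(tmpl$sub_cofactors)) st <- c(st, stats::setNames(
      -tmpl$sub_cofactors, paste0(names(tmpl$sub_cofactors), "_c")))
    if (length(tmpl$prod_cofactors)) st <- c(st, stats::setNames(
      tmpl$prod_cofactors, paste0(names(tmpl$prod_cofactors), "_c")))
    # no KEGG annotation: the parallel route documents the pair in the model
    # without contributing an operator of its own
    gene <- sprintf("gp%02d", length(parallel_entries) + 1L)
    ec <- sprintf("5.9.9.%d", length(parallel_entries) + 1L)
    rxns[[length(rxns) + 1L]] <- list(
      id = sprintf("RXN%03d", length(rxns) + 1L),
      ec = ec, genes = gene, kegg_reaction = character(0),
      reversible = TRUE, stoich = st, type = "parallel")
    parallel_entries[[length(parallel_entries) + 1L]] <- data.frame(
      sub = apps$substrate_key[i], prod = pk,
      pair = pair_key(apps$substrate_key[i], pk),
      ec = ec, genes = gene,
      reaction_id = rxns[[length(rxns)]]$id, stringsAsFactors = FALSE)
  }
  if (n_convert > 0) {
    model <- .toy_model(structures, rxns, extra_mets)
    model_pairs <- rbind(.model_pair_table(model),
                         do.call(rbind, parallel_entries))
  }

  lab_of <- c(rep("C1", length(c1_direct) + length(convert)),
              rep("C2", want[["C2"]]), rep("C3", want[["C3"]]),
              rep("C4", want[["C4"]]))
  c2 <- take(pool_new, want[["C2"]]); pool_new <- setdiff(pool_new, c2)
  c3 <- take(pool_new, want[["C3"]]); pool_new <- setdiff(pool_new, c3)
  c4 <- take(pool_new, want[["C4"]])
  chosen <- c(c1_direct, convert, c2, c3, c4)

  planted <- if (length(chosen)) tibble::tibble(
    substrate = apps$parent[chosen],
    substrate_key = apps$substrate_key[chosen],
    product_key = apps$product_key[chosen],
    reaction_id = apps$reaction_id[chosen],
    ec = apps$ec[chosen], genes = apps$genes[chosen],
    label = lab_of,
    graph = apps$graph[chosen]
  ) else tibble::tibble(substrate = character(0), substrate_key = character(0),
                        product_key = character(0), reaction_id = character(0),
                        ec = character(0), genes = character(0),
                        label = character(0), graph = list())

  ## 4. metabolome + xref + known-compound table
  mk <- .toy_metabolome(planted, seed)

  ## 5. reference index
  org <- planted[planted$label == "C2", c("substrate_key", "product_key")]
  oth <- planted[planted$label == "C3", c("substrate_key", "product_key")]
  converted_keys <- apps$product_key[convert]
  ref <- reference_index(
    model_metabolite_keys = c(keys, converted_keys),
    model_reactions = data.frame(substrate = model_pairs$sub,
                                 product = model_pairs$prod,
                                 ec = model_pairs$ec, genes = model_pairs$genes),
    organism_reactions = if (nrow(org)) data.frame(
      substrate = org$substrate_key, product = org$product_key,
      equation_sig = NA_character_) else NULL,
    other_organism_reactions = if (nrow(oth)) data.frame(
      substrate = oth$substrate_key, product = oth$product_key) else NULL)

  ## 6. concentrations: substrates comfortably above threshold, a couple of
  ## metabolites below (the remainder pool)
  ids <- names(structures)
  conc <- stats::setNames(stats::runif(length(ids), 2, 50) * threshold_uM, ids)
  low <- utils::tail(setdiff(ids, planted$substrate), 2)
  conc[low] <- 0.4 * threshold_uM
  conc_tab <- tibble::tibble(metabolite_id = ids,
                             concentration_uM = unname(conc[ids]))

  formulas <- c(
    lapply(structures, function(g) formula_of(g)),
    lapply(.TOY_COFACTOR_FORMULAS, parse_formula))

  structure(list(model = model, conc = conc_tab, metabolome = mk$records,
                 xref = mk$xref, known = mk$known, formulas = formulas,
                 ref = ref, planted = planted,
                 config = list(seed = seed, n_scaffolds = n_scaffolds,
                               n_reactions = n_reactions,
                               promiscuity_rate = promiscuity_rate,
                               category_mix = mix,
                               threshold_uM = threshold_uM)),
            class = "toy_universe")
}

#' @export
print.toy_universe <- function(x, ...) {
  cat("toy_universe: seed", x$config$seed, "-", nrow(x$model$metabolites),
      "metabolites,", nrow(x$model$reactions), "reactions,",
      nrow(x$planted), "planted products\n")
  invisible(x)
}

.toy_model <- function(structures, rxns, extra_mets = list()) {
  ids <- names(structures)
  cof <- names(.TOY_COFACTOR_FORMULAS)
  xids <- names(extra_mets)
  mets <- data.frame(
    id = paste0(c(ids, cof, xids), "_c"),
    name = c(ids, cof, xids),
    compartment = "c",
    formula = c(vapply(structures, function(g) format_formula(formula_of(g)), ""),
                unname(.TOY_COFACTOR_FORMULAS),
                unlist(extra_mets, use.names = FALSE)),
    charge = 0L, stringsAsFactors = FALSE)
  model <- .assemble_model(mets, lapply(rxns, function(r) {
    r[c("id", "ec", "genes", "kegg_reaction", "reversible", "stoich")]
  }), vapply(rxns, `[[`, "", "genes"))
  model$structures <- structures
  validate_model(model)
}

.model_pair_table <- function(model) {
  keys <- vapply(model$structures, canonical_key, "")
  rows <- lapply(seq_len(nrow(model$reactions)), function(i) {
    rx <- model$reactions[i, ]
    st <- rx$stoich[[1]]
    subs <- strip_compartment(names(st)[st < 0])
    prods <- strip_compartment(names(st)[st > 0])
    main <- .main_pair(subs, prods, model$structures, default_cofactors())
    if (is.null(main)) return(NULL)
    data.frame(sub = keys[[main$sub]], prod = keys[[main$prod]],
               pair = pair_key(keys[[main$sub]], keys[[main$prod]]),
               ec = join_field(rx$ec[[1]]), genes = join_field(rx$genes[[1]]),
               reaction_id = rx$id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

# every (operator, non-native substrate, site) application, deduplicated on
# the (substrate, product) pair
.cross_applications <- function(ops, model) {
  keys <- vapply(model$structures, canonical_key, "")
  rows <- list()
  for (oi in seq_along(ops$operators)) {
    op <- ops$operators[[oi]]
    for (id in names(model$structures)) {
      g <- model$structures[[id]]
      pk <- keys[[id]]
      for (site in find_sites(op, g)) {
        res <- apply_operator(op, g, site)
        if (is.null(res)) next
        if (identical(res$key, pk)) next
        if (identical(op$origin$substrate_key, pk) &&
            identical(op$origin$product_key, res$key)) next  # native chemistry
        rows[[length(rows) + 1L]] <- list(
          op_idx = oi, parent = id, substrate_key = pk, product_key = res$key,
          reaction_id = op$provenance$reaction_id,
          ec = join_field(op$provenance$ec),
          genes = join_field(op$provenance$genes),
          graph = res$graph)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(op_idx = integer(0), parent = character(0),
                          substrate_key = character(0), product_key = character(0),
                          reaction_id = character(0), ec = character(0),
                          genes = character(0), graph = list()))
  }
  out <- tibble::tibble(
    op_idx = vapply(rows, `[[`, 1L, "op_idx"),
    parent = vapply(rows, `[[`, "", "parent"),
    substrate_key = vapply(rows, `[[`, "", "substrate_key"),
    product_key = vapply(rows, `[[`, "", "product_key"),
    reaction_id = vapply(rows, `[[`, "", "reaction_id"),
    ec = vapply(rows, `[[`, "", "ec"),
    genes = vapply(rows, `[[`, "", "genes"),
    graph = lapply(rows, `[[`, "graph"))
  out[!duplicated(paste(out$substrate_key, out$product_key)), , drop = FALSE]
}

.op_template <- function(op, model) {
  i <- match(op$provenance$reaction_id, model$reactions$id)
  reaction_template(model$reactions[i, ], default_cofactors(),
                    op$provenance$direction)
}

.toy_metabolome <- function(planted, seed) {
  uniq <- planted[!duplicated(planted$product_key), , drop = FALSE]
  n <- nrow(uniq)
  recs <- list(); xr <- list(); known <- character(0)
  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", 1000 + i)
    db <- sprintf("ECM%05d", i)
    f <- format_formula(formula_of(uniq$graph[[i]]))
    recs[[length(recs) + 1L]] <- data.frame(
      db_id = db, name = sprintf("derivative-%03d", i), formula = f,
      pubchem = pid, inchikey = sprintf("IK%05d", i),
      kegg = sprintf("C9%04d", i), cas = sprintf("50-%02d-%d", i %% 90 + 10, i %% 9),
      chebi = NA_character_, biocyc = NA_character_,
      structure_key = uniq$product_key[i], stringsAsFactors = FALSE)
    xr[[length(xr) + 1L]] <- data.frame(
      source = c("inchikey", "kegg", "cas"),
      id = c(sprintf("IK%05d", i), sprintf("C9%04d", i),
             sprintf("50-%02d-%d", i %% 90 + 10, i %% 9)),
      primary_id = pid, stringsAsFactors = FALSE)
    known[uniq$product_key[i]] <- pid
  }
  ## distractors: one fully consistent but unrelated record, one record whose
  ## votes conflict with no strict majority (stays unresolved)
  recs[[length(recs) + 1L]] <- data.frame(
    db_id = "ECM90001", name = "distractor-consistent", formula = "C6H12O6",
    pubchem = "P90001", inchikey = "IKD0001", kegg = "C99991",
    cas = NA_character_, chebi = NA_character_, biocyc = NA_character_,
    structure_key = "no-such-structure-1", stringsAsFactors = FALSE)
  xr[[length(xr) + 1L]] <- data.frame(
    source = c("inchikey", "kegg"), id = c("IKD0001", "C99991"),
    primary_id = "P90001", stringsAsFactors = FALSE)
  recs[[length(recs) + 1L]] <- data.frame(
    db_id = "ECM90002", name = "distractor-conflict", formula = "C7H14O7",
    pubchem = "P90002", inchikey = "IKD0002", kegg = "C99992",
    cas = NA_character_, chebi = NA_character_, biocyc = NA_character_,
    structure_key = "no-such-structure-2", stringsAsFactors = FALSE)
  xr[[length(xr) + 1L]] <- data.frame(
    source = c("inchikey", "kegg"), id = c("IKD0002", "C99992"),
    primary_id = c("P90003", "P90004"), stringsAsFactors = FALSE)
  list(records = tibble::as_tibble(do.call(rbind, recs)),
       xref = xref_table(do.call(rbind, xr)),
       known = known)
}
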