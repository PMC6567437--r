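options(emmr.verbose = FALSE)

## --- tiny structure builders -------------------------------------------

smi <- function(s) parse_structure(s, "smiles")

# permute the atoms of a mol_graph with a given permutation (new[i] = old p[i])
permute_atoms <- function(g, p) {
  inv <- match(seq_along(p), p)
  at <- g$atoms[p, , drop = FALSE]
  rownames(at) <- NULL
  bd <- g$bonds
  if (nrow(bd)) {
    bd$from <- inv[bd$from]
    bd$to <- inv[bd$to]
  }
  assign_atom_types(mol_graph(at, bd))
}

## --- brute-force MCS oracle (independent of map_atoms) -----------------
## exhaustive search over connected substrate subsets and all injective,
## element/bond-order-preserving (induced) embeddings into the product;
## tractable for graphs with <= 7 heavy atoms
oracle_mcs_size <- function(s, p) {
  ns <- nrow(s$atoms); np <- nrow(p$atoms)
  sb <- matrix(0, ns, ns); pb <- matrix(0, np, np)
  for (i in seq_len(nrow(s$bonds))) {
    b <- s$bonds[i, ]; sb[b$from, b$to] <- sb[b$to, b$from] <- b$order
  }
  for (i in seq_len(nrow(p$bonds))) {
    b <- p$bonds[i, ]; pb[b$from, b$to] <- pb[b$to, b$from] <- b$order
  }
  connected <- function(sub) {
    if (length(sub) <= 1) return(TRUE)
    seen <- sub[1]; repeat {
      nxt <- unique(c(seen, sub[sapply(sub, function(x)
        any(sb[x, seen] > 0))]))
      if (length(nxt) == length(seen)) break
      seen <- nxt
    }
    length(seen) == length(sub)
  }
  embeds <- function(sub) {
    k <- length(sub)
    rec <- function(i, used) {
      if (i > k) return(TRUE)
      a <- sub[i]
      for (b in setdiff(seq_len(np), used)) {
        if (s$atoms$element[a] != p$atoms$element[b]) next
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          if (sb[a, sub[j]] != pb[b, used[j]]) { ok <- FALSE; break }
        }
        if (ok && rec(i + 1, c(used, b))) return(TRUE)
      }
      FALSE
    }
    rec(1, integer(0))
  }
  best <- 0
  for (size in ns:1) {
    if (size <= best) break
    subs <- utils::combn(ns, size, simplify = FALSE)
    for (sub in subs) {
      if (!connected(sub)) next
      if (embeds(sub)) { best <- size; break }
    }
    if (best == size) break
  }
  best
}

## --- tiny model builders -----------------------------------------------

# write a BiGG-style JSON model + SMILES sidecar; returns list(model=, structures=)
write_tiny_model <- function(dir, metabolites, reactions, smiles = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  j <- list(
    metabolites = lapply(names(metabolites), function(id)
      list(id = id, name = metabolites[[id]], compartment = "c")),
    reactions = reactions,
    genes = list())
  mp <- file.path(dir, "model.json")
  jsonlite::write_json(j, mp, auto_unbox = TRUE)
  sp <- NULL
  if (!is.null(smiles)) {
    sp <- file.path(dir, "structures.tsv")
    utils::write.table(data.frame(id = names(smiles), smiles = unname(smiles)),
                       sp, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(model = mp, structures = sp)
}

bigg_reaction <- function(id, stoich, ec = "1.1.1.1", gene = "g001",
                          kegg = "R00001", reversible = TRUE) {
  list(id = id, metabolites = as.list(stoich),
       lower_bound = if (reversible) -1000 else 0, upper_bound = 1000,
       gene_reaction_rule = gene,
       annotation = list(`ec-code` = list(ec), `kegg.reaction` = list(kegg)))
}

# one reversible alcohol <-> ketone toy model (isopropanol/acetone)
alcohol_ketone_model <- function(dir, reversible = TRUE) {
  paths <- write_tiny_model(
    dir,
    metabolites = list(ipa_c = "isopropanol", act_c = "acetone",
                       nad_c = "nad", nadh_c = "nadh"),
    reactions = list(bigg_reaction(
      "ADH", c(ipa_c = -1, nad_c = -1, act_c = 1, nadh_c = 1),
      reversible = reversible)),
    smiles = c(ipa = "CC(C)O", act = "CC(=O)C"))
  load_model(paths$model, "bigg-json", paths$structures)
}
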