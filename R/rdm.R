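## RDM pattern extraction and the biotransformation operator table.
##
## A reactant-product pair is aligned by a connected maximum common
## substructure search (elements must match; bonds between mapped atoms must
## agree in presence and order on both sides). Mapped atoms adjacent to
## unmapped material are reaction centers (R). The local decomposition into
## R (reaction center), D (difference region: atoms adjacent to R that are
## removed or added) and M (matched region: atoms adjacent to R preserved by
## the change) gives the operator key (R + M types of the substrate) and
## value (R + D types of the product), together with an explicit graph-edit
## payload so the operator can be replayed on new molecules.

#' Align substrate and product atoms by maximum common substructure
#'
#' Finds a partial injective map from substrate atoms to product atoms that
#' maximizes the number of mapped atoms under the constraints that mapped
#' atoms share an element and that every bond between two mapped substrate
#' atoms is present with the same order between their images (and vice
#' versa), with the mapped region connected. Ties are broken toward more
#' exact atom-type matches, then toward the lexicographically smallest map
#' under canonical atom order, so the result is deterministic and invariant
#' to input atom ordering.
#'
#' @param substrate,product typed mol_graph
#' @param max_nodes search-node budget; the best mapping found within the
#'   budget is returned (exhaustive for desk-scale molecules)
#' @return list(map = integer vector over substrate atoms, NA where unmapped;
#'   lost = unmapped substrate indices; gained = unmapped product indices)
#' @export
map_atoms <- function(substrate, product, max_nodes = 2e5) {
  cs <- canonical_form(substrate)
  cp <- canonical_form(product)
  s <- cs$graph; p <- cp$graph
  ns <- n_atoms(s); np <- n_atoms(p)
  if (ns == 0L || np == 0L) {
    return(list(map = rep(NA_integer_, n_atoms(substrate)),
                lost = seq_len(n_atoms(substrate)),
                gained = seq_len(n_atoms(product))))
  }
  s_adj <- lapply(seq_len(ns), function(i) neighbors_of(s, i))
  p_adj <- lapply(seq_len(np), function(i) neighbors_of(p, i))
  s_bond <- matrix(0, ns, ns); p_bond <- matrix(0, np, np)
  for (i in seq_len(nrow(s$bonds))) {
    b <- s$bonds[i, ]; s_bond[b$from, b$to] <- s_bond[b$to, b$from] <- b$order
  }
  for (i in seq_len(nrow(p$bonds))) {
    b <- p$bonds[i, ]; p_bond[b$from, b$to] <- p_bond[b$to, b$from] <- b$order
  }

  best <- list(size = 0L, typematch = -1L, map = rep(NA_integer_, ns))
  nodes <- 0L

  score_better <- function(size, tm, map) {
    if (size != best$size) return(size > best$size)
    if (tm != best$typematch) return(tm > best$typematch)
    # lexicographically smallest mapping vector (NA sorts last)
    a <- ifelse(is.na(map), np + 1L, map)
    b <- ifelse(is.na(best$map), np + 1L, best$map)
    for (k in seq_len(ns)) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    FALSE
  }

  compatible <- function(a, b, map) {
    if (s$atoms$element[a] != p$atoms$element[b]) return(FALSE)
    mapped <- which(!is.na(map))
    for (m in mapped) {
      if (s_bond[a, m] != p_bond[b, map[m]]) return(FALSE)
    }
    TRUE
  }

  # Branch on each frontier atom: either map it to some compatible product
  # atom adjacent to the mapped image, or block it permanently. This explores
  # every connected common subgraph containing the seed pair exactly once.
  extend <- function(map, blocked, size, tm) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes) return(invisible(NULL))
    if (score_better(size, tm, map)) {
      best <<- list(size = size, typematch = tm, map = map)
    }
    mapped <- which(!is.na(map))
    cand_a <- sort(setdiff(unique(unlist(s_adj[mapped])), c(mapped, blocked)))
    if (!length(cand_a)) return(invisible(NULL))
    ub <- size + min(ns - size - length(blocked), np - size)
    if (ub < best$size) return(invisible(NULL))
    a <- cand_a[1]
    # b must sit adjacent to the image of a mapped neighbor of a
    anchors <- intersect(s_adj[[a]], mapped)
    cand_b <- sort(setdiff(unique(unlist(p_adj[map[anchors]])), map[mapped]))
    for (b in cand_b) {
      if (compatible(a, b, map)) {
        map2 <- map; map2[a] <- b
        extend(map2, blocked, size + 1L,
               tm + (s$atoms$atom_type[a] == p$atoms$atom_type[b]))
      }
    }
    extend(map, c(blocked, a), size, tm)
  }

  # seed pairs: same element; canonical order makes the search deterministic
  for (a in seq_len(ns)) {
    for (b in seq_len(np)) {
      if (s$atoms$element[a] == p$atoms$element[b]) {
        map0 <- rep(NA_integer_, ns)
        map0[a] <- b
        extend(map0, integer(0), 1L,
               as.integer(s$atoms$atom_type[a] == p$atoms$atom_type[b]))
      }
    }
  }

  # translate back to original atom orders
  map_orig <- rep(NA_integer_, n_atoms(substrate))
  for (k in seq_len(ns)) {
    if (!is.na(best$map[k])) map_orig[cs$perm[k]] <- cp$perm[best$map[k]]
  }
  list(map = map_orig,
       lost = which(is.na(map_orig)),
       gained = setdiff(seq_len(n_atoms(product)), stats::na.omit(map_orig)))
}

#' Extract RDM patterns from an aligned reactant-product pair
#'
#' Reaction centers are mapped atoms whose radius-1 neighborhood differs
#' between the two sides (an adjacent atom lost or gained). One pattern is
#' produced per center; a pair with more than one center is flagged
#' multi-center (such pairs yield no operator). Each pattern carries an
#' explicit graph-edit payload: the rooted fragment to delete at the center
#' and the rooted fragment to attach.
#'
#' @param substrate,product typed mol_graph
#' @param mapping result of [map_atoms()]
#' @return list with `patterns` (list of rdm_pattern), `multi_center`
#'   (logical) and `reason` (NA or a skip reason)
#' @export
extract_rdm <- function(substrate, product, mapping) {
  map <- mapping$map
  lost <- mapping$lost
  gained <- mapping$gained
  if (!length(lost) && !length(gained)) {
    return(list(patterns = list(), multi_center = FALSE, reason = "identical"))
  }
  if (all(is.na(map))) {
    return(list(patterns = list(), multi_center = FALSE, reason = "no common substructure"))
  }
  inv <- rep(NA_integer_, n_atoms(product))
  inv[stats::na.omit(map)] <- which(!is.na(map))

  centers <- integer(0)
  for (a in which(!is.na(map))) {
    lost_nb <- intersect(neighbors_of(substrate, a), lost)
    gained_nb <- intersect(neighbors_of(product, map[a]), gained)
    if (length(lost_nb) || length(gained_nb)) centers <- c(centers, a)
  }
  if (length(centers) == 0L) {
    return(list(patterns = list(), multi_center = FALSE, reason = "no center"))
  }
  if (length(centers) > 1L) {
    return(list(patterns = list(), multi_center = TRUE, reason = "multi-center"))
  }
  r <- centers
  rp <- map[r]
  # all unmapped material must hang off the single center
  ok_sub <- all(vapply(lost, function(u) {
    nb <- neighbors_of(substrate, u)
    all(nb %in% c(lost, r))
  }, TRUE))
  ok_prod <- all(vapply(gained, function(u) {
    nb <- neighbors_of(product, u)
    all(nb %in% c(gained, rp))
  }, TRUE))
  if (!ok_sub || !ok_prod) {
    return(list(patterns = list(), multi_center = FALSE,
                reason = "difference region not rooted at the center"))
  }
  lost_frag <- .rooted_fragment(substrate, r, lost)
  gained_frag <- .rooted_fragment(product, rp, gained)
  # every connected piece of the difference region must be bonded to the
  # center (a disconnected piece cannot be expressed as a local edit)
  rooted_ok <- function(frag) {
    comps <- .fragment_components(frag)
    all(vapply(comps, function(cm) nrow(cm$anchors) >= 1L, TRUE))
  }
  if (!rooted_ok(lost_frag) || !rooted_ok(gained_frag)) {
    return(list(patterns = list(), multi_center = FALSE,
                reason = "difference region not rooted at the center"))
  }
  pat <- structure(list(
    r_substrate = substrate$atoms$atom_type[r],
    r_product = product$atoms$atom_type[rp],
    d_substrate = sort(substrate$atoms$atom_type[intersect(neighbors_of(substrate, r), lost)]),
    d_product = sort(product$atoms$atom_type[intersect(neighbors_of(product, rp), gained)]),
    m = sort(substrate$atoms$atom_type[setdiff(neighbors_of(substrate, r), lost)]),
    site = r,
    product_site = rp,
    lost_fragment = lost_frag,
    gained_fragment = gained_frag
  ), class = "rdm_pattern")
  list(patterns = list(pat), multi_center = FALSE, reason = NA_character_)
}

# A fragment rooted at a center: the subgraph on `atoms`, plus the anchor
# bonds that tied it to the center (local fragment index + bond order).
# Implicit hydrogens are preserved from the parent molecule.
.rooted_fragment <- function(g, center, atoms) {
  if (!length(atoms)) {
    return(list(graph = mol_graph(data.frame(element = character(0)), NULL,
                                  compute_h = FALSE),
                anchors = data.frame(atom = integer(0), order = numeric(0)),
                key = "empty"))
  }
  sg <- subgraph_of(g, atoms)
  rownames(sg$atoms) <- NULL
  kept <- sort(unique(atoms))
  anchors <- do.call(rbind, lapply(seq_along(kept), function(k) {
    o <- bond_between(g, center, kept[k])
    if (o > 0) data.frame(atom = k, order = o) else NULL
  }))
  if (is.null(anchors)) anchors <- data.frame(atom = integer(0), order = numeric(0))
  key <- .fragment_key(sg, anchors)
  list(graph = sg, anchors = anchors, key = key)
}

# order-invariant identity of a rooted fragment: canonical key of the
# fragment with a pseudo-atom standing in for the reaction center
.fragment_key <- function(sg, anchors) {
  n <- n_atoms(sg)
  atoms <- rbind(sg$atoms,
                 data.frame(element = "*", charge = 0L, implicit_h = 0L,
                            atom_type = "*"))
  bonds <- rbind(sg$bonds,
                 if (nrow(anchors)) data.frame(from = anchors$atom, to = n + 1L,
                                               order = anchors$order))
  g2 <- structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
  canonical_key(g2)
}

#' Build the biotransformation operator lookup table from a model
#'
#' For every reaction carrying at least one KEGG reaction id and resolvable
#' structures, the designated main reactant-product pair (the non-cofactor
#' reactant and non-cofactor product sharing the largest common
#' substructure) is decomposed into an RDM pattern. Single-center patterns
#' become operators in the forward direction and, for reversible reactions,
#' the reverse direction as well. Cofactor-to-cofactor pairs and multi-center
#' pairs are skipped with a logged reason.
#'
#' @param model metabolic_model with structures
#' @param cofactors character vector of cofactor base ids (default:
#'   [default_cofactors()])
#' @param require_kegg skip reactions without a KEGG reaction id (default
#'   TRUE, mirroring lookup-table construction from KEGG-annotated reactions)
#' @return an `operator_table`: list with `operators` (list of rdm_operator)
#'   and `skipped` (tibble of reaction id + reason)
#' @export
build_operator_table <- function(model, cofactors = default_cofactors(),
                                 require_kegg = TRUE) {
  ops <- list()
  skipped <- list()
  skip <- function(id, why) skipped[[length(skipped) + 1L]] <<- data.frame(reaction = id, reason = why)
  for (i in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[i, ]
    kegg <- rx$kegg_reaction[[1]]
    if (require_kegg && !length(kegg)) { skip(rx$id, "no KEGG reaction id"); next }
    st <- rx$stoich[[1]]
    subs <- strip_compartment(names(st)[st < 0])
    prods <- strip_compartment(names(st)[st > 0])
    main <- .main_pair(subs, prods, model$structures, cofactors)
    if (is.null(main)) { skip(rx$id, "no structure-bearing non-cofactor pair"); next }
    sgraph <- model$structures[[main$sub]]
    pgraph <- model$structures[[main$prod]]
    mapping <- map_atoms(sgraph, pgraph)
    rdm <- extract_rdm(sgraph, pgraph, mapping)
    if (!length(rdm$patterns)) { skip(rx$id, rdm$reason %||% "no pattern"); next }
    pat <- rdm$patterns[[1]]
    dirs <- if (isTRUE(rx$reversible)) c("forward", "reverse") else "forward"
    for (dir in dirs) {
      op <- if (dir == "forward") {
        .make_operator(pat, sgraph, pgraph, main$sub, main$prod, rx, dir)
      } else {
        rev_map <- list(map = .invert_map(mapping$map, n_atoms(pgraph)),
                        lost = mapping$gained, gained = mapping$lost)
        rpat <- extract_rdm(pgraph, sgraph, rev_map)
        if (!length(rpat$patterns)) next
        .make_operator(rpat$patterns[[1]], pgraph, sgraph, main$prod, main$sub, rx, dir)
      }
      ops[[length(ops) + 1L]] <- op
    }
  }
  structure(list(
    operators = ops,
    skipped = if (length(skipped)) tibble::as_tibble(do.call(rbind, skipped))
              else tibble::tibble(reaction = character(0), reason = character(0))
  ), class = "operator_table")
}

.invert_map <- function(map, np) {
  inv <- rep(NA_integer_, np)
  inv[stats::na.omit(map)] <- which(!is.na(map))
  inv
}

.main_pair <- function(subs, prods, structures, cofactors) {
  subs <- setdiff(unique(subs), cofactors)
  prods <- setdiff(unique(prods), cofactors)
  subs <- subs[subs %in% names(structures)]
  prods <- prods[prods %in% names(structures)]
  if (!length(subs) || !length(prods)) return(NULL)
  if (length(subs) == 1L && length(prods) == 1L) {
    return(list(sub = subs, prod = prods))
  }
  best <- NULL; best_size <- -1L
  for (s in sort(subs)) {
    for (p in sort(prods)) {
      m <- map_atoms(structures[[s]], structures[[p]])
      sz <- sum(!is.na(m$map))
      if (sz > best_size) { best_size <- sz; best <- list(sub = s, prod = p) }
    }
  }
  best
}

.make_operator <- function(pat, sgraph, pgraph, sub_id, prod_id, rx, direction) {
  structure(list(
    key = list(r = pat$r_substrate, m = pat$m, d = pat$d_substrate),
    value = list(r = pat$r_product, d = pat$d_product),
    edit = list(lost = pat$lost_fragment, gained = pat$gained_fragment),
    provenance = list(
      ec = rx$ec[[1]], genes = rx$genes[[1]],
      kegg_reaction = rx$kegg_reaction[[1]],
      reaction_id = rx$id, direction = direction),
    origin = list(substrate_id = sub_id, product_id = prod_id,
                  substrate_key = canonical_key(sgraph),
                  product_key = canonical_key(pgraph),
                  site = pat$site)
  ), class = "rdm_operator")
}

#' @export
print.rdm_operator <- function(x, ...) {
  cat(sprintf("rdm_operator [%s] %s(%s|%s) -> %s(+%s)  {%s %s, %s}\n",
              x$provenance$direction,
              x$key$r, paste(x$key$m, collapse = ","), paste(x$key$d, collapse = ","),
              x$value$r, paste(x$value$d, collapse = ","),
              paste(x$provenance$ec, collapse = ";"),
              paste(x$provenance$genes, collapse = ";"),
              x$provenance$reaction_id))
  invisible(x)
}

#' @export
print.operator_table <- function(x, ...) {
  cat("operator_table:", length(x$operators), "operators,",
      nrow(x$skipped), "skipped reaction(s)\n")
  invisible(x)
}

#' The bundled default cofactor list
#'
#' Base ids of common cofactors and small inorganic species; used to pick
#' main reactant-product pairs, to flag cofactor substrates in curation, and
#' to identify template cofactor couples.
#'
#' @return character vector of base ids
#' @export
default_cofactors <- function() {
  c("nad", "nadh", "nadp", "nadph", "atp", "adp", "amp", "coa", "accoa",
    "thf", "fad", "fadh2", "pi", "ppi", "h2o", "h", "co2", "o2", "nh4", "nh3",
    "nad+", "nadp+", "acetyl-coa", "orthophosphate", "diphosphate", "ammonia",
    "h+")
}

#' Serialize an operator table to JSON
#' @param table operator_table
#' @param path output path
#' @export
write_operator_table <- function(table, path) {
  ser <- lapply(table$operators, function(op) {
    list(key = op$key, value = op$value,
         edit = list(
           lost = .ser_frag(op$edit$lost),
           gained = .ser_frag(op$edit$gained)),
         provenance = op$provenance, origin = op$origin)
  })
  jsonlite::write_json(list(operators = ser,
                            skipped = table$skipped),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

.ser_frag <- function(fr) {
  list(atoms = fr$graph$atoms, bonds = fr$graph$bonds, anchors = fr$anchors,
       key = fr$key)
}

#' Human-readable TSV summary of an operator table
#' @param table operator_table
#' @param path output path
#' @export
write_operator_summary <- function(table, path) {
  rows <- lapply(table$operators, function(op) {
    data.frame(
      reaction = op$provenance$reaction_id,
      ec = join_field(op$provenance$ec),
      genes = join_field(op$provenance$genes),
      kegg_reaction = join_field(op$provenance$kegg_reaction),
      direction = op$provenance$direction,
      key = sprintf("%s|M:%s|D:%s", op$key$r, paste(op$key$m, collapse = ","),
                    paste(op$key$d, collapse = ",")),
      value = sprintf("%s|D:%s", op$value$r, paste(op$value$d, collapse = ",")),
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
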