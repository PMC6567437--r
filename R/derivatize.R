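## Applying operators to metabolites: site search and graph-edit replay.

#' Find applicable sites of an operator on a molecule
#'
#' A site is an atom whose atom type equals the operator key's reaction
#' center type and whose radius-1 neighbor-type multiset contains both the
#' matched-region (M) and difference-region (D) types of the key. Sites that
#' are automorphic images of one another (equal rooted canonical keys) are
#' collapsed to one representative, the lowest index in canonical order.
#'
#' @param op rdm_operator
#' @param m typed mol_graph
#' @return integer vector of site atom indices (possibly empty)
#' @export
find_sites <- function(op, m) {
  n <- n_atoms(m)
  if (n == 0L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (!identical(m$atoms$atom_type[i], op$key$r)) next
    nb <- neighbors_of(m, i)
    nb_types <- m$atoms$atom_type[nb]
    if (!multiset_contains(nb_types, c(op$key$m, op$key$d))) next
    hits <- c(hits, i)
  }
  if (length(hits) <= 1L) return(hits)
  # collapse automorphic duplicates via rooted keys
  rkeys <- vapply(hits, function(i) canonical_key(m, root = i), "")
  hits[!duplicated(rkeys)]
}

#' Apply a biotransformation operator at a site
#'
#' Replays the operator's graph edit: the key's difference fragment is
#' located among the branches hanging off the site (the whole branch must be
#' isomorphic to the stored rooted fragment, so only the exact local
#' difference is ever excised) and deleted, then the value fragment is
#' attached at the site. Implicit hydrogens are rebalanced and the product
#' revalidated; a valence violation or unmatched difference fragment yields
#' NULL with a reason attribute.
#'
#' @param op rdm_operator
#' @param m typed mol_graph
#' @param site atom index from [find_sites()]
#' @return list(graph, key) or NULL (with attribute "reason") when the edit
#'   cannot be realized
#' @export
apply_operator <- function(op, m, site) {
  if (!identical(m$atoms$atom_type[site], op$key$r)) {
    return(.fail("site type does not match operator key"))
  }
  lost <- op$edit$lost
  comps <- .fragment_components(lost)
  # match each lost component to a distinct branch at the site
  assignment <- .match_components(m, site, comps)
  if (is.null(assignment)) return(.fail("no matching difference fragment at site"))
  del <- unlist(lapply(assignment, `[[`, "branch"))
  keep <- setdiff(seq_len(n_atoms(m)), del)
  site_new <- match(site, keep)
  g <- subgraph_of(m, keep)
  # attach gained fragment
  gained <- op$edit$gained
  ng <- n_atoms(gained$graph)
  if (ng > 0 && nrow(gained$anchors) == 0L) {
    return(.fail("gained fragment has no anchor to the site"))
  }
  if (ng > 0) {
    off <- n_atoms(g)
    g$atoms <- rbind(g$atoms, gained$graph$atoms)
    add <- gained$graph$bonds
    if (nrow(add)) { add$from <- add$from + off; add$to <- add$to + off }
    anch <- gained$anchors
    anchor_bonds <- data.frame(from = anch$atom + off, to = site_new,
                               order = anch$order)
    g$bonds <- rbind(g$bonds, add, anchor_bonds)
  }
  g2 <- tryCatch(recompute_hydrogens(g), error = function(e) e)
  if (inherits(g2, "error")) return(.fail(conditionMessage(g2)))
  g2 <- assign_atom_types(g2)
  list(graph = g2, key = canonical_key(g2), site = site)
}

# applications that cannot be realized return NULL; the reason is logged
# when option emmr.verbose_apply is set
.fail <- function(reason) {
  emmr_log("operator application skipped: ", reason,
           verbose = getOption("emmr.verbose_apply", FALSE))
  NULL
}

# split a rooted fragment into connected components, each with its anchors
.fragment_components <- function(frag) {
  g <- frag$graph
  n <- n_atoms(g)
  if (n == 0L) return(list())
  left <- seq_len(n)
  comps <- list()
  while (length(left)) {
    comp <- component_of(g, left[1])
    sub <- subgraph_of(g, comp)
    anch <- frag$anchors[frag$anchors$atom %in% comp, , drop = FALSE]
    anch$atom <- match(anch$atom, comp)
    comps[[length(comps) + 1L]] <- list(graph = sub, anchors = anch,
                                        key = .fragment_key(sub, anch))
    left <- setdiff(left, comp)
  }
  comps
}

# match lost components to disjoint branches hanging off `site`; branches are
# compared by rooted fragment key (exact isomorphism of the whole branch)
.match_components <- function(m, site, comps) {
  if (!length(comps)) return(list())
  nb <- neighbors_of(m, site)
  branch_of <- function(n0) {
    br <- component_of(m, n0, banned = site)
    if (any(vapply(br, function(x) x != n0 && bond_between(m, site, x) > 0, TRUE))) {
      return(NULL)  # branch loops back to the site (ring): not a simple edit
    }
    br
  }
  cand <- list()
  for (n0 in nb) {
    br <- branch_of(n0)
    if (is.null(br)) next
    sub <- subgraph_of(m, br)
    anch <- data.frame(atom = match(n0, br), order = bond_between(m, site, n0))
    cand[[as.character(n0)]] <- list(branch = br, root = n0,
                                     key = .fragment_key(sub, anch))
  }
  assign_rec <- function(ci, used) {
    if (ci > length(comps)) return(list())
    want <- comps[[ci]]$key
    for (nm in names(cand)) {
      c0 <- cand[[nm]]
      if (c0$root %in% used) next
      if (!identical(c0$key, want)) next
      rest <- assign_rec(ci + 1L, c(used, c0$branch))
      if (!is.null(rest)) return(c(list(c0), rest))
    }
    NULL
  }
  assign_rec(1L, integer(0))
}

#' Enumerate putative derivative products over a substrate pool
#'
#' Applies every operator of the table to every pool metabolite at every
#' matching site. Products identical to the parent are dropped (logged);
#' products already present in the model are kept but flagged; products whose
#' provenance reaction itself contains the parent-to-product pair are flagged
#' self-transformations (native chemistry rediscovered, not a new
#' prediction). Results are deduplicated on (parent, product key, provenance)
#' and ordered deterministically.
#'
#' @param table operator_table
#' @param model metabolic_model providing pool structures and model keys
#' @param pool character vector of base metabolite ids to derivatize
#' @param known named character vector mapping product canonical keys to
#'   external ids of known compounds (optional)
#' @return tibble of predicted derivatives with provenance and flags; product
#'   graphs in the `graph` list-column
#' @export
enumerate_derivatives <- function(table, model, pool, known = character(0)) {
  model_keys <- vapply(model$structures, canonical_key, "")
  rows <- list()
  for (parent in sort(pool)) {
    g <- model$structures[[parent]]
    if (is.null(g)) next
    parent_key <- canonical_key(g)
    for (op in table$operators) {
      sites <- find_sites(op, g)
      for (site in sites) {
        res <- apply_operator(op, g, site)
        if (is.null(res)) next
        if (identical(res$key, parent_key)) next  # no-op edit
        self_tr <- identical(op$origin$substrate_key, parent_key) &&
          identical(op$origin$product_key, res$key)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          parent = parent,
          parent_key = parent_key,
          ec = join_field(op$provenance$ec),
          genes = join_field(op$provenance$genes),
          kegg_reaction = join_field(op$provenance$kegg_reaction),
          reaction_id = op$provenance$reaction_id,
          direction = op$provenance$direction,
          site = site,
          product_key = res$key,
          known_id = if (res$key %in% names(known)) known[[res$key]] else NA_character_,
          already_in_model = res$key %in% model_keys,
          self_transformation = self_tr,
          graph = list(res$graph))
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(parent = character(0), parent_key = character(0),
                          ec = character(0), genes = character(0),
                          kegg_reaction = character(0), reaction_id = character(0),
                          direction = character(0), site = integer(0),
                          product_key = character(0), known_id = character(0),
                          already_in_model = logical(0),
                          self_transformation = logical(0), graph = list()))
  }
  out <- do.call(rbind, rows)
  dedup_key <- paste(out$parent, out$product_key, out$ec, out$genes,
                     out$kegg_reaction, out$direction)
  out <- out[!duplicated(dedup_key), , drop = FALSE]
  out[order(out$parent, out$product_key, out$ec, out$direction), , drop = FALSE]
}

#' Write a derivative report as TSV (and product structures as SDF)
#'
#' @param derivs tibble from [enumerate_derivatives()]
#' @param path TSV output path
#' @param sdf_path optional SDF path for the (deduplicated) product structures
#' @export
write_derivative_report <- function(derivs, path, sdf_path = NULL) {
  tab <- derivs[, setdiff(names(derivs), "graph")]
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sdf_path) && nrow(derivs)) {
    uniq <- derivs[!duplicated(derivs$product_key), ]
    graphs <- stats::setNames(uniq$graph, paste0("derivative_", seq_len(nrow(uniq))))
    write_sdf(graphs, sdf_path)
  }
  invisible(path)
}
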