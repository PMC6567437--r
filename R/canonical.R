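## Canonical structure keys.
##
## Identity convention: molecular constitution plus bond orders; stereo is
## ignored everywhere. The key is computed by exact canonical labeling
## (igraph's BLISS backend) of a colored expansion of the molecular graph in
## which every bond becomes an auxiliary vertex colored by its order -- BLISS
## colors vertices only, so bond orders are carried by these vertices. Two
## graphs receive the same key iff they are isomorphic under the convention.

.atom_label <- function(g, i, root = integer(0)) {
  paste0(g$atoms$element[i], ",", g$atoms$charge[i], ",", g$atoms$implicit_h[i],
         if (i %in% root) ",root" else "")
}

.expanded_graph <- function(g, root = integer(0)) {
  n <- n_atoms(g)
  m <- nrow(g$bonds)
  alabs <- vapply(seq_len(n), function(i) .atom_label(g, i, root), "")
  blabs <- if (m) paste0("bond:", g$bonds$order) else character(0)
  labs <- c(alabs, blabs)
  pal <- sort(unique(labs))
  colors <- match(labs, pal)
  edges <- integer(0)
  if (m) {
    bv <- n + seq_len(m)
    edges <- c(t(cbind(g$bonds$from, bv, g$bonds$to, bv)))
  }
  ig <- igraph::make_empty_graph(n = n + m, directed = FALSE)
  if (length(edges)) ig <- igraph::add_edges(ig, edges)
  list(graph = ig, colors = colors, n = n)
}

#' Canonical ranks of atoms (1 = first in canonical order)
#' @noRd
canonical_ranks <- function(g, root = integer(0)) {
  n <- n_atoms(g)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  ex <- .expanded_graph(g, root)
  lab <- igraph::canonical_permutation(ex$graph, colors = ex$colors - 1L)$labeling
  rank(lab[seq_len(n)])
}

#' Canonical structure key of a molecular graph
#'
#' Order-invariant string identifier for a molecular constitution (elements,
#' charges, implicit hydrogens and bond orders; stereochemistry ignored).
#' With `root`, the given atom is distinguished, yielding a rooted key: two
#' sites of one molecule are automorphic exactly when their rooted keys are
#' equal.
#'
#' @param g mol_graph
#' @param root optional atom index to distinguish
#' @return a string; `"empty"` for the empty graph
#' @export
canonical_key <- function(g, root = NULL) {
  n <- n_atoms(g)
  if (n == 0L) return("empty")
  root <- if (is.null(root)) integer(0) else as.integer(root)
  rk <- canonical_ranks(g, root)
  ord <- order(rk)
  atom_str <- vapply(ord, function(i) .atom_label(g, i, root), "")
  bonds <- g$bonds
  bond_str <- character(0)
  if (nrow(bonds)) {
    a <- rk[bonds$from]; b <- rk[bonds$to]
    lo <- pmin(a, b); hi <- pmax(a, b)
    bond_str <- paste0(lo, "-", hi, ":", bonds$order)
    bond_str <- bond_str[order(lo, hi)]
  }
  paste0(format_formula(formula_of(g)), "|",
         paste(atom_str, collapse = ";"), "|",
         paste(bond_str, collapse = ";"))
}

#' Relabel a graph's atoms into canonical order
#'
#' Used to make downstream searches (atom mapping, site enumeration)
#' independent of the input atom ordering.
#'
#' @param g mol_graph
#' @return list(graph = relabeled mol_graph, perm = integer vector mapping
#'   new index -> original index)
#' @export
canonical_form <- function(g) {
  n <- n_atoms(g)
  if (n == 0L) return(list(graph = g, perm = integer(0)))
  rk <- canonical_ranks(g)
  perm <- order(rk)  # perm[new] = old
  inv <- match(seq_len(n), perm)  # inv[old] = new
  atoms <- g$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds$from <- inv[bonds$from]
    bonds$to <- inv[bonds$to]
    lo <- pmin(bonds$from, bonds$to); hi <- pmax(bonds$from, bonds$to)
    bonds$from <- lo; bonds$to <- hi
    bonds <- bonds[order(lo, hi), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  list(graph = structure(list(atoms = atoms, bonds = bonds), class = "mol_graph"),
       perm = perm)
}
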