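## Molecular graphs: atoms with implicit hydrogens, bonds with orders.
##
## A mol_graph is the substrate of every transformation in the package.
## Hydrogens are implicit throughout: they are recomputed from a small
## valence model whenever the heavy-atom skeleton changes, so a graph edit
## never has to book-keep hydrogen atoms explicitly. Aromatic bonds carry
## order 1.5.

# default valences used to derive implicit hydrogen counts; S and P pick the
# smallest valence state in the list that accommodates the bond order sum
.VALENCES <- list(
  C = 4, N = 3, O = 2, S = c(2, 4, 6), P = c(3, 5),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

#' Construct a molecular graph
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer, default 0). Columns `implicit_h` and `atom_type` are filled by
#'   [recompute_hydrogens()] / [assign_atom_types()].
#' @param bonds data.frame with columns `from`, `to` (atom indices) and
#'   `order` (1, 2, 3 or 1.5 for aromatic). May have zero rows.
#' @param compute_h recompute implicit hydrogens from the valence model
#'   (default TRUE). Set FALSE when atoms already carry trusted counts.
#' @return an object of class `mol_graph`
#' @export
mol_graph <- function(atoms, bonds = NULL, compute_h = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot("element" %in% names(atoms))
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, n)
  atoms$charge <- as.integer(atoms$charge)
  if (is.null(atoms$implicit_h)) atoms$implicit_h <- rep(NA_integer_, n)
  if (is.null(atoms$atom_type)) atoms$atom_type <- rep(NA_character_, n)
  atoms <- atoms[, c("element", "charge", "implicit_h", "atom_type")]
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(from = integer(0), to = integer(0), order = numeric(0))
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to", "order") %in% names(bonds)))
    bonds <- bonds[, c("from", "to", "order")]
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    bonds$order <- as.numeric(bonds$order)
  }
  if (nrow(bonds)) {
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n)) {
      stop("bond endpoint out of range")
    }
    if (any(bonds$from == bonds$to)) stop("self-bond not allowed")
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key)) stop("duplicate bond")
    if (!all(bonds$order %in% c(1, 2, 3, 1.5))) stop("bad bond order")
  }
  g <- structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
  if (compute_h) g <- recompute_hydrogens(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  f <- formula_of(x)
  cat("mol_graph:", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds; ",
      format_formula(f), "\n")
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

#' Bond order sum per atom (aromatic bonds count 1.5, sum rounded)
#' @noRd
bond_order_sums <- function(g) {
  bs <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      bs[b$from] <- bs[b$from] + b$order
      bs[b$to] <- bs[b$to] + b$order
    }
  }
  round(bs)
}

#' Recompute implicit hydrogen counts from the valence model
#'
#' Effective valence is charge-adjusted: +1 on N/P raises it by one, -1 on
#' O/S/C/halogen lowers it by one. A bond order sum exceeding the highest
#' accessible valence is a valence violation and errors, naming the atom.
#'
#' @param g mol_graph
#' @return g with `implicit_h` filled
#' @export
recompute_hydrogens <- function(g) {
  bs <- bond_order_sums(g)
  n <- n_atoms(g)
  h <- integer(n)
  for (i in seq_len(n)) {
    el <- g$atoms$element[i]
    ch <- g$atoms$charge[i]
    vals <- .VALENCES[[el]]
    if (is.null(vals)) { h[i] <- 0L; next }  # elements outside the scheme
    adj <- if (el %in% c("N", "P")) ch else if (el %in% c("O", "S", "C", "F", "Cl", "Br", "I")) -abs(ch) else 0L
    vals <- vals + adj
    v <- vals[vals >= bs[i]]
    if (length(v) == 0L) {
      stop(sprintf("valence violation at atom %d (%s, bond order sum %d)",
                   i, el, bs[i]))
    }
    h[i] <- as.integer(min(v) - bs[i])
  }
  g$atoms$implicit_h <- h
  g
}

#' Neighbor indices of an atom
#' @noRd
neighbors_of <- function(g, i) {
  b <- g$bonds
  c(b$to[b$from == i], b$from[b$to == i])
}

#' Order of the bond between two atoms, or 0 when absent
#' @noRd
bond_between <- function(g, i, j) {
  b <- g$bonds
  hit <- (b$from == i & b$to == j) | (b$from == j & b$to == i)
  if (any(hit)) b$order[hit][1] else 0
}

#' Elemental formula of a molecular graph
#'
#' Heavy atoms are counted from the atom table; hydrogen from the implicit
#' counts; net charge is the sum of formal charges.
#'
#' @param g typed or untyped mol_graph
#' @return named integer vector of element counts with a `charge` attribute
#' @export
formula_of <- function(g) {
  counts <- table(g$atoms$element)
  out <- stats::setNames(as.integer(counts), names(counts))
  hs <- sum(g$atoms$implicit_h) + sum(g$atoms$element == "H")
  # explicit H rows (rare; normally collapsed on parse) are merged
  out <- out[names(out) != "H"]
  if (hs > 0) out <- c(out, H = as.integer(hs))
  ord <- c(intersect(c("C", "H"), names(out)), sort(setdiff(names(out), c("C", "H"))))
  out <- out[ord]
  attr(out, "charge") <- sum(g$atoms$charge)
  out
}

#' Induced subgraph on a set of atoms
#'
#' Bonds are kept when both endpoints are retained; implicit hydrogen counts
#' are preserved from the parent graph (not recomputed), so fragment atoms
#' remember their saturation in context.
#' @noRd
subgraph_of <- function(g, keep) {
  keep <- sort(unique(keep))
  idx <- match(seq_len(n_atoms(g)), keep)
  b <- g$bonds[g$bonds$from %in% keep & g$bonds$to %in% keep, , drop = FALSE]
  if (nrow(b)) {
    b$from <- idx[b$from]
    b$to <- idx[b$to]
  }
  structure(list(atoms = g$atoms[keep, , drop = FALSE], bonds = b),
            class = "mol_graph")
}

#' Connected component containing a given atom
#' @noRd
component_of <- function(g, start, banned = integer(0)) {
  seen <- start
  queue <- start
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- setdiff(neighbors_of(g, cur), c(seen, banned))
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  sort(seen)
}
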