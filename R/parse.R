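## Structure parsing and writing.
##
## Molfiles (MDL V2000) are read through ChemmineR; SMILES strings are first
## converted to SDF by Open Babel (ChemmineOB) and then read the same way.
## ChemmineR does not surface "M  CHG" property lines, so formal charges are
## taken from the old-style atom-block charge column it exposes and, when
## present, overridden by a scan of the raw "M  CHG" lines (which supersede
## the atom block per the format). Explicit hydrogens are collapsed into
## implicit counts on parse; Kekule rings are normalized to aromatic bond
## order 1.5 by a small perception step.

.OLD_CHARGE <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "5" = -1L, "6" = -2L, "7" = -3L)

#' Parse a chemical structure into a molecular graph
#'
#' @param text a SMILES string, or the text of an MDL molfile (V2000)
#' @param format `"smiles"` or `"molfile"`
#' @param aromatize perceive aromatic rings and normalize Kekule forms
#'   (default TRUE)
#' @return a typed [mol_graph] (atom types assigned, hydrogens implicit,
#'   aromaticity perceived)
#' @export
parse_structure <- function(text, format = c("smiles", "molfile"), aromatize = TRUE) {
  format <- match.arg(format)
  if (format == "smiles") {
    text <- .smiles_to_molfile(text)
  }
  g <- .parse_molfile_text(text)
  g <- collapse_explicit_h(g)
  g <- recompute_hydrogens(g)
  if (aromatize) g <- perceive_aromaticity(g)
  assign_atom_types(g)
}

.smiles_to_molfile <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) stop("unparsable SMILES: ", smiles, " (", conditionMessage(e), ")")
  )
  if (!nzchar(out) || !grepl("V2000", out)) stop("unparsable SMILES: ", smiles)
  out
}

.parse_molfile_text <- function(text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  txt <- sub("\\s+$", "", text)
  if (!grepl("\\$\\$\\$\\$", txt)) txt <- paste0(txt, "\n$$$$")
  writeLines(txt, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  counts <- .molfile_counts(text)
  if (length(elements) != counts$natoms ||
      !all(grepl("^[A-Za-z]", elements))) {
    # upstream parser mishandles degenerate (e.g. single-atom) records;
    # fall back to positional parsing of the V2000 block
    return(.parse_v2000_text(text))
  }
  n <- length(elements)
  charge <- rep(0L, n)
  if ("C5" %in% colnames(ab)) {
    oc <- as.character(ab[, "C5"])
    charge <- unname(.OLD_CHARGE[oc])
    charge[is.na(charge)] <- 0L
  }
  # M  CHG lines supersede the atom-block column
  chg_lines <- grep("^M  CHG", strsplit(text, "\n")[[1]], value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0L, n)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", ln)), "\\s+")[[1]])
      if (length(f) >= 2) {
        idx <- f[seq(1, length(f), by = 2)]
        val <- f[seq(2, length(f), by = 2)]
        charge[idx] <- val
      }
    }
  }
  bonds <- NULL
  if (!is.null(bb) && !is.matrix(bb)) bb <- rbind(bb)  # single-bond records
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    ord <- as.numeric(bb[, 3])
    ord[ord == 4] <- 1.5
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = ord)
  }
  mol_graph(data.frame(element = elements, charge = charge,
                       stringsAsFactors = FALSE),
            bonds, compute_h = FALSE)
}

.molfile_counts <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  cl <- grep("V2000", lines, value = TRUE)[1]
  list(natoms = as.integer(substr(cl, 1, 3)),
       nbonds = as.integer(substr(cl, 4, 6)))
}

.parse_v2000_text <- function(text) {
  lines <- strsplit(text, "\n")[[1]]
  ci <- grep("V2000", lines)[1]
  counts <- .molfile_counts(text)
  atom_lines <- lines[ci + seq_len(counts$natoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  old <- trimws(substr(atom_lines, 37, 39))
  charge <- unname(.OLD_CHARGE[old])
  charge[is.na(charge)] <- 0L
  bonds <- NULL
  if (counts$nbonds > 0) {
    bond_lines <- lines[ci + counts$natoms + seq_len(counts$nbonds)]
    ord <- as.numeric(substr(bond_lines, 7, 9))
    ord[ord == 4] <- 1.5
    bonds <- data.frame(from = as.integer(substr(bond_lines, 1, 3)),
                        to = as.integer(substr(bond_lines, 4, 6)),
                        order = ord)
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) charge <- rep(0L, counts$natoms)
  for (ln in chg_lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+[0-9]+", "", ln)), "\\s+")[[1]])
    if (length(f) >= 2) {
      charge[f[seq(1, length(f), by = 2)]] <- f[seq(2, length(f), by = 2)]
    }
  }
  mol_graph(data.frame(element = elements, charge = charge,
                       stringsAsFactors = FALSE), bonds, compute_h = FALSE)
}

#' Collapse explicit hydrogen atoms into implicit counts
#' @noRd
collapse_explicit_h <- function(g) {
  hs <- which(g$atoms$element == "H")
  if (!length(hs)) return(g)
  keep <- setdiff(seq_len(n_atoms(g)), hs)
  if (!length(keep)) return(g)  # H2 and friends: keep as-is
  subgraph_of(g, keep)
}

#' Perceive aromatic rings and normalize Kekule input
#'
#' Simple 5- and 6-membered rings whose ring bonds alternate appropriately
#' (three ring double bonds in a 6-ring; two in a 5-ring whose remaining
#' atom is a heteroatom or carbanion) are rewritten with aromatic bond order
#' 1.5. Implicit hydrogens are preserved from the Kekule form, so
#' pyrrole-type NH survives perception.
#'
#' @param g mol_graph
#' @return g with aromatic bonds set to order 1.5
#' @export
perceive_aromaticity <- function(g) {
  if (!nrow(g$bonds)) return(g)
  rings <- .find_small_rings(g, max_size = 6L)
  for (ring in rings) {
    k <- length(ring)
    # ring bonds in cycle order
    pairs <- cbind(ring, c(ring[-1], ring[1]))
    orders <- apply(pairs, 1, function(p) bond_between(g, p[1], p[2]))
    if (any(orders == 1.5)) next  # already aromatic
    ndbl <- sum(orders == 2)
    ok <- FALSE
    if (k == 6L && ndbl == 3L && all(orders %in% c(1, 2))) {
      # alternating single/double
      ok <- all(abs(diff(c(orders, orders[1]))) == 1)
    } else if (k == 5L && ndbl == 2L && all(orders %in% c(1, 2))) {
      sp3 <- ring[!apply(pairs, 1, function(p) any(orders[pairs[, 1] == p[1] | pairs[, 2] == p[1]] == 2))]
      # the lone non-double atom must donate a lone pair: heteroatom only
      lone <- ring[vapply(seq_along(ring), function(i) {
        inc <- orders[c(i, if (i == 1) k else i - 1)]
        all(inc == 1)
      }, TRUE)]
      ok <- length(lone) == 1L && g$atoms$element[lone] %in% c("N", "O", "S")
    }
    if (ok) {
      for (r in seq_len(k)) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        hit <- (g$bonds$from == i & g$bonds$to == j) | (g$bonds$from == j & g$bonds$to == i)
        g$bonds$order[hit] <- 1.5
      }
    }
  }
  g
}

# enumerate simple cycles of size <= max_size (each once, as vertex sequences)
.find_small_rings <- function(g, max_size = 6L) {
  rings <- list()
  seen <- character(0)
  n <- n_atoms(g)
  adj <- lapply(seq_len(n), function(i) neighbors_of(g, i))
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < max_size && nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  rings
}

#' Write a molecular graph as an MDL V2000 molfile
#'
#' Coordinates are zero (connectivity only); charges are written both in the
#' atom block (old-style) and as `M  CHG` lines; aromatic bonds as type 4.
#'
#' @param g mol_graph
#' @param title molecule title (first line; metabolite id by convention)
#' @return molfile text
#' @export
write_molfile <- function(g, title = "") {
  n <- n_atoms(g)
  m <- nrow(g$bonds)
  old <- vapply(g$atoms$charge, function(ch) {
    names(.OLD_CHARGE)[match(ch, .OLD_CHARGE)] %||% "0"
  }, "")
  lines <- c(
    title, "  emmr", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    vapply(seq_len(n), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0%3s  0  0  0  0  0  0  0  0  0  0",
              0, 0, 0, g$atoms$element[i], old[i])
    }, ""),
    if (m) vapply(seq_len(m), function(i) {
      o <- g$bonds$order[i]
      sprintf("%3d%3d%3d  0  0  0  0", g$bonds$from[i], g$bonds$to[i],
              if (o == 1.5) 4L else as.integer(o))
    }, "")
  )
  chg <- which(g$atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, g$atoms$charge[grp]),
                                      collapse = "")))
    }
  }
  paste(c(lines, "M  END"), collapse = "\n")
}

#' Write a named list of molecular graphs as an SDF file
#'
#' Record titles are the list names (metabolite ids), so the file doubles as
#' a structure sidecar readable by [read_structures()].
#'
#' @param graphs named list of mol_graph
#' @param path output path
#' @export
write_sdf <- function(graphs, path) {
  stopifnot(!is.null(names(graphs)), all(nzchar(names(graphs))))
  txt <- vapply(names(graphs), function(id) {
    paste0(write_molfile(graphs[[id]], title = id), "\n$$$$")
  }, "")
  writeLines(txt, path)
  invisible(path)
}
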