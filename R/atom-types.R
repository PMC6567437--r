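## KEGG-style atom typing.
##
## Each heavy atom gets a short code describing its element class and its
## radius-1 environment (incident bond orders + neighbor elements + its own
## formal charge). The vocabulary is the package's own self-contained stand-in
## for the KEGG atom-type table: operator keys only need consistent,
## discriminating local labels. The full code list with descriptions is
## shipped in inst/extdata/atom_types.tsv.

#' Assign atom types to every atom of a molecular graph
#'
#' Typing is a pure function of the atom's element, formal charge and
#' radius-1 bonded neighborhood (incident bond orders, including the aromatic
#' flag, and neighbor elements). A non-zero formal charge is appended to the
#' code as a `+`/`-` suffix. Elements outside the supported set
#' (C, N, O, S, P, halogens, H) are typed as generic `X<element>`.
#'
#' @param g a parsed mol_graph (aromaticity already perceived)
#' @return g with the `atom_type` column filled
#' @export
assign_atom_types <- function(g) {
  n <- n_atoms(g)
  types <- character(n)
  for (i in seq_len(n)) {
    types[i] <- .type_one_atom(g, i)
  }
  g$atoms$atom_type <- types
  g
}

.type_one_atom <- function(g, i) {
  el <- g$atoms$element[i]
  ch <- g$atoms$charge[i]
  b <- g$bonds
  inc <- which(b$from == i | b$to == i)
  nb_idx <- ifelse(b$from[inc] == i, b$to[inc], b$from[inc])
  nb_el <- g$atoms$element[nb_idx]
  ord <- b$order[inc]
  aromatic <- any(ord == 1.5)
  dbl_to <- nb_el[ord == 2]
  trp_to <- nb_el[ord == 3]
  sgl_to <- nb_el[ord == 1]
  het <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")

  code <- if (el == "C") {
    if (aromatic) "C.ar"
    else if (length(trp_to) && any(trp_to == "N")) "C.ntr"
    else if (length(trp_to)) "C.yne"
    else if (any(dbl_to == "O") && any(sgl_to == "O")) "C.cox"
    else if (any(dbl_to == "O") && any(sgl_to == "N")) "C.amd"
    else if (any(dbl_to == "O")) "C.car"
    else if (any(dbl_to == "C")) "C.ene"
    else if (any(dbl_to == "N")) "C.imn"
    else if (any(dbl_to == "S")) "C.tho"
    else {
      nhet <- sum(sgl_to %in% het)
      if (nhet >= 2) "C.het"
      else if (nhet == 0) "C.alk"
      else if (any(sgl_to == "O")) "C.olc"
      else if (any(sgl_to == "N")) "C.nlc"
      else if (any(sgl_to == "S")) "C.slc"
      else "C.hal"
    }
  } else if (el == "O") {
    deg <- length(nb_idx)
    if (aromatic) "O.ar"
    else if (length(dbl_to) && any(dbl_to == "C")) "O.car"
    else if (length(dbl_to) && any(dbl_to == "P")) "O.pd"
    else if (length(dbl_to) && any(dbl_to == "S")) "O.sd"
    else if (length(dbl_to)) "O.d"
    else if (deg >= 2 && any(nb_el == "P")) "O.pho"
    else if (deg >= 2) "O.eth"
    else if (deg == 1 && nb_el[1] == "P") "O.pt"
    else "O.hyd"
  } else if (el == "N") {
    if (aromatic) "N.ar"
    else if (length(trp_to)) "N.ntr"
    else if (length(dbl_to)) "N.imn"
    else switch(as.character(length(nb_idx)),
                "0" = "N.am0", "1" = "N.am1", "2" = "N.am2", "N.am3")
  } else if (el == "S") {
    if (aromatic) "S.ar"
    else if (any(dbl_to == "O")) "S.oxo"
    else if (length(nb_idx) <= 1) "S.thl"
    else "S.thi"
  } else if (el == "P") {
    if (any(nb_el == "O")) "P.pho" else "P.phn"
  } else if (el %in% c("F", "Cl", "Br", "I")) {
    el
  } else if (el == "H") {
    "H"
  } else {
    paste0("X", el)
  }

  if (ch > 0) paste0(code, strrep("+", min(ch, 3))) else if (ch < 0) paste0(code, strrep("-", min(-ch, 3))) else code
}

#' The atom-type vocabulary
#'
#' Reads the package's typing table (code, element class, description) from
#' `inst/extdata/atom_types.tsv`.
#'
#' @return data.frame with columns `code`, `element`, `description`
#' @export
atom_type_table <- function() {
  utils::read.delim(system.file("extdata", "atom_types.tsv", package = "emmr"),
                    stringsAsFactors = FALSE)
}
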