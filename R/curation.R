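## Curation of predicted transformations into balanced reactions and their
## classification into the four evidence categories.
##
## Category semantics (decision tree):
##   C1 -- parallel route: the substrate/product pair is already documented
##         (in the model, or for the organism in the reference databases)
##         but under a different enzyme than the one whose operator produced
##         the prediction.
##   C2 -- curation gap: the predicted reaction itself (same transformation,
##         equation-level where the reference records one) is documented for
##         the organism but absent from the model.
##   C3 -- the transformation is documented only in other organisms.
##   C4 -- the transformation is not catalogued anywhere.
##   A prediction whose pair exists in the model under the same enzyme is
##   discarded as already-in-model.

#' Construct a candidate reaction
#'
#' @param substrate,product base ids (compartment-free)
#' @param ec,genes,kegg_reaction provenance of the operator that produced the
#'   prediction (character vectors; at least one of ec/genes non-empty)
#' @param substrate_key,product_key canonical keys or curated ids used for
#'   reference lookups (default: the ids themselves)
#' @param feasible externally supplied chemical-feasibility flag (stands in
#'   for manual review; default TRUE)
#' @param multi_center TRUE when the originating pattern had more than one
#'   reaction center
#' @param substrate_is_cofactor TRUE when the substrate is on the cofactor
#'   list
#' @return a `candidate_reaction`
#' @export
candidate_reaction <- function(substrate, product, ec = character(0),
                               genes = character(0), kegg_reaction = character(0),
                               substrate_key = substrate, product_key = product,
                               feasible = TRUE, multi_center = FALSE,
                               substrate_is_cofactor = FALSE) {
  if (!length(ec) && !length(genes)) stop("candidate needs provenance (ec or genes)")
  structure(list(substrate = substrate, product = product,
                 substrate_key = substrate_key, product_key = product_key,
                 ec = ec, genes = genes, kegg_reaction = kegg_reaction,
                 feasible = isTRUE(feasible), multi_center = isTRUE(multi_center),
                 substrate_is_cofactor = isTRUE(substrate_is_cofactor),
                 equation_sig = NA_character_),
            class = "candidate_reaction")
}

#' Apply the discard filters to a candidate
#'
#' Filters, in fixed order: chemically infeasible; substrate is a cofactor;
#' multi-center pattern. The first matching reason wins.
#'
#' @param c candidate_reaction
#' @return `"keep"` or `"DISCARD(<reason>)"`
#' @export
apply_discard_filters <- function(c) {
  if (!c$feasible) return("DISCARD(infeasible)")
  if (c$substrate_is_cofactor) return("DISCARD(cofactor)")
  if (c$multi_center) return("DISCARD(multi-center)")
  "keep"
}

#' Complete a substrate/product pair into a stoichiometric reaction
#'
#' Copies the cofactor couple(s) of the template reaction (the operator's
#' native reaction) onto the candidate pair, side for side: template
#' cofactors consumed with the native substrate are consumed with the
#' candidate substrate, and symmetrically for products. Template coefficients
#' are preserved. Without a template the bare pair is emitted flagged
#' uncompleted.
#'
#' @param substrate,product candidate base ids
#' @param template list with named numeric vectors `sub_cofactors` and
#'   `prod_cofactors` (coefficients positive), or NULL
#' @param ec,genes provenance carried onto the curated reaction
#' @return a `curated_reaction`: stoichiometric map (negative = substrate
#'   side), provenance, direction and completion flag
#' @export
complete_reaction <- function(substrate, product, template = NULL,
                              ec = character(0), genes = character(0)) {
  stoich <- stats::setNames(c(-1, 1), c(substrate, product))
  completed <- FALSE
  if (!is.null(template)) {
    sc <- template$sub_cofactors %||% numeric(0)
    pc <- template$prod_cofactors %||% numeric(0)
    for (nm in names(sc)) stoich[nm] <- (stoich[nm] %||% 0) - sc[[nm]]
    for (nm in names(pc)) stoich[nm] <- (stoich[nm] %||% 0) + pc[[nm]]
    stoich <- stoich[stoich != 0]
    completed <- TRUE
  }
  structure(list(stoich = stoich, ec = ec, genes = genes,
                 direction = "reversible", completed = completed),
            class = "curated_reaction")
}

#' Extract the cofactor couple of a model reaction as a completion template
#'
#' @param reaction one row of a model's reactions tibble
#' @param cofactors cofactor base-id list
#' @param direction `"forward"` uses the reaction as written; `"reverse"`
#'   swaps sides (for operators extracted in the reverse direction)
#' @return template list for [complete_reaction()]
#' @export
reaction_template <- function(reaction, cofactors = default_cofactors(),
                              direction = "forward") {
  st <- reaction$stoich[[1]]
  ids <- strip_compartment(names(st))
  is_cof <- ids %in% cofactors
  sub <- st[st < 0 & is_cof]; prod <- st[st > 0 & is_cof]
  sub <- stats::setNames(-as.numeric(sub), strip_compartment(names(sub)))
  prod <- stats::setNames(as.numeric(prod), strip_compartment(names(prod)))
  if (identical(direction, "reverse")) {
    tmp <- sub; sub <- prod; prod <- tmp
  }
  list(sub_cofactors = sub, prod_cofactors = prod)
}

#' @export
print.curated_reaction <- function(x, ...) {
  cat(format_equation(x), "\n")
  invisible(x)
}

#' Format a curated reaction as a human-readable equation
#' @param r curated_reaction
#' @return string like `"A + 2 B <=> C + D"`
#' @export
format_equation <- function(r) {
  lhs <- r$stoich[r$stoich < 0]; rhs <- r$stoich[r$stoich > 0]
  fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                  paste(abs(v), names(v))), collapse = " + ")
  paste(fmt(lhs), "<=>", fmt(rhs))
}

#' Check the elemental balance of a curated reaction
#'
#' Reports the signed per-element delta (product side minus substrate side).
#' The reaction is balanced when every heavy-atom (non-hydrogen) delta is
#' zero; hydrogen and charge deltas are reported separately. With
#' `tolerate_h = TRUE`, a residual imbalance explainable by H+ and/or H2O
#' alone (an O surplus matched by 2H per O, plus free protons) is absorbed by
#' auto-adding those species, and the additions are reported.
#'
#' @param r curated_reaction
#' @param formulas named list of element-count vectors (from
#'   [parse_formula()]), keyed by metabolite id
#' @param tolerate_h absorb H/charge imbalance with H+/H2O (default FALSE)
#' @return list(balanced, deltas (named numeric, heavy elements),
#'   h_delta, charge_delta, added (named numeric))
#' @export
check_balance <- function(r, formulas, tolerate_h = FALSE) {
  total <- numeric(0)
  charge <- 0
  for (nm in names(r$stoich)) {
    f <- formulas[[nm]]
    if (is.null(f)) stop("no formula for metabolite: ", nm)
    coef <- r$stoich[[nm]]
    for (el in names(f)) total[el] <- (total[el] %||% 0) + coef * f[[el]]
    charge <- charge + coef * (attr(f, "charge") %||% 0L)
  }
  total <- total[!is.na(total)]
  h_delta <- if ("H" %in% names(total)) total[["H"]] else 0
  heavy <- total[setdiff(names(total), "H")]
  heavy <- heavy[heavy != 0]
  added <- numeric(0)
  if (tolerate_h && length(heavy) == 1L && names(heavy) == "O") {
    # absorb an oxygen surplus with water on the deficient side
    added["h2o"] <- -heavy[["O"]]
    h_delta <- h_delta - 2 * heavy[["O"]]
    heavy <- numeric(0)
  }
  if (tolerate_h && h_delta != 0) {
    added["h+"] <- -h_delta
    charge <- charge - h_delta
    h_delta <- 0
  }
  list(balanced = length(heavy) == 0L,
       deltas = heavy, h_delta = h_delta, charge_delta = charge,
       added = added)
}

#' Build a reference index for classification
#'
#' @param model_metabolite_keys keys/ids of metabolites present in the model
#' @param model_reactions data.frame (substrate, product, ec, genes):
#'   pair-level model reactions with their enzymes
#' @param organism_reactions data.frame (substrate, product, optional
#'   equation_sig): transformations documented for the organism (KEGG/EcoCyc
#'   emulation); `equation_sig` NA means the pair is documented without a
#'   recorded equation
#' @param other_organism_reactions data.frame (substrate, product)
#' @return a `reference_index`
#' @export
reference_index <- function(model_metabolite_keys = character(0),
                            model_reactions = NULL,
                            organism_reactions = NULL,
                            other_organism_reactions = NULL) {
  empty_rx <- data.frame(substrate = character(0), product = character(0),
                         ec = character(0), genes = character(0),
                         stringsAsFactors = FALSE)
  empty_org <- data.frame(substrate = character(0), product = character(0),
                          equation_sig = character(0), stringsAsFactors = FALSE)
  fix <- function(df, tmpl) {
    if (is.null(df) || nrow(df) == 0L) return(tmpl)
    for (col in names(tmpl)) if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[, names(tmpl), drop = FALSE]
  }
  structure(list(
    model_metabolite_keys = unique(model_metabolite_keys),
    model_reactions = fix(model_reactions, empty_rx),
    organism_reactions = fix(organism_reactions, empty_org),
    other_organism_reactions = fix(other_organism_reactions,
                                   empty_org[, 1:2])
  ), class = "reference_index")
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Direction-agnostic equation signature
#'
#' Sorted participant ids (with coefficients) on each side, sides themselves
#' sorted, so that a reaction and its reverse share one signature.
#'
#' @param lhs,rhs named numeric vectors of coefficients (or character vectors
#'   of ids with implicit coefficient 1)
#' @return string signature
#' @export
equation_sig <- function(lhs, rhs) {
  fmt <- function(v) {
    if (is.character(v)) v <- stats::setNames(rep(1, length(v)), v)
    paste(sort(paste0(abs(v), "*", names(v))), collapse = "+")
  }
  sides <- sort(c(fmt(lhs), fmt(rhs)))
  paste(sides, collapse = "=")
}

curated_equation_sig <- function(r) {
  equation_sig(r$stoich[r$stoich < 0], r$stoich[r$stoich > 0])
}

# do two provenance descriptions denote the same enzyme? Gene sets are
# compared when both are known; otherwise EC numbers.
same_enzyme <- function(genes1, ec1, genes2, ec2) {
  g1 <- split_field(join_field(genes1)); g2 <- split_field(join_field(genes2))
  if (length(g1) && length(g2)) return(length(intersect(g1, g2)) > 0)
  e1 <- split_field(join_field(ec1)); e2 <- split_field(join_field(ec2))
  if (length(e1) && length(e2)) return(length(intersect(e1, e2)) > 0)
  FALSE
}

#' Classify a kept candidate into an evidence category
#'
#' Decision tree: (1) a product already in the model leads to C1 when the
#' model documents the same substrate/product pair under a different enzyme,
#' and to DISCARD(already-in-model) under the same enzyme; (2) otherwise a
#' candidate whose transformation is documented for the organism is C2 when
#' the documented record matches at the equation level (or records no
#' equation), and C1 (parallel route) when only the pair matches; (3) a pair
#' documented in other organisms is C3; (4) anything else is C4.
#'
#' @param c candidate_reaction (with `equation_sig` set when available)
#' @param ref reference_index
#' @return one of `"C1"`, `"C2"`, `"C3"`, `"C4"`,
#'   `"DISCARD(already-in-model)"`
#' @export
classify <- function(c, ref) {
  pk <- pair_key(c$substrate_key, c$product_key)
  mr <- ref$model_reactions
  if (c$product_key %in% ref$model_metabolite_keys && nrow(mr)) {
    hit <- pair_key(mr$substrate, mr$product) == pk
    if (any(hit)) {
      rows <- mr[hit, , drop = FALSE]
      same <- vapply(seq_len(nrow(rows)), function(i) {
        same_enzyme(c$genes, c$ec,
                    split_field(rows$genes[i]), split_field(rows$ec[i]))
      }, TRUE)
      return(if (any(same)) "DISCARD(already-in-model)" else "C1")
    }
  }
  org <- ref$organism_reactions
  if (nrow(org)) {
    hit <- pair_key(org$substrate, org$product) == pk
    if (any(hit)) {
      sigs <- org$equation_sig[hit]
      eq_match <- is.na(sigs) |
        (!is.na(c$equation_sig) & sigs == c$equation_sig)
      if (any(eq_match)) return("C2")
      return("C1")  # pair documented, equation differs: parallel route
    }
  }
  oth <- ref$other_organism_reactions
  if (nrow(oth) && pk %in% pair_key(oth$substrate, oth$product)) return("C3")
  "C4"
}

#' Filter, classify and summarize a candidate set
#'
#' Runs the discard filters and the decision tree over all candidates and
#' tallies the outcome: per-category counts and reaction lists, discard
#' reasons, and the distinct new-to-model metabolites contributed by C2-C4
#' reactions (C1 adds none: both partners already exist).
#'
#' @param candidates list of candidate_reaction
#' @param ref reference_index
#' @return list(table = tibble with label per candidate, counts = named
#'   integer vector over C1..C4, discarded = named integer vector by reason,
#'   new_metabolites = character vector)
#' @export
summarize_categories <- function(candidates, ref) {
  lab <- vapply(candidates, function(c) {
    d <- apply_discard_filters(c)
    if (d != "keep") d else classify(c, ref)
  }, "")
  tab <- tibble::tibble(
    substrate = vapply(candidates, `[[`, "", "substrate"),
    product = vapply(candidates, `[[`, "", "product"),
    ec = vapply(candidates, function(c) join_field(c$ec), ""),
    genes = vapply(candidates, function(c) join_field(c$genes), ""),
    label = lab)
  counts <- stats::setNames(vapply(c("C1", "C2", "C3", "C4"),
                                   function(k) sum(lab == k), 1L),
                            c("C1", "C2", "C3", "C4"))
  disc <- lab[startsWith(lab, "DISCARD")]
  new_mets <- unique(tab$product[tab$label %in% c("C2", "C3", "C4")])
  new_keys <- vapply(candidates, `[[`, "", "product_key")[match(new_mets, tab$product)]
  new_mets <- new_mets[!(new_keys %in% ref$model_metabolite_keys)]
  list(table = tab, counts = counts,
       discarded = if (length(disc)) table(disc) else
         stats::setNames(integer(0), character(0)),
       new_metabolites = sort(new_mets))
}
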