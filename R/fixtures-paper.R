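## The transcribed 23-reaction curated example set.
##
## A hand-transcription of a published curation of promiscuity predictions
## for E. coli iML1515: 23 candidate reactions with their enzymes, completed
## cofactor equations, molecular formulas for every participant, and the
## reference-database membership attributes asserted for each candidate
## (model membership, organism-level documentation in KEGG/EcoCyc, and
## other-organism documentation). Membership attributes are encoded exactly
## as asserted by the source curation -- not re-derived from live databases --
## so the decision-tree example is fully self-contained.

.fixture_path <- function(file) {
  system.file("extdata", "paper_fixture", file, package = "emmr")
}

#' Load the transcribed 23-reaction curated fixture
#'
#' @return list with:
#'   * `candidates`: list of [candidate_reaction()] (equation signatures set),
#'   * `reactions`: named list of `curated_reaction` (the completed equations),
#'   * `ref`: [reference_index()] with the asserted membership attributes,
#'   * `formulas`: named list of element-count vectors for all participants,
#'   * `groups`: named character vector candidate id -> curated evidence group
#' @export
load_paper_fixture <- function() {
  rd <- function(f) utils::read.delim(.fixture_path(f), stringsAsFactors = FALSE,
                                      colClasses = "character", na.strings = "")
  cand_tab <- rd("candidates.tsv")
  eq_tab <- rd("equations.tsv")
  eq_tab$coeff <- as.numeric(eq_tab$coeff)
  form_tab <- rd("formulas.tsv")
  formulas <- stats::setNames(
    lapply(seq_len(nrow(form_tab)), function(i) {
      parse_formula(form_tab$formula[i], as.integer(form_tab$charge[i]))
    }), form_tab$species)

  reactions <- list()
  sigs <- character(0)
  for (cid in cand_tab$candidate_id) {
    rows <- eq_tab[eq_tab$candidate_id == cid, , drop = FALSE]
    st <- stats::setNames(ifelse(rows$side == "S", -rows$coeff, rows$coeff),
                          rows$species)
    cand <- cand_tab[cand_tab$candidate_id == cid, ]
    reactions[[cid]] <- structure(
      list(stoich = st, ec = split_field(cand$ec),
           genes = split_field(cand$genes %||% ""),
           direction = "reversible", completed = TRUE),
      class = "curated_reaction")
    sigs[cid] <- curated_equation_sig(reactions[[cid]])
  }

  candidates <- lapply(seq_len(nrow(cand_tab)), function(i) {
    r <- cand_tab[i, ]
    c0 <- candidate_reaction(
      substrate = r$substrate, product = r$product,
      ec = split_field(r$ec), genes = split_field(r$genes %||% ""))
    c0$equation_sig <- sigs[[r$candidate_id]]
    c0
  })
  names(candidates) <- cand_tab$candidate_id

  org <- rd("organism_reactions.tsv")
  org$equation_sig <- ifelse(is.na(org$equation_of), NA_character_,
                             sigs[org$equation_of])
  ref <- reference_index(
    model_metabolite_keys = rd("model_metabolites.tsv")$species,
    model_reactions = rd("model_reactions.tsv"),
    organism_reactions = org[, c("substrate", "product", "equation_sig")],
    other_organism_reactions = rd("other_organism_reactions.tsv")[, c("substrate", "product")]
  )
  list(candidates = candidates, reactions = reactions, ref = ref,
       formulas = formulas,
       groups = stats::setNames(cand_tab$group, cand_tab$candidate_id))
}
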