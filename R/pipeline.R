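## End-to-end orchestration: operators -> derivatives -> metabolome matching
## -> curation -> classification, with diff-stable reports and a
## machine-readable run summary.

#' Write a toy universe to disk in the pipeline's input formats
#'
#' The bundle doubles as format documentation: BiGG-style JSON model, SDF
#' structure sidecar, and TSV tables for concentrations, metabolome, xrefs,
#' known compounds, formulas and the reference index.
#'
#' @param u toy_universe
#' @param dir output directory (created)
#' @return dir, invisibly
#' @export
write_universe <- function(u, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_model(u$model, p("model.json"))
  write_sdf(u$model$structures, p("structures.sdf"))
  wt(u$conc, "concentrations.tsv")
  wt(u$metabolome, "metabolome.tsv")
  xr <- do.call(rbind, strsplit(names(u$xref$map), "\r", fixed = TRUE))
  wt(data.frame(source = xr[, 1], id = xr[, 2], primary_id = unname(u$xref$map)),
     "xref.tsv")
  wt(data.frame(key = names(u$known), id = unname(u$known)), "known_compounds.tsv")
  wt(data.frame(id = names(u$formulas),
                formula = vapply(u$formulas, format_formula, ""),
                charge = vapply(u$formulas, function(f) attr(f, "charge") %||% 0L, 0L)),
     "formulas.tsv")
  wt(data.frame(key = u$ref$model_metabolite_keys), "ref_model_metabolites.tsv")
  wt(u$ref$model_reactions, "ref_model_reactions.tsv")
  wt(u$ref$organism_reactions, "ref_organism_reactions.tsv")
  wt(u$ref$other_organism_reactions, "ref_other_organism_reactions.tsv")
  wt(as.data.frame(u$planted[, setdiff(names(u$planted), "graph")]), "planted.tsv")
  jsonlite::write_json(u$config, p("config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a reference index from its TSV bundle
#'
#' @param dir directory holding `ref_model_metabolites.tsv`,
#'   `ref_model_reactions.tsv`, `ref_organism_reactions.tsv`,
#'   `ref_other_organism_reactions.tsv`
#' @return reference_index
#' @export
read_reference_index <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) return(NULL)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = "NA")
    if (nrow(tab) == 0L) NULL else tab
  }
  mets <- rd("ref_model_metabolites.tsv")
  reference_index(
    model_metabolite_keys = if (is.null(mets)) character(0) else mets$key,
    model_reactions = rd("ref_model_reactions.tsv"),
    organism_reactions = rd("ref_organism_reactions.tsv"),
    other_organism_reactions = rd("ref_other_organism_reactions.tsv"))
}

#' Assemble a run configuration
#'
#' @param dir a universe directory as written by [write_universe()]; the
#'   standard file names are filled in
#' @param outdir report directory
#' @param threshold_uM concentration cut for the high pool (default 1)
#' @param include_remainder also derivatize the non-high-concentration pool
#' @param tolerate_h allow H+/H2O absorption in balance checks
#' @return named list config for [run_pipeline()]
#' @export
run_config <- function(dir, outdir, threshold_uM = 1,
                       include_remainder = FALSE, tolerate_h = FALSE) {
  p <- function(f) file.path(dir, f)
  cfg <- list(model = p("model.json"), model_format = "bigg-json",
              structures = p("structures.sdf"),
              concentrations = p("concentrations.tsv"),
              metabolome = p("metabolome.tsv"), xref = p("xref.tsv"),
              known = p("known_compounds.tsv"), formulas = p("formulas.tsv"),
              reference_dir = dir, outdir = outdir,
              threshold_uM = threshold_uM,
              include_remainder = include_remainder, tolerate_h = tolerate_h)
  for (f in c("model", "structures", "concentrations", "metabolome",
              "xref", "known", "formulas")) {
    if (!file.exists(cfg[[f]])) stop("config error: missing input ", cfg[[f]])
  }
  cfg
}

#' Run the full prediction-to-classification pipeline
#'
#' Executes the three workflow stages -- operator extraction and derivative
#' prediction, metabolome comparison, and curation/classification -- and
#' writes the operator table, derivative report, match report, curated
#' reactions, category report and a machine-readable run summary with counts
#' at every stage. Reports are sorted for diff-stable output; reruns on the
#' same inputs are byte-identical.
#'
#' @param cfg configuration list from [run_config()] (or hand-built with the
#'   same fields)
#' @return the run summary list, invisibly; artifacts under `cfg$outdir`
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)

  ## Stage 1: operators and derivatives
  model <- load_model(cfg$model, cfg$model_format %||% "bigg-json",
                      structures = cfg$structures)
  conc <- read_concentrations(cfg$concentrations)
  pool <- select_substrate_pool(model, conc, cfg$threshold_uM %||% 1)
  use_pool <- pool$high
  if (isTRUE(cfg$include_remainder)) use_pool <- c(use_pool, pool$remainder)
  cofactors <- if (!is.null(cfg$cofactors)) {
    utils::read.delim(cfg$cofactors, stringsAsFactors = FALSE)$id
  } else default_cofactors()
  ops <- build_operator_table(model, cofactors)
  write_operator_table(ops, out("operator_table.json"))
  write_operator_summary(ops, out("operator_summary.tsv"))
  known_tab <- utils::read.delim(cfg$known, stringsAsFactors = FALSE,
                                 colClasses = "character")
  known <- stats::setNames(known_tab$id, known_tab$key)
  derivs <- enumerate_derivatives(ops, model, use_pool, known)
  new_preds <- derivs[!derivs$self_transformation, , drop = FALSE]
  write_derivative_report(new_preds, out("derivatives.tsv"),
                          out("derivatives.sdf"))

  ## Stage 2: metabolome comparison
  records <- reconcile_metabolome(read_metabolome(cfg$metabolome),
                                  read_xref_table(cfg$xref))
  matched <- match_derivatives(new_preds, records)
  utils::write.table(as.data.frame(matched[, setdiff(names(matched), "graph")]),
                     out("matches.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## Stage 3: curation and classification
  formula_tab <- utils::read.delim(cfg$formulas, stringsAsFactors = FALSE)
  formulas <- stats::setNames(
    lapply(seq_len(nrow(formula_tab)), function(i) {
      parse_formula(formula_tab$formula[i], formula_tab$charge[i] %||% 0L)
    }), formula_tab$id)
  rec_form <- records[!is.na(records$formula), , drop = FALSE]
  for (i in seq_len(nrow(rec_form))) {
    if (is.null(formulas[[rec_form$db_id[i]]])) {
      formulas[[rec_form$db_id[i]]] <- parse_formula(rec_form$formula[i])
    }
  }
  feas <- if (!is.null(cfg$feasibility)) {
    f <- utils::read.delim(cfg$feasibility, stringsAsFactors = FALSE)
    stats::setNames(as.logical(f$feasible), paste(f$substrate, f$product))
  } else character(0)

  ## one candidate reaction per verified (substrate, product) pair; when
  ## several operators predict the same pair the first (in report order)
  ## supplies the provenance and template
  pairs <- paste(matched$parent_key, matched$product_key)
  cand_rows <- matched[!duplicated(pairs), , drop = FALSE]

  candidates <- list()
  curated <- list()
  balance <- list()
  for (i in seq_len(nrow(cand_rows))) {
    row <- cand_rows[i, ]
    fkey <- paste(row$parent, row$matched_db_id)
    cand <- candidate_reaction(
      substrate = row$parent, product = row$matched_db_id,
      ec = split_field(row$ec), genes = split_field(row$genes),
      kegg_reaction = split_field(row$kegg_reaction),
      substrate_key = row$parent_key, product_key = row$product_key,
      feasible = if (fkey %in% names(feas)) feas[[fkey]] else TRUE,
      multi_center = FALSE,
      substrate_is_cofactor = row$parent %in% cofactors)
    ri <- match(row$reaction_id, model$reactions$id)
    tmpl <- if (!is.na(ri)) {
      reaction_template(model$reactions[ri, ], cofactors, row$direction)
    } else NULL
    cr <- complete_reaction(row$parent, row$matched_db_id, tmpl,
                            ec = split_field(row$ec),
                            genes = split_field(row$genes))
    cand$equation_sig <- curated_equation_sig(cr)
    candidates[[i]] <- cand
    curated[[i]] <- cr
    balance[[i]] <- tryCatch(
      check_balance(cr, formulas, tolerate_h = isTRUE(cfg$tolerate_h)),
      error = function(e) list(balanced = NA, error = conditionMessage(e)))
  }

  ref <- read_reference_index(cfg$reference_dir)
  summary <- summarize_categories(candidates, ref)

  ## category report, curated reactions, run summary
  cat_tab <- summary$table
  cat_tab$equation <- vapply(curated, format_equation, "")
  cat_tab$balanced <- vapply(balance, function(b) isTRUE(b$balanced), TRUE)
  cat_tab$substrate_key <- vapply(candidates, `[[`, "", "substrate_key")
  cat_tab$product_key <- vapply(candidates, `[[`, "", "product_key")
  ord <- order(cat_tab$label, cat_tab$ec, cat_tab$substrate_key)
  cat_tab <- cat_tab[ord, , drop = FALSE]
  utils::write.table(as.data.frame(cat_tab), out("categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(seq_along(curated)[ord], function(i) {
      list(stoich = as.list(curated[[i]]$stoich),
           ec = curated[[i]]$ec, genes = curated[[i]]$genes,
           direction = curated[[i]]$direction,
           equation = format_equation(curated[[i]]),
           label = summary$table$label[i],
           balanced = isTRUE(balance[[i]]$balanced))
    }),
    out("curated_reactions.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  n_disc <- sum(startsWith(summary$table$label, "DISCARD"))
  run_summary <- list(
    n_operators = length(ops$operators),
    n_operator_skips = nrow(ops$skipped),
    pool_high = length(pool$high),
    pool_remainder = length(pool$remainder),
    n_derivatives = nrow(derivs),
    n_self_transformations = nrow(derivs) - nrow(new_preds),
    n_new_predictions = nrow(new_preds),
    n_matched = nrow(matched),
    n_unmatched = nrow(new_preds) - nrow(matched),
    n_candidate_reactions = nrow(cand_rows),
    n_kept = sum(summary$counts),
    n_discarded = n_disc,
    counts = as.list(summary$counts),
    discarded = as.list(summary$discarded),
    n_balanced = sum(vapply(balance, function(b) isTRUE(b$balanced), TRUE)),
    new_metabolites = summary$new_metabolites)
  jsonlite::write_json(run_summary, out("run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = run_summary, categories = cat_tab,
                 candidates = candidates, curated = curated,
                 balance = balance, pool = pool, derivatives = derivs,
                 matched = matched, operator_table = ops))
}
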