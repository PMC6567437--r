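## Reading metabolic models (BiGG-style JSON, SBML L3 core subset),
## structure sidecars, and concentration tables; substrate-pool selection.

#' Load a metabolic model
#'
#' Reads a BiGG-style JSON model or an SBML Level 3 core subset, with an
#' optional structure sidecar (SDF keyed by metabolite id in the record
#' title, or a two-column TSV of id and SMILES). Metabolites without a
#' structure are kept in the model -- their formulas can still be used for
#' balance checks -- but are flagged structure-less and never enter operator
#' extraction or application.
#'
#' Compartment tags (`_c` style suffixes or `[c]` brackets) are stripped
#' into a `base_id`, and structures are shared across compartment instances
#' of one chemical species.
#'
#' @param path model file path
#' @param format `"bigg-json"` or `"sbml"`
#' @param structures path to an SDF or SMILES TSV sidecar (optional)
#' @return a `metabolic_model`: list with tibbles `metabolites`
#'   (id, name, compartment, base_id, formula, has_structure), `reactions`
#'   (id, ec, genes, kegg_reaction, reversible, stoich list-column), a
#'   `genes` character vector and a named list `structures` keyed by base_id
#' @export
load_model <- function(path, format = c("bigg-json", "sbml"), structures = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- switch(format,
                  "bigg-json" = .load_bigg_json(path),
                  "sbml" = .load_sbml(path))
  if (!is.null(structures)) {
    model$structures <- read_structures(structures)
  }
  validate_model(model)
}

strip_compartment <- function(id) {
  id <- sub("\\[[a-z]\\]$", "", id)
  sub("_[a-z]$", "", id)
}

.load_bigg_json <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% sub("^.*_", "", m$id),
               formula = m$formula %||% NA_character_,
               charge = as.integer(m$charge %||% 0L),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(j$reactions, function(r) {
    lb <- r$lower_bound %||% -1000
    rev <- if (!is.null(r$reversible)) isTRUE(r$reversible) else lb < 0
    ann <- r$annotation %||% list()
    list(id = r$id,
         ec = unlist(ann[["ec-code"]] %||% ann[["ec"]] %||% list()),
         genes = .parse_gpr(r$gene_reaction_rule %||% ""),
         kegg_reaction = unlist(ann[["kegg.reaction"]] %||% ann[["kegg_reaction"]] %||% list()),
         reversible = rev,
         stoich = stats::setNames(vapply(r$metabolites, as.numeric, 1),
                                  names(r$metabolites)))
  })
  genes <- unique(c(unlist(lapply(rxns, `[[`, "genes")),
                    vapply(j$genes, function(g) g$id %||% "", "")))
  .assemble_model(mets, rxns, genes[nzchar(genes)])
}

.parse_gpr <- function(rule) {
  if (is.null(rule) || !nzchar(rule)) return(character(0))
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}

.load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")), xml2::xml_attr(sp, "id"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = NA_character_, charge = 0L, stringsAsFactors = FALSE)
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(r) {
    refs <- function(xp, sign) {
      nodes <- xml2::xml_find_all(r, xp)
      if (!length(nodes)) return(numeric(0))
      stats::setNames(
        sign * as.numeric(ifelse(is.na(xml2::xml_attr(nodes, "stoichiometry")),
                                 1, xml2::xml_attr(nodes, "stoichiometry"))),
        xml2::xml_attr(nodes, "species"))
    }
    # after namespace stripping the RDF nodes may keep their literal prefix
    ann <- xml2::xml_find_all(r, ".//*[local-name()='li' or name()='rdf:li']")
    res <- xml2::xml_attr(ann, "resource")
    res <- c(res, xml2::xml_attr(ann, "rdf:resource"))
    res <- res[!is.na(res)]
    ec <- sub(".*ec-code[:/]", "", grep("ec-code", res, value = TRUE))
    kegg <- sub(".*kegg.reaction[:/]", "", grep("kegg.reaction", res, value = TRUE))
    notes <- xml2::xml_text(xml2::xml_find_first(r, ".//notes"))
    genes <- character(0)
    if (!is.na(notes)) {
      gm <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(gm)) genes <- .parse_gpr(sub("GENE_ASSOCIATION:\\s*", "", gm))
    }
    list(id = xml2::xml_attr(r, "id"), ec = ec, genes = genes,
         kegg_reaction = kegg,
         reversible = !identical(xml2::xml_attr(r, "reversible"), "false"),
         stoich = c(refs(".//listOfReactants/speciesReference", -1),
                    refs(".//listOfProducts/speciesReference", 1)))
  })
  genes <- unique(unlist(lapply(rxns, `[[`, "genes")))
  .assemble_model(mets, rxns, genes)
}

.assemble_model <- function(mets, rxns, genes) {
  if (is.null(mets)) {
    mets <- data.frame(id = character(0), name = character(0),
                       compartment = character(0), formula = character(0),
                       charge = integer(0))
  }
  mets$base_id <- strip_compartment(mets$id)
  structure(list(
    metabolites = tibble::as_tibble(mets),
    reactions = tibble::tibble(
      id = vapply(rxns, `[[`, "", "id"),
      ec = lapply(rxns, `[[`, "ec"),
      genes = lapply(rxns, `[[`, "genes"),
      kegg_reaction = lapply(rxns, `[[`, "kegg_reaction"),
      reversible = vapply(rxns, `[[`, TRUE, "reversible"),
      stoich = lapply(rxns, `[[`, "stoich")),
    genes = genes,
    structures = list()
  ), class = "metabolic_model")
}

#' Validate referential integrity of a metabolic model
#'
#' Every reaction must reference only metabolite ids present in the model;
#' metabolites without a structure are flagged (with a logged warning) and
#' excluded from operator work.
#'
#' @param model metabolic_model
#' @return the model, with `has_structure` filled
#' @export
validate_model <- function(model) {
  ids <- model$metabolites$id
  for (i in seq_len(nrow(model$reactions))) {
    ref <- names(model$reactions$stoich[[i]])
    missing <- setdiff(ref, ids)
    if (length(missing)) {
      stop("reaction ", model$reactions$id[i],
           " references unknown metabolite: ", paste(missing, collapse = ", "))
    }
  }
  model$metabolites$has_structure <-
    model$metabolites$base_id %in% names(model$structures)
  n_miss <- sum(!model$metabolites$has_structure)
  if (n_miss > 0) {
    emmr_log(n_miss, " metabolite(s) without structure; excluded from ",
             "operator extraction and application")
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes;",
      length(x$structures), "structures\n")
  invisible(x)
}

#' Read a structure sidecar
#'
#' @param path SDF file (record title = metabolite id) or a TSV with columns
#'   `id` and `smiles`
#' @return named list of typed [mol_graph], keyed by id
#' @export
read_structures <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  first <- readLines(path, n = 5)
  if (grepl("\\.(tsv|txt|smi)$", path, ignore.case = TRUE) ||
      any(grepl("\t", first))) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "smiles") %in% names(tab)))
    out <- lapply(tab$smiles, parse_structure, format = "smiles")
    names(out) <- tab$id
    return(out)
  }
  txt <- paste(readLines(path), collapse = "\n")
  records <- strsplit(txt, "\\$\\$\\$\\$")[[1]]
  records <- records[vapply(records, function(r) grepl("V2000", r), TRUE)]
  out <- list()
  for (rec in records) {
    rec <- sub("^\n+", "", rec)
    id <- trimws(strsplit(rec, "\n")[[1]][1])
    out[[id]] <- parse_structure(rec, format = "molfile")
  }
  out
}

#' Read a metabolite concentration table
#'
#' TSV with header `metabolite_id<TAB>concentration_uM`. Concentrations must
#' be non-negative and unique per metabolite.
#'
#' @param path TSV path
#' @return tibble (metabolite_id, concentration_uM)
#' @export
read_concentrations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "concentration_uM") %in% names(tab)))
  if (any(tab$concentration_uM < 0)) stop("negative concentration")
  if (anyDuplicated(tab$metabolite_id)) stop("duplicate metabolite in concentration table")
  tibble::as_tibble(tab[, c("metabolite_id", "concentration_uM")])
}

#' Select the substrate pool by concentration threshold
#'
#' Splits the model's structure-bearing metabolites (at the chemical-species
#' level, compartment tags stripped) into a high-concentration pool --
#' concentration strictly greater than `threshold_uM` -- and the remainder.
#' Metabolites absent from the table fall into the remainder pool.
#'
#' @param model metabolic_model
#' @param conc concentration tibble from [read_concentrations()] (ids may be
#'   full or base ids)
#' @param threshold_uM non-negative threshold in micromolar (default 1)
#' @return list(high = character ids, remainder = character ids), both at
#'   base-id level
#' @export
select_substrate_pool <- function(model, conc, threshold_uM = 1) {
  stopifnot(threshold_uM >= 0)
  eligible <- unique(model$metabolites$base_id[model$metabolites$has_structure])
  key <- strip_compartment(conc$metabolite_id)
  above <- unique(key[conc$concentration_uM > threshold_uM])
  high <- intersect(eligible, above)
  list(high = high, remainder = setdiff(eligible, high))
}

#' Serialize a metabolic model to BiGG-style JSON
#'
#' @param model metabolic_model
#' @param path output path
#' @export
write_model <- function(model, path) {
  j <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.na(m$formula)) out$formula <- m$formula
      out$charge <- m$charge
      out
    }),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      r <- model$reactions[i, ]
      list(id = r$id,
           metabolites = as.list(r$stoich[[1]]),
           lower_bound = if (r$reversible) -1000 else 0,
           upper_bound = 1000,
           gene_reaction_rule = paste(r$genes[[1]], collapse = " or "),
           annotation = list(`ec-code` = as.list(r$ec[[1]]),
                             `kegg.reaction` = as.list(r$kegg_reaction[[1]])))
    }),
    genes = lapply(model$genes, function(g) list(id = g))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
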