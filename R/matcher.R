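## Metabolite identity reconciliation and derivative matching.
##
## Metabolomics records carry a declared primary (PubChem-like) id plus
## cross-references (InChIKey, KEGG, CAS, ChEBI, BioCyc). Each resolvable
## cross-reference is looked up in an offline xref table to retrieve a
## primary id; the record's identity is settled by majority vote over the
## retrieved ids plus the declared id (one vote each). A strict majority
## (more than half of the cast votes) is required; ties leave the record
## unresolved and excluded from matching.

.XREF_SOURCES <- c("inchikey", "kegg", "cas", "chebi", "biocyc")

#' Read a metabolomics database table
#'
#' TSV or JSON with ECMDB-like export columns: `db_id`, `name`, `formula`,
#' optional `pubchem` (declared primary id), optional xref columns
#' `inchikey`, `kegg`, `cas`, `chebi`, `biocyc`, optional `structure_key`.
#'
#' @param path file path (.tsv or .json)
#' @return tibble of metabolite records
#' @export
read_metabolome <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = c("NA", ""))
  }
  stopifnot(all(c("db_id", "name") %in% names(tab)))
  if (anyDuplicated(tab$db_id)) stop("duplicate db_id in metabolome table")
  for (col in c("formula", "pubchem", "structure_key", .XREF_SOURCES)) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_character_
  }
  tibble::as_tibble(tab)
}

#' Read an offline cross-reference table
#'
#' TSV with columns `source`, `id`, `primary_id`: the offline stand-in for
#' live PubChem retrieval. One primary id per (source, id).
#'
#' @param path TSV path
#' @return xref lookup (environment-backed named list)
#' @export
read_xref_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(all(c("source", "id", "primary_id") %in% names(tab)))
  xref_table(tab)
}

#' Construct an xref table from a data frame
#' @param tab data.frame with columns source, id, primary_id
#' @return object of class `xref_table`
#' @export
xref_table <- function(tab) {
  key <- paste(tab$source, tab$id, sep = "\r")
  if (anyDuplicated(key)) stop("xref table not deterministic: duplicate (source, id)")
  structure(list(map = stats::setNames(tab$primary_id, key)), class = "xref_table")
}

xref_lookup <- function(x, source, id) {
  if (is.na(id) || !nzchar(id)) return(NA_character_)
  hit <- x$map[paste(source, id, sep = "\r")]
  if (is.na(hit)) NA_character_ else unname(hit)
}

#' Reconcile a record's primary id by majority vote
#'
#' Collects the primary ids retrieved through each available cross-reference
#' plus the declared primary id (one vote each, enumeration-order
#' independent) and returns the strict-majority winner. The consistency flag
#' is TRUE iff every retrieved id agrees with the declared id.
#'
#' @param rec one metabolome record (list or single-row data frame)
#' @param x xref_table
#' @return list(primary_id = id or NA (unresolved), consistent = logical,
#'   votes = named integer vector)
#' @export
reconcile_primary_id <- function(rec, x) {
  retrieved <- character(0)
  for (src in .XREF_SOURCES) {
    id <- rec[[src]]
    if (is.null(id) || length(id) == 0L) next
    hit <- xref_lookup(x, src, id)
    if (!is.na(hit)) retrieved <- c(retrieved, hit)
  }
  declared <- rec[["pubchem"]]
  declared <- if (is.null(declared) || length(declared) == 0L || is.na(declared) ||
                  !nzchar(declared)) NA_character_ else declared
  votes <- c(retrieved, if (!is.na(declared)) declared)
  if (!length(votes)) {
    return(list(primary_id = NA_character_, consistent = FALSE,
                votes = integer(0)))
  }
  tal <- sort(table(votes), decreasing = TRUE)
  winner <- if (tal[1] * 2L > sum(tal)) names(tal)[1] else NA_character_
  consistent <- !is.na(declared) &&
    (length(retrieved) == 0L || all(retrieved == declared))
  list(primary_id = winner, consistent = consistent,
       votes = stats::setNames(as.integer(tal), names(tal)))
}

#' Reconcile every record of a metabolome table
#'
#' @param records tibble from [read_metabolome()]
#' @param x xref_table
#' @return records with `primary_id`, `consistent` and `resolved` columns
#' @export
reconcile_metabolome <- function(records, x) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    reconcile_primary_id(as.list(records[i, ]), x)
  })
  records$primary_id <- vapply(res, function(r) r$primary_id, "")
  records$consistent <- vapply(res, function(r) r$consistent, TRUE)
  records$resolved <- !is.na(records$primary_id)
  records
}

#' Match predicted derivatives against a reconciled metabolome
#'
#' A derivative matches a record when its known-compound id equals the
#' record's reconciled primary id, or -- as a structural fallback -- when the
#' record carries a structure key equal to the derivative's product key.
#' Records that failed reconciliation are excluded. Matching is independent
#' of record order.
#'
#' @param derivs tibble from [enumerate_derivatives()]
#' @param records reconciled records from [reconcile_metabolome()]
#' @return derivs subset with a `matched_db_id` column
#' @export
match_derivatives <- function(derivs, records) {
  ok <- records[records$resolved, , drop = FALSE]
  ok <- ok[order(ok$db_id), , drop = FALSE]
  by_primary <- stats::setNames(ok$db_id, ok$primary_id)
  with_struct <- ok[!is.na(ok$structure_key), , drop = FALSE]
  by_struct <- stats::setNames(with_struct$db_id, with_struct$structure_key)
  hit <- rep(NA_character_, nrow(derivs))
  if (nrow(derivs)) {
    kid <- derivs$known_id
    has_kid <- !is.na(kid) & kid %in% names(by_primary)
    hit[has_kid] <- by_primary[kid[has_kid]]
    fall <- is.na(hit) & derivs$product_key %in% names(by_struct)
    hit[fall] <- by_struct[derivs$product_key[fall]]
  }
  derivs$matched_db_id <- hit
  derivs[!is.na(hit), , drop = FALSE]
}
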