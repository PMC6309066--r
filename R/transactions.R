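# Case-report transactions: the mining input.
#
# A transaction is one case report reduced to its set of canonical disease
# terms (drug indications). Raw FAERS-style indication files list one
# (report, indication) row per drug sequence; rows belonging to one report
# merge into one transaction.

#' Construct a transaction database
#'
#' @param transactions named list of character vectors; names are report ids,
#'   values the disease terms of each report. Duplicate terms within a report
#'   collapse (set semantics); empty reports are rejected.
#' @param n_raw_reports number of reports seen before filtering; defaults to
#'   the number of kept transactions.
#' @return an object of class `transaction_db` with fields `transactions`,
#'   `vocabulary`, `n_raw_reports`, `n_kept_reports`.
#' @export
transaction_db <- function(transactions, n_raw_reports = length(transactions)) {
  if (!is.list(transactions)) {
    stop("`transactions` must be a named list of character vectors", call. = FALSE)
  }
  if (length(transactions) > 0L &&
      (is.null(names(transactions)) || anyDuplicated(names(transactions)))) {
    stop("report ids must be present and unique", call. = FALSE)
  }
  transactions <- lapply(transactions, function(x) sort(unique(as.character(x))))
  if (any(lengths(transactions) == 0L)) {
    stop("transactions must not have empty disease sets", call. = FALSE)
  }
  structure(
    list(
      transactions = transactions,
      vocabulary = sort(unique(unlist(transactions, use.names = FALSE))),
      n_raw_reports = as.integer(n_raw_reports),
      n_kept_reports = length(transactions)
    ),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("Transaction DB:", x$n_kept_reports, "reports kept of",
      x$n_raw_reports, "raw;", length(x$vocabulary), "diseases\n")
  invisible(x)
}

#' Read raw (report, indication) records
#'
#' Parses either a FAERS quarterly ASCII indication file (`$`-delimited, with
#' a header naming at least a `primaryid` and an `indi_pt` column) or the
#' internal two-column TSV (`report_id <tab> disease`, with header). Rows
#' with an empty indication term are counted as malformed and dropped, not
#' fatal. Input order is preserved.
#'
#' @param path path to the file.
#' @param dialect `"faers_ascii"` or `"internal_tsv"`.
#' @return a data.frame with columns `report_id` and `term`, plus attribute
#'   `n_malformed`.
#' @export
read_faers_indications <- function(path, dialect = c("faers_ascii", "internal_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  sep <- if (dialect == "faers_ascii") "$" else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  cols <- tolower(names(df))
  if (dialect == "faers_ascii") {
    id_col <- match("primaryid", cols)
    term_col <- match("indi_pt", cols)
    missing_col <- c("primaryid", "indi_pt")[is.na(c(id_col, term_col))]
  } else {
    id_col <- match("report_id", cols)
    term_col <- match("disease", cols)
    missing_col <- c("report_id", "disease")[is.na(c(id_col, term_col))]
  }
  if (length(missing_col) > 0L) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  records <- data.frame(report_id = trimws(df[[id_col]]),
                        term = trimws(df[[term_col]]),
                        stringsAsFactors = FALSE)
  bad <- records$term == "" | is.na(records$term) |
    records$report_id == "" | is.na(records$report_id)
  if (any(bad)) {
    message(sum(bad), " malformed row(s) (empty report id or indication) excluded")
  }
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Read a term-normalization map
#'
#' Two-column TSV `raw_term <tab> canonical` (header required); `canonical`
#' may be the sentinel `DROP` to discard a term. Lookup is case-insensitive
#' after whitespace collapse. This table stands in for MetaMap/UMLS semantic
#' typing of MedDRA indication terms.
#'
#' @param path TSV path.
#' @return a `term_map` object: named character vector keyed by normalized
#'   raw term.
#' @export
read_term_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          stringsAsFactors = FALSE)
  cols <- tolower(names(df))
  if (!all(c("raw_term", "canonical") %in% cols)) {
    stop("term map must have columns raw_term and canonical", call. = FALSE)
  }
  term_map(stats::setNames(trimws(df[[match("canonical", cols)]]),
                           df[[match("raw_term", cols)]]))
}

#' Construct a term-normalization map from a named vector
#'
#' @param entries named character vector: names are raw indication strings,
#'   values are canonical disease terms or `"DROP"`.
#' @param provenance free-text note on where the mapping came from.
#' @return a `term_map` object.
#' @export
term_map <- function(entries, provenance = "user-supplied") {
  if (is.null(names(entries))) stop("`entries` must be named", call. = FALSE)
  structure(stats::setNames(as.character(entries), normalize_term(names(entries))),
            provenance = provenance, class = "term_map")
}

#' Identity term map over a vocabulary
#'
#' Maps each term (case/whitespace-insensitively) to itself; convenient when
#' the input already uses canonical terms, e.g. synthetic data.
#'
#' @param vocabulary character vector of canonical terms.
#' @export
identity_term_map <- function(vocabulary) {
  term_map(stats::setNames(vocabulary, vocabulary), provenance = "identity")
}

#' Normalize raw records into a clean transaction database
#'
#' Maps each record's indication term through the term map (case-insensitive,
#' whitespace-collapsed), drops `DROP`-mapped and unmapped terms (unmapped
#' terms are reported via a message, never silently kept), collapses
#' duplicate (report, disease) pairs, and removes reports whose disease set
#' becomes empty.
#'
#' @param records data.frame from [read_faers_indications()].
#' @param term_map a [term_map()].
#' @return a `transaction_db`; `n_raw_reports` counts distinct report ids in
#'   `records`, `n_kept_reports` those surviving filtering.
#' @export
normalize_and_filter <- function(records, term_map) {
  stopifnot(is.data.frame(records), inherits(term_map, "term_map"))
  n_raw <- length(unique(records$report_id))
  mapped <- unname(term_map[normalize_term(records$term)])
  unmapped <- is.na(mapped)
  if (any(unmapped)) {
    message(sum(unmapped), " record(s) with unmapped terms removed (",
            length(unique(records$term[unmapped])), " distinct term(s), e.g. '",
            records$term[unmapped][1L], "')")
  }
  keep <- !unmapped & mapped != "DROP"
  if (!any(keep)) {
    return(transaction_db(stats::setNames(list(), character(0L)),
                          n_raw_reports = n_raw))
  }
  txs <- split(mapped[keep], records$report_id[keep])
  # preserve first-appearance order of reports
  txs <- txs[unique(records$report_id[keep])]
  transaction_db(txs, n_raw_reports = n_raw)
}

#' Write / read the internal transaction TSV
#'
#' One row per (report, disease): columns `report_id`, `disease`, with
#' header. `read_transactions()` is `read_faers_indications(dialect =
#' "internal_tsv")` followed by an identity mapping, so a written database
#' round-trips exactly.
#'
#' @param db a `transaction_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  df <- data.frame(
    report_id = rep(names(db$transactions), lengths(db$transactions)),
    disease = unlist(db$transactions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(path) {
  records <- read_faers_indications(path, dialect = "internal_tsv")
  txs <- split(records$term, records$report_id)
  txs <- txs[unique(records$report_id)]
  transaction_db(txs, n_raw_reports = length(txs))
}

#' Write transactions in FAERS-style $-delimited INDI layout
#'
#' Emits `primaryid$caseid$indi_drug_seq$indi_pt` rows, one per (report,
#' disease), mirroring the quarterly ASCII indication files.
#'
#' @param db a `transaction_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_faers_indications <- function(db, path) {
  stopifnot(inherits(db, "transaction_db"))
  ids <- rep(names(db$transactions), lengths(db$transactions))
  seqs <- unlist(lapply(lengths(db$transactions), seq_len), use.names = FALSE)
  lines <- c("primaryid$caseid$indi_drug_seq$indi_pt",
             paste(ids, ids, seqs,
                   unlist(db$transactions, use.names = FALSE), sep = "$"))
  writeLines(lines, path)
  invisible(path)
}
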