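#' Construct a set of protein sequences
#'
#' A `protein_set` is the package's container for protein sequences: a
#' data frame with one row per sequence and columns `id`, `description`
#' and `residues`. Identifiers must be unique within a set and contain no
#' whitespace; residues are stored uppercase. No alphabet validation is
#' performed here — use [filter_standard()] to restrict a set to the 20
#' standard amino acids before encoding.
#'
#' @param id Character vector of unique, whitespace-free identifiers.
#' @param residues Character vector of residue strings (uppercased on
#'   construction). Empty strings are rejected.
#' @param description Character vector of free-text descriptions, recycled.
#' @return A `protein_set` object.
#' @export
#' @examples
#' ps <- protein_set(c("s1", "s2"), c("MKV", "ACDG"))
#' nseq(ps)
protein_set <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("'id' and 'residues' must have equal length")
  if (length(id)) {
    if (anyNA(id) || any(!nzchar(id)))
      stop("sequence ids must be non-empty")
    if (any(grepl("[[:space:]]", id)))
      stop("sequence ids must not contain whitespace: ",
           paste(id[grepl("[[:space:]]", id)], collapse = ", "))
    if (anyDuplicated(id))
      stop("duplicated sequence ids: ",
           paste(unique(id[duplicated(id)]), collapse = ", "))
    if (any(!nzchar(residues)))
      stop("empty sequence body for id: ",
           paste(id[!nzchar(residues)], collapse = ", "))
  }
  out <- data.frame(id = id, description = rep_len(as.character(description),
                                                   length(id)),
                    residues = residues, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Number of sequences in a protein set
#' @param x A `protein_set`.
#' @return Integer count of sequences.
#' @export
nseq <- function(x) nrow(x)

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set with %d sequence%s\n", nrow(x),
              if (nrow(x) == 1) "" else "s"))
  if (nrow(x)) {
    n <- min(nrow(x), 6L)
    for (i in seq_len(n)) {
      r <- x$residues[i]
      cat(sprintf("  %s  [%d aa]  %s%s\n", x$id[i], nchar(r),
                  substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
    }
    if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Accepts the common protein FASTA dialect: `>`-prefixed headers with the
#' identifier as the token before the first whitespace, arbitrary line
#' wrapping in sequence bodies, and lowercase residues (uppercased on read).
#' A single terminal `*` (stop marker) is stripped. No alphabet validation
#' is performed; follow with [filter_standard()].
#'
#' @param path Path to a FASTA file.
#' @return A [protein_set()] in file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a kinase", "MKV", ">s2", "ACDG"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[[:space:]]+$", "", lines)
  nonblank <- which(nzchar(lines))
  if (!length(nonblank)) stop("no records in FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop(sprintf("malformed FASTA: line %d does not start with '>'", first))
  headers <- which(startsWith(lines, ">"))
  bounds <- c(headers, length(lines) + 1L)
  ids <- character(length(headers))
  descs <- character(length(headers))
  seqs <- character(length(headers))
  for (k in seq_along(headers)) {
    h <- sub("^>", "", lines[headers[k]])
    tok <- regmatches(h, regexpr("^[^[:space:]]+", h))
    ids[k] <- if (length(tok)) tok else ""
    descs[k] <- sub("^[^[:space:]]*[[:space:]]*", "", h)
    body <- lines[seq.int(headers[k] + 1L, bounds[k + 1L] - 1L)[
      seq_len(max(0L, bounds[k + 1L] - headers[k] - 1L))]]
    s <- toupper(gsub("[[:space:]]", "", paste(body, collapse = "")))
    s <- sub("\\*$", "", s)
    if (!nzchar(s))
      stop("empty sequence body for id: ", ids[k])
    seqs[k] <- s
  }
  if (any(!nzchar(ids)))
    stop(sprintf("malformed FASTA: empty header at line %d",
                 headers[which(!nzchar(ids))[1]]))
  protein_set(ids, seqs, descs)
}

#' Write a protein set to a FASTA file
#'
#' @param x A [protein_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "protein_set"))
  hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  seqinr::write.fasta(as.list(x$residues), names = hdr, file.out = path,
                      nbchar = 60)
  invisible(path)
}

filter_report <- function(n_input, n_kept, removed_nonstandard = character(),
                          removed_duplicates = character()) {
  out <- list(n_input = n_input, n_kept = n_kept,
              removed_nonstandard = removed_nonstandard,
              removed_duplicates = removed_duplicates)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter report: %d in, %d kept, %d non-standard, %d duplicates\n",
              x$n_input, x$n_kept, length(x$removed_nonstandard),
              length(x$removed_duplicates)))
  invisible(x)
}

#' Remove sequences with non-standard residues
#'
#' Keeps exactly the sequences whose every residue is one of the 20
#' standard amino acids ([AA_ALPHABET]); ambiguity codes (B, J, O, U, X, Z)
#' and any other character disqualify a sequence. Order is preserved.
#'
#' @param x A [protein_set()].
#' @return A list with elements `kept` (a `protein_set`) and `report`
#'   (a `filter_report` listing removed ids).
#' @export
#' @examples
#' ps <- protein_set(c("a", "b"), c("MKV", "MXV"))
#' filter_standard(ps)$report
filter_standard <- function(x) {
  stopifnot(inherits(x, "protein_set"))
  ok <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
               x$residues)
  kept <- x[ok, , drop = FALSE]
  class(kept) <- c("protein_set", "data.frame")
  list(kept = kept,
       report = filter_report(nrow(x), sum(ok),
                              removed_nonstandard = x$id[!ok]))
}

#' Remove exact duplicate sequences
#'
#' Drops sequences whose residue string (case-insensitive) already occurred
#' earlier in the set; the first occurrence is kept and order is preserved.
#' Identity of the residue string, not of the id, defines a duplicate.
#'
#' @param x A [protein_set()].
#' @return A list with elements `kept` and `report` as in
#'   [filter_standard()].
#' @export
deduplicate <- function(x) {
  stopifnot(inherits(x, "protein_set"))
  dup <- duplicated(toupper(x$residues))
  kept <- x[!dup, , drop = FALSE]
  class(kept) <- c("protein_set", "data.frame")
  list(kept = kept,
       report = filter_report(nrow(x), sum(!dup),
                              removed_duplicates = x$id[dup]))
}

#' Write a prediction table
#'
#' Writes two-stage prediction records as a tab-separated table with a
#' header row and four columns: serial number (1-based, input order),
#' sequence identifier, predicted nif category — or the literal tokens
#' `"non-nif"` (rejected at stage 1) and `"unassigned"` (stage-1 positive
#' whose best stage-2 probability fell below the threshold) — and the
#' associated probability printed with six decimal places (the category
#' probability where a category or `"unassigned"` is reported, otherwise
#' the stage-1 non-nif probability).
#'
#' @param records Prediction records from [predict.nif_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_prediction_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  pred <- character(n)
  prob <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(records$category[i])) {
      pred[i] <- records$category[i]
      prob[i] <- records$category_prob[i]
    } else if (identical(records$stage1_label[i], "nif")) {
      pred[i] <- "unassigned"
      prob[i] <- records$category_prob[i]
    } else {
      pred[i] <- "non-nif"
      prob[i] <- 1 - records$stage1_prob[i]
    }
  }
  tab <- data.frame(serial = seq_len(n),
                    id = if (n) records$id else character(),
                    prediction = pred,
                    probability = sprintf("%.6f", prob),
                    stringsAsFactors = FALSE)
  if (!n) tab <- tab[0, , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
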