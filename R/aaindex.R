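# Three-letter -> one-letter residue code mapping used to reorder
# property tables into the canonical alphabet.
AA_THREE_TO_ONE <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
                     Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
                     Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
                     Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

new_aaindex_table <- function(property_ids, raw, normalized) {
  out <- list(property_ids = property_ids, raw = raw,
              normalized = normalized)
  class(out) <- "aaindex_table"
  out
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat(sprintf("aaindex_table: %d physicochemical properties x 20 residues\n",
              length(x$property_ids)))
  cat("  first properties:",
      paste(utils::head(x$property_ids, 4), collapse = ", "), "...\n")
  invisible(x)
}

# Shared post-processing: NA handling, degenerate-row exclusion, the
# n_properties cut, and per-property standardization across the 20 residues.
finalize_aaindex <- function(ids, raw, n_properties) {
  stopifnot(ncol(raw) == 20L)
  colnames(raw) <- AA_ALPHABET
  has_na <- rowSums(is.na(raw)) > 0L
  complete <- raw[!has_na, , drop = FALSE]
  ids_c <- ids[!has_na]
  if (nrow(complete) < n_properties) {
    # too few complete rows: impute NAs with the property's mean over the
    # residues that do have values, then retry
    imp <- raw
    for (i in which(has_na)) {
      m <- mean(raw[i, ], na.rm = TRUE)
      imp[i, is.na(imp[i, ])] <- m
    }
    complete <- imp
    ids_c <- ids
  }
  sds <- apply(complete, 1, stats::sd)
  usable <- is.finite(sds) & sds > 0
  complete <- complete[usable, , drop = FALSE]
  ids_c <- ids_c[usable]
  if (nrow(complete) < n_properties)
    stop(sprintf("only %d usable properties, need %d",
                 nrow(complete), n_properties))
  keep <- seq_len(n_properties)
  raw_kept <- complete[keep, , drop = FALSE]
  normalized <- t(apply(raw_kept, 1, function(v) (v - mean(v)) / stats::sd(v)))
  colnames(normalized) <- AA_ALPHABET
  rownames(raw_kept) <- rownames(normalized) <- ids_c[keep]
  new_aaindex_table(ids_c[keep], raw_kept, normalized)
}

#' Amino acid physicochemical property table
#'
#' Builds the table of 531 AAindex physicochemical properties backing the
#' autocorrelation encoder, from the AAindex snapshot distributed with the
#' seqinr package. Properties with a missing residue value are dropped,
#' leaving exactly 531 complete properties; each retained property is
#' standardized to mean 0 and standard deviation 1 across the 20 residues.
#' The result is cached for the session.
#'
#' @param n_properties Number of properties to retain (default 531).
#' @return An `aaindex_table` with elements `property_ids`, `raw`
#'   (property x residue matrix, canonical residue order) and `normalized`
#'   (per-property z-scores).
#' @seealso [load_aaindex()] to read a table from a file,
#'   [compute_acf()] for the encoder it backs.
#' @export
#' @examples
#' tab <- aaindex_table()
#' length(tab$property_ids)
aaindex_table <- local({
  cache <- NULL
  function(n_properties = 531L) {
    if (!is.null(cache) && length(cache$property_ids) == n_properties)
      return(cache)
    env <- new.env()
    utils::data("aaindex", package = "seqinr", envir = env)
    aa <- env$aaindex
    vals <- t(vapply(aa, function(p) p$I, numeric(20)))
    # seqinr orders residues by three-letter code; reorder to canonical
    colnames(vals) <- AA_THREE_TO_ONE[colnames(vals)]
    vals <- vals[, AA_ALPHABET, drop = FALSE]
    ids <- unname(vapply(aa, function(p) p$H, character(1)))
    tab <- finalize_aaindex(ids, vals, n_properties)
    if (n_properties == 531L) cache <<- tab
    tab
  }
})

#' Load an amino acid property table from a file
#'
#' Reads either an AAindex1 flat file (records delimited by `//`, numeric
#' values under the `I` line in the standard `A/L R/K ...` two-row layout)
#' or a tab-separated snapshot with columns `property_id` followed by the
#' 20 one-letter residue codes. Properties with missing values are dropped
#' when enough complete properties remain, otherwise imputed with the
#' property's mean; zero-variance properties are excluded; the first
#' `n_properties` surviving properties (file order) are retained and each
#' standardized to mean 0, sd 1 across residues.
#'
#' @param path Path to an AAindex1 flat file or TSV snapshot.
#' @param n_properties Number of properties required (default 531).
#' @return An `aaindex_table`; see [aaindex_table()].
#' @export
load_aaindex <- function(path, n_properties = 531L) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^H ", first)) {
    parsed <- parse_aaindex_flat(path)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!all(AA_ALPHABET %in% colnames(tab)))
      stop("TSV snapshot must have the 20 one-letter residue columns")
    parsed <- list(ids = as.character(tab[[1]]),
                   raw = as.matrix(tab[, AA_ALPHABET, drop = FALSE]))
  }
  finalize_aaindex(parsed$ids, parsed$raw, n_properties)
}

# AAindex1 flat-file records: accession on the 'H' line; values on the two
# lines after 'I', first line residues A R N D C Q E G H I, second
# L K M F P S T W Y V; 'NA' or '-' marks a missing value.
parse_aaindex_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  rows <- list()
  i <- 1L
  cur_id <- NA_character_
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  while (i <= length(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "H ")) {
      cur_id <- trimws(sub("^H ", "", ln))
    } else if (startsWith(ln, "I ")) {
      if (i + 2L > length(lines))
        stop("truncated AAindex record: ", cur_id)
      num <- function(s) {
        v <- strsplit(trimws(s), "[[:space:]]+")[[1]]
        suppressWarnings(as.numeric(ifelse(v %in% c("NA", "-", "."),
                                           NA, v)))
      }
      v1 <- num(lines[i + 1L])
      v2 <- num(lines[i + 2L])
      if (length(v1) != 10L || length(v2) != 10L)
        stop("malformed value lines in AAindex record: ", cur_id)
      vals <- c(stats::setNames(v1, order1), stats::setNames(v2, order2))
      ids <- c(ids, cur_id)
      rows[[length(rows) + 1L]] <- vals[AA_ALPHABET]
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (!length(rows)) stop("no AAindex records found in ", path)
  list(ids = ids, raw = do.call(rbind, rows))
}
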