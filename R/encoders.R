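# Coerce encoder input to a validated residue index vector.
# Accepts a residue string or a single-row protein_set.
encoder_indices <- function(seq) {
  if (inherits(seq, "protein_set")) {
    if (nrow(seq) != 1L)
      stop("encoders take one sequence at a time; use encode_dataset()")
    seq <- seq$residues
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  idx <- residue_indices(toupper(seq))
  if (anyNA(idx))
    stop("sequence contains non-standard residues; apply filter_standard()")
  if (!length(idx)) stop("empty sequence")
  idx
}

feature_vector <- function(values, labels, scheme, params = list()) {
  names(values) <- labels
  attr(values, "scheme") <- scheme
  attr(values, "params") <- params
  values
}

#' Amino acid composition (AAC)
#'
#' The proportion of each of the 20 standard amino acids in the sequence:
#' component i is the count of residue i divided by the sequence length N.
#' Components are in canonical alphabet order and sum to 1.
#'
#' @param seq A residue string or single-row [protein_set()].
#' @return Named numeric vector of length 20 with attributes `scheme`
#'   and `params`.
#' @export
#' @examples
#' compute_aac("ACDG")
compute_aac <- function(seq) {
  idx <- encoder_indices(seq)
  feature_vector(tabulate(idx, 20L) / length(idx), AA_ALPHABET, "aac")
}

#' Di-peptide composition (DPC)
#'
#' The proportion of each of the 400 ordered residue pairs among the N-1
#' adjacent pairs of the sequence: value for pair (i, j) is the number of
#' adjacent occurrences of i followed by j, divided by N-1. Pairs are
#' enumerated row-major over the canonical alphabet (AA, AC, ..., YY).
#'
#' @inheritParams compute_aac
#' @return Named numeric vector of length 400.
#' @export
compute_dpc <- function(seq) {
  idx <- encoder_indices(seq)
  n <- length(idx)
  if (n < 2L) stop("sequence too short for DPC (length >= 2 required)")
  code <- (idx[-n] - 1L) * 20L + idx[-1L]
  feature_vector(tabulate(code, 400L) / (n - 1L), aa_pair_labels(), "dpc")
}

#' Gap-pair composition (GPC)
#'
#' The proportion of ordered residue pairs separated by exactly G
#' intervening residues: value for pair (i, j) is the number of positions p
#' with residue i at p and residue j at p + G + 1, divided by N - G - 1.
#' `gap = 1` and `gap = 2` give the GPC-1 and GPC-2 feature sets.
#'
#' @inheritParams compute_aac
#' @param gap Number of intervening residues G (>= 1).
#' @return Named numeric vector of length 400.
#' @export
#' @examples
#' compute_gpc("ACACA", gap = 1)[c("AA", "CC")]
compute_gpc <- function(seq, gap = 1L) {
  stopifnot(length(gap) == 1L, gap >= 1)
  gap <- as.integer(gap)
  idx <- encoder_indices(seq)
  n <- length(idx)
  if (n < gap + 2L)
    stop(sprintf("sequence too short for GPC with gap %d (length >= %d required)",
                 gap, gap + 2L))
  m <- n - gap - 1L
  code <- (idx[seq_len(m)] - 1L) * 20L + idx[seq_len(m) + gap + 1L]
  feature_vector(tabulate(code, 400L) / m, aa_pair_labels(), "gpc",
                 list(gap = gap))
}

# Residue properties for the pseudo amino acid composition, canonical
# alphabet order: hydrophobicity, hydrophilicity, side-chain mass
# (the classical type-1 PseAAC property triple).
pseaac_properties <- function() {
  raw <- rbind(
    hydrophobicity = c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                       G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                       M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                       S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26),
    hydrophilicity = c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                       G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                       M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                       S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    side_chain_mass = c(A = 15.0, C = 47.0, D = 59.0, E = 73.0, F = 91.0,
                        G = 1.0, H = 82.0, I = 57.0, K = 73.0, L = 57.0,
                        M = 75.0, N = 58.0, P = 42.0, Q = 72.0, R = 101.0,
                        S = 31.0, T = 45.0, V = 43.0, W = 130.0, Y = 107.0))
  # standard conversion: centre and divide by the population sd over the
  # 20 residues, per property
  t(apply(raw[, AA_ALPHABET], 1, function(v) {
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }))
}

#' Pseudo amino acid composition (PseAAC)
#'
#' Type-1 pseudo amino acid composition: the 20 composition components are
#' augmented with `lambda` sequence-order correlation factors computed from
#' three standardized residue properties (hydrophobicity, hydrophilicity,
#' side-chain mass). The tier-k factor is the mean, over residue pairs k
#' positions apart, of the squared property differences averaged over the
#' three properties. With normalized composition frequencies f (summing to
#' 1) and factors tau, component i (i <= 20) is
#' `f_i / (1 + w * sum(tau))` and component 20 + k is
#' `w * tau_k / (1 + w * sum(tau))`, so all 20 + lambda components sum to 1.
#'
#' @inheritParams compute_aac
#' @param lambda Number of correlation tiers (>= 1); must be smaller than
#'   the sequence length.
#' @param w Weight of the sequence-order part (> 0, default 0.05).
#' @return Named numeric vector of length `20 + lambda`.
#' @export
compute_pseaac <- function(seq, lambda = 1L, w = 0.05) {
  stopifnot(length(lambda) == 1L, lambda >= 1, length(w) == 1L, w > 0)
  lambda <- as.integer(lambda)
  idx <- encoder_indices(seq)
  n <- length(idx)
  if (n <= lambda)
    stop("lambda must be smaller than sequence length")
  props <- pseaac_properties()
  tau <- vapply(seq_len(lambda), function(k) {
    d <- props[, idx[seq_len(n - k)], drop = FALSE] -
      props[, idx[seq_len(n - k) + k], drop = FALSE]
    mean(colMeans(d^2))
  }, numeric(1))
  f <- tabulate(idx, 20L) / n
  denom <- sum(f) + w * sum(tau)
  feature_vector(c(f / denom, w * tau / denom),
                 c(AA_ALPHABET, paste0("lambda", seq_len(lambda))),
                 "pseaac", list(lambda = lambda, w = w))
}

# Labels for the 190 unordered residue pairs, canonical order (i < j).
ctd_transition_labels <- function() {
  out <- character(0)
  for (i in 1:19)
    out <- c(out, paste0(AA_ALPHABET[i], AA_ALPHABET[(i + 1):20]))
  out
}

#' Composition-transition-distribution (CTD)
#'
#' A 310-dimensional descriptor over the 20-letter alphabet, the
#' concatenation of three blocks:
#' \describe{
#'   \item{Composition (20)}{residue fractions, identical to
#'     [compute_aac()].}
#'   \item{Transition (190)}{for each unordered residue pair \{i, j\}
#'     (i != j), the number of adjacent positions where i and j abut in
#'     either order, divided by N - 1.}
#'   \item{Distribution (100)}{for each residue with n_i occurrences, the
#'     1-based sequence positions of its 1st and of its
#'     ceiling(q * n_i)-th occurrence for q in 0.25, 0.50, 0.75, 1.00,
#'     each expressed as 100 * position / N; a residue absent from the
#'     sequence contributes five zeros.}
#' }
#'
#' @inheritParams compute_aac
#' @return Named numeric vector of length 310.
#' @export
compute_ctd <- function(seq) {
  idx <- encoder_indices(seq)
  n <- length(idx)
  if (n < 2L) stop("sequence too short for CTD (length >= 2 required)")
  comp <- tabulate(idx, 20L) / n
  # transition: unordered hetero pairs, counted in both orders
  a <- idx[-n]; b <- idx[-1L]
  het <- a != b
  lo <- pmin(a, b)[het]; hi <- pmax(a, b)[het]
  # map (lo, hi) with lo < hi onto 1..190 in canonical order
  pair_code <- (lo - 1L) * 20L - (lo * (lo - 1L)) %/% 2L + (hi - lo)
  trans <- tabulate(pair_code, 190L) / (n - 1L)
  # distribution: positional anchors per residue
  dist <- numeric(100L)
  for (i in seq_len(20L)) {
    pos <- which(idx == i)
    ni <- length(pos)
    if (ni) {
      anchors <- c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * ni))
      dist[(i - 1L) * 5L + 1:5] <- 100 * pos[anchors] / n
    }
  }
  labels <- c(paste0("C.", AA_ALPHABET),
              paste0("T.", ctd_transition_labels()),
              paste0("D.", rep(AA_ALPHABET, each = 5L), ".",
                     rep(c("first", "q25", "q50", "q75", "q100"), 20L)))
  feature_vector(c(comp, trans, dist), labels, "ctd")
}

#' AAindex autocorrelation features (ACF)
#'
#' For each of the 531 standardized AAindex physicochemical properties and
#' each lag k in 1..`order`, the lag-k autocorrelation
#' `r_k(p) = mean over t of v_p(s_t) * v_p(s_(t+k))`, where `v_p` maps a
#' residue to its standardized value under property p. Values are ordered
#' property-major, then by lag, giving a `531 * order`-dimensional vector.
#'
#' @inheritParams compute_aac
#' @param table An `aaindex_table` from [aaindex_table()] or
#'   [load_aaindex()].
#' @param order Maximum lag n (>= 1); the sequence must be longer than n.
#' @return Named numeric vector of length `nrow(table$normalized) * order`.
#' @export
compute_acf <- function(seq, table = aaindex_table(), order = 1L) {
  stopifnot(inherits(table, "aaindex_table"), length(order) == 1L,
            order >= 1)
  order <- as.integer(order)
  idx <- encoder_indices(seq)
  n <- length(idx)
  if (n <= order)
    stop(sprintf("sequence too short for ACF order %d (length > %d required)",
                 order, order))
  v <- table$normalized[, idx, drop = FALSE]  # properties x positions
  np <- nrow(v)
  vals <- matrix(0, nrow = np, ncol = order)
  for (k in seq_len(order)) {
    m <- n - k
    vals[, k] <- rowSums(v[, seq_len(m), drop = FALSE] *
                           v[, seq_len(m) + k, drop = FALSE]) / m
  }
  labels <- paste0(rep(table$property_ids, each = order), ".lag",
                   rep(seq_len(order), np))
  feature_vector(as.vector(t(vals)), labels, "acf", list(order = order))
}

scheme_dimension <- function(scheme, params = list()) {
  switch(scheme,
         aac = 20L, dpc = 400L, gpc = 400L, ctd = 310L,
         pseaac = 20L + as.integer(params$lambda %||% 1L),
         acf = 531L * as.integer(params$order %||% 1L),
         stop("unknown scheme: ", scheme))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a protein set as a feature matrix
#'
#' Applies one feature scheme to every sequence of a set, producing a dense
#' numeric matrix with one row per sequence (row names = sequence ids) and
#' one column per descriptor in the scheme's fixed order. All sequences are
#' checked against the scheme's length precondition first; any violation
#' aborts with the offending ids and no partial matrix is returned.
#'
#' @param x A [protein_set()] whose sequences use only standard residues.
#' @param scheme One of `"aac"`, `"dpc"`, `"gpc"`, `"pseaac"`, `"ctd"`,
#'   `"acf"`.
#' @param gap,lambda,w,order Scheme parameters, forwarded to the encoder.
#' @param table AAindex table for `scheme = "acf"`.
#' @return A `feature_matrix`: numeric matrix with attributes `scheme` and
#'   `params`.
#' @export
#' @examples
#' ps <- protein_set(c("a", "b"), c("MKVACDG", "ACDGACDG"))
#' dim(encode_dataset(ps, "ctd"))
encode_dataset <- function(x, scheme = c("ctd", "aac", "dpc", "gpc",
                                         "pseaac", "acf"),
                           gap = 1L, lambda = 1L, w = 0.05,
                           table = NULL, order = 1L) {
  stopifnot(inherits(x, "protein_set"))
  scheme <- match.arg(scheme)
  if (!nrow(x)) stop("empty dataset")
  params <- switch(scheme,
                   gpc = list(gap = as.integer(gap)),
                   pseaac = list(lambda = as.integer(lambda), w = w),
                   acf = list(order = as.integer(order)),
                   list())
  min_len <- switch(scheme, aac = 1L, dpc = 2L, ctd = 2L,
                    gpc = as.integer(gap) + 2L,
                    pseaac = as.integer(lambda) + 1L,
                    acf = as.integer(order) + 1L)
  lens <- nchar(x$residues)
  bad <- x$id[lens < min_len]
  if (length(bad))
    stop(sprintf("sequences too short for scheme '%s' (min length %d): %s",
                 scheme, min_len, paste(bad, collapse = ", ")))
  if (scheme == "acf" && is.null(table)) table <- aaindex_table()
  enc <- switch(scheme,
                aac = function(s) compute_aac(s),
                dpc = function(s) compute_dpc(s),
                gpc = function(s) compute_gpc(s, gap = gap),
                pseaac = function(s) compute_pseaac(s, lambda = lambda, w = w),
                ctd = function(s) compute_ctd(s),
                acf = function(s) compute_acf(s, table = table, order = order))
  rows <- lapply(x$residues, enc)
  mat <- do.call(rbind, rows)
  rownames(mat) <- x$id
  colnames(mat) <- names(rows[[1]])
  attr(mat, "scheme") <- scheme
  attr(mat, "params") <- params
  class(mat) <- c("feature_matrix", class(mat))
  mat
}

#' Write a feature matrix to a TSV file
#'
#' @param mat A `feature_matrix` from [encode_dataset()].
#' @param path Output path; columns are the descriptor labels, first
#'   column `id`.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
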