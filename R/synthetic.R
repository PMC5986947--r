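# Residues receiving extra mass in the shifted class of two_class_dataset.
# Fixed so the separability behaviour of the fixtures is stable.
SHIFT_RESIDUES <- c("A", "C", "D", "E", "G")

# Disjoint residue pairs enriched per class in multiclass_dataset.
CLASS_PAIRS <- list(c("A", "C"), c("D", "E"), c("F", "G"), c("H", "I"),
                    c("K", "L"), c("M", "N"), c("P", "Q"), c("R", "S"),
                    c("T", "V"), c("W", "Y"))

# All generators pin the RNG algorithm so fixtures are byte-identical
# across platforms and R sessions.
seed_rng <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Construct a residue composition profile
#'
#' @param probs 20 non-negative values in canonical alphabet order;
#'   normalized to sum to 1.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' composition_profile()  # uniform
composition_profile <- function(probs = rep(1, 20)) {
  stopifnot(length(probs) == 20L, all(probs >= 0), sum(probs) > 0)
  stats::setNames(probs / sum(probs), AA_ALPHABET)
}

#' Generate random protein sequences
#'
#' Draws `n` sequences with i.i.d. residues from a composition profile and
#' lengths uniform on `length_range`. Deterministic under `seed` (the RNG
#' algorithm is pinned). Ids are `syn_1`, `syn_2`, ...
#'
#' @param n Number of sequences (>= 0).
#' @param length_range Integer vector `c(min, max)`, min >= 1.
#' @param profile A [composition_profile()] (default uniform).
#' @param seed Integer seed.
#' @param prefix Id prefix (default `"syn"`).
#' @return A [protein_set()].
#' @export
#' @examples
#' random_sequences(3, c(10, 15), seed = 1)
random_sequences <- function(n, length_range = c(150L, 250L),
                             profile = composition_profile(), seed = 1L,
                             prefix = "syn") {
  stopifnot(n >= 0, length(length_range) == 2L,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (n == 0)
    return(protein_set(character(), character()))
  profile <- composition_profile(profile)
  seed_rng(seed)
  span <- seq.int(length_range[1], length_range[2])
  lens <- span[sample.int(length(span), n, replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = profile),
          collapse = "")
  }, character(1))
  protein_set(paste0(prefix, "_", seq_len(n)), seqs)
}

labeled_dataset <- function(sequences, labels) {
  stopifnot(inherits(sequences, "protein_set"),
            length(labels) == nrow(sequences))
  out <- list(sequences = sequences, labels = as.character(labels))
  class(out) <- "labeled_dataset"
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d sequences in %d classes (%s)\n",
              nrow(x$sequences), length(unique(x$labels)),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Generate a two-class dataset with tunable composition signal
#'
#' Class `A` draws residues from the uniform composition; class `B` shifts
#' probability mass `delta` onto a fixed five-residue subset
#' (A, C, D, E, G; renormalized). `delta = 0` yields two statistically
#' indistinguishable classes (the null fixture for chance-level
#' cross-validation); `delta >= 0.3` yields classes separable from amino
#' acid composition with high probability at typical fixture sizes
#' (100 sequences per class, lengths around 200).
#'
#' @param n_per_class Sequences per class.
#' @param delta Composition shift in `[0, 1]`.
#' @param seed Integer seed.
#' @param length_range Sequence length range (default 150-250).
#' @return A `labeled_dataset` with classes `"A"` and `"B"`.
#' @export
two_class_dataset <- function(n_per_class, delta = 0.3, seed = 1L,
                              length_range = c(150L, 250L)) {
  stopifnot(delta >= 0, delta <= 1)
  pa <- composition_profile()
  pb <- rep(1 / 20, 20)
  names(pb) <- AA_ALPHABET
  pb[SHIFT_RESIDUES] <- pb[SHIFT_RESIDUES] + delta / length(SHIFT_RESIDUES)
  pb <- composition_profile(pb)
  a <- random_sequences(n_per_class, length_range, pa, seed = seed,
                        prefix = "synA")
  b <- random_sequences(n_per_class, length_range, pb, seed = seed + 1L,
                        prefix = "synB")
  seqs <- rbind(a, b)
  class(seqs) <- c("protein_set", "data.frame")
  labeled_dataset(seqs, rep(c("A", "B"), each = n_per_class))
}

# One sequence from a first-order Markov construction: residues come from
# the class profile, but after a residue of the enriched pair the next
# residue is drawn from the pair with probability `bias`, creating
# class-specific adjacent-pair structure.
markov_sequence <- function(L, profile, pair, bias) {
  pair_idx <- match(pair, AA_ALPHABET)
  idx <- integer(L)
  idx[1] <- sample.int(20L, 1L, prob = profile)
  for (t in 2:L) {
    if (bias > 0 && idx[t - 1] %in% pair_idx &&
        stats::runif(1) < bias)
      idx[t] <- pair_idx[sample.int(2L, 1L)]
    else
      idx[t] <- sample.int(20L, 1L, prob = profile)
  }
  paste(AA_ALPHABET[idx], collapse = "")
}

#' Generate a multi-class dataset emulating nif gene categories
#'
#' Each class enriches a distinct residue pair (class 1: A/C, class 2:
#' D/E, ...) in its composition and additionally biases first-order
#' transitions into that pair, so di-peptide and transition descriptors
#' carry class information beyond plain composition. `signal = 0` gives
#' identically distributed classes (chance-level fixture); `signal >= 0.5`
#' gives classes separable at small sample sizes. With six classes the
#' labels are the six nif categories, standing in for real nif protein
#' families.
#'
#' @param n_per_class Sequences per class.
#' @param n_classes Number of classes (2-10, default 6).
#' @param signal Class-signal strength >= 0.
#' @param seed Integer seed.
#' @param length_range Sequence length range (default 150-250).
#' @return A `labeled_dataset`.
#' @export
multiclass_dataset <- function(n_per_class, n_classes = 6L, signal = 0.5,
                               seed = 1L, length_range = c(150L, 250L)) {
  stopifnot(n_classes >= 2L, n_classes <= length(CLASS_PAIRS), signal >= 0)
  class_names <- if (n_classes == 6L) NIF_CATEGORIES
                 else paste0("class", seq_len(n_classes))
  bias <- min(1, signal)
  all_seqs <- character(0)
  all_ids <- character(0)
  labels <- character(0)
  for (cl in seq_len(n_classes)) {
    pair <- CLASS_PAIRS[[cl]]
    p <- rep(1 / 20, 20)
    names(p) <- AA_ALPHABET
    p[pair] <- p[pair] + signal / 2
    p <- composition_profile(p)
    seed_rng(seed + cl)
    span <- seq.int(length_range[1], length_range[2])
    lens <- span[sample.int(length(span), n_per_class, replace = TRUE)]
    seqs <- vapply(lens, markov_sequence, character(1),
                   profile = p, pair = pair, bias = bias)
    all_seqs <- c(all_seqs, seqs)
    all_ids <- c(all_ids, paste0("syn_", class_names[cl], "_",
                                 seq_len(n_per_class)))
    labels <- c(labels, rep(class_names[cl], n_per_class))
  }
  labeled_dataset(protein_set(all_ids, all_seqs), labels)
}

#' Write a labeled dataset as one FASTA file per class
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_labeled_fasta <- function(dataset, dir) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  classes <- unique(dataset$labels)
  paths <- stats::setNames(file.path(dir, paste0(classes, ".fasta")),
                           classes)
  for (cl in classes) {
    sub <- dataset$sequences[dataset$labels == cl, , drop = FALSE]
    write_fasta(sub, paths[[cl]])
  }
  invisible(paths)
}
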