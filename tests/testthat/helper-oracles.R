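# Independent brute-force oracles the implementation is checked against.
# These deliberately use naive counting over string pairs, not the index
# arithmetic of the package encoders.

ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_aac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  vapply(ALPHA, function(a) sum(ch == a), numeric(1)) / nchar(s)
}

oracle_pair_comp <- function(s, gap) {
  # frequency of ordered pairs at offset gap + 1, counted as pair strings
  # (independent of the package's index arithmetic), labels row-major
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  m <- n - gap - 1L
  pairs <- paste0(ch[seq_len(m)], ch[seq_len(m) + gap + 1L])
  labels <- as.vector(t(outer(ALPHA, ALPHA, paste0)))
  as.vector(table(factor(pairs, levels = labels))) / m
}

oracle_dpc <- function(s) oracle_pair_comp(s, 0L)

oracle_ctd_transition <- function(s) {
  # unordered hetero pairs counted in both orders, denominator N - 1
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  labels <- character(0)
  for (i in 1:19) labels <- c(labels, paste0(ALPHA[i], ALPHA[(i + 1):20]))
  a <- ch[-n]; b <- ch[-1]
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  key <- key[a != b]
  as.vector(table(factor(key, levels = labels))) / (n - 1)
}

# classical confusion-matrix metrics from TP/FP/TN/FN
oracle_classical_metrics <- function(Np, Nn, Npn, Nnp) {
  TP <- as.numeric(Np - Nnp); FN <- as.numeric(Nnp)
  FP <- as.numeric(Npn); TN <- as.numeric(Nn - Npn)
  c(Sn = TP / (TP + FN),
    Sp = TN / (TN + FP),
    Ac = (TP + TN) / (TP + TN + FP + FN),
    Pre = TP / (TP + FP),
    MCC = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

# AUC by exhaustive concordant-pair counting, ties count one half
oracle_auc <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random valid residue string
random_residue_string <- function(len) {
  paste(sample(ALPHA, len, replace = TRUE), collapse = "")
}
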