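#' Fit a two-stage nif protein classifier
#'
#' Trains the two-stage prediction flow for nitrogen-fixation proteins:
#' stage 1 is a binary SVM separating nif from non-nif sequences, trained
#' on the pooled nif classes against the non-nif set; stage 2 is a
#' multi-class SVM distinguishing the six nif gene categories, trained on
#' the labeled nif sequences only. Both stages share one feature encoder
#' (composition-transition-distribution by default) and one kernel
#' (radial by default), so each query sequence is encoded once and scored
#' by both stages.
#'
#' At prediction time a query is first called nif or non-nif by stage-1
#' argmax; only stage-1 nif calls are passed to stage 2, where the best
#' category is assigned if its probability reaches the threshold `tau`
#' (default 0.4) and reported as `"unassigned"` otherwise.
#'
#' @param nif A [protein_set()] of nif sequences.
#' @param nif_labels Category label per nif sequence (e.g. `"nifH"`);
#'   at least two sequences per category.
#' @param non_nif A [protein_set()] of non-nif sequences.
#' @param scheme Feature scheme shared by both stages (default `"ctd"`).
#' @param kernel A [kernel_spec()] or kernel name (default radial).
#' @param tau Stage-2 probability threshold in `[0, 1]` (default 0.4).
#' @param seed Integer seed governing both fits.
#' @param ... Scheme parameters forwarded to [encode_dataset()]
#'   (`gap`, `lambda`, `w`, `order`, `table`).
#' @return A `nif_model` with components `stage1`, `stage2` (both
#'   `nif_svm`), `tau`, `scheme`, `params` and `categories`.
#' @seealso [predict.nif_model()], [top_k_report()],
#'   [write_prediction_table()], [save_model()].
#' @export
#' @examples
#' \donttest{
#' train <- multiclass_dataset(n_per_class = 10, signal = 0.6, seed = 1)
#' bg <- random_sequences(30, c(120, 200), seed = 2)
#' fit <- nif_model(train$sequences, train$labels, bg, seed = 3)
#' fit
#' }
nif_model <- function(nif, nif_labels, non_nif, scheme = "ctd",
                      kernel = kernel_spec("radial"), tau = 0.4,
                      seed = 1L, ...) {
  stopifnot(inherits(nif, "protein_set"), inherits(non_nif, "protein_set"),
            tau >= 0, tau <= 1)
  if (nrow(non_nif) == 0L) stop("non-nif training set is empty")
  nif_labels <- as.character(nif_labels)
  if (length(nif_labels) != nrow(nif))
    stop("one label per nif sequence required")
  tab <- table(nif_labels)
  if (any(tab < 2L))
    stop("nif categories with fewer than 2 sequences: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  kernel <- as_kernel_spec(kernel)
  x_nif <- encode_dataset(nif, scheme, ...)
  x_non <- encode_dataset(non_nif, scheme, ...)
  x1 <- rbind(x_nif, x_non)
  y1 <- rep(c("nif", "non-nif"), c(nrow(x_nif), nrow(x_non)))
  stage1 <- train_svm(x1, y1, kernel = kernel, seed = seed)
  stage2 <- train_svm(x_nif, nif_labels, kernel = kernel, seed = seed + 1L)
  stage1$scheme <- stage2$scheme <- scheme
  stage1$params <- stage2$params <- attr(x_nif, "params")
  out <- list(stage1 = stage1, stage2 = stage2, tau = tau,
              scheme = scheme, params = attr(x_nif, "params"),
              categories = stage2$class_labels, seed = seed,
              n_train = c(nif = nrow(x_nif), `non-nif` = nrow(x_non)))
  class(out) <- "nif_model"
  out
}

#' @export
print.nif_model <- function(x, ...) {
  cat("Two-stage nif protein classifier\n")
  cat(sprintf("  encoder: %s%s; kernel: %s; tau = %g\n", x$scheme,
              if (length(x$params))
                paste0(" (", paste(names(x$params), unlist(x$params),
                                   sep = " = ", collapse = ", "), ")")
              else "",
              x$stage1$kernel$name, x$tau))
  cat(sprintf("  stage 1: nif vs non-nif, trained on %d + %d sequences\n",
              x$n_train[["nif"]], x$n_train[["non-nif"]]))
  cat(sprintf("  stage 2: %s\n", paste(x$categories, collapse = ", ")))
  invisible(x)
}

#' @export
summary.nif_model <- function(object, ...) {
  print(object)
  cat(sprintf("  stage-1 support vectors: %d; stage-2 support vectors: %d\n",
              object$stage1$fit$tot.nSV, object$stage2$fit$tot.nSV))
  invisible(object)
}

#' Predict nif categories for protein sequences
#'
#' Runs the two-stage flow on a set of query sequences. Every input
#' yields exactly one record. Sequences the encoder cannot handle (e.g.
#' non-standard residues or too short for the scheme) are reported with
#' `stage1_label = NA` and an error message; the remaining sequences are
#' still processed.
#'
#' @param object A `nif_model`.
#' @param newdata A [protein_set()] of query sequences.
#' @param tau Stage-2 probability threshold; defaults to the model's.
#' @param ... Unused.
#' @return A data frame of class `nif_predictions`, one row per input
#'   sequence, with columns `id`, `stage1_label` (`"nif"`/`"non-nif"`),
#'   `stage1_prob` (probability of nif), `category` (one of the six nif
#'   categories, or `NA` for non-nif calls and for stage-1 positives
#'   below threshold), `category_prob` (best stage-2 probability for
#'   stage-1 nif calls, `NA` otherwise) and `error`. The number of
#'   failed sequences is in attribute `n_errors`.
#' @export
predict.nif_model <- function(object, newdata, tau = object$tau, ...) {
  stopifnot(inherits(newdata, "protein_set"), tau >= 0, tau <= 1)
  n <- nrow(newdata)
  rec <- data.frame(id = newdata$id,
                    stage1_label = NA_character_,
                    stage1_prob = NA_real_,
                    category = NA_character_,
                    category_prob = NA_real_,
                    error = NA_character_,
                    stringsAsFactors = FALSE)
  ok <- logical(n)
  xs <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- tryCatch(encode_dataset(newdata[i, ], object$scheme,
                                  gap = object$params$gap %||% 1L,
                                  lambda = object$params$lambda %||% 1L,
                                  w = object$params$w %||% 0.05,
                                  order = object$params$order %||% 1L),
                   error = function(e) conditionMessage(e))
    if (is.character(xi)) rec$error[i] <- xi
    else { ok[i] <- TRUE; xs[[i]] <- xi }
  }
  if (any(ok)) {
    x <- do.call(rbind, xs[ok])
    rownames(x) <- rec$id[ok]
    s1 <- predict_scores(object$stage1, x)
    rec$stage1_label[ok] <- s1$label
    rec$stage1_prob[ok] <- s1[["prob.nif"]]
    is_nif <- which(ok)[s1$label == "nif"]
    if (length(is_nif)) {
      s2 <- predict_scores(object$stage2,
                           x[s1$label == "nif", , drop = FALSE])
      rec$category_prob[is_nif] <- s2$prob_max
      assigned <- s2$prob_max >= tau
      rec$category[is_nif[assigned]] <- s2$label[assigned]
    }
  }
  attr(rec, "n_errors") <- sum(!is.na(rec$error))
  attr(rec, "tau") <- tau
  class(rec) <- c("nif_predictions", "data.frame")
  rec
}

# subsetting a protein_set must keep its class
#' @export
`[.protein_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("protein_set", "data.frame")
  out
}

#' @export
print.nif_predictions <- function(x, ...) {
  cat(sprintf("nif predictions for %d sequence%s (tau = %g): %d nif, %d non-nif, %d categorized, %d errors\n",
              nrow(x), if (nrow(x) == 1) "" else "s", attr(x, "tau"),
              sum(x$stage1_label == "nif", na.rm = TRUE),
              sum(x$stage1_label == "non-nif", na.rm = TRUE),
              sum(!is.na(x$category)),
              attr(x, "n_errors") %||% 0L))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Top-k predictions per nif category
#'
#' For each nif category, returns up to `k` prediction records with the
#' highest category probability (ties broken by input order). Only
#' records with an assigned category participate; categories with no
#' assigned record are absent from the result.
#'
#' @param records A `nif_predictions` data frame from
#'   [predict.nif_model()].
#' @param k Maximum records per category (default 3).
#' @return Named list mapping category to a data frame of up to `k`
#'   records, ordered by decreasing probability.
#' @export
top_k_report <- function(records, k = 3L) {
  stopifnot(is.data.frame(records), k >= 1)
  assigned <- records[!is.na(records$category), , drop = FALSE]
  out <- list()
  for (cat_ in unique(assigned$category)) {
    sub <- assigned[assigned$category == cat_, , drop = FALSE]
    ord <- order(-sub$category_prob)  # stable: ties keep input order
    out[[cat_]] <- sub[utils::head(ord, k), , drop = FALSE]
  }
  out[order(names(out))]
}
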