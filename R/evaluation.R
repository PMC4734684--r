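# Evaluation metrics and the leave-one-out verification protocol.

#' Prediction-quality coefficient (1 - SSE/SST)
#'
#' `pcc(e, p) = 1 - sum((e - p)^2) / sum((e - mean(e))^2)`.  Despite the
#' field's habit of calling this quantity a "correlation coefficient", it
#' is a coefficient-of-determination-type statistic: 1 for a perfect
#' predictor, 0 for the constant-mean predictor, and negative when
#' predictions do worse than the mean.  The genuine product-moment
#' correlation is reported alongside by [loocv_evaluate()] as `pearson_r`.
#'
#' @param e Measured affinities (length >= 2, not all equal).
#' @param p Predicted affinities, same length.
#' @return A single number <= 1.
#' @examples
#' pcc(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
pcc <- function(e, p) {
  stopifnot(length(e) == length(p), length(e) >= 2L,
            all(is.finite(e)), all(is.finite(p)))
  sst <- sum((e - mean(e))^2)
  if (sst == 0) stop("measured affinities are constant; PCC undefined")
  1 - sum((e - p)^2) / sst
}

#' Root mean squared error
#'
#' @inheritParams pcc
#' @return `sqrt(mean((e - p)^2))`, in the units of the affinities.
#' @export
rmse <- function(e, p) {
  stopifnot(length(e) == length(p), length(e) >= 1L,
            all(is.finite(e)), all(is.finite(p)))
  sqrt(mean((e - p)^2))
}

#' Precision and recall of a predicted binder set
#'
#' @param predicted Character vector of predicted motif strings (non-empty).
#' @param reference Character vector of reference motif strings (non-empty).
#' @return List with `precision` (= |intersection| / |predicted|) and
#'   `recall` (= |intersection| / |reference|); duplicates are dropped.
#' @examples
#' # 30 shared out of 51 predicted and 46 reference binders
#' # gives precision 0.588, recall 0.652
#' @export
precision_recall <- function(predicted, reference) {
  predicted <- unique(predicted)
  reference <- unique(reference)
  if (length(predicted) == 0L) stop("empty predicted set: precision undefined")
  if (length(reference) == 0L) stop("empty reference set: recall undefined")
  hit <- length(intersect(predicted, reference))
  list(precision = hit / length(predicted), recall = hit / length(reference))
}

#' Leave-one-out verification of the per-query predictor
#'
#' For every record: hold it out, select relevant motifs among the
#' remaining same-terminal records, fit the per-query elastic net
#' (cross-validated alpha and lambda), and predict the held-out affinity.
#' Metrics are then computed per terminal over all held-out predictions.
#'
#' @param records Data.frame of affinity records from one or both
#'   terminals, all with measured affinities.
#' @param config An [en_config()]; fewer than `config$min_train`
#'   same-terminal records is an error (cross-validation would be
#'   meaningless).
#' @return Data.frame with one row per terminal: `terminal`, `n`, `pcc`,
#'   `rmse`, `pearson_r`.  The per-motif held-out predictions are attached
#'   as attribute `"predictions"`.
#' @export
loocv_evaluate <- function(records, config = en_config()) {
  stopifnot(nrow(records) >= 2L, !any(is.na(records$affinity)))
  out <- list()
  preds <- list()
  for (term in intersect(c("N", "C"), unique(records$terminal))) {
    rec <- records[records$terminal == term, , drop = FALSE]
    n <- nrow(rec)
    if (n < config$min_train) {
      stop("only ", n, " ", term, "-terminal records; need at least ",
           config$min_train, " for leave-one-out cross-validation")
    }
    categories <- aa_category_table()
    Xall <- featurize_motifs(rec$sequence)
    res <- motif_residues(rec$sequence)
    p <- numeric(n)
    for (i in seq_len(n)) {
      r <- predict_one(res[i, ], Xall[i, ], res[-i, , drop = FALSE],
                       Xall[-i, , drop = FALSE], rec$affinity[-i],
                       categories, config,
                       derive_seed(config$seed, motif_key(res[i, ])))
      p[i] <- r$pred
    }
    out[[term]] <- data.frame(
      terminal = term, n = n, pcc = pcc(rec$affinity, p),
      rmse = rmse(rec$affinity, p),
      pearson_r = stats::cor(rec$affinity, p), stringsAsFactors = FALSE)
    preds[[term]] <- data.frame(rec[, c("motif_id", "terminal", "sequence")],
                                measured = rec$affinity, predicted = p,
                                stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "predictions") <- do.call(rbind, c(preds, make.row.names = FALSE))
  res
}
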