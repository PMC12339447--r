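#' Classification metrics for a binary prediction set
#'
#' AMD is the positive class. Accuracy and F1 use the 0.5 threshold on the
#' AMD probability (the argmax of a two-class softmax); AUC-ROC is the
#' Mann-Whitney statistic with half credit for score ties; AUC-PR is
#' step-interpolated average precision. With a single-class truth vector the
#' ranking metrics are reported as `NA` with `undefined = TRUE` rather than a
#' silent 0.
#'
#' @param y_true 0/1 vector (1 = AMD).
#' @param scores AMD probabilities in `[0, 1]`.
#' @param threshold decision threshold on the AMD probability.
#' @return list with `accuracy`, `auroc`, `aupr`, `f1`, confusion counts
#'   `tp`, `tn`, `fp`, `fn`, `n`, and `undefined`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) != length(scores))
    data_error("y_true and scores must have equal length")
  if (any(!is.finite(scores))) data_error("scores must be finite")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  n <- length(y_true)
  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  single <- length(unique(y_true)) < 2L
  list(accuracy = acc,
       auroc = if (single) NA_real_ else auroc_score(y_true, scores),
       aupr = if (single) NA_real_ else aupr_score(y_true, scores),
       f1 = f1, tp = tp, tn = tn, fp = fp, fn = fn, n = n,
       undefined = single)
}

#' @rdname compute_metrics
#' @export
auroc_score <- function(y_true, scores) {
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) data_error("auroc needs both classes")
  r <- rank(scores)  # mid-ranks give ties half credit
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname compute_metrics
#' @export
aupr_score <- function(y_true, scores) {
  n1 <- sum(y_true == 1L)
  if (n1 == 0L || all(y_true == 1L)) data_error("aupr needs both classes")
  # group tied scores at one threshold (descending)
  ord <- order(-scores)
  s <- scores[ord]; y <- y_true[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1, length(y)), grp, sum)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  rec <- tp_cum / n1
  drec <- diff(c(0, rec))
  sum(prec * drec)
}

#' Cross-dataset evaluation matrix
#'
#' Evaluates one trained classifier on each held-out test source, auditing by
#' image id that no test image was seen during training.
#'
#' @param ckpt a `classifier_checkpoint`.
#' @param tests named list (source -> binary-labeled test `oct_manifest`).
#' @param images,root image access as in [pretrain()].
#' @return an `eval_report`: named list of metric records (one per source),
#'   with the training provenance attached.
#' @export
cross_evaluate <- function(ckpt, tests, images = NULL, root = NULL) {
  if (!length(tests)) data_error("no test sets given")
  out <- list()
  for (s in names(tests)) {
    man <- tests[[s]]
    if (any(man$image_id %in% ckpt$train_ids))
      data_error(sprintf("leakage: test source %s shares images with training", s))
    preds <- predict_classifier(ckpt, man, images, root)
    out[[s]] <- compute_metrics(preds$y_true, preds$score)
  }
  structure(out, class = "eval_report",
            train_provenance = ckpt$provenance)
}

#' Serialize / read an evaluation report as JSON
#'
#' @param report an `eval_report` (or list of them keyed by train source).
#' @param path JSON file path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(lapply(report, function(r) r[setdiff(names(r), "undefined")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Exact Wilcoxon signed-rank test (tie-aware, enumerated null)
#'
#' Paired two-sided test on `b - a`. Zero differences are dropped (the
#' classical treatment); tied absolute differences receive mid-ranks; the
#' null distribution of the positive-rank sum is computed over all
#' `2^n` equiprobable sign assignments of the realized rank values, so the
#' p-value is exact even under ties. The two-sided p is
#' `2 * min(P(W+ <= w), P(W+ >= w))` capped at 1.
#'
#' @param a,b equal-length paired metric vectors (e.g. per-cell AUC-ROC of
#'   two models).
#' @return a `paired_comparison`: list with `differences`, `n_effective`,
#'   `W` (min of positive/negative rank sums), `w_pos`, and `p_two_sided`.
#' @export
wilcoxon_signed_rank_exact <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    data_error("a and b must be paired vectors of length >= 2")
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) data_error("no nonzero differences")
  if (n > 30L) data_error("exact enumeration limited to 30 nonzero pairs")
  r <- rank(abs(d))            # mid-ranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  # distribution of W+ over all 2^n sign assignments; mid-ranks are
  # multiples of 1/2, so doubling gives integer support
  r2 <- as.integer(round(2 * r))
  counts <- c(1, rep(0, sum(r2)))  # counts[s + 1] = #assignments with sum s
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  total <- 2^n
  w2 <- round(2 * w_pos)
  p_le <- sum(counts[seq_len(w2 + 1)]) / total
  p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(differences = d, n_effective = n,
                 W = min(w_pos, w_neg), w_pos = w_pos,
                 p_two_sided = p),
            class = "paired_comparison")
}

#' Count trainable parameters
#'
#' @param model an `rt_mae`, `rt_classifier`, checkpoint, or `rt_baseline`.
#' @return integer parameter count; `millions` attribute gives the count in
#'   millions at one decimal.
#' @export
count_parameters <- function(model) {
  n <- if (inherits(model, "rt_baseline")) sum(model$layers$n_params)
       else sum(vapply(model$params, length, numeric(1)))
  structure(as.integer(n), millions = round(n / 1e6, 1))
}
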