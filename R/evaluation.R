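# Detection evaluation: IoU matching of predictions to expert truth,
# counted/overlooked/overcounted bookkeeping, recall and precision.

#' Intersection over union of two pixel sets
#'
#' `mode = "union"` is the standard IoU, `|A ∩ B| / |A ∪ B|`.
#' `mode = "sum"` divides the overlap by the sum of the two areas,
#' `|A ∩ B| / (|A| + |B|)`, an alternative overlap ratio some
#' protocols describe; identical sets then score 0.5 rather than 1.
#'
#' @param pixels_a,pixels_b non-empty [pixel_set()]s.
#' @param mode `"union"` (default) or `"sum"`.
#' @return overlap ratio in `[0, 1]` (`[0, 0.5]` for `"sum"`).
#' @export
iou <- function(pixels_a, pixels_b, mode = c("union", "sum")) {
  mode <- match.arg(mode)
  stop_if(is.null(pixels_a) || nrow(pixels_a) == 0 ||
            is.null(pixels_b) || nrow(pixels_b) == 0,
          "pixel sets must be non-empty")
  ka <- paste(pixels_a[, "x"], pixels_a[, "y"])
  kb <- paste(pixels_b[, "x"], pixels_b[, "y"])
  inter <- sum(ka %in% kb)
  if (mode == "union") inter / (length(ka) + length(kb) - inter)
  else inter / (length(ka) + length(kb))
}

# IoU matrix between two lists of pixel sets, with a bounding-box
# prefilter so disjoint pairs cost nothing
iou_matrix <- function(preds, truths, mode = "union") {
  M <- matrix(0, nrow = length(preds), ncol = length(truths))
  if (!length(preds) || !length(truths)) return(M)
  bb <- function(p) c(min(p[, "x"]), max(p[, "x"]), min(p[, "y"]), max(p[, "y"]))
  bp <- lapply(preds, bb); bt <- lapply(truths, bb)
  for (i in seq_along(preds)) for (j in seq_along(truths)) {
    a <- bp[[i]]; b <- bt[[j]]
    if (a[1] > b[2] || b[1] > a[2] || a[3] > b[4] || b[3] > a[4]) next
    M[i, j] <- iou(preds[[i]], truths[[j]], mode)
  }
  M
}

#' Match predicted fibers to ground-truth fibers by IoU
#'
#' One-to-one matching: candidate pairs with IoU at or above
#' `iou_threshold` are accepted greedily in descending IoU order (ties
#' broken by smaller prediction index, then smaller truth index).
#' Matched pairs are true positives; unmatched truths are overlooked
#' (false negatives); unmatched predictions are overcounted (false
#' positives). `method = "optimal"` replaces the greedy order with an
#' exhaustive search maximizing the number of qualified matches (audit
#' use; exponential, capped at 10 x 10).
#'
#' @param predictions,truth lists of [pixel_set()]s.
#' @param iou_threshold matching threshold in `(0, 1]` (default 0.5).
#' @param mode IoU mode passed to [iou()].
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return list with `tp`, `fn`, `fp` (counts), `matches` (data.frame
#'   prediction, truth, iou), `unmatched_truth`, `unmatched_pred`
#'   (index vectors).
#' @export
match_detections <- function(predictions, truth, iou_threshold = 0.5,
                             mode = c("union", "sum"),
                             method = c("greedy", "optimal")) {
  mode <- match.arg(mode); method <- match.arg(method)
  stop_if(iou_threshold <= 0 || iou_threshold > 1,
          "iou_threshold must lie in (0, 1]")
  M <- iou_matrix(predictions, truth, mode)
  qual <- which(M >= iou_threshold, arr.ind = TRUE)
  pairs <- if (nrow(qual))
    data.frame(prediction = qual[, 1], truth = qual[, 2],
               iou = M[qual])
  else data.frame(prediction = integer(0), truth = integer(0),
                  iou = numeric(0))
  matches <- if (method == "greedy") {
    ord <- order(-pairs$iou, pairs$prediction, pairs$truth)
    used_p <- logical(length(predictions))
    used_t <- logical(length(truth))
    keep <- integer(0)
    for (k in ord) {
      i <- pairs$prediction[k]; j <- pairs$truth[k]
      if (!used_p[i] && !used_t[j]) {
        used_p[i] <- TRUE; used_t[j] <- TRUE
        keep <- c(keep, k)
      }
    }
    pairs[keep, , drop = FALSE]
  } else {
    stop_if(length(predictions) > 10 || length(truth) > 10,
            "optimal matching capped at 10 x 10 instances")
    best_assignment(pairs)
  }
  tp <- nrow(matches)
  list(tp = tp,
       fn = length(truth) - tp,
       fp = length(predictions) - tp,
       matches = matches[order(matches$prediction), , drop = FALSE],
       unmatched_truth = setdiff(seq_along(truth), matches$truth),
       unmatched_pred = setdiff(seq_along(predictions), matches$prediction))
}

# exhaustive one-to-one assignment maximizing (n matches, total IoU)
best_assignment <- function(pairs) {
  best <- pairs[0, ]
  recurse <- function(k, chosen) {
    if (k > nrow(pairs)) {
      cur <- pairs[chosen, , drop = FALSE]
      if (nrow(cur) > nrow(best) ||
          (nrow(cur) == nrow(best) && sum(cur$iou) > sum(best$iou)))
        best <<- cur
      return(invisible())
    }
    recurse(k + 1, chosen)  # skip pair k
    cur <- pairs[chosen, , drop = FALSE]
    if (!(pairs$prediction[k] %in% cur$prediction) &&
        !(pairs$truth[k] %in% cur$truth))
      recurse(k + 1, c(chosen, k))
    invisible()
  }
  recurse(1, integer(0))
  best
}

#' Recall (sensitivity of fiber detection)
#'
#' `tp / (tp + fn)`: the fraction of expert-counted fibers the model
#' detected. Returns `NA` when no fibers were expert-counted
#' (`tp + fn == 0`).
#'
#' @param tp,fn non-negative counts.
#' @return real in `[0, 1]`, or `NA` if undefined.
#' @export
recall <- function(tp, fn) {
  stop_if(tp < 0 || fn < 0, "counts must be non-negative")
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Precision of fiber detection
#'
#' `tp / (tp + fp)`: the fraction of model detections the expert also
#' counted. Returns `NA` when the model made no detections
#' (`tp + fp == 0`).
#'
#' @param tp,fp non-negative counts.
#' @return real in `[0, 1]`, or `NA` if undefined.
#' @export
precision <- function(tp, fp) {
  stop_if(tp < 0 || fp < 0, "counts must be non-negative")
  if (tp + fp == 0) return(NA_real_)
  tp / (tp + fp)
}

#' Pool per-image match results into a detection report
#'
#' Builds the standard per-image bookkeeping table — expert count,
#' counted (tp + fp detections), overlooked (fn), overcounted (fp) —
#' adds a totals row, and computes micro-averaged recall and precision
#' from the summed tp/fn/fp. Percentages are rounded half-up to
#' integers.
#'
#' @param per_image named list (names = image ids) of results from
#'   [match_detections()], or a data.frame with columns `image`,
#'   `expert_count`, `counted`, `overlooked`, `overcounted`.
#' @return object of class `match_report`: `per_image` data.frame,
#'   `totals` row, `tp`, `fn`, `fp`, `recall`, `precision`,
#'   `recall_pct`, `precision_pct`.
#' @export
tabulate_matches <- function(per_image) {
  if (is.data.frame(per_image)) {
    df <- per_image
    stop_if(!all(c("image", "expert_count", "counted", "overlooked",
                   "overcounted") %in% names(df)),
            "missing bookkeeping columns")
    tp <- sum(df$counted) - sum(df$overcounted)
    fn <- sum(df$overlooked); fp <- sum(df$overcounted)
  } else {
    stop_if(length(per_image) == 0, "need at least one per-image result")
    ids <- names(per_image) %||% as.character(seq_along(per_image))
    df <- do.call(rbind, lapply(seq_along(per_image), function(i) {
      m <- per_image[[i]]
      data.frame(image = ids[i],
                 expert_count = m$tp + m$fn,
                 counted = m$tp + m$fp,
                 overlooked = m$fn,
                 overcounted = m$fp)
    }))
    tp <- sum(vapply(per_image, `[[`, 0, "tp"))
    fn <- sum(vapply(per_image, `[[`, 0, "fn"))
    fp <- sum(vapply(per_image, `[[`, 0, "fp"))
  }
  totals <- data.frame(image = "Total",
                       expert_count = sum(df$expert_count),
                       counted = sum(df$counted),
                       overlooked = sum(df$overlooked),
                       overcounted = sum(df$overcounted))
  r <- recall(tp, fn); p <- precision(tp, fp)
  structure(list(per_image = df, totals = totals,
                 tp = tp, fn = fn, fp = fp,
                 recall = r, precision = p,
                 recall_pct = if (is.na(r)) NA_real_ else round_half_up(100 * r),
                 precision_pct = if (is.na(p)) NA_real_ else round_half_up(100 * p)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  print(rbind(x$per_image, x$totals), row.names = FALSE)
  cat(sprintf("tp=%d fn=%d fp=%d | recall %s%% precision %s%%\n",
              x$tp, x$fn, x$fp, format(x$recall_pct),
              format(x$precision_pct)))
  invisible(x)
}
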