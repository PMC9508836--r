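## Benchmarking layer: confusion tables against a truth set and the
## derived performance metrics (the de novo class is the positive class).

#' Confusion table from counts
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return a `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop2("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop2("all-zero confusion table")
  structure(as.list(counts), class = "confusion_table")
}

#' Confusion table from labels
#'
#' Truth and prediction label the same candidate keys; `"DNM"` is the
#' positive class.
#'
#' @param truth,predicted character vectors of `"DNM"`/`"IV"` labels. If
#'   both are named (candidate keys), they are matched by name and must
#'   cover the same key set.
#' @return a `confusion_table`.
#' @export
confusion <- function(truth, predicted) {
  if (!is.null(names(truth)) && !is.null(names(predicted))) {
    if (!setequal(names(truth), names(predicted))) {
      stop2("truth and prediction sets label different candidate keys")
    }
    predicted <- predicted[names(truth)]
  } else if (length(truth) != length(predicted)) {
    stop2("truth and prediction differ in length and carry no keys")
  }
  t_pos <- truth == "DNM"
  p_pos <- predicted == "DNM"
  confusion_table(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
                  tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos))
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Performance metrics from a confusion table
#'
#' Sensitivity (= recall), specificity, precision and accuracy as
#' percentages rounded half-up to 2 decimals, plus the F1 score as a
#' fraction and the number of positive calls (TP + FP). A metric with a
#' zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param table a [confusion_table()].
#' @return a `metric_set` list: `sensitivity`, `specificity`, `precision`,
#'   `accuracy` (percent), `f1` (fraction), `calls`.
#' @export
dnm_metrics <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  tp <- table$tp; fp <- table$fp; tn <- table$tn; fn <- table$fn
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  prec <- frac(tp, tp + fp)
  acc <- frac(tp + tn, tp + fp + tn + fn)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x, 2)
  structure(list(sensitivity = pct(sens), specificity = pct(spec),
                 precision = pct(prec), accuracy = pct(acc), f1 = f1,
                 calls = tp + fp),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf(paste0("<metric_set> calls %d\n",
                     "  sensitivity %s  specificity %s\n",
                     "  precision   %s  accuracy    %s\n"),
              x$calls, fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$precision), fmt(x$accuracy)))
  invisible(x)
}

#' Per-variant-type metric breakdown
#'
#' @param truth,predicted label vectors as in [confusion()].
#' @param variant_type character vector of types parallel to the labels.
#' @return named list of `metric_set` (one per type present) plus
#'   `overall`.
#' @export
per_type_breakdown <- function(truth, predicted, variant_type) {
  stopifnot(length(truth) == length(variant_type))
  out <- lapply(split(seq_along(truth), variant_type), function(i) {
    dnm_metrics(confusion(unname(truth[i]), unname(predicted[i])))
  })
  out$overall <- dnm_metrics(confusion(unname(truth), unname(predicted)))
  out
}

#' Published benchmark confusion counts for trio de novo callers
#'
#' Bundled TP/FP/TN/FN counts reported for several de novo calling
#' methods on three validation datasets: the Genome in a Bottle
#' Ashkenazim WGS trio (`"giab_wgs"`), 20 WES trios with
#' Sanger/IonTorrent-validated calls (`"wes_trios"`), and 7 WGS trios
#' validated against PacBio HiFi long-read calls (`"wgs_trios"`). Feeding
#' any row into [dnm_metrics()] reproduces the reported percentage
#' metrics.
#'
#' @param dataset optionally restrict to one dataset.
#' @return data.frame with columns dataset, tool, calls, tp, fp, tn, fn.
#' @export
benchmark_counts <- function(dataset = NULL) {
  df <- read.table(
    system.file("extdata", "benchmark_counts.tsv", package = "trioDNM"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!is.null(dataset)) df <- df[df$dataset %in% dataset, , drop = FALSE]
  df
}
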