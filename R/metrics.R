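#' Segmentation overlap metrics
#'
#' Per-class Dice, IoU (Jaccard), precision and recall between two label
#' maps, plus macro averages. For class `c` with prediction set `P1` and
#' reference set `T1`: `Dice = 2|P1 ^ T1| / (|P1| + |T1|)`,
#' `IoU = |P1 ^ T1| / |P1 u T1|`, `Pre = |P1 ^ T1| / |P1|`,
#' `Rec = |P1 ^ T1| / |T1|`. Dice is the F-score (harmonic mean of precision
#' and recall) and equals `2 IoU / (1 + IoU)`.
#'
#' Empty-class conventions (common challenge scoring): a class empty in both
#' maps scores 1 on every metric; a class empty in exactly one map scores 0.
#' The macro average excludes the background class (label 0) by default,
#' since published structure scores are reported on foreground classes.
#'
#' @param pred,truth integer label arrays of identical shape with labels in
#'   `0:(K-1)`.
#' @param K number of classes.
#' @param exclude_background logical; drop class 0 from the macro average.
#' @return an object of class `"nbac_metrics"`: per-class data frame plus
#'   macro averages.
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' evaluate_segmentation(a, a, K = 2)$macro["dice"]  # 1
#' @export
evaluate_segmentation <- function(pred, truth, K, exclude_background = TRUE) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch", call. = FALSE)
  K <- as.integer(K)
  pv <- as.integer(round(pred))
  tv <- as.integer(round(truth))
  if (min(pv, tv) < 0L || max(pv, tv) >= K) {
    stop("labels out of range [0, K)", call. = FALSE)
  }
  rows <- lapply(seq_len(K) - 1L, function(k) {
    P1 <- pv == k
    T1 <- tv == k
    i <- sum(P1 & T1)
    p <- sum(P1)
    t <- sum(T1)
    if (p == 0L && t == 0L) {
      c(dice = 1, iou = 1, precision = 1, recall = 1, n_pred = 0, n_truth = 0)
    } else {
      u <- p + t - i
      c(dice = 2 * i / (p + t),
        iou = i / u,
        precision = if (p > 0L) i / p else 0,
        recall = if (t > 0L) i / t else 0,
        n_pred = p, n_truth = t)
    }
  })
  per_class <- data.frame(class = seq_len(K) - 1L, do.call(rbind, rows))
  sel <- if (exclude_background && K > 1L) seq.int(2L, K) else seq_len(K)
  macro <- colMeans(per_class[sel, c("dice", "iou", "precision", "recall")])
  structure(list(per_class = per_class, macro = macro, K = K,
                 exclude_background = exclude_background),
            class = "nbac_metrics")
}

#' @export
print.nbac_metrics <- function(x, ...) {
  cat("<nbac_metrics> K =", x$K, "\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("macro (%s): dice %.4f | iou %.4f | pre %.4f | rec %.4f\n",
              if (x$exclude_background) "foreground" else "all classes",
              x$macro["dice"], x$macro["iou"], x$macro["precision"],
              x$macro["recall"]))
  invisible(x)
}

#' @export
as.data.frame.nbac_metrics <- function(x, ...) {
  pc <- x$per_class
  macro <- data.frame(class = NA_integer_, dice = x$macro["dice"],
                      iou = x$macro["iou"], precision = x$macro["precision"],
                      recall = x$macro["recall"], n_pred = NA, n_truth = NA,
                      row.names = NULL)
  out <- rbind(cbind(pc, scope = "class"), cbind(macro, scope = "macro"))
  rownames(out) <- NULL
  out
}

#' Write metric records to CSV
#'
#' One row per (case, class) plus macro rows. Columns: `case`, `scope`
#' (`"class"` or `"macro"`), `class`, `dice`, `iou`, `precision`, `recall`,
#' `n_pred`, `n_truth`.
#'
#' @param records a named list of `"nbac_metrics"` (names are case ids) or a
#'   single `"nbac_metrics"`.
#' @param path output CSV path.
#' @return the assembled data frame, invisibly.
#' @export
write_metrics_csv <- function(records, path) {
  if (inherits(records, "nbac_metrics")) records <- list(case1 = records)
  dfs <- lapply(names(records), function(nm) {
    cbind(case = nm, as.data.frame(records[[nm]]))
  })
  out <- do.call(rbind, dfs)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
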