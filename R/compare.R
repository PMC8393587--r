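#' Evaluate a fitted model over a dataset
#'
#' Runs the argmax decision rule over the model's softmax output for every
#' item and computes per-class and macro overlap metrics.
#'
#' @param model an `"nbac_model"`.
#' @param data list of items (`image`, `mask`) or a dataset directory.
#' @param csv optional path; when given, one row per (case, class) plus macro
#'   rows are written via [write_metrics_csv()].
#' @return named list of `"nbac_metrics"`, one per case, with an `"aggregate"`
#'   attribute holding the mean macro metrics.
#' @export
nbac_evaluate <- function(model, data, csv = NULL) {
  stopifnot(inherits(model, "nbac_model"))
  if (is.character(data)) data <- load_dataset(data)
  K <- model$backbone_cfg$num_classes
  records <- lapply(seq_along(data), function(i) {
    it <- data[[i]]
    if (max(it$mask) >= K) stop("class-count mismatch", call. = FALSE)
    pred <- predict(model, it$image)
    evaluate_segmentation(pred, it$mask, K)
  })
  names(records) <- sprintf("case_%03d", seq_along(data))
  agg <- colMeans(do.call(rbind, lapply(records, `[[`, "macro")))
  attr(records, "aggregate") <- agg
  if (!is.null(csv)) write_metrics_csv(records, csv)
  records
}

#' Compare losses on a shared dataset and seeds
#'
#' Desk-scale analogue of a loss-comparison benchmark table: trains the same
#' backbone with each requested loss under each seed on the same data, then
#' evaluates every fit on the same held-out items and reports macro Dice,
#' IoU, precision and recall per (loss, seed) plus per-loss medians. Runs are
#' fully deterministic given their seed: rerunning any cell reproduces its
#' loss curve exactly.
#'
#' @param data training items (list or dataset directory); the validation
#'   split inside [nbac_fit()] is shared across runs.
#' @param config base [nbac_config()]; its `loss` and `seed` fields are
#'   overridden per cell.
#' @param losses character vector from `c("ce", "dice", "focal", "osc",
#'   "nbac")`.
#' @param seeds integer vector of master seeds.
#' @param test_data optional held-out items for the reported metrics;
#'   defaults to the validation split of `data`.
#' @param out_dir optional directory: writes `comparison.csv` and per-cell
#'   training logs.
#' @return data frame with columns `loss`, `seed`, `stat`, `dice`, `iou`,
#'   `precision`, `recall` (stat is `"run"` or `"median"`), with the config
#'   hash and seeds as attributes. The fitted models are attached as the
#'   `"models"` attribute.
#' @export
nbac_compare <- function(data, config, losses = c("ce", "dice", "focal",
                         "nbac"), seeds = 1:3, test_data = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "nbac_config"))
  if (is.character(data)) data <- load_dataset(data)
  losses <- match.arg(losses, c("ce", "dice", "focal", "osc", "nbac"),
                      several.ok = TRUE)
  rows <- list()
  models <- list()
  failures <- character()
  for (loss in losses) {
    for (sd in seeds) {
      cfg <- config
      cfg$loss <- loss
      cfg$seed <- as.integer(sd)
      if (!is.null(out_dir)) {
        cfg$out_dir <- file.path(out_dir, sprintf("%s_seed%d", loss, sd))
      }
      fit <- tryCatch(nbac_fit(data, cfg), error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- c(failures, sprintf("%s/seed%d: %s", loss, sd,
                                        conditionMessage(fit)))
        next
      }
      eval_items <- if (is.null(test_data)) data[fit$val_idx] else test_data
      rec <- nbac_evaluate(fit, eval_items)
      agg <- attr(rec, "aggregate")
      rows[[length(rows) + 1L]] <- data.frame(
        loss = loss, seed = sd, stat = "run",
        dice = agg["dice"], iou = agg["iou"],
        precision = agg["precision"], recall = agg["recall"],
        row.names = NULL)
      models[[sprintf("%s_seed%d", loss, sd)]] <- fit
    }
  }
  if (length(failures)) {
    warning("partial comparison table; failed cells: ",
            paste(failures, collapse = "; "), call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  med <- do.call(rbind, lapply(unique(tab$loss), function(l) {
    sub <- tab[tab$loss == l, ]
    data.frame(loss = l, seed = NA_integer_, stat = "median",
               dice = stats::median(sub$dice), iou = stats::median(sub$iou),
               precision = stats::median(sub$precision),
               recall = stats::median(sub$recall), row.names = NULL)
  }))
  out <- rbind(tab, med)
  attr(out, "config_hash") <- config_hash(
    config[setdiff(names(config), c("out_dir", "loss", "seed"))])
  attr(out, "seeds") <- seeds
  attr(out, "models") <- models
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- cbind(out, config_hash = attr(out, "config_hash"))
    utils::write.csv(csv, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  out
}

#' Run the package's oracle self-checks
#'
#' Re-derives a compact set of the package's correctness properties at run
#' time — smooth-Heaviside identities, signed-distance against exhaustive
#' nearest-opposite-pixel search, dilation against a brute-force window
#' maximum, loss values against per-pixel reference loops, and the metric
#' identities — and prints one PASS/FAIL line per group.
#'
#' @param seed RNG seed for the random instances.
#' @param quiet suppress per-check output.
#' @return logical: all checks passed (invisibly).
#' @export
nbac_audit <- function(seed = 1L, quiet = FALSE) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ok <- TRUE
  report <- function(name, pass) {
    if (!quiet) cat(sprintf("%-28s %s\n", name, if (pass) "PASS" else "FAIL"))
    ok <<- ok && pass
    invisible(pass)
  }
  x <- matrix(stats::rnorm(64), 8, 8)
  report("heaviside identities",
         heaviside_smooth(0, 1) == 0.5 &&
           abs(heaviside_smooth(1, 1) - 0.75) < 1e-12 &&
           max(abs(heaviside_smooth(x, .3) + heaviside_smooth(-x, .3) - 1)) < 1e-12)
  m <- matrix(stats::rbinom(81, 1, 0.4), 9, 9)
  if (all(m == 0) || all(m == 1)) m[5, 5] <- 1 - m[5, 5]
  phi <- signed_distance(m)
  co <- which(m == 0, arr.ind = TRUE)
  ci <- which(m == 1, arr.ind = TRUE)
  errs <- vapply(seq_len(81), function(i) {
    rc <- arrayInd(i, dim(m))
    opp <- if (m[i] == 1) co else ci
    d <- sqrt(min((opp[, 1] - rc[1])^2 + (opp[, 2] - rc[2])^2))
    abs(phi[i] - if (m[i] == 1) d else -d)
  }, numeric(1))
  report("signed distance (brute force)", max(errs) < 1e-10)
  f <- matrix(stats::runif(144), 12, 12)
  bf <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    bf[i, j] <- max(f[max(1, i - 1):min(12, i + 1),
                      max(1, j - 1):min(12, j + 1)])
  }
  report("dilation (brute force)",
         max(abs(dilate_band(f, band_spec(3)) - bf)) == 0 &&
           all(edge_extract(matrix(2, 6, 6)) == 0))
  P <- matrix(stats::runif(16), 4, 4)
  Tm <- matrix(stats::rbinom(16, 1, .5), 4, 4)
  o <- mean(-(Tm * log(pmin(pmax(P, 1e-7), 1 - 1e-7)) +
                (1 - Tm) * log(1 - pmin(pmax(P, 1e-7), 1 - 1e-7))))
  report("loss oracles",
         abs(ce_loss(P, Tm) - o) < 1e-12 &&
           abs(focal_loss(P, Tm, 1, 0) - ce_loss(P, Tm)) < 1e-12)
  a <- matrix(sample(0:1, 64, TRUE), 8, 8)
  b <- matrix(sample(0:1, 64, TRUE), 8, 8)
  mt <- evaluate_segmentation(a, b, 2)$per_class[2, ]
  report("metric identities",
         abs(mt$dice - 2 * mt$iou / (1 + mt$iou)) < 1e-12)
  if (!quiet) cat(if (ok) "all checks passed\n" else "CHECK FAILURES\n")
  invisible(ok)
}
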