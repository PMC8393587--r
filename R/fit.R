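#' Experiment configuration
#'
#' Bundles the backbone, loss selection and optimiser settings for
#' [nbac_fit()]. Optimiser defaults follow the reference training setup:
#' Adam with learning rate 1e-2 and weight decay 1e-4 for 2D backbones, and
#' learning rate 2e-4 for 3D.
#'
#' @param backbone a [backbone_config()].
#' @param loss one of `"nbac"`, `"ce"`, `"dice"`, `"focal"`, `"osc"`.
#' @param weights an [nbac_weights()] (NB-AC loss weights and band mode).
#' @param osc an [osc_params()] (used when `loss = "osc"`).
#' @param focal_alpha,focal_gamma Focal loss parameters.
#' @param lr learning rate; default 1e-2 (2D) or 2e-4 (3D).
#' @param weight_decay L2 weight decay added to the gradients.
#' @param steps number of optimisation steps.
#' @param batch_size images per step.
#' @param patch_size optional square/cubic crop size; crops preferring at
#'   least one foreground pixel are drawn when smaller than the image.
#' @param val_every validation cadence in steps.
#' @param grad_clip optional global gradient-norm clip (off by default).
#' @param seed master seed controlling initialisation and sampling.
#' @param out_dir optional directory for the training log CSV and checkpoint.
#' @return an object of class `"nbac_config"`.
#' @export
nbac_config <- function(backbone = backbone_config(), loss = c("nbac", "ce",
                        "dice", "focal", "osc"), weights = nbac_weights(),
                        osc = osc_params(), focal_alpha = 0.25,
                        focal_gamma = 2, lr = NULL, weight_decay = 1e-4,
                        steps = 100L, batch_size = 8L, patch_size = NULL,
                        val_every = 25L, grad_clip = NULL, seed = 1L,
                        out_dir = NULL) {
  loss <- match.arg(loss)
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(weights, "nbac_weights"), inherits(osc, "osc_params"))
  if (is.null(lr)) lr <- if (backbone$kind == "unet3d") 2e-4 else 1e-2
  structure(list(backbone = backbone, loss = loss, weights = weights,
                 osc = osc, focal_alpha = focal_alpha,
                 focal_gamma = focal_gamma, lr = lr,
                 weight_decay = weight_decay, steps = as.integer(steps),
                 batch_size = as.integer(batch_size),
                 patch_size = if (is.null(patch_size)) NULL else
                   as.integer(patch_size),
                 val_every = as.integer(val_every), grad_clip = grad_clip,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "nbac_config")
}

# Stable hash of any R object through its deparsed text.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

# ---- Adam optimiser ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g + wd * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(state = state, params = params)
}

# ---- batch assembly ---------------------------------------------------------

onehot_mask <- function(mask, K) {
  d <- dim(mask)
  out <- array(0, c(d, K))
  m <- length(mask)
  flat <- matrix(0, m, K)
  flat[cbind(seq_len(m), as.integer(mask) + 1L)] <- 1
  array(flat, c(d, K))
}

crop_item <- function(image, mask, ps, ns, tries = 10L) {
  S <- dim(mask)
  if (all(S <= ps)) return(list(image = image, mask = mask))
  for (i in seq_len(tries)) {
    start <- vapply(seq_len(ns), function(d) {
      sample.int(S[d] - ps + 1L, 1L)
    }, integer(1))
    rr <- lapply(seq_len(ns), function(d) start[d]:(start[d] + ps - 1L))
    mk <- win_get(mask, rr)
    dim(mk) <- rep(ps, ns)
    if (any(mk > 0) || i == tries) {
      im <- win_get(image, rr)
      dim(im) <- c(rep(ps, ns), dim(image)[-seq_len(ns)])
      return(list(image = im, mask = mk))
    }
  }
}

# Build the NB-AC band loss tape node over a batch: mean over (item, fg class)
# of the band energies plus one contour-length term on the whole F_LC tensor.
batch_band_node <- function(tape, p_id, flc_id, fln_id, bands, spec, w, ns) {
  p <- tp_value(tape, p_id)
  flc <- tp_value(tape, flc_id)
  dp <- dim(p)
  N <- dp[ns + 1L]
  K <- dp[ns + 2L]
  literal <- w$band_mode == "literal_eq14"
  fln_agg <- NULL
  Cw <- NULL
  if (literal) {
    fln <- tp_value(tape, fln_id)
    Cw <- dim(fln)[ns + 2L]
    # channel-mean narrow-band map per item ([S, N, C] layout: C is slowest)
    fln_agg <- rowMeans(matrix(fln, ncol = Cw))
    dim(fln_agg) <- dim(fln)[seq_len(ns + 1L)]
  }
  gp <- array(0, dp)
  gfln <- if (literal) array(0, dim(tp_value(tape, fln_id))) else NULL
  e_sum <- 0
  count <- 0L
  skipped <- 0L
  w0 <- w
  w0$mu <- 0
  for (n in seq_len(N)) {
    for (c in seq.int(2L, K)) {
      band <- bands[[n]][[c]]
      if (is.null(band) || !any(band$indicator)) {
        skipped <- skipped + 1L
        next
      }
      pc <- apply_slice_get(p, ns, n, c)
      flnc <- if (literal) apply_slice_get(fln_agg, ns, n, NULL) else NULL
      core <- suppressWarnings(nbac_band_loss_core(
        pc, pc * 0, flnc, NULL, spec, w0, band = band, want_grad = TRUE))
      e_sum <- e_sum + core$e_in + core$e_out
      count <- count + 1L
      gp <- apply_slice_add(gp, ns, n, c, core$grad_p)
      if (literal && !is.null(core$grad_fln)) {
        for (ch in seq_len(Cw)) {
          gfln <- apply_slice_add(gfln, ns, n, ch, core$grad_fln / Cw)
        }
      }
    }
  }
  e_band <- if (count > 0L) e_sum / count else 0
  if (count > 0L) gp <- gp / count
  if (literal && count > 0L) gfln <- gfln / count
  mu_term <- w$mu * mean(abs(flc))
  gflc <- w$mu * sign(flc) / length(flc)
  parents <- c(p_id, flc_id, if (literal) fln_id)
  grads <- c(list(gp, gflc), if (literal) list(gfln))
  node <- tp_custom_scalar(tape, mu_term + e_band, parents, grads)
  list(node = node, mu_term = mu_term, e_band = e_band, skipped = skipped)
}

# Extract / accumulate a [spatial] slice at (item n, channel c) from a
# [spatial..., N, C] (or [spatial..., N] when c is NULL) tensor.
apply_slice_get <- function(a, ns, n, c) {
  d <- dim(a)
  out <- if (is.null(c)) {
    if (ns == 2L) a[, , n, drop = FALSE] else a[, , , n, drop = FALSE]
  } else {
    if (ns == 2L) a[, , n, c, drop = FALSE] else a[, , , n, c, drop = FALSE]
  }
  dim(out) <- d[seq_len(ns)]
  out
}

apply_slice_add <- function(a, ns, n, c, val) {
  cur <- apply_slice_get(a, ns, n, c)
  dim(val) <- dim(cur)
  if (is.null(c)) {
    if (ns == 2L) a[, , n] <- cur + val else a[, , , n] <- cur + val
  } else {
    if (ns == 2L) a[, , n, c] <- cur + val else a[, , , n, c] <- cur + val
  }
  a
}

# OsC band terms over a batch (value + grad into the softmax tensor).
batch_osc_node <- function(tape, p_id, osc, ns) {
  p <- tp_value(tape, p_id)
  dp <- dim(p)
  N <- dp[ns + 1L]
  K <- dp[ns + 2L]
  gp <- array(0, dp)
  L2s <- L3s <- numeric(0)
  for (n in seq_len(N)) {
    for (c in seq.int(2L, K)) {
      pc <- apply_slice_get(p, ns, n, c)
      ct <- suppressWarnings(osc_class_terms(pc, osc, want_grad = TRUE))
      if (ct$skipped) next
      L2s <- c(L2s, ct$L2)
      L3s <- c(L3s, ct$L3)
      gp <- apply_slice_add(gp, ns, n, c, ct$grad)
    }
  }
  L2 <- if (length(L2s)) mean(L2s) else 0
  L3 <- if (length(L3s)) mean(L3s) else 0
  if (length(L2s)) gp <- gp / length(L2s)
  node <- tp_custom_scalar(tape, osc$beta * L2 + osc$eta * L3, p_id,
                           list(osc$beta * gp))
  list(node = node, L2 = L2, L3 = L3)
}

# ---- main fitting function --------------------------------------------------

#' Fit a two-branch segmentation network
#'
#' Trains the configured backbone on image/mask pairs with the selected loss.
#' For `loss = "nbac"` the total loss is the weighted branch combination
#' `branch_region * L1 + branch_band * L2` with the categorical region loss
#' `L1` on the first branch and the narrow-band active contour loss `L2`
#' (contour length plus inner/outer band energies against the ground-truth
#' band) on the second. Training is deterministic given `config$seed`. The
#' model snapshot with the best validation Dice is kept.
#'
#' @param data a list of items, each `list(image =, mask =, seed =)` with an
#'   `[H, W]` (or `[H, W, C]`, 3D analogues) image and an integer label mask
#'   in `0:(K-1)`; or a dataset directory written by [make_dataset()].
#' @param config an [nbac_config()].
#' @return an object of class `"nbac_model"` with the best parameters, the
#'   full training history and the validation trajectory.
#' @seealso [predict.nbac_model()], [nbac_compare()]
#' @export
nbac_fit <- function(data, config = nbac_config()) {
  stopifnot(inherits(config, "nbac_config"))
  if (is.character(data)) data <- load_dataset(data)
  cfg <- config$backbone
  ns <- cfg_ns(cfg)
  K <- cfg$num_classes
  n_items <- length(data)
  if (n_items < 2L) stop("need at least 2 items", call. = FALSE)
  for (it in data) {
    if (max(it$mask) >= K || min(it$mask) < 0) {
      stop("mask labels out of range for num_classes", call. = FALSE)
    }
  }
  item_seeds <- vapply(seq_len(n_items), function(i) {
    s <- data[[i]]$seed
    if (is.null(s)) i else as.integer(s)
  }, integer(1))
  # deterministic 80/20 split on the item seed
  val_idx <- which(item_seeds %% 5L == 0L)
  if (length(val_idx) == 0L || length(val_idx) == n_items) {
    val_idx <- seq.int(n_items - max(1L, n_items %/% 5L) + 1L, n_items)
  }
  train_idx <- setdiff(seq_len(n_items), val_idx)

  net <- build_backbone(cfg, seed = config$seed)
  params <- net$params
  buffers <- net$buffers
  opt <- adam_init(params)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])

  cropping <- !is.null(config$patch_size) &&
    any(dim(data[[1L]]$mask)[seq_len(ns)] > config$patch_size)
  need_bands <- config$loss == "nbac"
  band_cache <- NULL
  if (need_bands && !cropping) {
    band_cache <- lapply(seq_len(n_items), function(i) {
      lapply(seq_len(K), function(c) {
        yb <- (data[[i]]$mask == (c - 1L)) * 1
        if (all(yb == 0) || all(yb == 1)) return(NULL)
        suppressWarnings(ground_truth_band(yb, cfg$band))
      })
    })
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)

  history <- vector("list", config$steps)
  val_history <- list()
  best <- list(dice = -Inf, params = params,
               buffers = as.list(buffers))
  skipped_total <- 0L

  for (step in seq_len(config$steps)) {
    idx <- sample(train_idx, config$batch_size,
                  replace = config$batch_size > length(train_idx))
    items <- lapply(idx, function(i) {
      if (cropping) {
        crop_item(data[[i]]$image, data[[i]]$mask, config$patch_size, ns)
      } else {
        data[[i]]
      }
    })
    Nb <- length(items)
    S <- dim(items[[1L]]$mask)[seq_len(ns)]
    # stack items along the last dim, then swap to the [S, N, C] layout
    perm <- c(seq_len(ns), ns + 2L, ns + 1L)
    x <- array(unlist(lapply(items, function(it) {
      array(it$image, c(S, cfg$in_channels))
    }), use.names = FALSE), c(S, cfg$in_channels, Nb))
    x <- aperm(x, perm)
    Tb <- array(unlist(lapply(items, function(it) {
      onehot_mask(it$mask, K)
    }), use.names = FALSE), c(S, K, Nb))
    Tb <- aperm(Tb, perm)
    bands <- if (need_bands) {
      lapply(seq_len(Nb), function(n) {
        if (!cropping) return(band_cache[[idx[n]]])
        lapply(seq_len(K), function(c) {
          yb <- (items[[n]]$mask == (c - 1L)) * 1
          if (all(yb == 0) || all(yb == 1)) return(NULL)
          suppressWarnings(ground_truth_band(yb, cfg$band))
        })
      })
    } else NULL

    tape <- new_tape()
    ids <- make_leaf_ids(tape, params)
    xid <- tp_leaf(tape, x)
    out <- net_forward(cfg, tape, xid, ids, buffers, training = TRUE)

    l1_node <- l2_node <- total_node <- NULL
    l1_val <- l2_val <- mu_val <- eband_val <- NA_real_
    if (config$loss == "ce") {
      total_node <- tp_ce_logits(tape, out$logits, Tb)
      l1_val <- tp_value(tape, total_node)
    } else if (config$loss == "dice") {
      pid <- tp_softmax(tape, out$logits)
      pv <- tp_value(tape, pid)
      total_node <- tp_custom_scalar(
        tape, dice_loss(pv, Tb, classes_last = TRUE), pid,
        list(dice_loss_grad(pv, Tb, classes_last = TRUE)))
      l1_val <- tp_value(tape, total_node)
    } else if (config$loss == "focal") {
      pid <- tp_softmax(tape, out$logits)
      pv <- tp_value(tape, pid)
      total_node <- tp_custom_scalar(
        tape, focal_loss(pv, Tb, config$focal_alpha, config$focal_gamma),
        pid, list(focal_loss_grad(pv, Tb, config$focal_alpha,
                                  config$focal_gamma)))
      l1_val <- tp_value(tape, total_node)
    } else if (config$loss == "osc") {
      l1_node <- tp_ce_logits(tape, out$logits, Tb)
      pid <- tp_softmax(tape, out$logits)
      ob <- batch_osc_node(tape, pid, config$osc, ns)
      total_node <- tp_axpy(tape, list(l1_node, ob$node),
                            c(config$osc$alpha, 1))
      l1_val <- tp_value(tape, l1_node)
      l2_val <- tp_value(tape, ob$node)
    } else { # nbac
      l1_node <- tp_ce_logits(tape, out$logits, Tb)
      pid <- tp_softmax(tape, out$logits)
      bb <- batch_band_node(tape, pid, out$F_LC, out$F_LN, bands, cfg$band,
                            config$weights, ns)
      skipped_total <- skipped_total + bb$skipped
      total_node <- tp_axpy(tape, list(l1_node, bb$node),
                            c(config$weights$branch_region,
                              config$weights$branch_band))
      l1_val <- tp_value(tape, l1_node)
      l2_val <- tp_value(tape, bb$node)
      mu_val <- bb$mu_term
      eband_val <- bb$e_band
    }
    total_val <- as.numeric(tp_value(tape, total_node))
    if (!is.finite(total_val)) {
      dump <- list(step = step, idx = idx, x = x, T = Tb,
                   loss = config$loss, hash = hash)
      dump_path <- file.path(if (is.null(config$out_dir)) tempdir() else
        config$out_dir, "nbac-nan-dump.rds")
      saveRDS(dump, dump_path)
      stop("non-finite loss at step ", step, "; offending batch dumped to ",
           dump_path, call. = FALSE)
    }

    grads_all <- tp_backward(tape, total_node)
    grads <- lapply(ids, function(id) grads_all[[id]])
    if (!is.null(config$grad_clip)) {
      gn <- sqrt(sum(vapply(grads, function(g) {
        if (is.null(g)) 0 else sum(g * g)
      }, numeric(1))))
      if (is.finite(gn) && gn > config$grad_clip) {
        sc <- config$grad_clip / gn
        grads <- lapply(grads, function(g) if (is.null(g)) NULL else g * sc)
        message("gradient clipped at step ", step,
                " (norm ", signif(gn, 4), ")")
      }
    }
    upd <- adam_step(opt, params, grads, config$lr, config$weight_decay)
    opt <- upd$state
    params <- upd$params

    history[[step]] <- data.frame(step = step, loss = config$loss,
                                  l1 = l1_val, l2 = l2_val, mu_term = mu_val,
                                  band_energy = eband_val, total = total_val)

    if (step %% config$val_every == 0L || step == config$steps) {
      vd <- validate_dice(cfg, params, buffers, data[val_idx], ns, K)
      val_history[[length(val_history) + 1L]] <-
        data.frame(step = step, val_dice = vd)
      if (vd >= best$dice) {
        best <- list(dice = vd, params = params, buffers = as.list(buffers))
      }
    }
  }

  history <- do.call(rbind, history)
  val_history <- do.call(rbind, val_history)
  model <- structure(list(
    params = best$params, final_params = params,
    buffers = list2env(best$buffers, new.env(parent = emptyenv())),
    backbone_cfg = cfg, config = config, history = history,
    val_history = val_history, best_val_dice = best$dice,
    train_idx = train_idx, val_idx = val_idx,
    band_skipped = skipped_total, config_hash = hash, seed = config$seed),
    class = "nbac_model")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    log <- cbind(history, config_hash = hash, seed = config$seed)
    utils::write.csv(log, file.path(config$out_dir, "training_log.csv"),
                     row.names = FALSE)
    nbac_save_model(model, file.path(config$out_dir, "model.rds"))
  }
  model
}

validate_dice <- function(cfg, params, buffers, val_items, ns, K) {
  scores <- vapply(val_items, function(it) {
    pred <- predict_labels(cfg, params, buffers, it$image, ns)
    evaluate_segmentation(pred, it$mask, K)$macro["dice"]
  }, numeric(1))
  mean(scores)
}

predict_labels <- function(cfg, params, buffers, image, ns) {
  x <- image_to_tensor(as_field(image, "image"), cfg)
  tape <- new_tape()
  ids <- make_leaf_ids(tape, params)
  xid <- tp_leaf(tape, x)
  out <- net_forward(cfg, tape, xid, ids, buffers, training = FALSE)
  logits <- drop_batch(tp_value(tape, out$logits), ns)
  d <- dim(logits)
  K <- d[length(d)]
  lm <- logits
  dim(lm) <- c(prod(d) / K, K)
  lab <- max.col(lm, ties.method = "first") - 1L
  array(lab, d[-length(d)])
}

#' Predict segmentation from a fitted model
#'
#' @param object an `"nbac_model"`.
#' @param image an image array (see [nbac_fit()] for accepted shapes).
#' @param type `"class"` for an integer label map (argmax decision rule over
#'   the softmax), `"prob"` for the softmax array (classes last), or
#'   `"logits"`.
#' @param ... unused.
#' @return label array, probability array, or logits array.
#' @export
predict.nbac_model <- function(object, image,
                               type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  cfg <- object$backbone_cfg
  ns <- cfg_ns(cfg)
  if (type == "class") {
    return(predict_labels(cfg, object$params, object$buffers, image, ns))
  }
  x <- image_to_tensor(as_field(image, "image"), cfg)
  tape <- new_tape()
  ids <- make_leaf_ids(tape, object$params)
  xid <- tp_leaf(tape, x)
  out <- net_forward(cfg, tape, xid, ids, object$buffers, training = FALSE)
  logits <- drop_batch(tp_value(tape, out$logits), ns)
  if (type == "logits") logits else softmax_last(logits)
}

#' @export
print.nbac_model <- function(x, ...) {
  cat(sprintf("<nbac_model> %s + %s loss | %d steps | best val macro-Dice %.4f\n",
              x$backbone_cfg$kind, x$config$loss, nrow(x$history),
              x$best_val_dice))
  cat(sprintf("  K = %d, depth = %d, base_width = %d | seed %d | config %s\n",
              x$backbone_cfg$num_classes, x$backbone_cfg$depth,
              x$backbone_cfg$base_width, x$seed,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' @export
summary.nbac_model <- function(object, ...) {
  h <- object$history
  cat("Two-branch segmentation model\n")
  print(object)
  cat(sprintf("  final total loss %.5f (first %.5f)\n",
              h$total[nrow(h)], h$total[1]))
  if (object$config$loss == "nbac") {
    cat(sprintf("  final L1 (region) %.5f | L2 (band) %.5f [mu %.5f + energy %.5f]\n",
                h$l1[nrow(h)], h$l2[nrow(h)], h$mu_term[nrow(h)],
                h$band_energy[nrow(h)]))
    if (object$band_skipped > 0) {
      cat(sprintf("  %d degenerate class bands skipped during training\n",
                  object$band_skipped))
    }
  }
  cat("  validation trajectory:\n")
  print(object$val_history, row.names = FALSE)
  invisible(object)
}

#' Plot training diagnostics
#'
#' Two panels: the per-step training loss (total plus, for the NB-AC loss,
#' the region and band components) and the validation macro-Dice trajectory.
#'
#' @param x an `"nbac_model"`.
#' @param ... unused.
#' @export
plot.nbac_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::plot(h$step, h$total, type = "l", xlab = "step", ylab = "loss",
                 main = paste(x$config$loss, "training loss"))
  if (x$config$loss %in% c("nbac", "osc")) {
    graphics::lines(h$step, h$l1, col = "grey50", lty = 2)
    graphics::lines(h$step, h$l2, col = "grey70", lty = 3)
    graphics::legend("topright", c("total", "L1 region", "L2 band"),
                     lty = 1:3, col = c("black", "grey50", "grey70"),
                     bty = "n", cex = 0.8)
  }
  graphics::plot(x$val_history$step, x$val_history$val_dice, type = "b",
                 xlab = "step", ylab = "macro Dice",
                 main = "validation Dice", ylim = c(0, 1))
  invisible(x)
}

#' Save / load a fitted model
#'
#' Single-file checkpoint with a versioned header.
#'
#' @param model an `"nbac_model"`.
#' @param path file path.
#' @return `nbac_load_model` returns the model; `nbac_save_model` returns
#'   `path` invisibly.
#' @export
nbac_save_model <- function(model, path) {
  stopifnot(inherits(model, "nbac_model"))
  obj <- list(header = list(format = "nbac_model", version = 1L,
                            created = format(Sys.time(), tz = "UTC")),
              buffers = as.list(model$buffers),
              model = unclass(model)[setdiff(names(model), "buffers")])
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname nbac_save_model
#' @export
nbac_load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$header$format, "nbac_model")) {
    stop("not an nbac model checkpoint", call. = FALSE)
  }
  if (obj$header$version > 1L) {
    stop("checkpoint version ", obj$header$version, " is newer than this ",
         "package supports", call. = FALSE)
  }
  model <- obj$model
  model$buffers <- list2env(obj$buffers, new.env(parent = emptyenv()))
  class(model) <- "nbac_model"
  model
}
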