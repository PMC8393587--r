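# Minimal reverse-mode autodiff tape used to train the two-branch networks.
# Nodes hold values (arrays) and backward closures; gradients are accumulated
# by walking the tape in reverse creation order. This is deliberately small:
# only the operations the backbones need are implemented.

new_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

tp_push <- function(tape, value, parents = integer(), backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = as.integer(parents),
                          backward = backward)
  tape$n <- n
  n
}

tp_leaf <- function(tape, value) tp_push(tape, value)

tp_value <- function(tape, id) tape$nodes[[id]]$value

# Backpropagate from scalar node `root`; returns a list of gradients indexed
# by node id (NULL where no gradient flowed).
tp_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  grads[[root]] <- 1
  for (i in seq.int(root, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (is.null(node$backward) || length(node$parents) == 0L) next
    pg <- node$backward(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# ---- primitive ops ---------------------------------------------------------

tp_conv <- function(tape, x, w, b, ns) {
  xv <- tp_value(tape, x); wv <- tp_value(tape, w); bv <- tp_value(tape, b)
  r <- conv_fwd(xv, wv, bv, ns, keep_windows = TRUE)
  if (!is.list(r)) r <- list(y = r, windows = NULL)
  tp_push(tape, r$y, c(x, w, b), function(g) {
    b <- conv_bwd(xv, wv, g, ns, windows = r$windows)
    list(b$gx, b$gw, b$gb)
  })
}

tp_relu <- function(tape, x) {
  xv <- tp_value(tape, x)
  mask <- xv > 0
  tp_push(tape, xv * mask, x, function(g) list(g * mask))
}

tp_leaky_relu <- function(tape, x, slope = 0.01) {
  xv <- tp_value(tape, x)
  mask <- xv > 0
  y <- ifelse(mask, xv, slope * xv)
  tp_push(tape, y, x, function(g) list(ifelse(mask, g, slope * g)))
}

tp_add <- function(tape, a, b) {
  tp_push(tape, tp_value(tape, a) + tp_value(tape, b), c(a, b),
          function(g) list(g, g))
}

tp_maxpool <- function(tape, x, ns) {
  xv <- tp_value(tape, x)
  y <- pool_fwd(xv, ns)
  tp_push(tape, y, x, function(g) list(pool_bwd(xv, y, g, ns)))
}

tp_upsample <- function(tape, x, f, ns) {
  xv <- tp_value(tape, x)
  S_in <- dim(xv)[seq_len(ns)]
  tp_push(tape, upsample_fwd(xv, f, ns), x,
          function(g) list(upsample_bwd(g, f, ns, S_in)))
}

tp_concat_last <- function(tape, a, b) {
  av <- tp_value(tape, a); bv <- tp_value(tape, b)
  da <- dim(av); db <- dim(bv)
  nd <- length(da)
  y <- array(c(av, bv), c(da[-nd], da[nd] + db[nd]))
  tp_push(tape, y, c(a, b), function(g) {
    ga <- slice_gather(g, nd, seq_len(da[nd]))
    gb <- slice_gather(g, nd, seq.int(da[nd] + 1L, da[nd] + db[nd]))
    list(ga, gb)
  })
}

# Batch norm: batch statistics in training mode (running stats updated in
# `buffers`), running statistics in eval mode.
tp_batchnorm <- function(tape, x, gamma, beta, buffers, key, training,
                         momentum = 0.1) {
  xv <- tp_value(tape, x)
  gv <- tp_value(tape, gamma); bv <- tp_value(tape, beta)
  rkey_m <- paste0(key, ".rmean"); rkey_v <- paste0(key, ".rvar")
  if (training) {
    r <- bn_fwd(xv, gv, bv)
    if (is.null(buffers[[rkey_m]])) {
      buffers[[rkey_m]] <- r$mu
      buffers[[rkey_v]] <- r$var
    } else {
      buffers[[rkey_m]] <- (1 - momentum) * buffers[[rkey_m]] + momentum * r$mu
      buffers[[rkey_v]] <- (1 - momentum) * buffers[[rkey_v]] + momentum * r$var
    }
    tp_push(tape, r$y, c(x, gamma, beta), function(g) {
      b <- bn_bwd(r, gv, g)
      list(b$gx, b$ggamma, b$gbeta)
    })
  } else {
    rm <- buffers[[rkey_m]]; rv <- buffers[[rkey_v]]
    if (is.null(rm)) { # never trained: fall back to batch stats
      r <- bn_fwd(xv, gv, bv)
      return(tp_push(tape, r$y, c(x, gamma, beta), function(g) {
        b <- bn_bwd(r, gv, g)
        list(b$gx, b$ggamma, b$gbeta)
      }))
    }
    tp_push(tape, bn_eval(xv, gv, bv, rm, rv), c(x, gamma, beta),
            function(g) {
              dx <- dim(g); C <- dx[length(dx)]
              gm <- g; dim(gm) <- c(prod(dx) / C, C)
              gx <- sweep(gm, 2, gv / sqrt(rv + 1e-5), `*`)
              dim(gx) <- dx
              list(gx, NULL, NULL)
            })
  }
}

tp_instnorm <- function(tape, x, gamma, beta, ns) {
  xv <- tp_value(tape, x)
  gv <- tp_value(tape, gamma); bv <- tp_value(tape, beta)
  r <- in_fwd(xv, gv, bv, ns)
  tp_push(tape, r$y, c(x, gamma, beta), function(g) {
    b <- in_bwd(r, gv, g, ns)
    list(b$gx, b$ggamma, b$gbeta)
  })
}

tp_softmax <- function(tape, x) {
  p <- softmax_last(tp_value(tape, x))
  tp_push(tape, p, x, function(g) list(softmax_bwd(p, g)))
}

# Fused categorical cross-entropy on logits (stable log-softmax).
tp_ce_logits <- function(tape, logits, T_onehot) {
  xv <- tp_value(tape, logits)
  dx <- dim(xv)
  K <- dx[length(dx)]
  m <- prod(dx) / K
  xm <- xv; dim(xm) <- c(m, K)
  mx <- xm[cbind(seq_len(m), max.col(xm, ties.method = "first"))]
  xs <- xm - mx
  lse <- log(rowSums(exp(xs)))
  logp <- xs - lse
  Tm <- T_onehot; dim(Tm) <- c(m, K)
  val <- -sum(Tm * logp) / m
  tp_push(tape, val, logits, function(g) {
    gx <- g * (exp(logp) - Tm) / m
    dim(gx) <- dx
    list(gx)
  })
}

# Fixed-stencil edge magnitude (transitional gate, first stage).
tp_edge <- function(tape, x, ns) {
  cache <- edge_core(tp_value(tape, x), ns)
  tp_push(tape, cache$mag, x, function(g) list(edge_core_bwd(cache, g)))
}

# Trainable-stencil edge magnitude: one kernel per spatial direction, each a
# length-3^ns weight vector over the stencil offsets.
tp_edge_trainable <- function(tape, x, kernel_ids, ns) {
  xv <- tp_value(tape, x)
  offs <- conv_offsets(3L, ns)
  kvs <- lapply(kernel_ids, function(id) tp_value(tape, id))
  shifted <- lapply(seq_len(nrow(offs)), function(o) shift_off(xv, offs[o, ]))
  comps <- lapply(kvs, function(kv) {
    Reduce(`+`, Map(function(s, w) w * s, shifted, as.list(kv)))
  })
  mag <- sqrt(Reduce(`+`, lapply(comps, function(z) z * z)))
  tp_push(tape, mag, c(x, unlist(kernel_ids)), function(g) {
    scale <- ifelse(mag > 0, g / mag, 0)
    gx <- NULL
    gks <- vector("list", length(kvs))
    for (d in seq_along(kvs)) {
      gc <- scale * comps[[d]]
      gk <- vapply(shifted, function(s) sum(gc * s), numeric(1))
      gks[[d]] <- gk
      for (o in seq_len(nrow(offs))) {
        contrib <- kvs[[d]][o] * shift_off_t(gc, offs[o, ])
        gx <- if (is.null(gx)) contrib else gx + contrib
      }
    }
    c(list(gx), gks)
  })
}

tp_dilate <- function(tape, x, B, ns) {
  xv <- tp_value(tape, x)
  y <- dilate_core(xv, B, ns)
  tp_push(tape, y, x, function(g) list(dilate_core_bwd(xv, y, g, B, ns)))
}

# Custom scalar node with precomputed gradients with respect to its parents
# (used for loss terms whose gradients are available in closed form).
tp_custom_scalar <- function(tape, value, parents, grads) {
  tp_push(tape, value, parents, function(g) {
    lapply(grads, function(G) if (is.null(G)) NULL else g * G)
  })
}

tp_axpy <- function(tape, terms, coefs) {
  vals <- vapply(terms, function(id) as.numeric(tp_value(tape, id)), numeric(1))
  tp_push(tape, sum(coefs * vals), unlist(terms), function(g) {
    as.list(g * coefs)
  })
}
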