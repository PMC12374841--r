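# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Only the operations needed by the equivariant graph network are
# implemented: matrix product, bias/elementwise arithmetic, smooth
# nonlinearities, row gather/scatter (message passing), column binding,
# broadcast products, row sums, per-graph max pooling and scalar losses.
# Gradients are checked against central finite differences in the test suite.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ad_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ad_node(tape, value)
}

ad_acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Run the backward pass from a scalar loss node (seed gradient 1).
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd)
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    ad_acc(nd$parents[[1]], tcrossprod(nd$grad, nd$parents[[2]]$value))
    ad_acc(nd$parents[[2]], crossprod(nd$parents[[1]]$value, nd$grad))
  })
}

# X + row-vector bias (b is 1 x k); column-major recycling avoids sweep()
ad_add_bias <- function(tape, x, b) {
  n <- nrow(x$value)
  ad_node(tape, x$value + rep(b$value[1, ], each = n), list(x, b),
          function(nd) {
            ad_acc(nd$parents[[1]], nd$grad)
            ad_acc(nd$parents[[2]], matrix(colSums(nd$grad), 1))
          })
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, list(x, y), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad)
    ad_acc(nd$parents[[2]], nd$grad)
  })
}

# fused n-ary elementwise sum (single pass, same gradient to every parent)
ad_addn <- function(tape, nodes) {
  v <- nodes[[1]]$value
  for (i in 2:length(nodes)) v <- v + nodes[[i]]$value
  ad_node(tape, v, nodes, function(nd) {
    for (p in nd$parents) ad_acc(p, nd$grad)
  })
}

ad_sub <- function(tape, x, y) {
  ad_node(tape, x$value - y$value, list(x, y), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad)
    ad_acc(nd$parents[[2]], -nd$grad)
  })
}

ad_mul <- function(tape, x, y) {
  ad_node(tape, x$value * y$value, list(x, y), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$parents[[2]]$value)
    ad_acc(nd$parents[[2]], nd$grad * nd$parents[[1]]$value)
  })
}

ad_silu <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, x$value * s, list(x), local({
    s_ <- s
    function(nd) {
      xv <- nd$parents[[1]]$value
      ad_acc(nd$parents[[1]], nd$grad * (s_ + xv * s_ * (1 - s_)))
    }
  }))
}

ad_tanh <- function(tape, x) {
  t <- tanh(x$value)
  ad_node(tape, t, list(x), local({
    t_ <- t
    function(nd) ad_acc(nd$parents[[1]], nd$grad * (1 - t_^2))
  }))
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(tape, s, list(x), local({
    s_ <- s
    function(nd) ad_acc(nd$parents[[1]], nd$grad * s_ * (1 - s_))
  }))
}

# gather rows: value = x[idx, ]
ad_gather <- function(tape, x, idx) {
  ad_node(tape, x$value[idx, , drop = FALSE], list(x), local({
    idx_ <- idx
    function(nd) {
      xv <- nd$parents[[1]]$value
      gg <- rowsum(nd$grad, idx_)
      out <- matrix(0, nrow(xv), ncol(xv))
      out[as.integer(rownames(gg)), ] <- gg
      ad_acc(nd$parents[[1]], out)
    }
  }))
}

# scatter-sum rows of x (one per directed edge) into n node rows by idx
ad_scatter_sum <- function(tape, x, idx, n) {
  gg <- rowsum(x$value, idx)
  val <- matrix(0, n, ncol(x$value))
  val[as.integer(rownames(gg)), ] <- gg
  ad_node(tape, val, list(x), local({
    idx_ <- idx
    function(nd) ad_acc(nd$parents[[1]], nd$grad[idx_, , drop = FALSE])
  }))
}

# scatter-mean: like scatter-sum but divided by the receiver's edge count
ad_scatter_mean <- function(tape, x, idx, n) {
  cnt <- tabulate(idx, n)
  cnt_safe <- pmax(cnt, 1L)
  gg <- rowsum(x$value, idx)
  val <- matrix(0, n, ncol(x$value))
  val[as.integer(rownames(gg)), ] <- gg
  val <- val / cnt_safe
  ad_node(tape, val, list(x), local({
    idx_ <- idx; cs <- cnt_safe
    function(nd) ad_acc(nd$parents[[1]],
                        (nd$grad / cs)[idx_, , drop = FALSE])
  }))
}

ad_cbind <- function(tape, nodes) {
  widths <- vapply(nodes, function(nd) ncol(nd$value), integer(1))
  ad_node(tape, do.call(cbind, lapply(nodes, function(nd) nd$value)), nodes,
          local({
            w <- widths
            function(nd) {
              off <- 0L
              for (i in seq_along(nd$parents)) {
                ad_acc(nd$parents[[i]],
                       nd$grad[, (off + 1L):(off + w[i]), drop = FALSE])
                off <- off + w[i]
              }
            }
          }))
}

# X (E x k) * s (E x 1), s broadcast across columns
ad_mul_bcast <- function(tape, x, s) {
  ad_node(tape, x$value * s$value[, 1], list(x, s), function(nd) {
    ad_acc(nd$parents[[1]], nd$grad * nd$parents[[2]]$value[, 1])
    ad_acc(nd$parents[[2]],
           matrix(rowSums(nd$grad * nd$parents[[1]]$value), ncol = 1))
  })
}

ad_rowsums <- function(tape, x) {
  k <- ncol(x$value)
  ad_node(tape, matrix(rowSums(x$value), ncol = 1), list(x), local({
    k_ <- k
    function(nd) ad_acc(nd$parents[[1]], nd$grad[, rep(1L, k_), drop = FALSE])
  }))
}

# per-graph, per-column max over node rows; gid maps rows to 1..ngraph
ad_maxpool <- function(tape, x, gid, ngraph) {
  k <- ncol(x$value)
  val <- matrix(-Inf, ngraph, k)
  arg <- matrix(NA_integer_, ngraph, k)
  for (g in seq_len(ngraph)) {
    rows <- which(gid == g)
    sub <- x$value[rows, , drop = FALSE]
    wm <- max.col(t(sub), ties.method = "first")
    arg[g, ] <- rows[wm]
    val[g, ] <- sub[cbind(wm, seq_len(k))]
  }
  ad_node(tape, val, list(x), local({
    arg_ <- arg; k_ <- k; ng <- ngraph
    function(nd) {
      xv <- nd$parents[[1]]$value
      gx <- matrix(0, nrow(xv), k_)
      idx <- cbind(as.vector(arg_), rep(seq_len(k_), each = ng))
      gx[idx] <- as.vector(nd$grad)
      ad_acc(nd$parents[[1]], gx)
    }
  }))
}

# mean squared error against a constant target vector
ad_mse <- function(tape, pred, y) {
  n <- length(y)
  ad_node(tape, matrix(mean((pred$value[, 1] - y)^2), 1, 1), list(pred),
          local({
            y_ <- y; n_ <- n
            function(nd) {
              p <- nd$parents[[1]]$value[, 1]
              ad_acc(nd$parents[[1]],
                     matrix(nd$grad[1, 1] * 2 * (p - y_) / n_, ncol = 1))
            }
          }))
}

# binary cross-entropy with logits against constant 0/1 targets
ad_bce_logits <- function(tape, logits, y) {
  n <- length(y)
  z <- logits$value[, 1]
  # stable log(1+exp(z)) formulation
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  ad_node(tape, matrix(loss, 1, 1), list(logits), local({
    y_ <- y; n_ <- n
    function(nd) {
      z_ <- nd$parents[[1]]$value[, 1]
      p <- 1 / (1 + exp(-z_))
      ad_acc(nd$parents[[1]], matrix(nd$grad[1, 1] * (p - y_) / n_, ncol = 1))
    }
  }))
}
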