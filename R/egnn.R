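# Siamese E(n)-equivariant graph network for ddG regression and single-graph
# binding classification.
#
# Each EGC layer computes edge messages from invariant inputs
#   m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2, a_ij),
# updates coordinates equivariantly
#   x_i <- x_i + mean_j (x_i - x_j) * phi_x(m_ij)        (tanh-bounded),
# and updates node states h_i <- h_i + phi_h(h_i, sum_j m_ij). Because node
# states see coordinates only through squared distances, predictions are
# exactly invariant under rotations/translations while coordinates transform
# covariantly. The ddG head pools each graph with a per-dimension max over
# nodes and applies a linear layer to the WT - mutant embedding difference;
# with the head bias off the prediction is exactly antisymmetric in its two
# arguments. phi_e, phi_x, phi_h are two-layer perceptrons of the hidden
# width with SiLU activations.

#' Model configuration
#'
#' Defaults follow the training recipe used throughout: Adam, learning rate
#' 0.001, batch size 32, edge dropout 0.2, weight decay 1e-16, three EGC
#' layers, max-over-nodes readout, tanh on the coordinate function output,
#' coordinate updates on, head bias off (making ddG antisymmetry exact).
#'
#' @param n_layers Number of EGC layers (>= 1).
#' @param hidden_dim Hidden width (>= 1).
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param edge_dropout Probability of dropping each (undirected) edge per
#'   training step; applied during training only.
#' @param weight_decay L2 coefficient added to gradients.
#' @param coord_tanh Bound the coordinate-function output with tanh.
#' @param update_coords Update coordinates between layers.
#' @param head_bias Include a bias in the final linear head.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling init, batching and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_layers = 3L, hidden_dim = 128L, learning_rate = 0.001,
                         batch_size = 32L, edge_dropout = 0.2,
                         weight_decay = 1e-16, coord_tanh = TRUE,
                         update_coords = TRUE, head_bias = FALSE,
                         epochs = 30L, seed = 1L) {
  stopifnot(n_layers >= 1, hidden_dim >= 1,
            edge_dropout >= 0, edge_dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 edge_dropout = edge_dropout, weight_decay = weight_decay,
                 coord_tanh = isTRUE(coord_tanh),
                 update_coords = isTRUE(update_coords),
                 head_bias = isTRUE(head_bias),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

EDGE_FEAT_DIM <- 2L

init_params <- function(config, V) {
  d <- config$hidden_dim
  glorot <- function(fi, fo, scale = 1)
    matrix(stats::rnorm(fi * fo, 0, scale * sqrt(2 / (fi + fo))), fi, fo)
  p <- list(embed_W = glorot(V, d), embed_b = matrix(0, 1, d))
  # phi_e's first layer acts on [h_i, h_j, d^2, a_ij]; its weight matrix is
  # stored in row blocks (Wh, Wn, Wd, Wf) so the two node-state blocks can be
  # projected once per node and gathered per edge - algebraically identical
  # to the concatenated form. All blocks share the full layer's fan-in.
  fe <- 2 * d + 1 + EDGE_FEAT_DIM
  gl_e <- function(fi_rows) matrix(stats::rnorm(fi_rows * d, 0, sqrt(2 / (fe + d))),
                                   fi_rows, d)
  for (l in seq_len(config$n_layers)) {
    p[[paste0("e_Wh_", l)]] <- gl_e(d)
    p[[paste0("e_Wn_", l)]] <- gl_e(d)
    p[[paste0("e_Wd_", l)]] <- gl_e(1)
    p[[paste0("e_Wf_", l)]] <- gl_e(EDGE_FEAT_DIM)
    p[[paste0("e_b1_", l)]] <- matrix(0, 1, d)
    p[[paste0("e_W2_", l)]] <- glorot(d, d)
    p[[paste0("e_b2_", l)]] <- matrix(0, 1, d)
    p[[paste0("x_V1_", l)]] <- glorot(d, d)
    p[[paste0("x_c1_", l)]] <- matrix(0, 1, d)
    p[[paste0("x_V2_", l)]] <- glorot(d, 1, scale = 1e-3)
    p[[paste0("x_c2_", l)]] <- matrix(0, 1, 1)
    # phi_h's first layer acts on [h_i, m_i]; same row-block storage
    gl_h <- function() matrix(stats::rnorm(d * d, 0, sqrt(2 / (3 * d))), d, d)
    p[[paste0("h_Uh_", l)]] <- gl_h()
    p[[paste0("h_Um_", l)]] <- gl_h()
    p[[paste0("h_u1_", l)]] <- matrix(0, 1, d)
    p[[paste0("h_U2_", l)]] <- glorot(d, d)
    p[[paste0("h_u2_", l)]] <- matrix(0, 1, d)
  }
  p$head_w <- glorot(d, 1)
  p$head_b <- matrix(0, 1, 1)
  p
}

# Concatenate graphs into one block-diagonal batch; optional edge dropout.
batch_graphs <- function(graphs, dropout = 0) {
  nnode <- vapply(graphs, function(g) nrow(g$coords), integer(1))
  off <- cumsum(c(0L, nnode[-length(nnode)]))
  feats <- do.call(rbind, lapply(graphs, function(g) g$features))
  coords <- do.call(rbind, lapply(graphs, function(g) g$coords))
  gid <- rep(seq_along(graphs), nnode)
  ei <- integer(0); ej <- integer(0); ef <- NULL
  efl <- vector("list", length(graphs))
  eil <- vector("list", length(graphs)); ejl <- vector("list", length(graphs))
  for (g in seq_along(graphs)) {
    e <- graphs[[g]]$edges
    fe <- graphs[[g]]$edge_features
    if (dropout > 0 && nrow(e)) {
      keep <- stats::runif(nrow(e)) >= dropout
      e <- e[keep, , drop = FALSE]
      fe <- fe[keep, , drop = FALSE]
    }
    # undirected edges become two directed message-passing edges
    eil[[g]] <- c(e[, 1], e[, 2]) + off[g]
    ejl[[g]] <- c(e[, 2], e[, 1]) + off[g]
    efl[[g]] <- rbind(fe, fe)
  }
  list(feats = feats, coords = coords, gid = gid,
       ei = unlist(eil), ej = unlist(ejl),
       ef = do.call(rbind, efl) %||% matrix(0, 0, EDGE_FEAT_DIM),
       ngraph = length(graphs))
}

egc_layer_tape <- function(tape, pn, l, h, x, ei, ej, efn, nnodes, config) {
  xi <- ad_gather(tape, x, ei); xj <- ad_gather(tape, x, ej)
  dx <- ad_sub(tape, xi, xj)
  d2 <- ad_rowsums(tape, ad_mul(tape, dx, dx))
  # phi_e layer 1 on [h_i, h_j, d2, a_ij]: node-state blocks projected once
  # per node, then gathered per edge (identical to the concatenated matmul)
  ph <- ad_mm(tape, h, pn[[paste0("e_Wh_", l)]])
  pnb <- ad_mm(tape, h, pn[[paste0("e_Wn_", l)]])
  pre <- ad_addn(tape, list(ad_gather(tape, ph, ei), ad_gather(tape, pnb, ej),
                            ad_mm(tape, d2, pn[[paste0("e_Wd_", l)]]),
                            ad_mm(tape, efn, pn[[paste0("e_Wf_", l)]])))
  m <- ad_silu(tape, ad_add_bias(tape, pre, pn[[paste0("e_b1_", l)]]))
  m <- ad_silu(tape, ad_add_bias(tape, ad_mm(tape, m, pn[[paste0("e_W2_", l)]]),
                                 pn[[paste0("e_b2_", l)]]))
  if (config$update_coords) {
    s <- ad_silu(tape, ad_add_bias(tape, ad_mm(tape, m, pn[[paste0("x_V1_", l)]]),
                                   pn[[paste0("x_c1_", l)]]))
    s <- ad_add_bias(tape, ad_mm(tape, s, pn[[paste0("x_V2_", l)]]),
                     pn[[paste0("x_c2_", l)]])
    if (config$coord_tanh) s <- ad_tanh(tape, s)
    upd <- ad_scatter_mean(tape, ad_mul_bcast(tape, dx, s), ei, nnodes)
    x <- ad_add(tape, x, upd)
  }
  agg <- ad_scatter_sum(tape, m, ei, nnodes)
  hu <- ad_add(tape, ad_mm(tape, h, pn[[paste0("h_Uh_", l)]]),
               ad_mm(tape, agg, pn[[paste0("h_Um_", l)]]))
  hu <- ad_silu(tape, ad_add_bias(tape, hu, pn[[paste0("h_u1_", l)]]))
  hu <- ad_add_bias(tape, ad_mm(tape, hu, pn[[paste0("h_U2_", l)]]),
                    pn[[paste0("h_u2_", l)]])
  h <- ad_add(tape, h, hu)  # residual node update
  list(h = h, x = x)
}

# Full EGC stack + max pooling for a batch; returns tape nodes.
egnn_pool_tape <- function(tape, pn, batch, config) {
  h <- ad_add_bias(tape, ad_mm(tape, ad_leaf(tape, batch$feats), pn$embed_W),
                   pn$embed_b)
  x <- ad_leaf(tape, batch$coords)
  efn <- ad_leaf(tape, batch$ef)
  n <- nrow(batch$feats)
  for (l in seq_len(config$n_layers)) {
    st <- egc_layer_tape(tape, pn, l, h, x, batch$ei, batch$ej, efn, n, config)
    h <- st$h; x <- st$x
  }
  list(pooled = ad_maxpool(tape, h, batch$gid, batch$ngraph), coords = x)
}

param_nodes <- function(tape, params) lapply(params, function(p) ad_leaf(tape, p))

#' One EGC layer forward pass
#'
#' Applies a single E(n)-equivariant graph convolution layer to a graph and
#' node-state matrix: scalar states update invariantly, coordinates
#' equivariantly, under any rigid motion of the input coordinates.
#'
#' @param graph A `mutation_graph`.
#' @param h Numeric N x hidden matrix of node states.
#' @param model An `egnn_model` (or a bare parameter list with a `config`
#'   attribute) supplying layer weights.
#' @param layer Which layer's weights to apply (default 1).
#' @return List with updated `h` (N x hidden) and `coords` (N x 3).
#' @export
egc_forward <- function(graph, h, model, layer = 1L) {
  params <- model$params %||% model
  config <- model$config %||% attr(model, "config")
  if (is.null(config)) stop("model must carry a config")
  if (nrow(h) != nrow(graph$coords)) stop("h row count must equal node count")
  tape <- ad_tape()
  pn <- param_nodes(tape, params)
  b <- batch_graphs(list(graph))
  st <- egc_layer_tape(tape, pn, layer, ad_leaf(tape, h),
                       ad_leaf(tape, b$coords), b$ei, b$ej,
                       ad_leaf(tape, b$ef), nrow(h), config)
  list(h = st$h$value, coords = st$x$value)
}

# Pooled embeddings (values only) for a list of graphs.
embed_graphs <- function(params, config, graphs) {
  tape <- ad_tape()
  pn <- param_nodes(tape, params)
  b <- batch_graphs(graphs)
  egnn_pool_tape(tape, pn, b, config)$pooled$value
}

#' Siamese ddG prediction
#'
#' `linear_head(readout(EGC(wt)) - readout(EGC(mut)))` with a max-over-nodes
#' readout. With the head bias off, `siamese_predict(m, g1, g2)` equals
#' `-siamese_predict(m, g2, g1)` exactly and `siamese_predict(m, g, g) = 0`.
#'
#' @param model An `egnn_model`.
#' @param wt,mut Wild-type and mutant `mutation_graph`s, or lists of graphs
#'   of equal length.
#' @return Numeric vector of ddG estimates (kcal/mol).
#' @export
siamese_predict <- function(model, wt, mut) {
  if (inherits(wt, "mutation_graph")) { wt <- list(wt); mut <- list(mut) }
  stopifnot(length(wt) == length(mut))
  emb <- embed_graphs(model$params, model$config, c(wt, mut))
  k <- length(wt)
  diff <- emb[seq_len(k), , drop = FALSE] - emb[k + seq_len(k), , drop = FALSE]
  out <- diff %*% model$params$head_w
  if (model$config$head_bias) out <- out + model$params$head_b[1, 1]
  as.numeric(out)
}

#' Single-graph binding probability
#'
#' Logistic of the linear head applied to the pooled embedding; invariant to
#' rigid motions of the input.
#'
#' @param model An `egnn_model` trained with `task = "classification"`.
#' @param graph A `mutation_graph` or list of them.
#' @return Probabilities in `[0, 1]`.
#' @export
classify_binding <- function(model, graph) {
  if (inherits(graph, "mutation_graph")) graph <- list(graph)
  emb <- embed_graphs(model$params, model$config, graph)
  z <- emb %*% model$params$head_w
  if (model$config$head_bias) z <- z + model$params$head_b[1, 1]
  as.numeric(1 / (1 + exp(-z)))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + wd * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# Forward + loss for one mini-batch; returns loss value and parameter grads.
train_step <- function(params, config, examples, task, dropout) {
  tape <- ad_tape()
  pn <- param_nodes(tape, params)
  y <- vapply(examples, function(ex) ex$y, numeric(1))
  if (task == "regression") {
    graphs <- c(lapply(examples, `[[`, "wt"), lapply(examples, `[[`, "mut"))
    b <- batch_graphs(graphs, dropout)
    pooled <- egnn_pool_tape(tape, pn, b, config)$pooled
    k <- length(examples)
    sel_wt <- ad_gather(tape, pooled, seq_len(k))
    sel_mut <- ad_gather(tape, pooled, k + seq_len(k))
    z <- ad_mm(tape, ad_sub(tape, sel_wt, sel_mut), pn$head_w)
    if (config$head_bias) z <- ad_add_bias(tape, z, pn$head_b)
    loss <- ad_mse(tape, z, y)
  } else {
    graphs <- lapply(examples, `[[`, "graph")
    b <- batch_graphs(graphs, dropout)
    pooled <- egnn_pool_tape(tape, pn, b, config)$pooled
    z <- ad_mm(tape, pooled, pn$head_w)
    if (config$head_bias) z <- ad_add_bias(tape, z, pn$head_b)
    loss <- ad_bce_logits(tape, z, y)
  }
  ad_backward(tape, loss)
  grads <- lapply(pn, function(nd) nd$grad)
  list(loss = loss$value[1, 1], grads = grads)
}

predict_examples <- function(params, config, examples, task, chunk = 256L) {
  out <- numeric(length(examples))
  idx <- split(seq_along(examples), ceiling(seq_along(examples) / chunk))
  model <- list(params = params, config = config)
  for (ii in idx) {
    if (task == "regression") {
      out[ii] <- siamese_predict(model, lapply(examples[ii], `[[`, "wt"),
                                 lapply(examples[ii], `[[`, "mut"))
    } else {
      out[ii] <- classify_binding(model, lapply(examples[ii], `[[`, "graph"))
    }
  }
  out
}

#' Train an EGNN
#'
#' Mini-batch Adam with MSE loss (regression, Siamese WT/mutant input) or
#' binary cross-entropy with logits (classification, single graph). Edge
#' dropout is applied during training only. After each epoch the validation
#' metric (Pearson's correlation for regression, ROC AUC for classification)
#' is logged and the returned model is the checkpoint with the highest
#' validation metric. Fully reproducible given `config$seed`.
#'
#' @param train,val Disjoint lists of examples: `list(wt=, mut=, y=)` for
#'   regression, `list(graph=, y=)` for classification.
#' @param config A [model_config()].
#' @param task `"regression"` or `"classification"`.
#' @param quiet Suppress per-epoch progress messages.
#' @return An `egnn_model`: `params` (best checkpoint), `config`, `task`,
#'   `log` (per-epoch training loss and validation metric), `best_epoch`.
#' @export
train_egnn <- function(train, val, config = model_config(),
                       task = c("regression", "classification"),
                       quiet = TRUE) {
  task <- match.arg(task)
  if (!length(train) || !length(val)) stop("empty train or validation set")
  V <- ncol(if (task == "regression") train[[1]]$wt$features
            else train[[1]]$graph$features)
  with_seed(config$seed, {
    params <- init_params(config, V)
    st <- adam_state(params)
    n <- length(train)
    yval <- vapply(val, function(ex) ex$y, numeric(1))
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_metric = numeric(0))
    best <- -Inf; best_params <- params; best_epoch <- NA_integer_
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        ii <- perm[start:min(start + config$batch_size - 1L, n)]
        stp <- train_step(params, config, train[ii], task, config$edge_dropout)
        if (!is.finite(stp$loss))
          stop(sprintf("non-finite loss at epoch %d (%.4g); aborting", ep, stp$loss))
        upd <- adam_step(params, stp$grads, st, config$learning_rate,
                         config$weight_decay)
        params <- upd$params; st <- upd$state
        losses <- c(losses, stp$loss)
      }
      pv <- predict_examples(params, config, val, task)
      metric <- if (task == "regression") {
        if (stats::sd(pv) < 1e-12 || stats::sd(yval) < 1e-12) NA_real_
        else stats::cor(yval, pv)
      } else {
        roc_auc_value(yval, pv)
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_metric = metric))
      if (!quiet)
        message(sprintf("epoch %3d  loss %.4f  val %.4f", ep, mean(losses),
                        metric))
      if (is.finite(metric) && metric > best) {
        best <- metric; best_params <- params; best_epoch <- ep
      }
    }
    if (!is.finite(best)) { best_params <- params; best_epoch <- config$epochs }
    structure(list(params = best_params, config = config, task = task,
                   log = log, best_epoch = best_epoch),
              class = "egnn_model")
  })
}

#' @export
print.egnn_model <- function(x, ...) {
  cat(sprintf("egnn_model (%s): %d EGC layers, hidden %d; best epoch %d (val %.4f)\n",
              x$task, x$config$n_layers, x$config$hidden_dim, x$best_epoch,
              max(x$log$val_metric, na.rm = TRUE)))
  invisible(x)
}

#' Predict from a trained EGNN
#'
#' @param object An `egnn_model`.
#' @param examples List of examples as in [train_egnn()].
#' @param ... Unused.
#' @return Numeric predictions (ddG or binding probability).
#' @export
predict.egnn_model <- function(object, examples, ...) {
  predict_examples(object$params, object$config, examples, object$task)
}

#' Write / read checkpoint files
#'
#' Checkpoints are plain-text: one file per parameter matrix plus the config
#' and training log, so they survive text-only storage.
#'
#' @param model An `egnn_model`.
#' @param dir Checkpoint directory.
#' @return `dir` (write) or an `egnn_model` (read).
#' @export
write_checkpoint <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(model$params))
    utils::write.table(model$params[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(c(unclass(model$config),
                     list(task = model$task, best_epoch = model$best_epoch)),
                   file.path(dir, "config.yaml"))
  utils::write.table(model$log, file.path(dir, "log.tsv"), sep = "\t",
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(model_config,
                    cfgl[setdiff(names(cfgl), c("task", "best_epoch"))])
  files <- list.files(dir, pattern = "\\.tsv$", full.names = FALSE)
  files <- setdiff(files, "log.tsv")
  params <- lapply(files, function(f)
    as.matrix(utils::read.table(file.path(dir, f), sep = "\t")))
  names(params) <- sub("\\.tsv$", "", files)
  params <- lapply(params, function(m) { dimnames(m) <- NULL; m })
  log <- utils::read.table(file.path(dir, "log.tsv"), sep = "\t", header = TRUE)
  structure(list(params = params, config = config, task = cfgl$task,
                 log = log, best_epoch = cfgl$best_epoch),
            class = "egnn_model")
}
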