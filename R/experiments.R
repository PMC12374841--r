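# Experiment runners: learning curves over training-set size and robustness
# to label noise (shuffling / Gaussian perturbation). Both train on
# perturbed or subsampled train+validation pools and always evaluate on the
# same untouched test fold.

split_examples <- function(examples, assignment) {
  ids <- vapply(seq_along(examples), function(i) as.character(i), character(1))
  fold <- assignment$fold[ids]
  list(train = examples[which(fold == "train")],
       val = examples[which(fold == "val")],
       test = examples[which(fold == "test")],
       fold = fold)
}

# Cluster-respecting subsample of the train+val pool: whole clusters are
# drawn in seeded random order until `size` examples are reached (members of
# the last cluster are truncated; train/test disjointness is unaffected).
sample_pool <- function(pool_idx, cluster_of, size, seed) {
  if (size > length(pool_idx)) stop("requested size exceeds the train+val pool")
  with_seed(seed, {
    cl <- split(pool_idx, cluster_of[pool_idx])
    cl <- cl[sample(length(cl))]
    out <- integer(0)
    for (g in cl) {
      take <- min(length(g), size - length(out))
      out <- c(out, with_seed(seed + length(out), sample(g))[seq_len(take)])
      if (length(out) == size) break
    }
    out
  })
}

#' Learning-curve experiment
#'
#' For each requested size, draws a cluster-respecting subsample of the
#' train+validation pool, trains a model, and evaluates on the common test
#' fold. Smaller training sets are expected to regress toward the mean:
#' correlation can stay moderate while the standard-deviation ratio drops.
#'
#' @param examples List of Siamese examples (see [build_siamese_examples()]).
#' @param assignment A `split_assignment` over example indices (as
#'   character ids "1".."n").
#' @param cluster_of Character vector: cluster id per example.
#' @param sizes Integer vector of train+validation sizes.
#' @param config A [model_config()].
#' @param seed Integer seed for subsampling.
#' @return data.frame (size, pearson, sdr, n_test, seed).
#' @export
learning_curve_experiment <- function(examples, assignment, cluster_of, sizes,
                                      config = model_config(), seed = 1L) {
  sp <- split_examples(examples, assignment)
  pool_idx <- which(sp$fold %in% c("train", "val"))
  ytest <- vapply(sp$test, `[[`, numeric(1), "y")
  out <- data.frame()
  for (size in sizes) {
    sub <- sample_pool(pool_idx, cluster_of, size, seed)
    n_val <- max(2L, floor(length(sub) / 9))   # ~80/10 within the pool
    val_idx <- sub[seq_len(n_val)]
    tr_idx <- setdiff(sub, val_idx)
    fit <- train_egnn(examples[tr_idx], examples[val_idx], config)
    pred <- predict(fit, sp$test)
    mr <- metrics_report(ytest, pred)
    out <- rbind(out, data.frame(size = size, pearson = mr$pearson_r,
                                 sdr = mr$sdr, n_test = length(ytest),
                                 seed = seed))
  }
  out
}

#' Noise-robustness experiment
#'
#' Perturbs the train+validation labels by shuffling (at each fraction) or
#' by additive Gaussian noise (at each scale), trains on the perturbed
#' labels, and evaluates on the clean test fold.
#'
#' @inheritParams learning_curve_experiment
#' @param shuffle_fractions Fractions in `[0, 1]` of train+val labels to
#'   permute (0 reproduces the unperturbed run).
#' @param gaussian_scales Standard deviations of additive label noise.
#' @return data.frame (perturbation, level, effective_percent, pearson,
#'   sdr, n_test).
#' @export
noise_robustness_experiment <- function(examples, assignment,
                                        shuffle_fractions = numeric(0),
                                        gaussian_scales = numeric(0),
                                        config = model_config(), seed = 1L) {
  sp <- split_examples(examples, assignment)
  ytest <- vapply(sp$test, `[[`, numeric(1), "y")
  pool <- c(sp$train, sp$val)
  n_tr <- length(sp$train)
  run_one <- function(perturbed_pool) {
    fit <- train_egnn(perturbed_pool[seq_len(n_tr)],
                      perturbed_pool[(n_tr + 1):length(perturbed_pool)], config)
    pred <- predict(fit, sp$test)
    metrics_report(ytest, pred)
  }
  relabel <- function(pool, labels) {
    for (i in seq_along(pool)) pool[[i]]$y <- labels[i]
    pool
  }
  y_pool <- vapply(pool, `[[`, numeric(1), "y")
  out <- data.frame()
  for (f in shuffle_fractions) {
    sh <- shuffle_labels(y_pool, f, seed = seed)
    mr <- run_one(relabel(pool, sh$labels))
    out <- rbind(out, data.frame(perturbation = "shuffle", level = f,
                                 effective_percent = sh$effective_percent,
                                 pearson = mr$pearson_r, sdr = mr$sdr,
                                 n_test = length(ytest)))
  }
  for (s in gaussian_scales) {
    lab <- add_gaussian_noise(y_pool, s, seed = seed)
    mr <- run_one(relabel(pool, lab))
    out <- rbind(out, data.frame(perturbation = "gaussian", level = s,
                                 effective_percent = NA_real_,
                                 pearson = mr$pearson_r, sdr = mr$sdr,
                                 n_test = length(ytest)))
  }
  out
}

#' Cluster examples of a synthetic dataset by complex sequence identity
#'
#' Concatenates the antibody chain sequences of each complex (the fixture
#' analogue of length-matched concatenated CDRs) and clusters them with
#' [length_binned_cluster()]; every example inherits its complex's cluster.
#'
#' @param dataset A `ddg_dataset`.
#' @param identity_cutoff Identity cutoff for clustering.
#' @return Character vector: cluster id per dataset row.
#' @export
dataset_clusters <- function(dataset, identity_cutoff = 0.9) {
  seqs <- vapply(dataset$complexes, function(cs) {
    sq <- attr(cs, "sequences")
    paste0(sq$H, sq$L)
  }, character(1))
  cl <- length_binned_cluster(seqs, identity_cutoff)
  unname(cl$membership[dataset$table$complex_id])
}

#' End-to-end split of a synthetic dataset
#'
#' Clusters complexes, assigns cluster-disjoint 80/10/10 folds weighted by
#' examples per complex, and returns the per-example assignment keyed by
#' example index.
#'
#' @param dataset A `ddg_dataset`.
#' @param identity_cutoff Identity cutoff for clustering.
#' @param seed Integer seed for fold tie-breaking.
#' @return List with `assignment` (a `split_assignment` keyed "1".."n") and
#'   `cluster_of` (cluster id per example).
#' @export
dataset_split <- function(dataset, identity_cutoff = 0.9, seed = 1L) {
  cluster_of <- dataset_clusters(dataset, identity_cutoff)
  n <- nrow(dataset$table)
  ids <- as.character(seq_len(n))
  cl <- new_cluster_set(stats::setNames(cluster_of, ids),
                        stats::setNames(ids[!duplicated(cluster_of)],
                                        unique(cluster_of)))
  assignment <- assign_folds(cl, scheme = "split", seed = seed)
  list(assignment = assignment, cluster_of = cluster_of)
}
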