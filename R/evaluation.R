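# Evaluation: regression/classification metrics (Pearson, Spearman,
# standard-deviation ratio, RMSE, ROC-AUC, average precision), filtered
# metric variants, and the simple baselines (contact-count change,
# structure-informed one-hot sequence features).

roc_auc_value <- function(y, p) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

# Average precision: sum over threshold steps of (recall gain x precision),
# predictions sorted by decreasing score.
average_precision_value <- function(y, p) {
  if (sum(y) == 0) return(NA_real_)
  ord <- order(-p)
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / sum(y)
  sum(diff(c(0, rec)) * prec)
}

#' Metrics report
#'
#' Pearson and Spearman correlations by their standard definitions, the
#' standard deviation ratio `sdr = min(sd_true, sd_pred) / max(sd_true,
#' sd_pred)` (sample standard deviations; detects regression-to-the-mean
#' despite high correlation), and RMSE. Classification additionally reports
#' ROC-AUC and average precision. Correlations on a constant vector are
#' flagged undefined (`NA` value plus `undefined = TRUE`) rather than
#' NaN-propagated; `sdr` is 0 when one standard deviation is 0.
#'
#' @param true_values,predictions Equal-length numeric vectors, n >= 2. For
#'   classification, `true_values` are 0/1 labels and `predictions` scores.
#' @param task `"regression"` or `"classification"`.
#' @return A `metrics_report` list: `pearson_r`, `spearman_rho`, `sdr`,
#'   `rmse`, `n_examples`, `undefined`; plus `roc_auc`, `average_precision`
#'   for classification.
#' @export
metrics_report <- function(true_values, predictions,
                           task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(length(true_values) == length(predictions))
  if (length(true_values) < 2) stop("need at least 2 examples")
  sd_t <- stats::sd(true_values); sd_p <- stats::sd(predictions)
  undefined <- sd_t < 1e-300 || sd_p < 1e-300
  pear <- if (undefined) NA_real_ else stats::cor(true_values, predictions)
  spear <- if (undefined) NA_real_ else
    stats::cor(true_values, predictions, method = "spearman")
  sdr <- if (undefined) 0 else min(sd_t, sd_p) / max(sd_t, sd_p)
  out <- list(pearson_r = pear, spearman_rho = spear, sdr = sdr,
              rmse = sqrt(mean((true_values - predictions)^2)),
              n_examples = length(true_values), undefined = undefined)
  if (task == "classification") {
    out$roc_auc <- roc_auc_value(true_values, predictions)
    out$average_precision <- average_precision_value(true_values, predictions)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n=%d): r=%.4f rho=%.4f sdr=%.4f rmse=%.4f%s\n",
              x$n_examples, x$pearson_r, x$spearman_rho, x$sdr, x$rmse,
              if (!is.null(x$roc_auc))
                sprintf(" auc=%.4f ap=%.4f", x$roc_auc, x$average_precision)
              else ""))
  invisible(x)
}

#' Filtered metrics
#'
#' `exclude_small` drops pairs with |true| < 1 kcal/mol (small-effect
#' mutations carry less signal); `exclude_deep` drops pairs with true <=
#' -12.2 kcal/mol (below the experimentally measurable range). Metrics are
#' computed on the remainder; the retained fraction is reported. An empty
#' remainder is flagged instead of erroring.
#'
#' @inheritParams metrics_report
#' @param rule `"exclude_small"` or `"exclude_deep"`.
#' @return A `metrics_report` with `retained_fraction`, or a flagged empty
#'   report (`empty = TRUE`) when nothing remains.
#' @export
filtered_metrics <- function(true_values, predictions,
                             rule = c("exclude_small", "exclude_deep")) {
  rule <- match.arg(rule)
  keep <- switch(rule,
                 exclude_small = abs(true_values) >= 1,
                 exclude_deep = true_values > -12.2)
  if (sum(keep) < 2) {
    return(structure(list(empty = TRUE, retained_fraction = mean(keep),
                          n_examples = sum(keep)),
                     class = "metrics_report"))
  }
  out <- metrics_report(true_values[keep], predictions[keep])
  out$retained_fraction <- mean(keep)
  out$empty <- FALSE
  out
}

#' Contact-count change baseline
#'
#' `score = contacts(mut) - contacts(wt)` with the 4 Angstrom interaction
#' cutoff; contact loss gives a negative score, aligned with destabilizing
#' negative ddG.
#'
#' @param wt,mut Paired [complex_structure()]s.
#' @param cutoff Contact cutoff in Angstrom.
#' @return Numeric score.
#' @export
contact_baseline <- function(wt, mut, cutoff = 4.0) {
  inter_partner_contacts(mut, cutoff) - inter_partner_contacts(wt, cutoff)
}

# Interface position layout shared by the one-hot featurization: antibody
# interface positions in sequence order, then antigen interface positions in
# the order of the first antibody interface position each contacts (ties by
# antigen position).
interface_layout <- function(cs, cutoff = 4.0) {
  a <- cs$atoms
  is_ab <- partner_mask(cs)
  d2 <- cross_dist2(coords_of(cs)[is_ab, , drop = FALSE],
                    coords_of(cs)[!is_ab, , drop = FALSE])
  hit <- d2 < cutoff^2
  ab_atoms <- a[is_ab, , drop = FALSE]; ag_atoms <- a[!is_ab, , drop = FALSE]
  ab_res <- res_key(ab_atoms); ag_res <- res_key(ag_atoms)
  ab_keys <- unique(ab_res[rowSums(hit) > 0])
  ab_keys <- ab_keys[order(match(ab_keys, ab_res))]   # sequence order
  ag_keys <- unique(ag_res[colSums(hit) > 0])
  first_contact <- vapply(ag_keys, function(k) {
    cols <- which(ag_res == k)
    rows <- which(rowSums(hit[, cols, drop = FALSE]) > 0)
    min(match(ab_res[rows], ab_keys), na.rm = TRUE)
  }, numeric(1))
  ag_keys <- ag_keys[order(first_contact, match(ag_keys, ag_res))]
  res_aa <- function(keys, atoms, res) {
    vapply(keys, function(k) aa_one(atoms$resid[match(k, res)]), character(1))
  }
  list(ab_keys = ab_keys, ag_keys = ag_keys,
       ab_aa = res_aa(ab_keys, ab_atoms, ab_res),
       ag_aa = res_aa(ag_keys, ag_atoms, ag_res))
}

onehot_block <- function(aa_list, width) {
  alphabet <- c(AA1, "-")
  m <- matrix(0, length(aa_list), width * length(alphabet))
  for (i in seq_along(aa_list)) {
    aa <- c(aa_list[[i]], rep("-", width - length(aa_list[[i]])))
    idx <- match(aa, alphabet)
    m[i, (seq_len(width) - 1L) * length(alphabet) + idx] <- 1
  }
  m
}

#' Structure-informed one-hot sequence features
#'
#' Four blocks per example - WT antibody, WT antigen, mutant antibody,
#' mutant antigen interface residues, in this order - each a per-position
#' 21-way one-hot (20 amino acids plus an explicit pad symbol), padded per
#' block to the dataset-wide maximum length. Antibody positions follow
#' sequence order; antigen positions follow the order in which they first
#' contact the antibody interface positions.
#'
#' @param complexes List of WT [complex_structure()]s, one per mutation.
#' @param mutations List of [mutation()]s, parallel to `complexes`.
#' @param cutoff Interface cutoff in Angstrom.
#' @return Numeric feature matrix, one row per example, with a
#'   `block_widths` attribute.
#' @export
sequence_onehot_features <- function(complexes, mutations, cutoff = 4.0) {
  stopifnot(length(complexes) == length(mutations))
  layouts <- lapply(complexes, interface_layout, cutoff = cutoff)
  mut_aa_at <- function(lay, cs, mut, keys, aa) {
    key <- paste(mut$chain, mut$resno, mut$ins, sep = "|")
    i <- match(key, keys)
    if (!is.na(i)) aa[i] <- mut$mut_aa
    aa
  }
  wt_ab <- lapply(layouts, `[[`, "ab_aa")
  wt_ag <- lapply(layouts, `[[`, "ag_aa")
  mu_ab <- vector("list", length(layouts))
  mu_ag <- vector("list", length(layouts))
  for (i in seq_along(layouts)) {
    lay <- layouts[[i]]; mut <- mutations[[i]]
    mu_ab[[i]] <- mut_aa_at(lay, complexes[[i]], mut, lay$ab_keys, lay$ab_aa)
    mu_ag[[i]] <- mut_aa_at(lay, complexes[[i]], mut, lay$ag_keys, lay$ag_aa)
  }
  w_ab <- max(vapply(wt_ab, length, integer(1)))
  w_ag <- max(vapply(wt_ag, length, integer(1)))
  out <- cbind(onehot_block(wt_ab, w_ab), onehot_block(wt_ag, w_ag),
               onehot_block(mu_ab, w_ab), onehot_block(mu_ag, w_ag))
  attr(out, "block_widths") <- c(wt_ab = w_ab, wt_ag = w_ag,
                                 mut_ab = w_ab, mut_ag = w_ag)
  out
}
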