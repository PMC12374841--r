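# Leakage-free splitting and dataset-design machinery: length-binned greedy
# sequence clustering (a deterministic stand-in for CD-HIT on equal-length
# strings), union-merge of antibody/antigen cluster sets, cluster-disjoint
# fold assignment, affinity-ordered splits, clonotype + edit-distance
# clustering, interface shell geometry, diversity profiles and min/max
# diversity subset construction, and the label perturbations (shuffling,
# Gaussian noise) used by the robustness experiments.

new_cluster_set <- function(membership, representatives) {
  structure(list(membership = membership, representatives = representatives),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$membership), "members in",
      length(unique(x$membership)), "clusters\n")
  invisible(x)
}

seq_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) return(0)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Length-binned greedy sequence clustering
#'
#' Sequences are binned by exact length; within a bin, greedy leader
#' clustering in a deterministic order (descending length, then
#' lexicographic): a sequence joins the first existing cluster whose
#' representative (founder) it matches at >= `identity_cutoff` fraction of
#' positions, else it founds a new cluster.
#'
#' @param seqs Named character vector of sequences (names are member ids).
#' @param identity_cutoff Identity fraction in `[0.7, 1]`.
#' @return A `cluster_set` (member -> cluster id, plus per-cluster
#'   representative).
#' @export
length_binned_cluster <- function(seqs, identity_cutoff = 0.9) {
  stopifnot(identity_cutoff >= 0.7, identity_cutoff <= 1)
  if (!length(seqs))
    return(new_cluster_set(stats::setNames(character(0), character(0)),
                           character(0)))
  if (is.null(names(seqs))) names(seqs) <- paste0("m", seq_along(seqs))
  ord <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[ord]
  membership <- stats::setNames(character(length(seqs)), names(seqs))
  reps <- character(0)      # representative sequence per cluster
  rep_member <- character(0)
  cid <- 0L
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    assigned <- NA_integer_
    for (k in seq_along(reps)) {
      if (nchar(reps[k]) == nchar(s) && seq_identity(s, reps[k]) >= identity_cutoff) {
        assigned <- k; break
      }
    }
    if (is.na(assigned)) {
      cid <- cid + 1L
      reps[cid] <- s
      rep_member[cid] <- names(seqs)[i]
      assigned <- cid
    }
    membership[i] <- paste0("c", assigned)
  }
  new_cluster_set(membership,
                  stats::setNames(rep_member, paste0("c", seq_along(rep_member))))
}

#' Merge antibody and antigen cluster sets
#'
#' Connected components of the union of the two cluster graphs (union-find),
#' so that no output cluster links to another through either antibody or
#' antigen similarity.
#'
#' @param ab_clusters,ag_clusters `cluster_set`s over the same member
#'   universe.
#' @return A merged `cluster_set`.
#' @export
merge_cluster_sets <- function(ab_clusters, ag_clusters) {
  ma <- ab_clusters$membership; mg <- ag_clusters$membership
  if (!setequal(names(ma), names(mg)))
    stop("cluster sets cover different member universes")
  members <- names(ma)
  parent <- stats::setNames(seq_along(members), members)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  link_clusters <- function(mm) {
    for (grp in split(names(mm), mm)) {
      if (length(grp) < 2) next
      r0 <- find(match(grp[1], members))
      for (g in grp[-1]) {
        r <- find(match(g, members))
        if (r != r0) parent[r] <<- r0
      }
    }
  }
  link_clusters(ma)
  link_clusters(mg)
  roots <- vapply(seq_along(members), find, integer(1))
  ids <- paste0("m", match(roots, unique(roots)))
  reps <- members[!duplicated(roots)]
  new_cluster_set(stats::setNames(ids, members),
                  stats::setNames(reps, unique(ids)))
}

#' Cluster-disjoint fold assignment
#'
#' Whole clusters (never individual members) are assigned greedily, largest
#' first with seeded tie-breaking, to the fold with the largest remaining
#' deficit, hitting the target fractions as closely as cluster granularity
#' permits. A `"random"` scheme ignores clusters and splits members at
#' random (the documented no-cutoff mode).
#'
#' @param clusters A `cluster_set`.
#' @param weights Optional named numeric member weights (default 1 each).
#' @param scheme `"split"` (train/val/test), `"kfold"`, or `"random"`.
#' @param fractions Target fractions for `"split"` (default 80/10/10).
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed for tie-breaking.
#' @param train_val_only Optional named logical; flagged members assigned to
#'   the test fold are moved to train (reverse-mutation contract).
#' @return A `split_assignment`: list with `fold` (named member -> fold
#'   label) and `scheme`.
#' @export
assign_folds <- function(clusters, weights = NULL,
                         scheme = c("split", "kfold", "random"),
                         fractions = c(0.8, 0.1, 0.1), k = 10L, seed = 1L,
                         train_val_only = NULL) {
  scheme <- match.arg(scheme)
  members <- names(clusters$membership)
  if (!length(members)) stop("empty cluster set")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(members)), members)
  fold_labels <- if (scheme == "kfold") as.character(seq_len(k))
                 else c("train", "val", "test")
  targets <- if (scheme == "kfold") rep(sum(weights[members]) / k, k)
             else fractions / sum(fractions) * sum(weights[members])
  fold <- stats::setNames(character(length(members)), members)
  if (scheme == "random") {
    ord <- with_seed(seed, sample(members))
    n <- length(ord)
    n_tr <- floor(fractions[1] / sum(fractions) * n)
    n_va <- floor(fractions[2] / sum(fractions) * n)
    fold[ord] <- c(rep("train", n_tr), rep("val", n_va),
                   rep("test", n - n_tr - n_va))
  } else {
    csize <- tapply(weights[members], clusters$membership[members], sum)
    cl_ids <- with_seed(seed, sample(names(csize)))   # seeded tie order
    cl_ids <- cl_ids[order(-csize[cl_ids])]           # stable: largest first
    if (max(csize) > max(targets))
      warning(sprintf("a cluster of weight %g exceeds the largest fold target %g; best-effort assignment",
                      max(csize), max(targets)))
    load <- stats::setNames(rep(0, length(fold_labels)), fold_labels)
    for (cl in cl_ids) {
      deficit <- targets - load
      f <- fold_labels[which.max(deficit)]
      mem <- members[clusters$membership[members] == cl]
      fold[mem] <- f
      load[f] <- load[f] + csize[[cl]]
    }
  }
  if (!is.null(train_val_only) && scheme != "kfold") {
    flagged <- names(train_val_only)[isTRUE_vec(train_val_only)]
    move <- intersect(flagged, members[fold[members] == "test"])
    fold[move] <- "train"
  }
  structure(list(fold = fold, scheme = scheme), class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("split_assignment (", x$scheme, "): ", sep = "")
  print(table(x$fold))
  invisible(x)
}

#' Affinity-ordered split
#'
#' Sorts by label (ties broken by stable input order): the lowest 80% of
#' ddG values go to training, the next 10% to validation, and the top 10%
#' to test.
#'
#' @param labels Numeric labels, optionally named.
#' @param fractions Train/val/test fractions.
#' @return A `split_assignment`.
#' @export
affinity_split <- function(labels, fractions = c(0.8, 0.1, 0.1)) {
  n <- length(labels)
  ids <- names(labels) %||% as.character(seq_len(n))
  ord <- order(labels)   # stable for ties
  n_tr <- floor(fractions[1] / sum(fractions) * n)
  n_va <- floor(fractions[2] / sum(fractions) * n)
  fold <- stats::setNames(character(n), ids)
  fold[ord] <- c(rep("train", n_tr), rep("val", n_va),
                 rep("test", n - n_tr - n_va))
  structure(list(fold = fold, scheme = "affinity"), class = "split_assignment")
}

#' Clonotype + edit-distance clustering
#'
#' Variants are grouped by (V gene, J gene); within a group, greedy leader
#' clustering in input order where a variant joins a cluster iff its Hamming
#' distance to the cluster center is at most
#' `floor((1 - identity_cutoff) * length)` (e.g. 70% identity on 10-mers
#' allows edit distances up to 3).
#'
#' @param variants data.frame with columns `v_gene`, `j_gene`, `cdrh3`
#'   (fixed-length strings); row names (or a `id` column) are member ids.
#' @param identity_cutoff Identity fraction.
#' @return A `cluster_set`.
#' @export
clonotype_edit_split <- function(variants, identity_cutoff = 0.7) {
  len <- unique(nchar(variants$cdrh3))
  if (length(len) != 1) stop("variant strings must share one fixed length")
  max_edit <- floor((1 - identity_cutoff) * len)
  ids <- variants$id %||% rownames(variants) %||% as.character(seq_len(nrow(variants)))
  membership <- stats::setNames(character(nrow(variants)), ids)
  reps <- character(0); rep_member <- character(0); cid <- 0L
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  grp_key <- paste(variants$v_gene, variants$j_gene, sep = "|")
  for (grp in split(seq_len(nrow(variants)), factor(grp_key, unique(grp_key)))) {
    local_reps <- integer(0)   # indices into reps founded in this group
    for (i in grp) {
      s <- variants$cdrh3[i]
      assigned <- NA_integer_
      for (k in local_reps) {
        if (hamming(s, reps[k]) <= max_edit) { assigned <- k; break }
      }
      if (is.na(assigned)) {
        cid <- cid + 1L
        reps[cid] <- s; rep_member[cid] <- ids[i]
        local_reps <- c(local_reps, cid)
        assigned <- cid
      }
      membership[i] <- paste0("c", assigned)
    }
  }
  new_cluster_set(membership,
                  stats::setNames(rep_member, paste0("c", seq_along(rep_member))))
}

# inner/outer classification given projected radii and the max radius:
# the outer shell circle has sqrt(2) times the inner radius, producing two
# equal areas; a point is inner iff r <= R / sqrt(2).
classify_shell_radii <- function(radii, outer_radius = max(radii)) {
  ifelse(radii <= outer_radius / sqrt(2), "inner", "outer")
}

#' Classify a mutation's interface location
#'
#' Interface residues (4 Angstrom rule, represented by their CA atoms) are
#' projected onto their best-fit plane (principal-component plane through
#' the interface centroid). With R the maximum projected radial distance,
#' the inner shell is the disc of radius `R / sqrt(2)` (equal areas with the
#' outer annulus); the mutation is classified inner iff its projected radius
#' is at most `R / sqrt(2)`. Degenerate (near-collinear) interfaces fall
#' back to 3-D radial distance from the centroid.
#'
#' @param cs A [complex_structure()].
#' @param mut A [mutation()] at an interface residue.
#' @param cutoff Interface cutoff in Angstrom.
#' @return List with `partner` ("antibody"/"antigen"), `shell`
#'   ("inner"/"outer"), `radius` and `outer_radius`.
#' @export
shell_classify <- function(cs, mut, cutoff = 4.0) {
  ifr <- interface_residues(cs, cutoff)
  hit <- ifr$chain == mut$chain & ifr$resno == mut$resno & ifr$ins == mut$ins
  if (!any(hit)) stop("mutation is not at an interface residue")
  a <- cs$atoms
  ca <- a[a$elety == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resno, ca$ins, sep = "|")
  ikey <- paste(ifr$chain, ifr$resno, ifr$ins, sep = "|")
  rep_xyz <- as.matrix(ca[match(ikey, key), c("x", "y", "z")])
  centroid <- colMeans(rep_xyz)
  centered <- sweep(rep_xyz, 2, centroid)
  mut_ca <- as.numeric(ca[match(paste(mut$chain, mut$resno, mut$ins, sep = "|"),
                                key), c("x", "y", "z")]) - centroid
  degenerate <- nrow(rep_xyz) < 3
  if (!degenerate) {
    pr <- stats::prcomp(centered, center = FALSE)
    degenerate <- pr$sdev[2] < 1e-8
  }
  if (degenerate) {
    message("degenerate (collinear) interface; falling back to 3-D radial distance")
    radii <- sqrt(rowSums(centered^2))
    r_mut <- sqrt(sum(mut_ca^2))
  } else {
    basis <- pr$rotation[, 1:2, drop = FALSE]
    radii <- sqrt(rowSums((centered %*% basis)^2))
    r_mut <- sqrt(sum((mut_ca %*% basis)^2))
  }
  R <- max(radii)
  list(partner = unname(cs$partner_of[[mut$chain]]),
       shell = classify_shell_radii(r_mut, R),
       radius = r_mut, outer_radius = R)
}

#' Diversity profile of an annotated dataset
#'
#' @param dataset data.frame with columns `cluster`, `wt_aa`, `mut_aa`,
#'   `partner`, `shell`.
#' @return List with `n_antibody_clusters`, `substitution_type_counts`
#'   (counts over wt->mut types, identity excluded by construction),
#'   `location_counts` (partner x inner/outer) and `n`.
#' @export
diversity_profile <- function(dataset) {
  stopifnot(all(c("cluster", "wt_aa", "mut_aa", "partner", "shell") %in%
                  names(dataset)))
  subs <- paste(dataset$wt_aa, dataset$mut_aa, sep = ">")
  loc <- paste(dataset$partner, dataset$shell, sep = "/")
  structure(list(n_antibody_clusters = length(unique(dataset$cluster)),
                 substitution_type_counts = table(subs),
                 location_counts = table(loc),
                 n = nrow(dataset)),
            class = "diversity_profile")
}

#' Select a minimum- or maximum-diversity subset
#'
#' `min`: fill `n` examples from as few categories as possible (largest
#' categories first). `max`: round-robin one example per category, cycling
#' until `n` examples are drawn. Category order and within-category order
#' are seeded and deterministic.
#'
#' @param dataset Annotated data.frame (as [diversity_profile()]).
#' @param metric One of `"sequence"` (antibody cluster),
#'   `"substitution_type"` (wt->mut pair), `"substitution_distribution"`
#'   (partner x shell).
#' @param direction `"min"` or `"max"`.
#' @param n Subset size (<= nrow(dataset)).
#' @param seed Integer seed.
#' @return Integer row indices of the subset.
#' @export
select_subset <- function(dataset, metric = c("sequence", "substitution_type",
                                              "substitution_distribution"),
                          direction = c("min", "max"), n, seed = 1L) {
  metric <- match.arg(metric); direction <- match.arg(direction)
  if (n > nrow(dataset)) stop("n exceeds dataset size")
  cat_of <- switch(metric,
                   sequence = as.character(dataset$cluster),
                   substitution_type = paste(dataset$wt_aa, dataset$mut_aa, sep = ">"),
                   substitution_distribution = paste(dataset$partner, dataset$shell,
                                                     sep = "/"))
  with_seed(seed, {
    groups <- split(seq_len(nrow(dataset)), cat_of)
    groups <- lapply(groups, sample)               # seeded within-category order
    sizes <- vapply(groups, length, integer(1))
    ord <- sample(names(groups))                   # seeded tie order
    ord <- ord[order(-sizes[ord])]                 # largest categories first
    groups <- groups[ord]
    if (direction == "min") {
      out <- integer(0)
      for (g in groups) {
        take <- min(length(g), n - length(out))
        out <- c(out, g[seq_len(take)])
        if (length(out) == n) break
      }
    } else {
      out <- integer(0); round <- 1L
      while (length(out) < n) {
        added <- FALSE
        for (g in groups) {
          if (length(out) == n) break
          if (length(g) >= round) { out <- c(out, g[round]); added <- TRUE }
        }
        if (!added) break
        round <- round + 1L
      }
    }
    sort(out)
  })
}

#' Shuffle a fraction of (train+validation) labels
#'
#' A seeded random subset of `ceiling(fraction * N)` eligible labels is
#' permuted among itself (uniform random permutation); ineligible (test)
#' labels are untouched. The effective percentage is the share of eligible
#' labels whose value actually changed - not necessarily equal to
#' `fraction`, since equal labels or fixed points of the permutation leave
#' values in place.
#'
#' @param labels Numeric label vector.
#' @param fraction Fraction in `[0, 1]` of eligible labels to permute.
#' @param seed Integer seed.
#' @param eligible Logical vector (default all): labels allowed to move.
#' @return List with `labels` (perturbed) and `effective_percent` (0-100).
#' @export
shuffle_labels <- function(labels, fraction, seed = 1L, eligible = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (is.null(eligible)) eligible <- rep(TRUE, length(labels))
  pool <- which(eligible)
  N <- length(pool)
  out <- labels
  if (fraction > 0 && N > 1) {
    with_seed(seed, {
      m <- min(N, ceiling(fraction * N))
      pick <- sample(pool, m)
      out[pick] <- out[sample(pick)]
    })
  }
  list(labels = out,
       effective_percent = 100 * mean(out[pool] != labels[pool]))
}

#' Add Gaussian label noise
#'
#' Adds seeded draws from Normal(0, `scale`) to eligible (train+validation)
#' labels; test labels are untouched.
#'
#' @inheritParams shuffle_labels
#' @param scale Noise standard deviation (>= 0).
#' @return Perturbed label vector.
#' @export
add_gaussian_noise <- function(labels, scale, seed = 1L, eligible = NULL) {
  stopifnot(scale >= 0)
  if (is.null(eligible)) eligible <- rep(TRUE, length(labels))
  if (scale == 0) return(labels)
  with_seed(seed, {
    labels[eligible] <- labels[eligible] +
      stats::rnorm(sum(eligible), 0, scale)
    labels
  })
}
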