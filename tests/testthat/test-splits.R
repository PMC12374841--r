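# Clustering, fold assignment, shells, diversity subsets, label perturbation.

random_seqs <- function(n, len, seed) {
  set.seed(seed)
  stats::setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "D", "E"), len, TRUE), collapse = ""),
    character(1)), paste0("s", seq_len(n)))
}

test_that("leader clustering groups identical sequences and splits dissimilar ones", {
  cl <- length_binned_cluster(c(a = "ACDEF", b = "ACDEF"), 0.9)
  expect_equal(unname(cl$membership["a"]), unname(cl$membership["b"]))
  # 40% of positions differ -> below a 0.9 cutoff
  cl2 <- length_binned_cluster(c(a = "AAAAAAAAAA", b = "CCCCAAAAAA"), 0.9)
  expect_false(cl2$membership[["a"]] == cl2$membership[["b"]])
  expect_equal(length(length_binned_cluster(character(0), 0.9)$membership), 0)
})

test_that("clustering matches the brute-force leader reference on random inputs", {
  for (seed in 1:4) {
    seqs <- random_seqs(50, 8, seed)
    got <- length_binned_cluster(seqs, 0.75)
    ref <- bf_leader_cluster(seqs, 0.75)
    expect_true(same_partition(got$membership, ref))
  }
})

test_that("a cutoff of 1.0 only groups identical sequences", {
  seqs <- random_seqs(60, 4, 99)
  cl <- length_binned_cluster(seqs, 1.0)
  for (grp in split(names(cl$membership), cl$membership)) {
    expect_equal(length(unique(seqs[grp])), 1)
  }
})

test_that("merging cluster sets takes connected components across both", {
  m <- function(x) graphddg:::new_cluster_set(x, x[!duplicated(x)])
  ab <- m(c(a = "c1", b = "c1", c = "c2"))
  ag <- m(c(a = "c9", b = "c8", c = "c8"))
  merged <- merge_cluster_sets(ab, ag)
  expect_equal(length(unique(merged$membership)), 1)   # a~b (ab), b~c (ag)
  same <- merge_cluster_sets(ab, ab)
  expect_true(same_partition(same$membership, ab$membership))
  expect_error(merge_cluster_sets(ab, m(c(a = "c1", z = "c2", c = "c3"))),
               "universe")
  # random overlapping partitions vs naive component search
  set.seed(3)
  for (rep in 1:5) {
    ids <- paste0("x", 1:30)
    p1 <- stats::setNames(sample(paste0("a", 1:8), 30, TRUE), ids)
    p2 <- stats::setNames(sample(paste0("b", 1:8), 30, TRUE), ids)
    got <- merge_cluster_sets(m(p1), m(p2))$membership
    # naive: iterate merging until fixed point
    lab <- seq_along(ids); names(lab) <- ids
    repeat {
      changed <- FALSE
      for (p in list(p1, p2)) for (grp in split(ids, p)) {
        tgt <- min(lab[grp])
        if (any(lab[grp] != tgt)) {
          lab[lab %in% lab[grp]] <- tgt
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    expect_true(same_partition(got, stats::setNames(as.character(lab),
                                                    names(lab))))
  }
})

test_that("fold assignment is cluster-disjoint and near target fractions", {
  # singleton clusters: sizes within 1 of 80/10/10
  ids <- paste0("e", 1:100)
  singles <- graphddg:::new_cluster_set(
    stats::setNames(paste0("c", 1:100), ids),
    stats::setNames(ids, paste0("c", 1:100)))
  sp <- assign_folds(singles, seed = 4)
  counts <- as.numeric(table(sp$fold)[c("train", "val", "test")])
  expect_true(all(abs(counts - c(80, 10, 10)) <= 1))
  # one giant cluster: everything lands in one fold with a warning
  giant <- graphddg:::new_cluster_set(
    stats::setNames(rep("c1", 50), paste0("g", 1:50)),
    c(c1 = "g1"))
  expect_warning(spg <- assign_folds(giant, seed = 1), "exceeds")
  expect_equal(length(unique(spg$fold)), 1)
  # random cluster structures: no cluster ever spans folds
  for (seed in 1:5) {
    set.seed(seed)
    ids <- paste0("m", 1:200)
    memb <- stats::setNames(sample(paste0("c", 1:40), 200, TRUE), ids)
    cl <- graphddg:::new_cluster_set(memb, stats::setNames(ids[!duplicated(memb)],
                                                           unique(memb)))
    for (scheme in c("split", "kfold")) {
      sp <- assign_folds(cl, scheme = scheme, seed = seed)
      spans <- tapply(sp$fold[ids], memb[ids],
                      function(f) length(unique(f)))
      expect_true(all(spans == 1))
    }
  }
})

test_that("the affinity split sends the lowest labels to train, stably for ties", {
  sp <- affinity_split(stats::setNames(1:10, letters[1:10]))
  expect_setequal(names(sp$fold)[sp$fold == "train"], letters[1:8])
  expect_equal(names(sp$fold)[sp$fold == "val"], "i")
  expect_equal(names(sp$fold)[sp$fold == "test"], "j")
  tie <- affinity_split(stats::setNames(rep(1, 10), letters[1:10]))
  expect_setequal(names(tie$fold)[tie$fold == "train"], letters[1:8])
  # split thresholds equal brute-force quantiles on synthetic labels
  set.seed(8)
  y <- rnorm(500)
  sp2 <- affinity_split(y)
  expect_lt(max(y[sp2$fold == "train"]), min(y[sp2$fold == "val"]))
  expect_lt(max(y[sp2$fold == "val"]), min(y[sp2$fold == "test"]))
  expect_equal(sum(sp2$fold == "train"), 400)
})

test_that("clonotype clustering allows edit distance 3 but not 4 at 70% on 10-mers", {
  v <- data.frame(v_gene = "V1", j_gene = "J1",
                  cdrh3 = c("AAAAAAAAAA", "AAAAAAACCC", "CCCCAAAAAA"))
  cl <- clonotype_edit_split(v, 0.7)
  expect_equal(cl$membership[[1]], cl$membership[[2]])   # Hamming 3
  expect_false(cl$membership[[1]] == cl$membership[[3]]) # Hamming 4
  ident <- data.frame(v_gene = "V1", j_gene = "J1",
                      cdrh3 = c("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_equal(length(unique(clonotype_edit_split(ident, 0.7)$membership)), 1)
  # different clonotypes never share a cluster
  v2 <- data.frame(v_gene = c("V1", "V2"), j_gene = "J1",
                   cdrh3 = c("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_equal(length(unique(clonotype_edit_split(v2, 0.7)$membership)), 2)
  bad <- data.frame(v_gene = "V1", j_gene = "J1", cdrh3 = c("AAA", "AAAA"))
  expect_error(clonotype_edit_split(bad, 0.7), "length")
})

test_that("shell classification puts the centroid inner and the farthest residue outer", {
  cs <- generate_complex(51, fixture_config())
  ifr <- interface_residues(cs)
  res <- lapply(seq_len(nrow(ifr)), function(k)
    shell_classify(cs, mutation(ifr$chain[k], ifr$resno[k],
                                aa_one(ifr$resid[k]), "A", ifr$ins[k])))
  radii <- vapply(res, `[[`, numeric(1), "radius")
  shells <- vapply(res, `[[`, character(1), "shell")
  R <- res[[1]]$outer_radius
  expect_equal(shells, ifelse(radii <= R / sqrt(2), "inner", "outer"))
  expect_equal(shells[which.max(radii)], "outer")
  expect_equal(res[[which.max(radii)]]$radius, R)
  expect_equal(res[[1]]$partner,
               unname(cs$partner_of[[ifr$chain[1]]]))
  far <- mutation("H", 1, aa_one(cs$atoms$resid[cs$atoms$chain == "H"][1]), "A")
  if (!any(ifr$chain == "H" & ifr$resno == 1))
    expect_error(shell_classify(cs, far), "interface")
})

test_that("the sqrt(2) shell construction halves a uniform disc", {
  set.seed(10)
  n <- 20000
  r <- sqrt(runif(n))          # uniform on the unit disc
  cls <- graphddg:::classify_shell_radii(r)
  expect_equal(mean(cls == "inner"), 0.5, tolerance = 0.02)
})

test_that("diversity profiles count consistently and subsets hit min/max bounds", {
  set.seed(5)
  ds <- data.frame(cluster = rep(paste0("c", 1:10), each = 100),
                   wt_aa = sample(c("A", "G", "W"), 1000, TRUE),
                   mut_aa = sample(c("F", "Y"), 1000, TRUE),
                   partner = sample(c("antibody", "antigen"), 1000, TRUE),
                   shell = sample(c("inner", "outer"), 1000, TRUE))
  prof <- diversity_profile(ds)
  expect_equal(sum(prof$substitution_type_counts), 1000)
  expect_equal(sum(prof$location_counts), 1000)
  mini <- select_subset(ds, "sequence", "min", 100, seed = 2)
  maxi <- select_subset(ds, "sequence", "max", 100, seed = 2)
  expect_equal(length(unique(ds$cluster[mini])), 1)
  expect_equal(length(unique(ds$cluster[maxi])), 10)
  # single-complex dataset: max diversity still bounded at 1 cluster
  one <- ds[ds$cluster == "c1", ]
  m1 <- select_subset(one, "sequence", "max", 50, seed = 2)
  expect_equal(length(unique(one$cluster[m1])), 1)
  # min categories never exceed max categories, across metrics and n
  for (metric in c("sequence", "substitution_type", "substitution_distribution")) {
    for (n in c(40, 200)) {
      cat_of <- switch(metric, sequence = ds$cluster,
                       substitution_type = paste(ds$wt_aa, ds$mut_aa),
                       substitution_distribution = paste(ds$partner, ds$shell))
      lo <- select_subset(ds, metric, "min", n, seed = 3)
      hi <- select_subset(ds, metric, "max", n, seed = 3)
      expect_lte(length(unique(cat_of[lo])), length(unique(cat_of[hi])))
      expect_equal(length(lo), n)
      expect_equal(length(hi), n)
    }
  }
  expect_error(select_subset(ds, "sequence", "min", 5000, seed = 1), "exceeds")
})

test_that("label shuffling is seeded, bounded, and reports the effective change", {
  y <- c(1, 2, 3, 4)
  expect_identical(shuffle_labels(y, 0, seed = 1)$labels, y)
  expect_equal(shuffle_labels(y, 0, seed = 1)$effective_percent, 0)
  same <- shuffle_labels(rep(7, 50), 1, seed = 3)
  expect_equal(same$effective_percent, 0)      # identical labels cannot change
  s1 <- shuffle_labels(1:100, 0.5, seed = 9)
  s2 <- shuffle_labels(1:100, 0.5, seed = 9)
  expect_identical(s1$labels, s2$labels)
  # effective percent equals a brute-force before/after comparison
  expect_equal(s1$effective_percent, 100 * mean(s1$labels != 1:100))
  expect_lte(s1$effective_percent, 50)
  # test labels (ineligible) are never touched
  elig <- rep(c(TRUE, FALSE), 50)
  s3 <- shuffle_labels(1:100, 1, seed = 2, eligible = elig)
  expect_identical(s3$labels[!elig], (1:100)[!elig])
})

test_that("gaussian label noise has the requested scale and respects eligibility", {
  y <- rnorm(10000)
  expect_identical(add_gaussian_noise(y, 0, seed = 1), y)
  z <- add_gaussian_noise(y, 2, seed = 4)
  expect_equal(sd(z - y), 2, tolerance = 0.1)     # within 5% at n = 10^4
  expect_identical(add_gaussian_noise(y, 2, seed = 4), z)
  elig <- c(rep(TRUE, 5000), rep(FALSE, 5000))
  z2 <- add_gaussian_noise(y, 2, seed = 4, eligible = elig)
  expect_identical(z2[!elig], y[!elig])
})
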