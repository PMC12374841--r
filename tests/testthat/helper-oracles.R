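# Independent brute-force references used across the suite. These are
# deliberately naive (double loops, no vectorized shortcuts) so they form an
# oracle independent of the package's implementations.

bf_dist <- function(a, b) sqrt(sum((a - b)^2))

bf_xyz <- function(cs) as.matrix(cs$atoms[, c("x", "y", "z")])

# all-pairs scan for inter-partner contacts
bf_contacts <- function(cs, cutoff = 4.0) {
  xyz <- bf_xyz(cs)
  ab <- cs$partner_of[cs$atoms$chain] == "antibody"
  count <- 0L
  for (i in which(ab)) for (j in which(!ab)) {
    if (bf_dist(xyz[i, ], xyz[j, ]) < cutoff) count <- count + 1L
  }
  count
}

bf_min_inter_dist <- function(cs) {
  xyz <- bf_xyz(cs)
  ab <- cs$partner_of[cs$atoms$chain] == "antibody"
  best <- Inf
  for (i in which(ab)) for (j in which(!ab)) {
    d <- bf_dist(xyz[i, ], xyz[j, ])
    if (d < best) best <- d
  }
  best
}

bf_res_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")

# all-pairs interface residue scan
bf_interface_residues <- function(cs, cutoff = 4.0) {
  xyz <- bf_xyz(cs)
  ab <- cs$partner_of[cs$atoms$chain] == "antibody"
  keys <- bf_res_key(cs$atoms)
  hit <- character(0)
  for (i in seq_len(nrow(xyz))) for (j in seq_len(nrow(xyz))) {
    if (ab[i] == ab[j]) next
    if (bf_dist(xyz[i, ], xyz[j, ]) < cutoff) hit <- c(hit, keys[i], keys[j])
  }
  sort(unique(hit))
}

# brute-force mutation-site neighborhood node set (as atom row keys)
bf_neighborhood_rows <- function(cs, mut, cutoff = 4.0) {
  a <- cs$atoms
  xyz <- bf_xyz(cs)
  site <- which(a$chain == mut$chain & a$resno == mut$resno & a$ins == mut$ins)
  local <- site
  for (i in which(a$chain == mut$chain)) {
    for (s in site) if (bf_dist(xyz[i, ], xyz[s, ]) < cutoff) {
      local <- c(local, i); break
    }
  }
  local <- sort(unique(local))
  my_partner <- cs$partner_of[[mut$chain]]
  opp <- which(cs$partner_of[a$chain] != my_partner)
  extra <- integer(0)
  for (i in opp) {
    for (s in local) if (bf_dist(xyz[i, ], xyz[s, ]) < cutoff) {
      extra <- c(extra, i); break
    }
  }
  sort(unique(c(local, extra)))
}

# node identity key for graph comparison
graph_node_keys <- function(g) {
  paste(g$atoms$chain, g$atoms$resno, g$atoms$ins, g$atoms$elety, sep = "|")
}

atom_row_keys <- function(cs, rows) {
  a <- cs$atoms[rows, , drop = FALSE]
  paste(a$chain, a$resno, a$ins, a$elety, sep = "|")
}

# naive greedy leader clustering reference (same stated rule, loop form)
bf_leader_cluster <- function(seqs, cutoff) {
  ord <- order(-nchar(seqs), seqs, names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  out <- character(length(seqs))
  names(out) <- names(seqs)
  ident <- function(a, b) {
    if (nchar(a) != nchar(b)) return(0)
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (ident(seqs[[i]], reps[k]) >= cutoff) {
        out[i] <- paste0("c", k); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, seqs[[i]])
      out[i] <- paste0("c", length(reps))
    }
  }
  out
}

# partition equality up to cluster relabeling
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(unique(a)) == length(unique(b)) &&
    all(as.integer(factor(a, levels = unique(a))) ==
          as.integer(factor(b, levels = unique(b))))
}

# hand-built minimal complex: one residue per chain, CA atoms `gap` apart,
# plus optional side-chain atoms supplied as offsets from each CA
toy_two_residue_complex <- function(gap, sc_h = NULL, sc_a = NULL,
                                    resid_h = "SER", resid_a = "SER") {
  mk <- function(chain, resno, resid, origin, sc) {
    bb <- data.frame(chain = chain, resno = resno, ins = "", resid = resid,
                     elety = c("N", "CA", "C"), element = c("N", "C", "C"),
                     x = origin[1] + c(-1.2, 0, 1.2), y = origin[2], z = origin[3],
                     stringsAsFactors = FALSE)
    if (!is.null(sc)) {
      bb <- rbind(bb, data.frame(chain = chain, resno = resno, ins = "",
                                 resid = resid,
                                 elety = paste0("SC", seq_len(nrow(sc))),
                                 element = "C",
                                 x = origin[1] + sc[, 1], y = origin[2] + sc[, 2],
                                 z = origin[3] + sc[, 3],
                                 stringsAsFactors = FALSE))
    }
    bb
  }
  complex_structure(rbind(mk("H", 1, resid_h, c(0, 0, 0), sc_h),
                          mk("A", 1, resid_a, c(gap, 0, 0), sc_a)),
                    c(H = "antibody", A = "antigen"))
}

# random small graph satisfying the mutation_graph invariants
random_graph <- function(seed, n = 12, V = 8) {
  set.seed(seed)
  coords <- matrix(runif(n * 3, 0, 6), n, 3)
  feats <- matrix(0, n, V)
  feats[cbind(seq_len(n), sample.int(V, n, TRUE))] <- 1
  partner <- sample(c("antibody", "antigen"), n, TRUE)
  d <- as.matrix(dist(coords))
  adj <- d < 4
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  e <- which(adj, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  inter <- if (nrow(e)) partner[e[, 1]] != partner[e[, 2]] else logical(0)
  structure(list(coords = coords, features = feats, edges = unname(e),
                 edge_features = cbind(intra = as.numeric(!inter),
                                       inter = as.numeric(inter)),
                 node_partner = partner,
                 atoms = data.frame(chain = "H", resno = seq_len(n), ins = "",
                                    resid = "ALA", elety = "CA")),
            class = "mutation_graph")
}

rigid_transform_graph <- function(g, R, t) {
  g$coords <- g$coords %*% t(R) + matrix(t, nrow(g$coords), 3, byrow = TRUE)
  g
}

# naive per-edge/per-node EGC layer reference (scalar loops)
naive_egc_layer <- function(graph, h, params, l, config) {
  nm <- function(s) params[[paste0(s, "_", l)]]
  silu <- function(x) x / (1 + exp(-x))
  n <- nrow(graph$coords)
  x <- graph$coords
  e <- graph$edges
  ei <- c(e[, 1], e[, 2]); ej <- c(e[, 2], e[, 1])
  ef <- rbind(graph$edge_features, graph$edge_features)
  E <- length(ei)
  d <- ncol(h)
  msgs <- matrix(0, E, d)
  phix <- numeric(E)
  for (k in seq_len(E)) {
    i <- ei[k]; j <- ej[k]
    d2 <- sum((x[i, ] - x[j, ])^2)
    pre <- h[i, ] %*% nm("e_Wh") + h[j, ] %*% nm("e_Wn") + d2 * nm("e_Wd") +
      ef[k, , drop = FALSE] %*% nm("e_Wf") + nm("e_b1")
    m1 <- silu(pre)
    m2 <- silu(m1 %*% nm("e_W2") + nm("e_b2"))
    msgs[k, ] <- m2
    s <- silu(m2 %*% nm("x_V1") + nm("x_c1")) %*% nm("x_V2") + nm("x_c2")
    phix[k] <- if (config$coord_tanh) tanh(s) else s
  }
  x_new <- x
  if (config$update_coords) {
    for (i in seq_len(n)) {
      ks <- which(ei == i)
      if (length(ks)) {
        upd <- c(0, 0, 0)
        for (k in ks) upd <- upd + (x[i, ] - x[ej[k], ]) * phix[k]
        x_new[i, ] <- x[i, ] + upd / length(ks)
      }
    }
  }
  h_new <- h
  for (i in seq_len(n)) {
    agg <- rep(0, d)
    for (k in which(ei == i)) agg <- agg + msgs[k, ]
    u <- silu(h[i, ] %*% nm("h_Uh") + agg %*% nm("h_Um") + nm("h_u1"))
    h_new[i, ] <- h[i, ] + u %*% nm("h_U2") + nm("h_u2")
  }
  list(h = h_new, x = x_new)
}

# naive full forward: EGC stack + per-column max pool
naive_embed <- function(graph, params, config) {
  h <- graph$features %*% params$embed_W +
    matrix(params$embed_b, nrow(graph$features), ncol(params$embed_W), byrow = TRUE)
  g <- graph
  for (l in seq_len(config$n_layers)) {
    st <- naive_egc_layer(g, h, params, l, config)
    h <- st$h; g$coords <- st$x
  }
  apply(h, 2, max)
}

naive_siamese <- function(wt, mut, params, config) {
  diff <- naive_embed(wt, params, config) - naive_embed(mut, params, config)
  out <- sum(diff * params$head_w)
  if (config$head_bias) out <- out + params$head_b[1, 1]
  out
}
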