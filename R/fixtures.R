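# Synthetic fixtures: deterministic toy antibody-antigen complexes with a
# genuine <4 A interface, template-based point mutations, and a FoldX-like
# ddG oracle (contact term + residue-volume term + optional Gaussian noise).
#
# The generator stands in for structurally resolved complexes so that the
# whole pipeline (graphs, training, splits, experiments) is testable without
# external downloads. Chains H and L form the antibody partner, chain A the
# antigen. Residues carry backbone pseudo-atoms (N, CA, C, O) on a smooth
# random walk with 3.8 A CA spacing, plus 0-6 side-chain pseudo-atoms from a
# fixed per-amino-acid template whose size scales with residue volume.
# Side-chain geometry is a pure function of the residue type and its backbone
# anchor, so rebuilding a side chain (mutation) is exact and deterministic.

#' Fixture generator configuration
#'
#' @param seed Integer master seed; all randomness in [generate_dataset()]
#'   flows from it.
#' @param n_complexes Number of complexes to generate (>= 1).
#' @param residues_per_chain Residues per chain (>= 5, default 30).
#' @param muts_per_complex Interface point mutations sampled per complex.
#' @param noise_sd Gaussian label noise, kcal/mol (>= 0).
#' @param alpha_contact Oracle weight, kcal/mol per inter-partner contact.
#' @param beta_volume Oracle weight, kcal/mol per cubic Angstrom of
#'   side-chain volume change.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_complexes = 10L, residues_per_chain = 30L,
                           muts_per_complex = 20L, noise_sd = 0,
                           alpha_contact = 0.5, beta_volume = 0.01) {
  stopifnot(n_complexes >= 1, residues_per_chain >= 5, muts_per_complex >= 1,
            noise_sd >= 0)
  structure(list(seed = as.integer(seed), n_complexes = as.integer(n_complexes),
                 residues_per_chain = as.integer(residues_per_chain),
                 muts_per_complex = as.integer(muts_per_complex),
                 noise_sd = noise_sd, alpha_contact = alpha_contact,
                 beta_volume = beta_volume),
            class = "fixture_config")
}

#' Oracle parameters
#'
#' @inheritParams fixture_config
#' @param seed Optional integer seed for the noise draw; when `NULL` the
#'   current RNG stream is used.
#' @return An `oracle_params` list.
#' @export
oracle_params <- function(alpha_contact = 0.5, beta_volume = 0.01,
                          noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0)
  structure(list(alpha_contact = alpha_contact, beta_volume = beta_volume,
                 noise_sd = noise_sd, seed = seed),
            class = "oracle_params")
}

#' A single-point mutation
#'
#' @param chain Chain id.
#' @param resno Residue number.
#' @param wt_aa,mut_aa One-letter wild-type and mutant residue codes.
#' @param ins Insertion code ("" when absent).
#' @return A `ddg_mutation` list.
#' @export
mutation <- function(chain, resno, wt_aa, mut_aa, ins = "") {
  stopifnot(wt_aa %in% AA1, mut_aa %in% AA1)
  structure(list(chain = chain, resno = as.integer(resno), ins = ins,
                 wt_aa = wt_aa, mut_aa = mut_aa),
            class = "ddg_mutation")
}

# --- geometry -----------------------------------------------------------

# Smooth random CA walk: fixed 3.8 A steps with a persistent direction.
ca_walk <- function(n) {
  dir <- unit(stats::rnorm(3))
  ca <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    dir <- unit(dir + 0.45 * stats::rnorm(3))
    ca[i + 1, ] <- ca[i, ] + 3.8 * dir
  }
  ca
}

# Local frame at residue i of a CA trace: tangent + two perpendiculars.
# Depends only on CA coordinates, so it is mutation-invariant.
res_frame <- function(ca, i) {
  n <- nrow(ca)
  t <- if (i == 1) ca[2, ] - ca[1, ]
       else if (i == n) ca[n, ] - ca[n - 1, ]
       else ca[i + 1, ] - ca[i - 1, ]
  t <- unit(t)
  p <- perp_unit(t)
  q <- cross3(t, p)
  list(t = t, p = p, q = q)
}

# Backbone pseudo-atoms for one residue.
backbone_atoms <- function(ca_i, fr) {
  rbind(N = ca_i - 1.2 * fr$t + 0.5 * fr$p,
        CA = ca_i,
        C  = ca_i + 1.2 * fr$t + 0.5 * fr$p,
        O  = ca_i + 1.6 * fr$t + 1.4 * fr$p)
}

# Side-chain pseudo-atoms: pure function of (aa, backbone anchor geometry).
# Atoms march outward from CA along the frame normal, with deterministic
# golden-angle lateral offsets; the count comes from the fixed template.
sidechain_atoms <- function(aa, ca_i, fr) {
  nsc <- aa_sidechain_atoms()[[aa]]
  if (nsc == 0L) return(matrix(numeric(0), 0, 3))
  u <- unit(-fr$p + 0.25 * fr$q)  # away from the backbone plane
  out <- matrix(0, nsc, 3)
  for (k in seq_len(nsc)) {
    theta <- 2.399963 * k
    lat <- if (k == 1) c(0, 0, 0) else
      0.9 * (cos(theta) * fr$t + sin(theta) * fr$q)
    out[k, ] <- ca_i + u * (1.5 + 0.7 * (k - 1)) + lat
  }
  out
}

# Full atom table for one chain given its CA trace and sequence.
chain_atoms <- function(chain_id, ca, seq1) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- res_frame(ca, i)
    bb <- backbone_atoms(ca[i, ], fr)
    sc <- sidechain_atoms(seq1[i], ca[i, ], fr)
    xyz <- rbind(bb, sc)
    nm <- c(rownames(bb), if (nrow(sc)) paste0("SC", seq_len(nrow(sc))))
    el <- c("N", "C", "C", "O", rep("C", nrow(sc)))
    rows[[i]] <- data.frame(chain = chain_id, resno = i, ins = "",
                            resid = aa_three(seq1[i]), elety = nm,
                            element = el, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Rotation matrix taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- cross3(a, b); c_ <- sum(a * b)
  if (c_ > 1 - 1e-10) return(diag(3))
  if (c_ < -1 + 1e-10) { p <- perp_unit(a); return(2 * tcrossprod(p) - diag(3)) }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate one synthetic antibody-antigen complex
#'
#' Builds chains H and L (antibody) and A (antigen) with random sequences and
#' smooth random-walk backbones, then docks the antigen against the middle of
#' chain H so that the minimum inter-partner atom distance falls strictly
#' below 4 Angstrom (a genuine interface) without steric collapse. Fully
#' deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @param config A [fixture_config()] (only `residues_per_chain` is used).
#' @return A [complex_structure()] with a `sequences` attribute (named list
#'   of one-letter sequences per chain).
#' @export
generate_complex <- function(seed, config = fixture_config()) {
  n <- config$residues_per_chain
  if (n < 5) stop("chains too short to place an interface (need >= 5 residues)")
  with_seed(seed, {
    seqs <- list(H = sample(AA1, n, replace = TRUE),
                 L = sample(AA1, n, replace = TRUE),
                 A = sample(AA1, n, replace = TRUE))
    ca_h <- ca_walk(n); ca_l <- ca_walk(n); ca_a <- ca_walk(n)
    m <- ceiling(n / 2)
    fr_h <- res_frame(ca_h, m)
    # random direction perpendicular to H's local tangent
    r <- stats::rnorm(3)
    off <- r - sum(r * fr_h$t) * fr_h$t
    off <- if (sqrt(sum(off^2)) < 1e-8) fr_h$p else unit(off)
    # light chain parked on the opposite side of H
    ca_l <- ca_l + matrix(colMeans(ca_h) - colMeans(ca_l) - 30 * off,
                          n, 3, byrow = TRUE)
    # align the antigen's local tangent with H's and slide it in along `off`
    fr_a <- res_frame(ca_a, m)
    rot <- rotation_between(fr_a$t, fr_h$t)
    ca_a <- ca_a %*% t(rot)
    atoms_h <- chain_atoms("H", ca_h, seqs$H)
    atoms_l <- chain_atoms("L", ca_l, seqs$L)
    ab_xyz <- as.matrix(rbind(atoms_h, atoms_l)[, c("x", "y", "z")])
    # antigen atoms at anchor offset 0; the scan then translates rigidly
    ca0 <- ca_a + matrix(ca_h[m, ] - ca_a[m, ], n, 3, byrow = TRUE)
    atoms_a <- chain_atoms("A", ca0, seqs$A)
    a_xyz <- as.matrix(atoms_a[, c("x", "y", "z")])
    # slide the antigen in from far away until the closest approach sits in
    # [3.2, 3.45] A: strictly inside the 4 A interface rule, with several
    # residues in range, but well above steric-clash distances. Each 0.25 A
    # step changes any pairwise distance by at most 0.25 A, so the scan
    # cannot jump over that window.
    min_at <- function(d) {
      shifted <- a_xyz + matrix(d * off, nrow(a_xyz), 3, byrow = TRUE)
      sqrt(min(cross_dist2(ab_xyz, shifted)))
    }
    placed_d <- NA_real_
    coarse <- NA_real_
    for (d in seq(120, 0, by = -1)) {
      if (min_at(d) < 5) { coarse <- d; break }
    }
    if (!is.na(coarse)) {
      for (d in seq(coarse + 1, 0, by = -0.25)) {
        mind <- min_at(d)
        if (mind < 3.45) {
          if (mind >= 3.2) placed_d <- d
          break
        }
      }
    }
    if (is.na(placed_d))
      stop("cannot place an interface for this seed/config (chains too short?)")
    shifted <- a_xyz + matrix(placed_d * off, nrow(a_xyz), 3, byrow = TRUE)
    placed <- atoms_a
    placed$x <- shifted[, 1]; placed$y <- shifted[, 2]; placed$z <- shifted[, 3]
    cs <- complex_structure(rbind(atoms_h, atoms_l, placed),
                            c(H = "antibody", L = "antibody", A = "antigen"))
    attr(cs, "sequences") <- lapply(seqs, paste, collapse = "")
    cs
  })
}

#' Apply a point mutation to a complex
#'
#' Replaces the residue identity and rebuilds the side-chain pseudo-atoms
#' from the target residue's template at the same backbone anchor. Backbone
#' atoms and all other residues are bitwise unchanged.
#'
#' @param cs A [complex_structure()] produced by [generate_complex()].
#' @param mut A [mutation()].
#' @return The mutated [complex_structure()].
#' @export
apply_mutation <- function(cs, mut) {
  a <- cs$atoms
  sel <- a$chain == mut$chain & a$resno == mut$resno & a$ins == mut$ins
  if (!any(sel)) stop("mutation site not found: ", mut$chain, mut$resno)
  found <- aa_one(a$resid[sel][1])
  if (found != mut$wt_aa)
    stop(sprintf("WT residue mismatch at %s%d: expected %s, found %s",
                 mut$chain, mut$resno, mut$wt_aa, found))
  bb_sel <- sel & a$elety %in% c("N", "CA", "C", "O")
  bb <- a[bb_sel, , drop = FALSE]
  ca_i <- as.numeric(bb[bb$elety == "CA", c("x", "y", "z")])
  n_i <- as.numeric(bb[bb$elety == "N", c("x", "y", "z")])
  c_i <- as.numeric(bb[bb$elety == "C", c("x", "y", "z")])
  # recover the generation frame from the backbone (pure function of it)
  t <- unit(c_i - n_i)
  p <- perp_unit(t)
  q <- cross3(t, p)
  sc <- sidechain_atoms(mut$mut_aa, ca_i, list(t = t, p = p, q = q))
  keep <- a[!(sel & !bb_sel), , drop = FALSE]
  keep$resid[keep$chain == mut$chain & keep$resno == mut$resno &
               keep$ins == mut$ins] <- aa_three(mut$mut_aa)
  if (nrow(sc)) {
    new_rows <- data.frame(chain = mut$chain, resno = mut$resno, ins = mut$ins,
                           resid = aa_three(mut$mut_aa),
                           elety = paste0("SC", seq_len(nrow(sc))),
                           element = "C", x = sc[, 1], y = sc[, 2], z = sc[, 3],
                           stringsAsFactors = FALSE)
    keep <- rbind(keep, new_rows)
  }
  out <- complex_structure(keep, cs$partner_of)
  attr(out, "sequences") <- attr(cs, "sequences")
  out
}

#' FoldX-like ddG oracle
#'
#' Deterministic surrogate label:
#' `ddG = alpha_contact * (contacts(mut) - contacts(wt)) +
#'        beta_volume * (vol(mut_res) - vol(wt_res)) + Normal(0, noise_sd)`,
#' where contacts are inter-partner non-hydrogen atom pairs < 4 Angstrom.
#' Negative values are destabilizing (contact loss / volume loss). With
#' `noise_sd = 0` the contact term is antisymmetric under WT/mutant exchange.
#'
#' @param wt,mut Wild-type and mutant [complex_structure()]s differing at
#'   exactly one residue.
#' @param params An [oracle_params()].
#' @return ddG in kcal/mol.
#' @export
oracle_ddg <- function(wt, mut, params = oracle_params()) {
  if (!setequal(names(wt$partner_of), names(mut$partner_of)))
    stop("mismatched chain sets between WT and mutant")
  kw <- res_key(wt$atoms); km <- res_key(mut$atoms)
  rw <- stats::setNames(wt$atoms$resid, kw)[!duplicated(kw)]
  rm_ <- stats::setNames(mut$atoms$resid, km)[!duplicated(km)]
  if (!setequal(names(rw), names(rm_))) stop("mismatched residue sets")
  diff_keys <- names(rw)[rw[names(rw)] != rm_[names(rw)]]
  if (length(diff_keys) > 1)
    stop("structures differ at more than one residue")
  dvol <- if (length(diff_keys) == 0) 0 else {
    vols <- aa_volumes()
    vols[[aa_one(rm_[[diff_keys]])]] - vols[[aa_one(rw[[diff_keys]])]]
  }
  dcon <- inter_partner_contacts(mut) - inter_partner_contacts(wt)
  noise <- if (params$noise_sd > 0) {
    if (!is.null(params$seed)) with_seed(params$seed, stats::rnorm(1, 0, params$noise_sd))
    else stats::rnorm(1, 0, params$noise_sd)
  } else 0
  params$alpha_contact * dcon + params$beta_volume * dvol + noise
}

#' Generate a labeled synthetic ddG dataset
#'
#' For each complex, samples `muts_per_complex` interface point mutations
#' (site from the 4 Angstrom interface-residue set, target from the 19 other
#' amino acids, without replacement over site x target pairs) and labels them
#' with the oracle. Optionally emits WT and mutant PDB files plus a
#' tab-delimited mutation table. Deterministic given `config$seed`.
#'
#' @param config A [fixture_config()].
#' @param dir Optional output directory for PDB files and `mutations.tsv`.
#' @return A `ddg_dataset`: list with `table` (one row per labeled mutation:
#'   complex_id, pdb_wt, pdb_mut, chain, position, ins, wt_aa, mut_aa, ddg),
#'   `complexes` (named list of WT structures) and `config`.
#' @export
generate_dataset <- function(config = fixture_config(), dir = NULL) {
  complexes <- list()
  rows <- list()
  with_seed(config$seed, {
    for (k in seq_len(config$n_complexes)) {
      id <- sprintf("CPLX%03d", k)
      cseed <- (config$seed %% 100000L) * 10000L + k
      cs <- generate_complex(cseed, config)
      complexes[[id]] <- cs
      ifr <- interface_residues(cs)
      cand <- merge(ifr, data.frame(mut_aa = AA1), by = NULL)
      cand$wt_aa <- aa_one(cand$resid)
      cand <- cand[cand$wt_aa != cand$mut_aa, , drop = FALSE]
      if (nrow(cand) < config$muts_per_complex)
        stop(sprintf("complex %s has only %d candidate interface mutations (< %d)",
                     id, nrow(cand), config$muts_per_complex))
      pick <- cand[sample.int(nrow(cand), config$muts_per_complex), , drop = FALSE]
      pars <- oracle_params(config$alpha_contact, config$beta_volume,
                            config$noise_sd, seed = NULL)
      for (j in seq_len(nrow(pick))) {
        mu <- mutation(pick$chain[j], pick$resno[j], pick$wt_aa[j],
                       pick$mut_aa[j], pick$ins[j])
        mut_cs <- apply_mutation(cs, mu)
        lab <- oracle_ddg(cs, mut_cs, pars)
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = id,
          pdb_wt = sprintf("%s_wt.pdb", id),
          pdb_mut = sprintf("%s_mut%03d.pdb", id, j),
          chain = mu$chain, position = mu$resno, ins = mu$ins,
          wt_aa = mu$wt_aa, mut_aa = mu$mut_aa, ddg = lab,
          stringsAsFactors = FALSE)
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          write_pdb_complex(mut_cs, file.path(dir, sprintf("%s_mut%03d.pdb", id, j)))
        }
      }
      if (!is.null(dir))
        write_pdb_complex(cs, file.path(dir, sprintf("%s_wt.pdb", id)))
    }
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(dir))
    utils::write.table(tab, file.path(dir, "mutations.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  structure(list(table = tab, complexes = complexes, config = config),
            class = "ddg_dataset")
}

#' @export
print.ddg_dataset <- function(x, ...) {
  cat("ddg_dataset:", nrow(x$table), "labeled mutations from",
      length(x$complexes), "complexes\n")
  invisible(x)
}

# The mutation object for row i of a dataset table.
dataset_mutation <- function(dataset, i) {
  r <- dataset$table[i, ]
  mutation(r$chain, r$position, r$wt_aa, r$mut_aa, r$ins)
}
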