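# Graph builder: atomistic 4 Angstrom graphs in the three flavors used for
# model input - mutation-site neighborhood, full interface, and CDR
# neighborhood. Nodes are non-hydrogen atoms (one-hot atom-type features),
# edges connect atoms strictly closer than 4 Angstrom, with a one-hot
# intra/inter-binding-partner edge feature.

new_mutation_graph <- function(cs, rows, table = atom_typing_table(),
                               cutoff = 4.0) {
  rows <- sort(unique(rows))
  a <- cs$atoms[rows, , drop = FALSE]
  # deterministic node order: chain, residue, then stored atom order
  ord <- order(a$chain, a$resno, a$ins)
  a <- a[ord, , drop = FALSE]
  n <- nrow(a)
  if (n < 1) stop("empty graph")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- cross_dist2(xyz, xyz)
  adj <- d2 < cutoff^2
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  e <- which(adj, arr.ind = TRUE)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  is_ab <- unname(cs$partner_of[a$chain] == "antibody")
  inter <- if (nrow(e)) is_ab[e[, 1]] != is_ab[e[, 2]] else logical(0)
  efeat <- cbind(intra = as.numeric(!inter), inter = as.numeric(inter))
  structure(list(coords = xyz,
                 features = atom_onehot(a, table),
                 edges = unname(e),
                 edge_features = efeat,
                 node_partner = ifelse(is_ab, "antibody", "antigen"),
                 atoms = a[, c("chain", "resno", "ins", "resid", "elety")]),
            class = "mutation_graph")
}

#' @export
print.mutation_graph <- function(x, ...) {
  cat("mutation_graph:", nrow(x$coords), "nodes,", nrow(x$edges), "edges (",
      sum(x$edge_features[, "inter"]), "inter-partner )\n")
  invisible(x)
}

# rows of cs$atoms within `cutoff` of any of the rows in `from`
rows_within <- function(cs, from, candidates, cutoff = 4.0) {
  if (!length(from) || !length(candidates)) return(integer(0))
  d2 <- cross_dist2(coords_of(cs, candidates), coords_of(cs, from))
  candidates[rowSums(d2 < cutoff^2) > 0]
}

#' Mutation-site neighborhood graph
#'
#' Node set: the mutated residue's own atoms, plus atoms on the same chain
#' within 4 Angstrom of any mutated-residue atom (local neighborhood), plus
#' atoms of the opposite binding partner within 4 Angstrom of any local
#' neighborhood atom. Edges connect retained nodes < 4 Angstrom apart.
#'
#' @param cs A [complex_structure()].
#' @param mut A [mutation()] whose site exists in `cs`.
#' @param table An [atom_typing_table()] for node features.
#' @param cutoff Distance cutoff in Angstrom (default 4).
#' @return A `mutation_graph`. If the complex has no inter-partner atom pair
#'   within `cutoff` at all, the graph carries an `exclude_no_interface`
#'   attribute so such cases can be filtered from datasets.
#' @export
mutation_neighborhood_graph <- function(cs, mut, table = atom_typing_table(),
                                        cutoff = 4.0) {
  a <- cs$atoms
  site <- which(a$chain == mut$chain & a$resno == mut$resno & a$ins == mut$ins)
  if (!length(site)) stop("mutation site not found: ", mut$chain, mut$resno)
  same_chain <- which(a$chain == mut$chain)
  local <- sort(unique(c(site, rows_within(cs, site, same_chain, cutoff))))
  opp_partner <- cs$partner_of[[mut$chain]]
  opp <- which(unname(cs$partner_of[a$chain]) != opp_partner)
  partner_nodes <- rows_within(cs, local, opp, cutoff)
  g <- new_mutation_graph(cs, c(local, partner_nodes), table, cutoff)
  # complexes whose partners are everywhere > cutoff apart carry no interface
  # signal at all and are flagged for exclusion upstream
  if (!length(partner_nodes) && inter_partner_contacts(cs, cutoff) == 0)
    attr(g, "exclude_no_interface") <- TRUE
  g
}

#' Full-interface graph
#'
#' Node set: all atoms of interface residues on both partners (4 Angstrom
#' rule); edges as for [mutation_neighborhood_graph()].
#'
#' @inheritParams mutation_neighborhood_graph
#' @return A `mutation_graph`.
#' @export
interface_graph <- function(cs, table = atom_typing_table(), cutoff = 4.0) {
  ifr <- interface_residues(cs, cutoff)
  if (!nrow(ifr)) stop("complex has no interface at ", cutoff, " Angstrom")
  keys <- paste(ifr$chain, ifr$resno, ifr$ins, sep = "|")
  rows <- which(res_key(cs$atoms) %in% keys)
  new_mutation_graph(cs, rows, table, cutoff)
}

#' CDR neighborhood graph
#'
#' Node set built by staged dilation: CDR atoms; antibody atoms within 4
#' Angstrom of CDR atoms (antibody neighborhood); antigen atoms within 4
#' Angstrom of that antibody set; and antigen atoms within 4 Angstrom of
#' those antigen atoms.
#'
#' @inheritParams mutation_neighborhood_graph
#' @param cdr_residues data.frame with columns `chain`, `resno` and
#'   optionally `ins`; all residues must lie on the antibody partner.
#' @return A `mutation_graph`.
#' @export
cdr_neighborhood_graph <- function(cs, cdr_residues, table = atom_typing_table(),
                                   cutoff = 4.0) {
  if (!nrow(cdr_residues)) stop("cdr_residues is empty")
  if (is.null(cdr_residues$ins)) cdr_residues$ins <- ""
  bad <- unname(cs$partner_of[cdr_residues$chain]) != "antibody"
  if (any(is.na(bad)) || any(bad))
    stop("cdr_residues must all lie on the antibody partner")
  keys <- paste(cdr_residues$chain, cdr_residues$resno, cdr_residues$ins, sep = "|")
  cdr_rows <- which(res_key(cs$atoms) %in% keys)
  if (!length(cdr_rows)) stop("no CDR atoms found in structure")
  is_ab <- partner_mask(cs)
  ab_rows <- which(is_ab)
  ag_rows <- which(!is_ab)
  ab_nb <- sort(unique(c(cdr_rows, rows_within(cs, cdr_rows, ab_rows, cutoff))))
  ag_nb1 <- rows_within(cs, ab_nb, ag_rows, cutoff)
  ag_nb2 <- rows_within(cs, ag_nb1, ag_rows, cutoff)
  new_mutation_graph(cs, c(ab_nb, ag_nb1, ag_nb2), table, cutoff)
}

#' Build Siamese WT/mutant graph examples from a synthetic dataset
#'
#' For each labeled mutation, builds the WT and mutant mutation-site
#' neighborhood graphs (each from its own structure's coordinates) and pairs
#' them with the oracle label.
#'
#' @param dataset A `ddg_dataset` from [generate_dataset()].
#' @param table An [atom_typing_table()].
#' @return List of examples: each `list(wt=, mut=, y=, complex_id=)`.
#' @export
build_siamese_examples <- function(dataset, table = atom_typing_table()) {
  tab <- dataset$table
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cs <- dataset$complexes[[tab$complex_id[i]]]
    mu <- dataset_mutation(dataset, i)
    mut_cs <- apply_mutation(cs, mu)
    out[[i]] <- list(wt = mutation_neighborhood_graph(cs, mu, table),
                     mut = mutation_neighborhood_graph(mut_cs, mu, table),
                     y = tab$ddg[i], complex_id = tab$complex_id[i])
  }
  out
}

#' Serialize / restore a graph as plain text
#'
#' Writes coords, features, edges and metadata as an RDS-free, reproducible
#' tab-delimited archive (a directory), for training caches.
#'
#' @param g A `mutation_graph`.
#' @param dir Output directory.
#' @return `dir` (write) or a `mutation_graph` (read).
#' @export
write_graph <- function(g, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(cbind(g$coords, g$features), file.path(dir, "nodes.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(g$edges, g$edge_features), file.path(dir, "edges.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- cbind(g$atoms, partner = g$node_partner)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  nodes <- unname(as.matrix(utils::read.table(file.path(dir, "nodes.tsv"),
                                              sep = "\t")))
  edges <- unname(as.matrix(utils::read.table(file.path(dir, "edges.tsv"),
                                              sep = "\t")))
  meta <- utils::read.table(file.path(dir, "meta.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = NULL,
                            colClasses = c(ins = "character"))
  ef <- edges[, 3:4, drop = FALSE]
  colnames(ef) <- c("intra", "inter")
  structure(list(coords = nodes[, 1:3, drop = FALSE],
                 features = nodes[, -(1:3), drop = FALSE],
                 edges = unname(edges[, 1:2, drop = FALSE]),
                 edge_features = ef,
                 node_partner = meta$partner,
                 atoms = meta[, c("chain", "resno", "ins", "resid", "elety")]),
            class = "mutation_graph")
}
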