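# Graph construction: neighborhoods, interface graphs, CDR dilation.

test_that("mutation neighborhood node sets match the brute-force reference", {
  for (s in c(21, 22, 23, 24)) {
    cs <- generate_complex(s, fixture_config())
    ifr <- interface_residues(cs)
    for (k in seq_len(min(3, nrow(ifr)))) {
      mu <- mutation(ifr$chain[k], ifr$resno[k], aa_one(ifr$resid[k]), "A",
                     ifr$ins[k])
      g <- mutation_neighborhood_graph(cs, mu)
      expect_setequal(graph_node_keys(g),
                      atom_row_keys(cs, bf_neighborhood_rows(cs, mu)))
      # every emitted edge satisfies the strict 4 A rule
      if (nrow(g$edges)) {
        d <- sqrt(rowSums((g$coords[g$edges[, 1], , drop = FALSE] -
                             g$coords[g$edges[, 2], , drop = FALSE])^2))
        expect_true(all(d < 4))
        expect_true(all(g$edges[, 1] != g$edges[, 2]))
        inter <- g$node_partner[g$edges[, 1]] != g$node_partner[g$edges[, 2]]
        expect_equal(as.numeric(inter), g$edge_features[, "inter"])
      }
    }
  }
})

test_that("an isolated mutated residue yields its own atoms with intra edges only", {
  atoms <- rbind(
    data.frame(chain = "H", resno = 1, ins = "", resid = "SER",
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(-1.2, 0, 1.2), y = 0, z = 0),
    data.frame(chain = "H", resno = 2, ins = "", resid = "GLY",
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(48.8, 50, 51.2), y = 0, z = 0),
    data.frame(chain = "A", resno = 1, ins = "", resid = "GLY",
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(18.8, 20, 21.2), y = 0, z = 0))
  cs <- complex_structure(atoms, c(H = "antibody", A = "antigen"))
  g <- mutation_neighborhood_graph(cs, mutation("H", 1, "S", "A"))
  expect_equal(nrow(g$coords), 3)
  expect_true(all(g$node_partner == "antibody"))
  expect_true(all(g$edge_features[, "intra"] == 1))
  # partners everywhere > 4 A apart: flagged for exclusion
  expect_true(isTRUE(attr(g, "exclude_no_interface")))
  cs2 <- generate_complex(33, fixture_config())
  ifr <- interface_residues(cs2)
  g2 <- mutation_neighborhood_graph(cs2, mutation(ifr$chain[1], ifr$resno[1],
                                                  aa_one(ifr$resid[1]), "A"))
  expect_null(attr(g2, "exclude_no_interface"))
})

test_that("rigid motions change only node coordinates", {
  cs <- generate_complex(25, fixture_config())
  ifr <- interface_residues(cs)
  mu <- mutation(ifr$chain[1], ifr$resno[1], aa_one(ifr$resid[1]), "A")
  g1 <- mutation_neighborhood_graph(cs, mu)
  shifted <- cs
  shifted$atoms$x <- shifted$atoms$x + 10
  shifted$atoms$y <- shifted$atoms$y + 10
  shifted$atoms$z <- shifted$atoms$z + 10
  g2 <- mutation_neighborhood_graph(shifted, mu)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$features, g2$features)
  expect_identical(g1$node_partner, g2$node_partner)
  expect_equal(g2$coords, g1$coords + 10)
})

test_that("the interface graph collects exactly the interface residues' atoms", {
  sc <- matrix(c(2.0, 0, 0), 1, 3)
  cs <- toy_two_residue_complex(gap = 6.0, sc_h = sc)
  g <- interface_graph(cs)
  expect_setequal(graph_node_keys(g), atom_row_keys(cs, seq_len(nrow(cs$atoms))))
  for (s in c(26, 27)) {
    cs <- generate_complex(s, fixture_config())
    g <- interface_graph(cs)
    keys <- bf_interface_residues(cs)
    rows <- which(paste(cs$atoms$chain, cs$atoms$resno, cs$atoms$ins, sep = "|")
                  %in% keys)
    expect_setequal(graph_node_keys(g), atom_row_keys(cs, rows))
  }
  far <- toy_two_residue_complex(gap = 40)
  expect_error(interface_graph(far), "no interface")
})

test_that("interface graph contains the inter-partner nodes of any interface mutation graph", {
  cs <- generate_complex(28, fixture_config())
  ig_keys <- graph_node_keys(interface_graph(cs))
  ifr <- interface_residues(cs)
  mu <- mutation(ifr$chain[1], ifr$resno[1], aa_one(ifr$resid[1]), "A")
  mg <- mutation_neighborhood_graph(cs, mu)
  opp <- mg$node_partner != cs$partner_of[[mu$chain]]
  inter_nodes <- graph_node_keys(mg)[opp]
  expect_true(all(inter_nodes %in% ig_keys))
})

test_that("CDR dilation matches a three-stage brute-force scan and is monotone", {
  cs <- generate_complex(29, fixture_config())
  cdr1 <- data.frame(chain = "H", resno = 14:16)
  cdr2 <- data.frame(chain = "H", resno = 13:17)
  g1 <- cdr_neighborhood_graph(cs, cdr1)
  g2 <- cdr_neighborhood_graph(cs, cdr2)
  expect_true(all(graph_node_keys(g1) %in% graph_node_keys(g2)))

  # brute-force three-stage dilation
  a <- cs$atoms; xyz <- as.matrix(a[, c("x", "y", "z")])
  ab <- cs$partner_of[a$chain] == "antibody"
  cdr_rows <- which(a$chain == "H" & a$resno %in% 14:16)
  within4 <- function(cand, from) {
    keep <- integer(0)
    for (i in cand) for (j in from) {
      if (bf_dist(xyz[i, ], xyz[j, ]) < 4) { keep <- c(keep, i); break }
    }
    keep
  }
  ab_nb <- sort(unique(c(cdr_rows, within4(which(ab), cdr_rows))))
  ag1 <- within4(which(!ab), ab_nb)
  ag2 <- within4(which(!ab), ag1)
  expect_setequal(graph_node_keys(g1),
                  atom_row_keys(cs, unique(c(ab_nb, ag1, ag2))))
})

test_that("a CDR far from the antigen yields an antibody-only graph; antigen CDRs error", {
  atoms <- rbind(
    data.frame(chain = "H", resno = 1, ins = "", resid = "SER",
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(-1.2, 0, 1.2), y = 0, z = 0),
    data.frame(chain = "A", resno = 1, ins = "", resid = "GLY",
               elety = c("N", "CA", "C"), element = c("N", "C", "C"),
               x = c(28.8, 30, 31.2), y = 0, z = 0))
  cs <- complex_structure(atoms, c(H = "antibody", A = "antigen"))
  g <- cdr_neighborhood_graph(cs, data.frame(chain = "H", resno = 1))
  expect_true(all(g$node_partner == "antibody"))
  expect_error(cdr_neighborhood_graph(cs, data.frame(chain = "A", resno = 1)),
               "antibody partner")
})

test_that("graph serialization round-trips", {
  cs <- generate_complex(30, fixture_config())
  ifr <- interface_residues(cs)
  mu <- mutation(ifr$chain[1], ifr$resno[1], aa_one(ifr$resid[1]), "A")
  g <- mutation_neighborhood_graph(cs, mu)
  dir <- withr::local_tempdir()
  write_graph(g, dir)
  g2 <- read_graph(dir)
  expect_equal(g2$coords, unname(g$coords), tolerance = 1e-10)
  expect_equal(unname(g2$edges), unname(g$edges))
  expect_equal(unname(g2$edge_features), unname(g$edge_features))
  expect_equal(g2$node_partner, g$node_partner)
})
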