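# Affinity arithmetic and benchmark curation rules.

test_that("delta G from Kd follows RT ln(Kd)", {
  expect_equal(delta_g_from_kd(1, 298), 0)
  expect_equal(delta_g_from_kd(1e-9, 298), 1.9872e-3 * 298 * log(1e-9))
  expect_equal(delta_g_from_kd(1e-9, 298), -12.27, tolerance = 1e-3)
  expect_equal(delta_g_from_kd(1e-6, 298), -8.18, tolerance = 1e-3)
  expect_error(delta_g_from_kd(0, 298), "positive")
  expect_error(delta_g_from_kd(-1, 298), "positive")
  # monotone increasing in Kd
  kds <- 10^seq(-12, -3)
  expect_true(all(diff(delta_g_from_kd(kds, 298)) > 0))
})

test_that("ddG is dG_WT - dG_Mut, antisymmetric, negative for weakened binding", {
  expect_equal(ddg(-10, -8), -2)     # weaker binder => destabilizing
  expect_equal(ddg(3.3, 3.3), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(ddg(a, b), -ddg(b, a))
  }
})

toy_skempi <- function() {
  data.frame(
    `#Pdb` = c("1ABC_H_A", "1ABC_H_A", "1DEF_H_A", "1GHI_H_A", "1JKL_H_A"),
    `Mutation(s)_cleaned` = c("YH33A", "YH33A,DH52A", "TA17G", "WH99F", "SH10A"),
    `Affinity_wt (M)` = c("1e-9", "1e-9", "2e-8", "1e-9", "5e-9"),
    `Affinity_mut (M)` = c("1e-7", "1e-6", "n.b.", "1e-8", ">1e-5"),
    Temperature = c("298", "298", "298", "296", "298"),
    Method = c("SPR", "SPR", "ITC", "SPR", "SPR"),
    Hold_out_type = c("AB/AG", "AB/AG", "AB/AG", "AB/AG", "AB/AG"),
    `koff_mut (s^(-1))` = c("0.01", "", "", "", ""),
    check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("SKEMPI filtering removes multipoint, non-binder and imprecise rows", {
  tab <- toy_skempi()
  cur <- filter_skempi(tab)
  expect_equal(nrow(cur), 2)                      # YH33A and WH99F survive
  expect_setequal(cur$complex_id, c("1ABC", "1GHI"))
  rep <- attr(cur, "report")
  expect_equal(rep$removed[rep$stage == "multipoint"], 1)
  expect_equal(rep$removed[rep$stage == "non_binder"], 1)
  expect_equal(rep$removed[rep$stage == "imprecise_affinity"], 1)
  # ddG computed per equations 1-2: weaker binding -> negative
  r <- cur[cur$complex_id == "1ABC", ]
  expect_equal(r$ddg, 1.9872e-3 * 298 * (log(1e-9) - log(1e-7)))
  expect_lt(r$ddg, 0)
  # no duplicate keys, no qualifier-bearing values survive
  key <- paste(cur$complex_id, cur$chain, cur$position, cur$wt_aa, cur$mut_aa)
  expect_false(any(duplicated(key)))
})

test_that("an empty table filters to an empty table", {
  out <- filter_skempi(data.frame())
  expect_equal(nrow(out), 0)
})

test_that("non-antibody rows are dropped and malformed rows are reported, not silent", {
  tab <- toy_skempi()
  tab$Hold_out_type[1] <- "Pr/PI"
  tab$`Affinity_wt (M)`[4] <- "garbage"
  expect_warning(cur <- filter_skempi(tab), "malformed")
  expect_equal(nrow(cur), 0)
})

test_that("duplicate resolution prefers kinetics, then method rank, then temperature rank", {
  grp <- data.frame(method = c("ITC", "SPR"), temperature_raw = c("298", "298"),
                    has_kinetics = c(FALSE, FALSE), id = 1:2)
  expect_equal(resolve_duplicates(grp)$method, "SPR")
  grp <- data.frame(method = c("SPR", "SPR"), temperature_raw = c("296", "298"),
                    has_kinetics = c(FALSE, FALSE), id = 1:2)
  expect_equal(resolve_duplicates(grp)$temperature_raw, "298")
  grp <- data.frame(method = c("ELISA", "SPR"), temperature_raw = c("298", "298"),
                    has_kinetics = c(TRUE, FALSE), id = 1:2)
  expect_equal(resolve_duplicates(grp)$method, "ELISA")   # kinetic data wins
  grp <- data.frame(method = c("SPR", "SPR"),
                    temperature_raw = c("298 (assumed)", "283"),
                    has_kinetics = c(FALSE, FALSE), id = 1:2)
  expect_equal(resolve_duplicates(grp)$temperature_raw, "283")
  single <- data.frame(method = "BI", temperature_raw = "310", id = 9)
  expect_identical(resolve_duplicates(single), single)
})

test_that("reverse augmentation doubles the data, negates labels, flags train/val-only", {
  ds <- data.frame(complex_id = c("X", "Y"), wt_aa = c("A", "G"),
                   mut_aa = c("W", "F"), pdb_wt = c("xw", "yw"),
                   pdb_mut = c("xm", "ym"), ddg = c(-2.0, 1.5))
  aug <- make_reverse_mutations(ds)
  expect_equal(nrow(aug), 4)
  fwd <- aug[!aug$is_reverse, ]
  expect_equal(fwd$ddg, ds$ddg)                     # forward subset preserved
  rev <- aug[aug$is_reverse, ]
  expect_equal(rev$ddg, c(2.0, -1.5))
  expect_equal(rev$wt_aa, ds$mut_aa)
  expect_equal(rev$pdb_wt, ds$pdb_mut)
  expect_true(all(rev$train_val_only))
  # negating a reverse label recovers the forward label (involution)
  expect_equal(-rev$ddg, fwd$ddg)
  # flagged members never land in a test fold
  n <- nrow(aug)
  ids <- as.character(seq_len(n))
  cl <- graphddg:::new_cluster_set(stats::setNames(ids, ids),
                                   stats::setNames(ids, ids))
  sp <- assign_folds(cl, seed = 1,
                     train_val_only = stats::setNames(aug$train_val_only, ids))
  expect_false(any(sp$fold[ids[aug$train_val_only]] == "test"))
})

test_that("non-binder flagging uses a strict -12.2 boundary", {
  expect_true(flag_non_binder(-12.3))
  expect_false(flag_non_binder(-12.2))
  expect_false(flag_non_binder(0))
})

test_that("evolutionary grounding requires positive and strictly-greater log-likelihood", {
  expect_true(evolutionarily_grounded(0.5, 0.2))
  expect_false(evolutionarily_grounded(-0.1, -0.5))
  expect_false(evolutionarily_grounded(0.5, 0.5))
  expect_false(evolutionarily_grounded(0.5, 0.9))
})

test_that("AB-Bind ingestion flips the sign and pins non-binders at -8", {
  tab <- data.frame(complex_id = c("1X", "1Y", "1Z"),
                    mutation = c("YH33A", "DA52E", "WH99F"),
                    ddg = c(2.0, -1.0, 5.0),
                    non_binder = c(FALSE, FALSE, TRUE))
  out <- read_abbind(tab)
  expect_equal(out$ddg, c(-2.0, 1.0, -8.0))
  expect_equal(out$chain, c("H", "A", "H"))
  expect_equal(sum(out$non_binder), 1)
})
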