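# Curation: Kd -> delta-G conversion, ddG arithmetic, SKEMPI-2.0-style
# filtering with duplicate resolution, reverse-mutation augmentation,
# non-binder handling and the evolutionary-grounding filter.
#
# Sign convention throughout: ddG = dG_WT - dG_Mutant, so a mutation that
# weakens binding (raises Kd, raises dG) has a negative ddG and is
# destabilizing.

#' Binding free energy from a dissociation constant
#'
#' `dG = R * T * ln(Kd)` in kcal/mol.
#'
#' @param kd Dissociation constant in molar (> 0).
#' @param temperature Temperature in Kelvin (> 0).
#' @param R Ideal gas constant, kcal/(mol K).
#' @return dG in kcal/mol.
#' @export
delta_g_from_kd <- function(kd, temperature, R = 1.9872e-3) {
  if (any(!is.finite(kd)) || any(kd <= 0)) stop("kd must be positive and finite")
  if (any(temperature <= 0)) stop("temperature must be positive")
  R * temperature * log(kd)
}

#' Change in binding free energy
#'
#' `ddG = value_wt - value_mut`; negative means destabilizing.
#'
#' @param value_wt,value_mut Wild-type and mutant dG (or interaction
#'   energies), kcal/mol.
#' @return ddG in kcal/mol.
#' @export
ddg <- function(value_wt, value_mut) {
  stopifnot(is.finite(value_wt), is.finite(value_mut))
  value_wt - value_mut
}

#' Flag likely non-binding mutations
#'
#' Mutations with ddG strictly below `threshold` (default -12.2 kcal/mol,
#' the lowest value observed in SKEMPI 2.0) fall outside the experimentally
#' measurable range and are flagged as likely non-binders.
#'
#' @param ddg_value Numeric ddG values, kcal/mol.
#' @param threshold Strict lower bound, kcal/mol.
#' @return Logical vector, TRUE = likely non-binder.
#' @export
flag_non_binder <- function(ddg_value, threshold = -12.2) {
  stopifnot(is.finite(ddg_value))
  ddg_value < threshold
}

#' Evolutionarily grounded mutations
#'
#' A mutation is evolutionarily grounded iff its (externally supplied, e.g.
#' PSSM-derived) log-likelihood is positive AND strictly greater than the
#' wild-type residue's log-likelihood at the same position.
#'
#' @param loglik_mut,loglik_wt Numeric log-likelihoods.
#' @return Logical vector.
#' @export
evolutionarily_grounded <- function(loglik_mut, loglik_wt) {
  stopifnot(is.finite(loglik_mut), is.finite(loglik_wt))
  loglik_mut > 0 & loglik_mut > loglik_wt
}

# Preference orders used when collapsing duplicated measurements.
skempi_method_rank <- function() {
  c("SPR" = 1, "ITC" = 2, "KinExA" = 3, "FL" = 4, "IASP" = 5,
    "SP" = 6, "CSPRIA" = 7, "ELISA" = 8, "BI" = 9)
}

skempi_temperature_rank <- function() {
  c("298" = 1, "296" = 2, "303" = 3, "310" = 4, "283" = 5, "298 (assumed)" = 6)
}

#' Resolve duplicated affinity measurements
#'
#' Among records sharing one (complex, chain, position, wt, mut) key, keeps a
#' single record by lexicographic preference: records with kinetic data
#' first, then by measurement method rank
#' (SPR > ITC > KinExA > FL > IASP > SP > CSPRIA > ELISA > BI), then by
#' temperature rank (298 > 296 > 303 > 310 > 283 > 298 (assumed)); the first
#' record under that ordering wins (input order breaks remaining ties).
#'
#' @param group data.frame of duplicated records with columns `method`,
#'   `temperature_raw` (character, may carry "(assumed)") and optionally
#'   `has_kinetics` (logical).
#' @return Single-row data.frame.
#' @export
resolve_duplicates <- function(group) {
  stopifnot(nrow(group) >= 1)
  if (nrow(group) == 1) return(group)
  mrank <- skempi_method_rank()[as.character(group$method)]
  mrank[is.na(mrank)] <- length(skempi_method_rank()) + 1
  trank <- skempi_temperature_rank()[trimws(as.character(group$temperature_raw))]
  trank[is.na(trank)] <- length(skempi_temperature_rank()) + 1
  kin <- if (!is.null(group$has_kinetics)) !isTRUE_vec(group$has_kinetics) else
    rep(1, nrow(group))
  ord <- order(kin, mrank, trank)
  group[ord[1], , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# Parse a SKEMPI-style mutation code like "YC33A": wt aa, chain, position
# (with optional insertion letter), mutant aa.
parse_mutation_code <- function(code) {
  m <- regmatches(code, regexec("^([A-Z])([A-Za-z0-9])(\\d+)([a-z]?)([A-Z])$", code))
  out <- lapply(m, function(g) {
    if (length(g) != 6) return(NULL)
    data.frame(wt_aa = g[2], chain = g[3], position = as.integer(g[4]),
               ins = g[5], mut_aa = g[6], stringsAsFactors = FALSE)
  })
  out
}

# Default column map for SKEMPI-2.0-style tables.
skempi_columns <- function() {
  list(complex = "#Pdb", mutation = "Mutation(s)_cleaned",
       kd_wt = "Affinity_wt (M)", kd_mut = "Affinity_mut (M)",
       temperature = "Temperature", method = "Method",
       hold_out = "Hold_out_type", koff = "koff_mut (s^(-1))")
}

has_qualifier <- function(x) grepl("[<>~]", x)

parse_kd <- function(x) {
  v <- suppressWarnings(as.numeric(gsub("[<>~ ]", "", x)))
  v
}

parse_temperature <- function(x) {
  suppressWarnings(as.numeric(gsub("[^0-9.]", "", x)))
}

#' Filter a SKEMPI-2.0-style table into a curated ddG benchmark
#'
#' Retains antibody-antigen, single-point, numerically measured binder
#' records; collapses duplicates with [resolve_duplicates()]; computes dG
#' for WT and mutant via [delta_g_from_kd()] and `ddG = dG_WT - dG_Mutant`.
#' Rows removed at each stage are reported in the `report` attribute, and
#' malformed rows are reported rather than silently dropped.
#'
#' @param records data.frame in SKEMPI 2.0 layout (see `cols`).
#' @param cols Column map; defaults to SKEMPI 2.0 headers.
#' @param ab_ag_types `Hold_out_type` values identifying antibody-antigen
#'   records.
#' @return data.frame of curated records (complex_id, chain, position, ins,
#'   wt_aa, mut_aa, kd_wt, kd_mut, temperature, method, dg_wt, dg_mut, ddg)
#'   with a `report` attribute tabulating removals.
#' @export
filter_skempi <- function(records, cols = skempi_columns(),
                          ab_ag_types = c("AB/AG", "AB/AG,Pr/PI")) {
  if (!nrow(records)) {
    out <- data.frame()
    attr(out, "report") <- data.frame(stage = character(0), removed = integer(0))
    return(out)
  }
  get <- function(nm) records[[cols[[nm]]]]
  report <- list()
  n0 <- nrow(records)

  keep <- get("hold_out") %in% ab_ag_types
  report$non_antibody_antigen <- sum(!keep)
  records <- records[keep, , drop = FALSE]

  mutcode <- as.character(get("mutation"))
  multi <- grepl(",", mutcode)
  report$multipoint <- sum(multi)
  records <- records[!multi, , drop = FALSE]
  mutcode <- mutcode[!multi]

  kd_mut_raw <- as.character(get("kd_mut"))
  kd_wt_raw <- as.character(get("kd_wt"))
  nb <- grepl("n\\.b\\.", kd_mut_raw, ignore.case = TRUE) | !nzchar(trimws(kd_mut_raw)) |
    is.na(kd_mut_raw)
  report$non_binder <- sum(nb)
  records <- records[!nb, , drop = FALSE]
  mutcode <- mutcode[!nb]; kd_wt_raw <- kd_wt_raw[!nb]; kd_mut_raw <- kd_mut_raw[!nb]

  imprecise <- has_qualifier(kd_wt_raw) | has_qualifier(kd_mut_raw)
  report$imprecise_affinity <- sum(imprecise)
  records <- records[!imprecise, , drop = FALSE]
  mutcode <- mutcode[!imprecise]
  kd_wt_raw <- kd_wt_raw[!imprecise]; kd_mut_raw <- kd_mut_raw[!imprecise]

  parsed <- parse_mutation_code(mutcode)
  kd_wt <- parse_kd(kd_wt_raw); kd_mut <- parse_kd(kd_mut_raw)
  temp_raw <- as.character(records[[cols$temperature]])
  temp <- parse_temperature(temp_raw)
  malformed <- vapply(parsed, is.null, logical(1)) | !is.finite(kd_wt) |
    !is.finite(kd_mut) | kd_wt <= 0 | kd_mut <= 0 | !is.finite(temp)
  if (any(malformed))
    warning(sum(malformed), " malformed row(s) removed (unparseable mutation/Kd/temperature): rows ",
            paste(utils::head(which(malformed), 10), collapse = ", "))
  report$malformed <- sum(malformed)
  records <- records[!malformed, , drop = FALSE]
  parsed <- parsed[!malformed]
  kd_wt <- kd_wt[!malformed]; kd_mut <- kd_mut[!malformed]
  temp <- temp[!malformed]; temp_raw <- temp_raw[!malformed]

  if (!nrow(records)) {
    out <- data.frame()
    attr(out, "report") <- data.frame(stage = names(report),
                                      removed = unlist(report))
    return(out)
  }
  pm <- do.call(rbind, parsed)
  complex_id <- sub("_.*$", "", as.character(records[[cols$complex]]))
  has_kin <- if (!is.null(cols$koff) && cols$koff %in% names(records)) {
    k <- suppressWarnings(as.numeric(as.character(records[[cols$koff]])))
    is.finite(k)
  } else rep(FALSE, nrow(records))
  cur <- data.frame(complex_id = complex_id, chain = pm$chain,
                    position = pm$position, ins = pm$ins, wt_aa = pm$wt_aa,
                    mut_aa = pm$mut_aa, kd_wt = kd_wt, kd_mut = kd_mut,
                    temperature = temp, temperature_raw = temp_raw,
                    method = as.character(records[[cols$method]]),
                    has_kinetics = has_kin, stringsAsFactors = FALSE)
  key <- paste(cur$complex_id, cur$chain, cur$position, cur$ins, cur$wt_aa,
               cur$mut_aa, sep = "|")
  dup_before <- nrow(cur)
  pieces <- lapply(split(seq_len(nrow(cur)), factor(key, levels = unique(key))),
                   function(ii) resolve_duplicates(cur[ii, , drop = FALSE]))
  cur <- do.call(rbind, pieces)
  rownames(cur) <- NULL
  report$duplicates <- dup_before - nrow(cur)

  cur$dg_wt <- delta_g_from_kd(cur$kd_wt, cur$temperature)
  cur$dg_mut <- delta_g_from_kd(cur$kd_mut, cur$temperature)
  cur$ddg <- cur$dg_wt - cur$dg_mut
  attr(cur, "report") <- data.frame(stage = names(report),
                                    removed = unname(unlist(report)))
  cur
}

#' Read an AB-Bind-style ddG table
#'
#' Applies the conventions used for that dataset: the ddG sign is flipped to
#' `ddG = dG_WT - dG_Mutant`, and non-binder rows are carried at the
#' sentinel value of -8 kcal/mol with a `non_binder` flag so they can be
#' included or excluded downstream.
#'
#' @param records data.frame with columns `complex_id`, `mutation` (code like
#'   "YC33A") and `ddg` (in the source's dG_Mut - dG_WT convention), plus
#'   optionally a logical `non_binder` column.
#' @return data.frame with parsed mutation fields, flipped `ddg` and a
#'   `non_binder` flag (non-binders set to -8).
#' @export
read_abbind <- function(records) {
  parsed <- parse_mutation_code(as.character(records$mutation))
  if (any(vapply(parsed, is.null, logical(1))))
    stop("unparseable mutation code(s) in AB-Bind table")
  pm <- do.call(rbind, parsed)
  nb <- if (!is.null(records$non_binder)) isTRUE_vec(records$non_binder)
        else rep(FALSE, nrow(records))
  out <- data.frame(complex_id = records$complex_id, chain = pm$chain,
                    position = pm$position, ins = pm$ins, wt_aa = pm$wt_aa,
                    mut_aa = pm$mut_aa,
                    ddg = -as.numeric(records$ddg),
                    non_binder = nb, stringsAsFactors = FALSE)
  out$ddg[nb] <- -8
  out
}

#' Add reverse mutations
#'
#' Appends one reverse example per forward example with swapped WT/mutant
#' identities and a negated ddG label. Reverse examples are marked
#' train/validation-only and must never appear in a test fold.
#'
#' @param dataset data.frame with columns `wt_aa`, `mut_aa`, `ddg` and
#'   optionally `pdb_wt`/`pdb_mut`.
#' @return Augmented data.frame with `is_reverse` and `train_val_only`
#'   columns; the forward subset is preserved bit-identically.
#' @export
make_reverse_mutations <- function(dataset) {
  fwd <- dataset
  if (is.null(fwd$is_reverse)) fwd$is_reverse <- FALSE
  if (is.null(fwd$train_val_only)) fwd$train_val_only <- FALSE
  rev <- fwd[!fwd$is_reverse, , drop = FALSE]
  tmp <- rev$wt_aa; rev$wt_aa <- rev$mut_aa; rev$mut_aa <- tmp
  if (!is.null(rev$pdb_wt)) {
    tmp <- rev$pdb_wt; rev$pdb_wt <- rev$pdb_mut; rev$pdb_mut <- tmp
  }
  rev$ddg <- -rev$ddg
  rev$is_reverse <- TRUE
  rev$train_val_only <- TRUE
  out <- rbind(fwd, rev)
  rownames(out) <- NULL
  out
}
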