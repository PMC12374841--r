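# Amino-acid constants used by the synthetic fixtures and the curation layer.

#' Amino-acid volumes
#'
#' Mean residue volumes in cubic Angstrom (Zamyatnin-style consensus values),
#' used by the synthetic ddG oracle's volume term and to size the side-chain
#' pseudo-atom templates of generated complexes.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
aa_volumes <- function() {
  c(A = 88.6,  R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G = 60.1,  H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S = 89.0,  T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
}

#' Side-chain pseudo-atom counts
#'
#' Number of side-chain pseudo-atoms (0-6) per residue type in generated
#' complexes. Counts scale with residue volume: glycine has none, tryptophan
#' the maximum of six. The table is fixed so that mutation rebuilding is
#' deterministic.
#'
#' @return Named integer vector over one-letter codes.
#' @export
aa_sidechain_atoms <- function() {
  c(A = 1L, R = 4L, N = 2L, D = 2L, C = 2L,
    Q = 3L, E = 3L, G = 0L, H = 3L, I = 4L,
    L = 4L, K = 4L, M = 3L, F = 4L, P = 2L,
    S = 1L, T = 2L, W = 6L, Y = 5L, V = 3L)
}

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x Character vector of codes.
#' @return Character vector of converted codes.
#' @export
aa_three <- function(x) {
  out <- AA3[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid one-letter code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname aa_three
#' @export
aa_one <- function(x) {
  map <- stats::setNames(names(AA3), AA3)
  out <- map[toupper(x)]
  if (anyNA(out)) stop("unknown amino-acid three-letter code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}
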