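GRANTHAM_AA <- c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                 "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W")

# upper triangle of the published amino-acid distance table, row by row in
# the order above
GRANTHAM_UPPER <- c(
  110, 145,  74,  58,  99, 124,  56, 142, 155, 144, 112,  89,  68,  46, 121,  65,  80, 135, 177,
       102, 103,  71, 112,  96, 125,  97,  97,  77, 180,  29,  43,  86,  26,  96,  54,  91, 101,
             98,  92,  96,  32, 138,   5,  22,  36, 198,  99, 113, 153, 107, 172, 138,  15,  61,
                  38,  27,  68,  42,  95, 114, 110, 169,  77,  76,  91, 103, 108,  93,  87, 147,
                       58,  69,  59,  89, 103,  92, 149,  47,  42,  65,  78,  85,  65,  81, 128,
                            64,  60,  94, 113, 112, 195,  86,  91, 111, 106, 126, 107,  84, 148,
                                109,  29,  50,  55, 192,  84,  96, 133,  97, 152, 121,  21,  88,
                                     135, 153, 147, 159,  98,  87,  80, 127,  94,  98, 127, 184,
                                           21,  33, 198,  94, 109, 149, 102, 168, 134,  10,  61,
                                                22, 205, 100, 116, 158, 102, 177, 140,  28,  40,
                                                    194,  83,  99, 143,  85, 160, 122,  36,  37,
                                                         174, 154, 139, 202, 154, 170, 196, 215,
                                                               24,  68,  32,  81,  40,  87, 115,
                                                                    46,  53,  61,  29, 101, 130,
                                                                         94,  23,  42, 142, 174,
                                                                             101,  56,  95, 110,
                                                                                   45, 160, 181,
                                                                                       126, 152,
                                                                                             67)

build_grantham_matrix <- function() {
  n <- length(GRANTHAM_AA)
  m <- matrix(0L, n, n, dimnames = list(GRANTHAM_AA, GRANTHAM_AA))
  k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    m[i, j] <- m[j, i] <- as.integer(GRANTHAM_UPPER[k])
  }
  m
}

.grantham_env <- new.env(parent = emptyenv())

#' The Grantham amino-acid distance matrix
#'
#' Symmetric, zero-diagonal 20 x 20 integer matrix of physicochemical
#' distances between amino acids (composition, polarity and molecular
#' volume combined).  Substitutions scoring above 100 are conventionally
#' regarded as moderate-to-severe.
#'
#' @return Integer matrix with one-letter amino-acid dimnames.
#' @export
grantham_matrix <- function() {
  if (is.null(.grantham_env$m)) .grantham_env$m <- build_grantham_matrix()
  .grantham_env$m
}

#' Grantham distance computed from first principles
#'
#' Recomputes the amino-acid distance from the underlying physicochemical
#' properties (composition c, polarity p, molecular volume v):
#' `D = rho * sqrt(alpha (ci-cj)^2 + beta (pi-pj)^2 + gamma (vi-vj)^2)`,
#' with the scale chosen so the mean over all pairs is 100.  This serves as
#' an independent cross-check of the tabulated matrix; a few published
#' entries differ by one unit from the formula because of rounding in the
#' original tabulation.
#'
#' @return Numeric 20 x 20 matrix (unrounded).
#' @export
grantham_from_properties <- function() {
  comp <- c(A = 0, R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89,
            E = 0.92, G = 0.74, H = 0.58, I = 0, L = 0, K = 0.33, M = 0,
            F = 0, P = 0.39, S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0)
  pol <- c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
           E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
           M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2,
           V = 5.9)
  vol <- c(A = 31, R = 124, N = 56, D = 54, C = 55, Q = 85, E = 83, G = 3,
           H = 96, I = 111, L = 111, K = 119, M = 105, F = 132, P = 32.5,
           S = 32, T = 61, W = 170, Y = 136, V = 84)
  aa <- GRANTHAM_AA
  raw <- outer(aa, aa, function(i, j)
    sqrt(1.833 * (comp[i] - comp[j])^2 + 0.1018 * (pol[i] - pol[j])^2 +
           0.000399 * (vol[i] - vol[j])^2))
  dimnames(raw) <- list(aa, aa)
  raw * 100 / mean(raw[upper.tri(raw)])
}

#' Grantham severity of an amino-acid substitution
#'
#' @param ref_aa,alt_aa standard one-letter amino-acid codes.
#' @param severe_cutoff substitutions scoring strictly above this are
#'   classed moderate-to-severe (default 100).
#' @return List with `score` (integer) and `class` (`"none"` for
#'   synonymous, `"moderate_to_severe"` above the cutoff, `"conservative"`
#'   otherwise).
#' @export
grantham_severity <- function(ref_aa, alt_aa, severe_cutoff = 100) {
  m <- grantham_matrix()
  ref_aa <- toupper(ref_aa); alt_aa <- toupper(alt_aa)
  if (!ref_aa %in% rownames(m) || !alt_aa %in% rownames(m))
    stop("nonstandard amino acid: ", ref_aa, "/", alt_aa)
  score <- m[ref_aa, alt_aa]
  cls <- if (score == 0) "none"
  else if (score > severe_cutoff) "moderate_to_severe"
  else "conservative"
  list(score = score, class = cls)
}
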