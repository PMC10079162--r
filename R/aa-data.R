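# Amino-acid reference tables used across the package. All tables are indexed
# by one-letter code in the fixed order of AA_ALPHABET.

#' The 20 standard amino acids, one-letter codes
#'
#' Fixed alphabetical ordering used for all matrix columns in the package.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

# Common modified residues mapped to their parent; everything else becomes 'X'
AA_NONSTANDARD <- c(MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
                    TPO = "T", PTR = "Y", CSO = "C", MLY = "K")

#' @keywords internal
aa_from_three <- function(resid3) {
  out <- AA_ONE[resid3]
  ns <- is.na(out)
  if (any(ns)) out[ns] <- AA_NONSTANDARD[resid3[ns]]
  out[is.na(out)] <- "X"
  unname(out)
}

# Kyte-Doolittle hydropathy
AA_HYDROPATHY <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                   G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                   M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                   S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Chou-Fasman beta-sheet conformational propensity
AA_BETA_PROPENSITY <- c(A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
                        G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
                        M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
                        S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)

# Net side-chain charge at pH 7 (His partially protonated)
AA_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0,
               G = 0, H = 0.1, I = 0, K = 1, L = 0,
               M = 0, N = 0, P = 0, Q = 0, R = 1,
               S = 0, T = 0, V = 0, W = 0, Y = 0)

# Residue volumes in cubic Angstrom (Zamyatnin 1972)
AA_VOLUME <- c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
               G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
               M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
               S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

# Theoretical maximum accessible surface area (A^2) of residue X in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical values)
AA_MAX_ASA <- c(A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
                G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
                M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
                S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0)

# Background amino-acid frequencies (Robinson & Robinson 1991), renormalised
AA_BACKGROUND <- local({
  f <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0624, F = 0.0385,
         G = 0.0738, H = 0.0226, I = 0.0514, K = 0.0574, L = 0.0901,
         M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
         S = 0.0711, T = 0.0584, V = 0.0643, W = 0.0132, Y = 0.0321)
  f / sum(f)
})

# van der Waals radii by element (Bondi); heavy atoms only are ever used
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                   SE = 1.90, H = 1.20)
ELEMENT_RADIUS_DEFAULT <- 1.70

# z-scored scales used by the solubility surrogate
aa_zscore <- function(x) (x - mean(x)) / stats::sd(x)
AA_HYDROPATHY_Z <- aa_zscore(AA_HYDROPATHY[AA_ALPHABET])
AA_BETA_Z <- aa_zscore(AA_BETA_PROPENSITY[AA_ALPHABET])
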