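# Amino-acid alphabets, the Atchley factor table, and the canonical
# 31-channel per-residue feature layout shared by every module.

## PSI-BLAST column order. PSSM feature indices (pssm_1 .. pssm_20) follow
## this order, so pssm_1 is conservation against A, pssm_8 against G,
## pssm_13 against M, pssm_17 against T.
PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_ALPHABET <- sort(PSSM_AA_ORDER)        # the 20 standard residues
AA_ALPHABET_X <- c(AA_ALPHABET, "X")      # plus the nominal padding residue

SS_STATES <- c("H", "E", "O")             # helix, strand, other
SA_STATES <- c("B", "E")                  # buried, exposed

## Atchley et al. factor solution: five standardized scores per residue
## summarising (1) polarity/hydrophobicity, (2) secondary-structure
## propensity, (3) molecular volume, (4) codon diversity and
## (5) electrostatic charge. Columns are standardized over the 20 residues
## (mean ~0, unit variance).
ATCHLEY_TABLE <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("polarity", "secondary_structure", "molecular_volume",
                    "codon_diversity", "electrostatic_charge")))

## One residue's 31 feature channels, in block order:
## 20 PSSM + 1 disorder + 5 Atchley factors + 3 SS one-hot + 2 SA one-hot.
BLOCK_CHANNELS <- c(paste0("pssm_", 1:20), "disorder_1", paste0("aaf_", 1:5),
                    paste0("ss_", 1:3), paste0("sa_", 1:2))
N_BLOCK_CHANNELS <- length(BLOCK_CHANNELS)   # 31

#' Atchley amino-acid factors for a residue
#'
#' Returns the five standardized Atchley factor scores (polarity,
#' secondary-structure propensity, molecular volume, codon diversity,
#' electrostatic charge) for one or more one-letter amino-acid codes. The
#' nominal residue \code{"X"} maps to the all-zero quintuple, matching the
#' zero-substitution rule used for window padding.
#'
#' @param residue character vector of one-letter codes (the 20 standard
#'   residues or \code{"X"}).
#' @return A numeric matrix with one row per input residue and the five
#'   factor columns; for a single residue, a named numeric vector of
#'   length 5.
#' @examples
#' atchleyFactors("G")
#' atchleyFactors(c("A", "X"))
#' @export
atchleyFactors <- function(residue) {
  residue <- toupper(as.character(residue))
  bad <- setdiff(unique(residue), AA_ALPHABET_X)
  if (length(bad))
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  out <- matrix(0, nrow = length(residue), ncol = 5,
                dimnames = list(residue, colnames(ATCHLEY_TABLE)))
  known <- residue != "X"
  out[known, ] <- ATCHLEY_TABLE[residue[known], , drop = FALSE]
  if (length(residue) == 1L) out[1L, ] else out
}

#' Names of the 31 per-residue feature channels
#'
#' The block layout every encoder and summary uses: 20 PSSM conservation
#' channels in PSI-BLAST column order (\code{pssm_1} = A ... \code{pssm_20}
#' = V), the disorder score, the five Atchley factors, the 3-state
#' secondary-structure one-hot and the 2-state solvent-accessibility
#' one-hot.
#'
#' @return Character vector of length 31.
#' @export
blockChannels <- function() BLOCK_CHANNELS

#' Feature names for a window of w subsites
#'
#' Window features are laid out subsite-major: all 31 channels of subsite 1,
#' then subsite 2, and so on. Names follow the
#' \code{"AA<subsite>_<channel>"} scheme, e.g. \code{"AA1_pssm_13"} is the
#' conservation score against methionine at subsite 1 and
#' \code{"AA13_aaf_5"} the electrostatic-charge factor at subsite 13.
#'
#' @param w odd window size (13, 15 or 17 in the reference setup).
#' @return Character vector of length \code{31 * w}.
#' @export
windowFeatureNames <- function(w) {
  w <- checkWindowSize(w)
  as.vector(vapply(seq_len(w), function(s) paste0("AA", s, "_", BLOCK_CHANNELS),
                   character(N_BLOCK_CHANNELS)))
}

checkWindowSize <- function(w) {
  w <- as.integer(w)
  if (length(w) != 1L || is.na(w) || w < 1L || w %% 2L == 0L)
    stop("window size must be a single odd positive integer, got ", w)
  w
}

## Parse "AA<subsite>_<type>_<index>" feature names into their parts.
parseFeatureNames <- function(names) {
  m <- regmatches(names, regexec("^AA([0-9]+)_([a-z]+)_([0-9]+)$", names))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed feature name(s): ", paste(names[bad], collapse = ", "))
  data.frame(name = names,
             subsite = as.integer(vapply(m, `[`, "", 2L)),
             type = vapply(m, `[`, "", 3L),
             index = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}
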