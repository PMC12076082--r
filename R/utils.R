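# Internal helpers shared across modules.

# 1 Da/A^3 expressed in mg/mL (1 Da = 1.66053906660e-24 g, 1 A^3 = 1e-24 cm^3).
.DA_PER_A3_IN_MG_ML <- 1660.53906660

# Average residue masses (Da) of the 20 standard amino acids as part of a
# peptide chain (free amino-acid mass minus water).
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.AA_ALPHABET <- names(.RESIDUE_MASS)

#' Chain mass of a peptide sequence
#'
#' Sums standard average residue masses over a one-letter amino-acid string.
#' Used to convert bead counts into mass densities (mg/mL) in the slab
#' analyses.
#'
#' @param sequence One-letter amino-acid string (20 standard residues).
#' @return Mass in Da.
#' @export
#' @examples
#' sequence_mass("GA")
sequence_mass <- function(sequence) {
  sum(residue_masses(sequence))
}

#' Per-residue masses of a peptide sequence
#'
#' @param sequence One-letter amino-acid string.
#' @return Numeric vector of residue masses (Da), one per residue.
#' @export
residue_masses <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% .AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-standard residue '", aa[bad[1L]], "' at position ", bad[1L])
  }
  unname(.RESIDUE_MASS[aa])
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators behave as pure functions of their parameters.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Wrap coordinates into [0, L) per axis.
wrap_coords <- function(x, box) {
  sweep_box <- matrix(box, nrow = nrow(x), ncol = 3L, byrow = TRUE)
  x - floor(x / sweep_box) * sweep_box
}

# Minimum-image displacement along one axis.
min_image <- function(dx, L) {
  dx - L * round(dx / L)
}

# Circular (periodic) weighted mean of positions on [0, L).
circular_mean <- function(z, L, w = NULL) {
  theta <- 2 * pi * z / L
  if (is.null(w)) w <- rep(1, length(z))
  s <- sum(w * sin(theta))
  c_ <- sum(w * cos(theta))
  ang <- atan2(s, c_)
  (ang %% (2 * pi)) * L / (2 * pi)
}
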