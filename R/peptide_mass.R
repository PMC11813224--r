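## Peptide elemental composition and monoisotopic mass, for assigning
## light vs heavy (uniform 13C/15N) isotope channels after 1:1 mixing of
## quenched reactions.

# Monoisotopic atomic masses (Da), CODATA/IUPAC 2021 values to >= 4 dp.
ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.9720706912
)

# Mass shifts per atom on uniform labeling.
DELTA_13C <- 13.0033548378 - ATOMIC_MASS[["C"]]  # 1.0033548
DELTA_15N <- 15.0001088984 - ATOMIC_MASS[["N"]]  # 0.9970349

# Residue (amino acid minus water) formulas, standard 20 letters.
RESIDUE_FORMULA <- list(
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0)
)

WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

#' Elemental composition of a peptide
#'
#' Sums residue formulas over the sequence and adds one water (the
#' peptide termini).  Only the 20 canonical one-letter residues are
#' accepted.
#'
#' @param sequence Amino-acid string, e.g. `"VIT"`.
#' @return Named integer vector with counts for C, H, N, O, S, of class
#'   `elemental_composition`.
#' @examples
#' peptide_composition("VIT")   # C15 H29 N3 O5
#' peptide_composition("VVIA")  # C19 H36 N4 O5
#' @export
peptide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence", call. = FALSE)
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters, names(RESIDUE_FORMULA))
  if (length(bad)) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  comp <- Reduce(`+`, RESIDUE_FORMULA[letters]) + WATER
  structure(comp, class = c("elemental_composition", class(comp)))
}

#' Monoisotopic mass of a composition
#'
#' For `labeling = "light"` the mass is the sum of counts times
#' monoisotopic atomic masses.  For `"uniform_13C15N"` (substrate grown
#' on 13C-glucose and 15NH4Cl as sole carbon/nitrogen sources) every
#' carbon and nitrogen is shifted:
#' `heavy = light + nC * (m13C - m12C) + nN * (m15N - m14N)`.
#'
#' @param comp Named numeric vector of element counts (C, H, N, O, S),
#'   e.g. from [peptide_composition()].
#' @param labeling `"light"` or `"uniform_13C15N"`.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(peptide_composition("VIT"))  # 331.2107
#' @export
monoisotopic_mass <- function(comp, labeling = c("light", "uniform_13C15N")) {
  labeling <- match.arg(labeling)
  comp <- comp[names(comp) %in% names(ATOMIC_MASS)]
  full <- stats::setNames(rep(0, length(ATOMIC_MASS)), names(ATOMIC_MASS))
  full[names(comp)] <- comp
  if (any(full < 0)) stop("negative element count", call. = FALSE)
  m <- sum(full * ATOMIC_MASS)
  if (labeling == "uniform_13C15N") {
    m <- m + full[["C"]] * DELTA_13C + full[["N"]] * DELTA_15N
  }
  unname(m)
}

#' Heavy-minus-light mass shift of a peptide
#'
#' @param sequence Amino-acid string.
#' @return Shift in Da, `nC * 1.0033548 + nN * 0.9970349`.
#' @export
heavy_shift <- function(sequence) {
  comp <- peptide_composition(sequence)
  unname(comp[["C"]] * DELTA_13C + comp[["N"]] * DELTA_15N)
}

#' Assign an observed mass to the light or heavy channel
#'
#' After quenching, the wild-type (light substrate) and mutant (heavy
#' substrate) reactions are mixed 1:1 and each coproduct is quantified
#' in both channels of the same run; channels are distinguished purely
#' by mass.  The observed mass is matched to the nearer of the two
#' theoretical masses within `tolerance`; ties and off-mass values are
#' `"unassigned"`.
#'
#' @param observed_mass Observed monoisotopic mass (Da).
#' @param sequence Peptide amino-acid string.
#' @param tolerance Match window in Da (> 0); default 0.02, the ion mass
#'   extraction width used for the small-peptide LC-MS/MS
#'   quantification.
#' @return `"light"`, `"heavy"` or `"unassigned"`.
#' @examples
#' m <- monoisotopic_mass(peptide_composition("VIT"))
#' assign_channel(m, "VIT")                        # "light"
#' assign_channel(m + heavy_shift("VIT"), "VIT")   # "heavy"
#' @export
assign_channel <- function(observed_mass, sequence, tolerance = 0.02) {
  stopifnot(is.numeric(observed_mass), length(observed_mass) == 1L,
            is.finite(observed_mass))
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be > 0", call. = FALSE)
  }
  comp <- peptide_composition(sequence)
  light <- monoisotopic_mass(comp, "light")
  heavy <- monoisotopic_mass(comp, "uniform_13C15N")
  dl <- abs(observed_mass - light)
  dh <- abs(observed_mass - heavy)
  if (dl > tolerance && dh > tolerance) return("unassigned")
  if (dl == dh) return("unassigned")
  if (dl < dh) "light" else "heavy"
}
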