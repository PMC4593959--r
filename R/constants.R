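# Physical constants and embedded reference tables.
#
# Isotope masses and abundances are the IUPAC/CIAAW 2013 representative
# values (as tabulated by NIST); they are embedded so that every envelope
# computed by the package is bit-stable against this fixed table.

#' Isotope table version tag
#'
#' Identifies the embedded isotope mass/abundance table. Envelopes computed
#' by [aggregate_envelope()] are reproducible against this exact table.
#' @return A single string.
#' @export
isotope_table_version <- function() "IUPAC-CIAAW-2013/NIST"

# proton mass in Da; electron mass is ignored throughout (well within the
# 15 ppm matching tolerances used for intact-protein work)
.PROTON_MASS <- 1.007276466

#' Mass of a proton in daltons
#' @return A single numeric (Da).
#' @export
proton_mass <- function() .PROTON_MASS

# per element: isotope masses (Da, strictly increasing) and natural
# abundances (fractions summing to 1)
.ISOTOPES <- list(
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.01410177812),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740048, 15.0001088989),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461956, 16.99913170, 17.99916100),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(mass = c(30.97376163),
           abundance = c(1.0))
)

#' Embedded isotope table
#'
#' Natural isotope masses and abundances for the elements supported by the
#' package (C, H, N, O, S, P). Abundances for each element sum to 1; masses
#' are strictly increasing.
#'
#' @param element Optional element symbol; if given, only that element's
#'   entry is returned.
#' @return A named list with components `mass` and `abundance` per element.
#' @export
isotope_table <- function(element = NULL) {
  if (is.null(element)) return(.ISOTOPES)
  if (!element %in% names(.ISOTOPES))
    stop("unknown element: ", element)
  .ISOTOPES[[element]]
}

# elemental composition of the 20 standard amino-acid residues
# (residue = amino acid minus water, as found in a peptide chain)
.RESIDUES <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1),
  A = c(C = 3, H = 5,  N = 1, O = 1),
  S = c(C = 3, H = 5,  N = 1, O = 2),
  P = c(C = 5, H = 7,  N = 1, O = 1),
  V = c(C = 5, H = 9,  N = 1, O = 1),
  T = c(C = 4, H = 7,  N = 1, O = 2),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6,  N = 2, O = 2),
  D = c(C = 4, H = 5,  N = 1, O = 3),
  Q = c(C = 5, H = 8,  N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7,  N = 1, O = 3),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1),
  F = c(C = 9, H = 9,  N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Elemental composition of an amino-acid residue
#'
#' @param aa One-letter code of a standard residue.
#' @return An [elem_comp] object.
#' @export
residue_composition <- function(aa) {
  r <- .RESIDUES[[aa]]
  if (is.null(r)) stop("unknown residue: ", aa)
  elem_comp(r)
}

# neutral-loss molecules and related small species
.LOSSES <- list(
  "NH3"      = c(N = 1, H = 3),
  "H2O"      = c(H = 2, O = 1),
  "NH3+H2O"  = c(N = 1, H = 5, O = 1),
  "2NH3"     = c(N = 2, H = 6),
  "2H2O"     = c(H = 4, O = 2)
)

#' Supported neutral-loss species
#' @return Character vector of loss names.
#' @export
neutral_losses <- function() names(.LOSSES)

.WATER <- c(H = 2, O = 1)
.CO    <- c(C = 1, O = 1)

# residues that make a fragment eligible for each loss class
.H2O_LOSS_RESIDUES <- c("D", "E", "S", "T")
.NH3_LOSS_RESIDUES <- c("K", "N", "Q", "R")
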