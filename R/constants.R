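## Physical constants and element/residue tables.
## Isotope masses and abundances: NIST/IUPAC 2013 compilation values.

#' Mass of a proton in Da (used for m/z arithmetic in positive-mode ESI)
#' @keywords internal
.PROTON <- 1.0072765

#' Mass of a hydrogen atom in Da (used for proton-displacement bookkeeping
#' of metal adducts on the neutral species)
#' @keywords internal
.HYDROGEN <- 1.0078250319

## Per-element isotope tables: mass (Da) and fractional abundance.
## "mono" is the most abundant isotope, the convention used for the
## monoisotopic mass of metal adducts as well as for CHNOPS.
.ISOTOPES <- list(
  H  = list(mass = c(1.0078250319, 2.0141017780),
            abund = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0000000, 13.0033548378),
            abund = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740052, 15.0001088984),
            abund = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146221, 16.9991315000, 17.9991604000),
            abund = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.9720706900, 32.9714585000, 33.9678668300, 35.9670808800),
            abund = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.9737615100, abund = 1.0),
  Se = list(mass = c(73.9224766, 75.9192141, 76.9199146, 77.9173095,
                     79.9165218, 81.9167000),
            abund = c(0.0089, 0.0937, 0.0763, 0.2377, 0.4961, 0.0873)),
  Na = list(mass = 22.9897696700, abund = 1.0),
  K  = list(mass = c(38.9637069, 39.9639987, 40.9618260),
            abund = c(0.932581, 0.000117, 0.067302)),
  Cu = list(mass = c(62.9295989, 64.9277929),
            abund = c(0.6915, 0.3085)),
  Zn = list(mass = c(63.9291448, 65.9260347, 66.9271291, 67.9248459, 69.9253325),
            abund = c(0.4917, 0.2773, 0.0404, 0.1845, 0.0061)),
  Fe = list(mass = c(53.9396127, 55.9349393, 56.9353958, 57.9332773),
            abund = c(0.05845, 0.91754, 0.02119, 0.00282)),
  Mg = list(mass = c(23.9850423, 24.9858374, 25.9825937),
            abund = c(0.7899, 0.1000, 0.1101)),
  Ca = list(mass = c(39.9625912, 41.9586183, 42.9587668, 43.9554811, 47.9525340),
            abund = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00187)),
  Ni = list(mass = c(57.9353462, 59.9307884, 60.9310579, 61.9283461, 63.9279679),
            abund = c(0.680769, 0.262231, 0.011399, 0.036345, 0.009256)),
  Mn = list(mass = 54.9380471, abund = 1.0)
)

## Monoisotopic mass of an element = mass of its MOST ABUNDANT isotope.
.elementMono <- function(sym) {
  iso <- .ISOTOPES[[sym]]
  if (is.null(iso)) stop("unknown element: '", sym, "'", call. = FALSE)
  iso$mass[which.max(iso$abund)]
}

## Average (abundance-weighted) mass of an element.
.elementAvg <- function(sym) {
  iso <- .ISOTOPES[[sym]]
  if (is.null(iso)) stop("unknown element: '", sym, "'", call. = FALSE)
  sum(iso$mass * iso$abund) / sum(iso$abund)
}

## Divalent cations by native-MS convention displace 2 protons when bound
## to the neutral species; monovalent displace 1.
.METAL_DEFAULT_DISPLACEMENT <- c(
  Cu = 2L, Zn = 2L, Fe = 2L, Mg = 2L, Ca = 2L, Ni = 2L, Mn = 2L,
  Na = 1L, K = 1L
)

## Residue (amino-acid minus water) elemental compositions, 20 canonical + U.
.RESIDUES <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  U = c(C = 3, H = 5, N = 1, O = 1, Se = 1)
)

.WATER <- c(H = 2, O = 1)

## Averagine: average elemental composition per 111.1254 Da of protein,
## used to model isotope envelopes when the exact composition is unknown.
.AVERAGINE <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
.AVERAGINE_UNIT_MASS <- 111.1254

#' Supported chemical elements
#'
#' @return Character vector of element symbols known to the mass tables.
#' @export
#' @examples
#' supportedElements()
supportedElements <- function() names(.ISOTOPES)
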