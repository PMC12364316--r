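# Element lookup tables used across the package: masses for dynamics,
# atomic numbers for density amplitudes, covalent radii for bond inference,
# and a small Lennard-Jones table for the structure-native restraint field.

.ELEMENTS <- data.frame(
  symbol  = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
              "NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU", "SE"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45,
              79.904, 126.904, 22.990, 39.098, 24.305, 40.078, 65.38,
              55.845, 54.938, 63.546, 78.971),
  z       = c(1L, 6L, 7L, 8L, 16L, 15L, 9L, 17L, 35L, 53L, 11L, 19L, 12L,
              20L, 30L, 26L, 25L, 29L, 34L),
  rcov    = c(0.31, 0.76, 0.71, 0.66, 1.05, 1.07, 0.57, 1.02, 1.20, 1.39,
              1.66, 2.03, 1.41, 1.76, 1.22, 1.32, 1.39, 1.32, 1.20),
  # LJ well parameters (sigma in Angstrom, epsilon in kJ/mol), Amber-like.
  lj_sigma = c(2.50, 3.40, 3.25, 2.96, 3.56, 3.74, 3.12, 3.47, 3.65, 3.88,
               3.33, 4.74, 2.11, 3.40, 1.96, 2.59, 2.59, 2.34, 3.56),
  lj_eps   = c(0.066, 0.360, 0.710, 0.880, 1.046, 0.840, 0.255, 1.110,
               1.250, 1.400, 0.012, 0.001, 3.660, 1.880, 0.052, 0.054,
               0.054, 0.005, 1.046),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

# canonical mixed-case display form ("Cl" not "CL")
.elementDisplay <- function(sym) {
  paste0(substr(sym, 1, 1), tolower(substr(sym, 2, nchar(sym))))
}

.isKnownElement <- function(sym) toupper(sym) %in% .ELEMENTS$symbol

.elementField <- function(sym, field) {
  i <- match(toupper(sym), .ELEMENTS$symbol)
  if (anyNA(i)) {
    bad <- unique(sym[is.na(i)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  .ELEMENTS[[field]][i]
}

elementMass <- function(sym) .elementField(sym, "mass")
elementZ <- function(sym) .elementField(sym, "z")
elementCovalentRadius <- function(sym) .elementField(sym, "rcov")

# Infer an element symbol from a PDB atom name when the element column is
# blank. Handles the common two-letter cases (CL/BR/NA/MG/...) by checking
# the left-justified two-character code first, then the first alpha char.
.elementFromAtomName <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[^A-Za-z]", "", nm)
    if (nchar(nm) == 0L) return(NA_character_)
    two <- toupper(substr(nm, 1, 2))
    one <- toupper(substr(nm, 1, 1))
    if (nchar(nm) >= 2L && two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN")) {
      two
    } else if (one %in% .ELEMENTS$symbol) {
      one
    } else if (two %in% .ELEMENTS$symbol) {
      two
    } else {
      NA_character_
    }
  }, character(1), USE.NAMES = FALSE)
}

.WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SOL")
.ION_NAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "BR", "IOD",
                "SO4", "PO4", "GOL", "EDO")
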