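# Element data used throughout the package.  Masses are standard atomic
# weights (u); default valences drive implicit-hydrogen assignment on the
# kekulized heavy-atom graph.

.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

atomic_mass <- function(element) {
  m <- .ATOMIC_MASS[element]
  if (anyNA(m)) {
    stop("no mass data for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# Implicit hydrogen count from the default valence model.  `charge` shifts
# the valence of N/P (protonation) and O/S (deprotonation); hypervalent S/P
# (sulfate, phosphate) simply saturate at their explicit bond-order sum.
implicit_hydrogens <- function(element, bond_order_sum, charge = 0) {
  v <- .DEFAULT_VALENCE[element]
  if (is.na(v)) return(0L)
  if (element %in% c("N", "P", "O", "S")) v <- v + charge
  if (element %in% c("C", "B", "Si")) v <- v - abs(charge)
  as.integer(max(0, v - bond_order_sum))
}
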