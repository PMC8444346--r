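# Thin wrappers around the OpenBabel toolkit (via ChemmineOB and the obabel
# command-line tool).  All chemistry I/O funnels through here so the rest of
# the package works on plain R data structures.

# Syntactic pre-checks: OpenBabel silently truncates some malformed SMILES,
# so unbalanced brackets and unclosed ring bonds are rejected up front.
check_smiles_syntax <- function(smiles) {
  s <- gsub("%[0-9]{2}", "", smiles)
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")") ||
      sum(chars == "[") != sum(chars == "]")) {
    stop("invalid SMILES (unbalanced brackets): ", smiles, call. = FALSE)
  }
  in_bracket <- FALSE
  digits <- character(0)
  for (ch in chars) {
    if (ch == "[") in_bracket <- TRUE
    if (ch == "]") in_bracket <- FALSE
    if (!in_bracket && grepl("[0-9]", ch)) digits <- c(digits, ch)
  }
  cnt <- table(digits)
  if (any(cnt %% 2 != 0)) {
    stop("invalid SMILES (unclosed ring bond): ", smiles, call. = FALSE)
  }
  invisible(TRUE)
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles a SMILES string.
#' @return the canonical SMILES string.
#' @keywords internal
ob_canonical_smiles <- function(smiles) {
  check_smiles_syntax(smiles)
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles))
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) stop("SMILES could not be parsed: ", smiles, call. = FALSE)
  out
}

# Convert an arbitrary-format chunk to canonical SMILES; returns NA on failure
# instead of erroring (used to probe validity of constructed test rings).
ob_to_canonical_or_na <- function(text, from = "SDF") {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, "CAN", text)),
    error = function(e) ""
  )
  out <- trimws(sub("\t.*$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

# Render a heavy-atom subgraph as a V2000 molfile (dummy 2D coordinates;
# only connectivity, bond orders and formal charges matter downstream).
graph_to_molfile <- function(elements, bonds, charges = NULL, title = "frag") {
  n <- length(elements)
  if (is.null(charges)) charges <- integer(n)
  nb <- if (is.null(bonds) || nrow(bonds) == 0) 0L else nrow(bonds)
  lines <- c(title, " autocg", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      (i - 1) %% 10, (i - 1) %/% 10, 0, elements[i]))
  }
  if (nb > 0) {
    for (k in seq_len(nb)) {
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                bonds$i[k], bonds$j[k], bonds$order[k]))
    }
  }
  chg <- which(charges != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, charges[chg]),
                                    collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}
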