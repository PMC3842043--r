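#' The degenerate bHLH consensus motif
#'
#' Builds the predictive basic helix-loop-helix (bHLH) consensus used
#' throughout the package. The motif is a left-to-right token list over
#' one-letter amino-acid codes with four token kinds:
#'
#' * `fixed`   -- a single invariant residue (E, R, N, L, K, A, Y),
#' * `class`   -- a small residue class: `+` = \{K, R\}, `alpha` = \{I, L, V\},
#'   `phi` = \{F, I, L\}, `delta` = \{I, V, T\},
#' * `wildcard` -- any residue (`X`),
#' * `spacer`  -- a variable-length run of any residues; the motif carries
#'   two, of length 3--6 (between the basic-region pair of basic residues
#'   and the invariant glutamate) and 5--22 (the loop).
#'
#' The 19 `fixed`/`class` tokens are the diagnostic (conserved) sites; a
#' scanned residue outside a diagnostic token's allowed set counts as one
#' mismatch, and a placement with at most nine mismatches is a putative bHLH
#' domain. The minimal concrete match spans 44 residues, the maximal 64.
#'
#' @return An object of class `bhlh_consensus`: a list with elements
#'   `tokens` (data frame with columns `kind`, `label`, `residues`,
#'   `min_len`, `max_len`), `diagnostic_indices` (integer positions of the
#'   19 diagnostic tokens within `tokens`), `min_length` and `max_length`.
#' @examples
#' motif <- bhlh_consensus()
#' length(motif$diagnostic_indices)  # 19
#' motif$min_length                  # 44
#' @export
bhlh_consensus <- function() {
  tok <- function(kind, label, residues = "", min_len = 1L, max_len = 1L) {
    data.frame(kind = kind, label = label, residues = residues,
               min_len = min_len, max_len = max_len,
               stringsAsFactors = FALSE)
  }
  plus  <- function() tok("class", "+", "KR")
  alpha <- function() tok("class", "a", "ILV")
  phi   <- function() tok("class", "f", "FIL")
  delta <- function() tok("class", "d", "IVT")
  fixed <- function(r) tok("fixed", r, r)
  wild  <- function(n) do.call(rbind, replicate(n, tok("wildcard", "X"),
                                                simplify = FALSE))
  spacer <- function(lo, hi) tok("spacer", "X*", "", as.integer(lo), as.integer(hi))

  tokens <- rbind(
    plus(), plus(),            # basic-region K/R pair
    spacer(3, 6),
    fixed("E"), plus(), wild(1), fixed("R"), wild(3),
    alpha(), fixed("N"), wild(2), phi(), wild(2), fixed("L"), plus(),
    spacer(5, 22),             # loop
    plus(), wild(2), fixed("K"), wild(2), delta(), fixed("L"), wild(2),
    fixed("A"), delta(), wild(1), fixed("Y"), alpha(), wild(2), fixed("L")
  )
  rownames(tokens) <- NULL
  diagnostic <- which(tokens$kind %in% c("fixed", "class"))
  structure(list(
    tokens = tokens,
    diagnostic_indices = diagnostic,
    min_length = sum(tokens$min_len),
    max_length = sum(tokens$max_len)
  ), class = "bhlh_consensus")
}

#' @export
print.bhlh_consensus <- function(x, ...) {
  lab <- ifelse(x$tokens$kind == "spacer",
                sprintf("X(%d-%d)", x$tokens$min_len, x$tokens$max_len),
                x$tokens$label)
  cat("bHLH consensus motif\n")
  cat("  pattern:   ", paste(lab, collapse = ""), "\n", sep = "")
  cat("  diagnostic sites: ", length(x$diagnostic_indices), "\n", sep = "")
  cat("  match length:     ", x$min_length, "-", x$max_length,
      " residues\n", sep = "")
  invisible(x)
}

# Residue offsets (0-based, relative to a placement start) of all tokens for
# a concrete pair of spacer lengths. Returns a list with per-token start
# offsets and the total span.
motif_layout <- function(motif, s1, s2) {
  lens <- motif$tokens$min_len
  lens[motif$tokens$kind == "spacer"] <- c(s1, s2)
  offs <- cumsum(c(0L, lens))[seq_along(lens)]
  list(offsets = offs, span = sum(lens))
}

# Offsets of the 19 diagnostic sites for spacer lengths (s1, s2).
diagnostic_offsets <- function(motif, s1, s2) {
  motif_layout(motif, s1, s2)$offsets[motif$diagnostic_indices]
}

# Allowed residue sets of the diagnostic sites, as a list of character
# vectors in motif order.
diagnostic_residues <- function(motif) {
  strsplit(motif$tokens$residues[motif$diagnostic_indices], "")
}
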