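#' Anchor-align bHLH domains on their 19 diagnostic sites
#'
#' Builds a gapped multiple alignment of bHLH domain sequences without any
#' optimisation: every domain's 19 diagnostic tokens are anchored to 19
#' shared columns and the two variable spacers are right-aligned against
#' their following anchor, left-padded with gaps up to the widest spacer in
#' the input set. With spacer maxima (6, 22) the frame is 64 columns wide; a
#' single domain aligns to itself with no gap columns.
#'
#' @param domains Named character vector of domain sequences (each the exact
#'   matched span of an accepted motif hit, e.g. cut out of a protein with
#'   [domain_sequence()]).
#' @param motif A [bhlh_consensus()] object.
#' @return Object of class `bhlh_alignment`: list with `ids`, `gapped`
#'   (equal-length gapped strings), `width`, `diagnostic_columns` (19 column
#'   indices), `regions` (column ranges of basic/helix1/loop/helix2) and the
#'   per-sequence spacer lengths.
#' @export
align_domains <- function(domains, motif = bhlh_consensus()) {
  stopifnot(is.character(domains), length(domains) >= 1L)
  if (is.null(names(domains))) names(domains) <- paste0("seq", seq_along(domains))
  # A domain string must be an exact matched span: its spacers satisfy
  # s1 + s2 = nchar - 36. Among the full-span spacer splits, keep the one
  # with fewest mismatches, preferring the smaller first spacer on ties.
  placements <- lapply(domains, function(d) {
    free <- nchar(d) - 36L
    s1s <- 3:6
    s1s <- s1s[free - s1s >= 5L & free - s1s <= 22L]
    if (!length(s1s)) {
      stop("sequence of length ", nchar(d), " is not a full-span bHLH domain")
    }
    mm <- vapply(s1s, function(s1)
      count_mismatches(d, 1L, s1, free - s1, motif), integer(1))
    s1 <- s1s[which.min(mm)]
    c(s1 = s1, s2 = free - s1)
  })
  s1 <- vapply(placements, function(p) as.integer(p["s1"]), integer(1))
  s2 <- vapply(placements, function(p) as.integer(p["s2"]), integer(1))
  S1 <- max(s1)
  S2 <- max(s2)

  gapped <- vapply(seq_along(domains), function(i) {
    d <- strsplit(domains[[i]], "")[[1]]
    blocks <- c(
      paste(d[1:2], collapse = ""),
      paste0(strrep("-", S1 - s1[i]),
             paste(d[3:(2 + s1[i])], collapse = "")),
      paste(d[(3 + s1[i]):(18 + s1[i])], collapse = ""),
      paste0(strrep("-", S2 - s2[i]),
             paste(d[(19 + s1[i]):(18 + s1[i] + s2[i])], collapse = "")),
      paste(d[(19 + s1[i] + s2[i]):(36 + s1[i] + s2[i])], collapse = "")
    )
    paste(blocks, collapse = "")
  }, character(1))

  mid_diag <- c(1L, 2L, 4L, 8L, 9L, 12L, 15L, 16L)
  tail_diag <- c(1L, 4L, 7L, 8L, 11L, 12L, 14L, 15L, 18L)
  diag_cols <- c(1L, 2L, 2L + S1 + mid_diag, 18L + S1 + S2 + tail_diag)
  structure(list(
    ids = names(domains),
    gapped = stats::setNames(gapped, names(domains)),
    width = 36L + S1 + S2,
    diagnostic_columns = diag_cols,
    regions = list(basic  = c(1L, 9L + S1),
                   helix1 = c(10L + S1, 18L + S1),
                   loop   = c(19L + S1, 18L + S1 + S2),
                   helix2 = c(19L + S1 + S2, 36L + S1 + S2)),
    spacer1 = s1, loop_len = s2
  ), class = "bhlh_alignment")
}

#' @export
print.bhlh_alignment <- function(x, ...) {
  cat("bHLH domain alignment: ", length(x$ids), " sequence(s), ",
      x$width, " columns, 19 diagnostic columns\n", sep = "")
  invisible(x)
}

#' Per-column conservation of an alignment
#'
#' @param alignment A [align_domains()] result.
#' @param threshold Fraction of sequences that must share one residue for a
#'   column to be flagged `high` (default 0.8).
#' @return Data frame with `column`, `consensus` (most frequent residue,
#'   gaps never count), `identity` (its fraction of sequences) and `level`
#'   (`"high"` or `""`), plus `diagnostic` flagging the 19 anchor columns.
#' @export
conservation <- function(alignment, threshold = 0.8) {
  mat <- do.call(rbind, strsplit(alignment$gapped, ""))
  n <- nrow(mat)
  stats_ <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (!length(col)) return(data.frame(consensus = "-", identity = 0))
    tab <- sort(table(col), decreasing = TRUE)
    data.frame(consensus = names(tab)[1], identity = tab[[1]] / n)
  })
  out <- do.call(rbind, stats_)
  out <- data.frame(column = seq_len(ncol(mat)), out,
                    level = ifelse(out$identity >= threshold, "high", ""),
                    diagnostic = seq_len(ncol(mat)) %in%
                      alignment$diagnostic_columns,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Normalised dissimilarity between two gapped domain strings
#'
#' One minus the fraction of identical residue pairs over the columns where
#' neither sequence carries a gap; columns gapped in either sequence are
#' skipped.
#'
#' @param a,b Gapped strings of equal length.
#' @return Distance in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  use <- ca != "-" & cb != "-"
  if (!any(use)) stop("undefined distance: no comparable (gap-free) columns")
  1 - sum(ca[use] == cb[use]) / sum(use)
}

#' All pairwise domain distances
#'
#' @param domains Named character vector of domain sequences.
#' @param motif A [bhlh_consensus()] object.
#' @return A symmetric matrix of [pairwise_distance()] values on the shared
#'   anchored frame.
#' @export
domain_distance_matrix <- function(domains, motif = bhlh_consensus()) {
  aln <- align_domains(domains, motif)
  n <- length(aln$gapped)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- pairwise_distance(aln$gapped[i], aln$gapped[j])
      }
    }
  }
  d
}

#' Cut the matched domain out of its protein
#'
#' @param seq Protein sequence the hit was found in.
#' @param hit One row of a [scan_sequence()] / [scan_proteome()] result.
#' @return The domain substring (the matched span).
#' @export
domain_sequence <- function(seq, hit) {
  substring(seq, hit$start, hit$end)
}

#' Write an alignment as aligned FASTA and a text conservation view
#'
#' @param alignment A [align_domains()] result.
#' @param fasta_path Output path for the gapped FASTA.
#' @param view_path Optional path for a plain-text view marking the 19
#'   diagnostic columns with `*` and high-conservation columns with `#`.
#' @param threshold Conservation threshold passed to [conservation()].
#' @export
write_alignment <- function(alignment, fasta_path, view_path = NULL,
                            threshold = 0.8) {
  writeLines(as.vector(rbind(paste0(">", alignment$ids), alignment$gapped)),
             fasta_path)
  if (!is.null(view_path)) {
    cons <- conservation(alignment, threshold)
    marks <- ifelse(cons$diagnostic, "*",
                    ifelse(cons$level == "high", "#", " "))
    pad <- max(nchar(alignment$ids)) + 2L
    lines <- c(paste0(strrep(" ", pad), paste(marks, collapse = "")),
               sprintf(paste0("%-", pad, "s%s"), alignment$ids,
                       alignment$gapped))
    writeLines(lines, view_path)
  }
  invisible(fasta_path)
}
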