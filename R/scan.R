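#' Scan a protein sequence for bHLH domains
#'
#' Enumerates every placement of the degenerate bHLH consensus (window start
#' crossed with both variable spacer lengths) that fits in the sequence,
#' keeps the best placement per start position, suppresses placements that
#' overlap a better-scoring one by more than half their span, and flags each
#' surviving hit as accepted when its diagnostic-site mismatch count is at
#' most `max_mismatch`.
#'
#' Best-placement tie-breaking is: fewest mismatches, then shortest total
#' match, then smaller first-spacer length, then leftmost start. Residues
#' outside the 20 canonical amino acids (ambiguity codes B, Z, X, U, stop
#' `*`, ...) are legal input but always count as mismatches at diagnostic
#' sites.
#'
#' @param seq Character scalar, one-letter amino-acid sequence.
#' @param motif A [bhlh_consensus()] object.
#' @param max_mismatch Acceptance budget over the 19 diagnostic sites
#'   (default 9: at most nine mismatches make a putative bHLH domain).
#' @return A `bhlh_hits` data frame, one row per surviving placement, sorted
#'   by `start`, with 1-based inclusive coordinates: `start`, `end`,
#'   `spacer1`, `loop_len`, `mismatches`, `accepted`, `site_matches`
#'   (19-character string of 1/0 over the diagnostic sites), region bounds
#'   (`basic_start`..`helix2_end`) and `binding_class`
#'   (`"E-box-binder"` or `"non-binder"`).
#' @examples
#' hit <- scan_sequence("KRAAAEKARAAAINAAFAALKAAAAARAAKAAVLAAAVAYIAAL")
#' hit$mismatches  # 0
#' @export
scan_sequence <- function(seq, motif = bhlh_consensus(), max_mismatch = 9) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  if (L < motif$min_length) return(empty_hits())

  diag_res <- diagnostic_residues(motif)
  sp <- motif$tokens[motif$tokens$kind == "spacer", c("min_len", "max_len")]
  n_start <- L - motif$min_length + 1L
  best_mism <- rep(Inf, n_start)
  best_span <- rep(Inf, n_start)
  best_s1   <- rep(Inf, n_start)
  best_s2   <- rep(NA_integer_, n_start)
  best_sites <- character(n_start)

  for (s1 in sp$min_len[1]:sp$max_len[1]) {
    for (s2 in sp$min_len[2]:sp$max_len[2]) {
      span <- motif$min_length - sp$min_len[1] - sp$min_len[2] + s1 + s2
      if (span > L) next
      offs <- diagnostic_offsets(motif, s1, s2)
      starts <- seq_len(L - span + 1L)
      ok <- matrix(FALSE, length(starts), length(offs))
      for (j in seq_along(offs)) {
        ok[, j] <- chars[starts + offs[j]] %in% diag_res[[j]]
      }
      mism <- length(offs) - rowSums(ok)
      better <- mism < best_mism[starts] |
        (mism == best_mism[starts] &
           (span < best_span[starts] |
              (span == best_span[starts] & s1 < best_s1[starts])))
      upd <- starts[better]
      if (length(upd)) {
        best_mism[upd] <- mism[better]
        best_span[upd] <- span
        best_s1[upd] <- s1
        best_s2[upd] <- s2
        best_sites[upd] <- apply(ok[better, , drop = FALSE], 1L,
                                 function(r) paste(as.integer(r), collapse = ""))
      }
    }
  }

  cand <- which(is.finite(best_mism))
  if (!length(cand)) return(empty_hits())
  hits <- data.frame(
    start = cand,
    end = cand + as.integer(best_span[cand]) - 1L,
    spacer1 = as.integer(best_s1[cand]),
    loop_len = as.integer(best_s2[cand]),
    mismatches = as.integer(best_mism[cand]),
    site_matches = best_sites[cand],
    stringsAsFactors = FALSE
  )

  # Greedy >50%-overlap suppression, best-scoring placements first.
  ord <- order(hits$mismatches, hits$end - hits$start, hits$spacer1, hits$start)
  keep <- integer(0)
  for (i in ord) {
    len_i <- hits$end[i] - hits$start[i] + 1L
    ov <- pmax(0L, pmin(hits$end[keep], hits$end[i]) -
                     pmax(hits$start[keep], hits$start[i]) + 1L)
    if (!length(keep) || all(ov <= len_i / 2)) keep <- c(keep, i)
  }
  hits <- hits[sort(keep), , drop = FALSE]
  rownames(hits) <- NULL

  hits$accepted <- hits$mismatches <= max_mismatch
  reg <- t(mapply(region_bounds, hits$start, hits$spacer1, hits$loop_len))
  hits <- cbind(hits, as.data.frame(reg))
  hits$binding_class <- vapply(hits$site_matches, diagnose_binding, "",
                               USE.NAMES = FALSE)
  class(hits) <- c("bhlh_hits", "data.frame")
  hits
}

empty_hits <- function() {
  hits <- data.frame(
    start = integer(0), end = integer(0), spacer1 = integer(0),
    loop_len = integer(0), mismatches = integer(0),
    site_matches = character(0), accepted = logical(0),
    basic_start = integer(0), basic_end = integer(0),
    helix1_start = integer(0), helix1_end = integer(0),
    loop_start = integer(0), loop_end = integer(0),
    helix2_start = integer(0), helix2_end = integer(0),
    binding_class = character(0), stringsAsFactors = FALSE
  )
  class(hits) <- c("bhlh_hits", "data.frame")
  hits
}

# 1-based inclusive bounds of the four structural regions for a placement
# at `start` with concrete spacer lengths. The basic region runs through
# the three wildcards after the invariant arginine; helix 1 runs from the
# hydrophobic anchor through the basic residue preceding the loop; the loop
# is exactly the second spacer; helix 2 is the remainder.
region_bounds <- function(start, s1, s2) {
  c(basic_start = start,              basic_end = start + 8L + s1,
    helix1_start = start + 9L + s1,   helix1_end = start + 17L + s1,
    loop_start = start + 18L + s1,    loop_end = start + 17L + s1 + s2,
    helix2_start = start + 18L + s1 + s2,
    helix2_end = start + 35L + s1 + s2)
}

#' Segment a hit into basic / helix 1 / loop / helix 2
#'
#' @param hit One row of a [scan_sequence()] result.
#' @return Named list of integer `c(start, end)` pairs (1-based inclusive)
#'   that tile the hit span contiguously; the loop interval has exactly the
#'   hit's second-spacer (loop) length.
#' @export
segment_hit <- function(hit) {
  stopifnot(nrow(hit) == 1L)
  list(basic  = c(hit$basic_start,  hit$basic_end),
       helix1 = c(hit$helix1_start, hit$helix1_end),
       loop   = c(hit$loop_start,   hit$loop_end),
       helix2 = c(hit$helix2_start, hit$helix2_end))
}

#' Count diagnostic-site mismatches of a concrete placement
#'
#' @param seq Amino-acid sequence.
#' @param start 1-based placement start.
#' @param spacer1,loop_len Concrete lengths of the two variable spacers.
#' @param motif A [bhlh_consensus()] object.
#' @return Integer number of the 19 diagnostic sites whose residue falls
#'   outside the site's allowed set.
#' @export
count_mismatches <- function(seq, start, spacer1, loop_len,
                             motif = bhlh_consensus()) {
  sum(!placement_site_matches(seq, start, spacer1, loop_len, motif))
}

placement_site_matches <- function(seq, start, spacer1, loop_len, motif) {
  chars <- strsplit(toupper(seq), "")[[1]]
  offs <- diagnostic_offsets(motif, spacer1, loop_len)
  stopifnot(start >= 1L, start + max(offs) <= length(chars))
  res <- diagnostic_residues(motif)
  vapply(seq_along(offs),
         function(j) chars[start + offs[j]] %in% res[[j]], logical(1))
}

#' Diagnose DNA-binding capability of a hit
#'
#' A domain is called an E-box binder when the invariant glutamate and
#' arginine of the basic region (structurally Glu-9/Arg-12 when the first
#' spacer is at its maximum) both match and at least one of the three
#' basic-region K/R sites is present; otherwise it is a non-binder, the
#' situation of the group D antagonists that lack a functional basic region.
#'
#' @param site_matches Either a 19-character "1"/"0" string (the
#'   `site_matches` column of a hits table) or a logical vector of length 19
#'   over the diagnostic sites in motif order.
#' @return `"E-box-binder"` or `"non-binder"`.
#' @export
diagnose_binding <- function(site_matches) {
  m <- site_matches
  if (is.character(m)) m <- strsplit(m, "")[[1]] == "1"
  stopifnot(length(m) == 19L)
  # diagnostic-site order: + + E + R a N f L + + K d L A d Y a L
  if (m[3] && m[5] && any(m[c(1, 2, 4)])) "E-box-binder" else "non-binder"
}

#' Scan a multi-record FASTA proteome
#'
#' @param fasta_path Path to a (possibly wrapped) protein FASTA file.
#' @param motif A [bhlh_consensus()] object.
#' @param max_mismatch Acceptance budget, see [scan_sequence()].
#' @param emit_rejected Keep best placements that exceed the mismatch budget
#'   (default drops them).
#' @return A `bhlh_hits` data frame with a leading `sequence_id` column,
#'   ordered by (`sequence_id`, `start`).
#' @export
scan_proteome <- function(fasta_path, motif = bhlh_consensus(),
                          max_mismatch = 9, emit_rejected = FALSE) {
  seqs <- read_fasta(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    h <- scan_sequence(seqs[[i]], motif, max_mismatch)
    if (nrow(h)) cbind(sequence_id = ids[i], h, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(sequence_id = character(0), empty_hits())
  if (!emit_rejected) out <- out[out$accepted, , drop = FALSE]
  out <- out[order(out$sequence_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bhlh_hits", "data.frame")
  out
}

# FASTA input via Biostrings; identifiers are the first whitespace-delimited
# word of each header. An empty file yields an empty named character vector.
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' @export
print.bhlh_hits <- function(x, ...) {
  cat("bHLH motif hits: ", nrow(x), " placement(s), ",
      sum(x$accepted), " accepted\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20L))
  invisible(x)
}

#' Write a hits table as TSV
#'
#' Columns follow the human-readable report convention (1-based inclusive
#' coordinates, regions as `start-end` strings).
#'
#' @param hits A `bhlh_hits` data frame (with or without `sequence_id`).
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  iv <- function(a, b) ifelse(is.na(a), "", paste0(a, "-", b))
  out <- data.frame(
    sequence_id = if ("sequence_id" %in% names(hits)) hits$sequence_id else "",
    start1 = hits$start, end1 = hits$end,
    mismatches = hits$mismatches, accepted = hits$accepted,
    spacer1 = hits$spacer1, loop_len = hits$loop_len,
    basic = iv(hits$basic_start, hits$basic_end),
    helix1 = iv(hits$helix1_start, hits$helix1_end),
    loop = iv(hits$loop_start, hits$loop_end),
    helix2 = iv(hits$helix2_start, hits$helix2_end),
    binding_class = hits$binding_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference brute-force placement scanner
#'
#' A deliberately naive residue-by-residue scanner kept independent of
#' [scan_sequence()]: it expands every (start, spacer1, loop length)
#' placement of a flat pattern vector and returns the best placement under
#' the same tie-breaking (fewest mismatches, shortest span, smaller first
#' spacer, leftmost). Used to certify synthetic planted domains and as the
#' test oracle for the production scanner.
#'
#' @param seq Amino-acid sequence.
#' @return `NULL` when no placement fits, else a list with `start`, `end`
#'   (1-based inclusive), `s1`, `s2` and `mismatches`.
#' @export
oracle_scan <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  best <- NULL
  for (s1 in 3:6) {
    for (s2 in 5:22) {
      pat <- c("KR", "KR", rep(".", s1),
               "E", "KR", ".", "R", rep(".", 3),
               "ILV", "N", rep(".", 2), "FIL", rep(".", 2), "L", "KR",
               rep(".", s2),
               "KR", rep(".", 2), "K", rep(".", 2), "IVT", "L",
               rep(".", 2), "A", "IVT", ".", "Y", "ILV", rep(".", 2), "L")
      span <- length(pat)
      if (span > L) next
      site_off <- which(pat != ".") - 1L
      allowed <- strsplit(pat[pat != "."], "")
      for (start in seq_len(L - span + 1L)) {
        mm <- 0L
        for (t in seq_along(site_off)) {
          if (!chars[start + site_off[t]] %in% allowed[[t]]) mm <- mm + 1L
        }
        # tie-break order: mismatches, span, first spacer, leftmost start
        if (is.null(best) || mm < best$mismatches ||
            (mm == best$mismatches &&
               (span < best$end - best$start + 1L ||
                  (span == best$end - best$start + 1L &&
                     (s1 < best$s1 ||
                        (s1 == best$s1 && start < best$start)))))) {
          best <- list(start = start, end = start + span - 1L,
                       s1 = s1, s2 = s2, mismatches = mm)
        }
      }
    }
  }
  best
}
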