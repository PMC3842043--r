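#' Assign bHLH domains to families and supergroups
#'
#' Places each query domain on the anchored alignment frame together with
#' the 45 registry representatives, computes normalised distances
#' ([pairwise_distance()]) and assigns the family of the minimum-distance
#' representative, falling back to `"orphan"` whenever even the nearest
#' representative is farther than `orphan_threshold`. Beyond roughly 55%
#' domain divergence, family identity under this scheme is not credible,
#' hence the default threshold of 0.55.
#'
#' With `bootstrap > 0`, assignment robustness is quantified by column
#' resampling: alignment columns are drawn with replacement, distances are
#' recomputed on the replicate, and the support is the percentage of
#' replicates in which the query stays nearest to its assigned family.
#'
#' When more than one query lands in the same family, queries are
#' additionally numbered `a`, `b`, `c`, ... in input order
#' (`assigned_name`), the multi-ortholog naming convention of the survey.
#'
#' @param domains Named character vector of full-span domain sequences.
#' @param registry A [load_family_registry()] data frame.
#' @param orphan_threshold Maximum credible distance to the nearest
#'   representative (default 0.55).
#' @param bootstrap Number of column-resampling replicates (0 disables).
#' @param seed Integer seed for the bootstrap, required for reproducibility
#'   when `bootstrap > 0`.
#' @param motif A [bhlh_consensus()] object.
#' @return Data frame of class `bhlh_assignment` with one row per query:
#'   `sequence_id`, `family`, `assigned_name`, `supergroup`,
#'   `nearest_reference`, `distance`, `support_percent` (NA without
#'   bootstrap).
#' @export
classify_domains <- function(domains, registry = load_family_registry(),
                             orphan_threshold = 0.55, bootstrap = 0,
                             seed = NULL, motif = bhlh_consensus()) {
  stopifnot(is.character(domains), length(domains) >= 1L)
  if (!nrow(registry)) stop("empty registry")
  if (is.null(names(domains))) names(domains) <- paste0("query", seq_along(domains))

  refs <- stats::setNames(registry$representative_domain, registry$family)
  aln <- align_domains(c(domains, refs), motif)
  nq <- length(domains)
  qg <- aln$gapped[seq_len(nq)]
  rg <- aln$gapped[nq + seq_along(refs)]

  dist_mat <- matrix(NA_real_, nq, length(refs),
                     dimnames = list(names(domains), registry$family))
  for (i in seq_len(nq)) {
    for (j in seq_along(refs)) {
      dist_mat[i, j] <- pairwise_distance(qg[i], rg[j])
    }
  }
  nearest_j <- apply(dist_mat, 1L, which.min)
  nearest <- registry$family[nearest_j]
  dist <- dist_mat[cbind(seq_len(nq), nearest_j)]
  is_orphan <- dist > orphan_threshold
  family <- ifelse(is_orphan, "orphan", nearest)
  supergroup <- ifelse(is_orphan, "orphan",
                       registry$supergroup[match(nearest, registry$family)])

  support <- rep(NA_real_, nq)
  if (bootstrap > 0) {
    if (is.null(seed)) stop("bootstrap requires a seed")
    support <- bootstrap_support(qg, rg, registry$family, nearest,
                                 n_replicates = bootstrap, seed = seed)
  }

  out <- data.frame(
    sequence_id = names(domains), family = family,
    assigned_name = multi_ortholog_names(family),
    supergroup = supergroup, nearest_reference = nearest,
    distance = dist, support_percent = support,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("bhlh_assignment", "data.frame")
  out
}

#' @rdname classify_domains
#' @param domain A single full-span domain sequence.
#' @export
assign_family <- function(domain, registry = load_family_registry(),
                          orphan_threshold = 0.55, motif = bhlh_consensus()) {
  classify_domains(stats::setNames(domain, "query"), registry,
                   orphan_threshold, motif = motif)
}

# "a"/"b"/"c" suffixing for multiple queries assigned to one family, in
# input order; orphans are never suffixed.
multi_ortholog_names <- function(family) {
  name <- family
  for (f in unique(family[family != "orphan"])) {
    idx <- which(family == f)
    if (length(idx) > 1L) name[idx] <- paste0(f, letters[seq_along(idx)])
  }
  name
}

#' Column-resampling bootstrap support for family assignments
#'
#' @param query_gapped,ref_gapped Gapped strings on a common alignment
#'   frame.
#' @param ref_families Family label of each reference.
#' @param assigned Family each query is being tested against (its
#'   nearest-reference family on the full alignment).
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical support.
#' @return Numeric vector of support percentages in `[0, 100]`.
#' @export
bootstrap_support <- function(query_gapped, ref_gapped, ref_families,
                              assigned, n_replicates = 100, seed = 1) {
  stopifnot(n_replicates >= 1)
  width <- unique(nchar(c(query_gapped, ref_gapped)))
  stopifnot(length(width) == 1L)
  qmat <- do.call(rbind, strsplit(query_gapped, ""))
  rmat <- do.call(rbind, strsplit(ref_gapped, ""))
  hits <- matrix(0L, length(query_gapped), n_replicates)
  with_preserved_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(width, width, replace = TRUE)
      for (i in seq_len(nrow(qmat))) {
        qc <- qmat[i, cols]
        d <- apply(rmat[, cols, drop = FALSE], 1L, function(rc) {
          use <- qc != "-" & rc != "-"
          if (!any(use)) return(Inf)
          1 - sum(qc[use] == rc[use]) / sum(use)
        })
        hits[i, b] <- as.integer(ref_families[which.min(d)] == assigned[i])
      }
    }
  })
  100 * rowMeans(hits)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (consistent on additive
#' distances), used as the desk-scale placement substitute for full
#' likelihood or Bayesian tree inference.
#'
#' @param dist_matrix Symmetric matrix with zero diagonal, at least three
#'   taxa, with row/column names.
#' @return Newick string of the unrooted tree.
#' @export
neighbor_joining <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  n <- nrow(dist_matrix)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(dist_matrix, t(dist_matrix))) ||
      any(diag(dist_matrix) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (is.null(rownames(dist_matrix))) {
    rownames(dist_matrix) <- colnames(dist_matrix) <-
      paste0("t", seq_len(n))
  }
  tree <- ape::nj(stats::as.dist(dist_matrix))
  ape::write.tree(tree)
}

#' @export
print.bhlh_assignment <- function(x, ...) {
  cat("bHLH family assignments: ", nrow(x), " quer",
      if (nrow(x) == 1) "y" else "ies", ", ",
      sum(x$family == "orphan"), " orphan(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 20L))
  invisible(x)
}

#' Write an assignments TSV
#'
#' @param assignments A [classify_domains()] result.
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(as.data.frame(assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
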