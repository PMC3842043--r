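#' Upper-tail hypergeometric probability
#'
#' Probability of observing `k` or more annotated genes in a sample of `n`
#' drawn without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Evaluated exactly (log-space summation via [stats::phyper()]).
#'
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @param K Annotated genes in the background (term size).
#' @param n Sample size.
#' @param N Background size.
#' @return The tail probability.
#' @examples
#' hypergeom_tail(2, 10, 5, 50)  # ~ 0.2581
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(K >= 0, K <= N, n >= 0, n <= N, k >= 0, k <= min(n, K))
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values `adj(i) = min over j with rank(j) >= rank(i) of
#' m * p(j) / rank(j)`, capped at 1 and returned in input order.
#'
#' @param pvals Numeric vector of raw P values in `[0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_correct <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Read gene-term annotations
#'
#' Two input shapes are supported: a two-column TSV `gene<TAB>term` with a
#' header and an optional term-metadata TSV (`term`, `category`, `source`),
#' or a GMT file (one term per line: term, description, then the member
#' genes, tab-separated).
#'
#' @param path Annotation file.
#' @param background_size Total number of annotated genes `N` in the
#'   population the sample is drawn from. The published survey never states
#'   the web services' backgrounds, so this is a required modelling input
#'   (conventionally ~20000 for a vertebrate genome).
#' @param metadata_path Optional term-metadata TSV for the two-column shape.
#' @param format `"tsv"` or `"gmt"`.
#' @return Object of class `bhlh_annotations`: list with `terms` (named
#'   list of gene vectors), `meta` (data frame `term`, `category`,
#'   `source`), and `background_size`.
#' @export
read_annotations <- function(path, background_size = 20000,
                             metadata_path = NULL,
                             format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    terms <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(terms) <- vapply(fields, `[[`, "", 1L)
    meta <- data.frame(term = names(terms), category = "BP", source = "GO",
                       stringsAsFactors = FALSE)
  } else {
    tab <- read_checked_tsv(path, c("gene", "term"))
    terms <- split(as.character(tab$gene), tab$term)
    terms <- lapply(terms, unique)
    if (!is.null(metadata_path)) {
      meta <- read_checked_tsv(metadata_path, c("term", "category", "source"))
    } else {
      meta <- data.frame(term = names(terms), category = "BP", source = "GO",
                         stringsAsFactors = FALSE)
    }
  }
  annotations(terms, background_size, meta)
}

#' @rdname read_annotations
#' @param terms Named list of gene-identifier vectors.
#' @param meta Optional term metadata (`term`, `category`, `source`).
#' @param background Optional explicit gene universe. When given, the
#'   background size defaults to its length, term members must belong to
#'   it, and sample genes outside it are excluded (with a warning) by
#'   [enrich()]. Without it the universe is abstract: only its size is
#'   known.
#' @export
annotations <- function(terms, background_size = NULL, meta = NULL,
                        background = NULL) {
  stopifnot(is.list(terms))
  if (is.null(meta)) {
    meta <- data.frame(term = names(terms), category = "BP", source = "GO",
                       stringsAsFactors = FALSE)
  }
  union_ <- unique(unlist(terms, use.names = FALSE))
  if (!is.null(background)) {
    background <- unique(as.character(background))
    if (length(setdiff(union_, background))) {
      stop("term members outside the stated background universe")
    }
    if (is.null(background_size)) background_size <- length(background)
  }
  if (is.null(background_size)) {
    stop("either background_size or an explicit background is required")
  }
  if (background_size < length(union_)) {
    stop("background_size (", background_size, ") smaller than the union ",
         "of annotated genes (", length(union_), ")")
  }
  structure(list(terms = terms, meta = meta,
                 background_size = background_size,
                 background = background),
            class = "bhlh_annotations")
}

#' @export
print.bhlh_annotations <- function(x, ...) {
  cat("bHLH annotation set: ", length(x$terms), " terms over a background ",
      "of ", x$background_size, " genes\n", sep = "")
  invisible(x)
}

#' Hypergeometric term enrichment of a gene list
#'
#' Tests every annotation term with at least one sample hit with the
#' upper-tail hypergeometric probability, then applies Benjamini-Hochberg
#' correction pooled across all tested terms of all sources together
#' (KEGG / PANTHER / Reactome / GO in one pool) -- the pooling under which
#' the published corrected pathway column is reproduced. Results are sorted
#' by raw P with a stable (`p`, `source`, `term`) tie-break.
#'
#' @param sample Character vector of gene identifiers.
#' @param annotations A [annotations()] / [read_annotations()] object.
#' @param p_cutoff Retrieval cutoff on the raw P value (default 0.5, the
#'   published pathway-retrieval default); terms above it are dropped after
#'   correction.
#' @return Data frame of class `bhlh_enrichment` with columns `term`,
#'   `source`, `category`, `k`, `K`, `n`, `raw_p`, `corrected_p`,
#'   `coherence`.
#' @export
enrich <- function(sample, annotations, p_cutoff = 0.5) {
  stopifnot(inherits(annotations, "bhlh_annotations"))
  sample <- unique(as.character(sample))
  if (!is.null(annotations$background)) {
    missing <- setdiff(sample, annotations$background)
    if (length(missing)) {
      warning(length(missing), " sample gene(s) absent from the ",
              "background were excluded: ",
              paste(utils::head(missing, 5L), collapse = ", "),
              if (length(missing) > 5L) ", ...")
      sample <- intersect(sample, annotations$background)
    }
  }
  n <- length(sample)
  if (n == 0) return(empty_enrichment())
  # coherence denominator: the group's annotated members
  n_annotated <- length(intersect(
    sample, unique(unlist(annotations$terms, use.names = FALSE))))
  N <- annotations$background_size
  rows <- lapply(names(annotations$terms), function(term) {
    genes <- annotations$terms[[term]]
    k <- length(intersect(sample, genes))
    if (k == 0) return(NULL)
    m <- annotations$meta[match(term, annotations$meta$term), ]
    data.frame(term = term,
               source = if (nrow(m) && !is.na(m$source)) m$source else "GO",
               category = if (nrow(m) && !is.na(m$category)) m$category else "BP",
               k = k, K = length(genes), n = n,
               raw_p = hypergeom_tail(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_enrichment())
  out <- do.call(rbind, rows)
  out$corrected_p <- bh_correct(out$raw_p)
  out$coherence <- coherence(out$k, max(n_annotated, 1L))
  out <- out[order(out$raw_p, out$source, out$term), , drop = FALSE]
  out <- out[out$raw_p <= p_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bhlh_enrichment", "data.frame")
  out
}

empty_enrichment <- function() {
  out <- data.frame(term = character(0), source = character(0),
                    category = character(0), k = integer(0), K = integer(0),
                    n = integer(0), raw_p = numeric(0),
                    corrected_p = numeric(0), coherence = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("bhlh_enrichment", "data.frame")
  out
}

#' @export
print.bhlh_enrichment <- function(x, ...) {
  cat("Enrichment: ", nrow(x), " term(s) with >= 1 hit, ",
      sum(x$corrected_p <= 0.05), " at FDR <= 0.05\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 15L))
  invisible(x)
}

#' Group coherence of an annotation
#'
#' Percentage of a group's annotated genes covered by the annotation,
#' rounded to one decimal.
#'
#' @param k Genes of the group carrying the annotation.
#' @param annotated_group_size Annotated genes in the group (>= 1).
#' @return Percentage with one decimal.
#' @examples
#' coherence(2, 7)  # 28.6
#' @export
coherence <- function(k, annotated_group_size) {
  stopifnot(all(annotated_group_size >= 1), all(k <= annotated_group_size))
  round(100 * k / annotated_group_size, 1)
}

#' Frequency summary of enriched terms across groups
#'
#' Counts in how many groups each term is significantly enriched, plus
#' per-category totals. Placeholder rows (`term == "None"`) mark groups
#' without significant annotation and contribute no counts.
#'
#' @param results Either a named list of per-group enrichment data frames
#'   (each with `term` and `category` columns) or one data frame with a
#'   `group` column.
#' @return List with `term_counts` (data frame `term`, `category`,
#'   `n_groups`) and `category_totals` (data frame `category`, `n_rows`).
#' @export
frequency_summary <- function(results) {
  if (is.data.frame(results)) {
    stopifnot("group" %in% names(results))
    df <- results
  } else {
    df <- do.call(rbind, lapply(names(results), function(g) {
      r <- results[[g]]
      if (!nrow(r)) return(NULL)
      cbind(group = g, as.data.frame(r), stringsAsFactors = FALSE)
    }))
  }
  term_col <- if ("term" %in% names(df)) "term" else "term_id"
  if (is.null(df) || !nrow(df)) {
    return(list(term_counts = data.frame(term = character(0),
                                         category = character(0),
                                         n_groups = integer(0)),
                category_totals = data.frame(category = character(0),
                                             n_rows = integer(0))))
  }
  df <- df[df[[term_col]] != "None", , drop = FALSE]
  agg <- stats::aggregate(list(n_groups = df$group),
                          by = list(term = df[[term_col]],
                                    category = df$category),
                          FUN = function(g) length(unique(g)))
  agg <- agg[order(-agg$n_groups, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  cat_tot <- stats::aggregate(list(n_rows = df[[term_col]]),
                              by = list(category = df$category), FUN = length)
  list(term_counts = agg, category_totals = cat_tot)
}

#' Write an enrichment TSV
#'
#' @param results An [enrich()] result.
#' @param path Output path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
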