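#' Load a bHLH family registry
#'
#' The registry is a tab-delimited table with header columns `family`,
#' `supergroup`, `dna_box` and `representative_domain`: one row per
#' recognised bHLH family, carrying its higher-order supergroup (A--F), the
#' DNA box bound by members of that supergroup (E-box variants for A/B, the
#' ACGTG/GCGTG core for the PAS-containing group C, N-box variants for
#' group E, empty for the non-binding groups D and F) and a representative
#' domain sequence used as the classification anchor.
#'
#' The packaged registry (`bhlh_registry_path()`) covers the 45 recognised
#' families. Its representative domains are synthetic stand-ins built to
#' satisfy the package's self-consistency contract (each passes the motif
#' scanner with zero mismatches and families are mutually well separated);
#' they are a data asset, not published reference residues.
#'
#' @param path Path to a registry TSV; defaults to the packaged registry.
#' @return Data frame of class `bhlh_registry` with the four columns above.
#' @export
load_family_registry <- function(path = bhlh_registry_path()) {
  req <- c("family", "supergroup", "dna_box", "representative_domain")
  reg <- read_checked_tsv(path, req)
  bad <- which(!reg$supergroup %in% c("A", "B", "C", "D", "E", "F", "orphan"))
  if (length(bad)) {
    stop("registry parse error at data line ", bad[1],
         ": unknown supergroup '", reg$supergroup[bad[1]], "'")
  }
  if (anyDuplicated(reg$family)) {
    stop("registry parse error: duplicated family name '",
         reg$family[duplicated(reg$family)][1], "'")
  }
  allowed_box <- list(A = c("CACCTG", "CAGCTG"), B = c("CACGTG", "CATGTTG"),
                      C = c("ACGTG", "GCGTG"), E = c("CACGCG", "CACGAG"),
                      D = "", F = "")
  for (i in seq_len(nrow(reg))) {
    g <- reg$supergroup[i]
    if (g %in% names(allowed_box) && !reg$dna_box[i] %in% allowed_box[[g]]) {
      stop("registry parse error at data line ", i, ": dna_box '",
           reg$dna_box[i], "' not valid for supergroup ", g)
    }
  }
  class(reg) <- c("bhlh_registry", "data.frame")
  reg
}

#' @rdname load_family_registry
#' @export
bhlh_registry_path <- function() {
  system.file("extdata", "bhlh_family_registry_synthetic.tsv",
              package = "bhlhscan", mustWork = TRUE)
}

#' Write a family registry TSV
#'
#' @param registry A registry data frame.
#' @param path Output path.
#' @export
write_family_registry <- function(registry, path) {
  utils::write.table(as.data.frame(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the bHLH survey catalog
#'
#' The catalog transcribes the published survey table of the 105 *Xenopus
#' tropicalis* bHLH transcription factors: one row per identified protein
#' with its family, gene name, human ortholog, phylogenetic support markers
#' and accessions. Support markers are kept as text: an integer percentage,
#' `n/m` (bootstrap below 50%) or `n/m*` (monophyletic only together with
#' further family members). Accessions are opaque identifiers; the literal
#' `No finding` marks an accession the survey could not resolve.
#'
#' @param path Path to a catalog TSV; defaults to the packaged fixture.
#' @return Data frame of class `bhlh_catalog` with columns `family`,
#'   `gene_name`, `human_ortholog`, `mle_bootstrap`, `bi_posterior`,
#'   `protein_accession`, `contig_accession`.
#' @export
load_catalog_fixture <- function(path = bhlh_catalog_path()) {
  req <- c("family", "gene_name", "human_ortholog", "mle_bootstrap",
           "bi_posterior", "protein_accession", "contig_accession")
  cat_ <- read_checked_tsv(path, req)
  dup <- duplicated(cat_[, c("family", "gene_name")])
  if (any(dup)) {
    stop("catalog validation error: duplicated (family, gene_name) pair ",
         cat_$family[dup][1], "/", cat_$gene_name[dup][1])
  }
  class(cat_) <- c("bhlh_catalog", "data.frame")
  cat_
}

#' @rdname load_catalog_fixture
#' @export
bhlh_catalog_path <- function() {
  system.file("extdata", "xtropicalis_bhlh_catalog.tsv",
              package = "bhlhscan", mustWork = TRUE)
}

#' Write a catalog TSV
#'
#' @param catalog A catalog data frame.
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged enrichment and network fixtures
#'
#' Machine-readable transcriptions of the published survey's summary tables:
#'
#' * `bhlh_go_enrichment_fixture()` -- the per-supergroup GO/KEGG enrichment
#'   table (65 significant annotation rows plus explicit `None` rows for the
#'   supergroups without significant annotation). Column `enriched_genes`
#'   is stored verbatim and is not used by any computation.
#' * `bhlh_pathway_fixture()` -- the 16-row pathway enrichment table
#'   (KEGG/PANTHER/Reactome) with raw and corrected P values.
#' * `bhlh_hub_fixture()` -- the 68 published hub protein names, for
#'   labeling demonstrations only (hub identity depends on the live
#'   interaction database and is not an offline target), plus the printed
#'   list of 9 predicted functional partners.
#' * `bhlh_reannotated_fixture()` -- the printed list of 34 reannotated
#'   protein accessions, kept verbatim (one accession is printed twice;
#'   column `duplicate` flags the repeat).
#'
#' @return A data frame (see details above).
#' @export
bhlh_go_enrichment_fixture <- function() {
  read_checked_tsv(
    system.file("extdata", "xtropicalis_go_enrichment.tsv",
                package = "bhlhscan", mustWork = TRUE),
    c("group", "enriched_genes", "term_id", "category", "definition",
      "coherence", "p_value"))
}

#' @rdname bhlh_go_enrichment_fixture
#' @export
bhlh_pathway_fixture <- function() {
  read_checked_tsv(
    system.file("extdata", "xtropicalis_pathway_enrichment.tsv",
                package = "bhlhscan", mustWork = TRUE),
    c("term", "database", "database_id", "sample_gene_number",
      "background_number", "p_value", "corrected_p_value", "genes"))
}

#' @rdname bhlh_go_enrichment_fixture
#' @export
bhlh_hub_fixture <- function() {
  read_checked_tsv(
    system.file("extdata", "xtropicalis_string_hubs.tsv",
                package = "bhlhscan", mustWork = TRUE),
    c("protein", "role"))
}

#' @rdname bhlh_go_enrichment_fixture
#' @export
bhlh_reannotated_fixture <- function() {
  read_checked_tsv(
    system.file("extdata", "xtropicalis_reannotated_accessions.tsv",
                package = "bhlhscan", mustWork = TRUE),
    c("protein_accession", "duplicate"))
}

# Strict TSV reader: header must contain the required columns; short or
# overlong rows surface as a parse error naming the data line.
read_checked_tsv <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("parse error: ", path, " is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop("parse error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad)) {
    stop("parse error in ", basename(path), " at data line ", bad[1],
         ": expected ", length(header), " fields, found ", nf[bad[1]])
  }
  if (!length(fields)) {
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  }
  names(df) <- header
  for (col in names(df)) {
    v <- df[[col]]
    suppressWarnings(num <- as.numeric(v))
    if (length(v) && !anyNA(num)) df[[col]] <- num
  }
  df
}

#' @export
print.bhlh_registry <- function(x, ...) {
  cat("bHLH family registry: ", nrow(x), " families; supergroups ",
      paste(sort(unique(x$supergroup)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
print.bhlh_catalog <- function(x, ...) {
  cat("bHLH catalog: ", nrow(x), " proteins, ",
      length(setdiff(unique(x$family), "Orphan")), " non-orphan families\n",
      sep = "")
  invisible(x)
}
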