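#' Configuration for a survey pipeline run
#'
#' Collects every input path and threshold of the scan -> classify ->
#' enrich -> network pipeline, with the survey's published defaults: a
#' nine-mismatch acceptance budget, orphan distance threshold 0.55,
#' pathway-retrieval cutoff P <= 0.5 with FDR cutoff 0.05, interaction
#' confidence 0.15 and hub degree 5.
#'
#' @param fasta Protein FASTA to scan (required for the scan stage).
#' @param registry_path Family registry TSV (defaults to the packaged one).
#' @param annotations_path Two-column gene/term TSV (optional; enables the
#'   enrichment stage).
#' @param annotation_metadata_path Optional term metadata TSV.
#' @param sample_genes Optional path to a one-id-per-line gene list tested
#'   for enrichment; defaults to the accepted sequence ids.
#' @param edges_path Interaction edge-list TSV (optional; enables the
#'   network stage).
#' @param node_labels_path Optional node-label TSV (`protein`, `family`).
#' @param out_dir Output directory for all reports.
#' @param max_mismatch,orphan_threshold,bootstrap,seed,background_size,
#'   p_cutoff,fdr_cutoff,min_confidence,string_scale,hub_threshold
#'   Stage parameters; see the stage functions.
#' @return A `bhlh_run_config` list.
#' @export
run_config <- function(fasta = NULL, registry_path = bhlh_registry_path(),
                       annotations_path = NULL,
                       annotation_metadata_path = NULL, sample_genes = NULL,
                       edges_path = NULL, node_labels_path = NULL,
                       out_dir = tempfile("bhlh_run_"), max_mismatch = 9,
                       orphan_threshold = 0.55, bootstrap = 100, seed = 1,
                       background_size = 20000, p_cutoff = 0.5,
                       fdr_cutoff = 0.05, min_confidence = 0.15,
                       string_scale = FALSE, hub_threshold = 5) {
  structure(list(
    fasta = fasta, registry_path = registry_path,
    annotations_path = annotations_path,
    annotation_metadata_path = annotation_metadata_path,
    sample_genes = sample_genes, edges_path = edges_path,
    node_labels_path = node_labels_path, out_dir = out_dir,
    max_mismatch = max_mismatch, orphan_threshold = orphan_threshold,
    bootstrap = bootstrap, seed = seed,
    background_size = background_size, p_cutoff = p_cutoff,
    fdr_cutoff = fdr_cutoff, min_confidence = min_confidence,
    string_scale = string_scale, hub_threshold = hub_threshold
  ), class = "bhlh_run_config")
}

#' Run the survey pipeline
#'
#' Executes the requested stages in order, writing every report into
#' `config$out_dir`. Stages are pure functions of their input files, so
#' re-running a single stage over saved intermediates reproduces the
#' full-run output for that stage. The serialized configuration
#' (`config.txt`) is written first and its MD5 hash is stamped into every
#' report and the run log.
#'
#' Reports: `hits.tsv` (all best placements, accepted and rejected),
#' `catalog.tsv` (one row per accepted domain with family, supergroup,
#' bootstrap support and binding class), `alignment.fasta` +
#' `alignment.txt` (anchored alignment with conservation marks),
#' `group_enrichment.tsv`, `pathway_enrichment.tsv`, `hubs.tsv`,
#' `modules.tsv`, `run.log`.
#'
#' @param config A [run_config()] object.
#' @param stages Subset of `c("scan", "classify", "enrich", "network")`.
#' @return Invisibly, a list with the output directory, the config hash and
#'   the per-stage report paths.
#' @export
run_pipeline <- function(config,
                         stages = c("scan", "classify", "enrich", "network")) {
  stopifnot(inherits(config, "bhlh_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.txt")
  serialize_config(config, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- c(sprintf("config_hash\t%s", hash))
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))

  paths <- list(config = cfg_path, log = log_path)
  catalog_empty <- FALSE
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- switch(stage,
      scan = stage_scan(config, hash),
      classify = stage_classify(config, hash),
      enrich = stage_enrich(config, hash),
      network = stage_network(config, hash),
      stop("unknown stage: ", stage))
    if (!is.null(res)) {
      paths[names(res$paths)] <- res$paths
      for (n in res$notes) logf("%s\t%s", stage, n)
      if (stage == "scan") catalog_empty <- res$n_accepted == 0
    }
    logf("%s\tfinished in %.2fs", stage, proc.time()[["elapsed"]] - t0)
  }
  writeLines(log_lines, log_path)
  invisible(list(out_dir = config$out_dir, config_hash = hash,
                 paths = paths))
}

serialize_config <- function(config, path) {
  vals <- vapply(unclass(config),
                 function(v) if (is.null(v)) "" else as.character(v), "")
  writeLines(sprintf("%s=%s", names(vals), vals), path)
  invisible(path)
}

report_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

stage_scan <- function(config, hash) {
  if (is.null(config$fasta)) stop("scan stage needs config$fasta")
  hits <- scan_proteome(config$fasta, max_mismatch = config$max_mismatch,
                        emit_rejected = TRUE)
  path <- file.path(config$out_dir, "hits.tsv")
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s", hash), con)
  close(con)
  tmp <- tempfile()
  write_hits_tsv(hits, tmp)
  file.append(path, tmp)
  unlink(tmp)
  list(paths = c(hits = path), n_accepted = sum(hits$accepted),
       notes = sprintf("%d accepted hit(s) of %d placement(s)",
                       sum(hits$accepted), nrow(hits)))
}

stage_classify <- function(config, hash) {
  hits_path <- file.path(config$out_dir, "hits.tsv")
  if (!file.exists(hits_path)) stop("classify stage needs hits.tsv (run scan)")
  hits <- read_report(hits_path)
  hits <- hits[hits$accepted, , drop = FALSE]
  if (!nrow(hits)) {
    empty <- data.frame(sequence_id = character(0), family = character(0),
                        assigned_name = character(0),
                        supergroup = character(0), distance = numeric(0),
                        support = numeric(0), mismatches = integer(0),
                        binding_class = character(0), stringsAsFactors = FALSE)
    cat_path <- report_tsv(empty, file.path(config$out_dir, "catalog.tsv"),
                           hash)
    return(list(paths = c(catalog = cat_path),
                notes = "no accepted hits; alignment skipped"))
  }
  seqs <- read_fasta(config$fasta)
  registry <- load_family_registry(config$registry_path)
  doms <- stats::setNames(
    substring(seqs[hits$sequence_id], hits$start1, hits$end1),
    hits$sequence_id)
  asn <- classify_domains(doms, registry,
                          orphan_threshold = config$orphan_threshold,
                          bootstrap = config$bootstrap, seed = config$seed)
  catalog <- data.frame(
    sequence_id = asn$sequence_id, family = asn$family,
    assigned_name = asn$assigned_name, supergroup = asn$supergroup,
    distance = round(asn$distance, 4),
    support = asn$support_percent,
    mismatches = hits$mismatches, binding_class = hits$binding_class,
    stringsAsFactors = FALSE)
  cat_path <- report_tsv(catalog, file.path(config$out_dir, "catalog.tsv"),
                         hash)
  aln <- align_domains(doms)
  fasta_path <- file.path(config$out_dir, "alignment.fasta")
  view_path <- file.path(config$out_dir, "alignment.txt")
  write_alignment(aln, fasta_path, view_path)
  list(paths = c(catalog = cat_path, alignment = fasta_path,
                 alignment_view = view_path),
       notes = sprintf("%d domain(s) classified, %d orphan(s)",
                       nrow(catalog), sum(catalog$family == "orphan")))
}

stage_enrich <- function(config, hash) {
  if (is.null(config$annotations_path)) {
    return(list(paths = character(0), notes = "skipped: no annotations"))
  }
  ann <- read_annotations(config$annotations_path, config$background_size,
                          config$annotation_metadata_path)
  sample <- if (!is.null(config$sample_genes)) {
    readLines(config$sample_genes)
  } else {
    cat_path <- file.path(config$out_dir, "catalog.tsv")
    if (!file.exists(cat_path)) character(0) else
      read_report(cat_path)$sequence_id
  }
  notes <- character(0)
  if (length(sample)) {
    path_res <- suppressWarnings(enrich(sample, ann, config$p_cutoff))
  } else {
    path_res <- empty_enrichment()
    notes <- c(notes, "skipped pathway table: empty gene list")
  }
  pw_path <- report_tsv(as.data.frame(path_res),
                        file.path(config$out_dir, "pathway_enrichment.tsv"),
                        hash)
  group_rows <- NULL
  cat_path <- file.path(config$out_dir, "catalog.tsv")
  if (file.exists(cat_path)) {
    catalog <- read_report(cat_path)
    for (g in sort(unique(catalog$supergroup))) {
      members <- catalog$sequence_id[catalog$supergroup == g]
      res <- suppressWarnings(enrich(members, ann, config$p_cutoff))
      res <- res[res$raw_p <= 0.05, , drop = FALSE]
      if (nrow(res)) {
        group_rows <- rbind(group_rows,
                            cbind(group = g, as.data.frame(res),
                                  stringsAsFactors = FALSE))
      } else {
        group_rows <- rbind(group_rows, data.frame(
          group = g, term = "None", source = "None", category = "None",
          k = NA, K = NA, n = length(members), raw_p = NA, corrected_p = NA,
          coherence = NA, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(group_rows)) {
    group_rows <- cbind(group = character(0),
                        as.data.frame(empty_enrichment()))
    notes <- c(notes, "skipped group table: no catalog")
  }
  grp_path <- report_tsv(group_rows,
                         file.path(config$out_dir, "group_enrichment.tsv"),
                         hash)
  list(paths = c(pathway_enrichment = pw_path, group_enrichment = grp_path),
       notes = c(notes, sprintf("%d pathway row(s) at raw P <= %g",
                                nrow(path_res), config$p_cutoff)))
}

stage_network <- function(config, hash) {
  if (is.null(config$edges_path)) {
    return(list(paths = character(0), notes = "skipped: no edge list"))
  }
  net <- load_network(config$edges_path, config$min_confidence,
                      config$string_scale, config$node_labels_path)
  hubs <- find_hubs(net, config$hub_threshold)
  hub_path <- report_tsv(hubs, file.path(config$out_dir, "hubs.tsv"), hash)
  mods <- family_modules(net)
  mod_path <- report_tsv(mods, file.path(config$out_dir, "modules.tsv"),
                         hash)
  list(paths = c(hubs = hub_path, modules = mod_path),
       notes = sprintf("%d hub(s), %d module(s)", nrow(hubs), nrow(mods)))
}

#' Summarise a survey catalog
#'
#' Totals, per-family and per-supergroup counts and the orphan count of a
#' catalog table -- either a pipeline `catalog.tsv` (which already carries a
#' `supergroup` column) or the packaged published catalog, whose supergroups
#' are looked up from the family registry.
#'
#' @param catalog A catalog data frame with at least a `family` column.
#' @param registry Registry used to map families to supergroups when the
#'   catalog has no `supergroup` column.
#' @return List with `total`, `n_families` (distinct non-orphan),
#'   `n_orphans`, `by_family` and `by_supergroup` (named integer vectors).
#' @export
summarize_counts <- function(catalog, registry = load_family_registry()) {
  catalog <- as.data.frame(catalog)
  if (!nrow(catalog)) {
    return(list(total = 0L, n_families = 0L, n_orphans = 0L,
                by_family = integer(0), by_supergroup = integer(0)))
  }
  fam <- catalog$family
  is_orphan <- tolower(fam) == "orphan"
  if ("supergroup" %in% names(catalog)) {
    sg <- catalog$supergroup
  } else {
    sg <- registry$supergroup[match(fam, registry$family)]
    sg[is_orphan] <- "orphan"
    if (anyNA(sg)) {
      stop("catalog families missing from the registry: ",
           paste(unique(fam[is.na(sg)]), collapse = ", "))
    }
  }
  list(total = nrow(catalog),
       n_families = length(unique(fam[!is_orphan])),
       n_orphans = sum(is_orphan),
       by_family = sort(table(fam), decreasing = TRUE),
       by_supergroup = table(sg))
}
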