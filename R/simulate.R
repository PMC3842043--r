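#' Generate a synthetic proteome with planted bHLH domains
#'
#' Every planted protein carries exactly one consensus-motif instance built
#' token by token: diagnostic sites receive a residue from their allowed
#' class except for a scheduled number of sites, which receive a residue
#' outside it; wildcards, spacers and flanks are uniform random residues.
#' Before emission each protein is certified with the independent
#' brute-force scanner ([oracle_scan()]), never the production scanner, so
#' generator and scanner defects cannot cancel: for schedules within the
#' acceptance budget (<= 9) the globally best placement must sit exactly on
#' the planted domain with exactly the scheduled mismatch count; for
#' schedules of 10+ no placement anywhere may fall inside the budget.
#' Decoys are uniform random sequences re-sampled until their best placement
#' carries at least `decoy_min_mismatch` mismatches.
#'
#' Alternatively (`registry` + `divergence`) planted domains are derived
#' from registry representative domains by mutating the stated fraction of
#' residues, for classifier recovery experiments; the realised mismatch
#' count is then emergent and the donor family is recorded in the truth
#' table.
#'
#' @param mismatch_schedule Integer vector of intended per-domain mismatch
#'   counts (0..19), one planted protein per entry.
#' @param n_decoys Number of decoy proteins.
#' @param seed Integer seed; identical arguments and seed give byte-identical
#'   output files.
#' @param flank_range Min/max length of the random flanks either side of a
#'   planted domain.
#' @param decoy_length_range Min/max decoy length (>= 44 so placements
#'   exist).
#' @param decoy_min_mismatch Certified lower bound on a decoy's best
#'   placement (default 12).
#' @param registry,divergence Optional family-donor mode (see above);
#'   `divergence` is the per-residue mutation fraction.
#' @param out_dir If given, writes `proteome.fasta` and
#'   `proteome_truth.tsv` there.
#' @param max_tries Certification retries per sequence before giving up.
#' @return List with `sequences` (named character vector), `truth` (data
#'   frame: `sequence_id`, `type`, `scheduled_mismatch`, `domain_start`,
#'   `domain_end`, `spacer1`, `loop_len`, `accepted`, `family`), and the
#'   file paths when `out_dir` is used.
#' @export
generate_proteome <- function(mismatch_schedule = c(0, 5, 9, 10),
                              n_decoys = 5, seed = 1,
                              flank_range = c(10, 30),
                              decoy_length_range = c(44, 80),
                              decoy_min_mismatch = 12,
                              registry = NULL, divergence = 0.1,
                              out_dir = NULL, max_tries = 100) {
  stopifnot(all(mismatch_schedule >= 0 & mismatch_schedule <= 19))
  motif <- bhlh_consensus()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- with_preserved_seed(seed, {
    seqs <- character(0)
    truth <- NULL
    for (i in seq_along(mismatch_schedule)) {
      m <- mismatch_schedule[i]
      rec <- NULL
      for (try_ in seq_len(max_tries)) {
        if (is.null(registry)) {
          fam <- NA_character_
          dom <- build_domain(motif, m, aa)
        } else {
          fam <- registry$family[1L + (i - 1L) %% nrow(registry)]
          dom <- mutate_domain(
            registry$representative_domain[match(fam, registry$family)],
            divergence, aa)
        }
        fl <- sample(flank_range[1]:flank_range[2], 2L, replace = TRUE)
        prot <- paste0(paste(sample(aa, fl[1], replace = TRUE), collapse = ""),
                       dom$seq,
                       paste(sample(aa, fl[2], replace = TRUE), collapse = ""))
        best <- oracle_scan(prot)
        planted_start <- fl[1] + 1L
        sched <- if (is.null(registry)) m else dom$mismatches
        ok <- if (sched <= 9) {
          !is.null(best) && best$mismatches == sched &&
            best$start == planted_start &&
            best$end == planted_start + nchar(dom$seq) - 1L
        } else {
          is.null(best) || best$mismatches >= 10L
        }
        if (ok) {
          rec <- list(prot = prot, start = planted_start,
                      end = planted_start + nchar(dom$seq) - 1L,
                      s1 = dom$s1, s2 = dom$s2, sched = sched, fam = fam)
          break
        }
      }
      if (is.null(rec)) {
        stop("could not certify planted domain with schedule ", m,
             " after ", max_tries, " tries")
      }
      id <- sprintf("planted_%02d", i)
      seqs[id] <- rec$prot
      truth <- rbind(truth, data.frame(
        sequence_id = id, type = "planted",
        scheduled_mismatch = rec$sched,
        domain_start = rec$start, domain_end = rec$end,
        spacer1 = rec$s1, loop_len = rec$s2,
        accepted = rec$sched <= 9, family = rec$fam,
        stringsAsFactors = FALSE))
    }
    for (i in seq_len(n_decoys)) {
      dec <- NULL
      for (try_ in seq_len(max_tries)) {
        len <- sample(decoy_length_range[1]:decoy_length_range[2], 1L)
        cand <- paste(sample(aa, len, replace = TRUE), collapse = "")
        best <- oracle_scan(cand)
        if (is.null(best) || best$mismatches >= decoy_min_mismatch) {
          dec <- cand
          break
        }
      }
      if (is.null(dec)) {
        stop("decoy certification failed after ", max_tries, " tries")
      }
      id <- sprintf("decoy_%02d", i)
      seqs[id] <- dec
      truth <- rbind(truth, data.frame(
        sequence_id = id, type = "decoy", scheduled_mismatch = NA_integer_,
        domain_start = NA_integer_, domain_end = NA_integer_,
        spacer1 = NA_integer_, loop_len = NA_integer_,
        accepted = FALSE, family = NA_character_,
        stringsAsFactors = FALSE))
    }
    list(sequences = seqs, truth = truth)
  })
  if (is.null(res$truth)) {
    res$truth <- data.frame(sequence_id = character(0), type = character(0),
                            scheduled_mismatch = integer(0),
                            domain_start = integer(0),
                            domain_end = integer(0), spacer1 = integer(0),
                            loop_len = integer(0), accepted = logical(0),
                            family = character(0), stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "proteome.fasta")
    write_fasta(res$sequences, fasta)
    truth_path <- file.path(out_dir, "proteome_truth.tsv")
    utils::write.table(res$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$fasta_path <- fasta
    res$truth_path <- truth_path
  }
  res
}

# One concrete motif instance with exactly `m` diagnostic-site violations.
build_domain <- function(motif, m, aa) {
  sp <- motif$tokens[motif$tokens$kind == "spacer", ]
  s1 <- sample(sp$min_len[1]:sp$max_len[1], 1L)
  s2 <- sample(sp$min_len[2]:sp$max_len[2], 1L)
  bad_sites <- sample(19L, m)
  d <- 0L
  out <- character(0)
  for (t in seq_len(nrow(motif$tokens))) {
    tok <- motif$tokens[t, ]
    if (tok$kind == "spacer") {
      len <- if (tok$max_len > 10) s2 else s1
      out <- c(out, sample(aa, len, replace = TRUE))
    } else if (tok$kind == "wildcard") {
      out <- c(out, sample(aa, 1L))
    } else {
      d <- d + 1L
      allowed <- strsplit(tok$residues, "")[[1]]
      pool <- if (d %in% bad_sites) setdiff(aa, allowed) else allowed
      out <- c(out, sample(pool, 1L))
    }
  }
  list(seq = paste(out, collapse = ""), s1 = s1, s2 = s2, mismatches = m)
}

# Mutate a donor domain at a fixed per-residue rate; reports the realised
# diagnostic mismatch count of the mutant on the donor's spacer layout.
mutate_domain <- function(donor, divergence, aa) {
  chars <- strsplit(donor, "")[[1]]
  n_mut <- round(divergence * length(chars))
  if (n_mut > 0) {
    pos <- sample(length(chars), n_mut)
    chars[pos] <- vapply(chars[pos],
                         function(r) sample(setdiff(aa, r), 1L), "")
  }
  seq <- paste(chars, collapse = "")
  best <- oracle_scan(seq)
  list(seq = seq, s1 = best$s1, s2 = best$s2, mismatches = best$mismatches)
}

write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}

#' Generate gene-term annotations with planted enrichments
#'
#' Builds a background of `background_size` genes, draws a study sample of
#' `sample_size` genes, and constructs annotation terms of two kinds:
#' planted terms whose overlap with the sample is forced to
#' `round(fold * K * n / N)` (the stated fold enrichment over the null
#' expectation `K n / N`), and null terms filled by uniform draws from the
#' background, whose overlap is hypergeometric by construction.
#'
#' @param planted Data frame with columns `term`, `K` (term size) and
#'   `fold` (>= 1), or NULL for no planted terms.
#' @param n_null Number of null (fold 1) terms.
#' @param null_size_range Min/max size of null terms.
#' @param sample_size Study-sample size `n`.
#' @param background_size Background size `N`.
#' @param seed Integer seed.
#' @param out_dir If given, writes `annotations.tsv`, `sample_genes.txt`
#'   and `annotation_truth.tsv` there.
#' @return List with `annotations` (gene/term data frame), `sample`
#'   (character vector), `truth` (data frame `term`, `fold`, `k`, `K`, `n`,
#'   `N`), `background_size`, plus file paths when `out_dir` is used.
#' @export
generate_annotations <- function(planted = data.frame(term = "planted_1",
                                                      K = 20, fold = 10),
                                 n_null = 20, null_size_range = c(10, 50),
                                 sample_size = 20, background_size = 1000,
                                 seed = 1, out_dir = NULL) {
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(planted$fold >= 1))
    if (any(planted$K > background_size)) {
      stop("planted term size K exceeds the background size N")
    }
  }
  res <- with_preserved_seed(seed, {
    genes <- sprintf("g%05d", seq_len(background_size))
    smp <- sort(sample(genes, sample_size))
    ann <- NULL
    truth <- NULL
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        K <- planted$K[i]
        k <- min(sample_size, K,
                 round(planted$fold[i] * K * sample_size / background_size))
        members <- c(sample(smp, k),
                     sample(setdiff(genes, smp), K - k))
        ann <- rbind(ann, data.frame(gene = members, term = planted$term[i],
                                     stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(
          term = planted$term[i], fold = planted$fold[i], k = k, K = K,
          n = sample_size, N = background_size, stringsAsFactors = FALSE))
      }
    }
    for (i in seq_len(n_null)) {
      K <- sample(null_size_range[1]:null_size_range[2], 1L)
      members <- sample(genes, K)
      term <- sprintf("null_%03d", i)
      ann <- rbind(ann, data.frame(gene = members, term = term,
                                   stringsAsFactors = FALSE))
      truth <- rbind(truth, data.frame(
        term = term, fold = 1, k = length(intersect(members, smp)), K = K,
        n = sample_size, N = background_size, stringsAsFactors = FALSE))
    }
    if (is.null(ann)) {
      ann <- data.frame(gene = character(0), term = character(0),
                        stringsAsFactors = FALSE)
      truth <- data.frame(term = character(0), fold = numeric(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), stringsAsFactors = FALSE)
    }
    list(annotations = ann, sample = smp, truth = truth,
         background_size = background_size)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res$annotations_path <- file.path(out_dir, "annotations.tsv")
    utils::write.table(res$annotations, res$annotations_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$sample_path <- file.path(out_dir, "sample_genes.txt")
    writeLines(res$sample, res$sample_path)
    res$truth_path <- file.path(out_dir, "annotation_truth.tsv")
    utils::write.table(res$truth, res$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

#' Generate an interaction network with planted hubs
#'
#' Wires `n_hubs` hub nodes to at least 5 (up to `hub_degree_max`) distinct
#' non-hub partners with confidences at or above 0.15 while keeping every
#' non-hub node at post-filter degree <= 4, plants `n_modules` labeled
#' three-node family cliques among non-hub nodes, and optionally adds a
#' block of noise edges with confidences strictly below 0.15 that the
#' confidence filter must remove.
#'
#' @param n_nodes Total node count.
#' @param n_hubs Planted hub count (<= n_nodes).
#' @param n_modules Planted three-node family cliques.
#' @param n_noise_edges Sub-threshold noise edges.
#' @param hub_degree_max Maximum hub degree (>= 5).
#' @param seed Integer seed.
#' @param out_dir If given, writes `edges.tsv`, `node_labels.tsv` and
#'   `network_truth.tsv` there.
#' @return List with `edges` (`node_a`, `node_b`, `confidence`), `labels`
#'   (`protein`, `family`), `truth` (`node`, `is_hub`, `expected_degree`,
#'   `family`), plus file paths when `out_dir` is used.
#' @export
generate_network <- function(n_nodes = 40, n_hubs = 6, n_modules = 2,
                             n_noise_edges = 10, hub_degree_max = 8,
                             seed = 1, out_dir = NULL) {
  stopifnot(n_hubs <= n_nodes, hub_degree_max >= 5)
  res <- with_preserved_seed(seed, {
    hubs <- sprintf("hub%02d", seq_len(n_hubs))
    others <- sprintf("node%03d", seq_len(n_nodes - n_hubs))
    avail <- stats::setNames(rep(4L, length(others)), others)
    edges <- NULL
    add_edge <- function(a, b, conf) {
      rbind(edges, data.frame(node_a = a, node_b = b,
                              confidence = round(conf, 3),
                              stringsAsFactors = FALSE))
    }
    labels <- NULL
    # family cliques among non-hub nodes (each clique member spends 2 slots)
    for (mlab in seq_len(n_modules)) {
      pool <- names(avail)[avail >= 2L & !(names(avail) %in% labels$protein)]
      if (length(pool) < 3L) stop("degree constraints unsatisfiable: no room for module")
      members <- sample(pool, 3L)
      for (i in 1:2) for (j in (i + 1):3) {
        edges <- add_edge(members[i], members[j], stats::runif(1, 0.3, 0.95))
      }
      avail[members] <- avail[members] - 2L
      labels <- rbind(labels, data.frame(
        protein = members, family = sprintf("fam%02d", mlab),
        stringsAsFactors = FALSE))
    }
    # hub spokes into non-hub nodes with spare degree
    hub_deg <- stats::setNames(integer(n_hubs), hubs)
    for (h in hubs) {
      d <- sample(5:hub_degree_max, 1L)
      pool <- names(avail)[avail > 0L]
      if (length(pool) < d) stop("degree constraints unsatisfiable: hub fan-out")
      partners <- sample(pool, d)
      for (p in partners) edges <- add_edge(h, p, stats::runif(1, 0.15, 0.99))
      avail[partners] <- avail[partners] - 1L
      hub_deg[h] <- d
    }
    # sub-threshold noise block between random node pairs
    all_nodes <- c(hubs, others)
    for (i in seq_len(n_noise_edges)) {
      pair <- sample(all_nodes, 2L)
      edges <- add_edge(pair[1], pair[2], stats::runif(1, 0.01, 0.149))
    }
    deg <- table(c(edges$node_a[edges$confidence >= 0.15],
                   edges$node_b[edges$confidence >= 0.15]))
    truth <- data.frame(
      node = all_nodes,
      is_hub = all_nodes %in% hubs,
      expected_degree = as.integer(deg[all_nodes]),
      family = labels$family[match(all_nodes, labels$protein)],
      stringsAsFactors = FALSE)
    truth$expected_degree[is.na(truth$expected_degree)] <- 0L
    if (is.null(labels)) {
      labels <- data.frame(protein = character(0), family = character(0),
                           stringsAsFactors = FALSE)
    }
    list(edges = edges, labels = labels, truth = truth)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res$edges_path <- file.path(out_dir, "edges.tsv")
    utils::write.table(res$edges, res$edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$labels_path <- file.path(out_dir, "node_labels.tsv")
    utils::write.table(res$labels, res$labels_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$truth_path <- file.path(out_dir, "network_truth.tsv")
    utils::write.table(res$truth, res$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
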