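test_that("anchor alignment pads spacers to the widest member", {
  doms <- c(a = make_perfect_domain(3, 5), b = make_perfect_domain(6, 22))
  aln <- align_domains(doms)
  expect_equal(aln$width, 64)
  expect_equal(unique(nchar(aln$gapped)), 64)
  expect_length(aln$diagnostic_columns, 19)
  # diagnostic columns are gap-free and carry the anchored residues
  mat <- do.call(rbind, strsplit(aln$gapped, ""))
  expect_true(all(mat[, aln$diagnostic_columns] != "-"))
  # spacers are right-aligned: gaps sit left of the short spacer
  expect_equal(substr(aln$gapped[["a"]], 3, 5), "---")
  # regions tile the frame
  reg <- aln$regions
  expect_equal(reg$basic[1], 1)
  expect_equal(reg$helix1[1], reg$basic[2] + 1)
  expect_equal(reg$loop[1], reg$helix1[2] + 1)
  expect_equal(reg$helix2[1], reg$loop[2] + 1)
  expect_equal(reg$helix2[2], aln$width)
})

test_that("a single domain aligns to itself without gaps", {
  aln <- align_domains(c(only = PERFECT))
  expect_equal(aln$gapped[["only"]], PERFECT)
  expect_equal(aln$width, nchar(PERFECT))
})

test_that("conservation flags columns where >= 80% of residues agree", {
  doms <- c(a = PERFECT, b = PERFECT, c = PERFECT, d = PERFECT,
            e = mutate_at(PERFECT, 3, "W"))  # first spacer position
  cons <- conservation(align_domains(doms), threshold = 0.8)
  expect_equal(cons$level[cons$column == 1], "high")   # K in 5/5
  expect_equal(cons$level[cons$column == 3], "high")   # A in 4/5 = 0.8
  doms2 <- c(a = PERFECT, b = PERFECT, c = PERFECT,
             d = mutate_at(PERFECT, 3, "W"), e = mutate_at(PERFECT, 3, "H"))
  cons2 <- conservation(align_domains(doms2), threshold = 0.8)
  expect_equal(cons2$level[cons2$column == 3], "")     # A in 3/5 = 0.6
})

test_that("pairwise distance is identity-based over gap-free columns", {
  expect_equal(pairwise_distance(PERFECT, PERFECT), 0)
  other <- paste(rev(strsplit(strrep("WH", 22), "")[[1]]), collapse = "")
  expect_equal(pairwise_distance(strrep("W", 44), strrep("H", 44)), 1)
  mut <- mutate_at(PERFECT, c(3, 4, 5, 8, 11, 17, 22, 23, 24, 25, 26), "W")
  expect_equal(pairwise_distance(PERFECT, mut), 11 / 44)
  # gapped columns are skipped entirely
  expect_equal(pairwise_distance("A--B", "A--B"), 0)
  expect_error(pairwise_distance("-A", "A-"), "no comparable")
})

test_that("registry representatives classify to their own family with full support", {
  reg <- load_family_registry()
  pick <- reg[c(1, 10, 25, 40, 45), ]
  asn <- classify_domains(
    stats::setNames(pick$representative_domain, paste0("q_", pick$family)),
    reg, bootstrap = 50, seed = 3)
  expect_equal(asn$family, pick$family)
  expect_equal(asn$supergroup, pick$supergroup)
  expect_equal(asn$distance, rep(0, 5))
  expect_equal(asn$support_percent, rep(100, 5))
})

test_that("planted families are recovered perfectly at <= 15% divergence", {
  reg <- load_family_registry()
  p <- generate_proteome(mismatch_schedule = rep(0, 50), n_decoys = 0,
                         seed = 13, registry = reg, divergence = 0.15)
  expect_gte(length(unique(p$truth$family)), 10)
  doms <- stats::setNames(
    substring(p$sequences, p$truth$domain_start, p$truth$domain_end),
    p$truth$sequence_id)
  asn <- classify_domains(doms, reg)
  expect_equal(asn$family, p$truth$family)
  expect_equal(asn$supergroup,
               reg$supergroup[match(p$truth$family, reg$family)])
  expect_true(all(asn$distance <= 0.55))
})

test_that("a domain far from every representative is an orphan", {
  # perfect diagnostic scaffold, every free position tryptophan: valid
  # domain, but unlike any registry representative
  motif <- bhlh_consensus()
  set.seed(99)
  d <- bhlhscan:::build_domain(motif, 0L,
                               strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  chars <- strsplit(d$seq, "")[[1]]
  offs <- bhlhscan:::diagnostic_offsets(motif, d$s1, d$s2) + 1
  chars[-offs] <- "W"
  asn <- assign_family(paste(chars, collapse = ""))
  expect_equal(asn$family, "orphan")
  expect_equal(asn$supergroup, "orphan")
  expect_gt(asn$distance, 0.55)
})

test_that("multi-ortholog queries get a/b/c suffixes in input order", {
  reg <- load_family_registry()
  myod <- reg$representative_domain[reg$family == "MyoD"]
  asn <- classify_domains(c(x = myod, y = myod,
                            z = reg$representative_domain[reg$family == "Hand"]),
                          reg)
  expect_equal(asn$assigned_name, c("MyoDa", "MyoDb", "Hand"))
})

test_that("bootstrap support is deterministic given a seed and high for close queries", {
  reg <- load_family_registry()
  donor <- reg$representative_domain[reg$family == "Twist"]
  set.seed(7)
  mut <- bhlhscan:::mutate_domain(donor, 0.05,
                                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  a1 <- classify_domains(c(q = mut$seq), reg, bootstrap = 100, seed = 7)
  a2 <- classify_domains(c(q = mut$seq), reg, bootstrap = 100, seed = 7)
  expect_equal(a1$support_percent, a2$support_percent)
  expect_equal(a1$family, "Twist")
  expect_gte(a1$support_percent, 90)
  a3 <- classify_domains(c(q = mut$seq), reg, bootstrap = 100, seed = 8)
  expect_equal(a3$family, a1$family)
  expect_error(classify_domains(c(q = mut$seq), reg, bootstrap = 10),
               "seed")
})

test_that("neighbor joining recovers additive four-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) as path distances
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  nwk <- neighbor_joining(dm)
  tree <- ape::read.tree(text = nwk)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(truth)), 0)
  # permuting the taxa leaves the topology unchanged
  perm <- c(3, 1, 4, 2)
  nwk2 <- neighbor_joining(dm[perm, perm])
  tree2 <- ape::read.tree(text = nwk2)
  expect_equal(phangorn::RF.dist(ape::unroot(tree2), ape::unroot(truth)), 0)
})

test_that("neighbor joining matches a brute-force minimum-evolution search", {
  # additive 5-taxon tree; enumerate all 15 unrooted topologies, fit OLS
  # branch lengths, and take the shortest total length
  truth <- ape::read.tree(text = "((A:2,B:1):1,(C:1,D:3):2,E:4);")
  dm <- ape::cophenetic.phylo(truth)
  taxa <- rownames(dm)
  nj_tree <- ape::unroot(ape::read.tree(text = neighbor_joining(dm)))
  all_topo <- phangorn::allTrees(5, tip.label = taxa)
  lens <- vapply(all_topo, function(tr) {
    fit <- phangorn::nnls.tree(dm, tr, method = "unrooted")
    sum(fit$edge.length)
  }, numeric(1))
  best <- ape::unroot(all_topo[[which.min(lens)]])
  expect_equal(phangorn::RF.dist(nj_tree, best), 0)
})

test_that("degenerate distance matrices are rejected", {
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  bad <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
  # three taxa resolve as the unique star
  dm3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  tree <- ape::read.tree(text = neighbor_joining(dm3))
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))
  expect_equal(tree$Nnode, 1)
})
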