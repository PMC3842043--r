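test_that("a minimal perfect consensus instance is one exact hit", {
  h <- scan_sequence(PERFECT)
  expect_equal(nrow(h), 1)
  expect_equal(h$mismatches, 0)
  expect_true(h$accepted)
  expect_equal(c(h$start, h$end), c(1, 44))
  expect_equal(c(h$spacer1, h$loop_len), c(3, 5))
  expect_equal(h$binding_class, "E-box-binder")
})

test_that("the nine-mismatch budget separates 9 (accepted) from 10 (rejected)", {
  pos <- diag_positions(3, 5)
  h9 <- scan_sequence(mutate_at(PERFECT, pos[c(1, 2, 4, 5, 7, 9, 10, 12, 14)]))
  expect_equal(h9$mismatches[1], 9)
  expect_true(h9$accepted[1])
  h10 <- scan_sequence(
    mutate_at(PERFECT, pos[c(1, 2, 4, 5, 7, 9, 10, 12, 14, 15)]))
  expect_equal(h10$mismatches[1], 10)
  expect_false(h10$accepted[1])
})

test_that("sequences shorter than the minimal 44-residue frame give no hits", {
  expect_equal(nrow(scan_sequence("GGGG")), 0)
  expect_equal(nrow(scan_sequence(substr(PERFECT, 1, 43))), 0)
})

test_that("non-canonical letters are legal input but always mismatch", {
  pos <- diag_positions(3, 5)
  for (bad in c("X", "B", "Z", "U", "*")) {
    h <- scan_sequence(mutate_at(PERFECT, pos[3], bad))  # the invariant E
    expect_equal(h$mismatches[1], 1)
    expect_equal(h$binding_class[1], "non-binder")
  }
})

test_that("the scanner agrees with the brute-force oracle on short sequences", {
  set.seed(42)
  for (rep_ in 1:12) {
    s <- random_protein(sample(44:80, 1))
    hits <- scan_sequence(s)
    best <- oracle_scan(s)
    expect_equal(min(hits$mismatches), best$mismatches)
    top <- hits[which.min(hits$mismatches), ]
    expect_equal(c(top$start, top$end, top$spacer1, top$loop_len),
                 c(best$start, best$end, best$s1, best$s2))
  }
  # and on planted domains with known placements
  p <- generate_proteome(mismatch_schedule = c(0, 4, 8), n_decoys = 0,
                         seed = 7)
  for (i in seq_along(p$sequences)) {
    hits <- scan_sequence(p$sequences[[i]])
    best <- oracle_scan(p$sequences[[i]])
    expect_equal(min(hits$mismatches), best$mismatches)
  }
})

test_that("mutating a matching diagnostic residue never decreases the mismatch count", {
  pos <- diag_positions(3, 5)
  base <- scan_sequence(PERFECT)$mismatches[1]
  prev <- base
  seq <- PERFECT
  for (p in pos) {
    seq_mut <- mutate_at(seq, p)
    mm <- scan_sequence(seq_mut, max_mismatch = 19)$mismatches[1]
    expect_gte(mm, prev)
    prev <- mm
    seq <- seq_mut
  }
  expect_equal(prev, 19)  # all diagnostic sites broken
})

test_that("count_mismatches scores placements site by site", {
  expect_equal(count_mismatches(PERFECT, 1, 3, 5), 0)
  # the alpha site (I/L/V) mutated to M counts exactly one mismatch
  pos <- diag_positions(3, 5)
  expect_equal(count_mismatches(mutate_at(PERFECT, pos[6], "M"), 1, 3, 5), 1)
  expect_equal(count_mismatches(strrep("G", 44), 1, 3, 5), 19)
})

test_that("hits segment into basic/helix1/loop/helix2 tiling the span", {
  h <- scan_sequence(PERFECT)
  reg <- segment_hit(h)
  expect_equal(reg$basic, c(1, 12))
  expect_equal(reg$helix1, c(13, 21))
  expect_equal(reg$loop, c(22, 26))
  expect_equal(reg$helix2, c(27, 44))
  # contiguous tiling of [start, end]
  expect_equal(reg$helix1[1], reg$basic[2] + 1)
  expect_equal(reg$loop[1], reg$helix1[2] + 1)
  expect_equal(reg$helix2[1], reg$loop[2] + 1)
  expect_equal(reg$helix2[2], h$end)

  # a 22-residue loop spacer gives a 22-column loop interval
  h22 <- scan_sequence(make_perfect_domain(3, 22))
  r22 <- segment_hit(h22)
  expect_equal(r22$loop[2] - r22$loop[1] + 1, 22)
  expect_equal(h22$loop_len, 22)

  # tiling holds for arbitrary generated placements
  p <- generate_proteome(mismatch_schedule = c(0, 3, 7), n_decoys = 0,
                         seed = 5)
  for (id in names(p$sequences)) {
    h <- scan_sequence(p$sequences[[id]])
    h <- h[h$accepted, ][1, ]
    reg <- segment_hit(h)
    widths <- sapply(reg, function(iv) iv[2] - iv[1] + 1)
    expect_equal(sum(widths), h$end - h$start + 1)
    expect_equal(unname(widths["loop"]), h$loop_len)
  }
})

test_that("binding diagnosis keys on the invariant Glu/Arg pair and the basic residues", {
  pos <- diag_positions(3, 5)
  expect_equal(scan_sequence(PERFECT)$binding_class, "E-box-binder")
  # Glu -> Gln: no E-box recognition
  expect_equal(scan_sequence(mutate_at(PERFECT, pos[3], "Q"))$binding_class,
               "non-binder")
  # Arg -> Gly with Glu intact: still no binding
  expect_equal(scan_sequence(mutate_at(PERFECT, pos[5], "G"))$binding_class,
               "non-binder")
  # all three basic K/R sites lost: group-D-like non-binder
  expect_equal(
    scan_sequence(mutate_at(PERFECT, pos[c(1, 2, 4)], "G"))$binding_class,
    "non-binder")
  # losing two of the three basic sites still binds
  expect_equal(
    scan_sequence(mutate_at(PERFECT, pos[c(1, 2)], "G"))$binding_class,
    "E-box-binder")
})

test_that("proteome scanning recovers exactly the planted domains", {
  p <- generate_proteome(mismatch_schedule = c(0, 5, 9), n_decoys = 5,
                         seed = 1)
  fa <- write_tmp_fasta(p$sequences)
  hits <- scan_proteome(fa)
  expect_equal(nrow(hits), 3)
  expect_setequal(hits$sequence_id,
                  p$truth$sequence_id[p$truth$type == "planted"])
  expect_equal(hits$start, p$truth$domain_start[match(hits$sequence_id,
                                                      p$truth$sequence_id)])
  # rejected best placements appear only on request
  all_hits <- scan_proteome(fa, emit_rejected = TRUE)
  expect_gt(nrow(all_hits), nrow(hits))
  expect_true(all(!all_hits$accepted[all_hits$sequence_id %in%
                                       paste0("decoy_0", 1:5)]))
})

test_that("FASTA handling: empty files, duplicate ids, repeated sequences", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_equal(nrow(scan_proteome(empty)), 0)

  dup <- write_tmp_fasta(c(a = PERFECT, a = PERFECT))
  expect_error(scan_proteome(dup), "duplicated FASTA identifier")

  twice <- write_tmp_fasta(c(a = PERFECT, b = PERFECT))
  h <- scan_proteome(twice)
  expect_equal(nrow(h), 2)
  expect_equal(h$start[1], h$start[2])
  expect_equal(h$mismatches[1], h$mismatches[2])
})

test_that("hits tables serialise with 1-based coordinates and region strings", {
  h <- scan_sequence(PERFECT)
  tmp <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, tmp)
  back <- read.delim(tmp)
  expect_equal(back$start1, 1)
  expect_equal(back$end1, 44)
  expect_equal(back$basic, "1-12")
  expect_equal(back$helix2, "27-44")
})
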