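test_that("anchors are found around a planted junction", {
  aa <- "MQKVTQCAASRGYWDDKLIFGSGTKLIVT"
  anch <- locate_anchors(aa)
  expect_equal(unname(anch["pos_104"]), 7L)   # the Cys
  expect_equal(unname(anch["pos_118"]), 20L)  # the F of FGSG
  # CDR3 = residues strictly between
  expect_equal(substr(aa, anch["pos_104"] + 1, anch["pos_118"] - 1),
               "AASRGYWDDKLI")
})

test_that("J-TRP (WGQG motif) is accepted at position 118", {
  aa <- "MQKVTQCAASRGYDDKLWGQGTKLIVT"
  anch <- locate_anchors(aa)
  expect_equal(substr(aa, anch["pos_118"], anch["pos_118"]), "W")
})

test_that("missing motifs and implausible spacing are fatal", {
  expect_error(locate_anchors("MQKVTQCAASRGYDDKLI"), "J-MOTIF")
  expect_error(locate_anchors("MQKVTQAASRGYWDDKLIFGSGTKLIVT"), "Cys")
})

test_that("anchors are recovered at planted offsets on 20 generated clones", {
  withr::local_seed(7)
  hits <- 0L
  for (seed in 1:20) {
    g <- gen_rearrangement(germ_v, germ_j, germ_d, n_d = sample(0:3, 1),
                           seed = seed)
    aa <- translate_nt(g$clone$nt_seq)
    anch <- locate_anchors(aa)
    L <- anch["pos_118"] - anch["pos_104"] - 1L
    if (unname(L) == g$truth$truth$cdr3_length_aa) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("the SC19-like clone yields length 37 and TRDD1/D2/D4/D5", {
  sc <- synthetic_sc19_clone()
  ann <- extract_cdr3(sc$clone, germ_v, germ_j, germ_d)
  expect_equal(ann$length_aa, 37L)
  expect_equal(ann$d_genes_used[[1]], c("TRDD1", "TRDD2", "TRDD4", "TRDD5"))
  # block conservation: blocks concatenate to the junction
  expect_equal(paste(ann$blocks[[1]]$seq, collapse = ""), ann$cdr3_nt)
  # case convention: V/J upper, D bracket-tagged lower, PN lower
  expect_match(ann$block_string, "^GCC")
  expect_match(ann$block_string, "\\[TRDD1:")
})

test_that("a pure V+J junction has no D and no PN blocks", {
  g <- gen_rearrangement(germ_v, germ_j, germ_d, n_d = 0,
                         pn_len_range = 0:0, seed = 3)
  ann <- extract_cdr3(g$clone, germ_v, germ_j, germ_d)
  expect_equal(sort(unique(ann$blocks[[1]]$origin)), c("3'V", "5'J"))
  expect_equal(ann$length_aa, g$truth$truth$cdr3_length_aa)
})

test_that("planted D blocks and PN regions are recovered exactly", {
  withr::local_seed(8)
  for (seed in c(11, 12, 13, 14, 15)) {
    g <- gen_rearrangement(germ_v, germ_j, germ_d, n_d = sample(1:4, 1),
                           seed = seed)
    ann <- extract_cdr3(g$clone, germ_v, germ_j, germ_d)
    truth_blocks <- g$truth$truth$blocks
    expect_equal(ann$blocks[[1]]$origin, truth_blocks$origin)
    expect_equal(ann$blocks[[1]]$seq, truth_blocks$seq)
  }
})

test_that("an exact planted TRDD3 substring is attributed with PN flanks", {
  junction <- paste0("AGCG", "CTGGGGGAT", "TCAA")  # 9 nt of TRDD3 inside
  blocks <- attribute_d_segments(junction, germ_d, min_match = 5,
                                 max_mismatch = 0)
  d_rows <- blocks[startsWith(blocks$origin, "D:"), ]
  expect_equal(d_rows$origin, "D:TRDD3")
  expect_equal(d_rows$seq, "CTGGGGGAT")
  expect_equal(blocks$origin, c("PN", "D:TRDD3", "PN"))
})

test_that("a single substitution inside a D match is located", {
  d1 <- germ_d$nt_seq[germ_d$gene_name == "TRDD1"]  # GAAATACGGGAC
  mutated <- d1
  substr(mutated, 6, 6) <- "T"  # C -> T at position 6
  junction <- paste0("TT", mutated, "CA")
  blocks <- attribute_d_segments(junction, germ_d, min_match = 5,
                                 max_mismatch = 1)
  hit <- blocks[blocks$origin == "D:TRDD1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mismatches[[1]], 8L)  # junction coordinate of the change
})

test_that("attribution equals the exhaustive window-enumeration oracle", {
  withr::local_seed(424)
  for (rep in 1:50) {
    junction <- paste(sample(c("A", "C", "G", "T"), sample(12:60, 1),
                             replace = TRUE), collapse = "")
    d_sub <- germ_d[sample(nrow(germ_d), sample(2:6, 1)), ]
    got <- attribute_d_segments(junction, d_sub, min_match = 5,
                                max_mismatch = 1)
    want <- oracle_attribute(junction, d_sub, min_match = 5,
                             max_mismatch = 1)
    expect_equal(got$origin, want$origin, info = paste("rep", rep))
    expect_equal(got$start, want$start, info = paste("rep", rep))
    expect_equal(got$seq, want$seq, info = paste("rep", rep))
    # conservation: blocks reassemble the junction
    expect_equal(paste(got$seq, collapse = ""), junction)
  }
})

test_that("length statistics summarise per tissue", {
  clones <- dplyr::bind_rows(lapply(1:12, function(i) {
    g <- gen_rearrangement(germ_v, germ_j, germ_d, n_d = (i %% 4),
                           tissue = c("spleen", "blood")[1 + i %% 2],
                           name = paste0("cl", i), seed = 100 + i)
    dplyr::mutate(g$clone, planted = g$truth$truth$cdr3_length_aa)
  }))
  ann <- extract_cdr3(clones, germ_v, germ_j, germ_d)
  expect_equal(ann$length_aa, clones$planted)
  st <- length_stats(ann)
  expect_equal(sum(st$n), 12)
  for (gp in st$tissue) {
    sub <- ann$length_aa[ann$tissue == gp]
    expect_equal(st$min[st$tissue == gp], min(sub))
    expect_equal(st$max[st$tissue == gp], max(sub))
    expect_equal(st$mean[st$tissue == gp], mean(sub))
  }
  single <- length_stats(ann[1, ])
  expect_equal(single$min, single$max)
  expect_equal(single$mean, ann$length_aa[1])
  expect_error(length_stats(ann[0, ]), "no annotated")
})

test_that("length_aa is independent of flanking context", {
  g <- gen_rearrangement(germ_v, germ_j, germ_d, n_d = 2, seed = 77)
  ann0 <- extract_cdr3(g$clone, germ_v, germ_j, germ_d)
  # add an in-frame leader and a constant-region stub
  padded <- g$clone
  padded$nt_seq <- paste0("ATGGCTGCA", padded$nt_seq, "GCAGCGGCT")
  ann1 <- extract_cdr3(padded, germ_v, germ_j, germ_d)
  expect_equal(ann1$length_aa, ann0$length_aa)
  expect_equal(ann1$cdr3_nt, ann0$cdr3_nt)
})
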