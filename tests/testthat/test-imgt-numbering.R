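test_that("the RTS88-like V-gamma numbers as [6.8.15]", {
  n <- assign_v_numbering(hallmark_domains$rts88_v_gamma)
  expect_equal(cdr_lengths(n), c(6L, 8L, 15L))
  expect_equal(attr(n, "domain_kind"), "V-GAMMA")
  expect_equal(n$aa[n$position == "23"], "C")
  expect_equal(n$aa[n$position == "41"], "W")
  expect_equal(n$aa[n$position == "104"], "C")
  expect_true(n$aa[n$position == "118"] %in% c("F", "W"))
  # Table-style hallmark residues at their positions
  expect_equal(n$aa[match(c("37", "38", "40", "44", "111.1", "116"),
                          n$position)],
               c("N", "Y", "H", "F", "Y", "K"))
})

test_that("the SC19-like V-delta numbers as [7.3.37] with the long-CDR3 insertions", {
  n <- assign_v_numbering(hallmark_domains$sc19_v_delta)
  expect_equal(cdr_lengths(n), c(7L, 3L, 37L))
  expect_true(all(c("111.7", "111.9", "111.10", "112.6") %in% n$position))
  expect_equal(n$aa[match(c("111.7", "111.9", "111.10", "112.6", "112"),
                          n$position)],
               c("R", "D", "W", "W", "R"))
  expect_equal(sum(n$region == "CDR3"), 37)
})

test_that("a 13-residue CDR3 occupies 105..117 with no insertions", {
  g <- gen_domain_sequence("V-GAMMA", cdr_lengths = c(12L, 10L, 13L),
                           seed = 4)
  n <- assign_v_numbering(g$sequence)
  cdr3 <- n$position[n$region == "CDR3"]
  expect_equal(cdr3, as.character(105:117))
})

test_that("a 15-residue CDR3 creates exactly {111.1, 112.1}", {
  g <- gen_domain_sequence("V-DELTA", cdr_lengths = c(8L, 6L, 15L), seed = 6)
  n <- assign_v_numbering(g$sequence)
  expect_equal(setdiff(n$position[n$region == "CDR3"],
                       as.character(105:117)),
               c("111.1", "112.1"))
})

test_that("numbering is invariant to flanking context given hints", {
  g <- gen_domain_sequence("V-GAMMA", cdr_lengths = c(6L, 8L, 15L), seed = 9)
  n0 <- assign_v_numbering(g$sequence)
  anch <- g$truth$truth$anchors
  flank <- paste0("MKTAYIAKQR", g$sequence, "GSHHHH")
  hints <- c(c23 = unname(anch["c23"]) + 10L, w41 = unname(anch["w41"]) + 10L,
             c104 = unname(anch["c104"]) + 10L,
             fw118 = unname(anch["fw118"]) + 10L)
  n1 <- assign_v_numbering(flank, hints = hints)
  expect_equal(n1$position, n0$position)
  expect_equal(n1$aa, n0$aa)
  expect_equal(n1$seq_index, n0$seq_index + 10L)
})

test_that("generated domains round-trip their planted CDR lengths", {
  for (seed in 1:12) {
    L <- c(sample(3:12, 1), sample(2:10, 1), NA)
    L[3] <- sample(5:min(38L, 140L - 93L - L[1] - L[2]), 1)
    kind <- sample(c("V-GAMMA", "V-DELTA"), 1)
    g <- gen_domain_sequence(kind, cdr_lengths = L, n_mutations = 3,
                             seed = seed)
    n <- assign_v_numbering(g$sequence)
    expect_equal(cdr_lengths(n), as.integer(L),
                 info = sprintf("seed %d kind %s", seed, kind))
    # position map matches the generator's answer key
    key <- g$truth$truth$positions
    expect_equal(n$position, key$position)
    expect_equal(n$aa, key$aa)
  }
})

test_that("anchor failure is reported when no V-domain pattern exists", {
  expect_error(assign_v_numbering(paste(rep("CA", 50), collapse = "")),
               "anchor")
})

test_that("a G-domain reference numbers itself with no insertions", {
  ref <- as.character(ref_g_scaffold("G-ALPHA1-LIKE"))
  n <- assign_g_numbering(ref, "G-ALPHA1-LIKE")
  expect_equal(n$position, as.character(1:92))
  expect_true(all(is.na(n$ins_letter)))
  expect_equal(n$region[n$base <= 49], rep("strand", 49))
  expect_equal(n$region[n$base >= 50], rep("helix", 43))
})

test_that("a residue duplicated after position 72 lands at 72A", {
  ref <- as.character(ref_g_scaffold("G-ALPHA2-LIKE"))
  dup <- paste0(substr(ref, 1, 72), substr(ref, 72, 72), substr(ref, 73, 92))
  n <- assign_g_numbering(dup, "G-ALPHA2-LIKE")
  expect_true("72A" %in% n$position)
  expect_equal(n$aa[n$position == "72A"], substr(ref, 72, 72))
})

test_that("the CD1D-like G-ALPHA2 fixture carries Ser at 72A", {
  n <- assign_g_numbering(hallmark_domains$cd1d_g_alpha2, "G-ALPHA2-LIKE")
  expect_equal(n$aa[n$position == "72A"], "S")
  expect_equal(n$region[n$position == "72A"], "helix")
  n1 <- assign_g_numbering(hallmark_domains$cd1d_g_alpha1, "G-ALPHA1-LIKE")
  expect_equal(n1$aa[match(c("43", "55", "61", "62", "65"), n1$position)],
               c("D", "F", "E", "N", "H"))
  expect_equal(n1$region[n1$position == "43"], "strand")
  expect_equal(n1$region[n1$position == "65"], "helix")
})

test_that("non-G-domain input is rejected on coverage", {
  expect_error(assign_g_numbering("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                                  "G-ALPHA1-LIKE"), "not a G-domain")
})

test_that("IMGT-to-author mapping is bijective and invertible", {
  g <- gen_domain_sequence("V-DELTA", cdr_lengths = c(7L, 3L, 37L), seed = 2)
  n <- assign_v_numbering(g$sequence)
  # chain hosting the domain with authored numbering starting at 12
  res_aa <- strsplit(g$sequence, "")[[1]]
  atoms <- dplyr::bind_rows(lapply(seq_along(res_aa), function(i)
    tibble::tibble(chain = "D", resno = i + 11L, icode = "",
                   resname = gdtr:::aa_one_to_three(res_aa[i]), atom = "CA",
                   element = "C", x = i * 3.8, y = (i %% 7), z = (i %% 3))))
  s <- as_structure(atoms)
  corr <- map_imgt_to_author(n, s, "D")
  expect_equal(nrow(corr), nrow(n))
  expect_equal(anyDuplicated(corr$author_number), 0L)
  expect_equal(anyDuplicated(corr$position), 0L)
  # round trip through the inverse lookup
  expect_equal(author_to_imgt(corr, imgt_to_author(corr, corr$position)),
               corr$position)
  # ordinal identity when author numbering starts at 1 on a pure-domain chain
  atoms1 <- dplyr::mutate(atoms, resno = .data$resno - 11L)
  corr1 <- map_imgt_to_author(n, as_structure(atoms1), "D")
  expect_equal(corr1$author_number, n$seq_index)
})

test_that("missing domain sequence reports the best partial match", {
  g <- gen_domain_sequence("V-GAMMA", cdr_lengths = c(6L, 8L, 13L), seed = 3)
  n <- assign_v_numbering(g$sequence)
  s <- helix_chain(20, chain = "A")
  expect_error(map_imgt_to_author(n, s, "A"), "partial match")
})

test_that("position maps render one labelled row per occupied position", {
  n_g <- assign_v_numbering(hallmark_domains$rts88_v_gamma)
  txt <- render_position_map(n_g)
  expect_length(txt, nrow(n_g))
  expect_equal(sum(grepl("CDR3", txt)), 15)
  n_d <- assign_v_numbering(hallmark_domains$sc19_v_delta)
  expect_equal(sum(grepl("CDR3", render_position_map(n_d))), 37)
  empty <- gdtr:::new_numbering(
    tibble::tibble(position = character(0), base = integer(0),
                   ins_num = integer(0), ins_letter = character(0),
                   aa = character(0), region = character(0),
                   seq_index = integer(0)), "V-GAMMA")
  expect_length(render_position_map(empty), 0)
})
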