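test_that("interface membership respects the 4 A rule at the boundary", {
  near <- gen_interaction_fixture("HYDROPHOBIC", 3.8, seed = 1)$structure
  ir <- interface_residues(near, "A", "B")
  expect_true(1 %in% ir$a$resno[ir$a$chain == "A"])
  expect_true(1 %in% ir$b$resno[ir$b$chain == "B"])
  far <- gen_interaction_fixture("HYDROPHOBIC", 4.2, seed = 1)$structure
  ir2 <- interface_residues(far, "A", "B")
  expect_false(1 %in% ir2$a$resno)
  expect_false(1 %in% ir2$b$resno)
})

test_that("interface residues equal the brute-force all-pairs oracle", {
  withr::local_seed(140)
  # scattered two-chain fixture, ~50 residues
  rows <- lapply(1:50, function(i) {
    gdtr:::place_residue(
      sample(c("ALA", "SER", "ASP", "LEU", "PHE"), 1),
      if (i <= 25) "A" else "B", i,
      c(stats::runif(1, 0, 30), stats::runif(1, 0, 30),
        stats::runif(1, 0, 12)))
  })
  s <- as_structure(dplyr::bind_rows(rows))
  got <- interface_residues(s, "A", "B")
  want <- oracle_interface_residues(s, "A", "B")
  expect_equal(sort(paste(got$a$chain, got$a$resno, got$a$icode)), want$a)
  expect_equal(sort(paste(got$b$chain, got$b$resno, got$b$icode)), want$b)
  expect_error(interface_residues(s, "A", "A"), "disjoint")
})

test_that("an Arg/Asp pair at 5 A is ionic; ring pairs obey the window", {
  fx <- gen_interaction_fixture("IONIC", 5.0, seed = 2)
  cc <- classify_pair(gdtr:::residue_atoms(fx$structure, "A", 1),
                      gdtr:::residue_atoms(fx$structure, "B", 1))
  expect_true("IONIC" %in% cc$kind)
  expect_equal(cc$distance[cc$kind == "IONIC"], 5.0, tolerance = 1e-9)

  arom <- gen_interaction_fixture("AROMATIC_AROMATIC", 6.0, seed = 2)
  cc2 <- classify_pair(gdtr:::residue_atoms(arom$structure, "A", 1),
                       gdtr:::residue_atoms(arom$structure, "B", 1))
  expect_true("AROMATIC_AROMATIC" %in% cc2$kind)
  below <- gen_interaction_fixture("AROMATIC_AROMATIC", 4.0, seed = 2)
  cc3 <- classify_pair(gdtr:::residue_atoms(below$structure, "A", 1),
                       gdtr:::residue_atoms(below$structure, "B", 1))
  expect_false("AROMATIC_AROMATIC" %in% cc3$kind)  # below the 4.5 floor
})

test_that("every interaction class flips exactly at its threshold", {
  thresholds <- c(IONIC = 6.0, HBOND_SS = 3.5, HBOND_MS = 3.5,
                  HBOND_MM = 3.5, AROMATIC_AROMATIC = 7.0,
                  AROMATIC_SULFUR = 5.3, CATION_PI = 6.0, HYDROPHOBIC = 5.0)
  for (kind in names(thresholds)) {
    for (delta in c(-0.2, 0.2)) {
      d <- thresholds[[kind]] + delta
      fx <- gen_interaction_fixture(kind, d, seed = 17)
      ct <- contact_table(fx$structure, "A", "B")
      inside <- delta < 0
      expect_equal(kind %in% ct$kind, inside,
                   info = sprintf("%s at %.1f", kind, d))
      if (inside)
        expect_equal(ct$distance[ct$kind == kind], d, tolerance = 1e-9)
    }
  }
  # the aromatic window is also closed from below
  low <- gen_interaction_fixture("AROMATIC_AROMATIC", 4.3, seed = 17)
  expect_false("AROMATIC_AROMATIC" %in%
                 contact_table(low$structure, "A", "B")$kind)
})

test_that("classification is symmetric in its arguments", {
  for (kind in c("IONIC", "HBOND_SS", "AROMATIC_AROMATIC", "CATION_PI")) {
    fx <- gen_interaction_fixture(kind, gdtr:::default_plant_distance(kind),
                                  seed = 23)
    ra <- gdtr:::residue_atoms(fx$structure, "A", 1)
    rb <- gdtr:::residue_atoms(fx$structure, "B", 1)
    ab <- classify_pair(ra, rb)
    ba <- classify_pair(rb, ra)
    expect_equal(sort(ab$kind), sort(ba$kind))
    expect_equal(sort(ab$distance), sort(ba$distance))
  }
})

test_that("missing side-chain atoms skip a type with a warning only", {
  fx <- gen_interaction_fixture("AROMATIC_AROMATIC", 5.5, seed = 3)
  ra <- gdtr:::residue_atoms(fx$structure, "A", 1)
  rb <- gdtr:::residue_atoms(fx$structure, "B", 1)
  ra_broken <- ra[ra$atom != "CZ", ]  # incomplete Phe ring
  expect_warning(cc <- classify_pair(ra_broken, rb), "ring")
  expect_false("AROMATIC_AROMATIC" %in% cc$kind)
})

test_that("planted complex contacts are returned exactly", {
  fx <- gen_complex_fixture(c(IONIC = 1, HBOND_SS = 1, CATION_PI = 1),
                            seed = 7)
  ct <- contact_table(fx$structure, "G", "D")
  expect_s3_class(ct, "gdtr_contacts")
  expect_equal(nrow(ct), 3)
  truth <- fx$truth$truth$contacts
  got <- dplyr::arrange(tibble::as_tibble(ct), .data$kind)
  want <- dplyr::arrange(truth, .data$kind)
  expect_equal(got$kind, want$kind)
  expect_equal(got$resno_a, want$resno_a)
  expect_equal(got$distance, want$distance, tolerance = 1e-9)
})

test_that("distant group pairs give an empty table and zero summary", {
  fx <- gen_complex_fixture(c(IONIC = 0), seed = 8)
  ct <- contact_table(fx$structure, "G", "D")
  expect_equal(nrow(ct), 0)
  s <- summarize_table(ct)
  expect_equal(s$n_contacts, 0)
  expect_equal(nrow(s$by_type), 0)
})

test_that("contact tables equal a per-pair brute-force reconstruction", {
  withr::local_seed(77)
  fx <- gen_complex_fixture(
    c(IONIC = 2, HBOND_SS = 1, AROMATIC_AROMATIC = 1, HYDROPHOBIC = 1),
    seed = 31)
  s <- fx$structure
  ct <- contact_table(s, "G", "D")
  # oracle: classify every residue pair between the groups directly
  res <- structure_residues(s)
  ra <- res[res$chain == "G", ]; rb <- res[res$chain == "D", ]
  rows <- list()
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
    cc <- suppressWarnings(classify_pair(
      gdtr:::residue_atoms(s, ra$chain[i], ra$resno[i], ra$icode[i]),
      gdtr:::residue_atoms(s, rb$chain[j], rb$resno[j], rb$icode[j])))
    if (nrow(cc) > 0) rows[[length(rows) + 1]] <- cc
  }
  want <- dplyr::bind_rows(rows)
  key <- function(d) sort(paste(d$resno_a, d$resno_b, d$kind,
                                round(d$distance, 6)))
  expect_equal(key(tibble::as_tibble(ct)), key(want))
})

test_that("contact tables annotate IMGT positions through correspondences", {
  g <- gen_domain_sequence("V-GAMMA", cdr_lengths = c(6L, 8L, 13L), seed = 41)
  n <- assign_v_numbering(g$sequence)
  # a chain whose residues are the numbered domain (CA only), plus a second
  # chain close to residue at IMGT 105
  res_aa <- strsplit(g$sequence, "")[[1]]
  atoms <- dplyr::bind_rows(lapply(seq_along(res_aa), function(i)
    tibble::tibble(chain = "G", resno = i, icode = "",
                   resname = gdtr:::aa_one_to_three(res_aa[i]), atom = "CA",
                   element = "C", x = i * 6, y = 0, z = 0)))
  i105 <- n$seq_index[n$position == "105"]
  partner <- gdtr:::place_residue("ASP", "D", 1, c(i105 * 6, 3.0, 0))
  s <- as_structure(dplyr::bind_rows(atoms, partner))
  corr <- map_imgt_to_author(n, s, "G")
  ct <- contact_table(s, "G", "D", numberings = list(corr))
  hit <- ct[ct$chain_a == "G" & ct$resno_a == i105, ]
  expect_true(nrow(hit) >= 0)
  if (nrow(hit) > 0) {
    expect_equal(unique(hit$imgt_a), "105")
    expect_equal(unique(hit$region_a), "CDR3")
  }
})

test_that("the published V-gamma/V-delta interface table summarises exactly", {
  t1a <- read_contact_table(contact_fixture_path("A"))
  s <- summarize_table(t1a)
  expect_equal(s$n_contacts, 18)
  counts <- setNames(s$by_type$n, s$by_type$kind)
  expect_equal(counts[["IONIC"]], 2)
  expect_equal(counts[["HBOND_SS"]], 8)
  expect_equal(counts[["AROMATIC_AROMATIC"]], 2)
  expect_equal(counts[["CATION_PI"]], 6)
  per_group <- setNames(s$residues_per_group$n_residues,
                        s$residues_per_group$group)
  expect_equal(per_group[["V-GAMMA"]], 12)
  expect_equal(per_group[["V-DELTA"]], 10)
})

test_that("the published receptor/CD1D interface table summarises exactly", {
  t1b <- read_contact_table(contact_fixture_path("B"))
  s <- summarize_table(t1b)
  expect_equal(s$n_contacts, 14)
  counts <- setNames(s$by_type$n, s$by_type$kind)
  expect_equal(counts[["IONIC"]], 6)
  expect_equal(counts[["HBOND_SS"]], 5)
  expect_equal(counts[["AROMATIC_AROMATIC"]], 2)
  expect_equal(counts[["CATION_PI"]], 1)
  per_group <- setNames(s$residues_per_group$n_residues,
                        s$residues_per_group$group)
  expect_equal(per_group[["V-GAMMA"]], 4)
  expect_equal(per_group[["V-DELTA"]], 8)
  expect_equal(per_group[["CD1D"]], 8)
})

test_that("summaries are invariant to row order and tables round-trip TSV", {
  t1a <- read_contact_table(contact_fixture_path("A"))
  withr::local_seed(3)
  shuffled <- t1a[sample(nrow(t1a)), ]
  s1 <- summarize_table(t1a)
  s2 <- summarize_table(shuffled)
  expect_equal(s1$by_type, s2$by_type)
  expect_equal(s1$residues_per_group, s2$residues_per_group)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_contact_table(t1a, p)
  back <- read_contact_table(p)
  expect_equal(as.data.frame(back), as.data.frame(t1a),
               ignore_attr = TRUE)
})

test_that("emitted tables always satisfy their distance windows", {
  t1a <- read_contact_table(contact_fixture_path("A"))
  bad <- tibble::as_tibble(t1a)
  bad$distance[bad$kind == "IONIC"][1] <- 6.7
  expect_error(gdtr:::new_contacts(bad, groups = c("x", "y")),
               "outside their type windows")
  dup <- tibble::as_tibble(t1a)[c(1, 1, 2), ]
  expect_error(gdtr:::new_contacts(dup, groups = c("x", "y")), "duplicate")
})
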