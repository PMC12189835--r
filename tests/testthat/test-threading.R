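test_that("identical sequences align with full identity and coverage", {
  a <- align_pair("MKTAYIAKQRQISFVK", "MKTAYIAKQRQISFVK")
  expect_equal(a$identity_pct, 100)
  expect_equal(a$coverage_pct, 100)
})

test_that("alignment scores match the affine-gap DP oracle on short pairs", {
  withr::local_seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    q <- paste(sample(aas, sample(3:10, 1), replace = TRUE), collapse = "")
    t <- paste(sample(aas, sample(3:10, 1), replace = TRUE), collapse = "")
    a <- align_pair(q, t)
    expect_equal(a$score, oracle_global_score(q, t),
                 info = paste(q, t))
  }
})

test_that("identity is symmetric under symmetric parameters", {
  withr::local_seed(32)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    q <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    t <- paste(sample(aas, 34, replace = TRUE), collapse = "")
    expect_equal(align_pair(q, t)$identity_pct,
                 align_pair(t, q)$identity_pct)
  }
})

test_that("threading a template onto itself is coordinate-identical", {
  h <- helix_chain(12)
  seq_h <- structure_sequence(h, "A")
  mdl <- thread_model(align_pair(seq_h, seq_h), h, "A", model_chain = "M")
  expect_equal(nrow(mdl), nrow(h))
  expect_equal(mdl$x, h$x)
  expect_equal(mdl$y, h$y)
  expect_equal(mdl$z, h$z)
  expect_equal(attr(mdl, "unmodeled"), integer(0))
  # renumbered 1..n
  expect_equal(unique(mdl$resno), 1:12)
})

test_that("a point mutant keeps the backbone and truncates to CB", {
  h <- helix_chain(12)
  seq_h <- structure_sequence(h, "A")
  mut <- paste0(substr(seq_h, 1, 5), "K", substr(seq_h, 7, nchar(seq_h)))
  mdl <- thread_model(align_pair(mut, seq_h), h, "A")
  r6 <- mdl[mdl$resno == 6, ]
  expect_equal(r6$resname, rep("LYS", 5))
  expect_equal(sort(r6$atom), sort(c("N", "CA", "C", "O", "CB")))
  # all other residues untouched
  other <- mdl[mdl$resno != 6, ]
  ref <- tibble::as_tibble(h)[h$resno != 6, ]
  expect_equal(other$x, ref$x)
})

test_that("query insertions relative to the template are flagged unmodeled", {
  h <- helix_chain(14)
  seq_h <- structure_sequence(h, "A")
  ins <- paste0(substr(seq_h, 1, 7), "GGSGG", substr(seq_h, 8, nchar(seq_h)))
  expect_warning(mdl <- thread_model(align_pair(ins, seq_h), h, "A"),
                 "unmodeled")
  expect_length(attr(mdl, "unmodeled"), 5)
  expect_false(any(attr(mdl, "unmodeled") %in% mdl$resno))
})

test_that("insufficient coverage makes the template unsuitable", {
  h <- helix_chain(12)
  seq_h <- structure_sequence(h, "A")
  long_query <- paste0(seq_h, paste(rep("GSTANDRE", 4), collapse = ""))
  expect_error(thread_model(align_pair(long_query, seq_h), h, "A"),
               "template unsuitable")
})

test_that("self-superposition has zero RMSD and identity rotation", {
  h <- helix_chain(10)
  sup <- superpose(h, h)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-10)
  expect_equal(glance(sup)$det_rotation, 1, tolerance = 1e-9)
})

test_that("a known rigid transform is recovered to 1e-6", {
  h <- helix_chain(10)
  th <- 0.83
  R0 <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- transform_structure(h, list(rotation = R0,
                                       translation = c(4, -7, 2.5)))
  sup <- superpose(moved, h)
  expect_lt(sup$rmsd, 1e-9)
  # inverse rotation recovered (row-vector convention)
  expect_equal(sup$rotation, t(R0), tolerance = 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)
})

test_that("superposition is invariant to rigid pre-transforms of mobile", {
  withr::local_seed(5150)
  h <- helix_chain(10)
  noisy <- tibble::as_tibble(h)
  noisy$x <- noisy$x + stats::rnorm(nrow(noisy), sd = 0.3)
  noisy$y <- noisy$y + stats::rnorm(nrow(noisy), sd = 0.3)
  noisy$z <- noisy$z + stats::rnorm(nrow(noisy), sd = 0.3)
  noisy <- as_structure(noisy)
  base_rmsd <- superpose(noisy, h)$rmsd
  for (th in c(0.4, 1.9)) {
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    pre <- transform_structure(noisy, list(rotation = Rz,
                                           translation = c(11, -3, 8)))
    expect_equal(superpose(pre, h)$rmsd, base_rmsd, tolerance = 1e-6)
  }
})

test_that("noisy-superposition RMSD matches an independent least-squares fit", {
  withr::local_seed(61)
  h <- helix_chain(15)
  noisy <- tibble::as_tibble(h)
  for (cc in c("x", "y", "z"))
    noisy[[cc]] <- noisy[[cc]] + stats::rnorm(nrow(noisy), sd = 0.4)
  noisy <- as_structure(noisy)
  ours <- superpose(noisy, h)
  # bio3d's fit as an independent implementation of the same problem
  ca_m <- as.matrix(tibble::as_tibble(noisy)[noisy$atom == "CA",
                                             c("x", "y", "z")])
  ca_r <- as.matrix(tibble::as_tibble(h)[h$atom == "CA", c("x", "y", "z")])
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(ca_r)),
                        mobile = as.numeric(t(ca_m)))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(fit, ncol = 3, byrow = TRUE) - ca_r)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate (collinear) point sets are rejected", {
  pts <- dplyr::bind_rows(lapply(1:4, function(i)
    tibble::tibble(chain = "A", resno = i, resname = "GLY", atom = "CA",
                   x = i * 3.8, y = 0, z = 0)))
  s <- as_structure(pts)
  expect_error(superpose(s, s), "degenerate")
})

test_that("clash counting finds planted overlaps and nothing else", {
  two <- as_structure(tibble::tibble(
    chain = c("A", "B"), resno = c(1L, 1L), resname = c("GLY", "GLY"),
    atom = c("CA", "CA"), x = c(0, 1), y = 0, z = 0))
  expect_equal(clash_count(two), 1L)
  expect_equal(clash_count(helix_chain(20)), 0L)
  # k planted overlaps -> k
  withr::local_seed(9)
  for (k in c(2, 4)) {
    rows <- lapply(seq_len(k), function(i) {
      base <- c(20 * i, 0, 0)
      tibble::tibble(chain = c("A", "B"), resno = c(i, i),
                     resname = "GLY", atom = "CA",
                     x = base[1] + c(0, 0.8), y = base[2], z = base[3])
    })
    s <- as_structure(dplyr::bind_rows(rows))
    expect_equal(clash_count(s), k)
  }
})
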