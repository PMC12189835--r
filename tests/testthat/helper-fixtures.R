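# shared fixtures, built in code at test time

germ_refs <- germline_segments()
germ_v <- germ_refs[germ_refs$gene_name == "TRDV1", ]
germ_j <- germ_refs[germ_refs$gene_name == "TRDJ4", ]
germ_d <- germ_refs[germ_refs$segment_type == "D", ]

hallmark_domains <- synthetic_hallmark_domains()

# independent brute-force interface oracle: plain loops, thresholds and
# atom sets restated from first principles (kept separate from the
# package's vectorised implementation)
oracle_interface_residues <- function(s, group_a, group_b, cutoff = 4.0) {
  at <- tibble::as_tibble(s)
  at <- at[toupper(at$element) != "H", ]
  A <- at[at$chain %in% group_a, ]
  B <- at[at$chain %in% group_b, ]
  keep_a <- character(0); keep_b <- character(0)
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                (A$z[i] - B$z[j])^2)
    if (d <= cutoff) {
      keep_a <- union(keep_a, paste(A$chain[i], A$resno[i], A$icode[i]))
      keep_b <- union(keep_b, paste(B$chain[j], B$resno[j], B$icode[j]))
    }
  }
  list(a = sort(keep_a), b = sort(keep_b))
}

# Gotoh affine-gap global alignment score oracle (BLOSUM62, open 10, ext 0.5)
oracle_global_score <- function(q, t, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  qa <- strsplit(q, "")[[1]]; ta <- strsplit(t, "")[[1]]
  n <- length(qa); m <- length(ta)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sub <- B[qa[i - 1], ta[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force D-attribution oracle: enumerate every (gene, start, length)
# window with simple loops, then apply the published tie-break order
oracle_attribute <- function(junction, d_refs, min_match = 5,
                             max_mismatch = 1) {
  ja <- strsplit(junction, "")[[1]]; n <- length(ja)
  cand <- list()
  for (g in seq_len(nrow(d_refs))) {
    da <- strsplit(toupper(d_refs$nt_seq[g]), "")[[1]]; nd <- length(da)
    for (s in 1:n) for (e in s:n) {
      len <- e - s + 1
      if (len < min_match || len > nd) next
      for (off in 0:(nd - len)) {
        w <- da[(off + 1):(off + len)]
        mm <- which(w != ja[s:e])
        if (length(mm) > max_mismatch) next
        if (length(mm) > 0 && (mm[1] == 1 || mm[length(mm)] == len)) next
        cand[[length(cand) + 1]] <- list(gene = d_refs$gene_name[g],
                                         start = s, end = e, len = len,
                                         n_mm = length(mm))
      }
    }
  }
  picked <- list()
  while (length(cand) > 0) {
    ord <- order(-sapply(cand, `[[`, "len"), sapply(cand, `[[`, "n_mm"),
                 sapply(cand, `[[`, "start"), sapply(cand, `[[`, "gene"))
    best <- cand[[ord[1]]]
    picked[[length(picked) + 1]] <- best
    cand <- Filter(function(x) x$end < best$start || x$start > best$end,
                   cand)
  }
  if (length(picked) == 0) {
    return(tibble::tibble(origin = "PN", start = 1L, end = n,
                          seq = junction))
  }
  picked <- picked[order(sapply(picked, `[[`, "start"))]
  out <- list(); cursor <- 1L
  for (b in picked) {
    if (b$start > cursor)
      out[[length(out) + 1]] <- tibble::tibble(
        origin = "PN", start = cursor, end = b$start - 1L,
        seq = substr(junction, cursor, b$start - 1))
    out[[length(out) + 1]] <- tibble::tibble(
      origin = paste0("D:", b$gene), start = b$start, end = b$end,
      seq = substr(junction, b$start, b$end))
    cursor <- b$end + 1L
  }
  if (cursor <= n)
    out[[length(out) + 1]] <- tibble::tibble(
      origin = "PN", start = cursor, end = n,
      seq = substr(junction, cursor, n))
  dplyr::bind_rows(out)
}

# a compact folded synthetic chain (non-collinear CA trace) for
# superposition and threading tests
helix_chain <- function(n = 12, chain = "A") {
  rows <- lapply(seq_len(n), function(i) {
    th <- i * 100 * pi / 180
    centre <- c(3.2 * cos(th), 3.2 * sin(th), 3.0 * i)
    tibble::tibble(
      chain = chain, resno = i, icode = "", resname = "ALA",
      atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = centre[1] + c(-1.2, 0, 1.3, 1.9, -0.4),
      y = centre[2] + c(-0.6, 0, 0.4, 1.4, 1.2),
      z = centre[3] + c(0.2, 0, -0.3, -0.4, 0.9),
      occupancy = 1, b = 0)
  })
  as_structure(dplyr::bind_rows(rows), source = "synthetic",
               title = "synthetic helical chain")
}
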