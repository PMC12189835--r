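#' Locate the CDR3-IMGT anchors in a translated clone
#'
#' The CDR3-IMGT runs from codon 105 (the codon after the 2nd-CYS 104 of the
#' V-REGION) to codon 117 (the codon before J-PHE/J-TRP 118, the F/W of the
#' J-MOTIF F/W-G-X-G). The J anchor is the F/W of the first motif match
#' downstream of the chosen cysteine; the 2nd-CYS is the last Cys preceding
#' it at plausible distance (at least 5 and at most 45 residues upstream).
#'
#' @param aa_seq Translated clone amino-acid string.
#' @return Named integer vector `c(pos_104, pos_118)` (1-based indices in
#'   `aa_seq`).
#' @export
locate_anchors <- function(aa_seq) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1)
  aa_seq <- toupper(aa_seq)
  motifs <- gregexpr("[FW]G.G", aa_seq)[[1]]
  if (motifs[1] == -1) abort("J-MOTIF not found (no F/W-G-X-G)")
  cys <- which(strsplit(aa_seq, "")[[1]] == "C")
  if (length(cys) == 0) abort("no Cys upstream of the J-MOTIF")
  for (m in as.integer(motifs)) {
    cand <- cys[m - cys - 1 >= 5 & m - cys - 1 <= 45]
    if (length(cand) > 0) {
      if (length(cand) > 1)
        warn("multiple candidate 2nd-CYS; using the nearest upstream")
      return(c(pos_104 = max(cand), pos_118 = m))
    }
  }
  abort("no Cys at plausible V-FR3 distance upstream of any J-MOTIF")
}

# longest prefix of x matching prefix of ref with <= max_mismatch
# substitutions; returns match length (mismatch positions as attribute)
prefix_match <- function(x, ref, max_mismatch = 0) {
  n <- min(nchar(x), nchar(ref))
  if (n == 0) return(structure(0L, mismatches = integer(0)))
  xa <- strsplit(substr(x, 1, n), "")[[1]]
  ra <- strsplit(substr(ref, 1, n), "")[[1]]
  mm <- cumsum(xa != ra)
  len <- if (any(mm > max_mismatch)) which(mm > max_mismatch)[1] - 1L else n
  # trim trailing mismatches: a match should not end on a substitution
  while (len > 0 && xa[len] != ra[len]) len <- len - 1L
  structure(as.integer(len), mismatches = which(xa[seq_len(len)] != ra[seq_len(len)]))
}

#' Attribute D-segment matches within a junction
#'
#' Finds non-overlapping germline D-segment matches in a junction nucleotide
#' string. A match covers at least `min_match` nt of a germline D with at
#' most `max_mismatch` substitutions (no indels). Among overlapping
#' candidates the longest wins, then fewest mismatches, then leftmost start,
#' then lexicographic gene name; accepted matches are reported left to right
#' and the unassigned stretches labelled `PN` (P- and N-nucleotides are not
#' distinguished).
#'
#' @param junction_nt Junction nucleotide string.
#' @param d_refs Tibble of germline D segments (`gene_name`, `nt_seq`), e.g.
#'   from [germline_segments()].
#' @param min_match Minimum match length in nt (default 5).
#' @param max_mismatch Maximum substitutions per match (default 1).
#' @return Tibble of blocks in left-to-right order: `origin` (`D:<gene>` or
#'   `PN`), `start`, `end` (1-based, inclusive), `seq`, `mismatches`
#'   (list-column of junction positions).
#' @export
attribute_d_segments <- function(junction_nt, d_refs, min_match = 5,
                                 max_mismatch = 1) {
  junction_nt <- toupper(junction_nt)
  n <- nchar(junction_nt)
  if (n == 0) abort("empty junction")
  d_refs <- as_tibble(d_refs)
  if ("segment_type" %in% names(d_refs))
    d_refs <- filter(d_refs, .data$segment_type == "D")
  # greedy selection with interval splitting: after a match is accepted the
  # remaining free stretches are re-scanned, so a candidate truncated by an
  # accepted block can still contribute its best non-overlapping window
  # (this makes the result identical to exhaustive window enumeration)
  free <- list(c(1L, n))
  picked <- list()
  repeat {
    cand <- bind_rows(lapply(free, function(iv) {
      if (iv[2] - iv[1] + 1L < min_match) return(NULL)
      cc <- d_candidates(substr(junction_nt, iv[1], iv[2]), d_refs,
                         min_match, max_mismatch)
      if (nrow(cc) > 0) {
        cc$start <- cc$start + iv[1] - 1L
        cc$end <- cc$end + iv[1] - 1L
        cc$mismatches <- lapply(cc$mismatches, function(m) m + iv[1] - 1L)
      }
      cc
    }))
    if (is.null(cand) || nrow(cand) == 0) break
    cand <- cand[order(-cand$len, cand$n_mm, cand$start, cand$gene), ]
    best <- cand[1, ]
    picked[[length(picked) + 1]] <- best
    hit <- which(vapply(free, function(iv)
      best$start >= iv[1] && best$end <= iv[2], logical(1)))[1]
    iv <- free[[hit]]
    free[[hit]] <- NULL
    if (best$start - 1L >= iv[1])
      free[[length(free) + 1]] <- c(iv[1], best$start - 1L)
    if (iv[2] >= best$end + 1L)
      free[[length(free) + 1]] <- c(best$end + 1L, iv[2])
  }
  blocks <- if (length(picked)) bind_rows(picked) else
    tibble(gene = character(0), start = integer(0), end = integer(0),
           len = integer(0), n_mm = integer(0), mismatches = list())
  blocks <- arrange(blocks, .data$start)
  # weave in PN gaps
  out <- list()
  cursor <- 1L
  add_pn <- function(from, to) {
    if (to >= from)
      tibble(origin = "PN", start = from, end = to,
             seq = substr(junction_nt, from, to), mismatches = list(integer(0)))
  }
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    out[[length(out) + 1]] <- add_pn(cursor, b$start - 1L)
    out[[length(out) + 1]] <- tibble(
      origin = paste0("D:", b$gene), start = b$start, end = b$end,
      seq = substr(junction_nt, b$start, b$end), mismatches = b$mismatches)
    cursor <- b$end + 1L
  }
  out[[length(out) + 1]] <- add_pn(cursor, n)
  bind_rows(out)
}

# enumerate all (gene, start, length) candidate D matches
d_candidates <- function(junction_nt, d_refs, min_match, max_mismatch) {
  n <- nchar(junction_nt)
  ja <- strsplit(junction_nt, "")[[1]]
  rows <- list()
  for (g in seq_len(nrow(d_refs))) {
    dseq <- toupper(d_refs$nt_seq[g])
    da <- strsplit(dseq, "")[[1]]
    nd <- length(da)
    if (nd < min_match) next
    # alignment of a D window to a junction window, no indels: slide the
    # full D across the junction at every offset (D may overhang)
    for (off in seq(-nd + min_match, n - min_match)) {
      j_from <- max(1L, off + 1L)
      j_to <- min(n, off + nd)
      len_w <- j_to - j_from + 1L
      if (len_w < min_match) next
      d_from <- j_from - off
      eq <- ja[j_from:j_to] == da[d_from:(d_from + len_w - 1L)]
      # maximal run-trimmed window: require match at both ends
      lo <- which(eq)[1]
      hi <- utils::tail(which(eq), 1)
      if (is.na(lo) || hi - lo + 1L < min_match) next
      sub_eq <- eq[lo:hi]
      if (sum(!sub_eq) > max_mismatch) {
        # shrink to best sub-window satisfying the mismatch budget
        best <- best_subwindow(sub_eq, min_match, max_mismatch)
        if (is.null(best)) next
        lo2 <- lo + best[1] - 1L
        hi2 <- lo + best[2] - 1L
      } else {
        lo2 <- lo; hi2 <- hi
      }
      s <- j_from + lo2 - 1L
      e <- j_from + hi2 - 1L
      mm <- s - 1L + which(!eq[lo2:hi2])
      rows[[length(rows) + 1]] <- tibble(
        gene = d_refs$gene_name[g], start = s, end = e,
        len = e - s + 1L, n_mm = length(mm), mismatches = list(mm))
    }
  }
  if (length(rows)) distinct(bind_rows(rows),
                             .data$gene, .data$start, .data$end,
                             .keep_all = TRUE)
  else tibble(gene = character(0), start = integer(0), end = integer(0),
              len = integer(0), n_mm = integer(0), mismatches = list())
}

# best sub-window of a logical match vector starting/ending on a match with
# at most max_mm FALSE entries: longest, then fewest mismatches, then
# leftmost; returns c(from, to) or NULL
best_subwindow <- function(eq, min_len, max_mm) {
  n <- length(eq)
  best <- NULL; best_mm <- NA_integer_
  for (i in which(eq)) {
    mm <- 0L
    for (j in i:n) {
      if (!eq[j]) mm <- mm + 1L
      if (mm > max_mm) break
      if (eq[j] && j - i + 1L >= min_len) {
        better <- is.null(best) ||
          j - i > best[2] - best[1] ||
          (j - i == best[2] - best[1] && mm < best_mm)
        if (better) { best <- c(i, j); best_mm <- mm }
      }
    }
  }
  best
}

#' Delimit and decompose the CDR3-IMGT junction of rearranged clones
#'
#' For each clone, translates in frame, locates the 104/118 anchors
#' ([locate_anchors()]), takes the CDR3-IMGT as codons 105-117, and
#' decomposes the junction nucleotides into the 3'V-REGION contribution
#' (prefix match to the germline V beyond its 2nd-CYS codon), D-segment
#' blocks ([attribute_d_segments()]), P/N stretches, and the 5'J-REGION
#' contribution (suffix match to the germline J before its J-PHE/TRP codon).
#'
#' @param clones Tibble of clones with columns `name`, `nt_seq`, and
#'   optionally `tissue`, `reading_frame` (default 0), `locus`.
#' @param v_ref,j_ref Single-row germline segments (`gene_name`, `nt_seq`);
#'   the V must end within the CDR3 (3'V-REGION after its 2nd-CYS codon),
#'   the J must carry the J-MOTIF.
#' @param d_refs Tibble of germline D segments.
#' @param min_match,max_mismatch Passed to [attribute_d_segments()].
#' @return Tibble, one row per clone: `name`, `tissue`, `cdr3_nt`,
#'   `cdr3_aa`, `length_aa`, `d_genes_used` (list-column), `blocks`
#'   (list-column of block tibbles covering `cdr3_nt` exactly), and
#'   `block_string` (repertoire-report case convention: V/J upper case, D lower case
#'   with gene tags, PN lower case).
#' @export
extract_cdr3 <- function(clones, v_ref, j_ref, d_refs,
                         min_match = 5, max_mismatch = 1) {
  clones <- as_tibble(clones)
  stopifnot(all(c("name", "nt_seq") %in% names(clones)))
  if (is.null(clones$tissue)) clones$tissue <- "unknown"
  if (is.null(clones$reading_frame)) clones$reading_frame <- 0L
  v_tail <- v_3prime_region(v_ref)
  j_head <- j_5prime_region(j_ref)
  res <- purrr::pmap(clones, function(name, nt_seq, tissue, reading_frame, ...) {
    nt <- toupper(nt_seq)
    aa <- translate_nt(nt, reading_frame)
    if (grepl("\\*", sub("\\*+$", "", aa)))
      abort(sprintf("clone %s: internal stop codon (unproductive)", name))
    anch <- locate_anchors(aa)
    # codon 105 starts 3 nt after the start of the 2nd-CYS codon
    start_nt <- reading_frame + (anch["pos_104"] - 1L) * 3L + 4L
    end_nt <- reading_frame + (anch["pos_118"] - 1L) * 3L
    cdr3_nt <- substr(nt, start_nt, end_nt)
    if (nchar(cdr3_nt) %% 3L != 0L)
      abort(sprintf("clone %s: frame-breaking junction (unproductive)", name))
    cdr3_aa <- translate_nt(cdr3_nt)
    v_len <- prefix_match(cdr3_nt, v_tail, max_mismatch = 0)
    j_len <- prefix_match(str_rev(cdr3_nt), str_rev(j_head), max_mismatch = 0)
    v_len <- min(v_len, nchar(cdr3_nt))
    j_len <- min(j_len, nchar(cdr3_nt) - v_len)
    mid_from <- v_len + 1L
    mid_to <- nchar(cdr3_nt) - j_len
    blocks <- list()
    if (v_len > 0)
      blocks[[1]] <- tibble(origin = "3'V", start = 1L, end = v_len,
                            seq = substr(cdr3_nt, 1, v_len),
                            mismatches = list(integer(0)))
    if (mid_to >= mid_from) {
      mid <- attribute_d_segments(substr(cdr3_nt, mid_from, mid_to), d_refs,
                                  min_match, max_mismatch)
      mid$start <- mid$start + v_len
      mid$end <- mid$end + v_len
      mid$mismatches <- lapply(mid$mismatches, function(m) m + v_len)
      blocks[[length(blocks) + 1]] <- mid
    }
    if (j_len > 0)
      blocks[[length(blocks) + 1]] <- tibble(
        origin = "5'J", start = mid_to + 1L, end = nchar(cdr3_nt),
        seq = substr(cdr3_nt, mid_to + 1L, nchar(cdr3_nt)),
        mismatches = list(integer(0)))
    blocks <- bind_rows(blocks)
    d_used <- sub("^D:", "", blocks$origin[startsWith(blocks$origin, "D:")])
    block_str <- render_blocks(blocks)
    tibble(name = name, tissue = tissue, cdr3_nt = cdr3_nt,
           cdr3_aa = cdr3_aa, length_aa = nchar(cdr3_aa),
           d_genes_used = list(d_used), blocks = list(blocks),
           block_string = block_str)
  })
  bind_rows(res)
}

str_rev <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

# repertoire-report case convention: germline V/J upper case, D and PN lower case
# (D blocks tagged with their gene)
render_blocks <- function(blocks) {
  paste(purrr::pmap_chr(blocks, function(origin, seq, ...) {
    if (origin %in% c("3'V", "5'J")) toupper(seq)
    else if (startsWith(origin, "D:"))
      paste0("[", sub("^D:", "", origin), ":", tolower(seq), "]")
    else tolower(seq)
  }), collapse = " ")
}

v_3prime_region <- function(v_ref) {
  nt <- toupper(v_ref$nt_seq[1])
  aa <- translate_nt(nt)
  cys <- gregexpr("C", aa)[[1]]
  if (cys[1] == -1) abort("germline V has no in-frame Cys (2nd-CYS expected)")
  last_c <- max(as.integer(cys))
  substr(nt, last_c * 3L + 1L, nchar(nt))
}

j_5prime_region <- function(j_ref) {
  nt <- toupper(j_ref$nt_seq[1])
  best <- NULL
  for (f in 0:2) {
    aa <- translate_nt(nt, f)
    m <- regexpr("[FW]G.G", aa)
    if (m != -1) { best <- c(f, as.integer(m)); break }
  }
  if (is.null(best)) abort("germline J lacks the F/W-G-X-G J-MOTIF")
  substr(nt, best[1] + 1L, best[1] + (best[2] - 1L) * 3L)
}

#' Per-tissue CDR3 length statistics
#'
#' @param annotated Output of [extract_cdr3()] (needs `tissue`,
#'   `length_aa`).
#' @param group_by Grouping column name (default `"tissue"`).
#' @return Tibble with one row per group: `n`, `min`, `max`, `mean`.
#' @export
length_stats <- function(annotated, group_by = "tissue") {
  annotated <- as_tibble(annotated)
  if (nrow(annotated) == 0) abort("no annotated clones")
  annotated |>
    group_by(.data[[group_by]]) |>
    summarise(n = dplyr::n(), min = min(.data$length_aa),
              max = max(.data$length_aa), mean = mean(.data$length_aa),
              .groups = "drop")
}
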