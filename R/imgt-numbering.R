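# global pairwise alignment -> tibble(qpos, tpos) of aligned residue pairs
aln_mapping <- function(query, template, gap_open = 10, gap_ext = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(template),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
  qg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  tg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qi <- cumsum(qg != "-")
  ti <- cumsum(tg != "-")
  both <- qg != "-" & tg != "-"
  list(pairs = tibble(qpos = qi[both], tpos = ti[both],
                      match = qg[both] == tg[both]),
       score = Biostrings::score(pa))
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# search +-win around an expected 1-based index for a residue in `classes`
find_anchor <- function(seq_chars, expected, classes, win = 5) {
  n <- length(seq_chars)
  for (d in order(abs(seq(-win, win)), seq(-win, win))) {
    i <- expected + seq(-win, win)[d]
    if (i >= 1 && i <= n && seq_chars[i] %in% classes) return(i)
  }
  NA_integer_
}

#' Assign the IMGT unique numbering to a V-domain sequence
#'
#' Locates the four conserved anchors (1st-CYS 23, CONSERVED-TRP 41,
#' 2nd-CYS 104, J-PHE/J-TRP 118) by a seed alignment to the shipped scaffold
#' references (search window of +-5 positions around the expected offsets),
#' then delimits the framework and CDR regions at the standard V-domain
#' boundaries (FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
#' CDR3 105-117, FR4 118-128). Short CDRs are gapped centre-out; CDR3 loops
#' longer than 13 receive 111.x/112.x insertion positions
#' (see [imgt_cdr_positions()]). Flanking residues outside positions 1-128
#' are left unnumbered, so the numbering is invariant to flanking context.
#'
#' @param seq Amino-acid string (one-letter), length 85-140, with at least
#'   two cysteines.
#' @param hints Optional named integer vector of anchor indices in `seq`:
#'   `c23`, `w41`, `c104`, `fw118`. When supplied, anchor detection is
#'   skipped.
#' @param kind Force `"V-GAMMA"` or `"V-DELTA"`; `"auto"` picks the
#'   better-scoring scaffold.
#' @return A `gdtr_numbering` tibble: one row per occupied position with
#'   columns `position`, `base`, `ins_num`, `ins_letter`, `aa`, `region`,
#'   `seq_index`; attributes `domain_kind` and `cdr_lengths` (integer
#'   triple, the bracketed `[CDR1.CDR2.CDR3]` notation).
#' @export
assign_v_numbering <- function(seq, hints = NULL,
                               kind = c("auto", "V-GAMMA", "V-DELTA")) {
  kind <- match.arg(kind)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (is.null(hints) && (n < 85 || n > 140))
    abort("V-domain sequence length outside 85-140; supply anchor hints")
  ch <- strsplit(seq, "")[[1]]
  if (sum(ch == "C") < 2) abort("fewer than two Cys: not a V-domain")

  if (!is.null(hints)) {
    need <- c("c23", "w41", "c104", "fw118")
    if (!all(need %in% names(hints)))
      abort("hints must name c23, w41, c104, fw118")
    a <- as.integer(hints[need])
  } else {
    kinds <- if (kind == "auto") names(V_SCAFFOLD) else kind
    seeds <- lapply(kinds, function(k) aln_mapping(seq, ref_v_scaffold(k)))
    best <- which.max(vapply(seeds, `[[`, numeric(1), "score"))
    kind <- kinds[best]
    mp <- seeds[[best]]$pairs
    expect_at <- function(tpos) {
      hit <- mp$qpos[mp$tpos == tpos]
      if (length(hit)) hit[1] else NA_integer_
    }
    a <- c(
      find_anchor(ch, expect_at(23) %|NA|% 23L, "C"),
      find_anchor(ch, expect_at(41) %|NA|% 41L, "W"),
      find_anchor(ch, expect_at(104) %|NA|% 104L, "C"),
      NA_integer_
    )
    # J anchor: first F/W-G-X-G motif downstream of the 2nd-CYS
    if (!is.na(a[3])) {
      m <- gregexpr("[FW]G.G", seq)[[1]]
      m <- m[m > a[3] + 1]
      if (length(m) > 0 && !is.na(m[1])) a[4] <- m[1]
    }
    if (anyNA(a)) abort("anchor detection failed (no Cys/Trp pattern in window); supply hints")
  }
  names(a) <- c("c23", "w41", "c104", "fw118")
  if (ch[a["c23"]] != "C" || ch[a["c104"]] != "C" ||
      ch[a["w41"]] != "W" || !ch[a["fw118"]] %in% c("F", "W"))
    abort("anchor residues do not match C23/W41/C104/F-W118")

  idx <- function(from, to) if (from > to) integer(0) else from:to
  fr1_i <- idx(max(1L, a["c23"] - 22L), min(n, a["c23"] + 3L))
  fr1_p <- as.character(idx(23L - (a["c23"] - fr1_i[1]),
                            23L + (fr1_i[length(fr1_i)] - a["c23"])))
  cdr1_i <- idx(a["c23"] + 4L, a["w41"] - 3L)
  fr2_i <- idx(a["w41"] - 2L, a["w41"] + 14L)
  cdr2_i <- idx(a["w41"] + 15L, a["c104"] - 39L)
  fr3_i <- idx(a["c104"] - 38L, a["c104"])
  cdr3_i <- idx(a["c104"] + 1L, a["fw118"] - 1L)
  fr4_i <- idx(a["fw118"], min(n, a["fw118"] + 10L))
  if (length(fr2_i) != 17L || length(fr3_i) != 39L)
    abort("anchor spacing inconsistent with FR2 (17) / FR3 (39) lengths")
  L <- c(length(cdr1_i), length(cdr2_i), length(cdr3_i))
  if (L[1] > 12L || L[2] > 10L || L[3] < 1L || L[3] > 40L)
    abort(sprintf("implausible CDR lengths [%d.%d.%d]", L[1], L[2], L[3]))

  rows <- list(
    tibble(position = fr1_p, seq_index = fr1_i),
    tibble(position = imgt_cdr_positions(L[1], "CDR1"), seq_index = cdr1_i),
    tibble(position = as.character(39:55), seq_index = fr2_i),
    tibble(position = imgt_cdr_positions(L[2], "CDR2"), seq_index = cdr2_i),
    tibble(position = as.character(66:104), seq_index = fr3_i),
    tibble(position = imgt_cdr_positions(L[3], "CDR3"), seq_index = cdr3_i),
    tibble(position = as.character(idx(118L, 118L + length(fr4_i) - 1L)),
           seq_index = fr4_i)
  )
  out <- bind_rows(rows)
  parts <- imgt_parse_positions(out$position)
  out <- mutate(out,
                base = parts$base, ins_num = parts$ins_num,
                ins_letter = parts$ins_letter,
                aa = ch[.data$seq_index],
                region = v_region_of(parts$base)) |>
    select("position", "base", "ins_num", "ins_letter", "aa", "region",
           "seq_index")
  new_numbering(out, domain_kind = if (kind == "auto") "V-DOMAIN" else kind,
                cdr_lengths = L)
}

new_numbering <- function(tbl, domain_kind, cdr_lengths = NULL) {
  structure(tbl, class = c("gdtr_numbering", class(tbl)),
            domain_kind = domain_kind, cdr_lengths = cdr_lengths)
}

#' @export
print.gdtr_numbering <- function(x, ...) {
  cl <- attr(x, "cdr_lengths")
  cat(sprintf("<gdtr_numbering> %s, %d positions%s\n",
              attr(x, "domain_kind"), nrow(x),
              if (!is.null(cl)) sprintf(" [%d.%d.%d]", cl[1], cl[2], cl[3])
              else ""))
  print(as_tibble(x), ...)
  invisible(x)
}

#' CDR-IMGT lengths of a numbered V-domain
#'
#' @param n A `gdtr_numbering` from [assign_v_numbering()].
#' @return Integer triple `[CDR1.CDR2.CDR3]`.
#' @export
cdr_lengths <- function(n) {
  stopifnot(inherits(n, "gdtr_numbering"))
  attr(n, "cdr_lengths")
}

#' Assign the IMGT G-domain numbering to an MH-like platform domain
#'
#' Aligns the query to a shipped 92-position G-domain reference scaffold
#' (positions 1-49 strand region, 50-92 helix) and transfers positions
#' through aligned columns. Query residues inserted relative to the
#' reference become letter-inserted positions after the preceding numbered
#' position (e.g. `72A`); unaligned flanking residues are flagged with
#' region `"unaligned"`.
#'
#' @param seq Amino-acid string.
#' @param reference `"G-ALPHA1-LIKE"`, `"G-ALPHA2-LIKE"`, or a list with
#'   elements `seq` (reference string) and `positions` (integer vector of
#'   IMGT base positions per reference residue).
#' @return A `gdtr_numbering` tibble (regions `strand`/`helix`/`unaligned`).
#' @export
assign_g_numbering <- function(seq, reference = "G-ALPHA1-LIKE") {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (is.character(reference)) {
    ref_seq <- as.character(ref_g_scaffold(reference))
    ref_pos <- seq_len(nchar(ref_seq))
    kind <- reference
  } else {
    ref_seq <- reference$seq
    ref_pos <- reference$positions %||% seq_len(nchar(ref_seq))
    kind <- "G-DOMAIN"
  }
  mp <- aln_mapping(seq, ref_seq)$pairs
  if (nrow(mp) < 0.5 * nchar(ref_seq))
    abort("not a G-domain: alignment covers < 50% of the reference")
  ch <- strsplit(seq, "")[[1]]
  pos <- rep(NA_character_, length(ch))
  pos[mp$qpos] <- as.character(ref_pos[mp$tpos])
  # insertions: unaligned run between aligned neighbours -> letters after
  # the preceding numbered position
  last_base <- NA_integer_
  letter_i <- 0L
  for (i in seq_along(ch)) {
    if (!is.na(pos[i])) {
      last_base <- as.integer(pos[i])
      letter_i <- 0L
    } else if (!is.na(last_base) && any(!is.na(pos[seq_len(length(ch)) > i]))) {
      letter_i <- letter_i + 1L
      pos[i] <- paste0(last_base, LETTERS[letter_i])
    }
  }
  keep <- !is.na(pos)
  parts <- imgt_parse_positions(pos[keep])
  out <- tibble(position = pos[keep], base = parts$base,
                ins_num = parts$ins_num, ins_letter = parts$ins_letter,
                aa = ch[keep], region = g_region_of(parts$base),
                seq_index = which(keep))
  flank <- tibble(position = NA_character_, base = NA_integer_,
                  ins_num = NA_integer_, ins_letter = NA_character_,
                  aa = ch[!keep], region = "unaligned",
                  seq_index = which(!keep))
  new_numbering(bind_rows(out, flank), domain_kind = kind)
}

#' Map IMGT positions to author (PDB) numbering for a chain
#'
#' Locates the numbered domain sequence within a chain of a structure and
#' returns the bijective correspondence between IMGT positions and author
#' residue numbers (plus insertion codes).
#'
#' @param n A `gdtr_numbering`.
#' @param s A `gdtr_structure`.
#' @param chain Chain id within `s`.
#' @param register Optional integer vector, one entry per `seq_index` of the
#'   numbered domain, giving the corresponding residue ordinal in the chain;
#'   by default the domain sequence is located as an exact substring.
#' @return Tibble with columns `chain`, `position`, `author_number`,
#'   `icode`, `aa`, `region`, class `gdtr_correspondence`.
#' @export
map_imgt_to_author <- function(n, s, chain, register = NULL) {
  stopifnot(inherits(n, "gdtr_numbering"))
  res <- structure_residues(s)
  res <- res[res$chain == chain, ]
  if (nrow(res) == 0) abort(paste0("no chain '", chain, "' in structure"))
  chain_seq <- paste(res$aa, collapse = "")
  dom_seq <- paste(n$aa[order(n$seq_index)], collapse = "")
  if (is.null(register)) {
    hit <- regexpr(dom_seq, chain_seq, fixed = TRUE)
    if (hit == -1) {
      mp <- aln_mapping(dom_seq, chain_seq)$pairs
      frac <- mean(mp$match)
      abort(sprintf(
        "domain sequence not found in chain '%s' (best partial match: %d aligned, %.0f%% identical)",
        chain, nrow(mp), 100 * frac))
    }
    register <- as.integer(hit) - 1L + n$seq_index - min(n$seq_index) + 1L
  }
  if (length(register) != nrow(n))
    abort("register length must equal the number of numbered positions")
  out <- tibble(chain = chain, position = n$position,
                author_number = res$resno[register],
                icode = res$icode[register],
                aa = n$aa, region = n$region)
  if (any(out$aa != res$aa[register]))
    abort("register maps positions onto different residues")
  structure(out, class = c("gdtr_correspondence", class(out)))
}

#' Author-position lookup in a correspondence table
#'
#' @param corr A `gdtr_correspondence`.
#' @param position IMGT position string(s).
#' @param author_number Author residue number(s) for the inverse lookup.
#' @return `imgt_to_author()` author numbers; `author_to_imgt()` IMGT
#'   position strings.
#' @export
imgt_to_author <- function(corr, position) {
  corr$author_number[match(position, corr$position)]
}

#' @rdname imgt_to_author
#' @export
author_to_imgt <- function(corr, author_number) {
  corr$position[match(author_number, corr$author_number)]
}

#' Plain-text position map of a numbered domain
#'
#' A deterministic one-row-per-position text rendering (IMGT position,
#' amino acid, region), ordered by the IMGT position order — a plain-text
#' stand-in for a bead-map representation.
#'
#' @param n A `gdtr_numbering`.
#' @return Character vector of lines, invisibly printable with `cat()`.
#' @export
render_position_map <- function(n) {
  stopifnot(inherits(n, "gdtr_numbering"))
  num <- n[!is.na(n$position), ]
  if (nrow(num) == 0) return(character(0))
  num <- num[order(imgt_position_key(num$position)), ]
  sprintf("%-7s %s  %s", num$position, num$aa, num$region)
}
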