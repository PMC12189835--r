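#' IMGT position strings and their total order
#'
#' IMGT positions are represented as strings: a base integer (`"104"`), a
#' numeric CDR3 insertion (`"111.7"`), or a letter insertion (`"72A"`).
#' The scheme defines a strict total order: numeric insertions at base 111
#' ascend away from 111 (`111 < 111.1 < 111.2 < ...`) while those at base 112
#' descend toward 112 (`... < 112.2 < 112.1 < 112`); letter insertions ascend
#' after their base (`72 < 72A < 72B < 73`).
#'
#' `imgt_position_key()` maps position strings to numeric sort keys realising
#' that order; `imgt_sort_positions()` sorts a character vector of positions.
#'
#' @param pos Character vector of IMGT position strings.
#' @return `imgt_position_key()`: numeric keys; `imgt_sort_positions()`: the
#'   sorted character vector.
#' @export
imgt_position_key <- function(pos) {
  parts <- imgt_parse_positions(pos)
  key <- as.numeric(parts$base)
  num <- !is.na(parts$ins_num)
  key[num] <- ifelse(parts$base[num] == 112L,
                     112 - parts$ins_num[num] * 1e-3,
                     parts$base[num] + parts$ins_num[num] * 1e-3)
  let <- !is.na(parts$ins_letter)
  key[let] <- parts$base[let] +
    match(parts$ins_letter[let], LETTERS) * 1e-3
  key
}

#' @rdname imgt_position_key
#' @export
imgt_sort_positions <- function(pos) pos[order(imgt_position_key(pos))]

# split "111.7" / "72A" / "104" into base / ins_num / ins_letter
imgt_parse_positions <- function(pos) {
  pos <- as.character(pos)
  ok <- grepl("^[0-9]+(\\.[0-9]+)?$|^[0-9]+[A-Z]$", pos)
  if (any(!ok)) abort(paste0("malformed IMGT position: ",
                             paste(pos[!ok], collapse = ", ")))
  base <- as.integer(sub("^([0-9]+).*$", "\\1", pos))
  ins_num <- ifelse(grepl("\\.", pos),
                    as.integer(sub("^[0-9]+\\.", "", pos)), NA_integer_)
  ins_letter <- ifelse(grepl("[A-Z]$", pos),
                       sub("^[0-9]+", "", pos), NA_character_)
  if (any(!is.na(ins_num) & ins_num < 1))
    abort("numeric insertion index must be positive")
  tibble(position = pos, base = base, ins_num = ins_num,
         ins_letter = ins_letter)
}

#' Occupied CDR-IMGT positions for a given loop length
#'
#' CDR3-IMGT spans positions 105-117 (13 slots). Loops shorter than 13 are
#' gapped centre-out (gaps at the top of the loop); loops longer than 13 gain
#' `L - 13` insertion positions between 111 and 112, filled alternately
#' starting on the 111 side (`111.1`, `112.1`, `111.2`, ...), the 111 side
#' taking the larger share for odd counts. CDR1 (27-38) and CDR2 (56-65)
#' use the same centre-out gapping and admit no insertions.
#'
#' @param length_aa Loop length in amino acids.
#' @param region `"CDR1"`, `"CDR2"` or `"CDR3"`.
#' @return Character vector of occupied positions in IMGT order.
#' @export
imgt_cdr_positions <- function(length_aa, region = c("CDR3", "CDR1", "CDR2")) {
  region <- match.arg(region)
  span <- switch(region, CDR1 = c(27L, 38L), CDR2 = c(56L, 65L),
                 CDR3 = c(105L, 117L))
  slots <- span[2] - span[1] + 1L
  L <- as.integer(length_aa)
  if (L < 0) abort("negative CDR length")
  if (L == 0) return(character(0))
  if (region != "CDR3" && L > slots)
    abort(sprintf("%s length %d exceeds %d available positions",
                  region, L, slots))
  if (L <= slots) {
    n_lead <- ceiling(L / 2)
    n_tail <- floor(L / 2)
    lead <- if (n_lead > 0) span[1] + seq_len(n_lead) - 1L else integer(0)
    tail_ <- if (n_tail > 0) span[2] - rev(seq_len(n_tail)) + 1L else integer(0)
    return(as.character(c(lead, tail_)))
  }
  extra <- L - slots
  n111 <- ceiling(extra / 2)
  n112 <- floor(extra / 2)
  c(as.character(105:111),
    paste0("111.", seq_len(n111)),
    if (n112 > 0) paste0("112.", rev(seq_len(n112))),
    as.character(112:117))
}

# FR/CDR region of a V-domain base position
v_region_of <- function(base) {
  dplyr::case_when(
    base >= 1 & base <= 26 ~ "FR1",
    base <= 38 ~ "CDR1",
    base <= 55 ~ "FR2",
    base <= 65 ~ "CDR2",
    base <= 104 ~ "FR3",
    base <= 117 ~ "CDR3",
    base <= 128 ~ "FR4",
    TRUE ~ NA_character_
  )
}

# strand/helix region of a G-domain base position
g_region_of <- function(base) ifelse(base <= 49, "strand", "helix")
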