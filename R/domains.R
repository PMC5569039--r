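# WRKY domain detection: heptapeptide hits and zinc-finger spacing signatures.
#
# The detector is anchor-based: W at motif position 1, K at 3, Y at 4 are
# fixed, up to `max_mismatches` substitutions elsewhere (admits every variant
# the family is known to carry: WRKYGKK, WRKYGEK, WRKYGRD, WRKYATN, WKKYGQK,
# WNKYGQK, WTKYGQK).  A variant heptapeptide only counts as a domain when a
# zinc finger downstream validates it.

HEPTA_CANON <- strsplit("WRKYGQK", "")[[1]]

validate_protein <- function(sequence) {
  if (length(sequence) != 1 || !is.character(sequence)) {
    stop("sequence must be a single character string")
  }
  s <- toupper(sequence)
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% c(AA20, "X"))
  if (length(bad) > 0) {
    stop("invalid residue '", ch[bad[1]], "' at position ", bad[1])
  }
  s
}

#' Find WRKY heptapeptide motifs in a protein sequence
#'
#' Reports every 7-residue window with W at position 1, K at position 3 and
#' Y at position 4 whose Hamming distance to `WRKYGQK` is at most
#' `max_mismatches`.  Overlapping windows are each reported.  `X` never
#' matches any literal.
#'
#' @param sequence protein string (20-letter alphabet, `X` tolerated).
#' @param max_mismatches mismatch tolerance outside the three anchors.
#' @return data.frame with columns start (0-based), motif, mismatches,
#'   canonical; ordered by start.
#' @export
find_heptapeptides <- function(sequence, max_mismatches = 3L) {
  stopifnot(max_mismatches >= 0)
  empty <- data.frame(start = integer(0), motif = character(0),
                      mismatches = integer(0), canonical = logical(0))
  if (nchar(sequence) == 0) return(empty)
  s <- validate_protein(sequence)
  n <- nchar(s)
  if (n < 7) return(empty)
  ch <- strsplit(s, "")[[1]]
  starts1 <- which(ch[1:(n - 6)] == "W")
  starts1 <- starts1[ch[starts1 + 2] == "K" & ch[starts1 + 3] == "Y"]
  if (length(starts1) == 0) return(empty)
  mism <- vapply(starts1, function(i) {
    sum(ch[i:(i + 6)] != HEPTA_CANON)
  }, integer(1))
  keep <- mism <= max_mismatches
  starts1 <- starts1[keep]
  mism <- mism[keep]
  if (length(starts1) == 0) return(empty)
  data.frame(start = starts1 - 1L,
             motif = substring(s, starts1, starts1 + 6),
             mismatches = mism,
             canonical = mism == 0L,
             stringsAsFactors = FALSE)
}

#' Render and parse zinc-finger spacing signatures
#'
#' Signatures are written `C-X<a>-C-X<b>-HX<T>` where `a` and `b` are the
#' Cys-Cys and Cys-His spacer lengths and `T` is the terminal coordinating
#' residue (H, C or Y; hence finger types CCHH, CCHC, CCHY).
#'
#' @param spacer1,spacer2 spacer lengths.
#' @param terminal terminal residue, one of "H", "C", "Y".
#' @return `render_signature`: the signature string; `parse_signature`: a
#'   list with spacer1, spacer2, terminal, finger_type.
#' @export
render_signature <- function(spacer1, spacer2, terminal) {
  stopifnot(terminal %in% c("H", "C", "Y"))
  sprintf("C-X%d-C-X%d-HX%s", as.integer(spacer1), as.integer(spacer2),
          terminal)
}

#' @rdname render_signature
#' @param signature a signature string.
#' @export
parse_signature <- function(signature) {
  m <- regmatches(signature,
                  regexec("^C-X([0-9]+)-C-X([0-9]+)-HX([HCY])$", signature))[[1]]
  if (length(m) != 4) stop("unparseable zinc-finger signature: '", signature, "'")
  list(spacer1 = as.integer(m[2]), spacer2 = as.integer(m[3]), terminal = m[4],
       finger_type = paste0("CCH", m[4]))
}

#' Find the first zinc-finger structure at or after an index
#'
#' Searches for `C X{a} C X{b} H X [HCY]` with `a` in `spacer1_range` and `b`
#' in `spacer2_range`.  The first match by smallest start wins; ties are
#' broken by smallest spacer1 then smallest spacer2 (bias toward compact
#' fingers).
#'
#' @param sequence protein string.
#' @param from_index 0-based index to search from.
#' @param spacer1_range,spacer2_range inclusive `[lo, hi]` bounds.
#' @return one-row data.frame (start 0-based, spacer1, spacer2, terminal,
#'   signature, finger_type) or NULL when no match exists.
#' @export
find_zinc_finger <- function(sequence, from_index = 0L,
                             spacer1_range = c(3L, 7L),
                             spacer2_range = c(5L, 27L)) {
  s <- validate_protein(sequence)
  n <- nchar(s)
  if (from_index < 0) stop("from_index must be >= 0")
  if (from_index >= n) return(NULL)
  ch <- strsplit(s, "")[[1]]
  cys <- which(ch == "C")
  cys <- cys[cys >= from_index + 1]            # 1-based candidates
  for (c1 in cys) {
    for (a in seq(spacer1_range[1], spacer1_range[2])) {
      c2 <- c1 + 1L + a
      if (c2 > n || ch[c2] != "C") next
      for (b in seq(spacer2_range[1], spacer2_range[2])) {
        h <- c2 + 1L + b
        t <- h + 2L
        if (t > n) break
        if (ch[h] == "H" && ch[t] %in% c("H", "C", "Y")) {
          return(data.frame(start = c1 - 1L, spacer1 = a, spacer2 = b,
                            terminal = ch[t],
                            signature = render_signature(a, b, ch[t]),
                            finger_type = paste0("CCH", ch[t]),
                            stringsAsFactors = FALSE))
        }
      }
    }
  }
  NULL
}

#' Assemble WRKY domains from heptapeptide + zinc-finger pairs
#'
#' Pairs each heptapeptide hit with the first zinc finger starting within
#' `linker_max` residues after the heptapeptide.  Hits with no validating
#' finger are dropped (the family definition's own filter: a variant
#' heptapeptide only counts when a finger confirms it).  For proteins with
#' exactly two assembled domains the upstream one is labelled `N` and the
#' downstream `C`; otherwise the label is `only`.
#'
#' @param sequence protein string.
#' @param config a [wrky_config()].
#' @return data.frame with one row per domain: hep_start, motif, mismatches,
#'   canonical, zf_start, spacer1, spacer2, terminal, signature, finger_type,
#'   terminal_position.
#' @export
assemble_domains <- function(sequence, config = wrky_config()) {
  heps <- find_heptapeptides(sequence, config$max_mismatches)
  rows <- list()
  for (i in seq_len(nrow(heps))) {
    hep <- heps[i, ]
    zf <- find_zinc_finger(sequence, from_index = hep$start + 7L,
                           spacer1_range = config$spacer1_range,
                           spacer2_range = config$spacer2_range)
    if (is.null(zf)) next
    if (zf$start - (hep$start + 7L) > config$linker_max) next
    rows[[length(rows) + 1L]] <- data.frame(
      hep_start = hep$start, motif = hep$motif, mismatches = hep$mismatches,
      canonical = hep$canonical, zf_start = zf$start, spacer1 = zf$spacer1,
      spacer2 = zf$spacer2, terminal = zf$terminal, signature = zf$signature,
      finger_type = zf$finger_type, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) {
    data.frame(hep_start = integer(0), motif = character(0),
               mismatches = integer(0), canonical = logical(0),
               zf_start = integer(0), spacer1 = integer(0),
               spacer2 = integer(0), terminal = character(0),
               signature = character(0), finger_type = character(0))
  } else {
    do.call(rbind, rows)
  }
  out$terminal_position <- if (nrow(out) == 2) c("N", "C") else
    rep("only", nrow(out))
  out
}

#' Identify WRKY proteins across a proteome
#'
#' Runs [assemble_domains()] on every sequence and returns one row per
#' protein, mirroring the family-survey gene-table layout.
#'
#' @param proteins named character vector of protein sequences (e.g. from
#'   [read_fasta_protein()]).
#' @param config a [wrky_config()].
#' @param keep_all keep proteins with zero domains (default FALSE).
#' @return data.frame with columns protein_id, length, n_domains, motifs,
#'   signatures (slash-joined).
#' @export
identify_wrky <- function(proteins, config = wrky_config(), keep_all = FALSE) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    dom <- assemble_domains(proteins[[id]], config)
    data.frame(protein_id = id, length = nchar(proteins[[id]]),
               n_domains = nrow(dom),
               motifs = paste(dom$motif, collapse = "/"),
               signatures = paste(dom$signature, collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!keep_all) out <- out[out$n_domains > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-protein domain tables for a proteome
#'
#' @inheritParams identify_wrky
#' @return named list of [assemble_domains()] data.frames.
#' @export
scan_proteome <- function(proteins, config = wrky_config()) {
  stopifnot(!is.null(names(proteins)))
  lapply(setNames(names(proteins), names(proteins)),
         function(id) assemble_domains(proteins[[id]], config))
}
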