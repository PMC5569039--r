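# File formats, configuration and logging shared by all pipeline stages.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Reverse complement of a DNA string (IUPAC codes supported)
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    comp <- IUPAC_COMPLEMENT[ch]
    if (anyNA(comp)) {
      stop("non-IUPAC character in DNA string: '",
           ch[which(is.na(comp))[1]], "'")
    }
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

validate_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- which(!ch %in% names(IUPAC_DNA))
  if (length(bad) > 0) {
    stop("non-IUPAC character '", ch[bad[1]], "' at position ", bad[1],
         " of pattern '", pattern, "'")
  }
  invisible(toupper(pattern))
}

# ---- logging ----------------------------------------------------------------

LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

wrky_log <- function(level, ...) {
  threshold <- getOption("wrkyscan.log_level", "info")
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[threshold]]) {
    message(sprintf("[wrkyscan %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Thin wrappers over Biostrings readers; record descriptions become names
#' (first whitespace-delimited token retained in full for `|`-tagged headers).
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_protein <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta_protein
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA, wrapped at 60 columns
#'
#' @param sequences named character vector.
#' @param path output path (written atomically).
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  lines <- unlist(lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    body <- if (nchar(s) == 0) character(0) else {
      starts <- seq(1, nchar(s), by = 60)
      substring(s, starts, pmin(starts + 59, nchar(s)))
    }
    c(paste0(">", id), body)
  }))
  write_lines_atomic(lines, path)
}

# ---- GFF3 -------------------------------------------------------------------

#' Read a GFF3 annotation file
#'
#' Hand-rolled reader so parse errors can name the offending line.  Only the
#' columns the pipeline needs are retained; `ID` and `Parent` are pulled from
#' column 9.  Coordinates stay 1-based closed as in the file; converters at
#' use sites go to 0-based half-open.  Absent mRNA features are tolerated
#' downstream by treating gene+CDS as one transcript.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns seqid, source, type, start, end, score,
#'   strand, phase, ID, Parent, line.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  keep <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    }
    st <- suppressWarnings(as.integer(f[4]))
    en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en)) {
      stop("malformed GFF3 at line ", i, ": non-numeric coordinates")
    }
    attr_one <- function(key) {
      m <- regmatches(f[9], regexec(paste0("(?:^|;)", key, "=([^;]*)"), f[9]))[[1]]
      if (length(m) == 2) m[2] else NA_character_
    }
    data.frame(seqid = f[1], source = f[2], type = f[3], start = st, end = en,
               score = f[6], strand = f[7], phase = f[8],
               ID = attr_one("ID"), Parent = attr_one("Parent"),
               line = i, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    stop("GFF3 file '", path, "' contains no feature lines")
  }
  do.call(rbind, rows)
}

#' Write a GFF3 annotation file
#'
#' @param features data.frame in the layout produced by [read_gff3()].
#' @param path output path (written atomically).
#' @export
write_gff3 <- function(features, path) {
  attrs <- ifelse(is.na(features$Parent),
                  paste0("ID=", features$ID),
                  paste0("ID=", features$ID, ";Parent=", features$Parent))
  lines <- c("##gff-version 3",
             paste(features$seqid, features$source, features$type,
                   features$start, features$end, features$score,
                   features$strand, features$phase, attrs, sep = "\t"))
  write_lines_atomic(lines, path)
}

# ---- TSV reports ------------------------------------------------------------

#' Write a report table as TSV with a commented header
#'
#' Every report carries a `#`-commented header naming its columns and the
#' package version, and is written atomically (temp file then rename).
#'
#' @param df data.frame to write.
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  con <- textConnection("out", "w", local = TRUE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  lines <- c(sprintf("# wrkyscan %s", as.character(packageVersion("wrkyscan"))),
             paste0("# columns: ", paste(names(df), collapse = "\t")),
             paste(names(df), collapse = "\t"),
             out)
  write_lines_atomic(lines, path)
}

#' Read a TSV report or input table, skipping `#` comments
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# ---- packaged data ----------------------------------------------------------

wrky_extdata <- function(file) {
  p <- system.file("extdata", file, package = "wrkyscan")
  if (p == "") stop("packaged data file not found: ", file)
  p
}

#' Load a substitution matrix from a TSV file
#'
#' @param path path to a tab-separated matrix with row and column names; the
#'   default is the packaged BLOSUM62 table.
#' @return numeric matrix.
#' @export
read_substitution_matrix <- function(path = wrky_extdata("blosum62.tsv")) {
  m <- as.matrix(read.delim(path, comment.char = "#", row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

#' Load a cis-element catalog
#'
#' 3-column TSV (`element_id`, `pattern`, `category`) with `#` comments; the
#' PLACE native format is not parsed -- convert it to this layout first.
#'
#' @param path catalog path; default is the packaged illustrative catalog.
#' @return data.frame with columns element_id, pattern, category.
#' @export
read_cis_catalog <- function(path = wrky_extdata("cis_elements.tsv")) {
  cat <- read_tsv_table(path)
  stopifnot(all(c("element_id", "pattern", "category") %in% names(cat)))
  for (p in cat$pattern) validate_iupac(p)
  cat
}

#' Load a subgroup-labelled reference panel from FASTA
#'
#' Headers must be `>id|subgroup` with subgroup one of I, IIa-IIe, III.  The
#' packaged default panel is a constructed synthetic stand-in (the survey's
#' actual reference selection is not redistributable) and is user-replaceable.
#'
#' @param path panel FASTA; default is the packaged synthetic panel.
#' @return data.frame with columns reference_id, subgroup, sequence.
#' @export
read_reference_panel <- function(path = wrky_extdata("reference_panel_synthetic.fasta")) {
  seqs <- read_fasta_protein(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad) > 0) {
    stop("panel header without '|subgroup' tag: ", names(seqs)[bad[1]])
  }
  panel <- data.frame(reference_id = vapply(parts, `[`, "", 1),
                      subgroup = vapply(parts, `[`, "", 2),
                      sequence = unname(seqs), stringsAsFactors = FALSE)
  ok <- panel$subgroup %in% c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")
  if (!all(ok)) stop("invalid panel subgroup label: ", panel$subgroup[!ok][1])
  if (any(nchar(panel$sequence) == 0)) stop("empty panel sequence")
  panel[order(panel$reference_id), , drop = FALSE]
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable with its default.  Defaults equal the survey
#' protocol's stated values where it states them (1-kb window, >=3 W-box
#' sites, fold-change thresholds 1.5 / 0.66, alpha 0.05, FPKM validity 10,
#' deviation probability 0.8, 1000 bootstrap replicates).
#'
#' @param window promoter window in nt upstream of the translation start.
#' @param min_sites W-box count needed to call a target gene.
#' @param up,down fold-change thresholds for up/down calls.
#' @param alpha significance level for qPCR calls.
#' @param validity FPKM validity threshold.
#' @param prob deviation-probability threshold for RNA-seq calls.
#' @param n_boot bootstrap resamples for the deviation probability.
#' @param n_replicates bootstrap replicates for tree support.
#' @param n_draws Monte-Carlo draws for Dunnett p-values.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param identity_floor minimum fractional identity for a reference call.
#' @param spacer1_range,spacer2_range allowed zinc-finger spacer lengths.
#' @param linker_max max residues between heptapeptide end and first Cys.
#' @param max_mismatches heptapeptide mismatch tolerance (anchors fixed).
#' @param seed integer seed for all stochastic steps.
#' @return a list of class `wrky_config`.
#' @export
wrky_config <- function(window = 1000L, min_sites = 3L, up = 1.5, down = 0.66,
                        alpha = 0.05, validity = 10, prob = 0.8,
                        n_boot = 1000L, n_replicates = 1000L,
                        n_draws = 200000L, gap_open = 10, gap_extend = 1,
                        identity_floor = 0.35,
                        spacer1_range = c(3L, 7L), spacer2_range = c(5L, 27L),
                        linker_max = 120L, max_mismatches = 3L, seed = 1L) {
  cfg <- list(window = as.integer(window), min_sites = as.integer(min_sites),
              up = up, down = down, alpha = alpha, validity = validity,
              prob = prob, n_boot = as.integer(n_boot),
              n_replicates = as.integer(n_replicates),
              n_draws = as.integer(n_draws),
              gap_open = gap_open, gap_extend = gap_extend,
              identity_floor = identity_floor,
              spacer1_range = as.integer(spacer1_range),
              spacer2_range = as.integer(spacer2_range),
              linker_max = as.integer(linker_max),
              max_mismatches = as.integer(max_mismatches),
              seed = as.integer(seed))
  class(cfg) <- "wrky_config"
  cfg
}

#' Read or write a configuration file (JSON)
#'
#' @param config a `wrky_config` list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(wrky_config, x)
}
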