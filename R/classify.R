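# Group assignment: structural rules first (domain count, finger type), then
# nearest-reference identity against a subgroup-labelled panel for the calls
# the rules cannot separate (IIa-IIe vs NG vs single-domain group I members,
# which can share identical finger grammars).

GROUP_LEVELS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "NG",
                  "unclassified")

domain_region <- function(sequence, domain) {
  end1 <- domain$zf_start + domain$spacer1 + domain$spacer2 + 5L
  substr(sequence, domain$hep_start + 1L, min(end1, nchar(sequence)))
}

#' Classify one protein into group I/IIa-e/III/NG
#'
#' Rule stage: two assembled domains imply group I; a single CCHC-finger
#' domain implies group III.  A single CCHH or CCHY domain goes to the
#' reference stage: the domain region (heptapeptide start through finger
#' end) is globally aligned to every panel entry, and the best fractional
#' identity at or above `identity_floor` decides the subgroup (an I-labelled
#' best reference yields a single-domain group-I call).  Best identity below
#' the floor yields NG.  Zero domains yield `unclassified`.  Panel ties are
#' broken by lexicographic reference id.
#'
#' @param sequence protein string.
#' @param panel reference panel ([read_reference_panel()]).
#' @param config a [wrky_config()] (identity floor, gap costs, detector
#'   settings).
#' @param domains optional precomputed [assemble_domains()] table.
#' @param submat substitution matrix.
#' @return one-row data.frame: group, basis, best_reference,
#'   reference_identity, n_domains.
#' @export
classify_protein <- function(sequence, panel = read_reference_panel(),
                             config = wrky_config(), domains = NULL,
                             submat = read_substitution_matrix()) {
  if (is.null(domains)) domains <- assemble_domains(sequence, config)
  n_dom <- nrow(domains)
  res <- function(group, basis, ref = NA_character_, ident = NA_real_) {
    data.frame(group = group, basis = basis, best_reference = ref,
               reference_identity = ident, n_domains = n_dom,
               stringsAsFactors = FALSE)
  }
  if (n_dom == 0) return(res("unclassified", "rule"))
  if (n_dom >= 2) return(res("I", "rule"))
  if (domains$finger_type[1] == "CCHC") return(res("III", "rule"))
  if (nrow(panel) == 0) {
    stop("reference panel is empty but a reference call is needed")
  }
  region <- domain_region(sequence, domains[1, ])
  idents <- vapply(seq_len(nrow(panel)), function(k) {
    align_pair(region, panel$sequence[k], submat,
               config$gap_open, config$gap_extend)$identity
  }, numeric(1))
  ord <- order(-idents, panel$reference_id)
  best <- ord[1]
  if (idents[best] < config$identity_floor) {
    return(res("NG", "rule+reference", panel$reference_id[best], idents[best]))
  }
  sub <- panel$subgroup[best]
  basis <- if (sub == "I") "reference" else "rule+reference"
  res(sub, basis, panel$reference_id[best], idents[best])
}

#' Classify every protein in a proteome
#'
#' Order-invariant: each protein is classified independently and the output
#' preserves input order.
#'
#' @param proteins named character vector of protein sequences.
#' @inheritParams classify_protein
#' @return data.frame with columns protein_id, group, basis, best_reference,
#'   reference_identity, n_domains.
#' @export
classify_proteome <- function(proteins, panel = read_reference_panel(),
                              config = wrky_config(),
                              submat = read_substitution_matrix()) {
  stopifnot(!is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    cbind(data.frame(protein_id = id, stringsAsFactors = FALSE),
          classify_protein(proteins[[id]], panel, config, submat = submat))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
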