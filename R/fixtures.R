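# Packaged transcriptions of the published D. officinale survey tables and
# helpers that recompute their summary statistics / replay their worked
# examples through the pipeline.

#' Packaged DoWRKY gene-table transcription
#'
#' 63 rows: gene name, annotation id, ORF length (aa), heptapeptide
#' motif(s), zinc-finger signature(s), domain count, group.
#'
#' @return data.frame.
#' @export
table1_fixture <- function() {
  read_tsv_table(wrky_extdata("table1_dowrky.tsv"))
}

#' Packaged polysaccharide-metabolism W-box target-table transcription
#'
#' @return data.frame with a `positions` list-column of integer offsets.
#' @export
table2_fixture <- function() {
  t2 <- read_tsv_table(wrky_extdata("table2_wbox_targets.tsv"))
  t2$positions <- lapply(strsplit(t2$positions, ","), as.integer)
  t2
}

#' Summary statistics over the gene-table transcription
#'
#' Recomputes, from the packaged table, the family-level tallies the survey
#' reports: row count, group and subgroup tallies, domain-number tally,
#' zinc-finger-type tally (parsed from the signature strings), and ORF
#' length min/max/mean.
#'
#' @param t1 the table ([table1_fixture()] by default).
#' @return list of summaries.
#' @export
table1_summary <- function(t1 = table1_fixture()) {
  main_group <- ifelse(t1$group %in% c("IIa", "IIb", "IIc", "IId", "IIe"),
                       "II", t1$group)
  finger_types <- vapply(strsplit(t1$zinc_finger, "/"), function(parts) {
    # two-domain rows carry two signatures; the finger type is shared
    sig <- strip_signature(parts[1])
    parse_signature(sig)$finger_type
  }, character(1))
  list(n_genes = nrow(t1),
       group_tally = table(factor(main_group, c("I", "II", "III", "NG"))),
       subgroup_tally = table(t1$group),
       domain_tally = table(t1$motif_number),
       finger_tally = table(factor(finger_types, c("CCHH", "CCHC", "CCHY"))),
       orf_min = min(t1$orf_aa), orf_max = max(t1$orf_aa),
       orf_mean = mean(t1$orf_aa))
}

# Remove the " (N)" / "(C)" domain-position tags from a printed signature.
strip_signature <- function(x) trimws(sub("\\s*\\([NC]\\)\\s*$", "", x))

#' Replay the W-box target table through the synthetic genome and scanner
#'
#' Builds a synthetic genome planting each row's W-box positions in the
#' promoter of a gene named by its annotation id, extracts promoters, scans
#' for the W-box on both strands and calls targets.  With a correct scanner
#' every row's count and position set are recovered exactly.
#'
#' @param t2 target-table rows ([table2_fixture()] by default); duplicated
#'   annotation ids are collapsed to one gene each.
#' @param seed integer RNG seed for the synthetic backgrounds.
#' @param window promoter window.
#' @return list with `targets` ([call_targets()] output), `hits`, and
#'   `expected` (named list of planted offset vectors).
#' @export
replay_table2 <- function(t2 = table2_fixture(), seed = 1L, window = 1000L) {
  uniq <- t2[!duplicated(t2$annotation_id), , drop = FALSE]
  planted <- setNames(uniq$positions, uniq$annotation_id)
  sim <- gen_genome(planted, window = window, seed = seed)
  regions <- extract_promoters(sim$genome, sim$annotation, window)
  hits <- scan_regions(regions, WBOX_PATTERN, "WBOX")
  targets <- call_targets(hits, gene_ids = regions$gene_id)
  list(targets = targets, hits = hits,
       expected = lapply(planted, function(x) sort(as.integer(x))))
}
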