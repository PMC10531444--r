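# RBP binding-motif scanning: summed signed motif scores per RBP over the
# acceptor-region windows, and presence/absence contingency tables for
# enrichment testing.

# scan window(s) of a (variant-applied) context: the full upstream intron
# window and the exonic sequence up to Ex+50, kept separate so motifs never
# straddle the intron-exon junction.
rbp_scan_windows <- function(context) {
  c(context$intronic3,
    substr(context$exonic, 1L, min(nchar(context$exonic), 50L)))
}

# count matrix: one row per window sequence, one column per motif entry;
# overlapping matches all count.
count_motif_matches <- function(windows, db) {
  subj <- Biostrings::DNAStringSet(windows)
  vapply(db$entries$motif, function(m) {
    Biostrings::vcountPattern(m, subj, fixed = FALSE)
  }, integer(length(windows)))
}

#' Summed RBP motif scores over sequence windows
#'
#' For every RBP in the database, sums `score x (number of match start
#' positions)` over all its motifs and all supplied windows. Overlapping
#' matches count independently; RBPs with no match map to 0, and every RBP
#' of the database appears in the output.
#'
#' @param windows character vector of one or more ACGT sequence windows
#'   (scanned independently and summed).
#' @param db a `motif_db` from [load_motif_db()].
#' @return named numeric vector, one summed score per RBP (database order).
#' @export
scan_rbp_scores <- function(windows, db) {
  stopifnot(inherits(db, "motif_db"))
  for (w in windows) assert_acgt(w, "scan window")
  counts <- count_motif_matches(windows, db)
  counts <- matrix(counts, nrow = length(windows))  # guard 1-window drop
  per_entry <- colSums(counts) * db$entries$score
  out <- setNames(numeric(length(db$rbp_names)), db$rbp_names)
  sums <- tapply(per_entry, factor(db$entries$rbp, levels = db$rbp_names), sum)
  out[names(sums)] <- ifelse(is.na(sums), 0, sums)
  out
}

#' Presence/absence contingency table of one RBP's motifs
#'
#' Counts, among labeled variants, how many splicing-affecting and how many
#' neutral variants carry at least one binding-motif match of the given RBP
#' in their (variant-applied) scan windows. The resulting 2x2 table feeds
#' [fisher_exact_two_sided()].
#'
#' @param variants list of labeled `FexVariant` objects.
#' @param rbp RBP name present in the database.
#' @param db a `motif_db`.
#' @return 2x2 integer matrix, rows = label (affecting, neutral), columns =
#'   motif present / absent.
#' @export
rbp_presence <- function(variants, rbp, db) {
  if (length(variants) == 0L) stop("empty variant dataset", call. = FALSE)
  if (!rbp %in% db$rbp_names) stop("unknown RBP '", rbp, "'", call. = FALSE)
  labels <- vapply(variants, function(v) {
    if (is.null(v$label)) stop("unlabeled variant: ", v$variant_id,
                               call. = FALSE)
    v$label
  }, character(1))
  entries <- db$entries[db$entries$rbp == rbp, , drop = FALSE]
  sub_db <- structure(list(entries = entries, rbp_names = rbp),
                      class = "motif_db")
  present <- vapply(variants, function(v) {
    windows <- rbp_scan_windows(apply_variant(v))
    sum(count_motif_matches(windows, sub_db)) > 0L
  }, logical(1))
  m <- matrix(c(sum(labels == "affecting" & present),
                sum(labels == "affecting" & !present),
                sum(labels == "neutral" & present),
                sum(labels == "neutral" & !present)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("affecting", "neutral"),
                              c("present", "absent")))
  m
}
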