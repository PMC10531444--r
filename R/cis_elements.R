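# Branch-point and polypyrimidine-tract detection in the 50-nt acceptor
# intron window. Offsets use the Int-k convention: Int-1 is the last intron
# base before the exon, so string position p in intronic3 is offset p - 51.

offset_to_pos <- function(offset) 51L + as.integer(offset)
pos_to_offset <- function(pos) as.integer(pos) - 51L

# per-window log2-odds of a 5-mer against a uniform background
pwm_logodds <- function(window, pwm) {
  ch <- seq_chars(window)
  sum(log2(pwm$freqs[cbind(seq_along(ch), match(ch, BASES))] / 0.25))
}

# lowest score any sequence could achieve under the PWM
pwm_min_score <- function(pwm) sum(log2(apply(pwm$freqs, 1, min) / 0.25))

#' Search for the best branch point sequence
#'
#' Scans every 5-mer lying wholly within Int-50..Int-3 of the acceptor
#' intron window, keeping only windows whose 4th position is the branch-point
#' adenosine, and returns the window with the maximal PWM log2-odds score.
#' Ties are broken toward the acceptor (smaller |offset|). If no window has
#' an A at position 4, `found` is `FALSE` and the score is floored at the
#' minimum achievable PWM score minus 1 so the feature stays numeric and
#' rank-consistent.
#'
#' @param intronic3 50-nt upstream intron sequence (Int-50..Int-1).
#' @param pwm a `bps_pwm` from [load_bps_pwm()] (5 positions).
#' @return object of class `BPSMatch`: `offset` (Int-k of the branch A,
#'   negative), `window` (5-mer), `score`, `found`.
#' @export
find_best_bps <- function(intronic3, pwm = load_bps_pwm()) {
  if (nchar(intronic3) < INTRON3_LEN) {
    stop("intronic3 must be ", INTRON3_LEN, " nt (got ", nchar(intronic3), ")",
         call. = FALSE)
  }
  stopifnot(pwm$width == 5L)
  assert_acgt(intronic3, "intronic3")
  # window starts: 5-mer must end at or before Int-3 (string position 48)
  starts <- seq_len(offset_to_pos(-3L) - 4L)
  windows <- substring(intronic3, starts, starts + 4L)
  has_a <- substr(windows, 4L, 4L) == "A"
  if (!any(has_a)) {
    return(structure(list(offset = NA_integer_, window = NA_character_,
                          score = pwm_min_score(pwm) - 1, found = FALSE),
                     class = "BPSMatch"))
  }
  cand <- which(has_a)
  scores <- vapply(windows[cand], pwm_logodds, numeric(1), pwm = pwm,
                   USE.NAMES = FALSE)
  # max score; ties toward the acceptor = largest start position
  best <- cand[max(which(scores == max(scores)))]
  structure(list(offset = pos_to_offset(best + 3L),
                 window = windows[match(best, starts)],
                 score = max(scores), found = TRUE),
            class = "BPSMatch")
}

#' Derive the polypyrimidine tract region and its features
#'
#' The PPT spans from one nucleotide 3' of the branch-point adenosine
#' through Int-3 (the standard branch-point-to-acceptor definition). When no
#' branch point was found the fallback window Int-20..Int-3 is used.
#' Reports length, the longest contiguous pyrimidine (C/T) run, base-ratio
#' features and whether the hnRNP-attracting GGG trinucleotide occurs.
#'
#' @param intronic3 50-nt upstream intron sequence.
#' @param bps a `BPSMatch` from [find_best_bps()].
#' @return object of class `PPTRegion`.
#' @export
derive_ppt <- function(intronic3, bps) {
  stopifnot(inherits(bps, "BPSMatch"))
  start_offset <- if (isTRUE(bps$found)) bps$offset + 1L else -20L
  end_offset <- -3L
  if (start_offset > end_offset) stop("PPT region is empty", call. = FALSE)
  region <- substr(intronic3, offset_to_pos(start_offset),
                   offset_to_pos(end_offset))
  ch <- seq_chars(region)
  n <- length(ch)
  counts <- table(factor(ch, levels = BASES))
  structure(list(
    start_offset = start_offset, end_offset = end_offset, length = n,
    region = region,
    longest_pyr_run = longest_pyr_run(region),
    ratio_T = unname(counts["T"]) / n,
    ratio_G = unname(counts["G"]) / n,
    ratio_purine = unname(counts["A"] + counts["G"]) / n,
    ratio_pyrimidine = unname(counts["C"] + counts["T"]) / n,
    has_GGG = grepl("GGG", region, fixed = TRUE)
  ), class = "PPTRegion")
}

# registry definition of the tracked positions
POSITIONAL_INTRON <- c(-7L, -6L, -5L, -3L)
POSITIONAL_EXON   <- c(1L, 2L, 3L)

#' One-hot positional nucleotide indicators
#'
#' Indicators for the bases at the intronic positions Int-7, Int-6, Int-5,
#' Int-3 and the exonic positions Ex+1, Ex+2, Ex+3 of a (variant-applied)
#' acceptor context: 4 bases x 7 positions = 28 features in {0,1}. For exons
#' shorter than 3 nt the Ex positions beyond the exon are read from the
#' downstream intron (the transcript continues there), keeping the encoding
#' total and deterministic.
#'
#' @param context an `AcceptorContext`, normally after [apply_variant()].
#' @return named integer vector of 28 zero/one indicators.
#' @export
positional_indicators <- function(context) {
  stopifnot(inherits(context, "AcceptorContext"))
  ext <- paste0(context$exonic, context$intron_down)
  vals <- c(
    setNames(substring(context$intronic3, offset_to_pos(POSITIONAL_INTRON),
                       offset_to_pos(POSITIONAL_INTRON)),
             sprintf("int_m%d", -POSITIONAL_INTRON)),
    setNames(substring(ext, POSITIONAL_EXON, POSITIONAL_EXON),
             sprintf("ex_p%d", POSITIONAL_EXON)))
  out <- integer(0)
  for (p in names(vals)) {
    ind <- setNames(as.integer(BASES == vals[[p]]),
                    sprintf("%s_%s", p, BASES))
    out <- c(out, ind)
  }
  out
}
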