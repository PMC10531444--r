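# Integrated splice-site strength scores: Shapiro-Senapathy (3' and 5'),
# maximum-entropy-style log-odds (3' and 5'), and the SD-score (5').
#
# Window conventions (transcript orientation):
#   donor window   = last 3 exonic + first 6 intronic nt (9-mer)
#   S&S acceptor   = Int-13 .. Ex+1 (14 positions)
#   MaxEnt acceptor= Int-20 .. Ex+3 (23 positions)

#' Shapiro-Senapathy consensus score
#'
#' Min-max-normalised per-position frequency sum, scaled 0-100:
#' `100 * (t - min) / (max - min)` where `t` is the sum over positions of
#' the frequency of the observed base and min/max are the sums of the
#' per-position minimum/maximum frequencies.
#'
#' @param seq window sequence; length must equal the matrix width.
#' @param matrix position-frequency matrix (rows = positions, columns
#'   A/C/G/T), as from [load_freq_matrix()].
#' @return numeric score in \[0, 100\].
#' @export
shapiro_senapathy_score <- function(seq, matrix) {
  ch <- seq_chars(toupper(seq))
  if (length(ch) != nrow(matrix)) {
    stop("sequence length ", length(ch), " does not match matrix width ",
         nrow(matrix), call. = FALSE)
  }
  m <- matrix / rowSums(matrix)  # normalisation first: scale-invariant
  t_obs <- sum(m[cbind(seq_along(ch), match(ch, BASES))])
  lo <- sum(apply(m, 1, min))
  hi <- sum(apply(m, 1, max))
  100 * (t_obs - lo) / (hi - lo)
}

#' Maximum-entropy-style splice-site score
#'
#' `log2(P_model(seq) / P_background(seq))`, where the model probability is
#' assembled from the sub-table decomposition of the loaded parameter set
#' (signed product of sub-table probabilities over their position windows)
#' and the background is an i.i.d. base model.
#'
#' @param seq window sequence (9-mer for `donor9`, 23-mer for `acceptor23`).
#' @param model a `maxent_model` from [load_maxent_model()].
#' @return numeric log2 odds.
#' @export
maxent_score <- function(seq, model) {
  stopifnot(inherits(model, "maxent_model"))
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  if (length(ch) != model$width) {
    stop("sequence length ", length(ch), " does not match ", model$site,
         " window (", model$width, " nt)", call. = FALSE)
  }
  assert_acgt(seq, paste0(model$site, " window"))
  log_p <- 0
  for (sm in model$submodels) {
    kmer <- paste(ch[sm$positions], collapse = "")
    p <- sm$probs[kmer]
    if (is.na(p)) {
      stop("k-mer '", kmer, "' absent from sub-table '", sm$name, "'",
           call. = FALSE)
    }
    log_p <- log_p + sm$sign * log2(unname(p))
  }
  log_bg <- sum(log2(model$background[ch]))
  log_p - log_bg
}

#' SD-score of a donor 9-mer
#'
#' log10 of the position-independent product frequency of the 9-nt donor
#' signal: `sum_i log10 f_i(base_i)`.
#'
#' @param donor9 9-mer (3 exonic + 6 intronic nt).
#' @param model position-frequency matrix (9 x 4) as from
#'   [load_freq_matrix()].
#' @return numeric log10 frequency (non-positive for proper frequencies).
#' @export
sd_score <- function(donor9, model) {
  ch <- seq_chars(toupper(donor9))
  if (length(ch) != nrow(model)) {
    stop("donor window must be ", nrow(model), " nt", call. = FALSE)
  }
  assert_acgt(donor9, "donor window")
  f <- model[cbind(seq_along(ch), match(ch, BASES))]
  if (any(f <= 0)) {
    stop("zero frequency encountered; load the table with a pseudocount",
         call. = FALSE)
  }
  sum(log10(f))
}

# window extraction helpers -------------------------------------------------

# Ex+1..Ex+3 of a (variant-applied) context; short exons continue into the
# downstream intron so the acceptor windows are always complete.
exon_first3 <- function(context) {
  substr(paste0(context$exonic, context$intron_down), 1L, 3L)
}

ss_acceptor_window <- function(context) {  # Int-13..Ex+1
  paste0(substr(context$intronic3, offset_to_pos(-13L), offset_to_pos(-1L)),
         substr(exon_first3(context), 1L, 1L))
}

maxent_acceptor_window <- function(context) {  # Int-20..Ex+3
  paste0(substr(context$intronic3, offset_to_pos(-20L), offset_to_pos(-1L)),
         exon_first3(context))
}

#' All five integrated site scores of a context
#'
#' Convenience wrapper computing the Shapiro-Senapathy acceptor and donor
#' scores, the maximum-entropy acceptor and donor scores, and the SD-score
#' on a (variant-applied) context.
#'
#' @param context an `AcceptorContext` (after [apply_variant()] if a variant
#'   should influence the acceptor-side scores).
#' @param resources a `fex_resources` bundle from [load_resources()].
#' @return named numeric vector of 5 scores.
#' @export
site_scores <- function(context, resources) {
  c(ss3_shapiro = shapiro_senapathy_score(ss_acceptor_window(context),
                                          resources$ss_acceptor),
    ss5_shapiro = shapiro_senapathy_score(context$donor9, resources$ss_donor),
    ss3_maxent = maxent_score(maxent_acceptor_window(context),
                              resources$maxent_acceptor),
    ss5_maxent = maxent_score(context$donor9, resources$maxent_donor),
    ss5_sdscore = sd_score(context$donor9, resources$sd_donor))
}
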