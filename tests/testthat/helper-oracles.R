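# Independent oracle implementations used to cross-check the package.
# These deliberately use brute-force / direct-formula routes and share no
# code with the implementations they verify.

# shared resource bundle (loading is cheap but repeated in many files)
fex_res <- load_resources()
fex_reg <- feature_registry(fex_res$motif_db)

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive branch-point search: enumerate every 5-mer window wholly within
# Int-50..Int-3, keep windows with A at position 4, score by direct log-odds
oracle_best_bps <- function(seq50, pwm) {
  best <- NULL
  for (start in 1:44) {
    w <- substr(seq50, start, start + 4)
    if (substr(w, 4, 4) != "A") next
    sc <- 0
    for (j in 1:5) {
      sc <- sc + unname(log2(pwm$freqs[j, substr(w, j, j)] / 0.25))
    }
    # >= : later (acceptor-proximal) window wins ties
    if (is.null(best) || sc >= best$score) {
      best <- list(offset = (start + 3L) - 51L, window = w, score = sc)
    }
  }
  best
}

# longest pyrimidine run by explicit scanning
oracle_longest_pyr_run <- function(region) {
  ch <- strsplit(region, "")[[1]]
  best <- cur <- 0L
  for (b in ch) {
    cur <- if (b %in% c("C", "T")) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# second, independent transcription of the seven statistic formulas
oracle_metrics <- function(TP, FP, TN, FN) {
  safe <- function(x) if (!is.finite(x)) NA_real_ else x
  acc <- safe((TP + TN) / (TP + TN + FP + FN))
  prec <- if (TP + FP == 0) NA_real_ else TP / (TP + FP)
  rec <- if (TP + FN == 0) NA_real_ else TP / (TP + FN)
  spc <- if (TN + FP == 0) NA_real_ else TN / (TN + FP)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else {
    2 * (prec * rec) / (prec + rec)
  }
  npv <- if (TN + FN == 0) NA_real_ else TN / (TN + FN)
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den == 0) NA_real_ else (TP * TN - FP * FN) / sqrt(den)
  c(accuracy = acc, precision = prec, recall = rec, specificity = spc,
    f1 = f1, npv = npv, mcc = mcc)
}

# O(n^2) pairwise Mann-Whitney concordance with ties counted one half
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# precision-recall area by direct per-threshold confusion counting
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in ths) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    r <- tp / sum(labels == 1)
    p <- tp / (tp + fp)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# full hypergeometric enumeration of the two-sided Fisher p-value
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# IUPAC-degenerate substring matching by exhaustive per-position comparison
oracle_motif_count <- function(motif, seq) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  mch <- strsplit(motif, "")[[1]]
  sch <- strsplit(seq, "")[[1]]
  k <- length(mch)
  hits <- 0
  for (s in seq_len(length(sch) - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!sch[s + j - 1] %in% codes[[mch[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1
  }
  hits
}

# tiny plus-strand single-exon-gene genome for context tests: returns the
# genome plus the annotation of its middle exon
toy_gene <- function(intron1_50, exon, intron2 = NULL, upstream = 30,
                     chrom = "chrT") {
  set.seed(nchar(exon) + nchar(intron1_50))
  if (is.null(intron2)) intron2 <- paste0("GTAAGT", random_dna(24))
  exon1 <- random_dna(15)
  exon3 <- random_dna(15)
  seqs <- paste0(exon1, random_dna(upstream), intron1_50, exon, intron2, exon3)
  genome <- Biostrings::DNAStringSet(setNames(seqs, chrom))
  e2_start <- 15 + upstream + 50 + 1
  ann <- data.frame(
    transcript_id = "TXT", chrom = chrom, strand = "+",
    exon_start = c(1, e2_start, e2_start + nchar(exon) + nchar(intron2)),
    exon_end = c(15, e2_start + nchar(exon) - 1,
                 e2_start + nchar(exon) + nchar(intron2) + 14),
    exon_index = 1:3, n_exons = 3)
  list(genome = genome, annotation = ann, middle = ann[2, ])
}
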