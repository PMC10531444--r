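# Seeded generator of labeled acceptor contexts: a miniature genome FASTA,
# exon annotations and a variant table whose labels follow the
# AG-dependence mechanism — acceptors whose polypyrimidine tract carries a
# long contiguous pyrimidine run tolerate a substitution of the exon's
# first G, short or degenerate tracts do not.

#' Parameters of the synthetic acceptor-context generator
#'
#' The defaults encode the study conditions the generator emulates: a
#' contiguous pyrimidine run of 10-15 nt or more renders the acceptor
#' insensitive to a first-nucleotide variant, so affecting acceptors are
#' planted with short runs (4-9 nt) and degenerate tract background, and
#' neutral acceptors with long runs (15-30 nt) and pyrimidine-rich
#' background; the label threshold of 12 nt sits mid-way in that 10-15 nt
#' window, and 5% label noise emulates annotation error.
#'
#' @param n_variants number of variants to generate.
#' @param class_balance fraction of splicing-affecting variants.
#' @param ppt_run_affecting,ppt_run_neutral inclusive range (min, max) of the
#'   planted contiguous pyrimidine run length per class, in nt.
#' @param pyr_frac_affecting,pyr_frac_neutral pyrimidine fraction of the
#'   tract-region background outside the planted run.
#' @param t_frac fraction of T (vs C) within planted pyrimidines.
#' @param bps_strength probability that each branch-point position takes its
#'   consensus base.
#' @param bps_gap range of the spacer (nt) between the branch-point window
#'   and the planted run.
#' @param motif_plant_rates named numeric vector: per-RBP probability of
#'   planting one binding-motif instance in the exon (applied to both
#'   classes alike).
#' @param label_noise probability of flipping the mechanism-derived label.
#' @param run_threshold run length (nt) at and above which the acceptor is
#'   AG-independent, hence neutral.
#' @param exon_length_range inclusive range of exon lengths (nt).
#' @param minus_strand_frac fraction of records placed on the minus strand.
#' @param seed mandatory integer RNG seed.
#' @return a `SynthParams` list.
#' @export
synth_params <- function(n_variants = 500L, class_balance = 0.5,
                         ppt_run_affecting = c(4L, 9L),
                         ppt_run_neutral = c(15L, 30L),
                         pyr_frac_affecting = 0.45,
                         pyr_frac_neutral = 0.65,
                         t_frac = 0.8, bps_strength = 0.85,
                         bps_gap = c(2L, 6L),
                         motif_plant_rates = c("ETR-3" = 0.15, "MBNL1" = 0.15),
                         label_noise = 0.05, run_threshold = 12L,
                         exon_length_range = c(30L, 90L),
                         minus_strand_frac = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (label_noise < 0 || label_noise > 0.5) {
    stop("label_noise must be in [0, 0.5]", call. = FALSE)
  }
  for (r in list(ppt_run_affecting, ppt_run_neutral, bps_gap,
                 exon_length_range)) {
    if (length(r) != 2L || r[1] > r[2]) stop("empty range", call. = FALSE)
  }
  if (ppt_run_affecting[2] >= run_threshold) {
    stop("affecting-class run range must stay below the threshold",
         call. = FALSE)
  }
  if (ppt_run_neutral[1] < run_threshold) {
    stop("neutral-class run range must start at or above the threshold",
         call. = FALSE)
  }
  # run + gap + 5-mer branch window must fit between Int-50 and Int-3
  if (ppt_run_neutral[2] + bps_gap[2] + 5L + 2L > 48L) {
    stop("planted tract does not fit in the 50-nt intron window",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "SynthParams")
}

rand_bases <- function(n, prob = rep(0.25, 4)) {
  sample(BASES, n, replace = TRUE, prob = prob)
}

# background with a given pyrimidine fraction (T:C at t_frac, A:G even)
tract_background <- function(n, pyr_frac, t_frac) {
  pur <- (1 - pyr_frac) / 2
  rand_bases(n, prob = c(pur, pyr_frac * (1 - t_frac), pur, pyr_frac * t_frac))
}

# flip the midpoint of any pyrimidine run of >= cap nt to a purine,
# repeating until none remain; never touches positions in `protect`
cap_pyr_runs <- function(ch, cap, protect = integer(0)) {
  repeat {
    r <- rle(ch %in% c("C", "T"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths >= cap)
    hit <- FALSE
    for (j in long) {
      idx <- setdiff(seq(starts[j], ends[j]), protect)
      if (length(idx) > 0L) {
        ch[idx[ceiling(length(idx) / 2)]] <- sample(c("A", "G"), 1L)
        hit <- TRUE
      }
    }
    if (!hit) return(ch)
  }
}

BPS_CONSENSUS <- c("T", "T", "A", "A", "T")  # yUnAy with A at position 4

# build one 50-nt acceptor intron window with a planted branch point and
# pyrimidine run; returns the window plus planting bookkeeping
build_intronic3 <- function(run_len, pyr_frac, t_frac, bps_strength, gap,
                            run_threshold, affecting) {
  ch <- tract_background(48L, pyr_frac, t_frac)
  run_start <- 49L - run_len  # run occupies Int-(run_len+2) .. Int-3
  run_idx <- seq(run_start, 48L)
  ch[run_idx] <- sample(c("C", "T"), run_len, replace = TRUE,
                        prob = c(1 - t_frac, t_frac))
  # branch-point 5-mer upstream of the run, A at window position 4
  a_pos <- run_start - gap - 2L
  bps_idx <- seq(a_pos - 3L, a_pos + 1L)
  bps <- vapply(seq_along(BPS_CONSENSUS), function(i) {
    if (i == 4L) "A"
    else if (stats::runif(1) < bps_strength) BPS_CONSENSUS[i]
    else sample(BASES, 1L)
  }, character(1))
  ch[bps_idx] <- bps
  # purine flanks keep the planted run exactly the planted length
  if (run_start - 1L > max(bps_idx)) ch[run_start - 1L] <- sample(c("A", "G"), 1L)
  # cap accidental runs: below threshold for affecting records, and below
  # the planted length elsewhere so the planted run stays the longest
  cap <- if (affecting) min(run_threshold, run_len + 1L) else run_threshold
  ch <- cap_pyr_runs(ch, cap, protect = run_idx)
  list(seq = paste0(paste(ch, collapse = ""), "AG"),
       bps_offset = a_pos - 51L, run_length = run_len)
}

#' Generate a synthetic labeled variant dataset
#'
#' Emits, per record, an internal exon (index 2 of 3) on its own
#' chromosome with a 50-nt acceptor intron window carrying a planted branch
#' point and pyrimidine run, an exon starting with G, and a canonical
#' GT donor. The mechanism label is `affecting` iff the planted run is
#' shorter than `run_threshold`; it is then flipped with probability
#' `label_noise` to give the observed label. Identical seeds give
#' byte-identical output.
#'
#' @param params a `SynthParams` from [synth_params()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `exons.tsv`, `snvs.tsv` and `truth.tsv` there.
#' @return list with `genome` ([Biostrings::DNAStringSet]), `annotation`,
#'   `snvs` (variant_id, chrom, pos, alt, label), `truth` (planted run
#'   length, branch offset, planted motifs, mechanism label) and `params`.
#' @export
generate_dataset <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "SynthParams"))
  p <- params
  n <- as.integer(p$n_variants)
  n_aff <- round(n * p$class_balance)
  with_seed(p$seed, {
    mech_label <- sample(rep(c("affecting", "neutral"),
                             c(n_aff, n - n_aff)))
    db <- load_motif_db()
    plant_pool <- lapply(names(p$motif_plant_rates), function(r) {
      db$entries$motif[db$entries$rbp == r]
    })
    names(plant_pool) <- names(p$motif_plant_rates)

    chroms <- character(n); ann <- vector("list", n)
    snvs <- vector("list", n); truth <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      aff <- mech_label[i] == "affecting"
      run_range <- if (aff) p$ppt_run_affecting else p$ppt_run_neutral
      run_len <- sample(seq(run_range[1], run_range[2]), 1L)
      gap <- sample(seq(p$bps_gap[1], p$bps_gap[2]), 1L)
      pyr <- if (aff) p$pyr_frac_affecting else p$pyr_frac_neutral
      intr <- build_intronic3(run_len, pyr, p$t_frac, p$bps_strength, gap,
                              p$run_threshold, aff)
      exon_len <- sample(seq(p$exon_length_range[1], p$exon_length_range[2]),
                         1L)
      exon <- c("G", rand_bases(exon_len - 1L))
      planted <- character(0)
      for (r in names(plant_pool)) {
        if (stats::runif(1) < p$motif_plant_rates[[r]] &&
            length(plant_pool[[r]]) > 0L) {
          mot <- sample(plant_pool[[r]], 1L)
          inst <- vapply(seq_chars(mot), function(code) {
            sample(IUPAC[[code]], 1L)
          }, character(1))
          # plant inside the scanned exonic window (Ex+1..Ex+50)
          hi <- min(exon_len, 50L) - length(inst)
          start <- sample(seq(4L, hi), 1L)
          exon[seq(start, start + length(inst) - 1L)] <- inst
          planted <- c(planted, r)
        }
      }
      # transcript-oriented gene: exon1, intron1 (ends in the built acceptor
      # window), exon2, intron2 (canonical GT donor), exon3
      exon1 <- paste(rand_bases(20L), collapse = "")
      intron1 <- paste0(paste(rand_bases(30L), collapse = ""), intr$seq)
      intron2 <- paste0("GT",
                        paste(sample(BASES, 4L, replace = TRUE,
                                     prob = c(0.5, 0.05, 0.3, 0.15)),
                              collapse = ""),
                        paste(rand_bases(24L), collapse = ""))
      exon3 <- paste(rand_bases(20L), collapse = "")
      tx <- paste0(exon1, intron1, paste(exon, collapse = ""), intron2, exon3)
      minus <- stats::runif(1) < p$minus_strand_frac
      chrom <- sprintf("synth_%04d", i)
      L <- nchar(tx)
      # transcript-oriented coordinates of the three exons
      b <- c(exon1 = 20L, intron1 = 80L, exon2 = exon_len, intron2 = 30L,
             exon3 = 20L)
      starts_t <- cumsum(c(1L, b[-5]))
      ends_t <- cumsum(b)
      if (minus) {
        seqs[i] <- revcomp(tx)
        g_start <- L + 1L - ends_t; g_end <- L + 1L - starts_t
        strand <- "-"
      } else {
        seqs[i] <- tx
        g_start <- starts_t; g_end <- ends_t
        strand <- "+"
      }
      exon_rows <- c(1L, 3L, 5L)  # transcript exons 1..3 among the 5 blocks
      ann[[i]] <- data.frame(
        transcript_id = sprintf("TX%04d", i), chrom = chrom, strand = strand,
        exon_start = g_start[exon_rows], g_end = g_end[exon_rows],
        exon_index = 1:3, n_exons = 3L)
      names(ann[[i]])[5] <- "exon_end"
      pos <- if (minus) g_end[3] else g_start[3]  # genomic coord of Ex+1
      obs_label <- mech_label[i]
      if (stats::runif(1) < p$label_noise) {
        obs_label <- setdiff(c("affecting", "neutral"), obs_label)
      }
      alt <- sample(c("A", "C", "T"), 1L)
      snvs[[i]] <- data.frame(
        variant_id = sprintf("V%04d", i), chrom = chrom, pos = pos,
        alt = alt, label = obs_label)
      truth[[i]] <- data.frame(
        variant_id = sprintf("V%04d", i), chrom = chrom,
        planted_run_length = intr$run_length,
        bps_offset = intr$bps_offset,
        planted_motifs = paste(planted, collapse = ","),
        mechanism_label = mech_label[i], observed_label = obs_label)
      chroms[i] <- chrom
    }
    genome <- Biostrings::DNAStringSet(setNames(seqs, chroms))
    annotation <- do.call(rbind, ann)
    # fix exon_index ordering for minus-strand records (exon 1 is the
    # 5'-most in transcript orientation = highest genomic coordinate)
    annotation <- annotation[order(annotation$transcript_id,
                                   annotation$exon_index), ]
    rownames(annotation) <- NULL
    out <- list(genome = genome, annotation = annotation,
                snvs = do.call(rbind, snvs), truth = do.call(rbind, truth),
                params = p)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
      for (nm in c("annotation", "snvs", "truth")) {
        fname <- c(annotation = "exons.tsv", snvs = "snvs.tsv",
                   truth = "truth.tsv")[[nm]]
        write.table(out[[nm]], file.path(out_dir, fname), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
    }
    out
  })
}

#' Variants of a synthetic dataset
#'
#' Builds the labeled `FexVariant` list of a generated dataset by running
#' every record through [build_context()].
#'
#' @param dataset result of [generate_dataset()].
#' @return list of labeled `FexVariant` objects.
#' @export
dataset_variants <- function(dataset) {
  ann <- dataset$annotation
  lapply(seq_len(nrow(dataset$snvs)), function(i) {
    s <- dataset$snvs[i, ]
    row <- ann[ann$chrom == s$chrom & ann$exon_index == 2L, , drop = FALSE]
    ctx <- build_context(row[1, ], dataset$genome)
    fex_variant(ctx, s$alt,
                coordinate = list(chrom = s$chrom, pos = s$pos,
                                  assembly = "synthetic"),
                label = s$label, variant_id = s$variant_id)
  })
}

#' Hand-auditable worked fixtures
#'
#' Small deterministic sequences with known cis-element content, used in
#' examples and tests: an all-T tract, a GGG-containing tract, an intron
#' window with a unique branch-point candidate, an adenosine-free window,
#' and a motif-planted exon window.
#'
#' @return named list of character sequences with a `notes` attribute.
#' @export
make_worked_fixtures <- function() {
  # 50-nt windows ending in AG (Int-2, Int-1)
  all_t_ppt <- paste0(strrep("G", 15), "TTTAAT",  # branch A at Int-31 (pos 20)
                      strrep("T", 27), "AG")
  ggg_ppt <- paste0(strrep("G", 15), "TTTAAT", "TTTGGG",
                    strrep("T", 21), "AG")
  unique_bps <- paste0(strrep("C", 23), "A",       # the only upstream A
                       strrep("T", 24), "AG")
  no_a <- paste0(strrep("CT", 24), "AG")           # A only at Int-2
  motif_window <- paste0("AAAA", "TGCA", "CCCC", "TGCA", "GGGG")
  out <- list(all_t_ppt = all_t_ppt, ggg_ppt = ggg_ppt,
              unique_bps = unique_bps, no_a = no_a,
              motif_window = motif_window)
  stopifnot(vapply(out[1:4], nchar, 1L) == 50L)
  attr(out, "notes") <- c(
    all_t_ppt = "branch A at Int-31; tract Int-30..Int-3 is all T",
    ggg_ppt = "as all_t_ppt but tract starts TTTGGG",
    unique_bps = "exactly one branch-point candidate window",
    no_a = "no A upstream of Int-2: branch-point search must fail",
    motif_window = "TGCA planted twice in a 20-mer")
  out
}
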