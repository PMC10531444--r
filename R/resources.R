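#' Load a position-frequency table
#'
#' Reads a tab-separated table with a header and columns
#' `position`, `A`, `C`, `G`, `T`, adds a pseudocount and renormalises each
#' position to sum to one.
#'
#' @param path file path to the table.
#' @param pseudocount small positive value added to every frequency before
#'   renormalisation (avoids zero probabilities on rare bases).
#' @return a numeric matrix, rows = positions, columns A/C/G/T, each row
#'   summing to one.
#' @export
load_freq_matrix <- function(path, pseudocount = 1e-4) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("frequency table must have columns A, C, G, T: ", path, call. = FALSE)
  }
  m <- as.matrix(df[, need])
  if (any(m < 0)) stop("negative frequency in ", path, call. = FALSE)
  m <- m + pseudocount
  m <- m / rowSums(m)
  rownames(m) <- NULL
  m
}

#' Load a branch-point position weight matrix
#'
#' The packaged default (`bps_pwm_synthetic.tsv`) is a synthetic
#' reconstruction shaped like the human branch-point yUnAy consensus; users
#' may supply their own 5-position matrix in the same layout.
#'
#' @param path frequency table path (positions 1..5 x A/C/G/T).
#' @param pseudocount pseudocount applied at load.
#' @return an object of class `bps_pwm` with elements `width`, `freqs`
#'   (normalised matrix) and `pseudocount`.
#' @export
load_bps_pwm <- function(path = fex_resource_file("bps_pwm_synthetic.tsv"),
                         pseudocount = 0.001) {
  freqs <- load_freq_matrix(path, pseudocount)
  structure(list(width = nrow(freqs), freqs = freqs, pseudocount = pseudocount),
            class = "bps_pwm")
}

#' Path of a packaged resource file
#' @param ... path components under `extdata/resources`.
#' @return file path.
#' @export
fex_resource_file <- function(...) {
  p <- system.file("extdata", "resources", ..., package = "fexsplice",
                   mustWork = FALSE)
  if (!nzchar(p) || !file.exists(p)) {
    stop("packaged resource not found: ", file.path(...), call. = FALSE)
  }
  p
}

#' Load a maximum-entropy-style splice-site model
#'
#' The model file is a single tab-separated table with columns `submodel`,
#' `positions` (comma-joined 1-based positions within the site window),
#' `sign` (1 for numerator tables, -1 for denominator/overlap-correction
#' tables), `kmer` and `prob`. Rows with `submodel == "background"` give the
#' per-base background frequencies. The site probability is the signed
#' product of sub-table probabilities, mirroring the product/quotient
#' decomposition of published maximum-entropy splice models; the packaged
#' defaults (`maxent_*_synthetic.tsv`) are synthetic per-position parameter
#' sets in the same layout.
#'
#' @param path model file path.
#' @param site `"donor9"` (9-nt window) or `"acceptor23"` (23-nt window).
#' @return an object of class `maxent_model`.
#' @export
load_maxent_model <- function(path, site = c("acceptor23", "donor9")) {
  site <- match.arg(site)
  width <- if (site == "donor9") 9L else 23L
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(submodel = "character", positions = "character",
                                  kmer = "character"))
  need <- c("submodel", "positions", "sign", "kmer", "prob")
  if (!all(need %in% names(df))) {
    stop("maxent model file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bg_rows <- df$submodel == "background"
  if (!any(bg_rows)) stop("maxent model lacks background rows", call. = FALSE)
  background <- setNames(as.numeric(df$prob[bg_rows]), df$kmer[bg_rows])
  if (!all(BASES %in% names(background))) {
    stop("background must cover A, C, G, T", call. = FALSE)
  }
  background <- background[BASES] / sum(background[BASES])
  submodels <- lapply(split(df[!bg_rows, ], df$submodel[!bg_rows]), function(d) {
    pos <- as.integer(strsplit(d$positions[1], ",")[[1]])
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > width)) {
      stop("submodel '", d$submodel[1], "' has positions outside the ",
           width, "-nt window", call. = FALSE)
    }
    probs <- setNames(as.numeric(d$prob), toupper(d$kmer))
    if (any(probs <= 0)) {
      stop("non-positive probability in submodel '", d$submodel[1], "'",
           call. = FALSE)
    }
    list(name = d$submodel[1], positions = pos,
         sign = as.integer(d$sign[1]), probs = probs)
  })
  structure(list(site = site, width = width, submodels = unname(submodels),
                 background = background),
            class = "maxent_model")
}

#' Load an RBP binding-motif table
#'
#' Tab-separated with header `rbp`, `motif`, `score`. Motifs may use RNA (U)
#' and IUPAC degenerate letters; U is converted to T at load. Scores are
#' signed integers (enhancer positive, silencer negative). The packaged
#' default (`rbp_motifs_synthetic.tsv`) is a synthetic 71-RBP table shaped
#' like a SpliceAid2 export; users can substitute a genuine export.
#'
#' @param path motif table path.
#' @return an object of class `motif_db` with `entries` (data.frame) and
#'   `rbp_names` (ordered unique RBP names).
#' @export
load_motif_db <- function(path = fex_resource_file("rbp_motifs_synthetic.tsv")) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(rbp = "character", motif = "character"))
  need <- c("rbp", "motif", "score")
  if (!all(need %in% names(df))) {
    stop("motif table must have columns rbp, motif, score", call. = FALSE)
  }
  df$motif <- gsub("U", "T", toupper(df$motif), fixed = TRUE)
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", df$motif)
  if (!all(ok)) {
    stop("invalid IUPAC character in motif '", df$motif[which(!ok)[1]], "'",
         call. = FALSE)
  }
  if (any(nchar(df$motif) < 3L)) stop("motif shorter than 3 nt", call. = FALSE)
  if (any(df$score == 0)) stop("motif score must be non-zero", call. = FALSE)
  structure(list(entries = df, rbp_names = unique(df$rbp)), class = "motif_db")
}

#' Load the full default resource bundle
#'
#' Collects every sequence-scoring resource the feature extractor needs:
#' branch-point PWM, Shapiro-Senapathy acceptor/donor matrices, SD-score
#' donor frequency table, maximum-entropy acceptor/donor models, and the RBP
#' motif table. All packaged defaults are synthetic reconstructions (see the
#' individual loaders); any element can be overridden with a user file.
#'
#' @param dir directory holding the resource files; defaults to the packaged
#'   set.
#' @return a named list of loaded resources of class `fex_resources`.
#' @export
load_resources <- function(dir = NULL) {
  pick <- function(fname) {
    if (is.null(dir)) fex_resource_file(fname) else file.path(dir, fname)
  }
  structure(list(
    bps_pwm     = load_bps_pwm(pick("bps_pwm_synthetic.tsv")),
    ss_acceptor = load_freq_matrix(pick("ss_acceptor14_synthetic.tsv")),
    ss_donor    = load_freq_matrix(pick("ss_donor9_synthetic.tsv")),
    sd_donor    = load_freq_matrix(pick("sdscore_donor9_synthetic.tsv")),
    maxent_acceptor = load_maxent_model(pick("maxent_acceptor23_synthetic.tsv"),
                                        site = "acceptor23"),
    maxent_donor = load_maxent_model(pick("maxent_donor9_synthetic.tsv"),
                                     site = "donor9"),
    motif_db    = load_motif_db(pick("rbp_motifs_synthetic.tsv"))
  ), class = "fex_resources")
}
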