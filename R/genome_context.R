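# Sequence context around the first nucleotide of an internal exon.
#
# All sequences are stored transcript-oriented: minus-strand exons are
# reverse-complemented so that Int-1 always abuts Ex+1 across the acceptor
# junction and the donor window always reads exon -> downstream intron.

INTRON3_LEN <- 50L   # Int-50 .. Int-1
EXONIC_CAP  <- 100L  # exonic sequence stored up to this many nt
DONOR_LEN   <- 9L    # 3 exonic + 6 intronic

#' Read a genome FASTA
#'
#' @param path FASTA file. Sequence names are truncated at the first
#'   whitespace so they match annotation chromosome names.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read an exon annotation table
#'
#' Tab-separated with header `transcript_id`, `chrom`, `strand`,
#' `exon_start`, `exon_end`, `exon_index`, `n_exons`; coordinates are
#' 1-based inclusive genomic positions (GTF convention).
#'
#' @param path annotation file.
#' @return a data.frame.
#' @export
read_exon_annotation <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(transcript_id = "character",
                                  chrom = "character", strand = "character"))
  need <- c("transcript_id", "chrom", "strand", "exon_start", "exon_end",
            "exon_index", "n_exons")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("annotation lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be + or -", call. = FALSE)
  if (any(df$exon_start > df$exon_end)) stop("exon_start > exon_end", call. = FALSE)
  df
}

# slice [start, end] (1-based inclusive) from a chromosome, with bounds checks
slice_chrom <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not in genome", call. = FALSE)
  }
  len <- length(genome[[chrom]])
  if (start < 1L || end > len) {
    stop(sprintf("window %d-%d exceeds bounds of %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start, end)))
}

#' Build the acceptor context of one internal exon
#'
#' Extracts, transcript-oriented, the 50 nt of upstream intron (Int-50 ..
#' Int-1), the exon sequence from Ex+1 (capped at 100 nt for motif scanning;
#' the true length is kept in `exon_length`), and the 9-nt donor window
#' (last 3 exonic + first 6 intronic nt). First and last exons are rejected
#' because they have no upstream / downstream sequence.
#'
#' @param annotation one exon: a list or single-row data.frame with fields
#'   `transcript_id`, `chrom`, `strand`, `exon_start`, `exon_end`,
#'   `exon_index`, `n_exons`.
#' @param genome a [Biostrings::DNAStringSet] (see [read_genome()]).
#' @return an object of class `AcceptorContext`.
#' @export
build_context <- function(annotation, genome) {
  a <- as.list(annotation)
  a$exon_start <- as.integer(a$exon_start); a$exon_end <- as.integer(a$exon_end)
  a$exon_index <- as.integer(a$exon_index); a$n_exons <- as.integer(a$n_exons)
  if (a$exon_index <= 1L || a$exon_index >= a$n_exons) {
    stop("terminal exon: exon_index ", a$exon_index, " of ", a$n_exons,
         " has no flanking intron on both sides", call. = FALSE)
  }
  exon_length <- a$exon_end - a$exon_start + 1L
  # downstream-intron bases needed for the donor window (more for tiny exons)
  n_down <- if (exon_length >= 3L) 6L else DONOR_LEN - exon_length
  if (a$strand == "+") {
    intronic3 <- slice_chrom(genome, a$chrom, a$exon_start - INTRON3_LEN,
                             a$exon_start - 1L)
    exonic <- slice_chrom(genome, a$chrom, a$exon_start,
                          min(a$exon_end, a$exon_start + EXONIC_CAP - 1L))
    exon_tail <- slice_chrom(genome, a$chrom,
                             max(a$exon_start, a$exon_end - 2L), a$exon_end)
    intron_down <- slice_chrom(genome, a$chrom, a$exon_end + 1L,
                               a$exon_end + n_down)
    coord_pos <- a$exon_start
  } else {
    intronic3 <- revcomp(slice_chrom(genome, a$chrom, a$exon_end + 1L,
                                     a$exon_end + INTRON3_LEN))
    exonic <- revcomp(slice_chrom(genome, a$chrom,
                                  max(a$exon_start, a$exon_end - EXONIC_CAP + 1L),
                                  a$exon_end))
    exon_tail <- revcomp(slice_chrom(genome, a$chrom, a$exon_start,
                                     min(a$exon_end, a$exon_start + 2L)))
    intron_down <- revcomp(slice_chrom(genome, a$chrom, a$exon_start - n_down,
                                       a$exon_start - 1L))
    coord_pos <- a$exon_end
  }
  for (s in list(c(intronic3, "upstream intron window"),
                 c(exonic, "exonic window"),
                 c(intron_down, "downstream intron window"))) {
    assert_acgt(s[1], s[2])
  }
  donor9 <- paste0(exon_tail, intron_down)
  stopifnot(nchar(donor9) == DONOR_LEN)
  if (substr(intronic3, 49L, 50L) != "AG") {
    warning("acceptor intron does not end in AG for ", a$transcript_id,
            " exon ", a$exon_index, call. = FALSE)
  }
  structure(list(
    transcript_id = a$transcript_id, chrom = a$chrom, strand = a$strand,
    exon_start = a$exon_start, exon_end = a$exon_end,
    exon_index = a$exon_index, n_exons = a$n_exons,
    intronic3 = intronic3, exonic = exonic, donor9 = donor9,
    intron_down = intron_down, exon_length = exon_length,
    ref_first_base = substr(exonic, 1L, 1L),
    coord = list(chrom = a$chrom, pos = coord_pos)
  ), class = "AcceptorContext")
}

#' @export
print.AcceptorContext <- function(x, ...) {
  cat(sprintf("AcceptorContext %s exon %d/%d (%s%s:%d, exon %d nt)\n",
              x$transcript_id, x$exon_index, x$n_exons, x$strand, x$chrom,
              x$coord$pos, x$exon_length))
  cat("  Int-50..Int-1:", x$intronic3, "\n")
  cat("  Ex+1.. :", substr(x$exonic, 1, 30),
      if (nchar(x$exonic) > 30) "..." else "", "\n")
  cat("  donor9 :", x$donor9, "\n")
  invisible(x)
}

#' Enumerate the three possible variants at a first-exon-nucleotide G
#'
#' @param context an `AcceptorContext` whose first exonic base is G.
#' @param coordinate optional list with `chrom`, `pos` (1-based) and
#'   `assembly`; defaults to the context's own coordinate.
#' @param label optional label (`"affecting"` or `"neutral"`) attached to all
#'   three variants.
#' @return list of three `FexVariant` objects with alt A, C, T (fixed order).
#' @export
enumerate_fex_variants <- function(context, coordinate = NULL, label = NULL) {
  stopifnot(inherits(context, "AcceptorContext"))
  if (context$ref_first_base != "G") {
    stop("reference first base is not G (found '", context$ref_first_base,
         "')", call. = FALSE)
  }
  if (is.null(coordinate)) {
    coordinate <- c(context$coord, list(assembly = NA_character_))
  }
  lapply(c("A", "C", "T"), function(alt) {
    fex_variant(context, alt, coordinate = coordinate, label = label)
  })
}

#' Construct a single Fex variant
#'
#' @param context an `AcceptorContext` with `ref_first_base == "G"`.
#' @param alt alternate base, one of A, C, T (transcript orientation).
#' @param coordinate optional genomic coordinate list (`chrom`, `pos`,
#'   `assembly`).
#' @param label optional `"affecting"` or `"neutral"`.
#' @param variant_id optional identifier string.
#' @return object of class `FexVariant`.
#' @export
fex_variant <- function(context, alt, coordinate = NULL, label = NULL,
                        variant_id = NULL) {
  stopifnot(inherits(context, "AcceptorContext"))
  if (context$ref_first_base != "G") {
    stop("reference first base is not G", call. = FALSE)
  }
  alt <- toupper(alt)
  if (!alt %in% c("A", "C", "T")) {
    stop("alt must be one of A, C, T (got '", alt, "')", call. = FALSE)
  }
  if (!is.null(label)) label <- match.arg(label, c("affecting", "neutral"))
  if (is.null(coordinate)) {
    coordinate <- c(context$coord, list(assembly = NA_character_))
  }
  if (is.null(variant_id)) {
    variant_id <- sprintf("%s:%d:G>%s_%s", coordinate$chrom,
                          as.integer(coordinate$pos), alt,
                          context$transcript_id)
  }
  structure(list(context = context, coordinate = coordinate, alt = alt,
                 label = label, variant_id = variant_id),
            class = "FexVariant")
}

#' Apply a variant to its context
#'
#' Returns the context with the alternate base substituted at Ex+1. The
#' donor window is re-derived, which changes it only when the exon is 3 nt
#' or shorter (then Ex+1 lies inside the donor window).
#'
#' @param variant a `FexVariant`.
#' @return an `AcceptorContext` carrying the variant allele.
#' @export
apply_variant <- function(variant) {
  stopifnot(inherits(variant, "FexVariant"))
  ctx <- variant$context
  substr(ctx$exonic, 1L, 1L) <- variant$alt
  ctx$ref_first_base <- variant$alt
  if (ctx$exon_length <= 3L) {
    exon_tail <- substr(ctx$exonic, max(1L, ctx$exon_length - 2L),
                        ctx$exon_length)
    ctx$donor9 <- paste0(exon_tail, ctx$intron_down)
  }
  ctx
}

#' Find annotated internal exons whose first nucleotide is a coordinate
#'
#' A coordinate hits an exon's first nucleotide at `exon_start` on the plus
#' strand and at `exon_end` on the minus strand. Every matching internal
#' exon (all overlapping transcripts) is returned.
#'
#' @param annotation data.frame from [read_exon_annotation()].
#' @param chrom,pos genomic coordinate (1-based).
#' @return data.frame of matching annotation rows (possibly empty).
#' @export
exons_at_first_base <- function(annotation, chrom, pos) {
  hit <- annotation$chrom == chrom &
    ((annotation$strand == "+" & annotation$exon_start == pos) |
     (annotation$strand == "-" & annotation$exon_end == pos)) &
    annotation$exon_index > 1L & annotation$exon_index < annotation$n_exons
  annotation[hit, , drop = FALSE]
}
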