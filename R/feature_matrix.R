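# The ordered registry of 115 named splicing cis-element features and the
# extraction of feature vectors/tables from variants.
#
# Registry composition (reconciling to the 115 total):
#   71 RBP summed motif scores
#   28 positional one-hot indicators (4 bases x {Int-7, Int-6, Int-5, Int-3,
#      Ex+1, Ex+2, Ex+3})
#    5 integrated site scores (S&S 3'/5', MaxEnt 3'/5', SD-score)
#    7 PPT features (length, longest pyrimidine run, ratio_T, ratio_G,
#      ratio_purine, ratio_pyrimidine, has_GGG)
#    3 BPS features (PWM score, conserved-A found flag, branch-to-acceptor
#      distance)
#    1 exon length

#' The ordered feature registry
#'
#' @param db the `motif_db` whose RBP names define the 71 RBP features (the
#'   packaged default has exactly 71).
#' @return data.frame with columns `name` and `group` (`RBP`, `positional`,
#'   `site_score`, `PPT`, `BPS`, `exon`), 115 rows for the default database,
#'   with the registry hash in attribute `registry_hash`.
#' @export
feature_registry <- function(db = load_motif_db()) {
  pos_names <- names(positional_indicator_template())
  reg <- rbind(
    data.frame(name = paste0("rbp_", gsub("[^A-Za-z0-9]+", "_", db$rbp_names)),
               group = "RBP"),
    data.frame(name = pos_names, group = "positional"),
    data.frame(name = c("ss3_shapiro", "ss5_shapiro", "ss3_maxent",
                        "ss5_maxent", "ss5_sdscore"), group = "site_score"),
    data.frame(name = c("ppt_length", "ppt_longest_pyr_run", "ppt_ratio_T",
                        "ppt_ratio_G", "ppt_ratio_purine",
                        "ppt_ratio_pyrimidine", "ppt_has_GGG"), group = "PPT"),
    data.frame(name = c("bps_pwm_score", "bps_found_A", "bps_distance"),
               group = "BPS"),
    data.frame(name = "exon_length", group = "exon"))
  if (anyDuplicated(reg$name)) stop("duplicate feature names in registry",
                                    call. = FALSE)
  attr(reg, "registry_hash") <- registry_hash(reg$name)
  reg
}

positional_indicator_template <- function() {
  pos <- c(sprintf("int_m%d", -POSITIONAL_INTRON),
           sprintf("ex_p%d", POSITIONAL_EXON))
  nm <- as.vector(t(outer(pos, BASES, paste, sep = "_")))
  setNames(integer(length(nm)), nm)
}

# non-RBP feature block of one variant-applied context
context_feature_block <- function(ctx, resources) {
  bps <- find_best_bps(ctx$intronic3, resources$bps_pwm)
  ppt <- derive_ppt(ctx$intronic3, bps)
  c(positional_indicators(ctx),
    site_scores(ctx, resources),
    ppt_length = ppt$length,
    ppt_longest_pyr_run = ppt$longest_pyr_run,
    ppt_ratio_T = ppt$ratio_T,
    ppt_ratio_G = ppt$ratio_G,
    ppt_ratio_purine = ppt$ratio_purine,
    ppt_ratio_pyrimidine = ppt$ratio_pyrimidine,
    ppt_has_GGG = as.integer(ppt$has_GGG),
    bps_pwm_score = bps$score,
    bps_found_A = as.integer(bps$found),
    # fallback distance when no branch A exists: one past the search window
    bps_distance = if (bps$found) -bps$offset else 51,
    exon_length = ctx$exon_length)
}

#' Extract the feature vector of one variant
#'
#' Applies the variant to its context first, so every sequence-dependent
#' feature (positional indicators at Ex+1, acceptor site scores, exonic RBP
#' sums) sees the alternate allele.
#'
#' @param variant a `FexVariant`.
#' @param resources a `fex_resources` bundle from [load_resources()].
#' @param registry the feature registry; defaults to the registry of the
#'   bundle's motif database.
#' @return named numeric vector aligned to registry order, with the registry
#'   hash in attribute `registry_hash`.
#' @export
extract_features <- function(variant, resources,
                             registry = feature_registry(resources$motif_db)) {
  ctx <- apply_variant(variant)
  rbp <- scan_rbp_scores(rbp_scan_windows(ctx), resources$motif_db)
  names(rbp) <- paste0("rbp_", gsub("[^A-Za-z0-9]+", "_", names(rbp)))
  vals <- c(rbp, context_feature_block(ctx, resources))
  miss <- setdiff(registry$name, names(vals))
  if (length(miss) > 0L) {
    stop("extractor produced no value for feature(s): ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  out <- vals[registry$name]
  if (anyNA(out)) {
    stop("missing value in feature(s): ",
         paste(registry$name[is.na(out)][1:3], collapse = ", "), call. = FALSE)
  }
  attr(out, "registry_hash") <- attr(registry, "registry_hash")
  out
}

#' Extract the feature table of a variant dataset
#'
#' Batch version of [extract_features()] with vectorised RBP motif scanning.
#'
#' @param variants list of `FexVariant` objects.
#' @param resources a `fex_resources` bundle.
#' @param registry the feature registry.
#' @return data.frame with columns `variant_id`, `label` (NA when variants
#'   are unlabeled) and one column per registry feature; registry hash in
#'   attribute `registry_hash`.
#' @export
extract_feature_table <- function(variants, resources,
                                  registry = feature_registry(resources$motif_db)) {
  stopifnot(length(variants) > 0L)
  ctxs <- lapply(variants, apply_variant)
  db <- resources$motif_db
  # batch RBP scan: one vcountPattern per motif over all windows
  introns <- Biostrings::DNAStringSet(vapply(ctxs, `[[`, "", "intronic3"))
  exons <- Biostrings::DNAStringSet(vapply(ctxs, function(ctx) {
    substr(ctx$exonic, 1L, min(nchar(ctx$exonic), 50L))
  }, ""))
  counts <- vapply(db$entries$motif, function(m) {
    Biostrings::vcountPattern(m, introns, fixed = FALSE) +
      Biostrings::vcountPattern(m, exons, fixed = FALSE)
  }, integer(length(variants)))
  counts <- matrix(counts, nrow = length(variants))
  scored <- sweep(counts, 2L, db$entries$score, `*`)
  grp <- factor(db$entries$rbp, levels = db$rbp_names)
  rbp_mat <- t(rowsum(t(scored), grp))  # variants x 71
  colnames(rbp_mat) <- paste0("rbp_", gsub("[^A-Za-z0-9]+", "_", db$rbp_names))
  rest <- t(vapply(ctxs, context_feature_block,
                   numeric(length(registry$name) - ncol(rbp_mat)),
                   resources = resources))
  mat <- cbind(rbp_mat, rest)[, registry$name, drop = FALSE]
  out <- data.frame(
    variant_id = vapply(variants, `[[`, "", "variant_id"),
    label = vapply(variants, function(v) {
      if (is.null(v$label)) NA_character_ else v$label
    }, character(1)),
    mat, check.names = FALSE)
  attr(out, "registry_hash") <- attr(registry, "registry_hash")
  out
}

#' Pairwise Spearman rank-correlation matrix of a feature table
#'
#' @param table feature table from [extract_feature_table()] (or any
#'   data.frame whose non-feature columns are `variant_id`/`label`).
#' @return symmetric matrix of Spearman correlations with unit diagonal;
#'   pairs involving a constant feature are set to 0 with a warning.
#' @export
spearman_matrix <- function(table) {
  feats <- feature_columns(table)
  if (nrow(feats) < 3L) stop("need at least 3 rows", call. = FALSE)
  m <- as.matrix(feats)
  const <- apply(m, 2L, function(x) diff(range(x)) == 0)
  s <- suppressWarnings(cor(m, method = "spearman"))
  if (any(const)) {
    warning("constant feature(s) set to zero correlation: ",
            paste(head(colnames(m)[const], 5), collapse = ", "), call. = FALSE)
    s[const, ] <- 0
    s[, const] <- 0
  }
  diag(s) <- 1
  s
}

feature_columns <- function(table) {
  table[, setdiff(names(table), c("variant_id", "label")), drop = FALSE]
}
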