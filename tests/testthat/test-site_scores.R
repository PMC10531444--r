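# Shapiro-Senapathy, maximum-entropy and SD splice-site strength scores.

test_that("consensus and anti-consensus bound the Shapiro-Senapathy scale", {
  m <- fex_res$ss_donor
  consensus <- paste(c("A", "C", "G", "T")[apply(m, 1, which.max)],
                     collapse = "")
  anti <- paste(c("A", "C", "G", "T")[apply(m, 1, which.min)], collapse = "")
  expect_equal(shapiro_senapathy_score(consensus, m), 100)
  expect_equal(shapiro_senapathy_score(anti, m), 0)
  expect_error(shapiro_senapathy_score("ACGT", m), "does not match")
})

test_that("Shapiro-Senapathy equals the direct min-max sum on random input", {
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(runif(9 * 4, 0.01, 1), 9, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m <- m / rowSums(m)
    s <- random_dna(9)
    ch <- strsplit(s, "")[[1]]
    t_obs <- sum(vapply(1:9, function(j) m[j, ch[j]], 0))
    want <- 100 * (t_obs - sum(apply(m, 1, min))) /
      (sum(apply(m, 1, max)) - sum(apply(m, 1, min)))
    expect_equal(shapiro_senapathy_score(s, m), want)
  }
})

test_that("Shapiro-Senapathy is invariant to per-position rescaling", {
  set.seed(22)
  m <- matrix(runif(9 * 4, 0.01, 1), 9, 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m2 <- m
  m2[3, ] <- m2[3, ] * 7
  m2[8, ] <- m2[8, ] * 0.2
  for (i in 1:20) {
    s <- random_dna(9)
    expect_equal(shapiro_senapathy_score(s, m),
                 shapiro_senapathy_score(s, m2))
  }
})

# build a maxent_model object directly (the loader path is tested separately)
toy_maxent <- function(submodels, background = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                       site = "donor9", width = 9L) {
  structure(list(site = site, width = width, submodels = submodels,
                 background = background), class = "maxent_model")
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1,
                                                                   drop = FALSE])
}

test_that("a model identical to its background scores zero everywhere", {
  # per-position tables equal to the background frequencies
  subs <- lapply(1:9, function(i) {
    list(name = paste0("p", i), positions = i, sign = 1L,
         probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  })
  model <- toy_maxent(subs)
  set.seed(23)
  for (i in 1:20) expect_equal(maxent_score(random_dna(9), model), 0)
})

test_that("doubling one 9-mer's probability scores exactly one bit", {
  # single full-window table: uniform except one 9-mer at twice background
  target <- "GATTACAGA"
  kmers <- all_kmers(5)
  # use a 5-mer head table x uniform tail to keep the table small
  head5 <- substr(target, 1, 5)
  p5 <- setNames(rep((1 - 2 * 0.25^5) / (4^5 - 1), 4^5), kmers)
  p5[head5] <- 2 * 0.25^5
  subs <- c(list(list(name = "head", positions = 1:5, sign = 1L, probs = p5)),
            lapply(6:9, function(i) {
              list(name = paste0("p", i), positions = i, sign = 1L,
                   probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
            }))
  model <- toy_maxent(subs)
  expect_equal(maxent_score(target, model), 1)
})

test_that("product/quotient decompositions match brute-force evaluation", {
  # overlapping 3-mer numerators with 1-mer overlap denominators on a 5-mer
  set.seed(24)
  k3 <- all_kmers(3)
  t1 <- setNames(runif(64, 0.5, 2), k3); t1 <- t1 / sum(t1)
  t2 <- setNames(runif(64, 0.5, 2), k3); t2 <- t2 / sum(t2)
  ov <- c(A = 0.2, C = 0.3, G = 0.25, T = 0.25)
  bg <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  model <- toy_maxent(list(
    list(name = "n1", positions = 1:3, sign = 1L, probs = t1),
    list(name = "n2", positions = 3:5, sign = 1L, probs = t2),
    list(name = "d1", positions = 3, sign = -1L, probs = ov)),
    background = bg, site = "acceptor23", width = 5L)
  for (i in 1:50) {
    s <- random_dna(5)
    ch <- strsplit(s, "")[[1]]
    want <- log2(t1[substr(s, 1, 3)] * t2[substr(s, 3, 5)] /
                   ov[ch[3]]) -
      sum(log2(bg[ch]))
    expect_equal(maxent_score(s, model), unname(want))
  }
})

test_that("swapping foreground and background negates the score", {
  set.seed(25)
  f <- matrix(runif(9 * 4, 0.05, 1), 9, 4); f <- f / rowSums(f)
  g <- matrix(runif(9 * 4, 0.05, 1), 9, 4); g <- g / rowSums(g)
  colnames(f) <- colnames(g) <- c("A", "C", "G", "T")
  per_pos <- function(m, bg_row) lapply(1:9, function(i) {
    list(name = paste0("p", i), positions = i, sign = 1L, probs = m[i, ])
  })
  # per-position foreground over per-position background and vice versa;
  # a position-dependent background is expressed through quotient tables
  fwd <- toy_maxent(c(per_pos(f), lapply(1:9, function(i) {
    list(name = paste0("b", i), positions = i, sign = -1L, probs = g[i, ])
  })), background = c(A = 1, C = 1, G = 1, T = 1) / 4)
  rev <- toy_maxent(c(per_pos(g), lapply(1:9, function(i) {
    list(name = paste0("b", i), positions = i, sign = -1L, probs = f[i, ])
  })), background = c(A = 1, C = 1, G = 1, T = 1) / 4)
  for (i in 1:20) {
    s <- random_dna(9)
    # each score carries a +9*log2(4) uniform-background term; after
    # removing it the swapped model's score is the exact negation
    expect_equal(maxent_score(s, fwd) - 9 * log2(4),
                 -(maxent_score(s, rev) - 9 * log2(4)))
  }
})

test_that("a k-mer missing from a sub-table raises a named error", {
  model <- toy_maxent(list(
    list(name = "partial", positions = 1:2,
         sign = 1L, probs = c(AA = 0.5, AC = 0.5)),
    list(name = "rest", positions = 3:9, sign = 1L,
         probs = setNames(rep(1 / 4^7, 4^7), all_kmers(7)))))
  expect_error(maxent_score("GGAAAAAAA", model), "partial")
})

test_that("SD-score closed forms and brute force agree", {
  ones <- matrix(1, 9, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(sd_score("GATTACAGA", ones), 0)
  unif <- ones / 4
  expect_equal(sd_score("GATTACAGA", unif), 9 * log10(0.25))
  set.seed(26)
  for (i in 1:50) {
    m <- matrix(runif(9 * 4, 0.01, 1), 9, 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m <- m / rowSums(m)
    s <- random_dna(9)
    ch <- strsplit(s, "")[[1]]
    want <- sum(vapply(1:9, function(j) log10(m[j, ch[j]]), 0))
    expect_equal(sd_score(s, m), want)
  }
})

test_that("SD-score decreases when an observed base's frequency decreases", {
  m <- fex_res$sd_donor
  s <- "CAGGTAAGT"
  base <- sd_score(s, m)
  m2 <- m
  m2[5, "T"] <- m2[5, "T"] / 10   # position 5 of s is T
  expect_lt(sd_score(s, m2), base)
  expect_error(sd_score(s, m * 0), "zero frequency")
})

test_that("acceptor-side scores respond to the variant allele", {
  g <- toy_gene(paste0(random_dna(44), "TTTCAG"), paste0("G", random_dna(39)))
  ctx <- build_context(g$middle, g$genome)
  ref_scores <- site_scores(ctx, fex_res)
  alt_scores <- site_scores(apply_variant(fex_variant(ctx, "T")), fex_res)
  expect_false(isTRUE(all.equal(ref_scores[["ss3_maxent"]],
                                alt_scores[["ss3_maxent"]])))
  expect_false(isTRUE(all.equal(ref_scores[["ss3_shapiro"]],
                                alt_scores[["ss3_shapiro"]])))
  # donor-side scores are untouched by an Ex+1 change in a long exon
  for (f in c("ss5_shapiro", "ss5_maxent", "ss5_sdscore")) {
    expect_equal(ref_scores[[f]], alt_scores[[f]])
  }
})
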