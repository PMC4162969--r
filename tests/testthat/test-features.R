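fixed_stats <- function(avg_len, N = 10, df = integer(0)) {
  structure(list(N = N, avg_len = avg_len, df = df),
            class = "crf_corpus_stats")
}

factor_env <- function(title, abstract, bounds = NULL) {
  ref <- new_reference("r1", title, abstract,
                       if (is.null(bounds)) {
                         matrix(c(0L, length(abstract)), ncol = 2)
                       } else bounds)
  gthes <- tiny_gene_thes()
  dthes <- tiny_disease_thes()
  list(ref = ref,
       gm = find_mentions(ref, gthes),
       dm = find_mentions(ref, dthes),
       gthes = gthes, dthes = dthes)
}

test_that("conclusiveness factors follow their closed-form definitions", {
  # |r| = 10; disease "scd" matches end at 1-based tokens 4 and 5 is
  # impossible (greedy), so plant two mentions ending at tokens 3 and 5
  e <- factor_env(c("x", "y"), c("scd", "w", "scd", "v", "u", "t", "s",
                                 "q"))
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  f <- conclusiveness_factors(e$ref, pair, e$gm, e$dm,
                              fixed_stats(avg_len = 10))
  expect_equal(unname(f["length"]), 1.0)
  expect_equal(unname(f["disease_tf"]), 2 / 3)
  expect_equal(unname(f["disease_at_ending"]), 5 / 10)
  expect_equal(unname(f["disease_at_title"]), 0)
  # absent gene zeroes all gene factors
  expect_equal(unname(f[c("gene_tf", "gene_at_title", "gene_at_ending")]),
               c(0, 0, 0))
})

test_that("a final-token mention scores ending exactly 1", {
  e <- factor_env(c("a", "b"), c("x", "y", "tp53"))
  pair <- list(gene_id = "TP53", disease_id = "SCD")
  f <- conclusiveness_factors(e$ref, pair, e$gm, e$dm, fixed_stats(5))
  expect_equal(unname(f["gene_at_ending"]), 1.0)
  expect_equal(unname(f["length"]), 1.0)
})

test_that("richness squash is c/(c+1) over distinct distractors", {
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  e0 <- factor_env(c("a"), c("beta", "globin", "scd"))
  expect_equal(unname(richness_factors(e0$ref, pair, e0$gm, e0$dm)),
               c(0, 0))
  # one distractor gene (TP53) -> 0.5; repeated mentions still 1 entity
  e1 <- factor_env(c("a"), c("tp53", "x", "p53", "scd"))
  expect_equal(unname(richness_factors(e1$ref, pair, e1$gm, e1$dm)
                      ["not_gene_num"]), 0.5)
  # two distinct distractor diseases -> 2/3
  e2 <- factor_env(c("a"), c("anemia", "beta", "thalassemia", "scd",
                             "hbb"))
  expect_equal(unname(richness_factors(e2$ref, pair, e2$gm, e2$dm)
                      ["not_disease_num"]), 2 / 3)
})

test_that("focus factors use any-title and max-ending over distractors", {
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  e <- factor_env(c("tp53", "z"), c("brca1", "x", "scd", "hbb"))
  f <- focus_factors(e$ref, pair, e$gm, e$dm)
  expect_equal(unname(f["not_gene_at_title"]), 1)
  # distractor endings: tp53 ends at 1, brca1 ends at 3; |r| = 6
  expect_equal(unname(f["not_gene_at_ending"]), 3 / 6)
  expect_equal(unname(f["not_disease_at_title"]), 0)
  expect_equal(unname(f["not_disease_at_ending"]), 0)
})

test_that("assembled variants are prefixes of the full vector", {
  e <- factor_env(c("beta", "globin"), c("scd", "x", "tp53", "anemia"))
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  st <- fixed_stats(6)
  f7 <- crfref_features(e$ref, pair, e$gm, e$dm, st, "conclusiveness")
  f9 <- crfref_features(e$ref, pair, e$gm, e$dm, st,
                        "conclusiveness_richness")
  f13 <- crfref_features(e$ref, pair, e$gm, e$dm, st, "full")
  expect_length(f7, 7)
  expect_length(f9, 9)
  expect_length(f13, 13)
  expect_equal(f13[1:9], f9)
  expect_equal(f9[1:7], f7)
  expect_equal(f13, c(conclusiveness_factors(e$ref, pair, e$gm, e$dm, st),
                      richness_factors(e$ref, pair, e$gm, e$dm),
                      focus_factors(e$ref, pair, e$gm, e$dm)))
  expect_error(crfref_features(e$ref, pair, e$gm, e$dm, st, "bogus"))
})

test_that("all factors match the slow oracle and stay in [0,1]", {
  set.seed(5)
  gthes <- tiny_gene_thes()
  dthes <- tiny_disease_thes()
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  st <- fixed_stats(40)
  for (i in 1:60) {
    ref <- random_test_ref(paste0("r", i), gthes, dthes,
                           n_tokens = sample(15:60, 1))
    gm <- find_mentions(ref, gthes)
    dm <- find_mentions(ref, dthes)
    f <- crfref_features(ref, pair, gm, dm, st, "full")
    expect_true(all(f >= 0 & f <= 1), info = paste("ref", i))
    expect_equal(f, oracle_factors(ref, pair, gthes, dthes, 40),
                 info = paste("ref", i))
  }
})

test_that("moving the last gene mention later never lowers its ending score", {
  gthes <- tiny_gene_thes()
  dthes <- tiny_disease_thes()
  pair <- list(gene_id = "TP53", disease_id = "SCD")
  st <- fixed_stats(12)
  base <- rep("zz1", 10)
  scores <- vapply(2:10, function(pos) {
    abstract <- base
    abstract[pos] <- "tp53"
    ref <- new_reference("r", "tt", abstract,
                         matrix(c(0L, 10L), ncol = 2))
    gm <- find_mentions(ref, gthes)
    dm <- find_mentions(ref, dthes)
    unname(conclusiveness_factors(ref, pair, gm, dm, st)["gene_at_ending"])
  }, 1.0)
  expect_true(all(diff(scores) >= 0))
})

test_that("adding a distractor mention never lowers richness or focus factors", {
  gthes <- tiny_gene_thes()
  dthes <- tiny_disease_thes()
  pair <- list(gene_id = "HBB", disease_id = "SCD")
  abstract <- c("beta", "globin", "scd", "zz1", "zz2", "zz3")
  with_distr <- c(abstract, "tp53")
  score <- function(ab) {
    ref <- new_reference("r", "tt", ab,
                         matrix(c(0L, length(ab)), ncol = 2))
    gm <- find_mentions(ref, gthes)
    dm <- find_mentions(ref, dthes)
    c(richness_factors(ref, pair, gm, dm),
      focus_factors(ref, pair, gm, dm))
  }
  expect_true(all(score(with_distr) >= score(abstract)))
})

test_that("degenerate zero-length references are rejected", {
  expect_error(new_reference("r", character(0), character(0)), "neither")
})

test_that("feature tables round-trip through TSV", {
  df <- data.frame(pair_id = c("p1", "p1"), ref_id = c("r1", "r2"),
                   label = c(1L, 0L), f1 = c(0.5, 0.25),
                   f2 = c(1, 0), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(df, path)
  expect_equal(read_feature_tsv(path), df)
})
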