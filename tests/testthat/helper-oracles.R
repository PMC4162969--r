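# Independent reference implementations used as oracles. Each is coded
# directly from the definitions, without reusing package internals.

# Character-by-character normalization oracle.
oracle_normalize <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  out <- character(0)
  cur <- ""
  flush_tok <- function(tok, acc) {
    if (tok == "") return(acc)
    letters_only <- gsub("[^A-Za-z]", "", tok)
    if (letters_only != toupper(letters_only)) tok <- tolower(tok)
    c(acc, tok)
  }
  for (ch in chars) {
    if (grepl("^[A-Za-z0-9]$", ch)) {
      cur <- paste0(cur, ch)
    } else {
      out <- flush_tok(cur, out)
      cur <- ""
    }
  }
  flush_tok(cur, out)
}

# Brute-force dictionary matcher: enumerate every (position, alias)
# full match, then resolve with the greedy longest-match rule.
oracle_find_mentions <- function(body, title_len, dict_entities,
                                 dict_aliases) {
  n <- length(body)
  cand <- list()  # each: entity, start0, len
  for (k in seq_along(dict_aliases)) {
    a <- dict_aliases[[k]]
    L <- length(a)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      j <- i + L - 1L
      if (i <= title_len && j > title_len) next
      if (all(body[i:j] == a)) {
        cand[[length(cand) + 1L]] <- list(entity = dict_entities[k],
                                          start = i - 1L, len = L)
      }
    }
  }
  hits <- list()
  i <- 1L
  while (i <= n) {
    here <- Filter(function(m) m$start == i - 1L, cand)
    if (length(here) == 0L) {
      i <- i + 1L
      next
    }
    best <- max(vapply(here, function(m) m$len, 1L))
    for (m in here) {
      if (m$len == best) hits[[length(hits) + 1L]] <- m
    }
    i <- i + best
  }
  hits
}

# Slow factor re-implementation from the prose definitions, driven by
# the brute-force matcher.
oracle_factors <- function(ref, pair, gene_thes, disease_thes, avg_len) {
  body <- c(ref$title_tokens, ref$abstract_tokens)
  tlen <- length(ref$title_tokens)
  n <- length(body)
  flatten <- function(thes) {
    ent <- character(0)
    al <- list()
    for (id in names(thes)) {
      for (a in thes[[id]]) {
        ent <- c(ent, id)
        al <- c(al, list(a))
      }
    }
    list(ent = ent, al = al)
  }
  gd <- flatten(gene_thes)
  dd <- flatten(disease_thes)
  ghits <- oracle_find_mentions(body, tlen, gd$ent, gd$al)
  dhits <- oracle_find_mentions(body, tlen, dd$ent, dd$al)
  stat <- function(hits, id) {
    own <- Filter(function(m) m$entity == id, hits)
    tf <- length(own)
    last_end <- if (tf > 0L) {
      max(vapply(own, function(m) m$start + m$len, 1L))
    } else 0L
    at_title <- any(vapply(own, function(m) m$start + m$len <= tlen, TRUE))
    list(tf = tf, last_end = last_end,
         at_title = isTRUE(at_title))
  }
  distractors <- function(hits, own_id) {
    unique(vapply(Filter(function(m) m$entity != own_id, hits),
                  function(m) m$entity, ""))
  }
  g <- stat(ghits, pair$gene_id)
  d <- stat(dhits, pair$disease_id)
  other_g <- distractors(ghits, pair$gene_id)
  other_d <- distractors(dhits, pair$disease_id)
  other_stat <- function(hits, ids) {
    if (length(ids) == 0L) return(list(at_title = FALSE, ending = 0))
    st <- lapply(ids, function(e) stat(hits, e))
    list(at_title = any(vapply(st, function(s) s$at_title, TRUE)),
         ending = max(vapply(st, function(s) s$last_end, 1L)) / n)
  }
  og <- other_stat(ghits, other_g)
  od <- other_stat(dhits, other_d)
  c(length = min(n / avg_len, 1),
    gene_tf = min(g$tf / 3, 1),
    disease_tf = min(d$tf / 3, 1),
    gene_at_title = as.numeric(g$at_title),
    disease_at_title = as.numeric(d$at_title),
    gene_at_ending = g$last_end / n,
    disease_at_ending = d$last_end / n,
    not_gene_num = length(other_g) / (length(other_g) + 1),
    not_disease_num = length(other_d) / (length(other_d) + 1),
    not_gene_at_title = as.numeric(og$at_title),
    not_disease_at_title = as.numeric(od$at_title),
    not_gene_at_ending = og$ending,
    not_disease_at_ending = od$ending)
}

# Brute-force average precision: mean over target ranks of the
# precision (targets seen / rank) at each target's rank.
oracle_average_precision <- function(ranked_ids, targets) {
  is_target <- ranked_ids %in% targets
  if (!any(is_target)) return(0)
  precisions <- numeric(0)
  for (r in seq_along(ranked_ids)) {
    if (is_target[r]) {
      precisions <- c(precisions, sum(is_target[seq_len(r)]) / r)
    }
  }
  mean(precisions)
}

# Independently coded Okapi BM25 term contribution.
oracle_bm25 <- function(tf, df, N, len, avg_len, k1 = 2, b = 0.75) {
  total <- 0
  for (i in seq_along(tf)) {
    idf <- log((N - df[i] + 0.5) / (df[i] + 0.5))
    if (idf < 0) idf <- 0
    if (tf[i] > 0) {
      total <- total +
        idf * (tf[i] * (k1 + 1)) / (tf[i] + k1 * (1 - b + b * len / avg_len))
    }
  }
  total
}

oracle_vsm <- function(tf, df, N, len) {
  total <- 0
  for (i in seq_along(tf)) {
    idf <- 1 + log(N / (df[i] + 1))
    total <- total + sqrt(tf[i]) * idf^2
  }
  total / sqrt(len)
}

# Random reference over a tiny planted thesaurus, for property tests.
random_test_ref <- function(id, gene_thes, disease_thes, n_tokens = 30,
                            title_len = 5) {
  vocab <- sprintf("zz%03d", 1:50)
  aliases <- c(unlist(gene_thes, recursive = FALSE),
               unlist(disease_thes, recursive = FALSE))
  tokens <- sample(vocab, n_tokens, replace = TRUE)
  n_ins <- sample(0:6, 1)
  for (i in seq_len(n_ins)) {
    a <- aliases[[sample(length(aliases), 1)]]
    pos <- sample(length(tokens) + 1, 1) - 1
    tokens <- append(tokens, a, after = pos)
  }
  title <- tokens[seq_len(min(title_len, length(tokens)))]
  abstract <- tokens[-seq_len(min(title_len, length(tokens)))]
  ends <- if (length(abstract) <= 10) {
    length(abstract)
  } else {
    unique(c(seq(10, length(abstract), by = 10), length(abstract)))
  }
  bounds <- cbind(start = c(0L, ends[-length(ends)]), end = ends)
  new_reference(id, title, abstract, bounds)
}

# Small fixed thesauri used across tests.
tiny_gene_thes <- function() {
  new_thesaurus(list(
    HBB = list("hbb", c("beta", "globin")),
    BRCA1 = list("brca1", c("breast", "cancer", "1", "gene")),
    TP53 = list("tp53", "p53")
  ), "gene")
}

tiny_disease_thes <- function() {
  new_thesaurus(list(
    SCD = list(c("sickle", "cell", "disease"), "scd"),
    THAL = list(c("beta", "thalassemia"), "thalassemia"),
    ANEMIA = list("anemia")
  ), "disease")
}
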