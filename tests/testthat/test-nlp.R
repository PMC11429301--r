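test_that("cleaning lowercases, strips punctuation, splits hyphens, drops empties", {
  tr <- transcript(c("Look,", "UP!", "...", "tongue-to-cheek", "don't"),
                   start_s = 0:4, end_s = 0:4 + 0.4, speaker = "doctor")
  cl <- clean_transcript(tr)
  expect_equal(cl$text, c("look", "up", "tongue", "to", "cheek", "dont"))
  # hyphen parts keep the original word's timestamps
  expect_equal(cl$start_s[cl$text %in% c("tongue", "to", "cheek")],
               rep(3, 3))
  # idempotent
  expect_identical(clean_transcript(cl)$text, cl$text)
  expect_identical(clean_transcript(cl)$start_s, cl$start_s)
})

test_that("cleaning matches a character-filter oracle on random tokens", {
  set.seed(42)
  pool <- c("Alpha", "beta!", "GAMMA,", "(delta)", "??", "ep-si",
            "zeta's", "ETA.")
  words <- sample(pool, 60, replace = TRUE)
  tr <- make_tr(words)
  cl <- clean_transcript(tr)
  oracle <- unlist(lapply(words, function(w) {
    w <- gsub("-", " ", tolower(w), fixed = TRUE)
    w <- gsub("[[:punct:]]", "", w)
    parts <- strsplit(trimws(w), "\\s+")[[1]]
    parts[nzchar(parts)]
  }))
  expect_equal(cl$text, oracle)
})

test_that("find_phrase locates contiguous matches timestamped at the first word", {
  tr <- clean_transcript(make_tr(
    c("please", "look", "up", "at", "the", "ceiling"), gap = 0.6))
  hit <- find_phrase(tr, "look up")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$t_s, tr$start_s[2])
  expect_equal(nrow(find_phrase(tr, "cheek puff")), 0)
  expect_error(find_phrase(tr, "..."), "non-empty")
})

test_that("find_phrase equals a regex oracle over the token sequence", {
  set.seed(7)
  vocab <- c("look", "up", "down", "the", "a", "now", "please")
  words <- sample(vocab, 50, replace = TRUE)
  # plant the phrase three times
  for (pos in c(5, 22, 41)) words[pos:(pos + 1)] <- c("look", "up")
  tr <- clean_transcript(make_tr(words, gap = 0.4))
  hits <- find_phrase(tr, "look up")
  # oracle: regex over the joined tokens, positions mapped back to words
  joined <- paste(tr$text, collapse = " ")
  m <- gregexpr("\\blook up\\b", joined)[[1]]
  starts_chr <- c(1, cumsum(nchar(tr$text) + 1) + 1)
  oracle_idx <- match(as.integer(m), starts_chr)
  expect_gte(nrow(hits), 3)
  expect_equal(hits$first_idx, oracle_idx)
  expect_equal(hits$t_s, tr$start_s[oracle_idx])
})

test_that("phrase matches respect the inter-word gap and the search window", {
  tr <- clean_transcript(transcript(
    c("look", "up", "look", "up"),
    start_s = c(0, 0.5, 10, 13.5), end_s = c(0.4, 0.9, 10.4, 13.9),
    speaker = "doctor"))
  hits <- find_phrase(tr, "look up", max_gap_s = 2)
  expect_equal(nrow(hits), 1)  # 3.1 s silence breaks the second occurrence
  expect_equal(nrow(find_phrase(tr, "look up", max_gap_s = 4)), 2)
  expect_equal(nrow(find_phrase(tr, "look up", window = c(5, 20),
                                max_gap_s = 4)), 1)
})

test_that("overlapping matches resolve greedily left to right", {
  tr <- clean_transcript(make_tr(c("go", "go", "go"), gap = 0.4))
  hits <- find_phrase(tr, "go go")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$first_idx, 1L)
})

test_that("find_keywords is the labeled union of per-phrase searches", {
  dict <- default_dictionary()
  tr <- clean_transcript(make_tr(
    c("now", "puff", "your", "cheeks", "then", "look", "up", "and",
      "count", "to", "fifty"), gap = 0.5))
  hits <- find_keywords(tr, dict,
                        c("cheek_puff", "ptosis", "count_to_50"))
  manual <- dplyr::bind_rows(lapply(
    c("cheek_puff", "ptosis", "count_to_50"),
    function(id) {
      dplyr::bind_rows(lapply(
        c(dict$tests[[id]]$explanation, dict$tests[[id]]$validation),
        function(p) find_phrase(tr, p)))
    }))
  expect_setequal(hits$t_s, manual$t_s)
  expect_true(all(diff(hits$t_s) >= 0))
  expect_equal(sum(hits$test == "cheek_puff"), 1)
  expect_error(find_keywords(tr, dict, "nonsense"), "unknown test")
})

test_that("cluster_two returns the exact optimum on worked examples", {
  cl <- cluster_two(c(10, 11, 200, 201))
  expect_equal(cl$means, c(10.5, 200.5))
  expect_equal(cl$assignment, c(1, 1, 2, 2))
  expect_false(cl$degenerate)
  expect_equal(cluster_two(c(0, 100))$means, c(0, 100))
  expect_error(cluster_two(5), "at least 2")
  expect_true(cluster_two(rep(3, 4))$degenerate)
})

test_that("cluster_two equals exhaustive-split brute force on random instances", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    x <- runif(n, 0, 1000)
    cl <- cluster_two(x)
    or <- oracle_split_two(x)
    expect_equal(cl$wss, or$wss, tolerance = 1e-9)
    expect_equal(cl$means, or$means, tolerance = 1e-9)
    expect_true(cl$means[1] <= cl$means[2])
  }
})

test_that("word_rate counts words per second within a half-open interval", {
  tr <- make_tr(rep("word", 10), t0 = 0, gap = 0.5)  # 10 words in [0, 5)
  expect_equal(word_rate(tr, c(0, 5)), 2.0)
  expect_equal(word_rate(tr, c(100, 105)), 0)
  expect_error(word_rate(tr, c(5, 5)), "positive duration")
  mixed <- transcript(rep("w", 6), start_s = 0:5, end_s = 0:5 + 0.3,
                      speaker = rep(c("doctor", "patient"), 3))
  expect_equal(word_rate(mixed, c(0, 6), speaker = "patient"), 3 / 6)
})
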