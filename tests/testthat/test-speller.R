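# Speller state machines, bigram suggestions and copy-spelling simulation.

pangram <- "THE QUICK BROWN FOX JUMPS OVER THE LAZY DOG"

test_that("layouts expose the documented target sets", {
  l4 <- speller_layout(4)
  expect_identical(l4$K, 4L)
  expect_length(l4$chars, 27)
  l32 <- speller_layout(32)
  expect_identical(l32$K, 32L)
  expect_length(l32$chars, 28)
  expect_identical(l32$suggestion_targets, 29:31)
  expect_identical(l32$undo_target, 32L)
  expect_error(speller_layout(7), "4 or 32")
})

test_that("spelling B on the 4-target speller takes the documented path", {
  l4 <- speller_layout(4)
  st <- new_speller_state()
  st <- apply_selection(st, l4, 1)   # group A-I
  expect_identical(st$typed, "")
  st <- apply_selection(st, l4, 1)   # subgroup A-C
  st <- apply_selection(st, l4, 2)   # letter B
  expect_identical(st$typed, "B")
  expect_identical(st$path, integer(0))
  # and the greedy policy reproduces it
  st2 <- new_speller_state()
  expect_identical(intended_target(st2, l4, "BCI"), 1L)
})

test_that("undo deletes a character at the root and ascends below it", {
  l4 <- speller_layout(4)
  st <- new_speller_state()
  for (tg in c(1, 1, 1, 1, 1, 2)) st <- apply_selection(st, l4, tg)  # "AB"
  expect_identical(st$typed, "AB")
  st <- apply_selection(st, l4, 4)            # root undo: delete B
  expect_identical(st$typed, "A")
  st <- apply_selection(st, l4, 2)            # descend to group J-R
  st <- apply_selection(st, l4, 4)            # undo: back to root, text kept
  expect_identical(st$typed, "A")
  expect_identical(st$path, integer(0))
  # 32-target undo removes the last selection's output
  l32 <- speller_layout(32)
  s2 <- new_speller_state()
  s2 <- apply_selection(s2, l32, 1)           # A
  s2 <- apply_selection(s2, l32, 2)           # B
  s2 <- apply_selection(s2, l32, 32)
  expect_identical(s2$typed, "A")
  # undo on empty text is a harmless no-op
  s3 <- apply_selection(new_speller_state(), l32, 32)
  expect_identical(s3$typed, "")
})

test_that("bigram training counts words and pairs exactly", {
  m <- train_bigram(c("A B", "A C"))
  expect_identical(unname(m$bigram[c("A B", "A C")]), c(1, 1))
  # conditional probabilities for context A: 0.5 / 0.5
  pa <- m$bigram[c("A B", "A C")] / sum(m$bigram[startsWith(names(m$bigram), "A ")])
  expect_equal(unname(pa), c(0.5, 0.5))
  expect_error(train_bigram(character(0)), "non-empty")
  expect_error(train_bigram(c("", "  ")), "empty model")
  # pair-count conservation: sum of bigram counts = sum(len - 1)
  corpus <- load_corpus()
  model <- train_bigram(corpus)
  lens <- vapply(corpus, function(s)
    length(strsplit(cvepr:::normalize_corpus_line(s), " ")[[1]]), integer(1))
  expect_identical(model$n_pairs, as.integer(sum(lens - 1)))
  expect_equal(sum(model$unigram), sum(lens))
})

test_that("suggestions rank by bigram counts with unigram fallback", {
  corpus <- c("THE CAT SAT", "THE CAT RAN", "THE DOG SAT", "A CAR DROVE")
  m <- train_bigram(corpus)
  # brute-force ranking for context THE, prefix "": bigram counts 2 and 1
  # for CAT and DOG, then the most frequent remaining word (THE itself)
  expect_identical(suggest(m, "THE", ""), c("CAT", "DOG", "THE"))
  expect_identical(suggest(m, "THE", "C"), c("CAT", "CAR"))
  # unseen context: pure unigram frequency ranking
  expect_identical(suggest(m, "ZEBRA", "C"), c("CAT", "CAR"))
  expect_identical(suggest(m, "THE", "XYZ"), character(0))
  # deterministic alphabetical tie-break mirrors exhaustive sort
  big <- m$bigram[paste("THE", m$vocab)]
  big[is.na(big)] <- 0
  ord <- order(-big, -m$unigram[m$vocab], m$vocab)
  expect_identical(suggest(m, "THE", "", n = 5),
                   utils::head(m$vocab[ord], 5))
})

test_that("the intent policy spells, corrects, and ignores suggestions in
           letter-by-letter mode", {
  l32 <- speller_layout(32)
  st <- new_speller_state()
  st$typed <- "X"                              # wrong character committed
  st$outputs <- "X"
  expect_identical(intended_target(st, l32, "BCI"), 32L)   # undo
  st2 <- new_speller_state()
  st2$typed <- "B"
  st2$outputs <- "B"
  st2$suggestions <- c("BCI", "BRAIN")         # visible but dictionary off
  expect_identical(intended_target(st2, l32, "BCI_X"), 3L) # letter C
  expect_identical(intended_target(st2, l32, "BCI_X", dictionary = TRUE),
                   29L)                        # suggestion slot 1
})

test_that("error-free pangram spelling needs 43 and 129 selections", {
  s32 <- simulate_copy_spelling(32, pangram, accuracy = 1)
  expect_identical(s32$n_selections, 43L)
  expect_identical(s32$final_text, gsub(" ", "_", pangram))
  s4 <- simulate_copy_spelling(4, pangram, accuracy = 1)
  expect_identical(s4$n_selections, 129L)
  expect_true(s4$completed)
  expect_error(simulate_copy_spelling(4, "HELLO."), "not representable")
})

test_that("an informative dictionary strictly reduces selections", {
  model <- train_bigram(load_corpus())
  plain <- simulate_copy_spelling(32, pangram, accuracy = 1)
  dict <- simulate_copy_spelling(32, pangram, accuracy = 1,
                                 dictionary = TRUE, model = model)
  expect_lt(dict$n_selections, plain$n_selections)
  expect_identical(dict$final_text, plain$final_text)
})

test_that("noisy sessions terminate with all errors corrected", {
  for (seed in 1:5) {
    s <- simulate_copy_spelling(32, "HELLO WORLD", accuracy = 0.85,
                                seed = seed)
    expect_true(s$completed)
    expect_identical(s$final_text, "HELLO_WORLD")
    # logged accuracy is the fraction of correct selections by construction
    expect_equal(selection_accuracy(s), mean(s$log$correct))
  }
  s4 <- simulate_copy_spelling(4, "BCI", accuracy = 0.8, seed = 2)
  expect_true(s4$completed)
  expect_identical(s4$final_text, "BCI")
})

test_that("decoder-in-the-loop spelling completes on clean signals", {
  model <- clean_model4()
  fm <- fm_clean()
  res <- spell_with_decoder(4, "AB", model, fm, seed = 5, max_dwell = 3)
  expect_true(res$completed)
  expect_identical(res$final_text, "AB")
  expect_true(all(res$log$correct))
  expect_true(all(res$log$selection_time >= 1.25))
})
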