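# Speller state machines and the bigram word-prediction model.
#
# Two layouts are modelled. The 4-target speller selects one of 27
# characters (A-Z and underscore) in three steps: three groups of nine,
# then groups of three, then single characters; the fourth target is the
# correction option, which deletes the last character at the root and goes
# back one step below the root. The 32-target speller selects in one step
# among 28 characters (A-Z, underscore, full stop), three dictionary
# suggestion slots and one undo target.

#' Speller layout description
#'
#' @param kind `"four_target"`, `"thirty_two_target"`, or the numbers 4/32.
#' @return A `cvep_speller_layout` with the ordered character set, the
#'   number of selectable targets `K`, suggestion slots and undo target.
#' @export
speller_layout <- function(kind = c("four_target", "thirty_two_target")) {
  if (is.numeric(kind)) kind <- if (kind == 4) "four_target" else
    if (kind == 32) "thirty_two_target" else stop("`kind` must be 4 or 32")
  kind <- match.arg(kind)
  if (kind == "four_target") {
    structure(
      list(kind = kind, K = 4L, chars = c(LETTERS, "_"),
           group_labels = c("A-I", "J-R", "S-_"), undo_target = 4L,
           suggestion_targets = integer(0)),
      class = "cvep_speller_layout")
  } else {
    structure(
      list(kind = kind, K = 32L, chars = c(LETTERS, "_", "."),
           undo_target = 32L, suggestion_targets = 29:31),
      class = "cvep_speller_layout")
  }
}

#' Create an empty speller state
#'
#' @return A `cvep_speller_state`: typed text, tree position (4-target),
#'   current suggestions, and the stack of per-selection outputs that the
#'   undo option removes.
#' @export
new_speller_state <- function() {
  structure(
    list(typed = "", path = integer(0), suggestions = character(0),
         outputs = character(0), last_selection = NA_integer_),
    class = "cvep_speller_state")
}

# Current partial word (text after the last word boundary) and the last
# completed word before it. Underscore and full stop act as boundaries.
split_context <- function(typed) {
  parts <- strsplit(typed, "[_.]")[[1]]
  ends_boundary <- grepl("[_.]$", typed) || typed == ""
  prefix <- if (ends_boundary || length(parts) == 0) "" else parts[length(parts)]
  done <- if (ends_boundary) parts else parts[-length(parts)]
  done <- done[nzchar(done)]
  prev <- if (length(done)) done[length(done)] else ""
  list(prefix = prefix, prev = prev)
}

pop_output <- function(state) {
  if (length(state$outputs) == 0) return(state)          # nothing to undo
  last <- state$outputs[length(state$outputs)]
  state$outputs <- state$outputs[-length(state$outputs)]
  if (nzchar(last))
    state$typed <- substr(state$typed, 1, nchar(state$typed) - nchar(last))
  state
}

push_output <- function(state, text) {
  state$typed <- paste0(state$typed, text)
  state$outputs <- c(state$outputs, text)
  state
}

#' Apply one selection to a speller state
#'
#' Implements the layout semantics: tree descent / character emission /
#' stepwise undo for the 4-target speller; character append, suggestion
#' completion (the suggested word completes the current prefix and appends
#' a trailing underscore) and undo (removing the entire output of the last
#' selection) for the 32-target speller. Selecting an empty suggestion slot
#' changes nothing but is still a selection.
#'
#' @param state A `cvep_speller_state`.
#' @param layout A `cvep_speller_layout`.
#' @param target Selected target index in `1..K`.
#' @param model Optional `cvep_bigram_model`; when given (32-target),
#'   suggestions are refreshed after the selection.
#' @return The updated state.
#' @export
apply_selection <- function(state, layout, target, model = NULL) {
  stopifnot(inherits(state, "cvep_speller_state"),
            inherits(layout, "cvep_speller_layout"))
  if (!is.numeric(target) || length(target) != 1 || target < 1 ||
      target > layout$K || target != round(target))
    stop("target index out of range 1..", layout$K)
  target <- as.integer(target)

  if (layout$kind == "four_target") {
    depth <- length(state$path)
    if (target == layout$undo_target) {
      if (depth == 0) state <- pop_output(state)      # delete last character
      else state$path <- state$path[-depth]           # go back one step
    } else if (depth < 2) {
      state$path <- c(state$path, target)
    } else {
      ci <- (state$path[1] - 1L) * 9L + (state$path[2] - 1L) * 3L + target
      state <- push_output(state, layout$chars[ci])
      state$path <- integer(0)
    }
  } else {
    if (target == layout$undo_target) {
      state <- pop_output(state)
    } else if (target %in% layout$suggestion_targets) {
      slot <- target - layout$suggestion_targets[1] + 1L
      word <- if (slot <= length(state$suggestions)) state$suggestions[slot]
              else NA_character_
      if (!is.na(word) && nzchar(word)) {
        prefix <- split_context(state$typed)$prefix
        if (startsWith(word, prefix)) {
          state <- push_output(
            state, paste0(substr(word, nchar(prefix) + 1, nchar(word)), "_"))
        } else state <- push_output(state, "")        # stale suggestion
      } else state <- push_output(state, "")          # empty slot: no text
    } else {
      state <- push_output(state, layout$chars[target])
    }
  }
  state$last_selection <- target
  if (!is.null(model) && layout$kind == "thirty_two_target") {
    ctx <- split_context(state$typed)
    state$suggestions <- suggest(model, ctx$prev, ctx$prefix)
  }
  state
}

normalize_corpus_line <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Train a bigram word-prediction model
#'
#' Builds word frequency and ordered word-pair counts from a corpus of
#' sentences (one sentence per element), the structure behind the
#' 32-target speller's three suggestion slots.
#'
#' @param corpus Character vector of sentences; normalized to uppercase
#'   A-Z words.
#' @return A `cvep_bigram_model`: `unigram` (named counts), `bigram`
#'   (named counts, names `"PREV NEXT"`), `vocab`, `n_pairs`.
#' @export
train_bigram <- function(corpus) {
  if (!is.character(corpus) || length(corpus) == 0)
    stop("`corpus` must be a non-empty character vector")
  sent <- lapply(corpus, function(s) {
    w <- strsplit(normalize_corpus_line(s), " ")[[1]]
    w[nzchar(w)]
  })
  words <- unlist(sent)
  if (length(words) == 0) stop("empty model: corpus contains no words")
  pairs <- unlist(lapply(sent, function(w) {
    if (length(w) < 2) character(0)
    else paste(w[-length(w)], w[-1])
  }))
  uni <- table(words)
  structure(
    list(unigram = setNames(as.numeric(uni), names(uni)),
         bigram = if (length(pairs)) {
           bt <- table(pairs); setNames(as.numeric(bt), names(bt))
         } else setNames(numeric(0), character(0)),
         vocab = sort(names(uni)), n_pairs = length(pairs)),
    class = "cvep_bigram_model")
}

#' Dictionary suggestions for the current context
#'
#' Words matching the current prefix, ranked by bigram probability given
#' the previously spelled word; words unseen after that context (or when
#' the context itself is unseen) fall back to unigram frequency. Ties break
#' alphabetically for determinism.
#'
#' @param model A `cvep_bigram_model`.
#' @param previous_word Last completed word (`""` at sentence start).
#' @param prefix Current partial word (uppercase; `""` matches all words).
#' @param n Maximum number of suggestions (default 3).
#' @return Character vector of up to `n` words (possibly empty).
#' @export
suggest <- function(model, previous_word = "", prefix = "", n = 3) {
  stopifnot(inherits(model, "cvep_bigram_model"))
  cand <- model$vocab[startsWith(model$vocab, prefix)]
  if (length(cand) == 0) return(character(0))
  big <- model$bigram[paste(previous_word, cand)]
  big[is.na(big)] <- 0
  uni <- model$unigram[cand]
  ord <- order(-big, -uni, cand)
  utils::head(cand[ord], n)
}

# Tree path (group, subgroup, position) for a 4-target character index.
char_path4 <- function(ci) {
  g <- ((ci - 1L) %/% 9L) + 1L
  r <- ci - (g - 1L) * 9L
  sg <- ((r - 1L) %/% 3L) + 1L
  c(g, sg, r - (sg - 1L) * 3L)
}

#' Greedy intent policy for copy-spelling simulation
#'
#' Returns the target a user aiming for `goal` would select next: undo
#' whenever the typed text is not a prefix of the goal (or, in the 4-target
#' tree, whenever the current branch cannot reach the next character); in
#' dictionary mode a suggestion slot whose word completes the goal's
#' current word (including the trailing underscore); otherwise the next
#' character (its tree branch for the 4-target layout).
#'
#' @param state A `cvep_speller_state`.
#' @param layout A `cvep_speller_layout`.
#' @param goal Goal text (spaces are treated as underscores).
#' @param dictionary If `TRUE` (32-target), suggestion slots may be chosen.
#' @return Target index in `1..K`.
#' @export
intended_target <- function(state, layout, goal, dictionary = FALSE) {
  stopifnot(inherits(state, "cvep_speller_state"),
            inherits(layout, "cvep_speller_layout"))
  goal <- gsub(" ", "_", toupper(goal))
  typed <- state$typed
  if (!startsWith(goal, typed)) return(layout$undo_target)
  if (nchar(typed) >= nchar(goal))
    stop("goal already spelled; nothing to select")
  nxt <- substr(goal, nchar(typed) + 1, nchar(typed) + 1)
  ci <- match(nxt, layout$chars)
  if (is.na(ci)) stop("task character not representable: '", nxt, "'")

  if (layout$kind == "four_target") {
    p <- char_path4(ci)
    depth <- length(state$path)
    if (depth > 0 && !identical(state$path, p[seq_len(depth)]))
      return(layout$undo_target)                       # wrong branch: back up
    return(p[depth + 1L])
  }

  if (dictionary && length(state$suggestions)) {
    # full goal word being typed right now
    before <- nchar(typed) - nchar(split_context(typed)$prefix)
    rest <- substr(goal, before + 1, nchar(goal))
    word <- sub("[_.].*$", "", rest)
    # selecting a suggestion appends word + "_": only useful if the goal
    # actually continues with an underscore after this word
    follows <- substr(goal, before + nchar(word) + 1, before + nchar(word) + 1)
    if (nzchar(word) && follows == "_") {
      hit <- match(word, state$suggestions)
      if (!is.na(hit)) return(layout$suggestion_targets[hit])
    }
  }
  ci
}

#' Simulate a copy-spelling session
#'
#' Runs the greedy intent policy against a per-selection error model until
#' the goal text is typed: each selection is the intended target with
#' probability `accuracy`, otherwise uniform over the other `K - 1`
#' targets; every error is subsequently corrected through the undo
#' mechanics. With `accuracy = 1` and no dictionary, the pangram task
#' takes exactly one selection per character (32-target) or three
#' (4-target).
#'
#' @param layout A `cvep_speller_layout` (or 4/32).
#' @param task Goal text; spaces become underscores.
#' @param accuracy Per-selection success probability in (0, 1].
#' @param dictionary Use dictionary suggestions (32-target only).
#' @param model A `cvep_bigram_model` (required when `dictionary = TRUE`).
#' @param seed RNG seed for the error draws.
#' @param max_steps Safety cap on the number of selections.
#' @return A `cvep_spelling_log`: list with `log` (data frame: `intended`,
#'   `actual`, `correct`, `typed`), `final_text`, `n_selections`,
#'   `n_chars`, `completed`.
#' @export
simulate_copy_spelling <- function(layout, task, accuracy = 1,
                                   dictionary = FALSE, model = NULL,
                                   seed = 1, max_steps = 10000) {
  if (!inherits(layout, "cvep_speller_layout")) layout <- speller_layout(layout)
  if (!is.numeric(accuracy) || accuracy <= 0 || accuracy > 1)
    stop("`accuracy` must be in (0, 1]")
  if (dictionary && layout$kind != "thirty_two_target")
    stop("dictionary mode requires the 32-target layout")
  if (dictionary && is.null(model))
    stop("dictionary mode requires a bigram model")
  goal <- gsub(" ", "_", toupper(task))
  bad <- setdiff(unique(strsplit(goal, "")[[1]]), layout$chars)
  if (length(bad))
    stop("task characters not representable in this layout: ",
         paste(bad, collapse = ", "))
  with_seed(seed, {
    state <- new_speller_state()
    if (dictionary) {
      ctx <- split_context(state$typed)
      state$suggestions <- suggest(model, ctx$prev, ctx$prefix)
    }
    rows <- vector("list", 0)
    while (state$typed != goal && length(rows) < max_steps) {
      intended <- intended_target(state, layout, goal, dictionary = dictionary)
      actual <- if (accuracy >= 1 || stats::runif(1) < accuracy) intended
                else sample(setdiff(seq_len(layout$K), intended), 1)
      state <- apply_selection(state, layout, actual,
                               model = if (dictionary) model)
      rows[[length(rows) + 1L]] <-
        data.frame(intended = intended, actual = actual,
                   correct = intended == actual, typed = state$typed)
    }
    completed <- state$typed == goal
    if (!completed)
      warning("spelling did not complete within ", max_steps, " selections")
    structure(
      list(log = do.call(rbind, rows), final_text = state$typed,
           n_selections = length(rows), n_chars = nchar(goal),
           completed = completed, task = goal, layout = layout$kind),
      class = "cvep_spelling_log")
  })
}

#' @export
print.cvep_spelling_log <- function(x, ...) {
  cat("copy-spelling (", x$layout, "): \"", x$task, "\" in ",
      x$n_selections, " selections, accuracy ",
      signif(mean(x$log$correct), 4), "\n", sep = "")
  invisible(x)
}

#' Copy spelling with the decoder in the loop
#'
#' Replaces the per-selection error model by the full pipeline: for every
#' step the greedy intent policy picks a target, a code-locked stream
#' segment for that target is synthesized, and the asynchronous decoder's
#' selection (or timeout) drives the speller state machine.
#'
#' @param layout A `cvep_speller_layout` whose `K` matches the decoder.
#' @param task Goal text.
#' @param decoder A trained `cvep_decoder_model`.
#' @param forward_model The `cvep_forward_model` generating the EEG.
#' @param seed RNG seed.
#' @param dictionary,model As in [simulate_copy_spelling()].
#' @param max_steps Safety cap on selections.
#' @param max_dwell Per-selection flicker cap in seconds.
#' @return A `cvep_spelling_log` with an extra `selection_time` column.
#' @export
spell_with_decoder <- function(layout, task, decoder, forward_model,
                               seed = 1, dictionary = FALSE, model = NULL,
                               max_steps = 500, max_dwell = 10) {
  if (!inherits(layout, "cvep_speller_layout")) layout <- speller_layout(layout)
  stopifnot(inherits(decoder, "cvep_decoder_model"))
  if (layout$K != decoder$codebook$K)
    stop("layout K and decoder K differ")
  goal <- gsub(" ", "_", toupper(task))
  with_seed(seed, {
    state <- new_speller_state()
    if (dictionary && !is.null(model)) {
      ctx <- split_context(state$typed)
      state$suggestions <- suggest(model, ctx$prev, ctx$prefix)
    }
    rows <- vector("list", 0)
    while (state$typed != goal && length(rows) < max_steps) {
      intended <- intended_target(state, layout, goal, dictionary = dictionary)
      stream <- simulate_online_stream(forward_model, decoder$codebook,
                                       intents = intended, seed = NULL,
                                       max_duration = max_dwell)
      ses <- run_session(stream, decoder, max_dwell = max_dwell)
      if (!ses$decided[1]) {
        rows[[length(rows) + 1L]] <-
          data.frame(intended = intended, actual = NA_integer_,
                     correct = FALSE, typed = state$typed,
                     selection_time = NA_real_)
        next                                          # non-control: no output
      }
      actual <- ses$class[1]
      state <- apply_selection(state, layout, actual,
                               model = if (dictionary) model)
      rows[[length(rows) + 1L]] <-
        data.frame(intended = intended, actual = actual,
                   correct = intended == actual, typed = state$typed,
                   selection_time = ses$selection_time[1])
    }
    completed <- state$typed == goal
    if (!completed)
      warning("spelling did not complete within ", max_steps, " selections")
    structure(
      list(log = do.call(rbind, rows), final_text = state$typed,
           n_selections = length(rows), n_chars = nchar(goal),
           completed = completed, task = goal, layout = layout$kind),
      class = "cvep_spelling_log")
  })
}

#' Load a plain-text corpus
#'
#' One sentence per line, UTF-8. Without a path, the bundled toy corpus of
#' everyday English sentences (a stand-in for a large web corpus) is
#' loaded.
#'
#' @param path Optional path to a corpus file.
#' @return Character vector of sentences.
#' @export
load_corpus <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "toy_corpus.txt", package = "cvepr")
  if (!nzchar(path) || !file.exists(path)) stop("corpus file not found")
  readLines(path, encoding = "UTF-8")
}
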