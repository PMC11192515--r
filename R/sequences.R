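#' Define a stimulus category
#'
#' A category is a labelled set of item identifiers, e.g. 32 words or 32
#' pseudofont strings. Categories are the building blocks of frequency-tagged
#' stimulation sequences: in an experimental trial two categories alternate at
#' the base presentation rate, so each category recurs at half that rate.
#'
#' @param label Short category label (single string).
#' @param items Character vector of unique item identifiers, length >= 2.
#' @return An object of class `stimulus_category`.
#' @export
#' @examples
#' stimulus_category("words", paste0("w", 1:32))
stimulus_category <- function(label, items) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a non-empty string", call. = FALSE)
  }
  items <- as.character(items)
  if (length(items) < 2L) stop("a category needs at least 2 items", call. = FALSE)
  if (anyDuplicated(items)) stop("item identifiers must be unique within a category", call. = FALSE)
  structure(list(label = label, items = items), class = "stimulus_category")
}

#' @export
print.stimulus_category <- function(x, ...) {
  cat(sprintf("<stimulus_category> '%s' with %d items\n", x$label, length(x$items)))
  invisible(x)
}

# Random permutation of `reps` copies of `items` with no two equal items
# adjacent, by bounded rejection sampling.
no_adjacent_shuffle <- function(items, reps, max_tries = 1000L) {
  pool <- rep(items, times = reps)
  if (length(items) == 1L && reps > 1L) {
    stop("cannot avoid adjacent repeats: single-item category with reps > 1", call. = FALSE)
  }
  for (i in seq_len(max_tries)) {
    cand <- sample(pool)
    if (!any(cand[-1L] == cand[-length(cand)])) return(cand)
  }
  stop("could not satisfy the no-adjacent-repeat constraint after bounded retries", call. = FALSE)
}

#' Generate a frequency-tagged stimulation sequence
#'
#' Builds the ordered token stream for one trial. In `uniform` mode (the
#' baseline design, xxxxxx) all tokens come from one category; in
#' `alternating` mode (the experimental design, XYXYXY) tokens from two
#' categories strictly alternate, so the second category is embedded as a
#' periodic oddball at half the presentation rate. Each item of every used
#' category appears exactly `reps` times, pseudo-randomized so the same item
#' never occurs twice in a row.
#'
#' @param cat_a A [stimulus_category()]; the only category in uniform mode,
#'   the first (odd positions) in alternating mode.
#' @param cat_b Second [stimulus_category()] (alternating mode only).
#' @param reps Number of repetitions of each item (>= 1).
#' @param mode `"uniform"` or `"alternating"`.
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @return An object of class `trial_sequence` with fields `tokens`,
#'   `category_of` (named character vector token -> label), `mode`, `seed`.
#' @export
#' @examples
#' cat_nw <- stimulus_category("nonwords", paste0("nw", 1:32))
#' seq1 <- generate_sequence(cat_nw, reps = 5, mode = "uniform", seed = 1)
#' length(seq1$tokens)  # 160
generate_sequence <- function(cat_a, cat_b = NULL, reps, mode = c("uniform", "alternating"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (!inherits(cat_a, "stimulus_category")) stop("`cat_a` must be a stimulus_category", call. = FALSE)
  stopifnot_scalar_number(reps, "reps", positive = TRUE)
  if (reps != round(reps)) stop("`reps` must be a whole number", call. = FALSE)
  reps <- as.integer(reps)

  tokens <- with_seed(seed, {
    if (mode == "uniform") {
      no_adjacent_shuffle(cat_a$items, reps)
    } else {
      if (is.null(cat_b)) stop("alternating mode requires `cat_b`", call. = FALSE)
      if (!inherits(cat_b, "stimulus_category")) stop("`cat_b` must be a stimulus_category", call. = FALSE)
      if (length(cat_a$items) != length(cat_b$items)) {
        stop("alternating mode requires categories of equal size", call. = FALSE)
      }
      if (identical(cat_a$label, cat_b$label)) {
        stop("alternating categories must have distinct labels", call. = FALSE)
      }
      a <- no_adjacent_shuffle(cat_a$items, reps)
      b <- no_adjacent_shuffle(cat_b$items, reps)
      out <- character(2L * length(a))
      out[seq(1L, by = 2L, length.out = length(a))] <- a
      out[seq(2L, by = 2L, length.out = length(b))] <- b
      out
    }
  })

  category_of <- c(
    stats::setNames(rep(cat_a$label, length(cat_a$items)), cat_a$items),
    if (!is.null(cat_b)) stats::setNames(rep(cat_b$label, length(cat_b$items)), cat_b$items)
  )

  structure(
    list(tokens = tokens, category_of = category_of, mode = mode, seed = as.integer(seed)),
    class = "trial_sequence"
  )
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf(
    "<trial_sequence> %d tokens, mode = %s, %d categories\n",
    length(x$tokens), x$mode, length(unique(x$category_of))
  ))
  invisible(x)
}

#' Category labels along a trial sequence
#'
#' @param x A `trial_sequence`.
#' @return Character vector of category labels, one per token.
#' @export
sequence_labels <- function(x) {
  if (!inherits(x, "trial_sequence")) stop("`x` must be a trial_sequence", call. = FALSE)
  unname(x$category_of[x$tokens])
}
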