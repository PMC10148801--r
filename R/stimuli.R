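#' Generate a balanced stimulus set
#'
#' Builds the stimulus inventory used throughout a session: `n_categories`
#' semantic categories of `n_exemplars` images each, with half of the
#' categories assigned to the "manmade" meta-category and half to "natural".
#' The default 10 x 10 layout yields the canonical 100-image inventory.
#'
#' @param n_categories Number of semantic categories (must be even so the
#'   manmade/natural split is balanced).
#' @param n_exemplars Number of exemplar images per category.
#' @param seed Optional integer; makes the meta-category assignment (and
#'   nothing else) reproducible.
#'
#' @return An object of class `stimulus_set`: a list with elements
#'   `stimuli` (character ids), `category_of` (named integer, one category
#'   id per stimulus), `meta_of` (named character, `"manmade"`/`"natural"`
#'   per category), `n_categories`, `n_exemplars`.
#' @examples
#' ss <- generate_stimulus_set(10, 10, seed = 1)
#' length(ss$stimuli)            # 100
#' table(ss$meta_of)             # 5 manmade, 5 natural
#' @export
generate_stimulus_set <- function(n_categories = 10, n_exemplars = 10,
                                  seed = NULL) {
  if (!is.numeric(n_categories) || n_categories < 2 ||
      n_categories %% 2 != 0) {
    stop("`n_categories` must be an even number >= 2", call. = FALSE)
  }
  if (!is.numeric(n_exemplars) || n_exemplars < 1) {
    stop("`n_exemplars` must be >= 1", call. = FALSE)
  }
  n_categories <- as.integer(n_categories)
  n_exemplars <- as.integer(n_exemplars)
  with_seed(seed, {
    cats <- seq_len(n_categories)
    manmade <- sort(sample(cats, n_categories %/% 2L))
    meta <- ifelse(cats %in% manmade, "manmade", "natural")
    names(meta) <- as.character(cats)
    stimuli <- sprintf("c%02d_e%02d", rep(cats, each = n_exemplars),
                       rep(seq_len(n_exemplars), times = n_categories))
    category_of <- rep(cats, each = n_exemplars)
    names(category_of) <- stimuli
    structure(
      list(stimuli = stimuli, category_of = category_of, meta_of = meta,
           n_categories = n_categories, n_exemplars = n_exemplars),
      class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli: %d categories x %d exemplars (%s)\n",
              length(x$stimuli), x$n_categories, x$n_exemplars,
              paste(sprintf("%d %s", table(x$meta_of),
                            names(table(x$meta_of))), collapse = ", ")))
  invisible(x)
}

# Meta-category of each stimulus id.
#' @noRd
meta_of_stimulus <- function(stim_set, stimulus) {
  unname(stim_set$meta_of[as.character(stim_set$category_of[stimulus])])
}
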