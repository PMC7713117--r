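AXCPT_LETTERS <- c("A", "E", "F", "H", "L", "N", "T", "V", "X", "Y", "Z")
AXCPT_FONT_SIZES <- c(100L, 120L, 140L, 160L, 180L)

#' Generate an AX-CPT trial sequence
#'
#' Builds a continuous-performance-task block in which a response is required
#' to the letter X only when it immediately follows the letter A. The block
#' contains an exact number of AX target pairs, A* catch pairs (A followed by
#' a non-X letter) and *X catch pairs (X preceded by a non-A letter); the
#' default composition is 7.5% of trials for each pair class, i.e. 60 of each
#' in an 800-trial block. Counts are exact by construction, not expected
#' values: pairs are laid down as two-trial blocks and filler letters are
#' drawn from the letter set excluding A and X, so no accidental A->X
#' adjacency (and no surplus pair of any class) can arise.
#'
#' The pair-class label is carried on the second trial of each pair; cue
#' trials (the A of a pair) and fillers are labelled `"filler"`. Letters come
#' from the angular letter set A, E, F, H, L, N, T, V, X, Y, Z; font size is
#' uniform over {100, 120, 140, 160, 180} points and the inter-stimulus
#' interval uniform over 500-1000 ms.
#'
#' @param n_trials Number of trials (default 800).
#' @param pair_fractions Proportions of trials that are AX, A* and *X pairs
#'   (each fraction times `n_trials` must be a whole number).
#' @param seed Integer seed; the same `(n_trials, pair_fractions, seed)`
#'   reproduce the identical sequence.
#' @return A tibble with one row per trial: `trial`, `letter`, `font_size`,
#'   `isi_ms`, `pair_class` (factor: `ax_target`, `a_star`, `star_x`,
#'   `filler`), and `is_cue_a` / `is_target_x` helper flags.
#' @examples
#' seq <- generate_task_sequence(800, seed = 1)
#' table(seq$pair_class)
#' @export
generate_task_sequence <- function(n_trials = 800,
                                   pair_fractions = c(
                                     ax = 0.075, a_star = 0.075, star_x = 0.075
                                   ),
                                   seed = 1) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop_invalid("n_trials must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  if (length(pair_fractions) != 3L || any(pair_fractions < 0) ||
    sum(pair_fractions) > 1) {
    stop_invalid("pair_fractions must be three proportions summing to <= 1")
  }
  counts <- n_trials * pair_fractions
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop_invalid(
      "each pair fraction times n_trials must be an integer (got %s)",
      paste(format(counts), collapse = ", ")
    )
  }
  counts <- as.integer(round(counts))
  if (2L * sum(counts) > n_trials) {
    stop_invalid("pair classes need %d trials but block has %d", 2L * sum(counts), n_trials)
  }
  other <- setdiff(AXCPT_LETTERS, c("A", "X")) # fillers can never seed a pair
  n_fill <- n_trials - 2L * sum(counts)

  with_seed(seed, {
    # two-trial pair units + single filler units, shuffled
    units <- c(
      rep("ax", counts[1]), rep("a_star", counts[2]),
      rep("star_x", counts[3]), rep("fill", n_fill)
    )
    units <- sample(units)
    letter <- character(n_trials)
    pair_class <- rep("filler", n_trials)
    i <- 1L
    for (u in units) {
      if (u == "ax") {
        letter[i] <- "A"
        letter[i + 1L] <- "X"
        pair_class[i + 1L] <- "ax_target"
        i <- i + 2L
      } else if (u == "a_star") {
        letter[i] <- "A"
        letter[i + 1L] <- sample(other, 1L)
        pair_class[i + 1L] <- "a_star"
        i <- i + 2L
      } else if (u == "star_x") {
        letter[i] <- sample(other, 1L)
        letter[i + 1L] <- "X"
        pair_class[i + 1L] <- "star_x"
        i <- i + 2L
      } else {
        letter[i] <- sample(other, 1L)
        i <- i + 1L
      }
    }
    tibble::tibble(
      trial = seq_len(n_trials),
      letter = letter,
      font_size = sample(AXCPT_FONT_SIZES, n_trials, replace = TRUE),
      isi_ms = runif(n_trials, 500, 1000),
      pair_class = factor(pair_class,
        levels = c("ax_target", "a_star", "star_x", "filler")
      ),
      is_cue_a = letter == "A",
      is_target_x = letter == "X"
    )
  })
}
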