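#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble as_tibble
#' @importFrom stats qt qf sd var cor.test pt pf quantile rnorm runif rbinom
#'   rlnorm aov p.adjust setNames complete.cases
#' @importFrom utils head
NULL

# consistent invalid-argument errors (class used by tests)
stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "erpcluster_invalid_argument")
}

# all windows are closed [lo, hi] in ms and mapped to nearest samples
ms_to_sample <- function(ms, sfreq, t_start) {
  as.integer(round((ms / 1000 - t_start) * sfreq)) + 1L
}

sample_times <- function(n, sfreq, t_start) {
  t_start + (seq_len(n) - 1L) / sfreq
}

# closed-interval window -> sample index range; length = round(span*sfreq)+1
window_to_idx <- function(window_ms, sfreq, t_start, n_samples) {
  if (length(window_ms) != 2L || window_ms[2] < window_ms[1]) {
    stop_invalid("window must be (lo, hi) ms with lo <= hi")
  }
  i0 <- ms_to_sample(window_ms[1], sfreq, t_start)
  i1 <- i0 + as.integer(round(diff(window_ms) / 1000 * sfreq))
  if (i0 < 1L || i1 > n_samples) {
    stop_invalid(
      "window [%g, %g] ms lies outside the epoch (%g to %g ms)",
      window_ms[1], window_ms[2], t_start * 1000,
      (t_start + (n_samples - 1) / sfreq) * 1000
    )
  }
  i0:i1
}

# derive a stream-specific 32-bit seed from a master seed (exact in doubles)
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483562) * 30269 + stream * 12345) %%
    2147483562)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
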