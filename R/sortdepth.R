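#' Binomial sorting-depth capture model
#'
#' When a flow sorter collects `N` events from a community in which a taxon of
#' interest is present at prevalence `p`, the number of cells of that taxon
#' captured is `X ~ Binomial(N, p)`. These functions answer the design
#' questions behind choosing a sorting depth: how likely is it that at least
#' `k` cells of a taxon at prevalence `p` end up in the sorted pool, how many
#' are captured on average, and how many events must be sorted to reach a
#' target capture with given confidence.
#'
#' `capture_probability()` returns the upper tail `P(X >= k)`, computed through
#' the regularised incomplete beta function (`pbinom` lower tail complement),
#' which is numerically stable for large `N`.
#'
#' An optional gate error purity adjustment replaces `p` by
#' `p * (1 - gate_error)`, modelling the fact that a fraction of sorted events
#' are not truly in the gated class.
#'
#' @param N number of sorted events (non-negative integer).
#' @param p taxon prevalence in the population, in `[0, 1]`.
#' @param k required number of captured cells (non-negative integer).
#' @param gate_error probability that a sorted event is not truly in-gate;
#'   default 0 (no purity adjustment).
#' @return `capture_probability()`: the probability of capturing at least `k`
#'   cells. `expected_capture()`: the expectation `N * p`. `min_events()`: the
#'   smallest `N` such that `P(X >= k) >= confidence`.
#' @examples
#' capture_probability(25000, 0.005, 100)
#' expected_capture(180000, 0.005)
#' min_events(0.005, 100, 0.95)
#' @export
capture_probability <- function(N, p, k, gate_error = 0) {
  if (length(N) != 1 || !is.finite(N) || N < 0 || N != floor(N))
    stopf("`N` must be a single non-negative integer")
  assert_prob(p, "p")
  assert_prob(gate_error, "gate_error")
  if (length(k) != 1 || !is.finite(k) || k < 0 || k != floor(k))
    stopf("`k` must be a single non-negative integer")
  p_eff <- p * (1 - gate_error)
  if (k == 0) return(1)
  if (k > N) return(0)
  stats::pbinom(k - 1, size = N, prob = p_eff, lower.tail = FALSE)
}

#' @rdname capture_probability
#' @export
expected_capture <- function(N, p, gate_error = 0) {
  assert_prob(p, "p")
  assert_prob(gate_error, "gate_error")
  N * p * (1 - gate_error)
}

#' @rdname capture_probability
#' @param confidence required probability of capturing at least `k` cells,
#'   in `(0, 1)`.
#' @export
min_events <- function(p, k, confidence, gate_error = 0) {
  assert_prob(p, "p")
  if (p * (1 - gate_error) <= 0)
    stopf("no sorting depth can capture cells at effective prevalence 0")
  if (length(confidence) != 1 || confidence <= 0 || confidence >= 1)
    stopf("`confidence` must lie strictly between 0 and 1")
  # tail probability is nondecreasing in N: double to bracket, then bisect
  hi <- max(k, 1L)
  while (capture_probability(hi, p, k, gate_error) < confidence) {
    hi <- hi * 2L
    if (hi > 2^40) stopf("no feasible sorting depth below 2^40 events")
  }
  lo <- k  # P(X >= k) at N = k - 1 is 0 < confidence, so k is a lower fence
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (capture_probability(mid, p, k, gate_error) >= confidence) hi <- mid else lo <- mid + 1
  }
  as.numeric(lo)
}

#' Sorting-depth design table
#'
#' Convenience summary for a design point: expected capture, tail probability,
#' and the minimal depth achieving a set of confidence levels.
#'
#' @inheritParams capture_probability
#' @param confidences confidence levels to tabulate minimal depths for.
#' @return a list with `expected`, `prob_at_least_k`, and a data frame
#'   `min_events` (confidence, N).
#' @export
sortdepth_design <- function(N, p, k, confidences = c(0.5, 0.8, 0.95, 0.99)) {
  list(
    expected = expected_capture(N, p),
    prob_at_least_k = capture_probability(N, p, k),
    min_events = data.frame(
      confidence = confidences,
      N = vapply(confidences, function(cf) min_events(p, k, cf), numeric(1))
    )
  )
}
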