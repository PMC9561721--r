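# Independent brute-force oracles. These enumerate subsets directly with
# utils::combn and never touch stats::phyper, so they stay independent of the
# implementation path they check.

# Exhaustive hypergeometric tails: draw n2 of N items where items 1..n1 are
# marked; overlap distribution by enumeration of all C(N, n2) draws.
enum_hyper <- function(N, n1, n2) {
  if (n2 == 0L) {
    counts <- 0L
  } else {
    subs <- utils::combn(N, n2)
    counts <- colSums(subs <= n1)
  }
  list(
    upper = function(k) mean(counts >= k),
    lower = function(k) mean(counts <= k),
    ks = sort(unique(counts))
  )
}

# Enumeration-backed signed RRHO cell value for explicit orderings.
enum_rrho_cell <- function(ord_x, ord_y, tx, ty, N, p_floor = 1e-320) {
  k <- length(intersect(utils::head(ord_x, tx), utils::head(ord_y, ty)))
  or <- enum_hyper(N, ty, tx)  # mark top-ty of y; draw tx
  expected <- tx * ty / N
  if (k > expected) {
    -log10(max(or$upper(k), p_floor))
  } else {
    log10(max(or$lower(k), p_floor))
  }
}
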