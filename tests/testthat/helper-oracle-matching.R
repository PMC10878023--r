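# Independent oracle for stratum matching: exhaustive recursive enumeration
# of all feasible matchings (with a simple cardinality bound for pruning),
# returning the maximum pair count and, among maximum matchings, the
# minimum total age difference. No memoization — a different algorithm from
# the package's DP.

oracle_best_matching <- function(age_a, age_b, max_diff) {
  na <- length(age_a)
  nb <- length(age_b)
  best <- c(count = 0, total = Inf)
  recurse <- function(i, used_b, count, total) {
    if (i > na) {
      if (count > best[["count"]] ||
          (count == best[["count"]] && total < best[["total"]])) {
        best <<- c(count = count, total = total)
      }
      return(invisible())
    }
    # bound: even pairing every remaining sample cannot beat best count
    if (count + min(na - i + 1L, sum(!used_b)) < best[["count"]]) {
      return(invisible())
    }
    for (j in seq_len(nb)) {
      if (!used_b[j] && abs(age_a[i] - age_b[j]) <= max_diff) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L, total + abs(age_a[i] - age_b[j]))
        used_b[j] <- FALSE
      }
    }
    recurse(i + 1L, used_b, count, total)
  }
  recurse(1L, logical(nb), 0L, 0)
  best
}
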