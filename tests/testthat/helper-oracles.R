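# Independent brute-force oracles used across tests.  Deliberately
# written as plain loops, separate from the package's vectorized paths.

# Pairwise scan: number of adjacent unequal calls.
oracle_count_switches <- function(v) {
  n <- 0L
  if (length(v) < 2) return(0L)
  for (i in 2:length(v)) if (v[i] != v[i - 1]) n <- n + 1L
  n
}

# Exhaustive application of the singleton-exclusion rule: flag every
# interior element whose two neighbours both differ from it (flags on
# the original vector), then drop flagged elements in one pass.
oracle_singleton_exclude <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  keep <- rep(TRUE, n)
  for (i in 2:(n - 1))
    if (v[i] != v[i - 1] && v[i] != v[i + 1]) keep[i] <- FALSE
  v[keep]
}

# All HOM/HET vectors of length len as a list.
all_zygosity_vectors <- function(len) {
  if (len == 0) return(list(character(0)))
  grid <- expand.grid(rep(list(c("HOM", "HET")), len),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# Countable recombination events implied by a truth crossover list,
# restricted to the marker grid: a switch between adjacent markers iff
# the interval (pos_k, pos_{k+1}] holds an odd number of crossovers
# (matching the simulator's breakpoint-at-or-before-position phase
# convention); the singleton rule is then applied to the implied state
# vector before the pairwise scan.
oracle_events_from_crossovers <- function(xo_pos, marker_pos) {
  m <- length(marker_pos)
  if (m < 2) return(0L)
  state <- integer(m)
  for (k in 2:m) {
    odd <- sum(xo_pos > marker_pos[k - 1] & xo_pos <= marker_pos[k]) %% 2
    state[k] <- (state[k - 1] + odd) %% 2
  }
  v <- ifelse(state == 0, "HOM", "HET")
  oracle_count_switches(oracle_singleton_exclude(v))
}
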