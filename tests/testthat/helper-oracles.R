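# Independent arithmetic oracle for the abridged life table: a plain
# step-by-step walk of the Chiang recursions using scalar loops, written
# separately from the package implementation.
oracle_e0 <- function(deaths, person_years, widths, a = 0.5, radix = 1e5) {
  n <- length(deaths)
  a <- rep_len(a, n)
  m <- numeric(n)
  for (i in seq_len(n)) m[i] <- if (person_years[i] > 0)
    deaths[i] / person_years[i] else 0
  q <- numeric(n)
  for (i in seq_len(n - 1)) {
    q[i] <- widths[i] * m[i] / (1 + widths[i] * (1 - a[i]) * m[i])
    if (q[i] > 1) q[i] <- 1
  }
  q[n] <- 1
  l <- numeric(n); l[1] <- radix
  for (i in 2:n) l[i] <- l[i - 1] * (1 - q[i - 1])
  L <- numeric(n)
  for (i in seq_len(n - 1)) L[i] <- widths[i] * (l[i] - (1 - a[i]) * l[i] * q[i])
  L[n] <- if (l[n] > 0) l[n] / m[n] else 0
  total <- 0
  for (i in seq_len(n)) total <- total + L[i]
  total / radix
}

# cached lattices shared across tests (eigen decomposition is the slow part)
.lattice_cache <- new.env(parent = emptyenv())
lattice_weights <- function(rows, cols) {
  key <- paste0(rows, "x", cols)
  if (is.null(.lattice_cache[[key]])) {
    w <- row_standardize(grid_queen_contiguity(rows, cols))
    .lattice_cache[[key]] <- list(w = w, ev = weights_eigenvalues(w))
  }
  .lattice_cache[[key]]
}

# one synthetic tract with a realistic death toll, as expected (noise-free)
# counts, for standard-error checks
expected_tract <- function(base_population = 5000) {
  X <- matrix(0, 1, 1, dimnames = list("t1", "x1"))
  sim <- simulate_mortality(X, base_population = base_population,
                            expected = TRUE)
  list(deaths = as.numeric(sim$mortality[1, -1]),
       person_years = person_years_from_population(
         as.numeric(sim$population[1, -1]), 5))
}
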