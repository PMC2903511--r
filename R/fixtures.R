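# Synthetic linear compartment fixtures with closed-form solutions.
# These serve as independent oracles: a random stable compartmental
# system integrates in closed form via the matrix exponential, and the
# same system can be realized as an assembled pbtk_system, so the engine
# can be checked against the closed form.

#' Generate a random linear compartmental fixture
#'
#' Draws a random compartmental rate matrix (Metzler: non-negative
#' off-diagonals; every column strictly diagonally dominated by a
#' first-order leak, so all eigenvalues have negative real part) and a
#' non-negative constant input vector. The closed-form solution
#' `y(t) = e^{At} y0 + A^{-1} (e^{At} - I) b` is attached as a function
#' handle (computed with `Matrix::expm`). Deterministic given `seed`.
#'
#' @param n_states Number of states, >= 1.
#' @param n_inputs Number of states receiving constant input.
#' @param seed Integer seed.
#' @return A `linear_fixture` with fields `A` (1/h), `b` (umol/h),
#'   `leaks` (1/h per state), `seed` and `solution(t, y0)`.
#' @export
generate_linear_fixture <- function(n_states, n_inputs = 1, seed = 1L) {
  if (n_states < 1) stop("n_states must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  A <- matrix(0, n_states, n_states)
  if (n_states > 1) {
    for (j in seq_len(n_states)) {
      targets <- setdiff(seq_len(n_states), j)
      on <- targets[stats::runif(length(targets)) < 0.5]
      if (!length(on)) on <- targets[sample.int(length(targets), 1)]
      A[on, j] <- stats::runif(length(on), 0.05, 2)
    }
  }
  leaks <- stats::runif(n_states, 0.05, 1)
  diag(A) <- -(colSums(A) + leaks)
  b <- numeric(n_states)
  receivers <- sample(seq_len(n_states), min(n_inputs, n_states))
  b[receivers] <- stats::runif(length(receivers), 0.5, 5)
  Ainv_b <- solve(A, b)
  solution <- function(t, y0 = numeric(n_states)) {
    E <- as.matrix(Matrix::expm(A * t))
    drop(E %*% y0 + (E %*% Ainv_b - Ainv_b))
  }
  structure(list(A = A, b = b, leaks = leaks, n_states = n_states,
                 seed = seed, solution = solution),
            class = "linear_fixture")
}

#' Realize a linear fixture as an assembled system
#'
#' Expresses the fixture's rate matrix as one chemical with `n` pool
#' states connected by first-order transfers (off-diagonal entries), a
#' urinary leak per state (the diagonal surplus) and constant oral input
#' (`F_abs = 1`), so integrating the assembled system must reproduce the
#' fixture's closed-form trajectory and close its mass ledger.
#'
#' @param fix A `linear_fixture`.
#' @param body Body physiology used as the carrier (volumes are
#'   irrelevant to the amount dynamics; unit pool volumes are used).
#' @return A `pbtk_system`.
#' @export
fixture_to_system <- function(fix, body = reference_adult()) {
  n <- fix$n_states
  st_names <- paste0("s", seq_len(n))
  chem <- chemical_species("X", 100,
                           lapply(st_names, function(nm)
                             list(compartment = nm, scheme = "pool", volume = 1)))
  tr <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && fix$A[i, j] > 0)
        tr <- c(tr, list(transport_process("first_order_transfer", "X",
                                           source = st_names[j],
                                           destination = st_names[i],
                                           rate = fix$A[i, j])))
    }
    if (fix$leaks[j] > 0)
      tr <- c(tr, list(transport_process("urinary_excretion", "X",
                                         source = st_names[j], rate = fix$leaks[j])))
  }
  exps <- list()
  for (j in which(fix$b > 0)) {
    exps <- c(exps, list(exposure_profile("X", "oral_continuous",
                                          events = list(list(start = 0, end = Inf,
                                                             magnitude = fix$b[j])),
                                          F_abs = 1, target = st_names[j])))
  }
  assemble_system(body, list(chem), transports = tr, exposures = exps)
}
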