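#' Model parameters for the conformational-spread lattice
#'
#' Bundles the parameters of the two-dimensional Ising conformational-spread
#' model: an `L` x `L` free-boundary lattice of allosteric units, each in an
#' active (`sigma = +1`) or inactive (`sigma = -1`) state, with
#' nearest-neighbour coupling `J`, a uniform biasing field `H_b`, a ligand
#' field `H_L` (all in units of kT) and fundamental flip frequency `omega0`.
#' With `omega0 = 1` all simulated times are in units of the fundamental
#' flipping timescale `1/omega0`.
#'
#' Positive fields enter the Hamiltonian as `+(H_b/2 + H_L/2) * sum(sigma)`,
#' so a positive field penalizes the active state: a positive ligand step
#' mimics attractant (kinase inactivation).
#'
#' @param L lattice side (integer, >= 2).
#' @param J nearest-neighbour coupling energy (kT, >= 0).
#' @param H_b uniform biasing field (kT).
#' @param H_L ligand field (kT).
#' @param omega0 fundamental flip frequency (> 0; default 1).
#' @return object of class `model_params`.
#' @export
model_params <- function(L, J, H_b = 0, H_L = 0, omega0 = 1) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 2L)
    stop("L must be a single integer >= 2")
  if (J < 0) stop("J must be >= 0")
  if (omega0 <= 0) stop("omega0 must be > 0")
  structure(list(L = L, J = J, H_b = H_b, H_L = H_L, omega0 = omega0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Conformational-spread model: %d x %d lattice, J = %g kT, H_b = %g, H_L = %g, omega0 = %g\n",
              x$L, x$L, x$J, x$H_b, x$H_L, x$omega0))
  invisible(x)
}

#' Adaptation (methylation feedback) parameters
#'
#' Each unit carries an integer methylation level `m` in `[0, M]` that sets
#' its biasing field `H_b,i = alpha * (m0 - m)`, i.e. methylation favours
#' activity. Active units demethylate at rate `k_B` and inactive units
#' methylate at rate `k_R` (both in units of `omega0`), a negative feedback
#' that adapts the array to a steady-state activity
#' `a0 = k_R / (k_R + k_B)`. Updates that would leave `[0, M]` are
#' suppressed (saturation).
#'
#' @param alpha energy per methylation unit (kT, default 1).
#' @param M maximum methylation level (default 64).
#' @param m0 methylation offset (default `M/8`).
#' @param k_R methylation rate per eligible inactive unit (omega0 units).
#' @param k_B demethylation rate per eligible active unit (omega0 units).
#' @return object of class `adaptation_params`.
#' @export
adaptation_params <- function(alpha = 1, M = 64, m0 = M / 8,
                              k_R = 0.0015, k_B = 0.0015) {
  if (m0 < 0 || m0 > M) stop("m0 must lie in [0, M]")
  if (k_R < 0 || k_B < 0) stop("adaptation rates must be >= 0")
  structure(list(alpha = alpha, M = as.integer(M), m0 = as.integer(round(m0)),
                 k_R = k_R, k_B = k_B),
            class = "adaptation_params")
}

#' Adaptation rate from enzyme copy number
#'
#' Converts a cellular methylation-enzyme copy number and per-enzyme maximum
#' rate into the per-unit (de)methylation rate of the lattice model,
#' `(n_R / L^2) * V_R / omega0` in units of `omega0`.
#'
#' @param n_R number of adaptation enzymes per cell (>= 0).
#' @param V_R maximum methylation rate per enzyme (1/s).
#' @param L lattice side.
#' @param omega0 fundamental flip frequency (1/s).
#' @return rate in omega0 units.
#' @examples
#' compute_adaptation_rates(200, 0.1, 20, 1 / 0.030)  # 0.0015
#' @export
compute_adaptation_rates <- function(n_R, V_R, L, omega0) {
  if (n_R < 0) stop("n_R must be >= 0")
  if (V_R <= 0 || L <= 0 || omega0 <= 0)
    stop("V_R, L and omega0 must be > 0")
  (n_R / L^2) * V_R / omega0
}

#' Build a lattice state
#'
#' Creates an `L` x `L` free-boundary lattice of spins. Spins are stored as
#' an R matrix with +1 (active) / -1 (inactive); the matrix is indexed
#' `[row, col]` with 1-based R indexing.
#'
#' @param params a [model_params()] object.
#' @param init one of `"all_active"`, `"all_inactive"`, `"random"`.
#' @param seed optional RNG seed for `init = "random"`.
#' @return object of class `lattice_state`: list with `spins` (matrix),
#'   `site_bias` (matrix, kT), `time`.
#' @export
build_lattice <- function(params, init = c("all_active", "all_inactive", "random"),
                          seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  init <- match.arg(init)
  L <- params$L
  spins <- switch(init,
    all_active = matrix(1L, L, L),
    all_inactive = matrix(-1L, L, L),
    random = {
      if (!is.null(seed)) set.seed(seed)
      matrix(sample(c(-1L, 1L), L * L, replace = TRUE), L, L)
    })
  structure(list(spins = spins,
                 site_bias = matrix(0, L, L),
                 methylation = NULL,
                 species = NULL,
                 time = 0),
            class = "lattice_state")
}

#' Nearest-neighbour counts of a free-boundary lattice
#'
#' @param L lattice side (>= 2).
#' @return `L` x `L` integer matrix with 2 at corners, 3 at edges, 4 in the
#'   interior.
#' @export
neighbour_counts <- function(L) {
  L <- as.integer(L)
  if (L < 2L) stop("L must be >= 2")
  n <- matrix(4L, L, L)
  n[1, ] <- n[L, ] <- n[, 1] <- n[, L] <- 3L
  n[c(1, L), c(1, L)] <- 2L
  n
}

# sum over neighbours of J_ij * sigma_j for one site (homogeneous J unless
# the state carries per-bond couplings via a species grid)
neighbour_field <- function(state, row, col, params) {
  L <- nrow(state$spins)
  sp <- state$spins
  jmat <- function(r1, c1, r2, c2) {
    if (is.null(state$species)) return(params$J)
    if (state$species[r1, c1] == state$species[r2, c2]) attr(state$species, "J_same")
    else attr(state$species, "J_cross")
  }
  nb <- 0
  if (col > 1) nb <- nb + jmat(row, col, row, col - 1) * sp[row, col - 1]
  if (col < L) nb <- nb + jmat(row, col, row, col + 1) * sp[row, col + 1]
  if (row > 1) nb <- nb + jmat(row, col, row - 1, col) * sp[row - 1, col]
  if (row < L) nb <- nb + jmat(row, col, row + 1, col) * sp[row + 1, col]
  nb
}

site_field <- function(state, row, col, params, adapt = NULL) {
  h <- params$H_b + state$site_bias[row, col]
  if (!is.null(adapt) && !is.null(state$methylation))
    h <- h + adapt$alpha * (adapt$m0 - state$methylation[row, col])
  h
}

#' Total configurational energy of a lattice state
#'
#' Evaluates the Hamiltonian `-J * sum_<ij> sigma_i sigma_j +
#' sum_i (H_b,i/2 + H_L/2) sigma_i` (kT) over all nearest-neighbour bonds of
#' the free-boundary lattice, with the per-site field actually in effect
#' (uniform field plus any per-site bias).
#'
#' @param state a `lattice_state`.
#' @param params a [model_params()] object.
#' @param adapt optional [adaptation_params()] if the state carries
#'   methylation levels.
#' @return energy in kT.
#' @export
total_energy <- function(state, params, adapt = NULL) {
  sp <- state$spins
  L <- nrow(sp)
  if (is.null(state$species)) {
    bond <- -params$J * (sum(sp[, -L] * sp[, -1]) + sum(sp[-L, ] * sp[-1, ]))
  } else {
    js <- attr(state$species, "J_same"); jc <- attr(state$species, "J_cross")
    Jh <- ifelse(state$species[, -L] == state$species[, -1], js, jc)
    Jv <- ifelse(state$species[-L, ] == state$species[-1, ], js, jc)
    bond <- -(sum(Jh * sp[, -L] * sp[, -1]) + sum(Jv * sp[-L, ] * sp[-1, ]))
  }
  h <- matrix(params$H_b, L, L) + state$site_bias
  if (!is.null(adapt) && !is.null(state$methylation))
    h <- h + adapt$alpha * (adapt$m0 - state$methylation)
  bond + sum((h / 2 + params$H_L / 2) * sp)
}

#' Flip rate of a single site
#'
#' Rate for the unit at `site = c(row, col)` to flip to its opposite state,
#' `omega0 * exp(-sigma_i * sum_j J_ij sigma_j + (H_b,i/2 + H_L/2) sigma_i)`.
#' Together with the Boltzmann measure of the Hamiltonian this satisfies
#' detailed balance exactly.
#'
#' @param state a `lattice_state`.
#' @param site integer vector `c(row, col)`, 1-based.
#' @param params a [model_params()] object.
#' @param adapt optional [adaptation_params()].
#' @return flip rate (1/time).
#' @export
site_flip_rate <- function(state, site, params, adapt = NULL) {
  L <- nrow(state$spins)
  row <- site[1]; col <- site[2]
  if (row < 1 || row > L || col < 1 || col > L) stop("site outside lattice")
  s <- state$spins[row, col]
  nb <- neighbour_field(state, row, col, params)
  h <- site_field(state, row, col, params, adapt)
  params$omega0 * exp(-s * nb + (h / 2 + params$H_L / 2) * s)
}

#' One rejection-free kinetic Monte Carlo step (reference implementation)
#'
#' Draws an exponential waiting time from the total flip rate, selects the
#' flipping site with probability proportional to its rate, and returns the
#' updated state. This pure-R path mirrors the compiled event loop and is
#' intended for small lattices and verification; long simulations should use
#' [simulate_activity()].
#'
#' @param state a `lattice_state`.
#' @param params a [model_params()] object.
#' @return list with `state` (spin flipped, `time` advanced) and
#'   `waiting_time`.
#' @export
kmc_step <- function(state, params) {
  L <- nrow(state$spins)
  rates <- matrix(0, L, L)
  for (r in seq_len(L)) for (c in seq_len(L))
    rates[r, c] <- site_flip_rate(state, c(r, c), params)
  total <- sum(rates)
  if (!is.finite(total) || total <= 0) stop("total event rate vanished")
  wait <- rexp(1, rate = total)
  k <- sample.int(L * L, 1, prob = as.vector(rates))
  row <- (k - 1) %% L + 1; col <- (k - 1) %/% L + 1
  state$spins[row, col] <- -state$spins[row, col]
  state$time <- state$time + wait
  list(state = state, waiting_time = wait)
}

#' Exact equilibrium distribution by enumeration
#'
#' Enumerates all `2^(L^2)` spin configurations of a tiny lattice and returns
#' their Boltzmann probabilities `exp(-H)/Z`. Intended as a brute-force
#' oracle for the stochastic dynamics; refuses lattices larger than 3 x 3.
#'
#' @param params a [model_params()] object with `L <= 3`.
#' @return data.frame with configuration `code` (bitmask over active sites,
#'   column-major within the spin matrix), `activity`, `energy` and
#'   probability `p`.
#' @export
exact_equilibrium <- function(params) {
  L <- params$L
  if (L > 3) stop("enumeration limited to L <= 3 (combinatorial explosion)")
  N <- L * L
  ncfg <- 2^N
  code <- 0:(ncfg - 1)
  energy <- numeric(ncfg)
  activity <- numeric(ncfg)
  st <- build_lattice(params, "all_inactive")
  for (k in code) {
    bits <- as.integer(intToBits(k))[seq_len(N)]
    st$spins <- matrix(2L * bits - 1L, L, L)
    energy[k + 1] <- total_energy(st, params)
    activity[k + 1] <- mean(bits)
  }
  w <- exp(-(energy - min(energy)))
  data.frame(code = code, activity = activity, energy = energy, p = w / sum(w))
}

#' Assign receptor species for bond disorder
#'
#' Labels each lattice site i.i.d. as species 1 ("Tar") with probability
#' `tar_fraction`, else species 0 ("Tsr"), emulating a well-mixed two-species
#' array. Bonds between like sites use `J_same`, unlike sites `J_cross`.
#'
#' @param L lattice side.
#' @param tar_fraction probability a site is species 1 (in `[0, 1]`).
#' @param J_same coupling for like-species bonds (kT).
#' @param J_cross coupling for unlike-species bonds (kT).
#' @param seed optional RNG seed.
#' @return integer `L` x `L` matrix of labels (0/1) with attributes
#'   `J_same`, `J_cross`.
#' @export
assign_species <- function(L, tar_fraction, J_same, J_cross, seed = NULL) {
  if (tar_fraction < 0 || tar_fraction > 1)
    stop("tar_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  sp <- matrix(rbinom(L * L, 1L, tar_fraction), L, L)
  attr(sp, "J_same") <- J_same
  attr(sp, "J_cross") <- J_cross
  sp
}
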