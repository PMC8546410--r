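#' Folding-run configuration
#'
#' Defaults are the standard two-chain schedule: temperatures 0.01 (hot) and
#' 0.001 (cold), at most 60,000 iterations, a model-exchange attempt every 100
#' iterations and a tag steric-hindrance check every 500 iterations (the run
#' stops early once the cold chain accommodates all tags without hindrance).
#'
#' @param t_hot,t_cold Unitless simulation temperatures, \code{t_hot > t_cold
#'   > 0}.
#' @param max_iterations Maximum MCMC iterations (one proposed move per chain
#'   per iteration).
#' @param exchange_interval Iterations between replica-exchange attempts.
#' @param hindrance_interval Iterations between steric-hindrance checks.
#' @param trace_energies Record the per-iteration energy trace (default TRUE).
#' @return An object of class \code{folding_config}.
#' @export
folding_config <- function(t_hot = 0.01, t_cold = 0.001,
                           max_iterations = 60000L,
                           exchange_interval = 100L,
                           hindrance_interval = 500L,
                           trace_energies = TRUE) {
  if (!(t_hot > t_cold && t_cold > 0)) stop("need t_hot > t_cold > 0")
  if (max_iterations %% exchange_interval != 0L ||
      max_iterations %% hindrance_interval != 0L) {
    stop("intervals must divide max_iterations evenly")
  }
  structure(list(t_hot = t_hot, t_cold = t_cold,
                 max_iterations = as.integer(max_iterations),
                 exchange_interval = as.integer(exchange_interval),
                 hindrance_interval = as.integer(hindrance_interval),
                 trace_energies = isTRUE(trace_energies)),
            class = "folding_config")
}

#' Metropolis acceptance
#'
#' Accepts a proposed modification with probability
#' \eqn{\min\{1, \exp(-\Delta E / T)\}}: energy-decreasing or energy-neutral
#' moves are always accepted, energy-increasing moves with exponentially
#' decaying probability. Uses the R session RNG.
#'
#' @param delta_e Energy difference (proposed minus current).
#' @param temperature Unitless simulation temperature, > 0.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temperature) {
  if (temperature <= 0) stop("temperature must be positive")
  if (delta_e <= 0) return(TRUE)
  stats::runif(1L) < exp(-delta_e / temperature)
}

#' Replica-exchange acceptance
#'
#' Accepts a swap of the two chains' models with probability
#' \eqn{\min\{1, \exp((E_{hot} - E_{cold})(1/T_{hot} - 1/T_{cold}))\}}. With
#' \eqn{T_{hot} > T_{cold}} the exponent is positive exactly when the hot
#' chain holds the lower energy, so beneficial swaps (moving the better model
#' to the stricter chain) are always accepted.
#'
#' @param e_hot,e_cold Current model energies of the two chains.
#' @param t_hot,t_cold Chain temperatures (positive; if equal the swap is
#'   always accepted).
#' @return Logical.
#' @export
exchange_accept <- function(e_hot, e_cold, t_hot, t_cold) {
  if (t_hot <= 0 || t_cold <= 0) stop("temperatures must be positive")
  if (t_hot == t_cold) return(TRUE)
  expo <- (e_hot - e_cold) * (1 / t_hot - 1 / t_cold)
  if (expo >= 0) return(TRUE)
  stats::runif(1L) < exp(expo)
}

# Structural energy (E_reg = 0): cached per chain as a breakdown.
.struct_energy <- function(s, params) total_energy(s, NULL, params)

# Staged proposal evaluation with a sound early reject: when the current
# structure is tag-clear (E_tag = 0), the proposal's E_tag is non-negative,
# so delta_E is at least the delta of the remaining terms; if that alone
# exceeds 40 T the acceptance probability is below exp(-40) and the move is
# rejected without the expensive clearance search. Returns NULL for such
# certain rejects, otherwise the proposal's structural breakdown (E_reg kept
# separately as the move penalty).
.eval_move <- function(cur, e_cur, prop, params, temperature) {
  cand <- cur
  cand$coords <- prop$new_coords
  ct <- contact_energy(cand, params)
  e_ss <- secondary_structure_energy(cand, params)
  e_dsb <- disulfide_energy(cand, params)
  other_new <- unname(ct["E_AA"] + ct["E_sol"]) + e_ss + e_dsb
  e_reg <- regularization_energy(cand, cur$coords, params)
  other_old <- e_cur$E_tot - e_cur$E_tag
  if (e_cur$E_tag == 0 &&
      (other_new + e_reg) - other_old > 40 * temperature) {
    return(NULL)
  }
  e_tag <- tag_energy(cand, params)
  e_new <- structure(list(E_AA = unname(ct["E_AA"]),
                          E_sol = unname(ct["E_sol"]),
                          E_ss = e_ss, E_dsb = e_dsb,
                          E_tag = e_tag, E_reg = 0,
                          E_tot = other_new + e_tag),
                     class = "energy_breakdown")
  list(cand = cand, e_new = e_new,
       delta = (other_new + e_tag + e_reg) - e_cur$E_tot)
}

#' Fold a lattice structure by two-chain Metropolis Monte Carlo
#'
#' Runs two chains from copies of the initial structure at temperatures
#' \code{t_hot} and \code{t_cold}. Each iteration proposes one move per chain
#' (\code{\link{propose_move}}), evaluates the energy difference including
#' the single-step reorganization penalty against the pre-move coordinates,
#' and applies \code{\link{metropolis_accept}}. Every
#' \code{exchange_interval} iterations the chains attempt to swap models
#' (\code{\link{exchange_accept}}); every \code{hindrance_interval} iterations
#' the cold chain is checked for tag steric hindrance and the run stops early
#' once \code{E_tag = 0} there. The returned structure is the
#' hindrance-free structure of lowest recorded \code{E_tot} seen in either
#' chain (or, when no hindrance-free structure was ever seen, the overall
#' lowest-energy structure, flagged accordingly).
#'
#' Deterministic for a fixed \code{seed}.
#'
#' @param initial A valid \code{lattice_structure} (tags applied, if any).
#' @param params An \code{\link{energy_params}}.
#' @param config A \code{\link{folding_config}}.
#' @param seed Optional integer seed.
#' @return A list of class \code{folding_result}: \code{structure},
#'   \code{energy} (breakdown of the returned structure), \code{iterations},
#'   \code{reason} (\code{"clearance"} or \code{"max_iterations"}),
#'   \code{hindrance_free}, \code{exchanges_accepted}, \code{energy_trace}
#'   (iterations x 2 matrix, hot and cold \code{E_tot}), plus the final
#'   chain states (\code{chains}) for continuation runs.
#' @export
fold <- function(initial, params = energy_params(),
                 config = folding_config(), seed = NULL) {
  if (!validate_structure(initial)) stop("invalid initial structure")
  if (!is.null(seed)) set.seed(seed)
  chains <- list(initial, initial)        # 1 = hot, 2 = cold
  temps <- c(config$t_hot, config$t_cold)
  energies <- list(.struct_energy(chains[[1L]], params),
                   .struct_energy(chains[[2L]], params))
  best <- NULL
  best_e <- Inf
  best_any <- chains[[2L]]
  best_any_e <- energies[[2L]]
  note_best <- function(s, e) {
    if (e$E_tot < best_any_e$E_tot) {
      best_any <<- s
      best_any_e <<- e
    }
    if (e$E_tag == 0 && e$E_tot < best_e) {
      best <<- s
      best_e <<- e$E_tot
    }
  }
  note_best(chains[[1L]], energies[[1L]])
  note_best(chains[[2L]], energies[[2L]])

  n_iter <- config$max_iterations
  etrace <- if (config$trace_energies) {
    matrix(NA_real_, n_iter, 2L, dimnames = list(NULL, c("hot", "cold")))
  } else NULL
  exchanges <- 0L
  iter_done <- 0L
  reason <- "max_iterations"

  for (iter in seq_len(n_iter)) {
    for (c_i in 1:2) {
      prop <- propose_move(chains[[c_i]])
      if (isTRUE(prop$valid)) {
        ev <- .eval_move(chains[[c_i]], energies[[c_i]], prop, params,
                         temps[c_i])
        if (!is.null(ev) && metropolis_accept(ev$delta, temps[c_i])) {
          chains[[c_i]] <- ev$cand
          energies[[c_i]] <- ev$e_new
          note_best(ev$cand, ev$e_new)
        }
      }
    }
    if (config$trace_energies) {
      etrace[iter, ] <- c(energies[[1L]]$E_tot, energies[[2L]]$E_tot)
    }
    if (iter %% config$exchange_interval == 0L) {
      if (exchange_accept(energies[[1L]]$E_tot, energies[[2L]]$E_tot,
                          temps[1L], temps[2L])) {
        chains <- chains[2:1]
        energies <- energies[2:1]
        exchanges <- exchanges + 1L
      }
    }
    if (iter %% config$hindrance_interval == 0L) {
      if (energies[[2L]]$E_tag == 0) {
        iter_done <- iter
        reason <- "clearance"
        break
      }
    }
    iter_done <- iter
  }

  hindrance_free <- !is.null(best)
  out_s <- if (hindrance_free) best else best_any
  out_e <- .struct_energy(out_s, params)
  structure(list(structure = out_s,
                 energy = out_e,
                 iterations = iter_done,
                 reason = reason,
                 hindrance_free = hindrance_free,
                 exchanges_accepted = exchanges,
                 energy_trace = if (is.null(etrace)) NULL else {
                   etrace[seq_len(iter_done), , drop = FALSE]
                 },
                 chains = chains,
                 params = params,
                 config = config),
            class = "folding_result")
}

#' @export
print.folding_result <- function(x, ...) {
  cat("folding_result:", x$iterations, "iterations, stopped on", x$reason,
      "\n")
  cat("  hindrance-free:", x$hindrance_free, "\n")
  print(x$energy)
  invisible(x)
}

# Continue a single chain at one temperature, returning snapshots every
# `interval` accepted-or-not iterations. Used for fingerprint sampling.
.continue_chain <- function(s, params, temperature, n_steps, interval) {
  e_cur <- .struct_energy(s, params)
  snaps <- vector("list", n_steps %/% interval)
  for (step in seq_len(n_steps)) {
    prop <- propose_move(s)
    if (isTRUE(prop$valid)) {
      ev <- .eval_move(s, e_cur, prop, params, temperature)
      if (!is.null(ev) && metropolis_accept(ev$delta, temperature)) {
        s <- ev$cand
        e_cur <- ev$e_new
      }
    }
    if (step %% interval == 0L) snaps[[step %/% interval]] <- s
  }
  snaps
}
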