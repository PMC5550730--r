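#' Synaptic projection parameters
#'
#' The six inter-population projections of the basal ganglia circuit with
#' their maximal conductances, reversal potentials, sign, fan-in (number of
#' presynaptic partners per postsynaptic neuron), and first-order gating
#' kinetics (rise `alpha`, decay `beta`).
#'
#' @return a data.frame with one row per projection.
#' @export
synapse_params <- function() {
  pj <- cell_params()$synapses
  kin <- pj$kinetics
  rows <- lapply(pj$projections, function(p) {
    k <- kin[[p$sign]]
    data.frame(pre = p$pre, post = p$post, g = p$g, E = p$E, sign = p$sign,
               fanin = p$fanin, alpha = k$alpha, beta = k$beta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the network wiring
#'
#' Assigns presynaptic partners per the circuit's fan-in table: each GPe
#' receives 2 STN + 2 GPe, each GPi 2 STN + 2 GPe, each STN 2 GPe, each TH
#' 1 GPi. `mode = "structured"` uses the deterministic wrap-around rule
#' (postsynaptic neuron i takes presynaptic i and i+1, modulo n);
#' `mode = "random"` draws partners uniformly without replacement (seeded).
#' GPe-to-GPe self-connections are excluded in both modes.
#'
#' @param n_per_pop neurons per population (>= 3).
#' @param seed integer seed (used in random mode).
#' @param mode `"structured"` or `"random"`.
#' @return an object of class `bgdbs_topology`: a list of 1-based index
#'   matrices (`gpi2th`, `gpe2stn`, `stn2gpe`, `gpe2gpe`, `stn2gpi`,
#'   `gpe2gpi`), plus `n_per_pop`, `seed`, `mode`.
#' @export
build_topology <- function(n_per_pop, seed = 1L,
                           mode = c("structured", "random")) {
  mode <- match.arg(mode)
  n <- as.integer(n_per_pop)
  if (n < 3) {
    stop("n_per_pop must be >= 3: cannot pick 2 distinct presynaptic partners ",
         "excluding self-connections")
  }
  pair_structured <- function() cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))
  if (mode == "structured") {
    topo <- list(
      gpi2th = matrix(seq_len(n), ncol = 1),
      gpe2stn = pair_structured(),
      stn2gpe = pair_structured(),
      gpe2gpe = cbind(c(n, seq_len(n - 1)), c(seq_len(n - 1) + 1L, 1L)),
      stn2gpi = pair_structured(),
      gpe2gpi = pair_structured()
    )
  } else {
    rng <- local({
      set.seed(as.integer(seed))
      pick2 <- function(exclude = NULL) {
        t(vapply(seq_len(n), function(i) {
          pool <- if (is.null(exclude)) seq_len(n) else setdiff(seq_len(n), i)
          sample(pool, 2L)
        }, integer(2)))
      }
      list(
        gpi2th = matrix(sample(n, n, replace = TRUE), ncol = 1),
        gpe2stn = pick2(),
        stn2gpe = pick2(),
        gpe2gpe = pick2(exclude = "self"),
        stn2gpi = pick2(),
        gpe2gpi = pick2()
      )
    })
    topo <- rng
  }
  structure(c(topo, list(n_per_pop = n, seed = as.integer(seed), mode = mode)),
            class = "bgdbs_topology")
}

#' @export
print.bgdbs_topology <- function(x, ...) {
  cat(sprintf("bgdbs topology: %d neurons/population, %s wiring (seed %d)\n",
              x$n_per_pop, x$mode, x$seed))
  cat(sprintf("  edges: %d (fan-in 2+2 GPe, 2+2 GPi, 2 STN, 1 TH)\n",
              topology_edge_count(x)))
  invisible(x)
}

topology_edge_count <- function(topo) {
  sum(vapply(topo[c("gpi2th", "gpe2stn", "stn2gpe", "gpe2gpe", "stn2gpi",
                    "gpe2gpi")], length, integer(1)))
}

#' Synaptic current onto one neuron for one projection
#'
#' `I = g * sum(s) * (V_post - E_syn)`. The value enters the membrane
#' equation with a leading minus sign, so inhibitory projections
#' (`E_syn = -85` mV) hyperpolarize and excitatory ones (`E_syn = 0` mV)
#' depolarize for membrane potentials between the two reversals.
#'
#' @param params one row of [synapse_params()] (or a list with `g`, `E`,
#'   `fanin`).
#' @param s_values gating values of the postsynaptic neuron's presynaptic
#'   partners for this projection; length must equal the projection fan-in.
#' @param V_post postsynaptic membrane potential, mV.
#' @return current, uA/cm^2 (signed as written; negate when adding to dV/dt).
#' @export
synaptic_current <- function(params, s_values, V_post) {
  if (length(s_values) != params$fanin) {
    stop(sprintf("wiring error: projection %s->%s expects %d presynaptic partners, got %d",
                 params$pre, params$post, params$fanin, length(s_values)))
  }
  params$g * sum(s_values) * (V_post - params$E)
}

#' Advance a synaptic gating variable by one step
#'
#' First-order kinetics `ds/dt = alpha * H(V_pre) * (1 - s) - beta * s` with
#' spike-shaped activation `H(V) = 1/(1 + exp(-(V + 20)/2))`, advanced with
#' the exact exponential update for `V_pre` held constant over the step.
#'
#' @param s current gating value in `[0, 1]`.
#' @param V_pre presynaptic membrane potential over the step, mV.
#' @param dt step, ms (> 0).
#' @param type `"excitatory"` or `"inhibitory"` (selects `alpha`, `beta`).
#' @return updated gating value in `[0, 1]`.
#' @export
update_synapse <- function(s, V_pre, dt, type = c("excitatory", "inhibitory")) {
  type <- match.arg(type)
  stopifnot(dt > 0)
  k <- cell_params()$synapses$kinetics[[type]]
  H <- sigm((V_pre + 20) / 2)
  rate <- k$alpha * H + k$beta
  s_inf <- k$alpha * H / rate
  s_new <- s_inf + (s - s_inf) * exp(-rate * dt)
  pmin(pmax(s_new, 0), 1)
}

#' Export / import topology as JSON for exact re-runs
#'
#' @param topo a `bgdbs_topology`.
#' @param path file path.
#' @return `topology_to_json` returns `path` invisibly; `topology_from_json`
#'   returns the reconstructed `bgdbs_topology`.
#' @export
topology_to_json <- function(topo, path) {
  payload <- list(
    n_per_pop = topo$n_per_pop, seed = topo$seed, mode = topo$mode,
    projections = lapply(topo[c("gpi2th", "gpe2stn", "stn2gpe", "gpe2gpe",
                                "stn2gpi", "gpe2gpi")], function(m) {
      unname(apply(m, 1, function(r) as.integer(r), simplify = FALSE))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname topology_to_json
#' @export
topology_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- lapply(p$projections, function(rows) {
    if (is.list(rows)) rows <- do.call(rbind, rows)
    m <- matrix(as.integer(rows), nrow = p$n_per_pop)
    m
  })
  structure(c(topo, list(n_per_pop = as.integer(p$n_per_pop),
                         seed = as.integer(p$seed), mode = p$mode)),
            class = "bgdbs_topology")
}
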