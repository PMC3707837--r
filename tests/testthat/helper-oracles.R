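# Independent oracles used across the suite.

# Brute-force maximum bipartite matching by exhaustive assignment
# (equations choose a free adjacent variable or stay unmatched).
brute_max_matching <- function(adj, nv) {
  ne <- length(adj)
  best <- 0L
  used <- logical(nv)
  rec <- function(e, size) {
    remaining <- ne - e + 1L
    if (size + remaining <= best) return()
    if (e > ne) {
      if (size > best) best <<- size
      return()
    }
    for (v in adj[[e]]) {
      if (!used[v]) {
        used[v] <<- TRUE
        rec(e + 1L, size + 1L)
        used[v] <<- FALSE
      }
    }
    rec(e + 1L, size)
  }
  rec(1L, 0L)
  best
}

# random bipartite graph as an adjacency list (equations -> variables)
random_bipartite <- function(ne, nv, p = 0.4) {
  lapply(seq_len(ne), function(e) which(stats::runif(nv) < p))
}

# wrap an adjacency list in the package's bipartite graph structure
adj_as_graph <- function(adj, nv) {
  structure(list(eq_labels = paste0("e", seq_along(adj)),
                 eq_type = rep("algebraic", length(adj)),
                 eq_rule_index = seq_along(adj),
                 vars = paste0("v", seq_len(nv)),
                 adj = lapply(adj, function(x) sort(as.integer(x)))),
            class = "bipartite_graph")
}

# Random expression tree over the given symbols; 'pool' plants shared
# subtrees to exercise hash-consing.
random_tree <- function(depth, syms, pool = NULL) {
  if (depth <= 0 || stats::runif(1) < 0.25) {
    r <- stats::runif(1)
    if (!is.null(pool) && length(pool) > 0 && r < 0.3)
      return(pool[[sample.int(length(pool), 1)]])
    if (r < 0.6) return(ast_symbol(sample(syms, 1)))
    return(ast_number(round(stats::runif(1, -5, 5), 3)))
  }
  op <- sample(c("plus", "times", "minus", "divide", "power"), 1)
  a <- random_tree(depth - 1L, syms, pool)
  b <- random_tree(depth - 1L, syms, pool)
  if (op == "power") b <- ast_number(sample(0:3, 1))  # keep values finite
  if (op == "divide") b <- ast_op("plus", list(ast_op("times",
    list(b, b)), ast_number(1)))                      # denominator >= 1
  ast_op(op, list(a, b))
}

# Random mass-action reaction network; returns both the package model
# and an independent dense-matrix derivative oracle built from plain R
# arithmetic (no package evaluation involved).
random_mass_action <- function(n_species = NULL, n_reactions = NULL) {
  ns <- n_species %||% sample(2:6, 1)
  nr <- n_reactions %||% sample(1:8, 1)
  sp_ids <- paste0("X", seq_len(ns))
  boundary <- stats::runif(ns) < 0.15

  species <- list()
  amounts <- round(stats::runif(ns, 0.5, 4), 3)
  for (i in seq_len(ns))
    species[[sp_ids[i]]] <- list(
      id = sp_ids[i], compartment = "c", initial_value = amounts[i],
      initial_is_amount = TRUE, has_only_substance_units = TRUE,
      boundary_condition = boundary[i], constant = FALSE)

  reactions <- list()
  N <- matrix(0, ns, nr, dimnames = list(sp_ids, NULL))
  vel_funs <- list()
  for (j in seq_len(nr)) {
    nreac <- sample(seq_len(min(2L, ns - 1L)), 1)
    reac <- sample(sp_ids, nreac)
    rest <- setdiff(sp_ids, reac)
    prod <- sample(rest, sample(seq_len(min(2L, length(rest))), 1))
    stoich_r <- sample(1:2, length(reac), replace = TRUE)
    stoich_p <- sample(1:2, length(prod), replace = TRUE)
    k <- round(stats::runif(1, 0.1, 2), 3)

    kin <- ast_number(k)
    for (s in reac) kin <- ast_op("times", list(kin, ast_symbol(s)))
    mkref <- function(sp, st) list(species = sp, stoichiometry = st,
                                   stoich_math = NULL, stoich_id = NA)
    reactions[[j]] <- list(
      id = paste0("R", j), reversible = FALSE,
      reactants = Map(mkref, reac, stoich_r),
      products = Map(mkref, prod, stoich_p),
      modifiers = character(0), kinetic_law = kin,
      local_parameters = numeric(0))

    for (i in seq_along(reac))
      if (!boundary[match(reac[i], sp_ids)])
        N[reac[i], j] <- N[reac[i], j] - stoich_r[i]
    for (i in seq_along(prod))
      if (!boundary[match(prod[i], sp_ids)])
        N[prod[i], j] <- N[prod[i], j] + stoich_p[i]
    vel_funs[[j]] <- local({
      k0 <- k; rs <- reac
      function(Q) k0 * prod(Q[rs])
    })
  }

  model <- sbml_model(
    compartments = list(c = list(id = "c", size = 1,
                                 spatial_dimensions = 3,
                                 constant = TRUE)),
    species = species, reactions = reactions)
  oracle <- function(Q) {
    v <- vapply(vel_funs, function(f) f(Q), numeric(1))
    drop(N %*% v)
  }
  list(model = model, oracle = oracle, sp_ids = sp_ids,
       amounts = stats::setNames(amounts, sp_ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# method-of-steps DDE reference (independent of the package's
# integrator and history machinery)
dde_reference <- function(times, k, tau, y0) {
  if (requireNamespace("deSolve", quietly = TRUE)) {
    ref <- deSolve::dede(
      c(S = y0), times = times,
      func = function(t, y, p) {
        ylag <- if (t < tau) y0 else deSolve::lagvalue(t - tau)
        list(-k * ylag)
      }, atol = 1e-10, rtol = 1e-10)
    return(ref[, "S"])
  }
  # fallback: explicit method of steps with dense RK4 on a fine grid
  hh <- tau / 400
  grid <- seq(min(times), max(times) + hh, by = hh)
  ys <- numeric(length(grid))
  ys[1] <- y0
  lag <- function(t) {
    if (t <= grid[1] + tau) return(y0)
    stats::approx(grid, ys, xout = t - tau, rule = 2)$y
  }
  for (i in seq_len(length(grid) - 1L)) {
    t <- grid[i]; y <- ys[i]
    k1 <- -k * lag(t)
    k2 <- -k * lag(t + hh / 2)
    k3 <- k2
    k4 <- -k * lag(t + hh)
    ys[i + 1L] <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  stats::approx(grid, ys, xout = times, rule = 2)$y
}
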