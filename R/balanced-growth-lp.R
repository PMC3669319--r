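#' Build the fixed-fraction balanced-growth linear program
#'
#' Under balanced growth every species grows at the shared community rate
#' `mu` and every variable metabolite, intra- or extracellular, is at
#' steady state. With the biomass fractions `f` fixed, these balances are
#' linear: for every metabolite row,
#'
#' \deqn{\sum_j f_j \Big(\sum_l n_{ij,l}\, q_{l,j} + c_{ij}\, \mu\Big)
#'       + \sum_k b_{ik}\, \phi_k = 0,}
#'
#' where `q` are specific reaction fluxes, `c_j` the biomass composition of
#' species `j`, and `phi` the specific environmental exchange fluxes. Each
#' species' flux columns are scaled by its fraction `f_j`; exchange columns
#' are unscaled; the biomass columns of all species share the single
#' variable `mu`, which structurally enforces equal specific growth rates.
#' When `fixed_mu` is given (chemostat mode, `mu` pinned to the dilution
#' rate) the `mu` column is replaced by a constant and moves to the
#' right-hand side.
#'
#' @param cm A `community_model`.
#' @param f Named biomass-fraction vector on the simplex.
#' @param objective `"max_mu"`, or a flux objective
#'   `list(sense = "min"|"max", flux = <flux id>)`.
#' @param fixed_mu Optional fixed growth rate in h^-1; required for flux
#'   objectives.
#' @param extra_constraints Optional list of extra linear rows, each
#'   `list(terms = c(<flux id> = coef, ...), sense = "<="|">="|"=",
#'   rhs = <number>)`; flux ids as in [flux_ids()], `"mu"` allowed.
#' @return An `lp_spec` list (objective, equality system, bounds,
#'   inequality rows, variable/row bookkeeping).
#' @export
build_lp <- function(cm, f, objective = "max_mu", fixed_mu = NULL,
                     extra_constraints = NULL) {
  stopifnot(inherits(cm, "community_model"))
  f <- as_fraction_vector(f, cm)
  # Flux objectives normally come with fixed_mu (chemostat mode); the
  # flux-variability path instead leaves mu free and pins it from below
  # with an extra constraint, so both are accepted here.
  flux_obj <- is.list(objective)
  if (!flux_obj && !identical(objective, "max_mu")) {
    abort("objective must be \"max_mu\" or list(sense=, flux=)")
  }
  if (identical(objective, "max_mu") && is.null(fixed_mu)) {
    finite_q <- any(is.finite(cm$cols$ub[cm$cols$type == "q"])) ||
      any(is.finite(cm$cols$lb[cm$cols$type == "q"]) & cm$cols$lb[cm$cols$type == "q"] != 0)
    finite_phi <- any(is.finite(cm$exchanges$phi_lb)) || any(is.finite(cm$exchanges$phi_ub))
    if (!finite_q && !finite_phi) {
      abort(paste0("unbounded by construction: maximising mu with every flux bound ",
                   "infinite is ill-posed; impose a finite uptake bound"))
    }
  }

  qcols <- cm$cols[cm$cols$type == "q", , drop = FALSE]
  bcols <- cm$cols[cm$cols$type == "biomass", , drop = FALSE]
  pcols <- cm$cols[cm$cols$type == "phi", , drop = FALSE]
  fq <- f[qcols$species]
  Aq <- cm$C[, qcols$col, drop = FALSE] %*% Matrix::Diagonal(x = unname(fq))
  colnames(Aq) <- qcols$col
  mu_col <- cm$C[, bcols$col, drop = FALSE] %*% unname(f[bcols$species])
  Aphi <- cm$C[, pcols$col, drop = FALSE]

  free_mu <- is.null(fixed_mu)
  if (free_mu) {
    A <- cbind(Aq, mu = mu_col, Aphi)
    var_ids <- c(qcols$col, "mu", pcols$col)
    lb <- c(qcols$lb, 0, pcols$lb)
    ub <- c(qcols$ub, Inf, pcols$ub)
    b <- rep(0, nrow(A))
  } else {
    stopifnot(is.numeric(fixed_mu), length(fixed_mu) == 1, fixed_mu >= 0)
    A <- cbind(Aq, Aphi)
    var_ids <- c(qcols$col, pcols$col)
    lb <- c(qcols$lb, pcols$lb)
    ub <- c(qcols$ub, pcols$ub)
    b <- -as.vector(mu_col) * fixed_mu
  }
  A <- as.matrix(A)
  rownames(A) <- cm$rows$row
  colnames(A) <- var_ids

  obj <- stats::setNames(rep(0, length(var_ids)), var_ids)
  if (flux_obj) {
    if (!objective$flux %in% var_ids) {
      abort(sprintf("objective flux '%s' not in model (is it the biomass column?)", objective$flux))
    }
    obj[objective$flux] <- 1
    maximize <- identical(objective$sense, "max")
    if (!objective$sense %in% c("min", "max")) abort("objective sense must be 'min' or 'max'")
  } else {
    obj["mu"] <- 1
    maximize <- TRUE
  }

  A_ineq <- NULL; b_ineq <- numeric(0)
  if (!is.null(extra_constraints)) {
    rows <- list()
    for (ec in extra_constraints) {
      terms <- ec$terms
      sense <- ec$sense %||% "<="
      rhs <- ec$rhs %||% 0
      unknown <- setdiff(names(terms), c(var_ids, "mu"))
      if (length(unknown)) {
        abort(sprintf("extra constraint references unknown flux id(s): %s",
                      paste(unknown, collapse = ", ")))
      }
      row <- stats::setNames(rep(0, length(var_ids)), var_ids)
      for (id in names(terms)) {
        if (id == "mu" && !free_mu) {
          rhs <- rhs - terms[[id]] * fixed_mu
        } else {
          row[id] <- row[id] + terms[[id]]
        }
      }
      if (sense == "=") {
        A <- rbind(A, row); b <- c(b, rhs)
      } else if (sense == "<=") {
        rows[[length(rows) + 1]] <- row; b_ineq <- c(b_ineq, rhs)
      } else if (sense == ">=") {
        rows[[length(rows) + 1]] <- -row; b_ineq <- c(b_ineq, -rhs)
      } else abort("extra constraint sense must be '<=', '>=' or '='")
    }
    if (length(rows)) A_ineq <- do.call(rbind, rows)
  }

  structure(
    list(obj = obj, A = A, b = b, lb = lb, ub = ub,
         A_ineq = A_ineq, b_ineq = b_ineq,
         maximize = maximize, var_ids = var_ids,
         f = f, fixed_mu = fixed_mu,
         objective = if (flux_obj) objective else "max_mu",
         cm_cols = cm$cols, cm_exchanges = cm$exchanges),
    class = "lp_spec")
}

# Solve an lp_spec: append slack variables for inequality rows, call the
# simplex core, and repack the solution by variable id.
lp_solve <- function(spec, tol = 1e-9) {
  A <- spec$A; b <- spec$b; lb <- spec$lb; ub <- spec$ub; obj <- spec$obj
  n <- ncol(A)
  n_slack <- if (is.null(spec$A_ineq)) 0L else nrow(spec$A_ineq)
  if (n_slack > 0) {
    A <- rbind(A, spec$A_ineq)
    Aslack <- rbind(matrix(0, nrow(spec$A), n_slack), diag(n_slack))
    A <- cbind(A, Aslack)
    b <- c(b, spec$b_ineq)
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
    obj <- c(obj, rep(0, n_slack))
  }
  res <- simplex_solve(obj, A, b, lb, ub, maximize = spec$maximize, tol = tol)
  if (res$status %in% c("maxit", "singular", "solver_error")) {
    abort(sprintf("LP solver failure (%s); this is not an infeasibility", res$status))
  }
  x <- res$x[seq_len(n)]
  names(x) <- spec$var_ids
  # a solution resting on the internal big-bound stand-in means the true
  # problem is unbounded in that direction
  if (res$status == "optimal") {
    active_obj <- names(obj[seq_len(n)])[obj[seq_len(n)] != 0]
    hit_big <- any(abs(x[active_obj]) >= LP_BIG * (1 - 1e-9) &
                     !is.finite(ifelse(x[active_obj] > 0,
                                       ub[match(active_obj, spec$var_ids)],
                                       lb[match(active_obj, spec$var_ids)])))
    if (hit_big) res$status <- "unbounded"
  }
  list(status = res$status, x = x,
       objective = if (res$status == "optimal") res$objective else NA_real_,
       duals = if (res$status == "optimal") {
         stats::setNames(res$duals[seq_len(nrow(spec$A))], rownames(spec$A))
       } else NULL,
       reduced_costs = if (res$status == "optimal") {
         stats::setNames(res$reduced_costs[seq_len(n)], spec$var_ids)
       } else NULL)
}

# Package an LP result as a balanced_growth_solution, with residual and
# bound checks on optimal solutions.
make_solution <- function(cm, spec, res, check_tol = 1e-8) {
  status <- switch(res$status,
                   optimal = "optimal",
                   infeasible = "infeasible",
                   unbounded = "unbounded")
  if (status != "optimal") {
    out <- list(status = status, mu = NA_real_, objective_value = NA_real_,
                f = spec$f, fluxes = tibble(
                  flux = character(0), type = character(0),
                  species = character(0), reaction = character(0),
                  value = numeric(0), lb = numeric(0), ub = numeric(0)),
                duals = NULL, binding = NULL, objective = spec$objective,
                fixed_mu = spec$fixed_mu)
    class(out) <- "balanced_growth_solution"
    return(out)
  }
  x <- res$x
  mu <- if ("mu" %in% names(x)) unname(x[["mu"]]) else spec$fixed_mu
  resid <- as.vector(spec$A %*% x) - spec$b
  if (max(abs(resid)) > check_tol) {
    abort(sprintf("steady-state residual %.3g exceeds %.1g", max(abs(resid)), check_tol))
  }
  if (any(x < spec$lb - 1e-9) || any(x > spec$ub + 1e-9)) {
    abort("solution violates flux bounds beyond tolerance")
  }
  qcols <- spec$cm_cols[spec$cm_cols$type == "q", , drop = FALSE]
  fluxes <- bind_rows(
    tibble(flux = qcols$col, type = "q", species = qcols$species,
           reaction = qcols$reaction, value = unname(x[qcols$col]),
           lb = qcols$lb, ub = qcols$ub),
    tibble(flux = "mu", type = "mu", species = NA_character_,
           reaction = NA_character_, value = mu,
           lb = 0, ub = Inf),
    tibble(flux = spec$cm_exchanges$ex_id, type = "phi",
           species = NA_character_,
           reaction = spec$cm_exchanges$metabolite,
           value = unname(x[spec$cm_exchanges$ex_id]),
           lb = spec$cm_exchanges$phi_lb, ub = spec$cm_exchanges$phi_ub))
  btol <- 1e-7
  binding <- fluxes |>
    filter(is.finite(.data$lb) & abs(.data$value - .data$lb) < btol |
             is.finite(.data$ub) & abs(.data$value - .data$ub) < btol) |>
    mutate(side = ifelse(is.finite(.data$lb) & abs(.data$value - .data$lb) < btol,
                         "lower", "upper"),
           bound = ifelse(.data$side == "lower", .data$lb, .data$ub)) |>
    select("flux", "type", "side", "bound", "value")
  out <- list(status = "optimal", mu = mu,
              objective_value = res$objective,
              f = spec$f, fluxes = fluxes,
              duals = res$duals,
              reduced_costs = res$reduced_costs,
              binding = binding,
              objective = spec$objective,
              fixed_mu = spec$fixed_mu)
  class(out) <- "balanced_growth_solution"
  out
}

#' @export
print.balanced_growth_solution <- function(x, ...) {
  cat(sprintf("<balanced_growth_solution> status: %s\n", x$status))
  if (x$status == "optimal") {
    cat(sprintf("  mu = %.6g h^-1 | objective = %.6g | f = (%s)\n",
                x$mu, x$objective_value,
                paste(sprintf("%s=%.4g", names(x$f), x$f), collapse = ", ")))
    cat(sprintf("  %d fluxes, %d binding bound(s)\n", nrow(x$fluxes), nrow(x$binding)))
  }
  invisible(x)
}

#' Maximise the community growth rate at fixed biomass fractions
#'
#' Solves the balanced-growth LP for the maximal shared growth rate
#' `mu*(f)` at the given biomass-fraction vector. `"infeasible"` means no
#' balanced steady state exists at these fractions at any `mu >= 0` — a
#' different statement than `mu* = 0`, which is an optimal solution with
#' zero growth.
#'
#' @param cm A `community_model`.
#' @param f Named biomass-fraction vector.
#' @param extra_constraints See [build_lp()].
#' @return A `balanced_growth_solution`.
#' @examples
#' cm <- single_species_community(yield_coeff = 0.1, uptake_bound = 10)
#' maximize_growth_at_fractions(cm, c(m1 = 1))$mu  # 0.1 * 10 = 1 h^-1
#' @export
maximize_growth_at_fractions <- function(cm, f, extra_constraints = NULL) {
  spec <- build_lp(cm, f, objective = "max_mu", extra_constraints = extra_constraints)
  make_solution(cm, spec, lp_solve(spec))
}

#' Optimise a named flux at a fixed community growth rate
#'
#' Chemostat-style query: pin the community growth rate to `fixed_mu`
#' (e.g. the dilution rate) and minimise or maximise one flux — typically
#' minimising a substrate exchange to find the most efficient metabolic
#' strategy that sustains the imposed rate. Infeasible whenever
#' `fixed_mu > mu*(f)`.
#'
#' @param cm A `community_model`.
#' @param f Named biomass-fraction vector.
#' @param fixed_mu Growth rate to hold, h^-1.
#' @param flux_id Flux to optimise (see [flux_ids()]).
#' @param sense `"min"` or `"max"`.
#' @param extra_constraints See [build_lp()].
#' @return A `balanced_growth_solution` (its `objective_value` is the
#'   optimised flux).
#' @export
optimize_flux_at_growth <- function(cm, f, fixed_mu, flux_id, sense = "min",
                                    extra_constraints = NULL) {
  spec <- build_lp(cm, f, objective = list(sense = sense, flux = flux_id),
                   fixed_mu = fixed_mu, extra_constraints = extra_constraints)
  make_solution(cm, spec, lp_solve(spec))
}

#' Flux-variability ranges at (near-)optimal community growth
#'
#' Alternate optima are the rule in stoichiometric models: the incumbent
#' flux vector returned by one solver run is not unique. This reports, for
#' every flux, its minimum and maximum over all solutions whose growth rate
#' is within a relative tolerance of the optimum `mu*`, i.e. subject to
#' `mu >= (1 - rel_tol) * mu*`.
#'
#' @param cm A `community_model`.
#' @param f Named biomass-fraction vector.
#' @param rel_tol Relative slack on the optimum (default 0: ranges at the
#'   exact optimum, up to solver tolerance).
#' @param flux_ids Fluxes to range over; default all (including exchanges).
#' @param extra_constraints See [build_lp()].
#' @return Tibble with columns `flux`, `lo`, `hi`, `incumbent`.
#' @export
flux_ranges_at_optimum <- function(cm, f, rel_tol = 0, flux_ids = NULL,
                                   extra_constraints = NULL) {
  sol <- maximize_growth_at_fractions(cm, f, extra_constraints)
  if (sol$status != "optimal") {
    abort(sprintf("no optimum to range around: status %s", sol$status))
  }
  mu_star <- sol$mu
  all_ids <- sol$fluxes$flux
  flux_ids <- flux_ids %||% setdiff(all_ids, "mu")
  floor_mu <- (1 - rel_tol) * mu_star
  ec <- c(extra_constraints %||% list(),
          list(list(terms = c(mu = 1), sense = ">=", rhs = floor_mu)))
  incumbent <- stats::setNames(sol$fluxes$value, sol$fluxes$flux)
  out <- map(flux_ids, function(id) {
    sp_lo <- build_lp(cm, f, list(sense = "min", flux = id), extra_constraints = ec)
    lo <- make_solution(cm, sp_lo, lp_solve(sp_lo))
    sp_hi <- build_lp(cm, f, list(sense = "max", flux = id), extra_constraints = ec)
    hi <- make_solution(cm, sp_hi, lp_solve(sp_hi))
    tibble(flux = id,
           lo = if (lo$status == "optimal") lo$objective_value else NA_real_,
           hi = if (hi$status == "optimal") hi$objective_value else NA_real_,
           incumbent = unname(incumbent[id]))
  })
  bind_rows(out)
}

#' Export an LP specification as CPLEX-LP-format text
#'
#' Debugging aid: writes the fixed-fraction LP in the plain-text LP format
#' understood by most solvers, so a model can be inspected or solved
#' externally.
#'
#' @param spec An `lp_spec` from [build_lp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp_format <- function(spec, path) {
  term_str <- function(coefs, ids) {
    nz <- which(coefs != 0)
    if (!length(nz)) return("0")
    paste(sprintf("%+.12g %s", coefs[nz], ids[nz]), collapse = " ")
  }
  lines <- c(if (spec$maximize) "Maximize" else "Minimize",
             paste(" obj:", term_str(unname(spec$obj), spec$var_ids)),
             "Subject To")
  for (i in seq_len(nrow(spec$A))) {
    lines <- c(lines, sprintf(" %s: %s = %.12g",
                              make.names(rownames(spec$A)[i]),
                              term_str(spec$A[i, ], spec$var_ids), spec$b[i]))
  }
  if (!is.null(spec$A_ineq)) {
    for (i in seq_len(nrow(spec$A_ineq))) {
      lines <- c(lines, sprintf(" extra_%d: %s <= %.12g", i,
                                term_str(spec$A_ineq[i, ], spec$var_ids),
                                spec$b_ineq[i]))
    }
  }
  lines <- c(lines, "Bounds")
  for (j in seq_along(spec$var_ids)) {
    lines <- c(lines, sprintf(" %s <= %s <= %s",
                              format(spec$lb[j]), spec$var_ids[j], format(spec$ub[j])))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}
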