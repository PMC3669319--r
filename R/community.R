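#' Assemble a community model from species models
#'
#' Merges the stoichiometric matrices of the member species into the
#' community matrix `C`. Each species keeps a private namespace for its
#' intracellular metabolite rows (prefixed `species__metabolite`);
#' extracellular metabolites are global, and crossfed metabolites declared
#' in `crossfed_ids` share a single row across all species that transport
#' them. Every extracellular metabolite receives one environmental
#' exchange column (id `EX_<metabolite>`), written export-positive: the
#' column carries coefficient -1 on its metabolite row, so efflux to the
#' environment is a positive exchange flux and uptake is negative.
#'
#' Environmental exchange bounds are supplied in absolute units
#' (`J`, mmol h^-1) and converted to specific bounds
#' `phi = J / X_T` (mmol gDW^-1 h^-1) at assembly; this is the only place
#' the total biomass `X_T` enters the mathematics. Crossfed metabolites
#' without an explicit entry in `env_exchanges` get an overflow exchange
#' that is efflux-only by default (the community may dump, but not draw,
#' crossfed intermediates), as do unique extracellular products; uptake of
#' a nutrient therefore always requires an explicit `env_exchanges` entry
#' with a negative `J_lb`.
#'
#' @param species List of [species_model()] objects (order is preserved but
#'   immaterial to the optimisation results).
#' @param crossfed_ids Character vector of extracellular metabolite ids
#'   that are cross-fed (or competed for) between species.
#' @param env_exchanges Optional tibble with columns `metabolite_id`,
#'   `J_lb`, `J_ub` (absolute flux bounds, mmol h^-1) overriding the
#'   default overflow bounds for specific extracellular metabolites.
#' @param X_T Total community biomass in grams dry weight (default 1).
#' @param allow_crossfeed_supply If `TRUE`, overflow exchanges of crossfed
#'   metabolites also allow environmental supply (negative flux).
#' @param overflow_J_ub Absolute upper bound for default overflow
#'   exchanges, mmol h^-1 (default `1000 * X_T`).
#' @return An object of class `community_model`.
#' @export
assemble_community <- function(species, crossfed_ids,
                               env_exchanges = NULL,
                               X_T = 1,
                               allow_crossfeed_supply = FALSE,
                               overflow_J_ub = 1000 * X_T) {
  if (inherits(species, "species_model")) species <- list(species)
  stopifnot(length(species) >= 1, all(map_lgl(species, inherits, "species_model")))
  stopifnot(is.numeric(X_T), length(X_T) == 1, X_T > 0)
  sp_ids <- map_chr(species, "species_id")
  stop_if_duplicated(sp_ids, "species")
  names(species) <- sp_ids
  crossfed_ids <- as.character(crossfed_ids %||% character(0))

  # collect extracellular metabolites and check role consistency
  ext <- bind_rows(map(species, function(s) {
    m <- s$metabolites[s$metabolites$role != "intracellular", , drop = FALSE]
    m$species <- s$species_id
    m
  }))
  for (cf in crossfed_ids) {
    owners <- ext$species[ext$id == cf]
    if (length(owners) == 0) {
      abort(sprintf("crossfed metabolite '%s' is unknown to every species", cf))
    }
    bad <- ext$species[ext$id == cf & ext$role != "crossfed"]
    if (length(bad)) {
      abort(sprintf("metabolite '%s' is listed as crossfed but species %s declare(s) it '%s'",
                    cf, paste(bad, collapse = ", "),
                    paste(unique(ext$role[ext$id == cf & ext$role != "crossfed"]), collapse = "/")))
    }
  }
  declared_cf <- unique(ext$id[ext$role == "crossfed"])
  undeclared <- setdiff(declared_cf, crossfed_ids)
  if (length(undeclared)) {
    abort(sprintf("metabolite(s) declared crossfed by a species but missing from crossfed_ids: %s",
                  paste(undeclared, collapse = ", ")))
  }
  uniq <- ext[ext$role == "unique", , drop = FALSE]
  shared_unique <- unique(uniq$id[duplicated(uniq$id) | uniq$id %in% uniq$id[duplicated(uniq$id)]])
  shared_unique <- names(which(table(uniq$id) > 1))
  if (length(shared_unique)) {
    abort(sprintf(
      "extracellular metabolite(s) %s declared 'unique' by more than one species; declare them 'crossfed'",
      paste(shared_unique, collapse = ", ")))
  }

  ext_ids <- unique(ext$id)
  # exchange bound table
  env_exchanges <- if (is.null(env_exchanges)) {
    tibble(metabolite_id = character(0), J_lb = numeric(0), J_ub = numeric(0))
  } else as_tibble(env_exchanges)
  stop_if_duplicated(env_exchanges$metabolite_id, "env exchange")
  unknown_ex <- setdiff(env_exchanges$metabolite_id, ext_ids)
  if (length(unknown_ex)) {
    intr <- unlist(map(species, function(s) s$metabolites$id[s$metabolites$role == "intracellular"]))
    offender <- intersect(unknown_ex, intr)
    if (length(offender)) {
      abort(sprintf("env exchange references intracellular metabolite(s): %s",
                    paste(offender, collapse = ", ")))
    }
    abort(sprintf("env exchange references unknown metabolite(s): %s",
                  paste(unknown_ex, collapse = ", ")))
  }
  default_lb <- function(id) {
    if (id %in% crossfed_ids && allow_crossfeed_supply) -overflow_J_ub else 0
  }
  exch <- tibble(
    metabolite = ext_ids,
    ex_id = paste0("EX_", ext_ids),
    J_lb = map_dbl(ext_ids, function(id) {
      i <- match(id, env_exchanges$metabolite_id)
      if (!is.na(i)) env_exchanges$J_lb[i] else default_lb(id)
    }),
    J_ub = map_dbl(ext_ids, function(id) {
      i <- match(id, env_exchanges$metabolite_id)
      if (!is.na(i)) env_exchanges$J_ub[i] else overflow_J_ub
    }))
  if (any(exch$J_lb > exch$J_ub)) abort("exchange J_lb exceeds J_ub")
  exch$phi_lb <- exch$J_lb / X_T
  exch$phi_ub <- exch$J_ub / X_T

  # rows: per-species intracellular (namespaced), then global extracellular
  row_tbl <- bind_rows(
    bind_rows(map(species, function(s) {
      ids <- s$metabolites$id[s$metabolites$role == "intracellular"]
      tibble(row = paste0(s$species_id, "__", ids), scope = "intracellular",
             species = s$species_id, metabolite = ids)
    })),
    tibble(row = ext_ids, scope = "extracellular", species = NA_character_,
           metabolite = ext_ids))
  # columns: per-species fluxes, per-species biomass, exchanges
  col_tbl <- bind_rows(
    bind_rows(map(species, function(s) {
      r <- s$reactions[s$reactions$kind != "biomass", , drop = FALSE]
      tibble(col = paste0(s$species_id, ".", r$id), type = "q",
             species = s$species_id, reaction = r$id, kind = r$kind,
             lb = r$lb, ub = r$ub)
    })),
    {
      bm_ids <- map_chr(species, "biomass_id")
      tibble(col = paste0(sp_ids, ".", bm_ids),
             type = "biomass", species = sp_ids,
             reaction = bm_ids,
             kind = "biomass", lb = 0, ub = Inf)
    },
    tibble(col = exch$ex_id, type = "phi", species = NA_character_,
           reaction = NA_character_, kind = "exchange",
           lb = exch$phi_lb, ub = exch$phi_ub))

  row_index <- stats::setNames(seq_len(nrow(row_tbl)), row_tbl$row)
  col_index <- stats::setNames(seq_len(nrow(col_tbl)), col_tbl$col)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (s in species) {
    role_of <- stats::setNames(s$metabolites$role, s$metabolites$id)
    rowname_of <- function(ids) {
      ifelse(role_of[ids] == "intracellular", paste0(s$species_id, "__", ids), ids)
    }
    for (rid in names(s$stoich)) {
      st <- s$stoich[[rid]]
      colname <- paste0(s$species_id, ".", rid)
      ii <- c(ii, row_index[rowname_of(names(st))])
      jj <- c(jj, rep(col_index[[colname]], length(st)))
      vv <- c(vv, unname(st))
    }
  }
  for (k in seq_len(nrow(exch))) {
    ii <- c(ii, row_index[[exch$metabolite[k]]])
    jj <- c(jj, col_index[[exch$ex_id[k]]])
    vv <- c(vv, -1)  # export-positive convention
  }
  C <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nrow(row_tbl), nrow(col_tbl)),
                            dimnames = list(row_tbl$row, col_tbl$col))

  structure(
    list(species = species,
         species_ids = sp_ids,
         crossfed_ids = crossfed_ids,
         exchanges = exch,
         X_T = X_T,
         C = C,
         rows = row_tbl,
         cols = col_tbl),
    class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf("<community_model> %d species (%s), %d crossfed metabolite(s), X_T = %g gDW\n",
              length(x$species_ids), paste(x$species_ids, collapse = ", "),
              length(x$crossfed_ids), x$X_T))
  cat(sprintf("  community matrix C: %d metabolite rows x %d columns (%d flux, %d biomass, %d exchange)\n",
              nrow(x$C), ncol(x$C), sum(x$cols$type == "q"),
              sum(x$cols$type == "biomass"), sum(x$cols$type == "phi")))
  invisible(x)
}

#' Flux identifiers of a community model
#'
#' Fluxes are addressed as `"<species>.<reaction>"` for specific reaction
#' fluxes and `"EX_<metabolite>"` for environmental exchange fluxes; the
#' shared growth rate is `"mu"`.
#'
#' @param cm A `community_model`.
#' @return Character vector of valid flux ids.
#' @export
flux_ids <- function(cm) {
  stopifnot(inherits(cm, "community_model"))
  c(cm$cols$col[cm$cols$type == "q"], "mu", cm$exchanges$ex_id)
}

#' Set bounds of a flux in a community model
#'
#' Returns a modified copy of the community model with new bounds for a
#' reaction flux (`"<species>.<reaction>"`, specific units) or an exchange
#' flux (`"EX_<metabolite>"`, also specific units, i.e. already divided by
#' `X_T`). Used by phase-plane scans and the cross-feeding screen.
#'
#' @param cm A `community_model`.
#' @param flux_id Flux identifier (see [flux_ids()]).
#' @param lb,ub New lower/upper bound; `NULL` leaves the bound unchanged.
#' @return The modified `community_model`.
#' @export
set_flux_bound <- function(cm, flux_id, lb = NULL, ub = NULL) {
  stopifnot(inherits(cm, "community_model"))
  iq <- match(flux_id, cm$cols$col)
  if (!is.na(iq) && cm$cols$type[iq] == "q") {
    if (!is.null(lb)) cm$cols$lb[iq] <- lb
    if (!is.null(ub)) cm$cols$ub[iq] <- ub
    if (cm$cols$lb[iq] > cm$cols$ub[iq]) abort("lb exceeds ub")
    return(cm)
  }
  ie <- match(flux_id, cm$exchanges$ex_id)
  if (!is.na(ie)) {
    if (!is.null(lb)) {
      cm$exchanges$phi_lb[ie] <- lb
      cm$exchanges$J_lb[ie] <- lb * cm$X_T
    }
    if (!is.null(ub)) {
      cm$exchanges$phi_ub[ie] <- ub
      cm$exchanges$J_ub[ie] <- ub * cm$X_T
    }
    if (cm$exchanges$phi_lb[ie] > cm$exchanges$phi_ub[ie]) abort("lb exceeds ub")
    ic <- match(flux_id, cm$cols$col)
    cm$cols$lb[ic] <- cm$exchanges$phi_lb[ie]
    cm$cols$ub[ic] <- cm$exchanges$phi_ub[ie]
    return(cm)
  }
  abort(sprintf("unknown flux id '%s'", flux_id))
}

get_flux_bounds <- function(cm, flux_id) {
  iq <- match(flux_id, cm$cols$col)
  if (is.na(iq)) abort(sprintf("unknown flux id '%s'", flux_id))
  c(lb = cm$cols$lb[iq], ub = cm$cols$ub[iq])
}

#' Validate a community model
#'
#' Report-based checks: dead-end crossfed metabolites (produced but with no
#' consumer and no exchange able to absorb them), elemental and charge
#' imbalances for reactions whose participants all carry formulas, and
#' bound inconsistencies. Exchange columns and biomass reactions are exempt
#' from balance checks (biomass is measured in grams, not moles).
#'
#' @param cm A `community_model`.
#' @return A tibble of class `validation_report` with columns `check`,
#'   `item`, `severity`, `message`; attribute `ok` is `TRUE` when no
#'   error-severity finding exists (see [community_ok()]).
#' @export
validate_community <- function(cm) {
  stopifnot(inherits(cm, "community_model"))
  findings <- list()
  add <- function(check, item, severity, message) {
    findings[[length(findings) + 1]] <<- tibble(
      check = check, item = item, severity = severity, message = message)
  }

  # dead-end crossfed metabolites
  for (cf in cm$crossfed_ids) {
    produced <- FALSE; consumed <- FALSE
    for (s in cm$species) {
      tr <- s$reactions$id[s$reactions$kind == "crossfeed_transport"]
      for (rid in tr) {
        st <- s$stoich[[rid]]
        if (!cf %in% names(st)) next
        coef <- st[[cf]]
        lbub <- s$reactions[s$reactions$id == rid, c("lb", "ub")]
        # production possible if coef*flux can be > 0 within bounds
        if ((coef > 0 && lbub$ub > 0) || (coef < 0 && lbub$lb < 0)) produced <- TRUE
        if ((coef < 0 && lbub$ub > 0) || (coef > 0 && lbub$lb < 0)) consumed <- TRUE
      }
    }
    ex <- cm$exchanges[cm$exchanges$metabolite == cf, ]
    can_exit <- nrow(ex) > 0 && ex$phi_ub[1] > 0
    if (produced && !consumed && !can_exit) {
      add("dead_end", cf, "error",
          sprintf("crossfed metabolite '%s' can be produced but has no consumer and no exchange outlet", cf))
    }
    if (!produced) {
      add("dead_end", cf, "warning",
          sprintf("crossfed metabolite '%s' has no producing transport", cf))
    }
  }

  # elemental/charge balance where formulas are available
  for (s in cm$species) {
    formula_of <- stats::setNames(s$metabolites$formula, s$metabolites$id)
    charge_of <- stats::setNames(s$metabolites$charge, s$metabolites$id)
    for (rid in names(s$stoich)) {
      kind <- s$reactions$kind[s$reactions$id == rid]
      if (kind == "biomass") next
      st <- s$stoich[[rid]]
      fl <- map(names(st), function(id) parse_formula(formula_of[[id]]))
      if (any(map_lgl(fl, is.null))) next  # incomplete formula info: skip
      bal <- list()
      for (k in seq_along(st)) {
        for (el in names(fl[[k]])) {
          bal[[el]] <- (bal[[el]] %||% 0) + st[[k]] * fl[[k]][[el]]
        }
      }
      imb <- names(bal)[map_lgl(bal, function(v) abs(v) > 1e-9)]
      if (length(imb)) {
        add("elemental_balance", paste0(s$species_id, ".", rid), "error",
            sprintf("reaction '%s' unbalanced for element(s): %s (%s)", rid,
                    paste(imb, collapse = ", "),
                    paste(sprintf("%s: %+g", imb, unlist(bal[imb])), collapse = "; ")))
      }
      ch <- charge_of[names(st)]
      if (!any(is.na(ch))) {
        net <- sum(st * ch)
        if (abs(net) > 1e-9) {
          add("charge_balance", paste0(s$species_id, ".", rid), "error",
              sprintf("reaction '%s' has net charge %+g", rid, net))
        }
      }
    }
  }

  # bound sanity
  bad <- cm$cols[cm$cols$lb > cm$cols$ub, , drop = FALSE]
  for (i in seq_len(nrow(bad))) {
    add("bounds", bad$col[i], "error", "lower bound exceeds upper bound")
  }
  report <- if (length(findings)) bind_rows(findings) else
    tibble(check = character(0), item = character(0),
           severity = character(0), message = character(0))
  attr(report, "ok") <- !any(report$severity == "error")
  class(report) <- c("validation_report", class(report))
  report
}

#' Is a community model valid?
#'
#' @param report A `validation_report` from [validate_community()].
#' @return Logical scalar.
#' @export
community_ok <- function(report) isTRUE(attr(report, "ok"))

# Validate and normalise a biomass-fraction vector against a community.
# Fractions must be named after the species, non-negative, and sum to one.
as_fraction_vector <- function(f, cm) {
  sp <- cm$species_ids
  if (is.null(names(f))) {
    if (length(f) != length(sp)) abort("unnamed fraction vector of wrong length")
    names(f) <- sp
  }
  missing <- setdiff(sp, names(f))
  if (length(missing)) abort(sprintf("fractions missing for species: %s", paste(missing, collapse = ", ")))
  f <- f[sp]
  if (any(f < -1e-12)) abort("biomass fractions must be non-negative")
  f <- pmax(f, 0)
  if (abs(sum(f) - 1) > 1e-9) abort(sprintf("biomass fractions must sum to 1 (got %.12g)", sum(f)))
  f / sum(f)
}
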