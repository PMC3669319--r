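#' Build a single-species stoichiometric model
#'
#' A species model is the unit from which communities are assembled. It
#' holds the species' metabolites, reactions, the sparse stoichiometric
#' matrix `N` (rows = metabolites, columns = non-biomass reactions) and the
#' biomass composition vector `c` (mmol of each metabolite consumed or
#' produced per gram dry weight of new biomass; consumption is negative).
#'
#' Metabolites are classified by `role`:
#' * `"intracellular"` — lives inside this species; balanced per gram of
#'   this species' biomass.
#' * `"crossfed"` — extracellular, shared with (produced/consumed by)
#'   other community members; merged across species on assembly.
#' * `"unique"` — extracellular but touched by this species only
#'   (e.g. a substrate nobody else uses, or a waste product).
#'
#' Reactions are classified by `kind`:
#' * `"intracellular"` — touches intracellular metabolites only.
#' * `"crossfeed_transport"` — moves a crossfed metabolite across the
#'   membrane; must touch at least one intracellular and one crossfed
#'   metabolite.
#' * `"unique_transport"` — as above but for unique extracellular
#'   metabolites.
#' * `"biomass"` — exactly one per species; its stoichiometry is the
#'   biomass composition `c` and its rate is the (shared) specific growth
#'   rate, so it never appears as an ordinary flux column.
#'
#' All specific fluxes are in mmol per gram dry weight per hour
#' (mmol gDW^-1 h^-1); growth rates are in h^-1.
#'
#' @param species_id Character scalar identifying the species.
#' @param metabolites Tibble/data frame with columns `id`, `role`
#'   (`"intracellular"`, `"crossfed"`, `"unique"`) and optionally `name`,
#'   `formula` (e.g. `"C6H12O6"`), `charge`.
#' @param reactions Tibble/data frame with columns `id`, `kind`,
#'   `equation` (e.g. `"1 G + 2 ATP -> 1 B"`, substrates left), `lb`, `ub`
#'   (specific-flux bounds; `lb < 0` marks the reaction reversible).
#' @return An object of class `species_model`.
#' @examples
#' mets <- tibble::tibble(
#'   id = c("S_x", "P", "B"),
#'   role = c("unique", "intracellular", "intracellular"))
#' rxns <- tibble::tibble(
#'   id = c("t_S", "conv", "growth"),
#'   kind = c("unique_transport", "intracellular", "biomass"),
#'   equation = c("S_x -> P", "P -> B", "1 B ->"),
#'   lb = 0, ub = c(10, 1000, 1000))
#' species_model("m1", mets, rxns)
#' @export
species_model <- function(species_id, metabolites, reactions) {
  stopifnot(is.character(species_id), length(species_id) == 1, nzchar(species_id))
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  for (col in c("id", "role")) {
    if (!col %in% names(metabolites)) abort(sprintf("metabolites lack column '%s'", col))
  }
  for (col in c("id", "kind", "equation", "lb", "ub")) {
    if (!col %in% names(reactions)) abort(sprintf("reactions lack column '%s'", col))
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"charge" %in% names(metabolites)) metabolites$charge <- NA_real_
  metabolites <- metabolites[, c("id", "name", "role", "formula", "charge")]

  stop_if_duplicated(metabolites$id, "metabolite")
  stop_if_duplicated(reactions$id, "reaction")
  bad_role <- setdiff(metabolites$role, c("intracellular", "crossfed", "unique"))
  if (length(bad_role)) abort(sprintf("unknown metabolite role(s): %s", paste(bad_role, collapse = ", ")))
  bad_kind <- setdiff(reactions$kind,
                      c("intracellular", "crossfeed_transport", "unique_transport", "biomass"))
  if (length(bad_kind)) abort(sprintf("unknown reaction kind(s): %s", paste(bad_kind, collapse = ", ")))
  if (sum(reactions$kind == "biomass") != 1) {
    abort(sprintf("species '%s' must have exactly one biomass reaction", species_id))
  }
  if (any(reactions$lb > reactions$ub)) {
    bad <- reactions$id[reactions$lb > reactions$ub]
    abort(sprintf("lower bound exceeds upper bound for reaction(s): %s", paste(bad, collapse = ", ")))
  }

  stoich <- map(reactions$equation, parse_equation)
  names(stoich) <- reactions$id
  unknown <- setdiff(unique(unlist(map(stoich, names))), metabolites$id)
  if (length(unknown)) {
    abort(sprintf("species '%s': equation references unknown metabolite(s): %s",
                  species_id, paste(unknown, collapse = ", ")))
  }

  role_of <- stats::setNames(metabolites$role, metabolites$id)
  for (i in seq_len(nrow(reactions))) {
    ids <- names(stoich[[i]])
    roles <- role_of[ids]
    kind <- reactions$kind[i]
    rid <- reactions$id[i]
    if (kind == "intracellular" && any(roles != "intracellular")) {
      abort(sprintf("intracellular reaction '%s' touches extracellular metabolite(s)", rid))
    }
    if (kind == "biomass" && any(roles != "intracellular")) {
      abort(sprintf("biomass reaction '%s' may only consume/produce intracellular metabolites", rid))
    }
    if (kind == "crossfeed_transport" &&
        (!any(roles == "crossfed") || !any(roles == "intracellular"))) {
      abort(sprintf(
        "crossfeed transport '%s' must touch >=1 intracellular and >=1 crossfed metabolite", rid))
    }
    if (kind == "unique_transport" &&
        (!any(roles == "unique") || !any(roles == "intracellular"))) {
      abort(sprintf(
        "unique transport '%s' must touch >=1 intracellular and >=1 unique metabolite", rid))
    }
  }

  biomass_id <- reactions$id[reactions$kind == "biomass"]
  flux_rxns <- reactions[reactions$kind != "biomass", , drop = FALSE]
  n_met <- nrow(metabolites)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  met_index <- stats::setNames(seq_len(n_met), metabolites$id)
  for (j in seq_len(nrow(flux_rxns))) {
    s <- stoich[[flux_rxns$id[j]]]
    ii <- c(ii, met_index[names(s)])
    jj <- c(jj, rep(j, length(s)))
    vv <- c(vv, unname(s))
  }
  N <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_met, nrow(flux_rxns)),
                            dimnames = list(metabolites$id, flux_rxns$id))
  cvec <- stats::setNames(rep(0, n_met), metabolites$id)
  bm <- stoich[[biomass_id]]
  cvec[names(bm)] <- bm

  structure(
    list(species_id = species_id,
         metabolites = metabolites,
         reactions = mutate(reactions, reversible = .data$lb < 0),
         stoich = stoich,
         N = N,
         c = cvec,
         biomass_id = biomass_id),
    class = "species_model")
}

#' @export
print.species_model <- function(x, ...) {
  cat(sprintf("<species_model> %s: %d metabolites (%d intracellular), %d reactions (+1 biomass)\n",
              x$species_id, nrow(x$metabolites),
              sum(x$metabolites$role == "intracellular"),
              ncol(x$N)))
  invisible(x)
}

#' Partition a species stoichiometric matrix into its modular blocks
#'
#' Rearranges rows and columns of the species matrix `N` into the canonical
#' block layout used for community assembly: intracellular metabolite rows
#' on top, then crossfed, then unique extracellular rows; intracellular
#' reaction columns first, then crossfeed transports, then unique
#' transports. Off-pattern blocks (e.g. an intracellular reaction hitting a
#' crossfed row) are structurally zero, which the species-model constructor
#' enforces; the permutations are returned so the original matrix can be
#' reconstructed exactly.
#'
#' @param sm A `species_model`.
#' @return A list of class `partitioned_matrix` with the six informative
#'   sub-blocks (`N_II`, `N_IC`, `N_IT`, `N_CC`, `N_UU`), the row/column
#'   permutations, and the permuted full matrix `N_perm`.
#' @export
partition_species_matrix <- function(sm) {
  stopifnot(inherits(sm, "species_model"))
  touched <- Matrix::colSums(abs(sm$N)) > 0
  if (any(!touched)) {
    abort(sprintf("reaction(s) with empty stoichiometry: %s",
                  paste(colnames(sm$N)[!touched], collapse = ", ")))
  }
  role <- sm$metabolites$role
  kind <- sm$reactions$kind[match(colnames(sm$N), sm$reactions$id)]
  row_order <- c(which(role == "intracellular"), which(role == "crossfed"),
                 which(role == "unique"))
  col_order <- c(which(kind == "intracellular"), which(kind == "crossfeed_transport"),
                 which(kind == "unique_transport"))
  Np <- sm$N[row_order, col_order, drop = FALSE]
  ri <- seq_len(sum(role == "intracellular"))
  rc <- sum(role == "intracellular") + seq_len(sum(role == "crossfed"))
  ru <- sum(role %in% c("intracellular", "crossfed")) + seq_len(sum(role == "unique"))
  ci <- seq_len(sum(kind == "intracellular"))
  cc <- sum(kind == "intracellular") + seq_len(sum(kind == "crossfeed_transport"))
  cu <- sum(kind %in% c("intracellular", "crossfeed_transport")) +
    seq_len(sum(kind == "unique_transport"))
  structure(
    list(N_II = Np[ri, ci, drop = FALSE],   # intracellular x intracellular
         N_IC = Np[ri, cc, drop = FALSE],   # intracellular rows of crossfeed transports
         N_IT = Np[ri, cu, drop = FALSE],   # intracellular rows of unique transports
         N_CC = Np[rc, cc, drop = FALSE],   # crossfed rows of crossfeed transports
         N_UU = Np[ru, cu, drop = FALSE],   # unique extracellular rows of unique transports
         row_order = row_order,
         col_order = col_order,
         N_perm = Np,
         species_id = sm$species_id),
    class = "partitioned_matrix")
}

#' Undo a species-matrix partition
#'
#' Inverse of [partition_species_matrix()]: restores the original row and
#' column order of the full permuted matrix.
#'
#' @param pm A `partitioned_matrix`.
#' @return The species matrix `N` in its original order.
#' @export
unpartition_matrix <- function(pm) {
  stopifnot(inherits(pm, "partitioned_matrix"))
  N <- pm$N_perm
  N[order(pm$row_order), order(pm$col_order), drop = FALSE]
}
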